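#' Localize one input against a node network
#'
#' The full estimation step for one tag and time window: apply the node
#' filter, convert each retained node's mean RSS to an estimated distance by
#' inverting the decay model, drop non-informative readings (those at or
#' below the decay asymptote, whose inverted distance is the sentinel), seed
#' the optimizer at the strongest retained node, and trilaterate.
#'
#' Too few usable nodes is an expected outcome, not an error: the returned
#' estimate carries status `"too_few_nodes"` and no coordinates.
#'
#' @param input A `"localization_input"`.
#' @param network A `"node_network"`.
#' @param model A fitted `"rss_decay"` model.
#' @param filter A `"node_filter"` (default `no_filter()`).
#' @param guard_db Asymptote guard passed to [invert_distance()].
#' @param tol,max_iter Gauss-Newton controls passed to [trilaterate()].
#' @return A `"location_estimate"`; `nodes_used` lists the nodes that
#'   entered the trilateration with their estimated distances.
#' @examples
#' nw <- make_network(100, 300)
#' m <- decay_model(47.23, 0.005, -105.16)
#' truth <- c(120, 160)
#' d <- sqrt((nw$nodes$x - truth[1])^2 + (nw$nodes$y - truth[2])^2)
#' inp <- localization_input(data.frame(node_id = nw$nodes$node_id,
#'                                      mean_rss = predict(m, d)))
#' localize(inp, nw, m)
#' @export
localize <- function(input, network, model, filter = no_filter(),
                     guard_db = 0.5, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(input, "localization_input"),
            inherits(network, "node_network"),
            inherits(model, "rss_decay"))
  if (nrow(input) == 0L) return(.no_estimate("too_few_nodes"))
  kept <- apply_filter(input, network, filter)
  if (nrow(kept) < 3L) return(.no_estimate("too_few_nodes"))

  d <- invert_distance(model, kept$mean_rss, guard_db = guard_db,
                       max_distance = Inf)
  use <- is.finite(d)
  if (sum(use) < 3L) return(.no_estimate("too_few_nodes"))
  kept <- kept[use, , drop = FALSE]
  d <- d[use]

  idx <- match(kept$node_id, network$nodes$node_id)
  if (anyNA(idx))
    stop("detected node(s) absent from the network table: ",
         paste(kept$node_id[is.na(idx)], collapse = ", "), call. = FALSE)
  nx <- network$nodes$x[idx]; ny <- network$nodes$y[idx]
  strongest <- .anchor_index(kept)
  trilaterate(nx, ny, d, start = c(nx[strongest], ny[strongest]),
              node_id = as.character(kept$node_id),
              tol = tol, max_iter = max_iter)
}

#' Localize every window of a detection log
#'
#' Convenience wrapper: slices the log with [window_detections()] and
#' localizes each window.
#'
#' @param detections Data frame from [read_detections()].
#' @param network,model,filter,guard_db Passed to [localize()].
#' @param window_s,stride_s Passed to [window_detections()].
#' @return A data frame with one row per tag window: `tag_id`,
#'   `window_start`, `x`, `y`, `n_nodes`, `status`, `residual_norm`.
#' @export
localize_log <- function(detections, network, model, filter = no_filter(),
                         window_s = 60, stride_s = 60, guard_db = 0.5) {
  inputs <- window_detections(detections, window_s, stride_s)
  rows <- lapply(inputs, function(inp) {
    est <- localize(inp, network, model, filter, guard_db = guard_db)
    data.frame(tag_id = attr(inp, "tag_id"),
               window_start = format(attr(inp, "window_start"),
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               x = est$x, y = est$y,
               n_nodes = nrow(est$nodes_used),
               status = est$status,
               residual_norm = est$residual_norm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tag_id = character(), window_start = character(),
                      x = numeric(), y = numeric(), n_nodes = integer(),
                      status = character(), residual_norm = numeric())
  out
}
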