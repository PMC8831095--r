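#' Node-selection filters
#'
#' Filters choose which detecting nodes feed the trilateration.  Distant
#' nodes report RSS values near the noise floor that correlate poorly with
#' distance; excluding them concentrates the estimate on the neighbourhood
#' of the transmitter.
#'
#' * `no_filter()` keeps every detecting node.
#' * `rss_filter(cutoff_db)` keeps nodes whose mean RSS is strictly greater
#'   than the cutoff (a reading exactly at the cutoff is excluded).
#' * `distance_filter(multiplier)` keeps nodes within
#'   `multiplier * avg_spacing_m` of the node with the strongest mean RSS
#'   (the anchor, always retained).  An absolute `radius_m` can be given
#'   instead of a multiplier, e.g. to replicate published radii exactly.
#'
#' @param cutoff_db RSS cutoff, dB, in `[-120, -30]`.
#' @param multiplier Positive multiple of the network's average spacing.
#' @param radius_m Absolute retention radius, metres (alternative to
#'   `multiplier`).
#' @param label Optional label used in result tables; a default is derived
#'   from the parameters.
#' @return An object of class `"node_filter"`.
#' @examples
#' rss_filter(-90)
#' distance_filter(1.25)
#' distance_filter(radius_m = 315)
#' @name filters
NULL

#' @rdname filters
#' @export
no_filter <- function(label = "none") {
  structure(list(kind = "none", label = label), class = "node_filter")
}

#' @rdname filters
#' @export
rss_filter <- function(cutoff_db, label = NULL) {
  if (!is.finite(cutoff_db) || cutoff_db < -120 || cutoff_db > -30)
    stop("RSS cutoff must lie in [-120, -30] dB", call. = FALSE)
  if (is.null(label)) label <- sprintf("rss %g dB", cutoff_db)
  structure(list(kind = "rss", cutoff_db = cutoff_db, label = label),
            class = "node_filter")
}

#' @rdname filters
#' @export
distance_filter <- function(multiplier = NULL, radius_m = NULL, label = NULL) {
  if (is.null(multiplier) && is.null(radius_m))
    stop("supply 'multiplier' or 'radius_m'", call. = FALSE)
  if (!is.null(multiplier) && (!is.finite(multiplier) || multiplier <= 0))
    stop("'multiplier' must be positive", call. = FALSE)
  if (!is.null(radius_m) && (!is.finite(radius_m) || radius_m <= 0))
    stop("'radius_m' must be positive", call. = FALSE)
  if (is.null(label)) {
    label <- if (!is.null(radius_m)) sprintf("dist %g m", radius_m)
             else sprintf("dist %gx", multiplier)
  }
  structure(list(kind = "distance", multiplier = multiplier,
                 radius_m = radius_m, label = label),
            class = "node_filter")
}

#' @export
print.node_filter <- function(x, ...) {
  cat("Node filter:", x$label, "\n")
  invisible(x)
}

#' Resolve a filter's retention radius for a network
#'
#' @param filter A `"node_filter"` of kind `distance`.
#' @param network A `"node_network"` supplying `avg_spacing_m`.
#' @return The retention radius in metres.
#' @export
resolve_radius <- function(filter, network) {
  stopifnot(inherits(filter, "node_filter"), filter$kind == "distance")
  if (!is.null(filter$radius_m)) return(filter$radius_m)
  filter$multiplier * network$avg_spacing_m
}

#' Apply an RSS filter to a localization input
#'
#' Retains nodes whose mean RSS is strictly greater than the cutoff.  The
#' original input is not modified.
#'
#' @param input A `"localization_input"`.
#' @param cutoff_db RSS cutoff, dB.
#' @return A filtered `"localization_input"`.
#' @export
apply_rss_filter <- function(input, cutoff_db) {
  keep <- input$mean_rss > cutoff_db
  localization_input(as.data.frame(input)[keep, , drop = FALSE],
                     tag_id = attr(input, "tag_id"),
                     window_start = attr(input, "window_start"),
                     window_end = attr(input, "window_end"))
}

#' Apply a distance filter to a localization input
#'
#' Identifies the anchor node -- the detected node with the strongest mean
#' RSS, ties broken deterministically by smallest `node_id` -- and retains
#' all detected nodes within the retention radius of the anchor (the anchor
#' itself always survives).
#'
#' @param input A non-empty `"localization_input"`.
#' @param network The `"node_network"` providing node coordinates.
#' @param filter A `"node_filter"` of kind `distance`, or a numeric radius
#'   in metres.
#' @return A filtered `"localization_input"`.
#' @export
apply_distance_filter <- function(input, network, filter) {
  if (nrow(input) == 0L)
    stop("distance filter needs a non-empty input", call. = FALSE)
  radius <- if (is.numeric(filter)) filter else resolve_radius(filter, network)
  nodes <- network$nodes
  idx <- match(input$node_id, nodes$node_id)
  if (anyNA(idx))
    stop("detected node(s) absent from the network table: ",
         paste(input$node_id[is.na(idx)], collapse = ", "), call. = FALSE)
  anchor <- .anchor_index(input)
  ax <- nodes$x[idx[anchor]]; ay <- nodes$y[idx[anchor]]
  d <- sqrt((nodes$x[idx] - ax)^2 + (nodes$y[idx] - ay)^2)
  keep <- d <= radius
  keep[anchor] <- TRUE
  localization_input(as.data.frame(input)[keep, , drop = FALSE],
                     tag_id = attr(input, "tag_id"),
                     window_start = attr(input, "window_start"),
                     window_end = attr(input, "window_end"))
}

# Strongest mean RSS; ties broken by smallest node_id for reproducibility.
.anchor_index <- function(input) {
  best <- which(input$mean_rss == max(input$mean_rss))
  if (length(best) > 1L) best <- best[order(as.character(input$node_id[best]))[1L]]
  best
}

#' Apply any node filter
#'
#' Dispatches on the filter kind; `no_filter()` returns the input unchanged.
#'
#' @inheritParams apply_distance_filter
#' @return A (possibly) filtered `"localization_input"`.
#' @export
apply_filter <- function(input, network, filter) {
  stopifnot(inherits(filter, "node_filter"))
  switch(filter$kind,
         none = input,
         rss = apply_rss_filter(input, filter$cutoff_db),
         distance = apply_distance_filter(input, network, filter))
}
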