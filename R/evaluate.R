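#' Localization error
#'
#' Euclidean distance between the true location and an estimate; `NA` when
#' the estimate has no coordinates (it then contributes to location loss,
#' not to error statistics).
#'
#' @param true_xy Numeric `c(x, y)` or a two-column matrix/data frame.
#' @param estimate A `"location_estimate"`, or numeric `c(x, y)`.
#' @return Error in metres, or `NA`.
#' @examples
#' localization_error(c(0, 0), c(3, 4))  # 5
#' @export
localization_error <- function(true_xy, estimate) {
  if (inherits(estimate, "location_estimate")) {
    if (estimate$status != "ok") return(NA_real_)
    estimate <- c(estimate$x, estimate$y)
  }
  true_xy <- as.numeric(true_xy)
  estimate <- as.numeric(estimate)
  sqrt(sum((true_xy - estimate)^2))
}

#' Distance to the nearest network edge
#'
#' Minimum perpendicular distance from a point to the four sides of the
#' network bounding box; points outside the box are at distance 0.
#'
#' @param xy Numeric `c(x, y)`, or a matrix/data frame with columns `x`, `y`.
#' @param extent A `"node_network"`, or a vector
#'   `c(xmin, xmax, ymin, ymax)`.
#' @return Numeric vector of edge distances, metres.
#' @examples
#' edge_distance(c(625, 625), c(0, 1250, 0, 1250))  # centre: 625
#' @export
edge_distance <- function(xy, extent) {
  if (inherits(extent, "node_network")) extent <- extent$extent
  extent <- unname(as.numeric(extent))
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent", call. = FALSE)
  if (is.null(dim(xy))) xy <- matrix(as.numeric(xy), ncol = 2)
  x <- if (is.data.frame(xy)) xy$x else xy[, 1]
  y <- if (is.data.frame(xy)) xy$y else xy[, 2]
  d <- pmin(x - extent[1], extent[2] - x, y - extent[3], extent[4] - y)
  pmax(d, 0)
}

#' Summarize localization error by configuration and filter
#'
#' Produces the standard error-summary table: per group, the percentage of
#' realizations with no estimate (location loss), the mean number of nodes
#' used in the trilateration over estimable realizations, and the mean,
#' bootstrap 95% CI, median, minimum and maximum localization error.
#'
#' Replicates at the same test location share that location and are
#' dependent, so the CI of the mean error uses a cluster bootstrap:
#' whole test locations are resampled with replacement and the pooled mean
#' recomputed (`boot_reps` resamples, seeded).
#'
#' @param results Data frame from [run_experiment()].
#' @param by Grouping columns (default `c("config", "filter")`).
#' @param boot_reps Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A data frame with one row per group: grouping columns plus
#'   `n_realizations`, `pct_location_loss`, `mean_n_nodes`, `mean_error_m`,
#'   `ci95_low_m`, `ci95_high_m`, `median_error_m`, `min_error_m`,
#'   `max_error_m`.
#' @export
summarize_errors <- function(results, by = c("config", "filter"),
                             boot_reps = 2000, conf = 0.95, seed = 1) {
  stopifnot(all(by %in% names(results)))
  groups <- unique(results[, by, drop = FALSE])
  rownames(groups) <- NULL
  set.seed(seed)
  alpha <- (1 - conf) / 2
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(results))
    for (col in by) sel <- sel & results[[col]] == groups[[col]][g]
    grp <- results[sel, , drop = FALSE]
    ok <- !is.na(grp$error_m)
    loss <- 100 * mean(!ok)
    row <- cbind(groups[g, , drop = FALSE],
                 data.frame(n_realizations = nrow(grp),
                            pct_location_loss = loss,
                            mean_n_nodes = NA_real_, mean_error_m = NA_real_,
                            ci95_low_m = NA_real_, ci95_high_m = NA_real_,
                            median_error_m = NA_real_, min_error_m = NA_real_,
                            max_error_m = NA_real_))
    if (!any(ok)) return(row)
    err <- grp$error_m[ok]
    row$mean_n_nodes <- mean(grp$n_used[ok])
    row$mean_error_m <- mean(err)
    row$median_error_m <- stats::median(err)
    row$min_error_m <- min(err)
    row$max_error_m <- max(err)
    # cluster bootstrap over test locations
    loc <- grp$loc_id[ok]
    sums <- tapply(err, loc, sum)
    cnts <- tapply(err, loc, length)
    L <- length(sums)
    bm <- vapply(seq_len(boot_reps), function(b) {
      pick <- sample.int(L, L, replace = TRUE)
      sum(sums[pick]) / sum(cnts[pick])
    }, numeric(1))
    qs <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
    row$ci95_low_m <- qs[1]
    row$ci95_high_m <- qs[2]
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Profile localization error against distance to the network edge
#'
#' Bins realizations by the true location's distance to the nearest network
#' edge and reports the mean error per bin and group -- a binned analogue of
#' a smoothed error-vs-edge-distance curve, used to quantify edge effects
#' and how filtering flattens them.
#'
#' @param results Data frame from [run_experiment()] (needs `edge_dist_m`
#'   and `error_m`).
#' @param bin_width_m Bin width, metres (default 100).
#' @param by Grouping columns (default `c("config", "filter")`).
#' @return Data frame with columns `by`, `edge_bin` (bin lower edge, m),
#'   `mean_error_m`, `n`.
#' @export
edge_profile <- function(results, bin_width_m = 100,
                         by = c("config", "filter")) {
  if (bin_width_m <= 0) stop("'bin_width_m' must be positive", call. = FALSE)
  ok <- !is.na(results$error_m)
  grp <- results[ok, , drop = FALSE]
  bin <- floor(grp$edge_dist_m / bin_width_m) * bin_width_m
  keyvals <- c(grp[, by, drop = FALSE], list(edge_bin = bin))
  agg <- stats::aggregate(grp$error_m, by = keyvals,
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(agg[, c(by, "edge_bin"), drop = FALSE],
                    mean_error_m = agg$x[, 1], n = as.integer(agg$x[, 2]))
  out <- out[do.call(order, out[c(by, "edge_bin")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
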