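#' Noise and detection-dropout model for simulated RSS
#'
#' Describes how a simulated node observes a transmitter at a given
#' distance.  Two modes are available:
#'
#' * `parametric`: the node detects the pulse with probability
#'   `plogis((detect_d50_m - d) / detect_slope_m)` (1 near the transmitter,
#'   falling to 1/2 at `detect_d50_m`); a detection reports the decay-curve
#'   mean plus Gaussian noise with standard deviation `sigma_db`, clipped to
#'   the receiver reporting range.
#' * `empirical`: a detection resamples an observed RSS value from a
#'   calibration table at a similar distance (bins of `bin_width_m`; if the
#'   query's bin is empty the nearest non-empty bin within `max_bin_gap_m`
#'   is used, otherwise the pulse is a non-detection).
#'
#' The parametric defaults (`sigma_db = 6`, `detect_slope_m = 150`,
#' `detect_d50_m = 844.71`) are calibrated so that about two thirds of all
#' node-transmitter pairs inside the default 1250 m study square are
#' detected; see [calibrate_dropout()].
#'
#' @param mode `"parametric"` or `"empirical"`.
#' @param sigma_db Gaussian RSS noise SD, dB (parametric mode).
#' @param detect_d50_m Distance at which detection probability is 1/2, m.
#' @param detect_slope_m Logistic scale of the dropout curve, m.
#' @param rss_floor,rss_ceiling Receiver reporting range, dB.
#' @param calibration Data frame with columns `distance` and `rss`
#'   (empirical mode).
#' @param bin_width_m,max_bin_gap_m Resampling bin width and maximum
#'   distance to a usable non-empty bin, metres (empirical mode).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(mode = c("parametric", "empirical"),
                        sigma_db = 6, detect_d50_m = 844.71,
                        detect_slope_m = 150,
                        rss_floor = -120, rss_ceiling = -30,
                        calibration = NULL,
                        bin_width_m = 10, max_bin_gap_m = 25) {
  mode <- match.arg(mode)
  if (mode == "parametric") {
    if (sigma_db < 0) stop("'sigma_db' must be non-negative", call. = FALSE)
    if (detect_slope_m <= 0)
      stop("'detect_slope_m' must be positive", call. = FALSE)
  } else {
    if (is.null(calibration))
      stop("empirical mode requires a calibration table", call. = FALSE)
    .require_columns(calibration, c("distance", "rss"), "calibration table")
  }
  structure(list(mode = mode, sigma_db = sigma_db,
                 detect_d50_m = detect_d50_m,
                 detect_slope_m = detect_slope_m,
                 rss_floor = rss_floor, rss_ceiling = rss_ceiling,
                 calibration = calibration,
                 bin_width_m = bin_width_m, max_bin_gap_m = max_bin_gap_m),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  if (x$mode == "parametric") {
    cat(sprintf("Parametric noise: sigma %.3g dB, dropout d50 %.5g m (slope %.3g m)\n",
                x$sigma_db, x$detect_d50_m, x$detect_slope_m))
  } else {
    cat(sprintf("Empirical resampling noise: %d calibration rows, %g m bins (max gap %g m)\n",
                nrow(x$calibration), x$bin_width_m, x$max_bin_gap_m))
  }
  invisible(x)
}

#' Simulate RSS readings at given distances
#'
#' Draws one simulated reading per element of `distance_m`; `NA` marks a
#' non-detection.  Parametric mode needs a decay model for the mean curve;
#' empirical mode draws from the noise model's calibration table.
#'
#' @param distance_m Numeric vector of true distances, metres (>= 0).
#' @param model An `"rss_decay"` model (parametric mode).
#' @param noise A `"noise_model"`.
#' @return Numeric vector of RSS readings, dB, with `NA` for non-detections.
#' @export
generate_rss <- function(distance_m, model, noise) {
  stopifnot(inherits(noise, "noise_model"))
  distance_m <- as.numeric(distance_m)
  if (any(distance_m < 0)) stop("distances must be >= 0", call. = FALSE)
  n <- length(distance_m)
  if (noise$mode == "parametric") {
    stopifnot(inherits(model, "rss_decay"))
    p <- stats::plogis((noise$detect_d50_m - distance_m) / noise$detect_slope_m)
    det <- stats::runif(n) < p
    rss <- predict(model, distance_m) + stats::rnorm(n, 0, noise$sigma_db)
    rss <- pmin(pmax(rss, noise$rss_floor), noise$rss_ceiling)
    rss[!det] <- NA_real_
    rss
  } else {
    .resample_rss(distance_m, noise)
  }
}

.resample_rss <- function(distance_m, noise) {
  cal <- noise$calibration
  w <- noise$bin_width_m
  bins <- floor(cal$distance / w)
  by_bin <- split(cal$rss, bins)
  occupied <- as.numeric(names(by_bin))
  maxgap <- floor(noise$max_bin_gap_m / w)
  vapply(distance_m, function(d) {
    b <- floor(d / w)
    gap <- abs(occupied - b)
    if (!length(gap) || min(gap) > maxgap) return(NA_real_)
    hit <- occupied[which.min(gap)]
    pool <- by_bin[[as.character(hit)]]
    pool[sample.int(length(pool), 1L)]
  }, numeric(1))
}

#' Calibrate the logistic dropout midpoint
#'
#' Solves for the dropout midpoint `detect_d50_m` so that the expected
#' fraction of detected node-transmitter pairs -- averaged over transmitter
#' locations uniform in the square study area and over the nodes of a
#' uniform grid -- equals a target fraction.  The average is computed by
#' deterministic quadrature on a location lattice, so the result does not
#' depend on a seed.
#'
#' @param target Target mean detection fraction (default `112.82 / 169`,
#'   about two thirds).
#' @param detect_slope_m Logistic scale, metres.
#' @param spacing_m,extent_m Uniform grid used as the reference geometry.
#' @param grid_n Quadrature lattice resolution per side.
#' @return The calibrated `detect_d50_m`, metres.
#' @examples
#' calibrate_dropout()  # ~844.71 m with the default geometry
#' @export
calibrate_dropout <- function(target = 112.82 / 169, detect_slope_m = 150,
                              spacing_m = 100, extent_m = 1250,
                              grid_n = 201L) {
  nw <- make_network(spacing_m, extent_m)
  q <- seq(extent_m / (2 * grid_n), extent_m * (1 - 1 / (2 * grid_n)),
           length.out = grid_n)
  loc <- as.matrix(expand.grid(q, q))
  D <- sqrt(outer(loc[, 1], nw$nodes$x, "-")^2 +
            outer(loc[, 2], nw$nodes$y, "-")^2)
  f <- function(d50) mean(stats::plogis((d50 - D) / detect_slope_m)) - target
  stats::uniroot(f, c(1, 5 * extent_m), tol = 1e-6)$root
}

#' Write a synthetic calibration table
#'
#' Generates a (distance, RSS) calibration table from a decay model under
#' the parametric noise law, for exercising the empirical-resampling mode
#' without field data.  The file is synthetic: it emulates a field
#' calibration campaign, it is not one.
#'
#' @param model An `"rss_decay"` model.
#' @param n Number of rows.
#' @param dmax Maximum distance sampled, metres.
#' @param noise A parametric `"noise_model"`.
#' @param seed Optional seed.
#' @param path Optional CSV output path.
#' @return Data frame with columns `distance`, `rss` (detections only).
#' @export
make_calibration_table <- function(model, n = 2000, dmax = 2500,
                                   noise = noise_model(), seed = NULL,
                                   path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- stats::runif(n, 0, dmax)
  rss <- generate_rss(d, model, noise)
  out <- data.frame(distance = d, rss = rss)
  out <- out[!is.na(out$rss), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
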