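#' Exponential RSS-distance decay model
#'
#' Construct a decay model `RSS(d) = a * exp(-S * d) + K` from known
#' parameters, without fitting.  `a` is the intercept term above the
#' asymptote (dB), `S` the decay rate per metre (stored positive, applied
#' with a negative sign), and `K` the horizontal asymptote (dB) -- in
#' practice the level at which signals become indistinguishable from the
#' receiver noise floor.
#'
#' @param a Intercept term, dB; must be positive.
#' @param S Decay rate per metre; must be positive.
#' @param K Horizontal asymptote, dB.
#' @param residual_sd Optional residual standard deviation of a fit, dB.
#' @param n_obs Optional number of observations behind the parameters.
#' @return An object of class `"rss_decay"`.
#' @examples
#' m <- decay_model(47.23, 0.005, -105.16)
#' predict(m, distance = c(0, 100, 500))
#' @seealso [rss_decay()] to estimate the parameters from calibration data,
#'   [invert_distance()] for the RSS-to-distance inverse.
#' @export
decay_model <- function(a, S, K, residual_sd = NA_real_, n_obs = NA_integer_) {
  if (!is.finite(a) || !is.finite(S) || !is.finite(K))
    stop("decay model parameters must be finite", call. = FALSE)
  if (a <= 0) stop("intercept term 'a' must be positive", call. = FALSE)
  if (S <= 0) stop("decay rate 'S' must be positive", call. = FALSE)
  structure(
    list(a = a, S = S, K = K,
         residual_sd = residual_sd, n_obs = as.integer(n_obs),
         converged = NA, fit = NULL),
    class = "rss_decay"
  )
}

#' Fit the exponential RSS-distance decay model
#'
#' Estimates the parameters of `RSS ~ a * exp(-S * distance) + K` from
#' calibration observations (true transmitter-to-node distances paired with
#' window-averaged RSS readings) by nonlinear least squares
#' (Gauss-Newton, via [stats::nls()]).  When no starting values are given a
#' closed-form self-start is used: `K` from the minimum observed RSS, `a`
#' from the observed range, and `S` from the slope of a log-linearised
#' regression of `log(RSS - K)` on distance.
#'
#' @param distance Numeric vector of true distances, metres (non-negative).
#' @param rss Numeric vector of mean RSS readings, dB; receivers report
#'   values in `[-120, -30]`.
#' @param start Optional starting values: an `"rss_decay"` object or a named
#'   list/vector with elements `a`, `S`, `K`.
#' @param weights Optional non-negative case weights (e.g. the number of
#'   detections averaged into each reading).  The default is an unweighted
#'   fit; every averaged reading counts once regardless of how many raw
#'   detections produced it.
#' @return An `"rss_decay"` object whose elements include the parameter
#'   estimates, `residual_sd` (residual standard deviation, dB), `n_obs`,
#'   a `converged` flag and the underlying `nls` fit (element `fit`).
#' @examples
#' d <- seq(1, 2500, length.out = 200)
#' y <- 47.23 * exp(-0.005 * d) - 105.16
#' fit <- rss_decay(d, y)
#' coef(fit)
#' @export
rss_decay <- function(distance, rss, start = NULL, weights = NULL) {
  distance <- as.numeric(distance)
  rss <- as.numeric(rss)
  if (length(distance) != length(rss))
    stop("'distance' and 'rss' must have the same length", call. = FALSE)
  keep <- is.finite(distance) & is.finite(rss)
  distance <- distance[keep]; rss <- rss[keep]
  if (!is.null(weights)) weights <- as.numeric(weights)[keep]
  if (length(distance) < 4L)
    stop("at least 4 calibration observations are required", call. = FALSE)
  if (length(unique(distance)) < 2L)
    stop("calibration observations must span at least 2 distinct distances",
         call. = FALSE)
  if (any(distance < 0))
    stop("distances must be non-negative", call. = FALSE)
  if (any(rss < -120 | rss > -30))
    stop("RSS values outside the receiver reporting range [-120, -30] dB",
         call. = FALSE)

  if (is.null(start)) {
    start <- .decay_selfstart(distance, rss)
  } else if (inherits(start, "rss_decay")) {
    start <- list(a = start$a, S = start$S, K = start$K)
  } else {
    start <- as.list(start)[c("a", "S", "K")]
    if (any(vapply(start, is.null, logical(1))))
      stop("'start' must supply a, S and K", call. = FALSE)
  }

  dat <- data.frame(distance = distance, rss = rss)
  fit <- tryCatch(
    stats::nls(rss ~ a * exp(-S * distance) + K,
               data = dat, start = start, weights = weights,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e)
      stop("decay model fit did not converge (start a=",
           signif(start$a, 4), ", S=", signif(start$S, 4),
           ", K=", signif(start$K, 4), "): ", conditionMessage(e),
           call. = FALSE)
  )

  cf <- stats::coef(fit)
  out <- decay_model(cf[["a"]], cf[["S"]], cf[["K"]],
                     residual_sd = stats::sigma(fit),
                     n_obs = length(distance))
  out$converged <- fit$convInfo$isConv
  out$fit <- fit
  out
}

# Closed-form self-start: asymptote from the weakest reading, intercept from
# the observed range, decay rate from a log-linearised slope.
.decay_selfstart <- function(distance, rss) {
  K0 <- min(rss) - 1
  a0 <- max(rss) - K0
  z <- rss - K0
  pos <- z > 0
  sl <- stats::coef(stats::lm(log(z[pos]) ~ distance[pos]))[[2]]
  S0 <- if (is.finite(sl) && sl < 0) -sl else 1 / max(diff(range(distance)), 1)
  list(a = a0, S = S0, K = K0)
}

#' @export
coef.rss_decay <- function(object, ...) {
  c(a = object$a, S = object$S, K = object$K)
}

#' @export
print.rss_decay <- function(x, digits = 6, ...) {
  cat("Exponential RSS-distance decay model\n")
  cat(sprintf("  RSS = %s * exp(-%s * distance) + (%s)  [dB, metres]\n",
              signif(x$a, digits), signif(x$S, digits), signif(x$K, digits)))
  if (is.finite(x$residual_sd))
    cat(sprintf("  residual SD %.3f dB on %d observations\n",
                x$residual_sd, x$n_obs))
  invisible(x)
}

#' @export
summary.rss_decay <- function(object, ...) {
  if (!is.null(object$fit)) return(summary(object$fit, ...))
  print(object)
  invisible(object)
}

#' @export
residuals.rss_decay <- function(object, ...) {
  if (is.null(object$fit))
    stop("model was constructed from parameters, not fitted", call. = FALSE)
  stats::residuals(object$fit)
}

#' Predict RSS at given distances
#'
#' Evaluates `a * exp(-S * d) + K` for a decay model.
#'
#' @param object An `"rss_decay"` model.
#' @param distance Numeric vector of distances, metres; finite and >= 0.
#' @param ... Unused.
#' @return Predicted RSS, dB.
#' @export
predict.rss_decay <- function(object, distance, ...) {
  distance <- as.numeric(distance)
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  object$a * exp(-object$S * distance) + object$K
}

#' Invert a decay model from RSS to distance
#'
#' Closed-form inverse of the decay curve:
#' `d = -log((rss - K) / a) / S` for `K < rss <= a + K`.  Readings stronger
#' than the modelled zero-distance value map to 0 m.  Readings at or below
#' `K + guard_db` sit in the asymptote region where distance is
#' unidentifiable; they map to `max_distance` (by default `Inf`) so callers
#' can recognise and drop them -- never to a silent `NaN`.
#'
#' @param model An `"rss_decay"` model.
#' @param rss Numeric vector of RSS readings, dB.
#' @param guard_db Guard band above the asymptote, dB; readings within it
#'   are treated as non-informative.  Default 0.5 dB.
#' @param max_distance Sentinel returned for non-informative readings.
#' @return Numeric vector of distances, metres; `max_distance` marks
#'   non-informative readings.
#' @examples
#' m <- decay_model(47.23, 0.005, -105.16)
#' invert_distance(m, c(-57.93, -80, -105.16))
#' @export
invert_distance <- function(model, rss, guard_db = 0.5, max_distance = Inf) {
  stopifnot(inherits(model, "rss_decay"))
  rss <- as.numeric(rss)
  out <- rep(NA_real_, length(rss))
  hi <- !is.na(rss) & rss > model$a + model$K
  lo <- !is.na(rss) & rss <= model$K + guard_db
  mid <- !is.na(rss) & !hi & !lo
  out[hi] <- 0
  out[lo] <- max_distance
  out[mid] <- -log((rss[mid] - model$K) / model$a) / model$S
  out
}

#' @export
plot.rss_decay <- function(x, dmax = NULL, ...) {
  if (is.null(dmax)) dmax <- 20 / x$S
  d <- seq(0, dmax, length.out = 400)
  if (!is.null(x$fit)) {
    env <- environment(stats::formula(x$fit))
    dat <- eval(x$fit$data, env)
    graphics::plot(dat$distance, dat$rss, pch = 16, cex = 0.4,
                   col = "grey50", xlab = "distance (m)", ylab = "RSS (dB)",
                   ...)
    graphics::lines(d, predict(x, d), lwd = 2)
  } else {
    graphics::plot(d, predict(x, d), type = "l", lwd = 2,
                   xlab = "distance (m)", ylab = "RSS (dB)", ...)
  }
  graphics::abline(h = x$K, lty = 3)
  invisible(x)
}

#' Read and write decay models as JSON
#'
#' A fitted model is persisted as a small JSON record with fields
#' `a`, `S`, `K`, `residual_sd` and `n_obs`.
#'
#' @param model An `"rss_decay"` model.
#' @param path File path.
#' @return `read_decay_model` returns an `"rss_decay"` object;
#'   `write_decay_model` returns `path` invisibly.
#' @export
write_decay_model <- function(model, path) {
  stopifnot(inherits(model, "rss_decay"))
  rec <- list(a = model$a, S = model$S, K = model$K,
              residual_sd = model$residual_sd, n_obs = model$n_obs)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_decay_model
#' @export
read_decay_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("a", "S", "K"))
    if (is.null(rec[[f]])) stop("model file lacks field '", f, "'", call. = FALSE)
  decay_model(rec$a, rec$S, rec$K,
              residual_sd = if (is.null(rec$residual_sd)) NA_real_ else rec$residual_sd,
              n_obs = if (is.null(rec$n_obs)) NA_integer_ else rec$n_obs)
}
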