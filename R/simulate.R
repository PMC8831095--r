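#' Run a localization-error simulation experiment
#'
#' Monte-Carlo evaluation of a node configuration: for each test location
#' and replicate, a noisy RSS value (or non-detection) is drawn for every
#' node in the network, and *every* filter is then evaluated on that same
#' draw -- a paired design, so filter comparisons are not confounded by
#' simulation noise.  Each filtered node set is inverted to distances
#' through the decay model and trilaterated exactly as [localize()] does
#' (same anchor rule, same asymptote guard, same Gauss-Newton core).
#'
#' The whole experiment is deterministic given `seed`.
#'
#' @param network A `"node_network"` (see [make_network()]).
#' @param model An `"rss_decay"` decay model.
#' @param noise A `"noise_model"`.
#' @param filters A list of `"node_filter"` objects (a single filter is
#'   accepted).
#' @param n_locations Number of random test locations (default 100).
#' @param n_reps Replicates per location (default 1000).
#' @param extent_m Side of the square from which test locations are drawn;
#'   defaults to the extent the network was built with, else its bounding
#'   box.
#' @param seed Integer seed.
#' @param config_label Label stored in the `config` column.
#' @param locations Optional data frame of test locations (`x`, `y`)
#'   overriding the random draw.
#' @param guard_db Asymptote guard for [invert_distance()].
#' @param tol,max_iter Gauss-Newton controls.
#' @return A data frame with one row per (filter, location, replicate):
#'   `config`, `filter`, `loc_id`, `rep`, `true_x`, `true_y`,
#'   `edge_dist_m`, `n_retained` (nodes surviving the filter), `n_used`
#'   (nodes entering the trilateration after the asymptote guard),
#'   `status`, `est_x`, `est_y`, `error_m` (`NA` unless status is `"ok"`).
#' @examples
#' nw <- make_network(250, 1250)
#' m <- decay_model(47.23, 0.005, -105.16)
#' res <- run_experiment(nw, m, noise_model(), list(no_filter()),
#'                       n_locations = 5, n_reps = 3, seed = 1)
#' head(res)
#' @export
run_experiment <- function(network, model, noise, filters,
                           n_locations = 100, n_reps = 1000,
                           extent_m = NULL, seed = 1,
                           config_label = "config", locations = NULL,
                           guard_db = 0.5, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(network, "node_network"),
            inherits(model, "rss_decay"),
            inherits(noise, "noise_model"))
  if (inherits(filters, "node_filter")) filters <- list(filters)
  stopifnot(length(filters) >= 1L,
            all(vapply(filters, inherits, logical(1), "node_filter")))
  if (is.null(extent_m))
    extent_m <- if (!is.null(network$extent_m)) network$extent_m
                else max(network$extent["xmax"], network$extent["ymax"])

  set.seed(seed)
  if (is.null(locations)) {
    locations <- sample_test_locations(n_locations, extent_m)
  } else {
    n_locations <- nrow(locations)
  }

  nx <- network$nodes$x; ny <- network$nodes$y
  nn <- length(nx)
  DD <- as.matrix(stats::dist(cbind(nx, ny)))
  radii <- vapply(filters, function(f)
    if (f$kind == "distance") resolve_radius(f, network) else NA_real_,
    numeric(1))
  labels <- vapply(filters, `[[`, character(1), "label")
  nf <- length(filters)
  edge <- edge_distance(locations[, c("x", "y")], network$extent)

  ntot <- n_locations * n_reps
  # per-filter result columns
  R <- lapply(seq_len(nf), function(i)
    list(n_retained = integer(ntot), n_used = integer(ntot),
         status = character(ntot), est_x = rep(NA_real_, ntot),
         est_y = rep(NA_real_, ntot), error = rep(NA_real_, ntot)))

  k <- 0L
  for (i in seq_len(n_locations)) {
    tx <- locations$x[i]; ty <- locations$y[i]
    dv <- sqrt((nx - tx)^2 + (ny - ty)^2)
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      rss <- generate_rss(dv, model, noise)
      det <- !is.na(rss)
      if (any(det)) {
        dist_est <- invert_distance(model, rss, guard_db = guard_db,
                                    max_distance = Inf)
        anchor <- which.max(rss)           # ties: lowest index = lowest id
      }
      for (fi in seq_len(nf)) {
        if (!any(det)) {
          R[[fi]]$status[k] <- "too_few_nodes"
          next
        }
        keep <- switch(filters[[fi]]$kind,
                       none = det,
                       rss = det & !is.na(rss) & rss > filters[[fi]]$cutoff_db,
                       distance = det & DD[anchor, ] <= radii[fi])
        nret <- sum(keep)
        R[[fi]]$n_retained[k] <- nret
        use <- keep & is.finite(dist_est)
        nuse <- sum(use)
        R[[fi]]$n_used[k] <- nuse
        if (nuse < 3L) {
          R[[fi]]$status[k] <- "too_few_nodes"
          next
        }
        idx <- which(use)
        st <- idx[which.max(rss[idx])]
        sol <- .gn_solve(nx[idx], ny[idx], dist_est[idx],
                         nx[st], ny[st], tol, max_iter)
        if (sol[["converged"]] == 1) {
          R[[fi]]$status[k] <- "ok"
          R[[fi]]$est_x[k] <- sol[["x"]]
          R[[fi]]$est_y[k] <- sol[["y"]]
          R[[fi]]$error[k] <- sqrt((sol[["x"]] - tx)^2 + (sol[["y"]] - ty)^2)
        } else {
          R[[fi]]$status[k] <- "no_convergence"
          R[[fi]]$est_x[k] <- sol[["x"]]
          R[[fi]]$est_y[k] <- sol[["y"]]
        }
      }
    }
  }

  loc_id <- rep(locations$loc_id %||% seq_len(n_locations), each = n_reps)
  base <- data.frame(
    loc_id = loc_id,
    rep = rep(seq_len(n_reps), times = n_locations),
    true_x = rep(locations$x, each = n_reps),
    true_y = rep(locations$y, each = n_reps),
    edge_dist_m = rep(edge, each = n_reps)
  )
  out <- do.call(rbind, lapply(seq_len(nf), function(fi) {
    cbind(data.frame(config = config_label, filter = labels[fi]),
          base,
          data.frame(n_retained = R[[fi]]$n_retained,
                     n_used = R[[fi]]$n_used,
                     status = R[[fi]]$status,
                     est_x = R[[fi]]$est_x, est_y = R[[fi]]$est_y,
                     error_m = R[[fi]]$error))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
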