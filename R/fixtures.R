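#' Write a synthetic end-to-end fixture set
#'
#' Generates a small, fully synthetic data set sufficient to exercise every
#' command offline: a calibration CSV drawn from a reference decay curve
#' with noise, a node table, a detection log of a stationary tag, and a
#' simulation config.  All files are plain text and reproducible for a
#' given seed.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed (default 1).
#' @param model Reference decay model used as the generator truth.
#' @param n_cal Number of calibration observations.
#' @return Invisibly, a named list of the file paths written
#'   (`calibration`, `nodes`, `detections`, `sim_config`).
#' @export
make_fixtures <- function(out_dir, seed = 1,
                          model = decay_model(47.23, 0.005, -105.16),
                          n_cal = 400) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  # calibration campaign: test transmitter at random offsets from nodes
  nw <- make_network(250, 1250)
  nodes_path <- file.path(out_dir, "nodes.csv")
  utils::write.csv(nw$nodes, nodes_path, row.names = FALSE)

  ni <- sample.int(nrow(nw$nodes), n_cal, replace = TRUE)
  ang <- stats::runif(n_cal, 0, 2 * pi)
  dd <- stats::runif(n_cal, 1, 2000)
  test_x <- nw$nodes$x[ni] + dd * cos(ang)
  test_y <- nw$nodes$y[ni] + dd * sin(ang)
  rss <- pmin(pmax(predict(model, dd) + stats::rnorm(n_cal, 0, 3),
                   -120), -30)
  cal <- data.frame(node_id = nw$nodes$node_id[ni],
                    node_x = nw$nodes$x[ni], node_y = nw$nodes$y[ni],
                    test_x = test_x, test_y = test_y,
                    mean_rss = rss,
                    n = sample(2:59, n_cal, replace = TRUE))
  cal_path <- file.path(out_dir, "calibration.csv")
  utils::write.csv(cal, cal_path, row.names = FALSE)

  # stationary tag near the network centre, 3-second pulses for 5 minutes
  truth <- c(640, 610)
  t0 <- as.POSIXct("2022-01-15 02:00:00", tz = "UTC")
  times <- t0 + seq(0, 297, by = 3)
  dv <- sqrt((nw$nodes$x - truth[1])^2 + (nw$nodes$y - truth[2])^2)
  det <- do.call(rbind, lapply(seq_along(times), function(i) {
    rss <- generate_rss(dv, model, noise_model())
    hit <- which(!is.na(rss))
    if (!length(hit)) return(NULL)
    data.frame(tag_id = "tagA", node_id = nw$nodes$node_id[hit],
               rss = round(rss[hit], 1),
               timestamp = format(times[i], "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  }))
  det_path <- file.path(out_dir, "detections.csv")
  utils::write.csv(det, det_path, row.names = FALSE)

  cfg <- list(
    label = "u250-demo",
    network = list(layout = "uniform", spacing_m = 250, extent_m = 1250),
    model = list(a = model$a, S = model$S, K = model$K),
    noise = list(mode = "parametric", sigma_db = 6,
                 detect_d50_m = 844.71, detect_slope_m = 150),
    filters = list("none", "dist:315m"),
    n_locations = 10, n_reps = 20, seed = seed
  )
  cfg_path <- file.path(out_dir, "sim.yaml")
  yaml::write_yaml(cfg, cfg_path)

  invisible(list(calibration = cal_path, nodes = nodes_path,
                 detections = det_path, sim_config = cfg_path))
}
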