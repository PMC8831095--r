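# Shared reference objects and independent oracles used across the suite.

# Field-calibrated decay curve used as generator truth throughout.
ref_model <- function() decay_model(47.23, 0.005, -105.16)

# Range-residual objective, written independently of the solver.
range_obj <- function(px, py, x, y, d) {
  sum((sqrt((px - x)^2 + (py - y)^2) - d)^2)
}

# Brute-force grid-search minimizer of the same objective (vectorized).
grid_search_min <- function(x, y, d, xlim, ylim, res = 1) {
  gx <- seq(xlim[1], xlim[2], by = res)
  gy <- seq(ylim[1], ylim[2], by = res)
  G <- expand.grid(px = gx, py = gy)
  obj <- numeric(nrow(G))
  for (i in seq_along(x)) {
    obj <- obj + (sqrt((G$px - x[i])^2 + (G$py - y[i])^2) - d[i])^2
  }
  k <- which.min(obj)
  c(x = G$px[k], y = G$py[k], obj = obj[k])
}

# Random trilateration instance with nodes surrounding the source -- the
# geometry the distance filter produces (anchor neighbourhood around the
# transmitter), where the range-residual objective is well-posed.
surround_instance <- function(n, noise_sd = 8) {
  tx <- runif(1, 100, 200); ty <- runif(1, 100, 200)
  ang <- 2 * pi * (seq_len(n) - 1 + runif(n)) / n  # stratified around circle
  rad <- runif(n, 60, 160)
  x <- tx + rad * cos(ang); y <- ty + rad * sin(ang)
  d <- pmax(sqrt((tx - x)^2 + (ty - y)^2) + rnorm(n, 0, noise_sd), 0)
  list(x = x, y = y, d = d, truth = c(tx, ty))
}

# Noise-free localization input: exact decay-curve RSS at every node.
noise_free_input <- function(network, model, truth) {
  dv <- sqrt((network$nodes$x - truth[1])^2 + (network$nodes$y - truth[2])^2)
  localization_input(data.frame(node_id = network$nodes$node_id,
                                mean_rss = predict(model, dv)))
}
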