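test_that("parametric noise collapses to the decay curve in the noiseless limit", {
  m <- ref_model()
  quiet <- noise_model(sigma_db = 0, detect_d50_m = 1e9)
  d <- c(0, 125.9548, 500, 2000)
  set.seed(61)
  expect_equal(generate_rss(d, m, quiet), predict(m, d))
  # full dropout
  never <- noise_model(detect_d50_m = -1e9)
  expect_true(all(is.na(generate_rss(d, m, never))))
  # readings are clipped to the reporting range
  loud <- noise_model(sigma_db = 60, detect_d50_m = 1e9)
  r <- generate_rss(rep(500, 2000), m, loud)
  expect_true(all(r >= -120 & r <= -30))
  expect_true(any(r == -120) && any(r == -30))
  expect_error(generate_rss(-1, m, quiet), ">= 0")
})

test_that("empirical resampling draws from nearby distance bins only", {
  cal <- data.frame(distance = c(rep(5, 4), rep(105, 4)),
                    rss = c(-60, -61, -62, -63, -90, -91, -92, -93))
  nz <- noise_model("empirical", calibration = cal)
  set.seed(62)
  # query inside an occupied 10 m bin resamples that bin's values
  r <- replicate(50, generate_rss(3, NULL, nz))
  expect_true(all(r %in% c(-60, -61, -62, -63)))
  # nearest non-empty bin within the 25 m gap is used
  r2 <- replicate(50, generate_rss(125, NULL, nz))
  expect_true(all(r2 %in% c(-90, -91, -92, -93)))
  # beyond the gap: non-detection
  expect_true(is.na(generate_rss(500, NULL, nz)))
  expect_error(noise_model("empirical"), "calibration")
})

test_that("synthetic calibration tables feed the empirical mode", {
  m <- ref_model()
  tab <- make_calibration_table(m, n = 500, seed = 63)
  expect_true(all(!is.na(tab$rss)))
  expect_true(all(tab$rss >= -120 & tab$rss <= -30))
  nz <- noise_model("empirical", calibration = tab)
  set.seed(64)
  r <- generate_rss(rep(100, 200), m, nz)
  got <- r[!is.na(r)]
  expect_gt(length(got), 100)
  # resampled readings at 100 m look like the curve there (+/- noise)
  expect_lt(abs(mean(got) - predict(m, 100)), 6)
})

test_that("experiments are reproducible and paired across filters", {
  m <- ref_model()
  nw <- make_network(250, 1250)
  fl <- list(no_filter(), distance_filter(radius_m = 5000))
  r1 <- run_experiment(nw, m, noise_model(), fl, n_locations = 6,
                       n_reps = 10, seed = 71)
  r2 <- run_experiment(nw, m, noise_model(), fl, n_locations = 6,
                       n_reps = 10, seed = 71)
  expect_identical(r1, r2)
  r3 <- run_experiment(nw, m, noise_model(), fl, n_locations = 6,
                       n_reps = 10, seed = 72)
  expect_false(identical(r1$error_m, r3$error_m))
  # a radius covering the whole network sees exactly the no-filter draw:
  # identical retained sets and identical estimates, realization by realization
  a <- r1[r1$filter == "none", ]
  b <- r1[r1$filter == "dist 5000 m", ]
  expect_equal(a$n_retained, b$n_retained)
  expect_equal(a$est_x, b$est_x)
  expect_equal(a$error_m, b$error_m)
})

test_that("the noise-free limit of the experiment recovers every location", {
  m <- ref_model()
  nw <- make_network(175, 1250)
  quiet <- noise_model(sigma_db = 0, detect_d50_m = 1e9)
  res <- run_experiment(nw, m, quiet, list(no_filter()),
                        n_locations = 15, n_reps = 1, seed = 73)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$error_m < 1e-2))
})

test_that("the calibrated dropout detects about two thirds of node pairs", {
  m <- ref_model()
  nw <- make_network(100, 1250)
  res <- run_experiment(nw, m, noise_model(), list(no_filter()),
                        n_locations = 60, n_reps = 25, seed = 74)
  frac <- mean(res$n_retained) / nrow(nw$nodes)
  expect_gt(frac, 0.60)
  expect_lt(frac, 0.72)
  # and the calibration routine reproduces the default midpoint
  expect_equal(calibrate_dropout(), 844.71, tolerance = 1e-3)
})

test_that("unfiltered estimates are pulled toward the network centre", {
  m <- ref_model()
  nw <- make_network(100, 1250)
  res <- run_experiment(nw, m, noise_model(), list(no_filter()),
                        n_locations = 40, n_reps = 10, seed = 75)
  ok <- res$status == "ok"
  centre <- c(625, 625)
  d_est <- sqrt((res$est_x[ok] - centre[1])^2 + (res$est_y[ok] - centre[2])^2)
  d_true <- sqrt((res$true_x[ok] - centre[1])^2 + (res$true_y[ok] - centre[2])^2)
  expect_lt(mean(d_est), mean(d_true))
})
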