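test_that("noise-free calibration recovers the generating curve to high precision", {
  m <- ref_model()
  d <- seq(1, 2500, length.out = 200)
  fit <- rss_decay(d, predict(m, d))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(47.23, 0.005, -105.16),
               tolerance = 1e-7)
  expect_lt(fit$residual_sd, 1e-6)
  expect_equal(fit$n_obs, 200L)

  # user-supplied start reaches the same solution
  fit2 <- rss_decay(d, predict(m, d), start = list(a = 30, S = 0.01, K = -110))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
})

test_that("noisy calibration recovers parameters within sampling error", {
  set.seed(101)
  m <- ref_model()
  d <- runif(600, 1, 2500)
  rss <- pmin(pmax(predict(m, d) + rnorm(600, 0, 3), -120), -30)
  fit <- rss_decay(d, rss)
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  est <- coef(fit)
  truth <- c(a = 47.23, S = 0.005, K = -105.16)
  expect_true(all(abs(est - truth) < 3 * se))
  expect_gt(fit$residual_sd, 2)
  expect_lt(fit$residual_sd, 4)
})

test_that("prediction follows the decay curve with its asymptote", {
  m <- ref_model()
  expect_equal(predict(m, 0), 47.23 - 105.16)
  # approaches K beyond ~20 decay lengths
  expect_equal(predict(m, 20 / m$S + 500), m$K, tolerance = 1e-6)
  # strictly decreasing
  d <- seq(0, 3000, by = 10)
  expect_true(all(diff(predict(m, d)) < 0))
  expect_error(predict(m, -5), "non-negative")
  expect_error(predict(m, Inf), "finite")
})

test_that("inversion is the closed-form inverse with documented sentinels", {
  m <- ref_model()
  # independent oracle: solve predict(d) = -80 numerically on the forward curve
  d80 <- uniroot(function(d) predict(m, d) + 80, c(0, 2000), tol = 1e-10)$root
  expect_equal(invert_distance(m, -80), d80, tolerance = 1e-6)
  expect_equal(invert_distance(m, -80), 125.955, tolerance = 1e-4)
  # zero-distance reading and anything stronger
  expect_equal(invert_distance(m, -57.93), 0)
  expect_equal(invert_distance(m, -40), 0)
  # asymptote region is a flagged sentinel, never NaN
  expect_identical(invert_distance(m, m$K), Inf)
  expect_identical(invert_distance(m, m$K + 0.5), Inf)
  expect_identical(invert_distance(m, -120, max_distance = 5000), 5000)
  expect_false(anyNA(invert_distance(m, c(-31, -80, -119))))
})

test_that("predict and invert are mutually inverse and monotone", {
  m <- ref_model()
  # the full inverse branch, with the asymptote guard disabled
  d <- seq(0.5, 20 / m$S - 1, length.out = 200)
  expect_equal(invert_distance(m, predict(m, d), guard_db = 0), d,
               tolerance = 1e-6)
  # with the default 0.5 dB guard the round trip holds on the informative range
  di <- seq(0.5, log(m$a / 0.5) / m$S - 1, length.out = 100)
  expect_equal(invert_distance(m, predict(m, di)), di, tolerance = 1e-6)
  rss <- seq(m$K + 0.6, m$a + m$K, length.out = 200)
  dd <- invert_distance(m, rss)
  expect_true(all(diff(dd) < 0))  # stronger signal, shorter distance
})

test_that("calibration input is validated", {
  expect_error(rss_decay(c(1, 2, 3), c(-60, -70, -80)), "at least 4")
  expect_error(rss_decay(rep(10, 5), rep(-60, 5), start = list(a = 1, S = 1, K = -100)),
               "distinct distances")
  expect_error(rss_decay(1:5, c(-60, -70, -80, -90, -20)), "reporting range")
  expect_error(decay_model(-1, 0.005, -105), "positive")
  expect_error(decay_model(47, -0.005, -105), "positive")
})

test_that("detection-count weighting is available as a flag", {
  set.seed(7)
  m <- ref_model()
  d <- runif(120, 1, 1500)
  rss <- pmin(pmax(predict(m, d) + rnorm(120, 0, 4), -120), -30)
  w <- sample(1:59, 120, replace = TRUE)
  fu <- rss_decay(d, rss)
  fw <- rss_decay(d, rss, weights = w)
  expect_true(fw$converged)
  # weighting changes the solution but both stay near the truth
  expect_false(isTRUE(all.equal(coef(fu), coef(fw), tolerance = 1e-8)))
  expect_equal(unname(coef(fw)), c(47.23, 0.005, -105.16), tolerance = 0.25)
})

test_that("decay models round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  m <- decay_model(47.23, 0.005, -105.16, residual_sd = 3.2, n_obs = 3390L)
  write_decay_model(m, path)
  m2 <- read_decay_model(path)
  expect_equal(coef(m2), coef(m))
  expect_equal(m2$residual_sd, 3.2)
  expect_equal(m2$n_obs, 3390L)
  # malformed record is rejected
  jsonlite::write_json(list(a = 1), path, auto_unbox = TRUE)
  expect_error(read_decay_model(path), "lacks field")
})
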