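mk_det <- function(tag, node, rss, t) {
  data.frame(tag_id = tag, node_id = node, rss = rss,
             timestamp = as.POSIXct("2022-03-01 10:00:00", tz = "UTC") + t)
}

test_that("window trimming keeps the central period", {
  det <- mk_det("t1", "A", -70, seq(0, 299, by = 3))
  ws <- as.POSIXct("2022-03-01 10:00:00", tz = "UTC")
  we <- ws + 300
  kept <- trim_window(det, ws, we, trim_s = 60)
  off <- as.numeric(difftime(kept$timestamp, ws, units = "secs"))
  expect_true(all(off >= 60 & off <= 240))  # central 3 of 5 minutes
  expect_equal(nrow(kept), sum(seq(0, 299, by = 3) >= 60 &
                                 seq(0, 299, by = 3) <= 240))
  # zero trim is the identity
  expect_equal(nrow(trim_window(det, ws, we, trim_s = 0)), nrow(det))
  # everything trimmed away is an empty result, not an error
  early <- mk_det("t1", "A", -70, c(1, 5, 10))
  expect_equal(nrow(trim_window(early, ws, we, trim_s = 60)), 0L)
  # degenerate window is an error
  expect_error(trim_window(det, ws, ws + 100, trim_s = 60), "shorter")
})

test_that("per-node averaging matches hand-computed means and counts", {
  det <- mk_det("t1", c("A", "A", "B"), c(-70, -72, -90), c(0, 3, 6))
  inp <- average_by_node(det)
  expect_s3_class(inp, "localization_input")
  expect_equal(inp$node_id, c("A", "B"))
  expect_equal(inp$mean_rss, c(-71, -90))
  expect_equal(inp$n, c(2L, 1L))
  # idempotent mean over many identical readings
  many <- mk_det("t1", "C", rep(-65, 59), seq_len(59))
  inp2 <- average_by_node(many)
  expect_equal(inp2$mean_rss, -65)
  expect_equal(inp2$n, 59L)
  # single node is a valid input (estimability is decided downstream)
  expect_equal(nrow(average_by_node(mk_det("t1", "A", -80, 0))), 1L)
  # empty input gives an empty input object
  expect_equal(nrow(average_by_node(det[0, ])), 0L)
})

test_that("averaging respects raw reading bounds and detection counts", {
  set.seed(11)
  det <- mk_det("t1", sample(LETTERS[1:6], 200, replace = TRUE),
                runif(200, -115, -40), seq_len(200))
  inp <- average_by_node(det)
  expect_equal(sum(inp$n), 200L)
  for (i in seq_len(nrow(inp))) {
    raw <- det$rss[det$node_id == inp$node_id[i]]
    expect_gte(inp$mean_rss[i], min(raw))
    expect_lte(inp$mean_rss[i], max(raw))
  }
})

test_that("unrelated tags do not affect trimming or averaging", {
  ws <- as.POSIXct("2022-03-01 10:00:00", tz = "UTC")
  a <- mk_det("tagA", c("A", "B", "A"), c(-70, -80, -74), c(70, 90, 110))
  b <- mk_det("tagB", c("A", "C"), c(-50, -55), c(80, 100))
  both <- rbind(a, b)
  t1 <- average_by_node(trim_window(both, ws, ws + 300, 60), tag_id = "tagA")
  t2 <- average_by_node(trim_window(a, ws, ws + 300, 60), tag_id = "tagA")
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("localization inputs enforce their invariants", {
  expect_error(localization_input(data.frame(node_id = c("A", "A"),
                                             mean_rss = c(-70, -71))),
               "at most once")
  expect_error(localization_input(data.frame(node_id = "A", mean_rss = -70,
                                             n = 0L)),
               ">= 1")
  expect_error(localization_input(data.frame(node_id = "A")), "mean_rss")
})

test_that("a detection log slices into per-window inputs", {
  det <- rbind(mk_det("t1", "A", -70, seq(0, 179, by = 3)),
               mk_det("t1", "B", -85, seq(1, 179, by = 6)))
  det <- det[order(det$timestamp), ]
  inputs <- window_detections(det, window_s = 60, stride_s = 60)
  expect_length(inputs, 3L)
  expect_true(all(vapply(inputs, function(x) all(x$node_id %in% c("A", "B")),
                         logical(1))))
  # counts over all windows account for every detection
  expect_equal(sum(vapply(inputs, function(x) sum(x$n), numeric(1))),
               nrow(det))
  # writer emits one tidy row per node and window
  path <- tempfile(fileext = ".csv")
  write_localization_inputs(inputs, path)
  tidy <- read.csv(path)
  expect_equal(nrow(tidy), sum(vapply(inputs, nrow, integer(1))))
  expect_named(tidy, c("tag_id", "window_start", "node_id", "mean_rss", "n"))
})
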