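#' Read a detection log
#'
#' Reads a CSV of raw node detections with columns `tag_id`, `node_id`,
#' `rss` (dB) and `timestamp` (ISO-8601, UTC).
#'
#' @param path CSV file path.
#' @return A data frame sorted by timestamp with `timestamp` parsed as
#'   `POSIXct` (UTC).
#' @export
read_detections <- function(path) {
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(det, c("tag_id", "node_id", "rss", "timestamp"), path)
  det$timestamp <- as.POSIXct(det$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(det$timestamp))
    stop("unparseable timestamps in ", path, call. = FALSE)
  det[order(det$timestamp), , drop = FALSE]
}

#' Trim the margins of a detection window
#'
#' Stationary calibration tests keep only the central part of each test
#' window so that clock offsets at the start and end do not contaminate the
#' averages: detections within `trim_s` seconds of either end are removed.
#'
#' @param detections Data frame with a `timestamp` column (`POSIXct`).
#' @param window_start,window_end Window bounds (`POSIXct` or anything
#'   coercible).
#' @param trim_s Seconds trimmed from each end; must satisfy
#'   `2 * trim_s <` window length.
#' @return The detections with timestamps in
#'   `[window_start + trim_s, window_end - trim_s]`; an empty result is
#'   valid.
#' @export
trim_window <- function(detections, window_start, window_end, trim_s = 60) {
  window_start <- as.POSIXct(window_start, tz = "UTC")
  window_end <- as.POSIXct(window_end, tz = "UTC")
  if (trim_s < 0) stop("'trim_s' must be non-negative", call. = FALSE)
  len <- as.numeric(difftime(window_end, window_start, units = "secs"))
  if (2 * trim_s >= len)
    stop("window (", len, " s) shorter than twice the trim (", trim_s, " s)",
         call. = FALSE)
  lo <- window_start + trim_s
  hi <- window_end - trim_s
  detections[detections$timestamp >= lo & detections$timestamp <= hi, ,
             drop = FALSE]
}

#' Average detections by node into a localization input
#'
#' One time slice of the pipeline: the (already trimmed) detections of one
#' tag are averaged per node, damping outlier RSS readings caused by signal
#' bounce and multipathing.  Nodes without detections are absent from the
#' result.
#'
#' @param detections Data frame with columns `tag_id`, `node_id`, `rss`.
#' @param tag_id Tag to average; defaults to the single tag present.
#' @param window_start,window_end Window bounds recorded on the result.
#' @return A `"localization_input"`: a data frame with columns `node_id`,
#'   `mean_rss`, `n` and attributes `tag_id`, `window_start`, `window_end`.
#' @examples
#' det <- data.frame(tag_id = "t", node_id = c("A", "A", "B"),
#'                   rss = c(-70, -72, -90),
#'                   timestamp = Sys.time() + 0:2)
#' average_by_node(det)
#' @export
average_by_node <- function(detections, tag_id = NULL,
                            window_start = NULL, window_end = NULL) {
  if (is.null(tag_id)) {
    tags <- unique(detections$tag_id)
    if (length(tags) > 1L)
      stop("multiple tags present; supply 'tag_id'", call. = FALSE)
    tag_id <- if (length(tags)) tags else NA_character_
  } else {
    detections <- detections[detections$tag_id == tag_id, , drop = FALSE]
  }
  if (nrow(detections) == 0L) {
    out <- data.frame(node_id = character(), mean_rss = numeric(),
                      n = integer())
  } else {
    agg <- stats::aggregate(rss ~ node_id, data = detections,
                            FUN = function(v) c(mean(v), length(v)))
    out <- data.frame(node_id = agg$node_id,
                      mean_rss = agg$rss[, 1],
                      n = as.integer(agg$rss[, 2]))
    out <- out[order(out$node_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  localization_input(out, tag_id = tag_id,
                     window_start = window_start, window_end = window_end)
}

#' Construct a localization input
#'
#' A localization input is the unit of estimation: per-node mean RSS values
#' (with detection counts) for one tag in one time window.
#'
#' @param signals Data frame with columns `node_id`, `mean_rss` and
#'   optionally `n` (detection counts, default 1).
#' @param tag_id,window_start,window_end Metadata stored as attributes.
#' @return An object of class `"localization_input"`.
#' @export
localization_input <- function(signals, tag_id = NA_character_,
                               window_start = NULL, window_end = NULL) {
  .require_columns(signals, c("node_id", "mean_rss"), "signals")
  if (is.null(signals$n)) signals$n <- 1L
  if (anyDuplicated(signals$node_id))
    stop("each node may appear at most once in a localization input",
         call. = FALSE)
  if (any(signals$n < 1L))
    stop("detection counts must be >= 1", call. = FALSE)
  structure(signals, class = c("localization_input", "data.frame"),
            tag_id = tag_id, window_start = window_start,
            window_end = window_end)
}

#' @export
print.localization_input <- function(x, ...) {
  cat("Localization input: tag ", attr(x, "tag_id"), ", ",
      nrow(x), " node(s)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Slice a detection log into localization inputs
#'
#' Generalizes the stationary-test protocol to free-moving animals: the log
#' of each tag is cut into fixed windows and averaged per node.  Windows are
#' aligned to the tag's first detection.
#'
#' @param detections Data frame as returned by [read_detections()].
#' @param window_s Window length, seconds (default 60).
#' @param stride_s Stride between window starts, seconds (default 60, i.e.
#'   non-overlapping).
#' @return A list of `"localization_input"` objects (empty windows are
#'   skipped).
#' @export
window_detections <- function(detections, window_s = 60, stride_s = 60) {
  if (window_s <= 0 || stride_s <= 0)
    stop("'window_s' and 'stride_s' must be positive", call. = FALSE)
  out <- list()
  for (tag in unique(detections$tag_id)) {
    det <- detections[detections$tag_id == tag, , drop = FALSE]
    t0 <- min(det$timestamp)
    tmax <- max(det$timestamp)
    starts <- seq(from = 0,
                  to = max(0, as.numeric(difftime(tmax, t0, units = "secs"))),
                  by = stride_s)
    for (s in starts) {
      ws <- t0 + s
      we <- ws + window_s
      sel <- det[det$timestamp >= ws & det$timestamp < we, , drop = FALSE]
      if (nrow(sel) == 0L) next
      out[[length(out) + 1L]] <- average_by_node(sel, tag_id = tag,
                                                 window_start = ws,
                                                 window_end = we)
    }
  }
  out
}

#' Write localization inputs as a tidy CSV
#'
#' @param inputs A list of `"localization_input"` objects.
#' @param path Output CSV path (columns `tag_id`, `window_start`, `node_id`,
#'   `mean_rss`, `n`).
#' @return `path`, invisibly.
#' @export
write_localization_inputs <- function(inputs, path) {
  rows <- lapply(inputs, function(x) {
    if (nrow(x) == 0L) return(NULL)
    data.frame(tag_id = attr(x, "tag_id"),
               window_start = format(attr(x, "window_start"),
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               node_id = x$node_id, mean_rss = x$mean_rss, n = x$n)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s) in ", what, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}
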