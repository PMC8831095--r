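#' Construct a node network
#'
#' A node network is the fixed receiver geometry: node identifiers with
#' planar (projected, metre) coordinates, a nominal average spacing, and the
#' bounding box that defines the network's edges.
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y` (projected
#'   metres, e.g. UTM).
#' @param avg_spacing_m Nominal spacing between neighbouring nodes, metres.
#'   When `NULL` it is estimated as the mean distance from each node to its
#'   six nearest neighbours, the convention for irregular networks.
#' @return An object of class `"node_network"` with elements `nodes`,
#'   `avg_spacing_m` and `extent` (`c(xmin, xmax, ymin, ymax)`).
#' @examples
#' nw <- make_network(spacing_m = 250, extent_m = 1250)
#' nw
#' @export
node_network <- function(nodes, avg_spacing_m = NULL) {
  .require_columns(nodes, c("node_id", "x", "y"), "node table")
  if (anyDuplicated(nodes$node_id))
    stop("node ids must be unique", call. = FALSE)
  if (any(!is.finite(nodes$x)) || any(!is.finite(nodes$y)))
    stop("node coordinates must be finite", call. = FALSE)
  if (nrow(nodes) < 3L)
    stop("a network needs at least 3 nodes", call. = FALSE)
  extent <- c(xmin = min(nodes$x), xmax = max(nodes$x),
              ymin = min(nodes$y), ymax = max(nodes$y))
  if (extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"])
    stop("degenerate network extent: nodes span no area", call. = FALSE)
  if (is.null(avg_spacing_m)) avg_spacing_m <- .mean_knn_spacing(nodes, 6L)
  if (avg_spacing_m <= 0)
    stop("'avg_spacing_m' must be positive", call. = FALSE)
  structure(list(nodes = nodes, avg_spacing_m = avg_spacing_m,
                 extent = extent),
            class = "node_network")
}

.mean_knn_spacing <- function(nodes, k = 6L) {
  D <- as.matrix(stats::dist(cbind(nodes$x, nodes$y)))
  diag(D) <- Inf
  k <- min(k, nrow(nodes) - 1L)
  mean(apply(D, 1L, function(r) mean(sort(r)[seq_len(k)])))
}

#' @export
print.node_network <- function(x, ...) {
  cat("Node network: ", nrow(x$nodes), " nodes, average spacing ",
      round(x$avg_spacing_m, 1), " m\n", sep = "")
  cat(sprintf("  extent: x [%.1f, %.1f], y [%.1f, %.1f] m\n",
              x$extent["xmin"], x$extent["xmax"],
              x$extent["ymin"], x$extent["ymax"]))
  invisible(x)
}

#' @export
plot.node_network <- function(x, ...) {
  graphics::plot(x$nodes$x, x$nodes$y, pch = 8, asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  graphics::rect(x$extent["xmin"], x$extent["ymin"],
                 x$extent["xmax"], x$extent["ymax"], border = "grey60",
                 lty = 2)
  invisible(x)
}

#' Read a node table
#'
#' @param path CSV with columns `node_id`, `x`, `y`.
#' @param avg_spacing_m Optional nominal spacing passed to [node_network()].
#' @return A `"node_network"`.
#' @export
read_nodes <- function(path, avg_spacing_m = NULL) {
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(nodes, c("node_id", "x", "y"), path)
  node_network(nodes, avg_spacing_m = avg_spacing_m)
}

#' Build a simulated node configuration
#'
#' Lays receivers out over a square study area.  The `uniform` layout
#' anchors a regular grid at the origin with `floor(extent/spacing) + 1`
#' nodes per side.  The `random_in_cell` layout emulates an irregular
#' network of the same density: the square is divided into `k x k` equal
#' cells (`k` the uniform grid's side count) and one node is placed
#' uniformly at random inside each cell.
#'
#' @param spacing_m Nominal node spacing, metres (positive, <= `extent_m`).
#' @param extent_m Side length of the square study area, metres
#'   (default 1250).
#' @param layout `"uniform"` or `"random_in_cell"`.
#' @param seed Integer seed for the random layout (ignored for uniform).
#' @return A `"node_network"` whose `avg_spacing_m` is the nominal
#'   `spacing_m`.
#' @examples
#' make_network(250, 1250)                      # 6 x 6 = 36 nodes
#' make_network(175, 1250)                      # 8 x 8 = 64 nodes
#' make_network(250, 1250, "random_in_cell", seed = 1)
#' @export
make_network <- function(spacing_m, extent_m = 1250,
                         layout = c("uniform", "random_in_cell"),
                         seed = NULL) {
  layout <- match.arg(layout)
  if (!is.finite(spacing_m) || spacing_m <= 0)
    stop("'spacing_m' must be positive", call. = FALSE)
  if (spacing_m > extent_m)
    stop("'spacing_m' must not exceed 'extent_m'", call. = FALSE)
  k <- floor(extent_m / spacing_m) + 1L
  if (layout == "uniform") {
    g <- seq(0, by = spacing_m, length.out = k)
    grid <- expand.grid(x = g, y = g)
  } else {
    if (!is.null(seed)) set.seed(seed)
    cell <- extent_m / k
    cells <- expand.grid(cx = seq_len(k) - 1L, cy = seq_len(k) - 1L)
    grid <- data.frame(
      x = (cells$cx + stats::runif(nrow(cells))) * cell,
      y = (cells$cy + stats::runif(nrow(cells))) * cell
    )
  }
  nodes <- data.frame(node_id = sprintf("n%03d", seq_len(nrow(grid))),
                      x = grid$x, y = grid$y)
  nw <- node_network(nodes, avg_spacing_m = spacing_m)
  nw$layout <- layout
  nw$extent_m <- extent_m
  nw
}

#' Sample random test locations
#'
#' Draws locations uniformly over the square study area, reproducibly for a
#' given seed.
#'
#' @param n Number of locations (>= 1).
#' @param extent_m Side length of the square, metres.
#' @param seed Optional integer seed.
#' @return A data frame with columns `loc_id`, `x`, `y`.
#' @export
sample_test_locations <- function(n, extent_m = 1250, seed = NULL) {
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data.frame(loc_id = seq_len(n),
             x = stats::runif(n, 0, extent_m),
             y = stats::runif(n, 0, extent_m))
}
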