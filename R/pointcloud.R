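#' @useDynLib phenocast, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.pc_label_levels <- c("UNCLASSIFIED", "GROUND", "ABOVE_GROUND", "NOISE")

#' Construct a point cloud
#'
#' A `point_cloud` holds x/y/z coordinates in metres (projected CRS) and an
#' optional per-point class label in `UNCLASSIFIED`, `GROUND`,
#' `ABOVE_GROUND`, `NOISE`.
#'
#' @param x,y,z Numeric coordinate vectors of equal length, metres.
#' @param label Optional character vector of per-point class labels.
#' @param crs_note Free-text tag describing the projected CRS.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(c(0, 1), c(0, 0), c(0.2, 0.4))
#' n_points(pc)
#' @export
point_cloud <- function(x, y, z, label = NULL, crs_note = "") {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (n && (anyNA(x) || anyNA(y) || anyNA(z) ||
            any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))))
    stop("point coordinates must be finite")
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != n)
      stop("label must have one entry per point")
    bad <- setdiff(unique(label), .pc_label_levels)
    if (length(bad))
      stop("unknown point labels: ", paste(bad, collapse = ", "))
  }
  structure(list(x = x, y = y, z = z, label = label,
                 crs_note = as.character(crs_note)[1]),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud A `point_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(cloud) length(cloud$x)

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", n_points(x), "points\n")
  if (n_points(x)) {
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
                min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  }
  if (!is.null(x$label))
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$label)),
                                   as.integer(table(x$label))), collapse = " "), "\n")
  if (nzchar(x$crs_note)) cat("  crs:", x$crs_note, "\n")
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  d <- data.frame(x = x$x, y = x$y, z = x$z)
  if (!is.null(x$label)) d$label <- x$label
  d
}

.pc_subset <- function(cloud, keep) {
  point_cloud(cloud$x[keep], cloud$y[keep], cloud$z[keep],
              label = if (!is.null(cloud$label)) cloud$label[keep],
              crs_note = cloud$crs_note)
}

#' Set point labels
#' @param cloud A `point_cloud`.
#' @param label Character vector of labels, recycled if scalar.
#' @return The relabelled cloud.
#' @export
set_labels <- function(cloud, label) {
  if (length(label) == 1L) label <- rep(label, n_points(cloud))
  point_cloud(cloud$x, cloud$y, cloud$z, label = label, crs_note = cloud$crs_note)
}

#' Statistical outlier removal by k-nearest-neighbour distances
#'
#' Neighbourhood thresholding: each point's mean distance to its `k_neighbors`
#' nearest neighbours is computed; points whose mean distance exceeds the
#' global mean by more than `std_multiplier` standard deviations are removed.
#' Point order is preserved (removed points are excised, not relabelled).
#'
#' @param cloud A `point_cloud`.
#' @param k_neighbors Number of neighbours (>= 1); default 8.
#' @param std_multiplier Threshold in standard deviations (> 0); default 3.
#' @return A list with `cloud` (filtered) and `removed_count`.
#' @export
remove_outliers <- function(cloud, k_neighbors = 8, std_multiplier = 3.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (std_multiplier <= 0) stop("std_multiplier must be > 0")
  n <- n_points(cloud)
  if (n <= k_neighbors) {
    warning("cloud has <= k_neighbors points; returned unchanged")
    return(list(cloud = cloud, removed_count = 0L))
  }
  pts <- cbind(cloud$x, cloud$y, cloud$z)
  nn <- FNN::get.knn(pts, k = k_neighbors)
  d <- rowMeans(nn$nn.dist)
  thr <- mean(d) + std_multiplier * stats::sd(d)
  keep <- d <= thr
  list(cloud = .pc_subset(cloud, keep),
       removed_count = as.integer(sum(!keep)))
}

#' Tile a point cloud on a regular grid
#'
#' Tiles form a regular grid over the cloud's xy bounding box. Each tile's
#' cloud contains every point within its bounds expanded by `overlap`; the
#' tile cores (bounds without the overlap margin) partition the bounding box.
#' Cells are half-open on their max edges, so a point on a shared boundary
#' belongs to the tile on the min side; points on the global max edges are
#' assigned to the last tile.
#'
#' @param cloud A `point_cloud`.
#' @param tile_size Tile edge length, metres; must exceed `2 * overlap`.
#' @param overlap Overlap margin, metres (>= 0).
#' @return A list of tiles, each a list with `cloud`, `bounds`,
#'   `core_bounds` (xmin, ymin, xmax, ymax) and `core` (logical: point of
#'   the tile cloud lies in the core).
#' @export
tile_cloud <- function(cloud, tile_size, overlap = 0) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!(tile_size > 2 * overlap) || overlap < 0)
    stop("require tile_size > 2 * overlap >= 0")
  if (n_points(cloud) == 0) return(list())
  x0 <- min(cloud$x); y0 <- min(cloud$y)
  nx <- max(1L, ceiling((max(cloud$x) - x0) / tile_size))
  ny <- max(1L, ceiling((max(cloud$y) - y0) / tile_size))
  ix <- pmin(nx - 1L, floor((cloud$x - x0) / tile_size))
  iy <- pmin(ny - 1L, floor((cloud$y - y0) / tile_size))
  tiles <- list()
  for (j in seq_len(ny) - 1L) {
    for (i in seq_len(nx) - 1L) {
      core <- c(xmin = x0 + i * tile_size, ymin = y0 + j * tile_size,
                xmax = x0 + (i + 1) * tile_size, ymax = y0 + (j + 1) * tile_size)
      bounds <- core + c(-overlap, -overlap, overlap, overlap)
      inb <- cloud$x >= bounds["xmin"] & cloud$x < bounds["xmax"] &
             cloud$y >= bounds["ymin"] & cloud$y < bounds["ymax"]
      # points on the global max edge belong to the last tile's core
      inb <- inb | (ix == i & iy == j)
      if (!any(inb)) next
      tiles[[length(tiles) + 1L]] <- list(
        cloud = .pc_subset(cloud, inb),
        bounds = bounds,
        core_bounds = core,
        core = (ix == i & iy == j)[inb],
        index = which(inb))
    }
  }
  tiles
}
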