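# Ground / above-ground separation by progressive TIN densification (PTD)
# and height normalization against the triangulated ground surface.

.as_cloud <- function(x) {
  if (inherits(x, "point_cloud")) return(x)
  if (is.list(x) && inherits(x$cloud, "point_cloud")) return(x$cloud)
  stop("expected a point_cloud or a tile")
}

.delaunay_xy <- function(x, y) {
  tm <- tryCatch(interp::tri.mesh(x, y),
                 error = function(e) stop("triangulation error: ", conditionMessage(e),
                                          call. = FALSE))
  tr <- interp::triangles(tm)
  list(x = tm$x, y = tm$y, triangles = unname(tr[, 1:3, drop = FALSE]))
}

#' Select seed ground points on a coarse grid
#'
#' For each `seed_grid` x `seed_grid` cell of the tile that contains at
#' least one point, the lowest-z point is selected (ties broken by smallest
#' point index). These seeds initialize progressive TIN densification.
#'
#' @param tile A tile from [tile_cloud()] or a bare `point_cloud`.
#' @param seed_grid Cell size in metres (> 0).
#' @return Integer indices of seed points within the tile's cloud.
#' @export
select_seeds <- function(tile, seed_grid) {
  cloud <- .as_cloud(tile)
  if (seed_grid <= 0) stop("seed_grid must be > 0")
  if (n_points(cloud) == 0) stop("tile is empty")
  if (is.list(tile) && !is.null(tile$bounds)) {
    x0 <- tile$bounds[["xmin"]]; y0 <- tile$bounds[["ymin"]]
  } else {
    x0 <- min(cloud$x); y0 <- min(cloud$y)
  }
  ix <- floor((cloud$x - x0) / seed_grid)
  iy <- floor((cloud$y - y0) / seed_grid)
  cell <- paste(ix, iy)
  ord <- order(cell, cloud$z, seq_along(cell))
  sort(ord[!duplicated(cell[ord])])
}

# Distance and angle of points against the facets of a ground TIN.
# The perpendicular distance is measured to the containing facet; the angle
# criterion uses the segment from the point to the nearest vertex of the
# (full) accepted ground set, which blocks points hovering above ground.
# Points outside the current hull are assessed against their nearest ground
# vertex (vertical offset and segment angle), so border ground points can
# still densify the surface.
.ptd_criteria <- function(verts, triangles, ground_pts, px, py, pz) {
  loc <- .locate_points_cpp(verts[, 1], verts[, 2], triangles, px, py)
  n <- length(px)
  dist <- rep(NA_real_, n)
  inside <- loc$tri > 0L
  nn <- FNN::get.knnx(ground_pts, cbind(px, py, pz), k = 1)
  seg <- nn$nn.dist[, 1]
  if (any(inside)) {
    t3 <- triangles[loc$tri[inside], , drop = FALSE]
    v1 <- verts[t3[, 1], , drop = FALSE]
    v2 <- verts[t3[, 2], , drop = FALSE]
    v3 <- verts[t3[, 3], , drop = FALSE]
    e1 <- v2 - v1; e2 <- v3 - v1
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    nrm <- sqrt(nx^2 + ny^2 + nz^2)
    dx <- px[inside] - v1[, 1]; dy <- py[inside] - v1[, 2]; dz <- pz[inside] - v1[, 3]
    dist[inside] <- abs(nx * dx + ny * dy + nz * dz) / nrm
  }
  if (any(!inside)) {
    vi <- nn$nn.index[!inside, 1]
    dist[!inside] <- abs(pz[!inside] - ground_pts[vi, 3])
  }
  sina <- ifelse(seg < 1e-12, 0, pmin(1, dist / seg))
  list(dist = dist, angle = asin(sina) * 180 / pi)
}

#' Classify ground points by progressive TIN densification
#'
#' Starting from seed ground points, a Delaunay TIN is built and every
#' unclassified point is accepted as ground when its perpendicular distance
#' to the containing facet is at most `max_dist` and the angle between the
#' facet plane and the segment to the facet's nearest vertex is at most
#' `max_angle` degrees. The TIN is rebuilt and the test repeated until no
#' point is added or `max_iters` is reached. Points outside the current hull
#' are assessed against the nearest TIN vertex so the surface can grow to
#' the tile border. Remaining points are labelled `ABOVE_GROUND`.
#'
#' For speed the working TIN of each iteration is built on a spatially
#' thinned ground set (lowest accepted point per `tin_thin` cell); the full
#' accepted ground set is what the function labels, and [build_ground_tin()]
#' triangulates all ground points afterwards. Set `tin_thin = 0` to
#' densify against the unthinned TIN.
#'
#' @param tile A tile from [tile_cloud()] or a bare `point_cloud`.
#' @param seeds Integer indices of seed points (>= 3, non-collinear).
#' @param max_dist Maximum perpendicular distance to the facet, metres
#'   (default 0.05: above the ground micro-relief but below the foliage
#'   base of young vegetable plants).
#' @param max_angle Maximum point-to-facet angle, degrees (0, 90).
#' @param max_iters Iteration cap.
#' @param tin_thin Working-TIN thinning cell size, metres (0 disables).
#' @return Character label vector (`GROUND` / `ABOVE_GROUND`) over all
#'   points of the tile's cloud.
#' @export
classify_ground_ptd <- function(tile, seeds, max_dist = 0.05, max_angle = 30,
                                max_iters = 50, tin_thin = 0.2) {
  cloud <- .as_cloud(tile)
  n <- n_points(cloud)
  if (length(seeds) < 3) stop("need at least 3 seed points")
  if (max_dist <= 0) stop("max_dist must be > 0")
  if (max_angle <= 0 || max_angle >= 90) stop("max_angle must be in (0, 90)")
  ground <- logical(n)
  ground[seeds] <- TRUE
  for (iter in seq_len(max_iters)) {
    idx <- which(!ground)
    if (!length(idx)) break
    gi <- which(ground)
    ord <- gi[order(cloud$z[gi])]
    if (tin_thin > 0) {
      # lowest accepted point per thinning cell carries the working TIN
      cell <- paste(floor(cloud$x[ord] / tin_thin), floor(cloud$y[ord] / tin_thin))
      keep <- ord[!duplicated(cell)]
    } else {
      # keep the lowest point of any xy-duplicate pair for the triangulation
      keep <- ord[!duplicated(cbind(cloud$x[ord], cloud$y[ord]))]
    }
    tin <- .delaunay_xy(cloud$x[keep], cloud$y[keep])
    vm <- match(paste(tin$x, tin$y), paste(cloud$x[keep], cloud$y[keep]))
    verts <- cbind(tin$x, tin$y, cloud$z[keep][vm])
    cr <- .ptd_criteria(verts, tin$triangles,
                        cbind(cloud$x[gi], cloud$y[gi], cloud$z[gi]),
                        cloud$x[idx], cloud$y[idx], cloud$z[idx])
    accept <- cr$dist <= max_dist & cr$angle <= max_angle
    if (!any(accept)) break
    ground[idx[accept]] <- TRUE
  }
  ifelse(ground, "GROUND", "ABOVE_GROUND")
}

#' Build a ground TIN from classified points
#'
#' Delaunay triangulation (in the xy plane) of all `GROUND`-labelled points.
#'
#' @param cloud A labelled `point_cloud` with >= 3 non-collinear ground points.
#' @return An object of class `ground_tin` with `vertices` (n x 3 matrix)
#'   and `triangles` (m x 3 vertex-index matrix).
#' @export
build_ground_tin <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$label)) stop("cloud has no labels; run classify_ground_ptd first")
  gi <- which(cloud$label == "GROUND")
  if (length(gi) < 3) stop("need at least 3 GROUND points to build a TIN")
  ord <- gi[order(cloud$z[gi])]
  keep <- ord[!duplicated(cbind(cloud$x[ord], cloud$y[ord]))]
  tin <- .delaunay_xy(cloud$x[keep], cloud$y[keep])
  vm <- match(paste(tin$x, tin$y), paste(cloud$x[keep], cloud$y[keep]))
  structure(list(vertices = cbind(x = tin$x, y = tin$y, z = cloud$z[keep][vm]),
                 triangles = tin$triangles),
            class = "ground_tin")
}

#' @export
print.ground_tin <- function(x, ...) {
  cat("ground_tin:", nrow(x$vertices), "vertices,", nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Interpolate ground elevation from a TIN
#'
#' Barycentric interpolation of the containing triangle's vertex elevations;
#' exact for planar surfaces. Queries outside the convex hull return the
#' elevation of the nearest TIN vertex and are flagged as extrapolated.
#'
#' @param tin A `ground_tin`.
#' @param x,y Query coordinates, metres.
#' @return A list with numeric `z` and logical `extrapolated`.
#' @export
ground_elevation <- function(tin, x, y) {
  stopifnot(inherits(tin, "ground_tin"))
  loc <- .locate_points_cpp(tin$vertices[, 1], tin$vertices[, 2], tin$triangles, x, y)
  z <- rep(NA_real_, length(x))
  inside <- loc$tri > 0L
  if (any(inside)) {
    t3 <- tin$triangles[loc$tri[inside], , drop = FALSE]
    z[inside] <- loc$b1[inside] * tin$vertices[t3[, 1], 3] +
                 loc$b2[inside] * tin$vertices[t3[, 2], 3] +
                 loc$b3[inside] * tin$vertices[t3[, 3], 3]
  }
  if (any(!inside)) {
    nn <- FNN::get.knnx(tin$vertices[, 1:2, drop = FALSE],
                        cbind(x[!inside], y[!inside]), k = 1)
    z[!inside] <- tin$vertices[nn$nn.index[, 1], 3]
  }
  list(z = z, extrapolated = !inside)
}

#' Normalize point heights to the ground surface
#'
#' Replaces each point's z by its height above the TIN-interpolated ground
#' elevation (the furrow-level datum). Negative heights, which arise from
#' sensor noise below the fitted surface, are clamped to zero and counted.
#'
#' @param cloud A `point_cloud`.
#' @param tin A `ground_tin`.
#' @return The normalized `point_cloud`; the number of clamped points is
#'   reported via `message()` and attached as attribute `clamped`.
#' @export
normalize_heights <- function(cloud, tin) {
  stopifnot(inherits(cloud, "point_cloud"))
  g <- ground_elevation(tin, cloud$x, cloud$y)
  h <- cloud$z - g$z
  clamped <- sum(h < 0)
  if (clamped > 0) {
    message("normalize_heights: clamped ", clamped, " negative heights to 0")
    h[h < 0] <- 0
  }
  out <- point_cloud(cloud$x, cloud$y, h, label = cloud$label,
                     crs_note = cloud$crs_note)
  attr(out, "clamped") <- as.integer(clamped)
  out
}
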