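# Canopy height model raster: south-west origin, row 1 is the southernmost
# row, cells are half-open [x0 + j*res, x0 + (j+1)*res) x [y0 + i*res, ...).
# Nodata is NA internally and -1.0 at the file boundary.

#' Construct a CHM raster
#'
#' @param values Numeric matrix of canopy heights (rows x cols), row 1
#'   southernmost; `NA` marks nodata.
#' @param origin Numeric (x0, y0), the south-west corner in metres.
#' @param resolution Cell size in metres (> 0).
#' @param crs_note Free-text projected-CRS tag.
#' @return An object of class `chm_raster`.
#' @export
chm_raster <- function(values, origin, resolution, crs_note = "") {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (resolution <= 0) stop("resolution must be > 0")
  if (any(values < 0, na.rm = TRUE)) stop("canopy heights must be >= 0")
  structure(list(values = values, origin = as.numeric(origin)[1:2],
                 resolution = as.numeric(resolution), crs_note = crs_note),
            class = "chm_raster")
}

#' @export
print.chm_raster <- function(x, ...) {
  cat(sprintf("chm_raster: %d x %d cells @ %.3g m, origin (%.2f, %.2f)\n",
              nrow(x$values), ncol(x$values), x$resolution,
              x$origin[1], x$origin[2]))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  heights: [%.3f, %.3f] m, %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

# cell centre coordinates of given (row, col)
.cell_center <- function(chm, row, col) {
  cbind(x = chm$origin[1] + (col - 0.5) * chm$resolution,
        y = chm$origin[2] + (row - 0.5) * chm$resolution)
}

#' Rasterize a normalized point cloud into a CHM
#'
#' Each cell takes the maximum normalized height among its `ABOVE_GROUND`
#' points (unlabelled points count as above-ground); cells containing only
#' `GROUND` points are 0; cells with no points are nodata. Points on the
#' extent's max edges fall into the last row/column.
#'
#' @param cloud A height-normalized `point_cloud`.
#' @param resolution Cell size, metres (> 0).
#' @param extent Optional bounds (xmin, ymin, xmax, ymax); defaults to the
#'   cloud's xy bounding box.
#' @return A [chm_raster()].
#' @export
rasterize_chm <- function(cloud, resolution, extent = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (resolution <= 0) stop("resolution must be > 0")
  if (n_points(cloud) == 0) stop("cannot rasterize an empty cloud")
  if (is.null(extent))
    extent <- c(min(cloud$x), min(cloud$y), max(cloud$x), max(cloud$y))
  x0 <- extent[1]; y0 <- extent[2]
  nc <- max(1L, ceiling((extent[3] - x0) / resolution))
  nr <- max(1L, ceiling((extent[4] - y0) / resolution))
  inb <- cloud$x >= x0 & cloud$y >= y0 &
         cloud$x <= x0 + nc * resolution & cloud$y <= y0 + nr * resolution
  col <- pmin(nc - 1L, floor((cloud$x[inb] - x0) / resolution))
  row <- pmin(nr - 1L, floor((cloud$y[inb] - y0) / resolution))
  lin <- row + nr * col + 1
  vals <- matrix(NA_real_, nr, nc)
  lab <- if (is.null(cloud$label)) rep("ABOVE_GROUND", sum(inb)) else cloud$label[inb]
  gnd <- lab == "GROUND"
  if (any(gnd)) vals[unique(lin[gnd])] <- 0
  ag <- lab == "ABOVE_GROUND"
  if (any(ag)) {
    mx <- tapply(cloud$z[inb][ag], lin[ag], max)
    cells <- as.integer(names(mx))
    vals[cells] <- pmax(as.numeric(mx), vals[cells], na.rm = TRUE)
  }
  vals[vals < 0] <- 0
  chm_raster(vals, c(x0, y0), resolution, crs_note = cloud$crs_note)
}

#' Fill isolated nodata cells in a CHM
#'
#' Single-pass median filling: a nodata cell whose `window` x `window`
#' neighbourhood (centre excluded) has at least half of its cells valid is
#' replaced by the median of those neighbours. Applied once, so large
#' nodata blocks keep their interior.
#'
#' @param chm A `chm_raster`.
#' @param window Odd window size >= 3 (cells).
#' @return The filled `chm_raster`.
#' @export
fill_chm_gaps <- function(chm, window = 3) {
  stopifnot(inherits(chm, "chm_raster"))
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  v <- chm$values
  nr <- nrow(v); nc <- ncol(v)
  h <- (window - 1) / 2
  need <- ceiling((window^2 - 1) / 2)
  na_idx <- which(is.na(v), arr.ind = TRUE)
  if (!nrow(na_idx)) return(chm)
  cnt <- matrix(0L, nr, nc)
  for (di in -h:h) for (dj in -h:h) {
    if (di == 0 && dj == 0) next
    sr <- max(1, 1 - di):min(nr, nr - di)
    sc <- max(1, 1 - dj):min(nc, nc - dj)
    cnt[sr, sc] <- cnt[sr, sc] + !is.na(v[sr + di, sc + dj])
  }
  fill <- na_idx[cnt[na_idx] >= need, , drop = FALSE]
  if (!nrow(fill)) return(chm)
  offs <- expand.grid(di = -h:h, dj = -h:h)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  nb <- matrix(NA_real_, nrow(fill), nrow(offs))
  for (k in seq_len(nrow(offs))) {
    ri <- fill[, 1] + offs$di[k]
    ci <- fill[, 2] + offs$dj[k]
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    nb[ok, k] <- v[cbind(ri[ok], ci[ok])]
  }
  med <- apply(nb, 1, stats::median, na.rm = TRUE)
  out <- v
  out[fill] <- med
  chm_raster(out, chm$origin, chm$resolution, chm$crs_note)
}

#' Median-smooth a CHM
#'
#' Replaces every valid cell by the median of the valid cells in its
#' `window` x `window` neighbourhood (nodata cells stay nodata). Standard
#' preparation before local-maxima search: isolated one- or two-cell noise
#' bumps, e.g. from residual outlier returns, disappear while broad crown
#' shapes are preserved.
#'
#' @param chm A `chm_raster`.
#' @param window Odd window size >= 3.
#' @return The smoothed `chm_raster`.
#' @export
smooth_chm <- function(chm, window = 3) {
  stopifnot(inherits(chm, "chm_raster"))
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  chm_raster(.median_filter_cpp(chm$values, as.integer(window)),
             chm$origin, chm$resolution, chm$crs_note)
}

#' Write a CHM to TIFF + world file, or CSV
#'
#' The raster is written north-up as a single-band 16-bit TIFF holding
#' heights in millimetres (the sensor-noise scale; 65535 marks nodata),
#' with an ESRI world file (`.tfw`) carrying the georeferencing.
#' `format = "csv"` writes the exact value grid (row 1 southernmost, nodata
#' -1) with origin/resolution header comments.
#'
#' @param chm A `chm_raster`.
#' @param path Output path.
#' @param format `"tiff"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_chm <- function(chm, path, format = c("tiff", "csv")) {
  stopifnot(inherits(chm, "chm_raster"))
  format <- match.arg(format)
  v <- chm$values
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# origin %.10g %.10g", chm$origin[1], chm$origin[2]),
                 sprintf("# resolution %.10g", chm$resolution),
                 "# nodata -1"), con)
    v[is.na(v)] <- -1
    utils::write.table(v, con, sep = ",", row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  mm <- pmin(round(v * 1000), 65534)
  mm[is.na(mm)] <- 65535
  img <- mm[rev(seq_len(nrow(mm))), , drop = FALSE]  # north-up for the image
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  res <- chm$resolution
  tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  if (identical(tfw, path)) tfw <- paste0(path, ".tfw")
  top_center_y <- chm$origin[2] + (nrow(v) - 0.5) * res
  writeLines(format(c(res, 0, 0, -res,
                      chm$origin[1] + 0.5 * res, top_center_y),
                    digits = 15), tfw)
  invisible(path)
}

#' Read a CHM written by [write_chm()]
#'
#' @param path TIFF (with sibling `.tfw`) or CSV path.
#' @param format `"auto"`, `"tiff"` or `"csv"`.
#' @return A [chm_raster()].
#' @export
read_chm <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "tiff", "csv"))
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tiff"
  if (format == "csv") {
    hdr <- readLines(path, n = 3)
    origin <- as.numeric(strsplit(hdr[1], " ")[[1]][3:4])
    res <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
    v <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#"))
    dimnames(v) <- NULL
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img[img == 65535] <- NA_integer_
    img <- img / 1000
    v <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
    if (identical(tfw, path)) tfw <- paste0(path, ".tfw")
    if (!file.exists(tfw)) stop("world file not found: ", tfw)
    w <- as.numeric(readLines(tfw))
    res <- w[1]
    origin <- c(w[5] - 0.5 * res, (w[6] + 0.5 * res) - nrow(v) * res)
  }
  v[!is.na(v) & v < 0] <- NA_real_
  chm_raster(v, origin, res)
}
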