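# Crown-top detection (variable window filter), marker-controlled watershed
# delineation, segment pruning and per-plant structural records.

#' Detect plant crown tops with a variable window filter
#'
#' A cell is a crown top iff its height is at least `min_height` and no
#' other valid cell within the height-adaptive radius
#' `r(h) = max(radius_intercept, radius_slope * h)` of its centre is higher;
#' among exactly tied cells only the first in row-major order is kept.
#'
#' @param chm A [chm_raster()].
#' @param radius_intercept Minimum window radius, metres (>= one cell).
#' @param radius_slope Unitless slope of the radius law (>= 0).
#' @param min_height Minimum crown-top height, metres (> 0).
#' @return A data frame of crown tops: `row`, `col` (cell indices), `x`,
#'   `y` (cell centres, m), `height` (m).
#' @export
detect_crown_tops <- function(chm, radius_intercept = 0.10, radius_slope = 0.3,
                              min_height = 0.10) {
  stopifnot(inherits(chm, "chm_raster"))
  if (radius_intercept < chm$resolution)
    stop("radius_intercept must be at least one cell size")
  if (radius_slope < 0) stop("radius_slope must be >= 0")
  if (min_height <= 0) stop("min_height must be > 0")
  rc <- .vwf_cpp(chm$values, chm$resolution, radius_intercept, radius_slope,
                 min_height)
  if (!nrow(rc))
    return(data.frame(row = integer(), col = integer(), x = numeric(),
                      y = numeric(), height = numeric()))
  ctr <- .cell_center(chm, rc[, 1], rc[, 2])
  data.frame(row = rc[, 1], col = rc[, 2], x = ctr[, "x"], y = ctr[, "y"],
             height = chm$values[rc])
}

#' Delineate crowns by marker-controlled watershed
#'
#' Runs a watershed on the negated CHM restricted to the canopy mask
#' `CHM >= min_height`, with one marker per crown top. Every labelled
#' region is connected and contains its marker; mask components containing
#' no marker stay background (label 0).
#'
#' @param chm A [chm_raster()].
#' @param tops Crown tops from [detect_crown_tops()]; non-empty.
#' @param min_height Canopy mask threshold, metres.
#' @return A `label_raster`: same geometry as `chm`, integer labels
#'   (0 = background, k = crown of `tops[k, ]`).
#' @export
segment_crowns <- function(chm, tops, min_height = 0.10) {
  stopifnot(inherits(chm, "chm_raster"))
  if (!nrow(tops)) stop("tops must be non-empty")
  v <- chm$values
  v[!is.na(v) & v < min_height] <- NA_real_
  top_cells <- cbind(tops$row, tops$col)
  if (any(is.na(v[top_cells])))
    stop("crown top outside the canopy mask; inconsistent inputs")
  markers <- matrix(0L, nrow(v), ncol(v))
  markers[top_cells] <- seq_len(nrow(tops))
  lab <- .watershed_cpp(v, markers, TRUE)
  structure(list(values = lab, origin = chm$origin,
                 resolution = chm$resolution, crs_note = chm$crs_note),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  k <- setdiff(unique(as.vector(x$values)), 0L)
  cat(sprintf("label_raster: %d x %d cells, %d segments\n",
              nrow(x$values), ncol(x$values), length(k)))
  invisible(x)
}

#' Remove segments without a crown top
#'
#' Segments that contain no crown top are set to background; the survivors
#' are renumbered 1..K in crown-top order.
#'
#' @param labels A `label_raster` from [segment_crowns()].
#' @param tops The crown-top data frame.
#' @return The pruned `label_raster`.
#' @export
prune_segments <- function(labels, tops) {
  stopifnot(inherits(labels, "label_raster"))
  v <- labels$values
  top_labels <- v[cbind(tops$row, tops$col)]
  keep <- unique(top_labels[top_labels > 0])
  remap <- integer(max(v, 1L))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(v), ncol(v))
  nz <- v > 0L
  out[nz] <- remap[v[nz]]
  structure(list(values = out, origin = labels$origin,
                 resolution = labels$resolution, crs_note = labels$crs_note),
            class = "label_raster")
}

#' Extract per-plant structural records
#'
#' Per segment: height is the maximum CHM value inside the segment,
#' crown area is cell count times squared resolution, and the centroid is
#' the mean of the segment's cell centres.
#'
#' With `edge_correction = "half-boundary"` the cells on a segment's
#' boundary (8-neighbour to a different label or to background) count half
#' a cell each, removing the first-order perimeter bias of rasterized
#' areas; the default `"none"` is the plain cell count.
#'
#' @param labels A pruned `label_raster`.
#' @param chm The matching [chm_raster()] (same geometry).
#' @param tops Crown tops (kept for provenance; unused fields tolerated).
#' @param date_index Ordinal growth stage to stamp on the records.
#' @param edge_correction `"none"` or `"half-boundary"` (area only).
#' @return A data frame with `plant_id`, `date_index`, `height`,
#'   `crown_area`, `centroid_x`, `centroid_y`.
#' @export
extract_plant_records <- function(labels, chm, tops = NULL, date_index = 1L,
                                  edge_correction = c("none", "half-boundary")) {
  edge_correction <- match.arg(edge_correction)
  stopifnot(inherits(labels, "label_raster"), inherits(chm, "chm_raster"))
  if (!all(dim(labels$values) == dim(chm$values)) ||
      labels$resolution != chm$resolution)
    stop("labels and chm must share geometry")
  lv <- labels$values
  ids <- sort(setdiff(unique(as.vector(lv)), 0L))
  if (!length(ids))
    return(data.frame(plant_id = integer(), date_index = integer(),
                      height = numeric(), crown_area = numeric(),
                      centroid_x = numeric(), centroid_y = numeric()))
  cells <- which(lv > 0L, arr.ind = TRUE)
  seg <- factor(lv[cells], levels = ids)
  hts <- chm$values[cells]
  ctr <- .cell_center(chm, cells[, 1], cells[, 2])
  if (edge_correction == "half-boundary") {
    nr <- nrow(lv); nc <- ncol(lv)
    pad <- matrix(0L, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- lv
    boundary <- rep(FALSE, nrow(cells))
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pad[cbind(cells[, 1] + 1 + di, cells[, 2] + 1 + dj)]
      boundary <- boundary | nb != lv[cells]
    }
    wts <- ifelse(boundary, 0.5, 1)
    area <- as.numeric(tapply(wts, seg, sum)) * chm$resolution^2
  } else {
    area <- as.numeric(table(seg)) * chm$resolution^2
  }
  data.frame(
    plant_id = ids,
    date_index = as.integer(date_index),
    height = as.numeric(tapply(hts, seg, max, na.rm = TRUE)),
    crown_area = area,
    centroid_x = as.numeric(tapply(ctr[, "x"], seg, mean)),
    centroid_y = as.numeric(tapply(ctr[, "y"], seg, mean)))
}

#' Match plant records across acquisition dates
#'
#' Greedy nearest-centroid matching between consecutive dates under a
#' maximum shift (plants do not move). Records that cannot be chained
#' through every date are dropped with a reported count.
#'
#' @param records_by_date A list of per-date record data frames (>= 2),
#'   ordered by date.
#' @param max_shift Maximum centroid displacement between dates, metres.
#' @return A single data frame of matched records with a consistent
#'   `plant_id` (series id) and one row per (plant, date), ordered by
#'   `plant_id` then `date_index`.
#' @export
match_plants_across_dates <- function(records_by_date, max_shift = 0.3) {
  if (length(records_by_date) < 2) stop("need records for at least 2 dates")
  chains <- lapply(seq_len(nrow(records_by_date[[1]])), function(i) i)
  for (t in seq_len(length(records_by_date) - 1)) {
    a <- records_by_date[[t]]; b <- records_by_date[[t + 1]]
    ends <- vapply(chains, function(ch) ch[length(ch)], 0L)
    live <- !is.na(ends)
    if (!any(live) || !nrow(b)) { chains <- lapply(chains, function(ch) c(ch, NA_integer_)); next }
    pa <- cbind(a$centroid_x[ends[live]], a$centroid_y[ends[live]])
    pb <- cbind(b$centroid_x, b$centroid_y)
    d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
    cand <- which(d <= max_shift, arr.ind = TRUE)
    cand <- cand[order(d[cand]), , drop = FALSE]
    ai_used <- logical(nrow(pa)); bi_used <- logical(nrow(pb))
    nxt <- rep(NA_integer_, length(chains))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (ai_used[i] || bi_used[j]) next
      ai_used[i] <- TRUE; bi_used[j] <- TRUE
      nxt[which(live)[i]] <- j
    }
    chains <- lapply(seq_along(chains), function(q) c(chains[[q]], nxt[q]))
  }
  complete <- vapply(chains, function(ch) !anyNA(ch), TRUE)
  n_total <- sum(vapply(records_by_date, nrow, 0L))
  n_kept <- sum(complete) * length(records_by_date)
  if (n_total > n_kept)
    message("match_plants_across_dates: dropped ", n_total - n_kept,
            " records not matched across all dates")
  chains <- chains[complete]
  if (!length(chains))
    return(data.frame(plant_id = integer(), date_index = integer(),
                      height = numeric(), crown_area = numeric(),
                      centroid_x = numeric(), centroid_y = numeric()))
  out <- do.call(rbind, lapply(seq_along(chains), function(q) {
    rows <- do.call(rbind, lapply(seq_along(records_by_date), function(t) {
      r <- records_by_date[[t]][chains[[q]][t], ]
      r$plant_id <- q
      r
    }))
    rows
  }))
  rownames(out) <- NULL
  out[order(out$plant_id, out$date_index), ]
}

#' Write plant records to CSV
#' @param records Record data frame from [extract_plant_records()] or
#'   [match_plants_across_dates()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_plant_records <- function(records, path) {
  n <- nrow(records)
  out <- data.frame(plant_id = records$plant_id,
                    date_index = records$date_index,
                    height_m = records$height,
                    crown_area_m2 = records$crown_area,
                    centroid_x = if (is.null(records$centroid_x))
                      rep(NA_real_, n) else records$centroid_x,
                    centroid_y = if (is.null(records$centroid_y))
                      rep(NA_real_, n) else records$centroid_y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a label raster to TIFF + world file
#'
#' Plant labels are stored as 16-bit integers (0 = background) north-up,
#' with an ESRI world file for the georeferencing.
#'
#' @param labels A `label_raster`.
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_label_raster <- function(labels, path) {
  stopifnot(inherits(labels, "label_raster"))
  chm <- chm_raster(labels$values / 1000, labels$origin, labels$resolution)
  write_chm(chm, path, format = "tiff")
}

#' Read a label raster written by [write_label_raster()]
#' @param path TIFF path (with sibling `.tfw`).
#' @return A `label_raster`.
#' @export
read_label_raster <- function(path) {
  chm <- read_chm(path, format = "tiff")
  v <- chm$values * 1000
  v[is.na(v)] <- 0
  structure(list(values = matrix(as.integer(round(v)), nrow(v), ncol(v)),
                 origin = chm$origin, resolution = chm$resolution,
                 crs_note = ""),
            class = "label_raster")
}

#' Read plant records written by [write_plant_records()]
#' @param path CSV path.
#' @return A record data frame with the internal column names.
#' @export
read_plant_records <- function(path) {
  d <- utils::read.csv(path)
  data.frame(plant_id = d$plant_id, date_index = d$date_index,
             height = d$height_m, crown_area = d$crown_area_m2,
             centroid_x = d$centroid_x, centroid_y = d$centroid_y)
}
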