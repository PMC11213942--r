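# End-to-end structural-parameter extraction: outlier removal -> tiling ->
# PTD ground classification -> height normalization -> CHM -> crown tops ->
# watershed crowns -> per-plant records -> cross-date matching.

#' Default extraction parameters
#'
#' Defaults are sized for short vegetable crops (0.1-1 m): 1 m PTD seed
#' grid (about one planting spacing), 0.05 m facet distance (above ground
#' micro-relief, below the foliage base of young plants), 30 degree facet
#' angle, 0.008 m CHM resolution, median smoothing before top detection,
#' a 0.10 m canopy threshold and a 10 cm2 minimum segment area.
#'
#' @return A named list of parameters accepted by [extract_plant_parameters()].
#' @export
extraction_params <- function() {
  list(knn_k = 8, knn_mult = 3.0,
       tile_size = 50, tile_overlap = 1,
       seed_grid = 1.0, max_dist = 0.05, max_angle = 30, max_iters = 50,
       tin_thin = 0.2,
       resolution = 0.008, fill_window = 3, smooth_window = 3,
       radius_intercept = 0.10, radius_slope = 0.3, min_height = 0.10,
       edge_correction = "half-boundary", min_segment_area = 0.001,
       max_shift = 0.3)
}

# classify one cloud tile-by-tile; returns the full label vector
.classify_cloud <- function(cloud, par) {
  tiles <- tile_cloud(cloud, par$tile_size, par$tile_overlap)
  labels <- rep("ABOVE_GROUND", n_points(cloud))
  for (tl in tiles) {
    seeds <- select_seeds(tl, par$seed_grid)
    if (length(seeds) < 3) {
      warning("tile skipped: fewer than 3 seed ground points")
      next
    }
    lab <- tryCatch(
      classify_ground_ptd(tl, seeds, par$max_dist, par$max_angle,
                          par$max_iters, par$tin_thin),
      error = function(e) {
        warning("tile skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(lab)) next
    labels[tl$index[tl$core]] <- lab[tl$core]
  }
  labels
}

#' Extract per-plant structural records from multi-date point clouds
#'
#' Runs the full geometry pipeline on each date's cloud and, when more than
#' one date is given, matches the plants across dates by centroid.
#'
#' @param clouds A list of `point_cloud`s ordered by acquisition date (or a
#'   single cloud).
#' @param params Parameter list as from [extraction_params()]; entries can
#'   be overridden selectively.
#' @param date_indices Ordinal stage of each cloud (default `1:n`).
#' @return A list with `records_by_date`, `matched` (cross-date series,
#'   `NULL` for a single date), `chm` (per-date [chm_raster()]s) and
#'   `labels` (per-date label rasters).
#' @export
extract_plant_parameters <- function(clouds, params = list(),
                                     date_indices = NULL) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  if (!length(clouds)) stop("no point clouds supplied")
  par <- utils::modifyList(extraction_params(), params)
  if (is.null(date_indices)) date_indices <- seq_along(clouds)
  records <- chms <- labs <- vector("list", length(clouds))
  for (t in seq_along(clouds)) {
    cloud <- clouds[[t]]
    if (n_points(cloud) == 0) stop("empty point cloud at date ", t)
    cloud <- remove_outliers(cloud, par$knn_k, par$knn_mult)$cloud
    cloud <- set_labels(cloud, .classify_cloud(cloud, par))
    tin <- build_ground_tin(cloud)
    norm <- normalize_heights(cloud, tin)
    chm <- fill_chm_gaps(rasterize_chm(norm, par$resolution), par$fill_window)
    if (par$smooth_window >= 3) chm <- smooth_chm(chm, par$smooth_window)
    tops <- detect_crown_tops(chm, par$radius_intercept, par$radius_slope,
                              par$min_height)
    if (!nrow(tops)) {
      records[[t]] <- data.frame(plant_id = integer(), date_index = integer(),
                                 height = numeric(), crown_area = numeric(),
                                 centroid_x = numeric(), centroid_y = numeric())
      chms[[t]] <- chm
      next
    }
    seg <- prune_segments(segment_crowns(chm, tops, par$min_height), tops)
    rec <- extract_plant_records(seg, chm, tops, date_indices[t],
                                 edge_correction = par$edge_correction)
    small <- rec$crown_area < par$min_segment_area
    if (any(small)) {
      message("date ", t, ": dropped ", sum(small),
              " segments below the minimum crown area")
      rec <- rec[!small, , drop = FALSE]
    }
    records[[t]] <- rec
    chms[[t]] <- chm
    labs[[t]] <- seg
  }
  matched <- if (length(clouds) >= 2)
    match_plants_across_dates(records, par$max_shift)
  list(records_by_date = records, matched = matched, chm = chms, labels = labs)
}
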