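# a radially symmetric crown bump on a raster, centred at (cx, cy) metres
bump_raster <- function(nr, nc, res, peaks, base = NA_real_) {
  v <- matrix(base, nr, nc)
  xc <- (col(v) - 0.5) * res
  yc <- (row(v) - 0.5) * res
  for (p in peaks) {
    d2 <- (xc - p$x)^2 + (yc - p$y)^2
    hb <- p$h * pmax(0, 1 - d2 / p$r^2)
    v <- ifelse(is.na(v), ifelse(hb > 0, hb, v), pmax(v, hb))
  }
  chm_raster(v, c(0, 0), res)
}

test_that("variable window filter finds isolated crown tops", {
  chm <- bump_raster(40, 40, 0.1, list(list(x = 2, y = 2, h = 0.6, r = 1)))
  tops <- detect_crown_tops(chm, 0.2, 0.3, 0.1)
  expect_equal(nrow(tops), 1)
  expect_equal(chm$values[tops$row[1], tops$col[1]], max(chm$values, na.rm = TRUE))

  two <- bump_raster(40, 40, 0.1, list(list(x = 1.3, y = 2, h = 0.6, r = 0.7),
                                       list(x = 3.3, y = 2, h = 0.5, r = 0.7)))
  tops2 <- detect_crown_tops(two, 0.2, 0.8, 0.1)
  expect_equal(nrow(tops2), 2)

  flat <- chm_raster(matrix(0.05, 20, 20), c(0, 0), 0.1)
  expect_equal(nrow(detect_crown_tops(flat, 0.2, 0.3, 0.1)), 0)
  allna <- chm_raster(matrix(NA_real_, 5, 5), c(0, 0), 0.1)
  expect_equal(nrow(detect_crown_tops(allna, 0.2, 0.3, 0.1)), 0)
  expect_error(detect_crown_tops(flat, 0.05, 0.3, 0.1), "cell size")
})

test_that("variable window filter equals the brute-force windowed scan", {
  set.seed(31)
  peaks <- lapply(1:6, function(i)
    list(x = runif(1, 1, 11), y = runif(1, 1, 11),
         h = runif(1, 0.3, 1), r = runif(1, 0.5, 1.2)))
  chm <- bump_raster(120, 120, 0.1, peaks)
  chm$values <- chm$values + matrix(runif(120 * 120, 0, 0.01), 120, 120)
  chm$values[sample(120 * 120, 500)] <- NA
  tops <- detect_crown_tops(chm, 0.3, 0.4, 0.1)
  oracle <- bf_crown_tops(chm$values, 0.1, 0.3, 0.4, 0.1)
  expect_equal(as.matrix(tops[, c("row", "col")]), oracle,
               ignore_attr = TRUE)
})

test_that("exact plateau ties keep only the first cell in row-major order", {
  v <- matrix(0.05, 15, 15)
  v[7:8, 7:8] <- 0.5  # 4-cell plateau
  chm <- chm_raster(v, c(0, 0), 0.1)
  tops <- detect_crown_tops(chm, 0.3, 0.3, 0.1)
  expect_equal(nrow(tops), 1)
  expect_equal(c(tops$row, tops$col), c(7, 7))
})

test_that("watershed segments follow markers, saddles and the mask", {
  one <- bump_raster(30, 30, 0.1, list(list(x = 1.5, y = 1.5, h = 0.6, r = 1)))
  tops <- detect_crown_tops(one, 0.2, 0.3, 0.1)
  seg <- segment_crowns(one, tops, 0.1)
  mask <- !is.na(one$values) & one$values >= 0.1
  expect_equal(seg$values > 0, mask)

  # two bumps whose saddle is below the canopy threshold: two components
  low <- bump_raster(30, 60, 0.1, list(list(x = 1.5, y = 1.5, h = 0.6, r = 1),
                                       list(x = 4.5, y = 1.5, h = 0.6, r = 1)))
  topsl <- detect_crown_tops(low, 0.2, 0.3, 0.2)
  segl <- segment_crowns(low, topsl, 0.2)
  # connected-component oracle on the thresholded mask
  maskl <- !is.na(low$values) & low$values >= 0.2
  comp <- matrix(0L, nrow(maskl), ncol(maskl))
  nextid <- 0L
  for (i in seq_len(nrow(maskl))) for (j in seq_len(ncol(maskl))) {
    if (!maskl[i, j] || comp[i, j] > 0) next
    nextid <- nextid + 1L
    queue <- list(c(i, j)); comp[i, j] <- nextid
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1 || jj < 1 || ii > nrow(maskl) || jj > ncol(maskl)) next
        if (maskl[ii, jj] && comp[ii, jj] == 0L) {
          comp[ii, jj] <- nextid
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  expect_equal(nextid, 2L)
  for (k in 1:2) {
    cells <- segl$values == k
    expect_true(all(comp[cells] == comp[segl$values == k][1]))
  }

  # saddle above the threshold: one blob, two segments, area conserved
  hi <- bump_raster(30, 50, 0.1, list(list(x = 1.6, y = 1.5, h = 0.6, r = 1.2),
                                      list(x = 3.4, y = 1.5, h = 0.6, r = 1.2)))
  topsh <- detect_crown_tops(hi, 0.2, 0.5, 0.1)
  expect_equal(nrow(topsh), 2)
  segh <- segment_crowns(hi, topsh, 0.1)
  maskh <- !is.na(hi$values) & hi$values >= 0.1
  expect_equal(sum(segh$values > 0), sum(maskh))      # area conservation
  expect_setequal(unique(segh$values[segh$values > 0]), 1:2)
  expect_equal(segh$values[cbind(topsh$row, topsh$col)], 1:2)

  bad_tops <- data.frame(row = 1, col = 1, x = 0.05, y = 0.05, height = 0)
  expect_error(segment_crowns(hi, bad_tops, 0.1), "outside")
})

test_that("pruning drops topless segments and renumbers by top order", {
  hi <- bump_raster(30, 50, 0.1, list(list(x = 1.6, y = 1.5, h = 0.6, r = 1.2),
                                      list(x = 3.4, y = 1.5, h = 0.6, r = 1.2)))
  tops <- detect_crown_tops(hi, 0.2, 0.5, 0.1)
  seg <- segment_crowns(hi, tops, 0.1)
  expect_equal(prune_segments(seg, tops)$values, seg$values)

  # inject a stray labelled blob with no top
  seg2 <- seg
  seg2$values[25:28, 45:48] <- 99L
  pr <- prune_segments(seg2, tops)
  expect_equal(sort(unique(pr$values[pr$values > 0])), 1:2)
  expect_true(all(pr$values[25:28, 45:48] == 0))
  expect_equal(length(setdiff(unique(pr$values), 0L)), nrow(tops))
})

test_that("plant records report area, height and centroid per segment", {
  lv <- matrix(0L, 10, 10)
  lv[2:6, 2:9] <- 1L  # 40 cells
  labels <- structure(list(values = lv, origin = c(0, 0), resolution = 0.05,
                           crs_note = ""), class = "label_raster")
  cv <- matrix(NA_real_, 10, 10)
  cv[2:6, 2:9] <- 0.3
  cv[4, 4] <- 0.62
  chm <- chm_raster(cv, c(0, 0), 0.05)
  rec <- extract_plant_records(labels, chm, date_index = 2)
  expect_equal(rec$crown_area, 40 * 0.05^2)
  expect_equal(rec$height, 0.62)
  expect_equal(rec$date_index, 2L)
  expect_equal(rec$centroid_x, mean((2:9 - 0.5) * 0.05))
})

test_that("records recover an ellipsoid crown's analytic footprint and height", {
  # dense surface sampling of an elliptic crown, a = 0.30, b = 0.25, h = 0.62
  set.seed(33)
  n <- 6000
  u <- runif(n); phi <- runif(n, 0, 2 * pi)
  x <- 1.5 + 0.30 * sqrt(1 - u^2) * cos(phi)
  y <- 1.5 + 0.25 * sqrt(1 - u^2) * sin(phi)
  z <- 0.62 * u
  ground <- expand.grid(gx = seq(0.05, 2.95, by = 0.1),
                        gy = seq(0.05, 2.95, by = 0.1))
  cloud <- point_cloud(c(x, ground$gx), c(y, ground$gy),
                       c(pmax(z, 0.001), rep(0, nrow(ground))),
                       label = c(rep("ABOVE_GROUND", n),
                                 rep("GROUND", nrow(ground))))
  chm <- fill_chm_gaps(rasterize_chm(cloud, 0.02, c(0, 0, 3, 3)), 3)
  tops <- detect_crown_tops(chm, 0.1, 0.3, 0.1)
  expect_equal(nrow(tops), 1)
  seg <- prune_segments(segment_crowns(chm, tops, 0.1), tops)
  rec <- extract_plant_records(seg, chm, tops, 1,
                               edge_correction = "half-boundary")
  expect_lt(abs(rec$crown_area - pi * 0.30 * 0.25) / (pi * 0.30 * 0.25), 0.10)
  expect_lt(abs(rec$height - 0.62), 0.03)
})

test_that("cross-date matching chains identical and jittered centroids", {
  mk <- function(date, jitter = 0, drop = integer()) {
    g <- expand.grid(x = 1:10, y = 1:10)
    d <- data.frame(plant_id = seq_len(100), date_index = date,
                    height = 0.2 + 0.1 * date + runif(100, 0, 0.01),
                    crown_area = 0.05 + 0.01 * date,
                    centroid_x = g$x + rnorm(100, 0, jitter),
                    centroid_y = g$y + rnorm(100, 0, jitter))
    if (length(drop)) d <- d[-drop, ]
    d
  }
  set.seed(41)
  ident <- lapply(1:4, mk)
  m <- match_plants_across_dates(ident, 0.3)
  expect_equal(length(unique(m$plant_id)), 100)
  expect_equal(nrow(m), 400)

  # a plant missing at date 3 drops its whole series
  holey <- lapply(1:4, function(t) mk(t, drop = if (t == 3) 7L else integer()))
  expect_message(m2 <- match_plants_across_dates(holey, 0.3), "dropped")
  expect_equal(length(unique(m2$plant_id)), 99)

  # jittered centroids on a 1 m grid match their true plant: every series
  # stays on a single grid node (no cross-plant confusion); the shift cap
  # may conservatively drop an extreme-jitter chain, never mis-assign one
  jit <- lapply(1:4, mk, jitter = 0.05)
  m3 <- suppressMessages(match_plants_across_dates(jit, 0.3))
  expect_gte(length(unique(m3$plant_id)), 98)
  sp <- split(m3, m3$plant_id)
  expect_true(all(vapply(sp, function(d)
    max(dist(cbind(d$centroid_x, d$centroid_y))) < 0.5, TRUE)))
  expect_error(match_plants_across_dates(ident[1], 0.3), "2 dates")
})

test_that("label rasters round-trip through TIFF", {
  lv <- matrix(0L, 8, 6)
  lv[2:4, 2:4] <- 1L; lv[6:7, 3:5] <- 2L
  labels <- structure(list(values = lv, origin = c(10, 20), resolution = 0.05,
                           crs_note = ""), class = "label_raster")
  f <- tempfile(fileext = ".tif")
  write_label_raster(labels, f)
  back <- read_label_raster(f)
  expect_equal(back$values, lv)
  expect_equal(back$origin, c(10, 20))
})
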