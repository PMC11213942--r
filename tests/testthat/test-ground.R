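make_plane_cloud <- function(n = 400, slope = c(0, 0), noise = 0, seed = 1,
                             extent = 5) {
  set.seed(seed)
  x <- runif(n, 0, extent); y <- runif(n, 0, extent)
  z <- slope[1] * x + slope[2] * y + rnorm(n, 0, noise)
  point_cloud(x, y, z)
}

test_that("seed selection takes the lowest point per coarse cell", {
  pc <- make_plane_cloud(60, extent = 5)
  seeds <- select_seeds(pc, 5)
  expect_length(seeds, 1)
  expect_equal(pc$z[seeds], min(pc$z))

  # brute-force per-cell minimum on a 1 m grid anchored at the cloud's min
  pc <- make_plane_cloud(300, noise = 0.02, seed = 2, extent = 5)
  seeds1 <- select_seeds(pc, 1)
  cell <- paste(floor(pc$x - min(pc$x)), floor(pc$y - min(pc$y)))
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    expect_true(any(seeds1 %in% idx))
    expect_equal(pc$z[intersect(seeds1, idx)], min(pc$z[idx]))
  }

  # tie goes to the earlier index
  tie <- point_cloud(c(0.2, 0.6), c(0.2, 0.6), c(0.5, 0.5))
  expect_equal(select_seeds(tie, 5), 1L)
})

test_that("PTD separates a flat field from plants above it", {
  pc <- make_plane_cloud(500, extent = 6)
  seeds <- select_seeds(pc, 1)
  # seed-only cloud: everything becomes ground in one pass
  seed_cloud <- point_cloud(pc$x[seeds], pc$y[seeds], pc$z[seeds])
  lab0 <- classify_ground_ptd(seed_cloud, seq_along(seeds), 0.1, 30, 50)
  expect_true(all(lab0 == "GROUND"))

  set.seed(2)
  np <- 80
  plants <- point_cloud(runif(np, 1, 5), runif(np, 1, 5), runif(np, 0.3, 0.8))
  allpc <- point_cloud(c(pc$x, plants$x), c(pc$y, plants$y), c(pc$z, plants$z))
  lab <- classify_ground_ptd(allpc, select_seeds(allpc, 1), 0.1, 30, 50)
  expect_true(all(lab[seq_len(500)] == "GROUND"))
  expect_true(all(lab[500 + seq_len(np)] == "ABOVE_GROUND"))
  # brute force: every plant point is farther than max_dist from the plane
  expect_true(all(plants$z > 0.1))
})

test_that("PTD accepts a tilted plane entirely as ground", {
  pc <- make_plane_cloud(600, slope = c(tan(5 * pi / 180), 0), seed = 4)
  lab <- classify_ground_ptd(pc, select_seeds(pc, 1), 0.1, 30, 50)
  expect_true(all(lab == "GROUND"))
})

test_that("PTD validates its inputs", {
  pc <- make_plane_cloud(50)
  expect_error(classify_ground_ptd(pc, 1:2), "3 seed")
  # collinear seeds plus one point to classify force a triangulation error
  col <- point_cloud(c(1:10, 5), c(1:10, 2), rep(0, 11))
  expect_error(classify_ground_ptd(col, 1:10, 0.1, 30, 5), "triangulation")
  expect_error(classify_ground_ptd(pc, 1:5, -1), "max_dist")
  expect_error(classify_ground_ptd(pc, 1:5, 0.1, 95), "max_angle")
})

test_that("ground TIN is a Delaunay triangulation covering the hull", {
  tri3 <- build_ground_tin(point_cloud(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0),
                                       label = rep("GROUND", 3)))
  expect_equal(nrow(tri3$triangles), 1)

  sq <- build_ground_tin(point_cloud(c(0, 1, 1, 0), c(0, 0, 1, 1), rep(0, 4),
                                     label = rep("GROUND", 4)))
  expect_equal(nrow(sq$triangles), 2)

  set.seed(8)
  pc <- make_plane_cloud(100, seed = 8)
  tin <- build_ground_tin(set_labels(pc, "GROUND"))
  tri_area <- function(v) {
    a <- tin$vertices[v[1], 1:2]; b <- tin$vertices[v[2], 1:2]
    cc <- tin$vertices[v[3], 1:2]
    abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
  }
  total <- sum(apply(tin$triangles, 1, tri_area))
  hull <- chull(pc$x, pc$y)
  hx <- pc$x[hull]; hy <- pc$y[hull]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  expect_equal(total, hull_area, tolerance = 1e-9)
  expect_error(build_ground_tin(set_labels(pc, "ABOVE_GROUND")), "GROUND")
})

test_that("TIN interpolation is exact for planes and flags extrapolation", {
  set.seed(9)
  x <- runif(80, 0, 5); y <- runif(80, 0, 5)
  z <- 0.1 * x + 0.05 * y
  tin <- build_ground_tin(point_cloud(x, y, z, label = rep("GROUND", 80)))
  # vertex identity
  g <- ground_elevation(tin, x[5], y[5])
  expect_equal(g$z, z[5], tolerance = 1e-12)
  # interior exactness for the plane
  qx <- runif(30, 1, 4); qy <- runif(30, 1, 4)
  gi <- ground_elevation(tin, qx, qy)
  expect_true(all(!gi$extrapolated))
  expect_equal(gi$z, 0.1 * qx + 0.05 * qy, tolerance = 1e-9)
  # far outside: nearest vertex elevation, flagged
  go <- ground_elevation(tin, 15, 15)
  expect_true(go$extrapolated)
  nearest <- which.min((x - 15)^2 + (y - 15)^2)
  expect_equal(go$z, z[nearest])
})

test_that("height normalization subtracts the TIN and clamps noise", {
  set.seed(10)
  x <- runif(60, 0, 4); y <- runif(60, 0, 4)
  z <- 0.25 + 0 * x
  tin <- build_ground_tin(point_cloud(x, y, z, label = rep("GROUND", 60)))
  # the TIN's own vertices normalize to zero
  nv <- normalize_heights(point_cloud(x, y, z), tin)
  expect_equal(nv$z, rep(0, 60), tolerance = 1e-12)
  # plant point 0.75 above datum 0.25 -> 0.50
  np <- normalize_heights(point_cloud(2, 2, 0.75), tin)
  expect_equal(np$z, 0.5, tolerance = 1e-9)
  # below-TIN noise clamps to zero with a message
  expect_message(nn <- normalize_heights(point_cloud(2, 2, 0.1), tin), "clamped")
  expect_equal(nn$z, 0)
  expect_equal(attr(nn, "clamped"), 1L)
})

test_that("rasterization takes per-cell maxima with ground zeros", {
  one <- rasterize_chm(set_labels(point_cloud(0.5, 0.5, 0.4), "ABOVE_GROUND"),
                       1, extent = c(0, 0, 3, 3))
  expect_equal(one$values[1, 1], 0.4)
  expect_equal(sum(!is.na(one$values)), 1)

  two <- rasterize_chm(set_labels(point_cloud(c(0.2, 0.8), c(0.5, 0.5),
                                              c(0.3, 0.6)), "ABOVE_GROUND"), 1)
  expect_equal(two$values[1, 1], 0.6)

  mix <- rasterize_chm(point_cloud(c(0.5, 1.5), c(0.5, 0.5), c(0.02, 0.7),
                                   label = c("GROUND", "ABOVE_GROUND")),
                       1, extent = c(0, 0, 2, 1))
  expect_equal(mix$values[1, ], c(0, 0.7))
  expect_error(rasterize_chm(point_cloud(numeric(), numeric(), numeric()), 1),
               "empty")
})

test_that("rasterization equals the exhaustive per-cell maximum oracle", {
  sim <- generate_field_series(field_config(n_plants = 4, plot_size = c(4, 4),
                                            ground_density = 100,
                                            min_crown_points = 300,
                                            n_dates = 1, outlier_frac = 0),
                               seed = 13)
  cloud <- sim$dates[[1]]$cloud
  cloud <- set_labels(cloud, sim$dates[[1]]$truth_label)
  ext <- c(min(cloud$x), min(cloud$y), max(cloud$x), max(cloud$y))
  chm <- rasterize_chm(cloud, 0.05, ext)
  oracle <- bf_cell_max(cloud, 0.05, ext)
  oracle[!is.na(oracle) & oracle < 0] <- 0
  expect_equal(chm$values, oracle)
})

test_that("gap filling fills isolated pits only, in one pass", {
  v <- matrix(0.4, 5, 5)
  chm <- chm_raster(v, c(0, 0), 1)
  expect_equal(fill_chm_gaps(chm, 3)$values, v)

  v2 <- v; v2[3, 3] <- NA
  expect_equal(fill_chm_gaps(chm_raster(v2, c(0, 0), 1), 3)$values[3, 3], 0.4)

  v3 <- matrix(0.4, 9, 9)
  v3[3:7, 3:7] <- NA
  filled <- fill_chm_gaps(chm_raster(v3, c(0, 0), 1), 3)$values
  expect_true(all(is.na(filled[4:6, 4:6])))   # block interior untouched
  expect_false(is.na(filled[3, 3]))           # corner has 5 valid neighbours
  expect_true(is.na(filled[3, 5]))            # edge midpoint has only 3
  expect_error(fill_chm_gaps(chm, 4), "odd")
})

test_that("CHM round-trips through TIFF+world file and CSV", {
  set.seed(14)
  v <- matrix(runif(63, 0, 1.6), 7, 9)
  v[sample(63, 8)] <- NA
  chm <- chm_raster(v, c(100.25, 200.5), 0.05)
  ftif <- tempfile(fileext = ".tif")
  write_chm(chm, ftif)
  back <- read_chm(ftif)
  expect_equal(back$values, chm$values, tolerance = 5.1e-4)  # mm storage
  expect_equal(back$origin, chm$origin)
  expect_equal(back$resolution, chm$resolution)
  fcsv <- tempfile(fileext = ".csv")
  write_chm(chm, fcsv, format = "csv")
  back2 <- read_chm(fcsv)
  expect_equal(back2$values, chm$values, tolerance = 1e-9)
  expect_equal(back2$origin, chm$origin)
})

test_that("ground classification reaches 99% accuracy on synthetic fields", {
  cfg <- field_config(n_plants = 9, plot_size = c(5, 5), spacing = 1,
                      n_dates = 1, growth_midpoint = 0.5,  # mature canopy
                      roughness_sd = 0.005, outlier_frac = 0)
  sim <- generate_field_series(cfg, seed = 15)
  cloud <- sim$dates[[1]]$cloud
  lab <- classify_ground_ptd(cloud, select_seeds(cloud, 1),
                             max_dist = 0.05, max_angle = 30)
  truth <- sim$dates[[1]]$truth_label
  acc <- mean((lab == "GROUND") == (truth == "GROUND"))
  expect_gte(acc, 0.99)
  # label partition: everything is exactly one of the two classes
  expect_true(all(lab %in% c("GROUND", "ABOVE_GROUND")))
})
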