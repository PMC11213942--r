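# Synthetic multi-date field simulator with known per-plant ground truth.
# Emulates a drip-irrigated vegetable trial scanned by a terrestrial laser
# scanner: a gently sloping, slightly rough ground surface; plants on a
# planting grid whose height follows per-plant logistic growth; crowns as
# surface-sampled ellipsoid caps (TLS sees surfaces); sparse outliers.

#' Configuration for the synthetic field generator
#'
#' Defaults describe the well-separated test preset: a 12 m x 12 m plot
#' with 100 plants on a 1 m grid (spacing > 2x the largest crown radius),
#' four acquisition dates, crown surface sampling at TLS-like density
#' (32,000 pts/m2, ~6 mm spacing) and millimetre-level range noise.
#'
#' @param plot_size Plot extent (x, y), metres.
#' @param spacing Planting grid spacing, metres.
#' @param n_plants Number of plants (placed row-major on the grid).
#' @param n_dates Acquisition dates.
#' @param slope Ground plane gradient (dz/dx, dz/dy), unitless.
#' @param roughness_sd Ground micro-relief standard deviation, metres.
#' @param h_inf_range Per-plant asymptotic height range (uniform), metres.
#' @param growth_rate,growth_midpoint Logistic growth parameters (per
#'   stage; midpoint in stage units).
#' @param crown_ratio Crown radius as a fraction of plant height.
#' @param crown_base_frac Height fraction where the foliage starts.
#' @param ground_density Ground returns per m2.
#' @param crown_density Crown-surface returns per m2 of footprint.
#' @param min_crown_points Floor on returns per plant.
#' @param point_noise_sd Per-coordinate sensor noise, metres.
#' @param outlier_frac Outliers as a fraction of regular points.
#' @param outlier_zmax Outlier height ceiling above ground, metres.
#' @return A `field_config` list.
#' @export
field_config <- function(plot_size = c(12, 12), spacing = 1.0, n_plants = 100,
                         n_dates = 4, slope = c(0.02, 0.01),
                         roughness_sd = 0.005,
                         h_inf_range = c(0.4, 1.0), growth_rate = 1.3,
                         growth_midpoint = 1.6, crown_ratio = 0.3,
                         crown_base_frac = 0.3,
                         ground_density = 200, crown_density = 32000,
                         min_crown_points = 600, point_noise_sd = 0.003,
                         outlier_frac = 5e-4, outlier_zmax = 3) {
  cfg <- as.list(environment())
  stopifnot(cfg$ground_density > 0, cfg$crown_density > 0, cfg$n_dates >= 1,
            cfg$spacing > 0, all(cfg$plot_size > 0))
  structure(cfg, class = "field_config")
}

.logistic_height <- function(h_inf, r, t0, t) h_inf / (1 + exp(-r * (t - t0)))

.ground_z <- function(cfg, x, y) cfg$slope[1] * x + cfg$slope[2] * y

#' Generate a multi-date synthetic field with ground truth
#'
#' For each date, ground points are sampled on the sloped plane with
#' Gaussian micro-relief, each plant contributes surface points on an
#' ellipsoid-cap crown (footprint radius `crown_ratio * height`, foliage
#' from `crown_base_frac * height` up to `height`), and sparse outliers are
#' sprinkled in a tall box. Plant positions are identical across dates and
#' everything is reproducible under the seed.
#'
#' @param cfg A [field_config()].
#' @param seed RNG seed.
#' @return A list with `dates` (per date: `date_index`, `cloud`, and the
#'   generator's `truth_label` per point) and `truth` (per plant and date:
#'   true height, crown footprint area, centroid).
#' @export
generate_field_series <- function(cfg = field_config(), seed = 1L) {
  stopifnot(inherits(cfg, "field_config"))
  set.seed(seed)
  # planting grid, row-major from the south-west, centred margins
  nx <- max(1L, ceiling(sqrt(cfg$n_plants)))
  ny <- ceiling(cfg$n_plants / nx)
  mx <- (cfg$plot_size[1] - (nx - 1) * cfg$spacing) / 2
  my <- (cfg$plot_size[2] - (ny - 1) * cfg$spacing) / 2
  grid <- expand.grid(gx = seq_len(nx) - 1, gy = seq_len(ny) - 1)
  px <- mx + grid$gx[seq_len(cfg$n_plants)] * cfg$spacing
  py <- my + grid$gy[seq_len(cfg$n_plants)] * cfg$spacing
  h_inf <- stats::runif(cfg$n_plants, cfg$h_inf_range[1], cfg$h_inf_range[2])

  area <- prod(cfg$plot_size)
  n_ground <- round(cfg$ground_density * area)
  truth <- list(); dates <- list()
  for (t in seq_len(cfg$n_dates)) {
    gx <- stats::runif(n_ground, 0, cfg$plot_size[1])
    gy <- stats::runif(n_ground, 0, cfg$plot_size[2])
    gz <- .ground_z(cfg, gx, gy) + stats::rnorm(n_ground, 0, cfg$roughness_sd)
    X <- list(gx); Y <- list(gy); Z <- list(gz)
    L <- list(rep("GROUND", n_ground))
    h_t <- .logistic_height(h_inf, cfg$growth_rate, cfg$growth_midpoint, t)
    R_t <- cfg$crown_ratio * h_t
    for (i in seq_len(cfg$n_plants)) {
      npts <- max(cfg$min_crown_points, round(cfg$crown_density * pi * R_t[i]^2))
      u <- stats::runif(npts)            # hemisphere: z uniform (Archimedes)
      phi <- stats::runif(npts, 0, 2 * pi)
      rho <- R_t[i] * sqrt(1 - u^2)
      zb <- cfg$crown_base_frac * h_t[i]
      cz <- zb + (h_t[i] - zb) * u
      base <- .ground_z(cfg, px[i], py[i])
      X[[length(X) + 1]] <- px[i] + rho * cos(phi) + stats::rnorm(npts, 0, cfg$point_noise_sd)
      Y[[length(Y) + 1]] <- py[i] + rho * sin(phi) + stats::rnorm(npts, 0, cfg$point_noise_sd)
      Z[[length(Z) + 1]] <- base + cz + stats::rnorm(npts, 0, cfg$point_noise_sd)
      L[[length(L) + 1]] <- rep("ABOVE_GROUND", npts)
    }
    x <- unlist(X); y <- unlist(Y); z <- unlist(Z); lab <- unlist(L)
    n_out <- round(cfg$outlier_frac * length(x))
    if (n_out > 0) {
      ox <- stats::runif(n_out, 0, cfg$plot_size[1])
      oy <- stats::runif(n_out, 0, cfg$plot_size[2])
      oz <- .ground_z(cfg, ox, oy) + stats::runif(n_out, 0.2, cfg$outlier_zmax)
      x <- c(x, ox); y <- c(y, oy); z <- c(z, oz)
      lab <- c(lab, rep("NOISE", n_out))
    }
    dates[[t]] <- list(date_index = t,
                       cloud = point_cloud(x, y, z, crs_note = "synthetic local metric grid"),
                       truth_label = lab)
    truth[[t]] <- data.frame(plant_id = seq_len(cfg$n_plants),
                             date_index = rep(t, cfg$n_plants),
                             true_height = h_t,
                             true_crown_area = pi * R_t^2,
                             true_centroid_x = px, true_centroid_y = py)
  }
  list(dates = dates, truth = do.call(rbind, truth), config = cfg)
}

#' Generate per-plant logistic growth series (tabular)
#'
#' Tabular stand-in for LiDAR-derived records:
#' `height_t = H_inf / (1 + exp(-r (t - t0))) * (1 + eps)` with
#' `eps ~ N(0, noise_sd^2)` and
#' `crown_area_t = pi * (crown_ratio * height_t)^2 * (1 + eps')`.
#' Per-plant asymptotes are uniform on `h_inf_range`; everything is
#' reproducible under the seed.
#'
#' @param n_plants Number of plant series.
#' @param h_inf_range Asymptotic height range, metres.
#' @param growth_rate,growth_midpoint Logistic parameters.
#' @param crown_ratio Crown radius fraction of height.
#' @param noise_sd Multiplicative noise standard deviation (fraction).
#' @param n_stages Number of growth stages (>= 2).
#' @param seed RNG seed.
#' @return A long record data frame (`plant_id`, `date_index`, `height`,
#'   `crown_area`) with noiseless `height_true`, `crown_area_true` columns.
#' @export
generate_growth_dataset <- function(n_plants = 200, h_inf_range = c(0.3, 1.0),
                                    growth_rate = 1.2, growth_midpoint = 2,
                                    crown_ratio = 0.3, noise_sd = 0.05,
                                    n_stages = 4, seed = 1L) {
  stopifnot(n_plants >= 1, n_stages >= 2, noise_sd >= 0)
  set.seed(seed)
  h_inf <- stats::runif(n_plants, h_inf_range[1], h_inf_range[2])
  out <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    t <- seq_len(n_stages)
    h0 <- .logistic_height(h_inf[i], growth_rate, growth_midpoint, t)
    h <- h0 * (1 + stats::rnorm(n_stages, 0, noise_sd))
    a <- pi * (crown_ratio * h)^2 * (1 + stats::rnorm(n_stages, 0, noise_sd))
    out[[i]] <- data.frame(plant_id = i, date_index = t, height = h,
                           crown_area = a, height_true = h0,
                           crown_area_true = pi * (crown_ratio * h0)^2)
  }
  do.call(rbind, out)
}
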