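#' @import data.table
NULL

# ---- configuration ---------------------------------------------------------

#' Configuration for the synthetic study region
#'
#' Defines the study conditions emulated by [generate_world()]: grid size,
#' study years, monitor network size and PM2.5 share, the satellite-AOD
#' cloud-mask target, and the noise scales of every observed product. Defaults
#' describe a 40 x 40 km region observed for one year by 120 monitors (about a
#' third also measuring PM2.5), with ~90% of satellite AOD lost to cloud —
#' the density and missingness regime of a national 1 km analysis, scaled down.
#'
#' @param grid_nx,grid_ny cell counts (>= 8 each).
#' @param cell_size cell edge, km.
#' @param years calendar years of the study period.
#' @param n_monitors number of monitor sites.
#' @param frac_pm25_monitors fraction of monitors also measuring PM2.5 (all
#'   measure PM10), in (0, 1].
#' @param aod_missing_target target fraction of satellite-AOD cell-days lost to
#'   cloud, in \[0.5, 0.99\].
#' @param sigma_resid standard deviation of the unexplained log-PM2.5 residual.
#' @param sigma_pm10_ratio sd of the PM2.5/PM10 ratio around 0.6
#'   (truncated to (0.3, 0.95)).
#' @param sigma_aod sd of satellite-AOD retrieval noise.
#' @param sigma_ctm log-sd of the chemical-transport-model multiplicative bias
#'   field.
#' @param mu grand mean of log-PM2.5 (log ug/m3).
#' @param n_duplicate_pairs number of cross-network duplicated monitor pairs
#'   injected to exercise network deduplication.
#' @param seed integer RNG seed; identical seeds give bit-identical worlds.
#' @return a `world_config` list.
#' @export
world_config <- function(grid_nx = 40, grid_ny = 40, cell_size = 1,
                         years = 2018, n_monitors = 120,
                         frac_pm25_monitors = 0.35,
                         aod_missing_target = 0.90,
                         sigma_resid = 0.2, sigma_pm10_ratio = 0.05,
                         sigma_aod = 0.01, sigma_ctm = 0.15,
                         mu = log(9), n_duplicate_pairs = 1,
                         seed = 1L) {
  if (!is.numeric(grid_nx) || grid_nx < 8) stop_field("grid_nx", "must be >= 8")
  if (!is.numeric(grid_ny) || grid_ny < 8) stop_field("grid_ny", "must be >= 8")
  if (!is.numeric(frac_pm25_monitors) || frac_pm25_monitors <= 0 ||
      frac_pm25_monitors > 1) {
    stop_field("frac_pm25_monitors", "must be in (0, 1]")
  }
  if (!is.numeric(aod_missing_target) || aod_missing_target < 0.5 ||
      aod_missing_target > 0.99) {
    stop_field("aod_missing_target", "must be in [0.5, 0.99]")
  }
  if (!is.numeric(n_monitors) || n_monitors < 4) {
    stop_field("n_monitors", "must be >= 4")
  }
  for (nm in c("sigma_resid", "sigma_pm10_ratio", "sigma_aod", "sigma_ctm")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) stop_field(nm, "must be >= 0")
  }
  if (!is.numeric(seed) || is.na(seed)) stop_field("seed", "must be an integer")
  structure(list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    cell_size = cell_size, years = as.integer(years),
    n_monitors = as.integer(n_monitors),
    frac_pm25_monitors = frac_pm25_monitors,
    aod_missing_target = aod_missing_target,
    sigma_resid = sigma_resid, sigma_pm10_ratio = sigma_pm10_ratio,
    sigma_aod = sigma_aod, sigma_ctm = sigma_ctm,
    mu = mu, n_duplicate_pairs = as.integer(n_duplicate_pairs),
    seed = as.integer(seed)
  ), class = "world_config")
}

# ---- low-level field builders ----------------------------------------------

# Smooth spatial field over cell centroids: sum of Gaussian bumps with
# N(0, 1) amplitudes, standardized to zero mean / unit sd.
smooth_field <- function(cc, n_bumps, width) {
  xr <- range(cc$x); yr <- range(cc$y)
  bx <- runif(n_bumps, xr[1], xr[2])
  by <- runif(n_bumps, yr[1], yr[2])
  amp <- rnorm(n_bumps)
  f <- numeric(nrow(cc))
  for (k in seq_len(n_bumps)) {
    f <- f + amp[k] * exp(-((cc$x - bx[k])^2 + (cc$y - by[k])^2) / (2 * width^2))
  }
  if (sd(f) < 1e-12) return(rep(0, nrow(cc)))
  (f - mean(f)) / sd(f)
}

ar1_series <- function(n, rho = 0.7) {
  e <- rnorm(n, sd = sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + e[t]
  x
}

# N(mean, sd) truncated to (lo, hi), by vectorized rejection
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

zstd <- function(m) (m - mean(m)) / max(sd(m), 1e-12)

# ---- static covariates -----------------------------------------------------

# inverse distance (1/(d + 0.5 km)) from each cell to the nearest of a set of
# source cells
inv_dist_to_cells <- function(cc, source_ids) {
  sx <- cc$x[source_ids]; sy <- cc$y[source_ids]
  d2 <- outer(cc$x, sx, "-")^2 + outer(cc$y, sy, "-")^2
  d <- sqrt(apply(d2, 1L, min))
  1 / (d + 0.5)
}

generate_statics <- function(grid, cc) {
  n <- nrow(cc)
  # population: a few urban centres over a low rural base
  n_city <- max(2L, round(n / 600))
  city_ix <- sample.int(n, n_city)
  logpop <- rep(0, n)
  for (k in seq_len(n_city)) {
    w <- runif(1, 2.5, 4.5)
    a <- runif(1, 1.6, 2.6)
    logpop <- logpop +
      a * exp(-((cc$x - cc$x[city_ix[k]])^2 + (cc$y - cc$y[city_ix[k]])^2) / (2 * w^2))
  }
  logpop <- logpop + 0.4 * smooth_field(cc, 20, 0.25 * min(grid$nx, grid$ny))
  pop <- 40 * exp(logpop)          # persons / km2
  popz <- zstd(log(pop))

  elevation <- pmax(0, 120 + 140 * smooth_field(cc, 8, 0.35 * min(grid$nx, grid$ny)) -
                      25 * popz)
  impervious <- plogis(-1.6 + 1.4 * popz + 0.35 * smooth_field(cc, 25, 2.5))
  night_light <- pmax(0, 5 + 30 * impervious + 4 * popz + rnorm(n, 0, 1))

  rd_hw <- pmax(0, exp(0.15 + 0.6 * popz + 0.5 * smooth_field(cc, 15, 4)) - 0.6)
  rd_sec <- pmax(0, exp(0.5 + 0.7 * popz + 0.3 * smooth_field(cc, 20, 3)) - 0.4)
  rd_loc <- pmax(0.1, exp(1.1 + 0.9 * popz + 0.2 * smooth_field(cc, 25, 2)))

  top_cells <- function(v, frac = 0.05) which(v >= quantile(v, 1 - frac))
  inv_hw <- inv_dist_to_cells(cc, top_cells(rd_hw))
  inv_sec <- inv_dist_to_cells(cc, top_cells(rd_sec))
  inv_loc <- inv_dist_to_cells(cc, top_cells(rd_loc, 0.15))

  # land-cover shares from a softmax over correlated latent fields
  lat <- cbind(
    lc_urban_fabric    = 1.5 * popz,
    lc_industrial      = 0.8 * popz + 0.6 * smooth_field(cc, 12, 3),
    lc_mine_construction = -1.5 + 0.5 * smooth_field(cc, 10, 2),
    lc_green_urban     = -0.5 + 0.6 * popz,
    lc_arable          = 0.8 - 0.8 * popz + 0.6 * smooth_field(cc, 10, 6),
    lc_pasture         = 0.6 - 0.6 * popz + 0.6 * smooth_field(cc, 10, 6),
    lc_forest          = -0.2 - 0.5 * popz + 0.8 * smooth_field(cc, 10, 5),
    lc_natural_open    = -0.6 + 0.004 * elevation + 0.4 * smooth_field(cc, 10, 5),
    lc_water_wetland   = -1.2 + 0.5 * smooth_field(cc, 8, 4)
  )
  e <- exp(lat)
  lc <- e / rowSums(e)

  # a couple of airports near (but not in) the densest areas
  ap_ix <- sample.int(n, 2L, prob = (pop / max(pop))^0.5)
  airport_invdist <- inv_dist_to_cells(cc, ap_ix)
  # shoreline = the domain boundary
  d_shore <- pmin(cc$x - (grid$origin_x), (grid$origin_x + grid$nx * grid$cell_size) - cc$x,
                  cc$y - (grid$origin_y), (grid$origin_y + grid$ny * grid$cell_size) - cc$y)
  seashore_invdist <- 1 / (d_shore + 0.5)

  st <- data.table::data.table(
    cell_id = cc$cell_id,
    elevation = elevation
  )
  for (j in seq_along(STATIC_LANDCOVER)) st[[STATIC_LANDCOVER[j]]] <- lc[, j]
  st$impervious <- impervious
  st$night_light <- night_light
  st$road_dens_highway <- rd_hw
  st$road_dens_secondary <- rd_sec
  st$road_dens_local <- rd_loc
  st$road_invdist_highway <- inv_hw
  st$road_invdist_secondary <- inv_sec
  st$road_invdist_local <- inv_loc
  st$pop_density <- pop
  st$airport_invdist <- airport_invdist
  st$seashore_invdist <- seashore_invdist
  data.table::setcolorder(st, c("cell_id", STATIC_COLUMNS))
  st
}

# ---- meteorology -----------------------------------------------------------

# clamp preserving dim attributes (pmin/pmax with a scalar first drops them)
clampm <- function(m, lo = -Inf, hi = Inf) {
  m[m < lo] <- lo
  m[m > hi] <- hi
  m
}

generate_met <- function(cc, dates) {
  n <- nrow(cc); nd <- length(dates)
  cosw <- cos(2 * pi * (date_yday(dates) - 15) / 365.25)  # 1 in mid-winter
  sp <- function(width) smooth_field(cc, 12, width)
  field <- function(day_series, spatial, noise_sd) {
    outer(spatial, rep(1, nd)) + outer(rep(1, n), day_series) +
      matrix(rnorm(n * nd, 0, noise_sd), n, nd)
  }
  temp <- field(10 - 8 * cosw + 3 * ar1_series(nd), 0.8 * sp(8), 0.5)
  slp <- field(1013 + 8 * ar1_series(nd, 0.85), 0.8 * sp(12), 0.3)
  rh <- clampm(field(80 + 5 * cosw + 6 * ar1_series(nd), 2 * sp(8), 1), 30, 100)
  wet <- rbinom(nd, 1, pmin(0.9, pmax(0.1, 0.45 + 0.12 * cosw)))
  amt <- rgamma(nd, shape = 0.8, scale = 4) * wet
  precip <- clampm(outer(exp(0.3 * sp(10)), amt) +
                     matrix(rnorm(n * nd, 0, 0.05), n, nd), lo = 0)
  wind_speed <- clampm(field(4.5 + 1.8 * ar1_series(nd), 0.5 * sp(10), 0.3), lo = 0.3)
  dir_day <- cumsum(c(runif(1, 0, 360), rnorm(nd - 1, 0, 25))) %% 360
  wind_dir <- (outer(rep(0, n), dir_day, "+") +
                 matrix(rnorm(n * nd, 0, 5), n, nd)) %% 360
  blh_12 <- clampm(field(700 - 250 * cosw + 180 * ar1_series(nd), sp(8), 30), lo = 100)
  blh_00 <- clampm(0.45 * blh_12 + 80 + matrix(rnorm(n * nd, 0, 20), n, nd), lo = 50)
  list(air_temp = temp, sea_level_pressure = slp, rel_humidity = rh,
       precipitation = precip, wind_speed = wind_speed, wind_dir = wind_dir,
       blh_00 = blh_00, blh_12 = blh_12)
}

# ---- the generator ---------------------------------------------------------

#' Generate a synthetic study region
#'
#' Builds a complete toy study region from a latent daily PM2.5 truth field:
#' the truth on the log scale is a grand mean plus a smooth regional surface,
#' sparse hotspot bumps co-located with high road-density/impervious cells, an
#' annual cosine with a winter peak, a linear weather term (boundary-layer
#' height and wind speed negative, temperature positive, precipitation
#' negative), and an iid Gaussian residual. Every observed product — co-located
#' PM10, cloud-masked two-overpass satellite AOD with QA flags, coarse
#' multi-wavelength multi-hour reanalysis AOD, a biased block-smoothed
#' model-PM2.5 surface, meteorology, monthly vegetation index, and 21 static
#' covariates — is a deterministic function of (truth, parameters, seed).
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_world`.
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) config <- do.call(world_config, config)
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  grid <- grid_spec(config$grid_nx, config$grid_ny, config$cell_size)
  cc <- cell_centroids(grid)
  dates <- pm_dates(config$years)
  n <- nrow(cc); nd <- length(dates)
  yday <- date_yday(dates)

  statics <- generate_statics(grid, cc)

  # latent spatial structure
  regional <- 0.25 * smooth_field(cc, 3, 0.4 * min(grid$nx, grid$ny))
  hot_score <- zstd(statics$road_dens_highway) + zstd(statics$impervious)
  n_hot <- max(3L, round(n / 400))
  hot_ix <- order(hot_score, decreasing = TRUE)[seq_len(n_hot)]
  hotspot <- numeric(n)
  for (k in hot_ix) {
    hotspot <- hotspot + runif(1, 0.25, 0.5) *
      exp(-((cc$x - cc$x[k])^2 + (cc$y - cc$y[k])^2) / (2 * 1.5^2))
  }

  season <- 0.25 * cos(2 * pi * (yday - 15) / 365.25)

  met <- generate_met(cc, dates)
  weather <- -0.25 * zstd(met$blh_12) - 0.15 * zstd(met$wind_speed) +
    0.08 * zstd(met$air_temp) - 0.10 * zstd(log1p(met$precipitation))

  eps <- matrix(rnorm(n * nd, 0, config$sigma_resid), n, nd)
  log_signal <- config$mu + outer(regional + hotspot, rep(1, nd)) +
    outer(rep(1, n), season) + weather
  truth <- exp(log_signal + eps)

  # chemical-transport-model surface: block-smoothed signal x lognormal bias
  ctm_blocks <- block_index(grid, 5L)
  ctm_bias <- exp(config$sigma_ctm * smooth_field(cc, 10, 0.3 * min(grid$nx, grid$ny)))
  ctm <- block_mean(exp(log_signal), ctm_blocks)[ctm_blocks, , drop = FALSE] * ctm_bias

  # columnar AOD truth at 0.55 um; overpass scenes with cloud mask and QA
  aod_true_055 <- 0.02 * truth * (met$blh_12 / 1000)
  cloud_basis <- matrix(0, n, 40L)
  bx <- runif(40L, min(cc$x), max(cc$x)); by <- runif(40L, min(cc$y), max(cc$y))
  for (k in 1:40) {
    cloud_basis[, k] <- exp(-((cc$x - bx[k])^2 + (cc$y - by[k])^2) / (2 * runif(1, 3, 8)^2))
  }
  cloud_field <- cloud_basis %*% matrix(rnorm(40L * nd), 40L, nd) +
    matrix(rnorm(n * nd, 0, 0.3), n, nd)
  p_day <- pmin(0.99, pmax(0.5, config$aod_missing_target +
                             0.04 * cos(2 * pi * (yday - 15) / 365.25) +
                             rnorm(nd, 0, 0.01)))
  cloud_mask <- matrix(FALSE, n, nd)
  for (t in seq_len(nd)) {
    thr <- quantile(cloud_field[, t], p_day[t], names = FALSE)
    cloud_mask[, t] <- cloud_field[, t] <= thr
  }

  wf47 <- aod_wavelength_factor(0.47)
  make_scene <- function(overpass) {
    extra <- matrix(runif(n * nd) < 0.05, n, nd)
    mask <- cloud_mask | extra
    a055 <- aod_true_055 + matrix(rnorm(n * nd, 0, config$sigma_aod), n, nd)
    a047 <- aod_true_055 * wf47 + matrix(rnorm(n * nd, 0, config$sigma_aod), n, nd)
    a055[mask] <- NA_real_; a047[mask] <- NA_real_
    unc <- matrix(abs(rnorm(n * nd, 0.02, 0.01)), n, nd)
    qa_best <- matrix(runif(n * nd) < 0.95, n, nd)
    list(overpass = overpass, aod_047 = pmax(a047, 0), aod_055 = pmax(a055, 0),
         uncertainty = unc, qa_best = qa_best, mask = mask)
  }
  scenes <- list(make_scene("terra"), make_scene("aqua"))

  # coarse reanalysis AOD: 10x block mean + smooth bias, 5 wavelengths x 7 hours
  cams_blocks <- block_index(grid, 10L)
  cams_cent <- block_centroids(grid, 10L)
  nb <- nrow(cams_cent)
  bm <- block_mean(aod_true_055, cams_blocks)     # nb x nd at 0.55 um
  diurnal <- 0.8 + 0.4 * sin(pi * CAMS_HOURS / 24)
  cams <- array(NA_real_, dim = c(nb, nd, length(AOD_WAVELENGTHS), length(CAMS_HOURS)))
  for (w in seq_along(AOD_WAVELENGTHS)) {
    bias_w <- rnorm(nb, 0, 0.01)
    for (h in seq_along(CAMS_HOURS)) {
      cams[, , w, h] <- bm * aod_wavelength_factor(AOD_WAVELENGTHS[w]) * diurnal[h] +
        bias_w + matrix(rnorm(nb * nd, 0, 0.005), nb, nd)
    }
  }
  cams_link <- link_nearest_centroid(cams_cent$x, cams_cent$y, grid)

  # monthly NDVI (per calendar month of each study year)
  ym <- unique(format(dates, "%Y-%m"))
  mon_of_ym <- as.integer(substr(ym, 6, 7))
  ndvi_spatial <- 0.05 * smooth_field(cc, 15, 5)
  ndvi <- sapply(seq_along(ym), function(j) {
    summer <- -cos(2 * pi * (mon_of_ym[j] - 1.5) / 12)
    pmin(0.95, pmax(-0.1, 0.55 - 0.45 * statics$impervious + 0.2 * summer +
                      ndvi_spatial + rnorm(n, 0, 0.02)))
  })
  colnames(ndvi) <- ym

  monitors <- place_monitors(config, grid, cc, statics)
  records <- simulate_records(config, monitors, truth, dates)
  dup <- inject_duplicates(config, monitors, records)

  structure(list(
    config = config, grid = grid, cells = cc, dates = dates,
    truth_pm25 = truth,
    components = list(mu = config$mu, regional = regional, hotspot = hotspot,
                      season = season, weather = weather, eps = eps),
    statics = statics, met = met, ndvi = ndvi, ndvi_months = ym,
    ctm_pm25 = ctm,
    aod = list(true_055 = aod_true_055, scenes = scenes,
               wavelengths = AOD_WAVELENGTHS),
    cams = list(values = cams, blocks = cams_blocks, centroids = cams_cent,
                link = cams_link, hours = CAMS_HOURS,
                wavelengths = AOD_WAVELENGTHS),
    monitors = dup$monitors, records = dup$records
  ), class = "synthetic_world")
}

place_monitors <- function(config, grid, cc, statics) {
  n <- nrow(cc)
  nm <- config$n_monitors
  cells <- sample.int(n, nm, prob = (statics$pop_density / max(statics$pop_density))^0.7)
  r <- rank(statics$pop_density[cells]) / nm
  types <- c("traffic", "industrial", "urban", "suburban", "rural")
  type <- vapply(r, function(ri) {
    sample(types, 1L, prob = c(0.05 + 0.25 * ri, 0.05 + 0.05 * ri,
                               0.10 + 0.30 * ri, 0.25 - 0.10 * ri,
                               0.55 - 0.50 * ri))
  }, character(1))
  networks <- sample(c("AURN", "AQE", "KCL", "SAQN", "WAQN"), nm, replace = TRUE,
                     prob = c(0.4, 0.2, 0.15, 0.15, 0.1))
  networks[1L] <- "AURN"   # anchor for the injected duplicate pair
  jx <- runif(nm, -0.3, 0.3); jy <- runif(nm, -0.3, 0.3)
  measures <- rep(FALSE, nm)
  measures[sample.int(nm, max(2L, round(config$frac_pm25_monitors * nm)))] <- TRUE
  measures[1L] <- TRUE
  # completeness regimes: most near-complete, some flaky, two too sparse to
  # survive the 30-day annual rule
  p_valid <- rep(0.97, nm)
  p_valid[sample.int(nm, max(1L, round(0.1 * nm)))] <- 0.6
  if (nm >= 6) p_valid[c(nm - 1L, nm)] <- 0.055
  data.table::data.table(
    monitor_id = sprintf("M%03d", seq_len(nm)),
    network = networks, monitor_type = type,
    cell_id = cells,
    x = cc$x[cells] + jx, y = cc$y[cells] + jy,
    measures_pm25 = measures, p_valid = p_valid
  )
}

simulate_records <- function(config, monitors, truth, dates) {
  nd <- length(dates)
  recs <- lapply(seq_len(nrow(monitors)), function(i) {
    m <- monitors[i]
    pm25_true <- truth[m$cell_id, ]
    ratio <- rnorm_trunc(nd, 0.6, config$sigma_pm10_ratio, 0.3, 0.95)
    pm10_true <- pm25_true / ratio
    draw_hours <- function() {
      valid <- rbinom(nd, 1, m$p_valid) == 1
      h <- integer(nd)
      full <- runif(nd) < 0.8
      h[valid & full] <- 24L
      h[valid & !full] <- sample(18:23, sum(valid & !full), replace = TRUE)
      h[!valid] <- sample(0:17, sum(!valid), replace = TRUE)
      h
    }
    h10 <- draw_hours()
    h25 <- if (m$measures_pm25) draw_hours() else rep(0L, nd)
    data.table::data.table(
      monitor_id = m$monitor_id, date = dates,
      pm25 = ifelse(h25 > 0, pm25_true, NA_real_),
      pm10 = ifelse(h10 > 0, pm10_true, NA_real_),
      hours_pm25 = h25, hours_pm10 = h10
    )
  })
  recs <- data.table::rbindlist(recs)
  recs[!(is.na(recs$pm25) & is.na(recs$pm10))]
}

inject_duplicates <- function(config, monitors, records) {
  k <- min(config$n_duplicate_pairs, 1L)   # one pair exercises the rule
  if (k < 1L) return(list(monitors = monitors, records = records))
  orig <- monitors[1L]
  dup <- data.table::copy(orig)
  dup$monitor_id <- sprintf("D%03d", 1L)
  dup$network <- if (orig$network == "AQE") "KCL" else "AQE"
  dup$x <- orig$x + 0.03; dup$y <- orig$y + 0.03
  dup_rec <- data.table::copy(records[records$monitor_id == orig$monitor_id])
  dup_rec$monitor_id <- dup$monitor_id
  list(monitors = rbind(monitors, dup),
       records = rbind(records, dup_rec))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d km grid, %d days (%s..%s), %d monitors\n",
              x$grid$nx, x$grid$ny, length(x$dates),
              format(min(x$dates)), format(max(x$dates)), nrow(x$monitors)))
  invisible(x)
}

#' Latent truth PM2.5 at a cell and date
#'
#' @param world a [generate_world()] result.
#' @param cell_id cell id (row-major).
#' @param date a `Date` (or coercible) inside the study period.
#' @return concentration in ug/m3.
#' @export
truth_at <- function(world, cell_id, date) {
  date <- as.Date(date)
  j <- match(date, world$dates)
  if (any(is.na(j))) stop("date outside the study period", call. = FALSE)
  if (any(cell_id < 1L | cell_id > nrow(world$cells))) {
    stop("cell_id outside the grid", call. = FALSE)
  }
  world$truth_pm25[cbind(cell_id, j)]
}

# realized fraction of satellite cell-days with no QA-passing overpass value
# (i.e. missing in the daily composite before Stage-2)
realized_aod_missing <- function(world, qa_policy = default_qa_policy()) {
  comp <- composite_world_aod(world, wavelength = 0.55, qa_policy = qa_policy)
  mean(is.na(comp$values))
}
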