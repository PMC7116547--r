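# Independent brute-force oracles, kept deliberately naive.

# IDW weighted mean by explicit loop over donors
brute_idw <- function(tx, ty, donors, power, floor = 0.5) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(donors))) {
    d <- max(sqrt((donors$x[i] - tx)^2 + (donors$y[i] - ty)^2), floor)
    num <- num + d^(-power) * donors$mean_pm25[i]
    den <- den + d^(-power)
  }
  if (den == 0) NA_real_ else num / den
}

# two-pass spatial/temporal decomposition with explicit means and centering
brute_decompose <- function(pred, obs, ids) {
  uid <- unique(ids)
  mp <- sapply(uid, function(u) mean(pred[ids == u]))
  mo <- sapply(uid, function(u) mean(obs[ids == u]))
  sp_fit <- lm(mp ~ mo)
  pc <- numeric(length(pred)); oc <- numeric(length(obs))
  for (u in uid) {
    sel <- ids == u
    pc[sel] <- pred[sel] - mean(pred[sel])
    oc[sel] <- obs[sel] - mean(obs[sel])
  }
  tm_fit <- lm(pc ~ oc)
  list(
    spatial = c(r2 = cor(mp, mo)^2, rmse = sqrt(mean((mp - mo)^2)),
                intercept = unname(coef(sp_fit)[1]), slope = unname(coef(sp_fit)[2])),
    temporal = c(r2 = cor(pc, oc)^2, rmse = sqrt(mean((pc - oc)^2)),
                 intercept = unname(coef(tm_fit)[1]), slope = unname(coef(tm_fit)[2]))
  )
}

# random monitor layout for feature oracles
random_sites <- function(n, seed) {
  set.seed(seed)
  data.table::data.table(
    monitor_id = sprintf("S%02d", seq_len(n)),
    monitor_type = sample(c("traffic", "industrial", "urban", "suburban", "rural"),
                          n, replace = TRUE),
    x = runif(n, 0, 30), y = runif(n, 0, 30)
  )
}

# minimal record table for hand-built QC scenarios
make_records <- function(monitor_id, dates, pm25 = NA_real_, pm10 = NA_real_,
                         hours_pm25 = 24L, hours_pm10 = 24L) {
  data.table::data.table(monitor_id = monitor_id, date = as.Date(dates),
                         pm25 = pm25, pm10 = pm10,
                         hours_pm25 = hours_pm25, hours_pm10 = hours_pm10)
}

# identity Stage-2 fixture: a world where the composited satellite AOD equals
# the reanalysis 12:00 value at 0.55 um (coarse pixels = fine cells), with a
# configurable share of cloud-masked cell-days
identity_aod_fixture <- function(nx = 10, ny = 10, n_days = 60, miss_frac = 0.5,
                                 seed = 3L, sigma_aod = 0.01) {
  set.seed(seed)
  grid <- grid_spec(nx, ny)
  cc <- cell_centroids(grid)
  n <- nrow(cc)
  dates <- pm_dates(2018)[seq_len(n_days)]
  base <- outer(0.15 + 0.1 * sin(cc$x / 3) + 0.1 * cos(cc$y / 4),
                1 + 0.5 * sin(seq_len(n_days) / 9))
  cams_vals <- array(NA_real_, dim = c(n, n_days, 5, 7))
  for (w in 1:5) for (h in 1:7) {
    cams_vals[, , w, h] <- base * (0.8 + 0.05 * w) * (0.9 + 0.02 * h)
  }
  truth <- cams_vals[, , 2, 4]   # 0.55 um at 12:00
  vals <- truth + matrix(rnorm(n * n_days, 0, sigma_aod), n, n_days)
  mask <- matrix(runif(n * n_days) < miss_frac, n, n_days)
  vals[mask] <- NA_real_
  field <- daily_aod_field(pmax(vals, 0), 0.55, dates)
  cams <- list(values = cams_vals, link = seq_len(n),
               hours = c(3L, 6L, 9L, 12L, 15L, 18L, 21L),
               wavelengths = c(0.47, 0.55, 0.67, 0.865, 1.24))
  list(grid = grid, field = field, cams = cams, truth = truth, mask = mask,
       dates = dates, sigma_aod = sigma_aod)
}
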