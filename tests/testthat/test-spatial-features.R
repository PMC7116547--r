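test_that("annual class means average observed PM2.5 and omit empty monitors", {
  sites <- data.table::data.table(
    monitor_id = c("a", "b"), monitor_type = c("urban", "traffic"),
    x = c(0, 1), y = c(0, 0))
  r <- rbind(
    make_records("a", as.Date("2018-03-01") + 0:2, pm25 = c(8, 10, 12)),
    make_records("b", as.Date("2018-03-01") + 0:1, pm25 = NA_real_, pm10 = 20)
  )
  m <- annual_class_means(r, sites, 2018)
  expect_equal(nrow(m), 1L)
  expect_equal(m$mean_pm25, 10)
  expect_equal(m$n_days, 3L)
  expect_identical(m$class, "background")
  expect_equal(nrow(annual_class_means(r, sites, 2017)), 0L)
})

test_that("IDW-LOOCV reproduces hand-computed weighted means", {
  sites <- data.table::data.table(
    monitor_id = c("t", "d1", "d2"),
    monitor_type = c("urban", "urban", "urban"),
    x = c(0, 1, 2), y = c(0, 0, 0))
  means <- data.table::data.table(
    monitor_id = c("d1", "d2"), class = "background",
    mean_pm25 = c(10, 16), x = c(1, 2), y = c(0, 0))
  # donors at 1 km (10) and 2 km (16): power 1 -> 12.0, power 2 -> 11.2
  expect_equal(idw_loocv_lagged(means, sites, "t", "background", 1), 12.0)
  expect_equal(idw_loocv_lagged(means, sites, "t", "background", 2), 11.2)
  # single donor: weights cancel
  expect_equal(idw_loocv_lagged(means[1], sites, "t", "background", 1), 10)
  expect_equal(idw_loocv_lagged(means[1], sites, "t", "background", 2), 10)
  # equidistant donors 8 and 12 -> 10 under both powers
  means2 <- data.table::data.table(
    monitor_id = c("d1", "d2"), class = "background",
    mean_pm25 = c(8, 12), x = c(1, -1), y = c(0, 0))
  expect_equal(idw_loocv_lagged(means2, sites, "t", "background", 1), 10)
  expect_equal(idw_loocv_lagged(means2, sites, "t", "background", 2), 10)
  # no eligible donor -> NA, not zero
  expect_true(is.na(idw_loocv_lagged(means, sites, "t", "hotspot", 1)))
  # the target's own mean is never a donor
  means3 <- rbind(means, data.table::data.table(
    monitor_id = "t", class = "background", mean_pm25 = 1000, x = 0, y = 0))
  expect_equal(idw_loocv_lagged(means3, sites, "t", "background", 1), 12.0)
})

test_that("IDW features agree with the brute-force oracle on 50 monitors", {
  sites <- random_sites(50, seed = 101)
  set.seed(202)
  means <- data.table::data.table(
    monitor_id = sites$monitor_id,
    class = site_class(sites$monitor_type),
    mean_pm25 = runif(50, 5, 25), x = sites$x, y = sites$y)
  for (id in sites$monitor_id[seq(1, 50, by = 3)]) {
    t <- sites[sites$monitor_id == id]
    for (cl in c("hotspot", "background")) {
      for (p in 1:2) {
        don <- means[means$class == cl & means$monitor_id != id]
        expect_equal(idw_loocv_lagged(means, sites, id, cl, p),
                     brute_idw(t$x, t$y, don, p), tolerance = 1e-10)
      }
    }
  }
})

test_that("IDW estimates are convex in the donors and power 2 is more local", {
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    sites <- random_sites(n + 1, seed = 303 + rep)
    sites$monitor_type <- c("urban", rep("traffic", n))   # target + hotspot donors
    means <- data.table::data.table(
      monitor_id = sites$monitor_id[-1], class = "hotspot",
      mean_pm25 = runif(n, 2, 30), x = sites$x[-1], y = sites$y[-1])
    v1 <- idw_loocv_lagged(means, sites, sites$monitor_id[1], "hotspot", 1)
    v2 <- idw_loocv_lagged(means, sites, sites$monitor_id[1], "hotspot", 2)
    expect_gte(v1, min(means$mean_pm25)); expect_lte(v1, max(means$mean_pm25))
    expect_gte(v2, min(means$mean_pm25)); expect_lte(v2, max(means$mean_pm25))
  }
  # with two disagreeing donors at unequal distances the inverse-squared
  # weighting always lands closer to the nearer donor's mean
  for (rep in 1:20) {
    sites <- random_sites(3, seed = 500 + rep)
    sites$monitor_type <- c("urban", "traffic", "traffic")
    means <- data.table::data.table(
      monitor_id = sites$monitor_id[-1], class = "hotspot",
      mean_pm25 = runif(2, 2, 30), x = sites$x[-1], y = sites$y[-1])
    v1 <- idw_loocv_lagged(means, sites, sites$monitor_id[1], "hotspot", 1)
    v2 <- idw_loocv_lagged(means, sites, sites$monitor_id[1], "hotspot", 2)
    d <- pmax(sqrt((means$x - sites$x[1])^2 + (means$y - sites$y[1])^2), 0.5)
    nearest <- means$mean_pm25[which.min(d)]
    if (abs(diff(means$mean_pm25)) > 1e-6 && abs(diff(d)) > 1e-6) {
      expect_lte(abs(v2 - nearest), abs(v1 - nearest) + 1e-9)
    }
  }
})

test_that("grid IDW differs from LOOCV exactly by self-inclusion", {
  g <- grid_spec(12, 12)
  sites <- random_sites(12, seed = 404)
  sites$x <- runif(12, 0, 12); sites$y <- runif(12, 0, 12)
  sites$monitor_type <- "urban"
  set.seed(405)
  means <- data.table::data.table(
    monitor_id = sites$monitor_id, class = "background",
    mean_pm25 = runif(12, 5, 20), x = sites$x, y = sites$y)
  fld <- idw_grid_lagged(means, g, "background", 2)
  # uniform donors give a constant field
  meansc <- data.table::copy(means); meansc$mean_pm25 <- 7
  expect_equal(idw_grid_lagged(meansc, g, "background", 1), rep(7, 144))
  # at a monitor's centroid, brute-force all-donor sum equals the field value
  cid <- assign_cell_id(sites$x[1], sites$y[1], g)
  cc <- cell_centroids(g)
  all_val <- brute_idw(cc$x[cid], cc$y[cid], means, 2)
  expect_equal(fld[cid], all_val, tolerance = 1e-10)
  loo_val <- brute_idw(cc$x[cid], cc$y[cid], means[-1], 2)
  expect_gt(abs(all_val - loo_val), 0)   # self-inclusion changes the estimate
  expect_error(idw_grid_lagged(means, g, "hotspot", 1), "no monitors")
})

test_that("nearest-class distances exclude the target monitor itself", {
  sites <- data.table::data.table(
    monitor_id = c("a", "b", "c"),
    monitor_type = c("urban", "urban", "urban"),
    x = c(0, 3, 4), y = c(0, 0, 0))
  expect_equal(nearest_class_distance(0, 0, sites, "background",
                                      exclude_ids = "a"), 3)
  expect_equal(nearest_class_distance(0, 0, sites, "background"), 0)
  expect_equal(nearest_class_distance(c(10, 3.5), c(0, 0), sites, "background"),
               c(6, 0.5))
  expect_error(nearest_class_distance(0, 0, sites, "hotspot"), "no monitors")
})

test_that("the monitor feature table carries all six spatial variables", {
  lf <- monitor_lagged_features(tw_records, tw_sites, 2018)
  expect_identical(setdiff(names(lf), c("monitor_id", "year")),
                   pm25grid:::LAGGED_COLUMNS)
  expect_equal(nrow(lf), nrow(tw_sites))
  expect_true(all(lf$dist_hotspot > 0))   # self excluded, so never zero
  done <- !is.na(lf$lag_background_regional)
  expect_true(all(lf$lag_background_regional[done] >= 0))
})
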