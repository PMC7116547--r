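test_that("fold assignment partitions monitors uniformly and reproducibly", {
  ids <- sprintf("M%02d", 1:20)
  f <- make_folds(ids, k = 10, seed = 5)
  expect_setequal(names(f), ids)
  expect_equal(unname(table(f)), rep(2L, 10), ignore_attr = TRUE)
  expect_identical(f, make_folds(ids, k = 10, seed = 5))
  expect_false(identical(f, make_folds(ids, k = 10, seed = 6)))
  expect_error(make_folds(ids[1:5], k = 10), "at least 10")
})

test_that("cross-validation never lets a monitor influence its own predictions", {
  set.seed(11)
  data <- data.table::data.table(
    monitor_id = rep(sprintf("M%02d", 1:12), each = 30),
    xv = rnorm(360)
  )
  data$yv <- 2 * data$xv + rnorm(360, 0, 0.1)
  folds <- make_folds(unique(data$monitor_id), k = 4, seed = 1)
  fit_fn <- function(tr) lm(yv ~ xv, data = tr)
  predict_fn <- function(m, te) predict(m, newdata = te)
  pred <- cross_validate(fit_fn, predict_fn, data, folds)
  expect_length(pred, nrow(data))
  expect_false(anyNA(pred))
  # corrupting one monitor's outcomes leaves its own held-out predictions
  # unchanged (its rows are excluded from the model that predicts them)
  poisoned <- data.table::copy(data)
  poisoned$yv[poisoned$monitor_id == "M03"] <-
    poisoned$yv[poisoned$monitor_id == "M03"] + 100
  pred2 <- cross_validate(fit_fn, predict_fn, poisoned, folds)
  sel <- data$monitor_id == "M03"
  expect_equal(pred2[sel], pred[sel])
  expect_false(isTRUE(all.equal(pred2[!sel], pred[!sel])))
  # k = number of monitors behaves as leave-one-monitor-out
  loo <- make_folds(unique(data$monitor_id), k = 12, seed = 2)
  expect_equal(unname(table(loo)), rep(1L, 12), ignore_attr = TRUE)
  pred3 <- cross_validate(fit_fn, predict_fn, data, loo)
  expect_length(pred3, nrow(data))
  expect_error(cross_validate(fit_fn, predict_fn,
                              data[data$monitor_id == "M01"],
                              folds), "no training data")
})

test_that("performance statistics match closed-form least squares", {
  obs <- c(1, 2, 3); pred <- c(2, 2, 2)
  st <- performance_stats(pred, obs)
  expect_equal(st$slope, 0)
  expect_equal(st$intercept, 2)
  expect_equal(st$r2, 0)
  expect_equal(st$rmse, sqrt(2 / 3))
  set.seed(21); obs2 <- runif(50, 5, 20)
  st2 <- performance_stats(obs2, obs2)
  expect_equal(st2$r2, 1); expect_equal(st2$rmse, 0)
  expect_equal(st2$intercept, 0); expect_equal(st2$slope, 1)
  st3 <- performance_stats(2 * obs2, obs2)
  expect_equal(st3$slope, 2); expect_equal(st3$r2, 1)
  expect_equal(st3$rmse, sqrt(mean(obs2^2)))
  expect_error(performance_stats(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(performance_stats(1, 1), "at least 3")
})

test_that("the spatial/temporal decomposition matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n_mon <- sample(5:15, 1)
    ids <- rep(sprintf("M%02d", seq_len(n_mon)), each = 40)
    obs <- 10 + rnorm(n_mon)[match(ids, unique(ids))] + rnorm(length(ids), 0, 2)
    pred <- 0.5 + 0.9 * obs + rnorm(length(ids), 0, 1.5)
    got <- decompose_spatial_temporal(pred, obs, ids)
    want <- brute_decompose(pred, obs, ids)
    for (dm in c("spatial", "temporal")) {
      row <- got[got$domain == dm]
      expect_equal(row$r2, unname(want[[dm]]["r2"]), tolerance = 1e-10)
      expect_equal(row$rmse, unname(want[[dm]]["rmse"]), tolerance = 1e-10)
      expect_equal(row$intercept, unname(want[[dm]]["intercept"]), tolerance = 1e-10)
      expect_equal(row$slope, unname(want[[dm]]["slope"]), tolerance = 1e-10)
    }
    # structural identity: the temporal intercept vanishes for any input
    expect_lt(abs(got[got$domain == "temporal"]$intercept), 1e-6)
  }
})

test_that("per-monitor constant shifts are invisible to the temporal component", {
  set.seed(41)
  ids <- rep(c("a", "b", "c"), each = 30)
  obs <- 10 + rnorm(90, 0, 3)
  shift <- c(a = -2, b = 1, c = 4)
  pred <- obs + shift[ids]
  got <- decompose_spatial_temporal(pred, obs, ids)
  tm <- got[got$domain == "temporal"]
  expect_equal(tm$r2, 1)
  expect_equal(tm$rmse, 0)
  # the shifts survive only in the spatial component, exactly as the
  # explicit regression of shifted means on means
  sp <- got[got$domain == "spatial"]
  want <- brute_decompose(pred, obs, ids)
  expect_equal(sp$slope, unname(want$spatial["slope"]), tolerance = 1e-10)
  expect_equal(sp$intercept, unname(want$spatial["intercept"]), tolerance = 1e-10)
  expect_error(decompose_spatial_temporal(obs, obs, rep("a", 90)), ">= 2 monitors")
  ok <- decompose_spatial_temporal(obs, obs, ids)
  expect_equal(ok$r2, c(1, 1))
})

test_that("seasonal stratification partitions rows by meteorological season", {
  set.seed(51)
  dates <- pm_dates(2018)
  ids <- rep(c("a", "b", "c", "d"), length.out = length(dates) * 4)
  dts <- rep(dates, 4)
  obs <- 8 + 3 * cos(2 * pi * (as.integer(format(dts, "%j")) - 15) / 365) +
    rnorm(length(dts))
  pred <- obs + rnorm(length(dts), 0, 0.5)
  out <- seasonal_stats(pred, obs, dts, ids)
  overall <- out[out$domain == "overall"]
  expect_setequal(overall$season, c("DJF", "MAM", "JJA", "SON"))
  expect_equal(sum(overall$n), length(dts))
  # JJA subset equals a brute-force month filter
  jja <- which(as.integer(format(dts, "%m")) %in% 6:8)
  expect_equal(overall$n[overall$season == "JJA"], length(jja))
  st <- performance_stats(pred[jja], obs[jja])
  expect_equal(overall$r2[overall$season == "JJA"], st$r2)
  # identical series: every season perfect
  perf <- seasonal_stats(obs, obs, dts, ids)
  expect_equal(perf$r2[perf$domain == "overall"], rep(1, 4), tolerance = 1e-12)
})

test_that("importance ranking is normalized, sorted, and recovers a dominant predictor", {
  set.seed(61)
  n <- 600
  tab <- data.table::data.table(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- tab$x1 + rnorm(n, 0, 0.05)
  m <- pm25grid:::fit_rf(tab, y, c("x1", "x2", "x3"),
                         learner_spec(100, 2, seed = 3), stage = 3L, year = 2018)
  imp <- importance_table(m)
  expect_equal(sum(imp$importance_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(imp$importance_pct) <= 0))
  expect_identical(imp$predictor[1], "x1")
  expect_error(importance_table(list()), "not a fitted model")
})

test_that("strict CV recomputes lagged features without the held-out donors", {
  donors <- tw_sites$monitor_id[1:20]
  restricted <- monitor_lagged_features(tw_records, tw_sites, 2018, donors = donors)
  full <- tw_lagged
  # every monitor still receives features, but donor-restricted values differ
  expect_equal(restricted$monitor_id, full$monitor_id)
  expect_false(isTRUE(all.equal(restricted$lag_background_regional,
                                full$lag_background_regional)))
  # a held-out monitor's own mean cannot influence its restricted feature:
  # recomputing with that monitor's records deleted gives the same value
  held <- setdiff(tw_sites$monitor_id, donors)[1]
  no_held <- monitor_lagged_features(
    tw_records[tw_records$monitor_id != held], tw_sites, 2018, donors = donors)
  i <- match(held, restricted$monitor_id)
  expect_equal(unlist(restricted[i, -(1:2)]), unlist(no_held[i, -(1:2)]))

  cv_strict <- cv_stage3(tw_tab3, tw_keys$pm25, 2018, learner_spec(25, 20),
                         k = 4L, seed = 3L, strict = TRUE,
                         records = tw_records, sites = tw_sites)
  cv_fixed <- cv_stage3(tw_tab3, tw_keys$pm25, 2018, learner_spec(25, 20),
                        k = 4L, seed = 3L)
  expect_length(cv_strict$pred, nrow(tw_tab3))
  expect_false(anyNA(cv_strict$pred))
  expect_identical(cv_strict$folds, cv_fixed$folds)
  expect_false(isTRUE(all.equal(cv_strict$pred, cv_fixed$pred)))
  expect_lt(abs(cv_strict$stats[cv_strict$stats$domain == "temporal"]$intercept), 1e-6)
  expect_error(cv_stage3(tw_tab3, tw_keys$pm25, 2018, learner_spec(5, 20),
                         k = 4L, strict = TRUE), "records and sites")
})
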