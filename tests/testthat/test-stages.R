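test_that("Stage-1 recovers an exact PM10 ratio and records its hyperparameters", {
  m <- fit_stage1(wlin_records, wlin$monitors, 2018, learner_spec(100, 4, seed = 5))
  st <- performance_stats(oob_predictions(m), m$y_train)
  expect_gt(st$r2, 0.99)           # PM2.5 = 0.6 * PM10 exactly
  expect_equal(m$spec$ntree, 100L)
  expect_equal(m$spec$mtry, 4L)
  expect_identical(m$schema, pm25grid:::STAGE1_SCHEMA)
  expect_identical(m$transform, "identity")
  # default spec carries the tuned values
  d <- learner_spec(500, 4)
  expect_equal(c(d$ntree, d$mtry), c(500L, 4L))
  # per-year contract: training rows never leave the requested year
  tab <- pm25grid:::stage1_table(wlin_records, wlin$monitors, 2018)
  expect_equal(m$n_train, sum(!is.na(tab$pm25) & !is.na(tab$pm10)))
  expect_error(fit_stage1(wlin_records, wlin$monitors, 2017), "no co-located")
})

test_that("Stage-1 augmentation keeps observed values and fills PM10-only rows", {
  m <- fit_stage1(wlin_records, wlin$monitors, 2018, learner_spec(50, 4))
  aug <- augment_pm25(wlin_records, wlin$monitors, 2018, m)
  r <- wlin_records
  n_obs <- sum(!is.na(r$pm25))
  n_pm10_only <- sum(is.na(r$pm25) & !is.na(r$pm10))
  expect_equal(nrow(aug), n_obs + n_pm10_only)
  expect_identical(sort(unique(aug$pm25_source)), c("observed", "stage1"))
  # observed rows pass through bit-identically
  ob <- merge(aug[aug$pm25_source == "observed"], r, by = c("monitor_id", "date"))
  expect_identical(ob$pm25.x, ob$pm25.y)
  expect_true(all(!is.na(aug$pm25)))
  # near noise-free ratio: imputed values sit close to the latent truth
  st1 <- aug[aug$pm25_source == "stage1"]
  cells <- wlin$monitors$cell_id[match(st1$monitor_id, wlin$monitors$monitor_id)]
  expect_gt(cor(st1$pm25, truth_at(wlin, cells, st1$date)), 0.97)
})

test_that("Stage-2 schema is 35 reanalysis columns plus calendar and coordinates", {
  expect_length(pm25grid:::STAGE2_SCHEMA, 38L)
  expect_equal(sum(grepl("^cams_", pm25grid:::STAGE2_SCHEMA)), 35L)
  fx <- identity_aod_fixture(nx = 8, ny = 8, n_days = 20)
  tab <- build_stage2_table(fx$field, fx$cams, fx$grid)
  expect_true(all(pm25grid:::STAGE2_SCHEMA %in% names(tab)))
  expect_equal(nrow(tab), 64 * 20)
  # the linked reanalysis column reproduces the source array
  expect_equal(tab$cams_055_12, as.vector(fx$cams$values[, , 2, 4]))
})

test_that("Stage-2 recovers satellite AOD when it equals the 12:00 reanalysis value", {
  # noise-free identity: the learner must reproduce the 12:00 column
  fx0 <- identity_aod_fixture(nx = 10, ny = 10, n_days = 60, miss_frac = 0.5,
                              seed = 30, sigma_aod = 0)
  tab0 <- build_stage2_table(fx0$field, fx0$cams, fx0$grid)
  m0 <- fit_stage2(tab0, 2018, 0.55, learner_spec(50, 20, seed = 6))
  expect_gt(performance_stats(oob_predictions(m0), m0$y_train)$r2, 0.99)
  # noisy variant for the imputation-error bound
  fx <- identity_aod_fixture(nx = 10, ny = 10, n_days = 60, miss_frac = 0.5, seed = 31)
  tab <- build_stage2_table(fx$field, fx$cams, fx$grid)
  m <- fit_stage2(tab, 2018, 0.55, learner_spec(50, 20, seed = 6))
  expect_equal(m$spec$ntree, 50L)
  expect_equal(m$spec$mtry, 20L)
  filled <- impute_aod(m, fx$field, tab)
  expect_equal(sum(is.na(filled$values)), 0L)
  # observed cells bitwise untouched, imputed cells flagged
  obs <- !is.na(fx$field$values)
  expect_identical(filled$values[obs], fx$field$values[obs])
  expect_true(all(filled$provenance[obs] == 1L))
  expect_true(all(filled$provenance[!obs] == 2L))
  # withheld-truth error stays within twice the retrieval noise
  expect_lt(mean(abs(filled$values[!obs] - fx$truth[!obs])), 2 * fx$sigma_aod)
  # a complete field comes back identical
  expect_identical(impute_aod(m, filled, tab), filled)
  expect_error(impute_aod(m, daily_aod_field(fx$field$values, 0.47, fx$dates), tab),
               "wavelength")
})

test_that("the Stage-3 table carries exactly the 15 + 27 named predictors", {
  sch <- stage3_schema()
  expect_length(sch$spatiotemporal, 15L)
  expect_length(sch$spatial, 27L)
  inputs <- tw_inputs; lagged <- tw_lagged; keys <- tw_keys; tab3 <- tw_tab3
  expect_equal(nrow(tab3), nrow(keys))
  expect_identical(setdiff(names(tab3), c("monitor_id", "cell_id", "date")),
                   unlist(sch, use.names = FALSE))
  expect_false(anyNA(tab3))
  # model-surface PM2.5 enters as its logarithm
  j <- match(as.Date(tab3$date), tw$dates)
  expect_equal(tab3$log_ctm_pm25, log(tw$ctm_pm25[cbind(tab3$cell_id, j)]))
  # NDVI is constant within a calendar month for a given cell
  one <- tab3[tab3$monitor_id == tab3$monitor_id[1]]
  mo <- format(as.Date(one$date), "%Y-%m")
  expect_true(all(tapply(one$ndvi, mo, function(v) max(v) - min(v)) == 0))
  # missing sources fail loudly naming the column
  broken <- data.table::copy(lagged)
  broken$lag_hotspot_regional[1] <- NA_real_
  expect_error(build_stage3_table(keys[keys$monitor_id == lagged$monitor_id[1],
                                       c("monitor_id", "cell_id", "date")],
                                  inputs, broken),
               "lag_hotspot_regional")
})

test_that("Stage-3 fits on the log scale and predicts positive concentrations", {
  tab3 <- tw_tab3
  tgt <- merge(tab3[, c("monitor_id", "date")],
               tw_records[!is.na(tw_records$pm25),
                          c("monitor_id", "date", "pm25")],
               by = c("monitor_id", "date"), sort = FALSE)$pm25
  m <- fit_stage3(tab3, tgt, 2018, learner_spec(60, 20, seed = 2))
  expect_identical(m$transform, "log")
  expect_equal(m$spec$mtry, 20L)
  p <- predict_stage3(m, tab3)
  expect_true(all(p > 0))
  # permuting rows permutes predictions identically
  idx <- rev(seq_len(200))
  expect_equal(predict_stage3(m, tab3[idx]), p[idx])
  # column order is irrelevant given named schema
  shuffled <- tab3[, rev(names(tab3)), with = FALSE]
  expect_equal(predict_stage3(m, shuffled), p)
  expect_error(fit_stage3(tab3, -tgt, 2018), "nonpositive")
  expect_error(predict_stage3(m, tab3[, 1:10, with = FALSE]), "schema")
  # degenerate constant target returns the training constant
  mc <- fit_stage3(tab3[1:500], rep(12, 500), 2018, learner_spec(25, 20))
  expect_equal(unique(round(predict_stage3(mc, tab3[1:20]), 10)), 12)
})
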