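# Monitor-grouped cross-validation and the R2 / RMSE / intercept / slope
# statistics, overall and decomposed into spatial and temporal components.

#' Random monitor fold assignment
#'
#' Uniform random partition of the monitors into `k` groups, reproducible
#' under the seed. Held-out prediction of a whole group measures performance
#' at locations without a monitor.
#'
#' @param monitor_ids character vector of monitor ids.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return named integer vector: fold (1..k) per monitor.
#' @export
make_folds <- function(monitor_ids, k = 10L, seed = 1L) {
  monitor_ids <- unique(monitor_ids)
  n <- length(monitor_ids)
  if (n < k) stop(sprintf("need at least %d monitors for %d folds (have %d)", k, k, n),
                  call. = FALSE)
  with_seed(seed, {
    fold <- sample(rep(seq_len(k), length.out = n))
    stats::setNames(fold, sample(monitor_ids))  # shuffle id order too
  })
}

#' Monitor-grouped cross-validation
#'
#' For each fold, fits on the rows of all other folds and predicts the
#' held-out monitors' complete series; a monitor's predictions therefore come
#' from a model never trained on any of its rows.
#'
#' @param fit_fn `function(train_rows)` returning a fitted model.
#' @param predict_fn `function(model, test_rows)` returning predictions.
#' @param data `data.table` with a `monitor_id` column.
#' @param folds a [make_folds()] assignment covering `data`'s monitors.
#' @return numeric vector of held-out predictions aligned to `data` rows.
#' @export
cross_validate <- function(fit_fn, predict_fn, data, folds) {
  data <- data.table::as.data.table(data)
  if (!all(data$monitor_id %in% names(folds))) {
    stop("folds do not cover all monitors in the data", call. = FALSE)
  }
  fold_of_row <- unname(folds[data$monitor_id])
  pred <- rep(NA_real_, nrow(data))
  for (f in sort(unique(fold_of_row))) {
    train <- data[fold_of_row != f]
    if (nrow(train) == 0L) stop("fold ", f, " has no training data", call. = FALSE)
    model <- fit_fn(train)
    pred[fold_of_row == f] <- predict_fn(model, data[fold_of_row == f])
  }
  pred
}

#' Prediction performance statistics
#'
#' Ordinary least squares of predicted on observed
#' (`pred = intercept + slope * obs`); `r2` is the squared Pearson correlation
#' (0 when either series is constant), `rmse` the root mean squared raw
#' prediction error — not the regression residual.
#'
#' @param pred,obs aligned numeric vectors (n >= 3).
#' @param domain,method,year,season labels carried into the output.
#' @return one-row `data.table`: `r2`, `rmse`, `intercept`, `slope` plus the
#'   labels.
#' @export
performance_stats <- function(pred, obs, domain = "overall", method = NA_character_,
                              year = NA_integer_, season = NA_character_) {
  keep <- !is.na(pred) & !is.na(obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(obs) < 3L) stop("need at least 3 aligned pairs", call. = FALSE)
  if (sd(obs) < 1e-12) stop("zero variance in observations", call. = FALSE)
  fit <- lm(pred ~ obs)
  r2 <- if (sd(pred) < 1e-12) 0 else cor(pred, obs)^2
  data.table::data.table(
    domain = domain, method = method, year = year, season = season,
    n = length(obs), r2 = r2,
    rmse = sqrt(mean((pred - obs)^2)),
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2])
  )
}

#' Spatial / temporal decomposition of prediction performance
#'
#' Spatial statistics regress the per-monitor means of predictions on the
#' per-monitor means of observations (one point per monitor) and measure
#' long-term average skill. Temporal statistics pool the per-monitor-centered
#' daily deviations and measure skill on day-to-day variation; because both
#' pooled centered series have mean zero, the temporal intercept is zero up to
#' floating point for any input.
#'
#' @param pred,obs aligned numeric vectors.
#' @param monitor_ids monitor id per row.
#' @param ... labels passed to [performance_stats()].
#' @return two-row `data.table` (domains `spatial`, `temporal`).
#' @export
decompose_spatial_temporal <- function(pred, obs, monitor_ids, ...) {
  keep <- !is.na(pred) & !is.na(obs)
  pred <- pred[keep]; obs <- obs[keep]; monitor_ids <- monitor_ids[keep]
  ids <- unique(monitor_ids)
  if (length(ids) < 2L) stop("spatial component needs >= 2 monitors", call. = FALSE)
  mp <- tapply(pred, monitor_ids, mean)
  mo <- tapply(obs, monitor_ids, mean)
  spatial <- performance_stats(as.vector(mp), as.vector(mo), domain = "spatial", ...)
  pc <- pred - mp[monitor_ids]
  oc <- obs - mo[monitor_ids]
  temporal <- performance_stats(as.vector(pc), as.vector(oc), domain = "temporal", ...)
  rbind(spatial, temporal)
}

#' Performance statistics stratified by meteorological season
#'
#' Rows are partitioned by DJF/MAM/JJA/SON and the overall statistics plus the
#' spatial/temporal decomposition are computed within each non-empty season
#' (empty seasons are skipped with a message).
#'
#' @param pred,obs aligned numeric vectors.
#' @param dates `Date` per row.
#' @param monitor_ids monitor id per row.
#' @param ... labels passed through.
#' @return `data.table` of per-season statistics.
#' @export
seasonal_stats <- function(pred, obs, dates, monitor_ids, ...) {
  seas <- met_season(dates)
  out <- list()
  for (s in levels(seas)) {
    i <- which(seas == s)
    if (length(i) < 3L) { message("season ", s, " empty; skipped"); next }
    blocks <- list(performance_stats(pred[i], obs[i], domain = "overall",
                                     season = s, ...))
    if (length(unique(monitor_ids[i])) >= 2L) {
      dec <- decompose_spatial_temporal(pred[i], obs[i], monitor_ids[i], ...)
      dec$season <- s
      blocks <- c(blocks, list(dec))
    }
    out <- c(out, blocks)
  }
  data.table::rbindlist(out)
}

#' Relative predictor importance of a fitted stage model
#'
#' Split-impurity importances (error reduction attributed to each predictor's
#' splits over all trees) normalized to percentages summing to 100, in
#' descending order.
#'
#' @param model a `fitted_stage_model`.
#' @return `data.table` with `predictor`, `importance_pct`, `year`.
#' @export
importance_table <- function(model) {
  if (!inherits(model, "fitted_stage_model")) stop("not a fitted model", call. = FALSE)
  imp <- model$learner$variable.importance
  if (is.null(imp)) stop("model carries no importances", call. = FALSE)
  imp <- pmax(imp, 0)
  pct <- 100 * imp / sum(imp)
  data.table::data.table(predictor = names(pct), importance_pct = as.vector(pct),
                         year = model$year)[order(-importance_pct)]
}

#' Ten-fold monitor-grouped cross-validation of Stage-3
#'
#' Refits the Stage-3 learner per fold and evaluates held-out predictions
#' against the combined observed/Stage-1 target series on the concentration
#' scale. By default the six monitor-derived spatial features are held fixed
#' across folds; in strict mode they are recomputed per fold with the
#' held-out monitors removed from the donor set, eliminating that leakage
#' path (see the methods vignette for the trade-off).
#'
#' @param table a [build_stage3_table()] result for the monitors.
#' @param targets PM2.5 series aligned to the table.
#' @param year calendar year.
#' @param spec a [learner_spec()].
#' @param k,seed fold settings.
#' @param strict recompute the lagged/distance features per fold (requires
#'   `records` and `sites`).
#' @param records,sites inputs for the per-fold feature recomputation.
#' @return list: `pred` (held-out concentrations), `stats` (overall +
#'   spatial/temporal `data.table`), `folds`.
#' @export
cv_stage3 <- function(table, targets, year, spec = learner_spec(500, 20),
                      k = 10L, seed = 1L, strict = FALSE,
                      records = NULL, sites = NULL) {
  stopifnot(length(targets) == nrow(table))
  table <- data.table::as.data.table(table)
  table$..target <- targets
  folds <- make_folds(unique(table$monitor_id), k = k, seed = seed)
  if (!strict) {
    pred <- cross_validate(
      fit_fn = function(tr) fit_stage3(tr, tr$..target, year, spec),
      predict_fn = function(m, te) predict_stage3(m, te),
      data = table, folds = folds
    )
  } else {
    if (is.null(records) || is.null(sites)) {
      stop("strict mode needs records and sites to recompute features", call. = FALSE)
    }
    fold_of_row <- unname(folds[table$monitor_id])
    pred <- rep(NA_real_, nrow(table))
    for (f in sort(unique(fold_of_row))) {
      train_ids <- names(folds)[folds != f]
      lag_f <- monitor_lagged_features(records, sites, year, donors = train_ids)
      tab_f <- data.table::copy(table)
      idx <- match(tab_f$monitor_id, lag_f$monitor_id)
      for (col in LAGGED_COLUMNS) tab_f[[col]] <- lag_f[[col]][idx]
      m <- fit_stage3(tab_f[fold_of_row != f],
                      tab_f$..target[fold_of_row != f], year, spec)
      pred[fold_of_row == f] <- predict_stage3(m, tab_f[fold_of_row == f])
    }
  }
  stats <- rbind(
    performance_stats(pred, targets, domain = "overall", method = "kfold", year = year),
    decompose_spatial_temporal(pred, targets, table$monitor_id,
                               method = "kfold", year = year)
  )
  list(pred = pred, stats = stats, folds = folds)
}
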