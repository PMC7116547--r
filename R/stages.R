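# Stage-1 (PM2.5 from co-located PM10), Stage-2 (satellite-AOD gap filling
# from coarse reanalysis AOD) and Stage-3 (log-PM2.5 prediction) models.
# Every stage fits one model per calendar year on that year's rows only.

STAGE1_SCHEMA <- c("pm10", "monitor_type", "month", "dow", "northing", "easting")

#' Stage-3 predictor schema
#'
#' 15 spatio-temporal predictors (model-surface log-PM2.5, imputed AOD at 0.47
#' and 0.55 um, six meteorological variables, boundary-layer height at 0:00 and
#' 12:00, monthly NDVI, day-of-year, month, day-of-week) and 27 spatial
#' predictors (four IDW-lagged annual means, two nearest-class distances, and
#' 21 static covariates).
#'
#' @format list with character vectors `spatiotemporal` (15) and `spatial`
#'   (27).
#' @export
stage3_schema <- function() {
  list(
    spatiotemporal = c("log_ctm_pm25", "aod_047", "aod_055", "air_temp",
                       "sea_level_pressure", "rel_humidity", "precipitation",
                       "wind_speed", "wind_direction", "blh_00", "blh_12",
                       "ndvi", "yday", "month", "dow"),
    spatial = c(LAGGED_COLUMNS, STATIC_COLUMNS)
  )
}

# ---- Stage-1 ---------------------------------------------------------------

#' Fit the Stage-1 model for one year
#'
#' Predicts daily PM2.5 from co-located PM10 plus monitor type, month,
#' day-of-week and coordinates, trained only on the year's monitor-days where
#' both pollutants are observed.
#'
#' @param records filtered record table.
#' @param sites site table with `monitor_id`, `monitor_type`, `x`, `y`.
#' @param year calendar year.
#' @param spec a [learner_spec()]; default `ntree = 500`, `mtry = 4`.
#' @return a `fitted_stage_model` with OOB predictions.
#' @export
fit_stage1 <- function(records, sites, year, spec = learner_spec(500, 4)) {
  tab <- stage1_table(records, sites, year)
  tab <- tab[!is.na(tab$pm25) & !is.na(tab$pm10)]
  if (nrow(tab) == 0L) stop("no co-located PM2.5/PM10 data in ", year, call. = FALSE)
  fit_rf(tab, tab$pm25, STAGE1_SCHEMA, spec, stage = 1L, year = year)
}

stage1_table <- function(records, sites, year) {
  r <- data.table::as.data.table(records)
  r <- r[date_year(r$date) == year]
  s <- data.table::as.data.table(sites)
  tab <- merge(r, s[, c("monitor_id", "monitor_type", "x", "y")], by = "monitor_id")
  tab$monitor_type <- factor(tab$monitor_type,
                             levels = c("traffic", "industrial", "urban",
                                        "suburban", "rural"))
  tab$month <- date_month(tab$date)
  tab$dow <- date_dow(tab$date)
  tab$easting <- tab$x
  tab$northing <- tab$y
  tab
}

#' Augment monitor PM2.5 with Stage-1 predictions
#'
#' Observed PM2.5 takes precedence; monitor-days with only PM10 receive the
#' Stage-1 prediction; rows with neither pollutant are dropped. A `pm25_source`
#' flag records provenance.
#'
#' @param records filtered record table.
#' @param sites site table.
#' @param year calendar year (must match the model's).
#' @param model a [fit_stage1()] result.
#' @return record table with columns `monitor_id`, `date`, `pm25`,
#'   `pm25_source` (`"observed"` or `"stage1"`).
#' @export
augment_pm25 <- function(records, sites, year, model) {
  if (model$stage != 1L || model$year != year) {
    stop("model is not a Stage-1 model for year ", year, call. = FALSE)
  }
  tab <- stage1_table(records, sites, year)
  tab <- tab[!(is.na(tab$pm25) & is.na(tab$pm10))]
  need <- is.na(tab$pm25) & !is.na(tab$pm10)
  out <- data.table::data.table(
    monitor_id = tab$monitor_id, date = tab$date,
    pm25 = tab$pm25,
    pm25_source = ifelse(is.na(tab$pm25), "stage1", "observed")
  )
  if (any(need)) out$pm25[need] <- predict_rf(model, tab[need])
  out
}

# ---- Stage-2 ---------------------------------------------------------------

cams_column_names <- function() {
  wl <- c("047", "055", "067", "865", "124")
  as.vector(outer(wl, sprintf("%02d", CAMS_HOURS),
                  function(w, h) paste0("cams_", w, "_", h)))
}

STAGE2_SCHEMA <- c(cams_column_names(), "yday", "northing", "easting")

#' Assemble the Stage-2 predictor table
#'
#' One row per (cell, day) with the composited satellite-AOD value (NA where
#' missing), the 35 reanalysis-AOD predictors (5 wavelengths x 7 sub-day
#' times) linked to each cell by nearest coarse-pixel centroid, day-of-year
#' and cell coordinates.
#'
#' @param field a `daily_aod_field` (composited satellite AOD).
#' @param cams the world's coarse reanalysis-AOD bundle (`values` array
#'   `[pixel, day, wavelength, hour]`, `link` index per fine cell).
#' @param grid a [grid_spec()].
#' @return `data.table` with `cell_id`, `date`, `aod` and the 38 predictors.
#' @export
build_stage2_table <- function(field, cams, grid) {
  nc <- nrow(field$values); nd <- ncol(field$values)
  dates <- field$dates
  tab <- data.table::data.table(
    cell_id = rep(seq_len(nc), times = nd),
    date = rep(dates, each = nc),
    aod = as.vector(field$values)
  )
  # column order follows cams_column_names(): wavelength fastest within hour
  for (h in seq_along(CAMS_HOURS)) {
    for (w in seq_along(AOD_WAVELENGTHS)) {
      nm <- paste0("cams_", c("047", "055", "067", "865", "124")[w], "_",
                   sprintf("%02d", CAMS_HOURS[h]))
      tab[[nm]] <- as.vector(cams$values[cams$link, , w, h])
    }
  }
  cc <- cell_centroids(grid)
  tab$yday <- rep(date_yday(dates), each = nc)
  tab$easting <- rep(cc$x, times = nd)
  tab$northing <- rep(cc$y, times = nd)
  tab
}

#' Fit the Stage-2 AOD gap-filling model for one year and wavelength
#'
#' Trained on the year's cell-days with an observed composited satellite-AOD
#' value; predictors are the 35 reanalysis-AOD columns plus day-of-year and
#' coordinates.
#'
#' @param table a [build_stage2_table()] result.
#' @param year calendar year.
#' @param wavelength 0.47 or 0.55 (um), recorded in the model.
#' @param spec a [learner_spec()]; default `ntree = 50`, `mtry = 20`.
#' @return a `fitted_stage_model`.
#' @export
fit_stage2 <- function(table, year, wavelength, spec = learner_spec(50, 20)) {
  tr <- table[date_year(table$date) == year & !is.na(table$aod)]
  if (nrow(tr) == 0L) stop("no observed AOD in ", year, call. = FALSE)
  fit_rf(tr, tr$aod, STAGE2_SCHEMA, spec, stage = 2L, year = year,
         wavelength = wavelength)
}

#' Impute the missing cells of a daily AOD field
#'
#' Observed values are untouched (bitwise); missing cell-days are filled with
#' Stage-2 predictions and flagged `imputed`. The output has zero missing
#' cells.
#'
#' @param model a [fit_stage2()] result.
#' @param field the `daily_aod_field` to fill.
#' @param table the matching [build_stage2_table()] predictor table.
#' @return a complete `daily_aod_field`.
#' @export
impute_aod <- function(model, field, table) {
  if (model$stage != 2L) stop("not a Stage-2 model", call. = FALSE)
  if (!isTRUE(all.equal(model$wavelength, field$wavelength))) {
    stop("model wavelength does not match the field", call. = FALSE)
  }
  nc <- nrow(field$values)
  miss <- which(is.na(field$values))          # column-major == table row order
  if (length(miss) == 0L) return(field)
  if (nrow(table) != length(field$values)) {
    stop("predictor table does not cover the field", call. = FALSE)
  }
  sub <- table[miss]
  if (anyNA(sub[, STAGE2_SCHEMA, with = FALSE])) {
    bad <- unique(sub$cell_id[!stats::complete.cases(sub[, STAGE2_SCHEMA, with = FALSE])])
    stop("missing reanalysis predictors for cells: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  vals <- field$values
  vals[miss] <- pmax(predict_rf(model, sub), 0)
  prov <- field$provenance
  prov[miss] <- 2L
  daily_aod_field(vals, field$wavelength, field$dates, prov)
}

# ---- Stage-3 ---------------------------------------------------------------

#' Bundle the gridded Stage-3 input sources of a world
#'
#' Collects the model-surface PM2.5, meteorology, NDVI, statics and the two
#' imputed AOD fields into one source object consumed by
#' [build_stage3_table()].
#'
#' @param world a [generate_world()] result.
#' @param aod047,aod055 complete `daily_aod_field`s from [impute_aod()].
#' @return a `stage3_inputs` list.
#' @export
stage3_inputs <- function(world, aod047, aod055) {
  stopifnot(inherits(aod047, "daily_aod_field"), inherits(aod055, "daily_aod_field"))
  if (anyNA(aod047$values) || anyNA(aod055$values)) {
    stop("AOD fields must be complete (run impute_aod first)", call. = FALSE)
  }
  structure(list(grid = world$grid, dates = world$dates,
                 ctm = world$ctm_pm25, met = world$met,
                 ndvi = world$ndvi, ndvi_months = world$ndvi_months,
                 statics = world$statics,
                 aod047 = aod047$values, aod055 = aod055$values),
            class = "stage3_inputs")
}

#' Assemble the Stage-3 predictor table
#'
#' One row per requested (cell, day) key carrying exactly the
#' [stage3_schema()] columns: the model-surface PM2.5 enters as its logarithm,
#' NDVI is the month's value repeated over its days, and the six
#' lagged/distance columns are joined from the supplied feature table (keyed
#' by `monitor_id` for monitor rows, by `cell_id` for grid rows). Any missing
#' source value is an error naming the column.
#'
#' @param keys `data.table` with `cell_id`, `date` and (for monitor targets)
#'   `monitor_id`.
#' @param inputs a [stage3_inputs()] bundle.
#' @param lagged lagged-feature table from [monitor_lagged_features()] or
#'   [grid_lagged_features()].
#' @return `data.table`: the key columns plus the 42 predictors.
#' @export
build_stage3_table <- function(keys, inputs, lagged) {
  keys <- data.table::as.data.table(keys)
  j <- match(as.Date(keys$date), inputs$dates)
  if (anyNA(j)) stop("keys contain dates outside the input coverage", call. = FALSE)
  idx <- cbind(keys$cell_id, j)
  tab <- data.table::copy(keys)
  ctmv <- inputs$ctm[idx]
  if (any(ctmv <= 0)) stop("nonpositive model-surface PM2.5", call. = FALSE)
  tab$log_ctm_pm25 <- log(ctmv)
  tab$aod_047 <- inputs$aod047[idx]
  tab$aod_055 <- inputs$aod055[idx]
  tab$air_temp <- inputs$met$air_temp[idx]
  tab$sea_level_pressure <- inputs$met$sea_level_pressure[idx]
  tab$rel_humidity <- inputs$met$rel_humidity[idx]
  tab$precipitation <- inputs$met$precipitation[idx]
  tab$wind_speed <- inputs$met$wind_speed[idx]
  tab$wind_direction <- inputs$met$wind_dir[idx]
  tab$blh_00 <- inputs$met$blh_00[idx]
  tab$blh_12 <- inputs$met$blh_12[idx]
  ymk <- match(format(as.Date(keys$date), "%Y-%m"), inputs$ndvi_months)
  tab$ndvi <- inputs$ndvi[cbind(keys$cell_id, ymk)]
  tab$yday <- date_yday(keys$date)
  tab$month <- date_month(keys$date)
  tab$dow <- date_dow(keys$date)

  lag_key <- if ("monitor_id" %in% names(lagged)) "monitor_id" else "cell_id"
  lg <- data.table::as.data.table(lagged)[, c(lag_key, LAGGED_COLUMNS), with = FALSE]
  tab <- merge(tab, lg, by = lag_key, all.x = TRUE, sort = FALSE)
  tab <- merge(tab, inputs$statics, by = "cell_id", all.x = TRUE, sort = FALSE)

  sch <- unlist(stage3_schema(), use.names = FALSE)
  for (col in sch) {
    if (anyNA(tab[[col]])) {
      bad <- which(is.na(tab[[col]]))[1L]
      stop(sprintf("missing value in column '%s' (e.g. cell %d, %s)", col,
                   tab$cell_id[bad], format(as.Date(tab$date[bad]))), call. = FALSE)
    }
  }
  data.table::setcolorder(tab, c(intersect(c("monitor_id", "cell_id", "date"),
                                           names(tab)), sch))
  tab
}

#' Fit the Stage-3 log-PM2.5 model for one year
#'
#' The target is log-transformed so back-transformed predictions are strictly
#' positive; OOB predictions are retained on the log scale.
#'
#' @param table a [build_stage3_table()] result.
#' @param targets PM2.5 concentrations (ug/m3) aligned to the table rows; must
#'   be strictly positive.
#' @param year calendar year.
#' @param spec a [learner_spec()]; default `ntree = 500`, `mtry = 20`.
#' @return a `fitted_stage_model` with `transform = "log"`.
#' @export
fit_stage3 <- function(table, targets, year, spec = learner_spec(500, 20)) {
  stopifnot(length(targets) == nrow(table))
  keep <- date_year(table$date) == year
  if (!any(keep)) stop("no rows for year ", year, call. = FALSE)
  if (any(targets[keep] <= 0)) stop("nonpositive target", call. = FALSE)
  sch <- unlist(stage3_schema(), use.names = FALSE)
  fit_rf(table[keep], targets[keep], sch, spec, stage = 3L, year = year,
         transform = "log")
}

#' Predict PM2.5 concentrations from a Stage-3 model
#'
#' Naive exponentiation of the ensemble's log-scale output; no bias
#' correction. Output is strictly positive.
#'
#' @param model a [fit_stage3()] result.
#' @param table predictor table matching the model schema.
#' @return concentrations in ug/m3.
#' @export
predict_stage3 <- function(model, table) {
  if (model$stage != 3L) stop("not a Stage-3 model", call. = FALSE)
  exp(predict_rf(model, table))
}
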