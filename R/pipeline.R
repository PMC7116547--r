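# End-to-end orchestration: simulate -> preprocess -> Stage-1 -> Stage-2 ->
# Stage-3 -> validate -> Stage-4.

#' Pipeline configuration
#'
#' @param world a [world_config()].
#' @param qa_policy a [default_qa_policy()].
#' @param stage1_spec,stage2_spec,stage3_spec [learner_spec()]s per stage;
#'   defaults are the tuned values (500/4, 50/20, 500/20).
#' @param cv_k,cv_seed monitor-grouped cross-validation settings.
#' @param stage4_dates `Date` vector to reconstruct (`NULL` = every study
#'   day).
#' @param run_cv set `FALSE` to skip the k-fold CV (OOB statistics are always
#'   computed).
#' @param run_stage4 set `FALSE` to stop after validation.
#' @param outdir optional directory for CSV/JSON artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(),
                            qa_policy = default_qa_policy(),
                            stage1_spec = learner_spec(500, 4),
                            stage2_spec = learner_spec(50, 20),
                            stage3_spec = learner_spec(500, 20),
                            cv_k = 10L, cv_seed = 1L,
                            stage4_dates = NULL, run_cv = TRUE,
                            run_stage4 = TRUE, outdir = NULL) {
  structure(list(world = world, qa_policy = qa_policy,
                 stage1_spec = stage1_spec, stage2_spec = stage2_spec,
                 stage3_spec = stage3_spec, cv_k = as.integer(cv_k),
                 cv_seed = as.integer(cv_seed), stage4_dates = stage4_dates,
                 run_cv = isTRUE(run_cv),
                 run_stage4 = isTRUE(run_stage4), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full multi-stage pipeline
#'
#' Generates the synthetic study region, applies monitor QC, fits the
#' per-year Stage-1/2/3 models, validates Stage-3 by OOB and monitor-grouped
#' k-fold CV with the spatial/temporal decomposition and seasonal
#' stratification, and (optionally) reconstructs the full grid. When `outdir`
#' is set, validation tables, the importance ranking and gridded outputs are
#' written as CSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a report list (world, models, stats, importance, reconstruction,
#'   timings).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }

  say("simulate: %dx%d grid, years %s, seed %d", config$world$grid_nx,
      config$world$grid_ny, paste(config$world$years, collapse = ","),
      config$world$seed)
  world <- clock("simulate", generate_world(config$world))
  years <- unique(date_year(world$dates))

  say("preprocess: dedup + completeness filters on %d monitors", nrow(world$monitors))
  prep <- clock("preprocess", {
    dd <- dedupe_colocated(world$monitors, world$records)
    list(sites = dd$sites, records = apply_completeness_filters(dd$records))
  })
  sites <- prep$sites; records <- prep$records

  say("stage1: per-year PM2.5 augmentation from PM10")
  s1 <- clock("stage1", {
    out <- list()
    for (y in years) {
      m <- fit_stage1(records, sites, y, config$stage1_spec)
      out[[as.character(y)]] <- list(model = m,
                                     augmented = augment_pm25(records, sites, y, m))
    }
    out
  })
  augmented <- data.table::rbindlist(lapply(s1, `[[`, "augmented"))

  say("stage2: AOD compositing + gap filling (0.47, 0.55 um)")
  s2 <- clock("stage2", {
    out <- list()
    for (wl in c(0.47, 0.55)) {
      f <- composite_world_aod(world, wl, config$qa_policy)
      tab <- build_stage2_table(f, world$cams, world$grid)
      models <- list(); filled <- f
      for (y in years) {
        m <- fit_stage2(tab, y, wl, config$stage2_spec)
        models[[as.character(y)]] <- m
        yr_cols <- date_year(filled$dates) == y
        filled_y <- impute_aod(m, filled, tab)
        filled$values[, yr_cols] <- filled_y$values[, yr_cols]
        filled$provenance[, yr_cols] <- filled_y$provenance[, yr_cols]
      }
      out[[sprintf("%.2f", wl)]] <- list(field = f, filled = filled,
                                         models = models, missing = mean(is.na(f$values)))
    }
    out
  })

  say("stage3: assemble 15+27 predictor table and fit per year")
  inputs <- stage3_inputs(world, s2[["0.47"]]$filled, s2[["0.55"]]$filled)
  s3 <- clock("stage3", {
    out <- list()
    for (y in years) {
      lagged <- monitor_lagged_features(records, sites, y)
      aug_y <- augmented[date_year(augmented$date) == y]
      keys <- merge(aug_y, sites[, c("monitor_id", "cell_id")], by = "monitor_id")
      tab <- build_stage3_table(keys[, c("monitor_id", "cell_id", "date")],
                                inputs, lagged)
      # merge preserves no particular order; realign targets by key
      tgt <- merge(tab[, c("monitor_id", "date")], aug_y, by = c("monitor_id", "date"),
                   sort = FALSE)
      m <- fit_stage3(tab, tgt$pm25, y, config$stage3_spec)
      out[[as.character(y)]] <- list(model = m, table = tab, targets = tgt$pm25,
                                     lagged = lagged)
    }
    out
  })

  say("validate: OOB + %d-fold monitor CV with spatial/temporal decomposition",
      config$cv_k)
  val <- clock("validate", {
    rows <- list(); seas <- list(); cvpred <- list()
    for (y in years) {
      ys <- as.character(y)
      m1 <- s1[[ys]]$model
      rows[[length(rows) + 1L]] <- performance_stats(
        oob_predictions(m1), m1$y_train, method = "OOB", year = y)[
          , c("stage", "wavelength") := .("stage1", NA_character_)]
      for (wl in c("0.47", "0.55")) {
        m2 <- s2[[wl]]$models[[ys]]
        rows[[length(rows) + 1L]] <- performance_stats(
          oob_predictions(m2), m2$y_train, method = "OOB", year = y)[
            , c("stage", "wavelength") := .("stage2", wl)]
      }
      m3 <- s3[[ys]]$model
      rows[[length(rows) + 1L]] <- performance_stats(
        m3$oob, m3$y_train, method = "OOB_log", year = y)[
          , c("stage", "wavelength") := .("stage3", NA_character_)]
      if (config$run_cv) {
        cv <- cv_stage3(s3[[ys]]$table, s3[[ys]]$targets, y, config$stage3_spec,
                        k = config$cv_k, seed = config$cv_seed)
        cvst <- data.table::copy(cv$stats)[, c("stage", "wavelength") := .("stage3", NA_character_)]
        rows[[length(rows) + 1L]] <- cvst
        seas[[ys]] <- seasonal_stats(cv$pred, s3[[ys]]$targets,
                                     s3[[ys]]$table$date, s3[[ys]]$table$monitor_id,
                                     method = "kfold", year = y)
        cvpred[[ys]] <- cv$pred
      }
    }
    list(stats = data.table::rbindlist(rows, fill = TRUE),
         seasonal = data.table::rbindlist(seas), cv_pred = cvpred)
  })
  importance <- data.table::rbindlist(
    lapply(s3, function(e) importance_table(e$model)))

  recon <- NULL
  if (config$run_stage4) {
    say("stage4: full-grid reconstruction")
    recon <- clock("stage4", {
      models <- lapply(s3, `[[`, "model")
      gl <- list()
      for (y in years) gl[[as.character(y)]] <-
          grid_lagged_features(records, sites, world$grid, y)
      series <- predict_grid(models, inputs, gl, dates = config$stage4_dates)
      list(series = series, annual = aggregate_series(series, "annual"))
    })
  }

  report <- list(world = world, sites = sites, records = records,
                 augmented = augmented, stage1 = s1, stage2 = s2, stage3 = s3,
                 inputs = inputs, validation = val, importance = importance,
                 reconstruction = recon, timings = timings, config = config)
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$validation$stats, file.path(outdir, "validation_stats.csv"))
  data.table::fwrite(report$validation$seasonal, file.path(outdir, "validation_seasonal.csv"))
  data.table::fwrite(report$importance, file.path(outdir, "importance.csv"))
  if (!is.null(report$reconstruction)) {
    write_grid(report$reconstruction$series, file.path(outdir, "stage4_daily"))
    data.table::fwrite(report$reconstruction$annual,
                       file.path(outdir, "stage4_annual_mean.csv"))
  }
  jsonlite::write_json(
    list(seed = report$config$world$seed, timings = report$timings),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE)
  invisible(outdir)
}
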