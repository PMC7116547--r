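# Stage-4: apply the per-year Stage-3 models to every grid cell and day.

#' Reconstruct daily PM2.5 over the full grid
#'
#' For each requested date, assembles the grid-keyed Stage-3 predictor table
#' (lagged features via the all-donors grid formula) and applies the year's
#' Stage-3 model, yielding a complete positive field.
#'
#' @param models named list of Stage-3 models keyed by year (`"2018"` etc.).
#' @param inputs a [stage3_inputs()] bundle.
#' @param grid_lagged named list of [grid_lagged_features()] tables keyed by
#'   year.
#' @param dates `Date` vector to reconstruct (default: all input dates).
#' @param chunk_days dates processed per prediction batch (memory control).
#' @return a `gridded_series`: list with `grid`, `dates`, `values`
#'   (cells x days matrix, ug/m3) and `model_year` per date.
#' @export
predict_grid <- function(models, inputs, grid_lagged, dates = NULL,
                         chunk_days = 32L) {
  dates <- as.Date(dates %||% inputs$dates)
  yrs <- date_year(dates)
  for (y in unique(yrs)) {
    if (is.null(models[[as.character(y)]])) {
      stop("no Stage-3 model for year ", y, call. = FALSE)
    }
    if (is.null(grid_lagged[[as.character(y)]])) {
      stop("no grid lagged features for year ", y, call. = FALSE)
    }
  }
  nc <- n_cells(inputs$grid)
  values <- matrix(NA_real_, nc, length(dates))
  for (start in seq(1L, length(dates), by = chunk_days)) {
    idx <- start:min(start + chunk_days - 1L, length(dates))
    for (y in unique(yrs[idx])) {
      di <- idx[yrs[idx] == y]
      keys <- data.table::data.table(
        cell_id = rep(seq_len(nc), times = length(di)),
        date = rep(dates[di], each = nc)
      )
      tab <- build_stage3_table(keys, inputs, grid_lagged[[as.character(y)]])
      p <- predict_stage3(models[[as.character(y)]], tab)
      # tab preserves key order (cell within date)
      values[, di] <- matrix(p, nc, length(di))
    }
  }
  structure(list(grid = inputs$grid, dates = dates, values = values,
                 model_year = yrs),
            class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("<gridded_series> %d cells x %d days (%s..%s), mean %.2f ug/m3\n",
              nrow(x$values), ncol(x$values), format(min(x$dates)),
              format(max(x$dates)), mean(x$values)))
  invisible(x)
}

#' Aggregate a gridded series to per-cell period means
#'
#' @param series a [predict_grid()] result.
#' @param period `"annual"` (one mean field per calendar year) or a `Date`
#'   vector defining a custom period (all dates must be in the series).
#' @return `data.table` with `cell_id`, `period`, `pm25` (arithmetic mean over
#'   the period's days).
#' @export
aggregate_series <- function(series, period = "annual") {
  if (identical(period, "annual")) {
    yrs <- date_year(series$dates)
    out <- lapply(unique(yrs), function(y) {
      data.table::data.table(
        cell_id = seq_len(nrow(series$values)),
        period = as.character(y),
        pm25 = rowMeans(series$values[, yrs == y, drop = FALSE])
      )
    })
    return(data.table::rbindlist(out))
  }
  period <- as.Date(period)
  if (length(period) == 0L) stop("empty period", call. = FALSE)
  j <- match(period, series$dates)
  if (anyNA(j)) stop("period contains dates outside the series", call. = FALSE)
  data.table::data.table(
    cell_id = seq_len(nrow(series$values)),
    period = sprintf("%s..%s", format(min(period)), format(max(period))),
    pm25 = rowMeans(series$values[, j, drop = FALSE])
  )
}

#' Write a gridded series or field to disk
#'
#' Long-format CSV (`cell_id, date, pm25`) plus a JSON metadata sidecar
#' recording the grid geometry and units (`ug m-3`); values round-trip
#' exactly through [read_grid()].
#'
#' @param x a `gridded_series` or an [aggregate_series()] field table.
#' @param path output path without extension; `<path>.csv` and `<path>.json`
#'   are written.
#' @param format only `"csv"` is supported.
#' @return the CSV path, invisibly.
#' @export
write_grid <- function(x, path, format = "csv") {
  if (!identical(format, "csv")) stop("unknown format: ", format, call. = FALSE)
  if (inherits(x, "gridded_series")) {
    long <- data.table::data.table(
      cell_id = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
      date = rep(x$dates, each = nrow(x$values)),
      pm25 = as.vector(x$values)
    )
    meta <- list(kind = "gridded_series", units = "ug m-3",
                 nx = x$grid$nx, ny = x$grid$ny, cell_size = x$grid$cell_size,
                 origin_x = x$grid$origin_x, origin_y = x$grid$origin_y,
                 dates = format(x$dates))
  } else {
    long <- data.table::as.data.table(x)
    meta <- list(kind = "field_table", units = "ug m-3")
  }
  csv <- paste0(path, ".csv")
  data.table::fwrite(long, csv)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a gridded series written by [write_grid()]
#'
#' @param path path without extension.
#' @return for `gridded_series` metadata, the reconstructed object; otherwise
#'   the long table.
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- data.table::fread(paste0(path, ".csv"))
  if (!identical(meta$kind, "gridded_series")) return(long)
  grid <- grid_spec(meta$nx, meta$ny, meta$cell_size, meta$origin_x, meta$origin_y)
  dates <- as.Date(meta$dates)
  values <- matrix(long$pm25, nrow = n_cells(grid), ncol = length(dates))
  structure(list(grid = grid, dates = dates, values = values,
                 model_year = date_year(dates)),
            class = "gridded_series")
}
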