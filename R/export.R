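# Plain-text export of a synthetic world: CSV tables for monitors, records
# and statics; long-format CSV for the daily fields; JSON metadata. All values
# round-trip exactly (fwrite/fread at full precision).

#' Export a synthetic world to a directory
#'
#' Writes `monitors.csv`, `records.csv`, `statics.csv`, `aod_scenes.csv`
#' (observed overpass values only; cloud-masked cell-days are the absent
#' rows), `ctm.csv`, `met.csv`, `cams.csv`, `ndvi.csv` and `meta.json`.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  fw(world$monitors, "monitors.csv")
  fw(world$records, "records.csv")
  fw(world$statics, "statics.csv")

  nc <- nrow(world$truth_pm25); nd <- ncol(world$truth_pm25)
  scene_rows <- lapply(world$aod$scenes, function(sc) {
    obs <- which(!sc$mask)
    data.table::data.table(
      overpass = sc$overpass,
      cell_id = ((obs - 1L) %% nc) + 1L,
      date = world$dates[((obs - 1L) %/% nc) + 1L],
      aod_047 = sc$aod_047[obs], aod_055 = sc$aod_055[obs],
      uncertainty = sc$uncertainty[obs], qa_best = sc$qa_best[obs]
    )
  })
  fw(data.table::rbindlist(scene_rows), "aod_scenes.csv")

  long_field <- function(mat) {
    data.table::data.table(
      cell_id = rep(seq_len(nc), times = nd),
      date = rep(world$dates, each = nc),
      value = as.vector(mat)
    )
  }
  fw(long_field(world$ctm_pm25), "ctm.csv")

  met <- long_field(world$met[[1]])
  data.table::setnames(met, "value", names(world$met)[1])
  for (nm in names(world$met)[-1]) met[[nm]] <- as.vector(world$met[[nm]])
  fw(met, "met.csv")

  cams <- world$cams
  nb <- dim(cams$values)[1]
  rows <- list()
  for (w in seq_along(cams$wavelengths)) {
    for (h in seq_along(cams$hours)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        block = rep(seq_len(nb), times = nd),
        date = rep(world$dates, each = nb),
        wavelength = cams$wavelengths[w], hour = cams$hours[h],
        value = as.vector(cams$values[, , w, h])
      )
    }
  }
  fw(data.table::rbindlist(rows), "cams.csv")

  ndvi <- data.table::data.table(
    cell_id = rep(seq_len(nc), times = length(world$ndvi_months)),
    year_month = rep(world$ndvi_months, each = nc),
    ndvi = as.vector(world$ndvi)
  )
  fw(ndvi, "ndvi.csv")

  jsonlite::write_json(list(
    grid = world$grid[c("nx", "ny", "cell_size", "origin_x", "origin_y")],
    dates = format(range(world$dates)),
    n_days = nd,
    seed = world$config$seed,
    aod_mask_count = vapply(world$aod$scenes, function(sc) sum(sc$mask), numeric(1)),
    units = list(pm25 = "ug m-3", aod = "1")
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-import the tabular products of an exported world
#'
#' @param dir directory written by [export_world()].
#' @return list of `data.table`s (`monitors`, `records`, `statics`,
#'   `aod_scenes`, `ctm`, `met`, `cams`, `ndvi`) plus `meta`.
#' @export
import_world <- function(dir) {
  rd <- function(f, ...) data.table::fread(file.path(dir, f), ...)
  out <- list(
    monitors = rd("monitors.csv"),
    records = rd("records.csv"),
    statics = rd("statics.csv"),
    aod_scenes = rd("aod_scenes.csv"),
    ctm = rd("ctm.csv"),
    met = rd("met.csv"),
    cams = rd("cams.csv"),
    ndvi = rd("ndvi.csv"),
    meta = jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  )
  out$records$date <- as.Date(out$records$date)
  out$aod_scenes$date <- as.Date(out$aod_scenes$date)
  out$ctm$date <- as.Date(out$ctm$date)
  out$met$date <- as.Date(out$met$date)
  out$cams$date <- as.Date(out$cams$date)
  out
}
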