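# Monitor-network quality control, class grouping and AOD compositing.

#' Monitor class from monitor type
#'
#' Traffic and industrial monitors form the hotspot class; urban, suburban and
#' rural monitors the background class.
#'
#' @param monitor_type character vector.
#' @return character vector, `"hotspot"` or `"background"`.
#' @export
site_class <- function(monitor_type) {
  ok <- monitor_type %in% c("traffic", "industrial", "urban", "suburban", "rural")
  if (!all(ok)) stop("unknown monitor_type: ", paste(unique(monitor_type[!ok]), collapse = ", "))
  ifelse(monitor_type %in% c("traffic", "industrial"), "hotspot", "background")
}

#' Drop cross-network duplicate monitors
#'
#' When two monitors from different networks report exactly the same series
#' (pairwise correlation 1 within `1e-9` on overlapping days, requiring at
#' least two overlapping days) and sit within `max_dist` km of each other, the
#' monitor from the non-preferred network is dropped together with its records.
#'
#' @param sites `data.table` with `monitor_id`, `network`, `x`, `y`.
#' @param records long record table with `monitor_id`, `date`, `pm25`, `pm10`.
#' @param preferred network kept when a duplicate pair is found.
#' @param max_dist separation threshold in km.
#' @return list with deduplicated `sites` and `records`.
#' @export
dedupe_colocated <- function(sites, records, preferred = "AURN", max_dist = 0.1) {
  sites <- data.table::as.data.table(sites)
  records <- data.table::as.data.table(records)
  drop <- character(0)
  ids <- sites$monitor_id
  series <- function(id, col) {
    r <- records[records$monitor_id == id]
    stats::setNames(r[[col]], as.character(r$date))
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      si <- sites[i]; sj <- sites[j]
      if (si$network == sj$network) next
      d <- sqrt((si$x - sj$x)^2 + (si$y - sj$y)^2)
      if (d >= max_dist) next
      dup <- FALSE
      for (col in c("pm25", "pm10")) {
        a <- series(si$monitor_id, col); b <- series(sj$monitor_id, col)
        common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
        if (length(common) < 2L) next
        va <- a[common]; vb <- b[common]
        if (sd(va) < 1e-12 || sd(vb) < 1e-12) {
          if (max(abs(va - vb)) < 1e-9) dup <- TRUE
        } else if (cor(va, vb) >= 1 - 1e-9) dup <- TRUE
      }
      if (!dup) next
      victim <- if (si$network == preferred) sj$monitor_id
                else if (sj$network == preferred) si$monitor_id
                else max(si$monitor_id, sj$monitor_id)
      drop <- union(drop, victim)
    }
  }
  list(sites = sites[!sites$monitor_id %in% drop],
       records = records[!records$monitor_id %in% drop])
}

#' Apply the daily and annual completeness filters
#'
#' Per pollutant: monitor-days with fewer than 18 observed hours are removed,
#' then monitor-years left with fewer than 30 surviving days are removed. Rows
#' where both pollutants fail are dropped entirely. Idempotent.
#'
#' @param records long record table with `hours_pm25`, `hours_pm10`.
#' @param min_hours daily completeness threshold (hours).
#' @param min_days annual completeness threshold (days).
#' @return filtered record table.
#' @export
apply_completeness_filters <- function(records, min_hours = 18L, min_days = 30L) {
  r <- data.table::as.data.table(records)
  yr <- date_year(r$date)
  for (p in c("pm25", "pm10")) {
    hcol <- paste0("hours_", p)
    bad_day <- is.na(r[[p]]) | r[[hcol]] < min_hours
    r[[p]][bad_day] <- NA_real_
    # annual rule on the surviving days
    key <- paste(r$monitor_id, yr)
    ok_days <- tapply(!is.na(r[[p]]), key, sum)
    bad_year <- names(ok_days)[ok_days < min_days]
    r[[p]][key %in% bad_year] <- NA_real_
  }
  r[!(is.na(r$pm25) & is.na(r$pm10))]
}

#' QA policy for satellite-AOD compositing
#'
#' @param require_best drop overpass values whose QA flag is not "best".
#' @param max_uncertainty drop overpass values with retrieval uncertainty above
#'   this threshold.
#' @return a `qa_policy` list.
#' @export
default_qa_policy <- function(require_best = TRUE, max_uncertainty = 0.05) {
  structure(list(require_best = require_best, max_uncertainty = max_uncertainty),
            class = "qa_policy")
}

#' Composite per-overpass AOD scenes into a daily field
#'
#' Per cell, overpass values failing QA (flag not best, or uncertainty above
#' the threshold) are dropped and the survivors averaged; a cell with no
#' surviving overpass value is missing.
#'
#' @param scenes list of scenes sharing one date; each scene is a list with
#'   vectors `aod` (NA where cloud-masked), `uncertainty`, `qa_best` over the
#'   same cells.
#' @param qa_policy a [default_qa_policy()].
#' @return numeric vector of composited AOD per cell (NA = missing).
#' @export
composite_daily_aod <- function(scenes, qa_policy = default_qa_policy()) {
  if (length(scenes) == 0L) stop("no scenes to composite", call. = FALSE)
  n <- length(scenes[[1]]$aod)
  acc <- numeric(n); cnt <- integer(n)
  for (sc in scenes) {
    v <- sc$aod
    pass <- !is.na(v)
    if (isTRUE(qa_policy$require_best)) pass <- pass & sc$qa_best
    pass <- pass & sc$uncertainty <= qa_policy$max_uncertainty
    acc[pass] <- acc[pass] + v[pass]
    cnt[pass] <- cnt[pass] + 1L
  }
  out <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  out
}

#' Daily composited AOD field for a whole synthetic world
#'
#' Vectorized application of the [composite_daily_aod()] rule over every study
#' day, returning a `daily_aod_field`: a cells x days value matrix with NA for
#' missing and a provenance matrix (`0` missing, `1` observed, `2` imputed).
#'
#' @param world a [generate_world()] result.
#' @param wavelength 0.47 or 0.55 (um).
#' @param qa_policy a [default_qa_policy()].
#' @return a `daily_aod_field` object.
#' @export
composite_world_aod <- function(world, wavelength = 0.55,
                                qa_policy = default_qa_policy()) {
  col <- switch(as.character(wavelength), "0.47" = "aod_047", "0.55" = "aod_055",
                stop("wavelength must be 0.47 or 0.55"))
  dims <- dim(world$truth_pm25)
  acc <- matrix(0, dims[1], dims[2]); cnt <- matrix(0L, dims[1], dims[2])
  for (sc in world$aod$scenes) {
    v <- sc[[col]]
    pass <- !is.na(v)
    if (isTRUE(qa_policy$require_best)) pass <- pass & sc$qa_best
    pass <- pass & sc$uncertainty <= qa_policy$max_uncertainty
    acc[pass] <- acc[pass] + v[pass]
    cnt[pass] <- cnt[pass] + 1L
  }
  values <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  daily_aod_field(values, wavelength, world$dates,
                  provenance = ifelse(cnt > 0L, 1L, 0L))
}

#' Construct a daily AOD field container
#'
#' @param values cells x days numeric matrix, NA = missing.
#' @param wavelength wavelength in um.
#' @param dates `Date` vector matching the columns.
#' @param provenance integer matrix (or scalar): 0 missing, 1 observed,
#'   2 imputed.
#' @return a `daily_aod_field`.
#' @export
daily_aod_field <- function(values, wavelength, dates, provenance = NULL) {
  values <- as.matrix(values)
  if (is.null(provenance)) provenance <- ifelse(is.na(values), 0L, 1L)
  if (length(provenance) == 1L) {
    provenance <- matrix(as.integer(provenance), nrow(values), ncol(values))
  }
  stopifnot(ncol(values) == length(dates), all(dim(values) == dim(provenance)))
  if (any(!is.na(values) & values < 0)) stop("AOD values must be >= 0")
  structure(list(values = values, wavelength = wavelength,
                 dates = as.Date(dates), provenance = provenance),
            class = "daily_aod_field")
}

#' @export
print.daily_aod_field <- function(x, ...) {
  cat(sprintf("<daily_aod_field> %.2f um, %d cells x %d days, %.1f%% missing (%d imputed)\n",
              x$wavelength, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values)), sum(x$provenance == 2L)))
  invisible(x)
}
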