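#' @importFrom stats rnorm runif rbinom rgamma sd cor lm coef predict quantile aggregate
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

#' Daily temporal index for a set of study years
#'
#' Builds the sequence of civil days covering whole calendar years, the unit of
#' the per-year models (leap years contribute 366 days).
#'
#' @param years integer vector of calendar years.
#' @return a `Date` vector covering every day of `years`, in order.
#' @export
pm_dates <- function(years) {
  years <- sort(unique(as.integer(years)))
  do.call(c, lapply(years, function(y) {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")
  }))
}

#' Meteorological season of a date
#'
#' @param dates `Date` vector.
#' @return factor with levels DJF, MAM, JJA, SON.
#' @export
met_season <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
         "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}

date_year <- function(dates) as.integer(format(as.Date(dates), "%Y"))
date_month <- function(dates) as.integer(format(as.Date(dates), "%m"))
date_yday <- function(dates) as.integer(format(as.Date(dates), "%j"))
# ISO day-of-week, Monday = 1
date_dow <- function(dates) {
  d <- as.integer(format(as.Date(dates), "%u"))
  d
}
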