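# IDW-LOOCV spatially-lagged annual PM2.5 features and nearest-class distances.
#
# Four lagged variables per target and year: hotspot/background class means
# combined with inverse-distance (power 1, "regional") or inverse-squared-
# distance (power 2, "local") weights; plus the distance to the nearest
# monitor of each class.

#' Annual class-labelled monitor means of PM2.5
#'
#' Arithmetic mean of the available daily PM2.5 per monitor and year, carrying
#' the monitor class; monitors with no PM2.5 data that year are omitted.
#'
#' @param records filtered record table (`monitor_id`, `date`, `pm25`).
#' @param sites site table with `monitor_id`, `monitor_type`, `x`, `y`.
#' @param year calendar year.
#' @return `data.table` with `monitor_id`, `year`, `class`, `mean_pm25`,
#'   `n_days`, `x`, `y`.
#' @export
annual_class_means <- function(records, sites, year) {
  r <- data.table::as.data.table(records)
  r <- r[date_year(r$date) == year & !is.na(r$pm25)]
  if (nrow(r) == 0L) {
    return(data.table::data.table(monitor_id = character(0), year = integer(0),
                                  class = character(0), mean_pm25 = numeric(0),
                                  n_days = integer(0), x = numeric(0), y = numeric(0)))
  }
  pm25 <- NULL  # NSE
  m <- r[, .(mean_pm25 = mean(pm25), n_days = .N), by = "monitor_id"]
  s <- data.table::as.data.table(sites)
  m <- merge(m, s[, c("monitor_id", "monitor_type", "x", "y")], by = "monitor_id")
  m$class <- site_class(m$monitor_type)
  m$year <- as.integer(year)
  m[, c("monitor_id", "year", "class", "mean_pm25", "n_days", "x", "y")]
}

idw_weighted_mean <- function(tx, ty, dx, dy, dm, power) {
  d <- pmax(sqrt((dx - tx)^2 + (dy - ty)^2), IDW_DIST_FLOOR)
  w <- d^(-power)
  sum(w * dm) / sum(w)
}

#' IDW-LOOCV spatially-lagged annual mean at a monitor
#'
#' Inverse-distance weighted mean of the annual class means of all *other*
#' monitors of the given class: power 1 ("regional") or power 2 ("local").
#' Distances are Euclidean km, floored at 0.5 km for co-located pairs. With no
#' eligible donor the value is `NA` (propagated, never zero).
#'
#' @param means [annual_class_means()] output.
#' @param sites site table (used for the target's coordinates).
#' @param target_monitor monitor id of the target (always excluded).
#' @param class `"hotspot"` or `"background"`.
#' @param power 1 or 2.
#' @return concentration in ug/m3, or `NA`.
#' @export
idw_loocv_lagged <- function(means, sites, target_monitor, class, power) {
  stopifnot(power %in% c(1, 2), class %in% c("hotspot", "background"))
  s <- data.table::as.data.table(sites)
  t <- s[s$monitor_id == target_monitor]
  if (nrow(t) != 1L) stop("unknown target monitor: ", target_monitor)
  keep <- means$class == class & means$monitor_id != target_monitor
  don <- means[which(keep)]
  if (nrow(don) == 0L) return(NA_real_)
  idw_weighted_mean(t$x, t$y, don$x, don$y, don$mean_pm25, power)
}

#' IDW spatially-lagged annual mean field over grid cells
#'
#' Same weighting as [idw_loocv_lagged()] but with *all* monitors of the class
#' as donors (no exclusion — cells are unmonitored targets).
#'
#' @param means [annual_class_means()] output.
#' @param grid a [grid_spec()].
#' @param class monitor class.
#' @param power 1 or 2.
#' @return numeric vector over cells (cell_id order).
#' @export
idw_grid_lagged <- function(means, grid, class, power) {
  stopifnot(power %in% c(1, 2))
  keep <- means$class == class
  don <- means[which(keep)]
  if (nrow(don) == 0L) stop("no monitors of class ", class, call. = FALSE)
  cc <- cell_centroids(grid)
  d <- sqrt(outer(cc$x, don$x, "-")^2 + outer(cc$y, don$y, "-")^2)
  d <- pmax(d, IDW_DIST_FLOOR)
  w <- d^(-power)
  as.vector((w %*% don$mean_pm25) / rowSums(w))
}

#' Distance to the nearest monitor of a class
#'
#' Minimum Euclidean distance (km) from each target to the monitors of the
#' class. A target that is itself one of those monitors is excluded from its
#' own search (identified by `exclude_ids`).
#'
#' @param tx,ty target coordinates (km).
#' @param sites site table with `monitor_id`, `monitor_type`, `x`, `y`.
#' @param class monitor class.
#' @param exclude_ids optional character vector, one per target (NA = none):
#'   monitor id to exclude for that target.
#' @return numeric vector of distances (km).
#' @export
nearest_class_distance <- function(tx, ty, sites, class, exclude_ids = NULL) {
  s <- data.table::as.data.table(sites)
  s <- s[which(site_class(s$monitor_type) == class)]
  if (nrow(s) == 0L) stop("no monitors of class ", class, call. = FALSE)
  if (is.null(exclude_ids)) exclude_ids <- rep(NA_character_, length(tx))
  vapply(seq_along(tx), function(i) {
    keep <- is.na(exclude_ids[i]) | s$monitor_id != exclude_ids[i]
    if (!any(keep)) return(NA_real_)
    min(sqrt((s$x[keep] - tx[i])^2 + (s$y[keep] - ty[i])^2))
  }, numeric(1))
}

#' Full lagged-feature set at the monitors for one year
#'
#' @param records filtered record table. Pass the observed series for the
#'   default behaviour, or a Stage-1-augmented table to base the annual means
#'   on the extended series.
#' @param sites site table (all monitors receive features).
#' @param year calendar year.
#' @param donors optional character vector of monitor ids allowed to act as
#'   donors (annual-mean contributors and nearest-distance candidates);
#'   default all. Used by the leakage-controlled cross-validation mode, where
#'   held-out monitors must not donate.
#' @return `data.table` keyed by `monitor_id` with the four IDW-LOOCV lagged
#'   variables and the two nearest-class distances (self-excluded for targets
#'   of the same class).
#' @export
monitor_lagged_features <- function(records, sites, year, donors = NULL) {
  m <- annual_class_means(records, sites, year)
  s <- data.table::as.data.table(sites)
  if (!is.null(donors)) {
    m <- m[which(m$monitor_id %in% donors)]
    ds <- s[which(s$monitor_id %in% donors)]
  } else {
    ds <- s
  }
  cls <- site_class(s$monitor_type)
  out <- data.table::data.table(monitor_id = s$monitor_id, year = as.integer(year))
  lag1 <- function(class, power) {
    vapply(s$monitor_id, function(id) idw_loocv_lagged(m, s, id, class, power),
           numeric(1))
  }
  out$lag_hotspot_regional <- lag1("hotspot", 1)
  out$lag_background_regional <- lag1("background", 1)
  out$lag_hotspot_local <- lag1("hotspot", 2)
  out$lag_background_local <- lag1("background", 2)
  excl_hot <- ifelse(cls == "hotspot", s$monitor_id, NA_character_)
  excl_bg <- ifelse(cls == "background", s$monitor_id, NA_character_)
  out$dist_hotspot <- nearest_class_distance(s$x, s$y, ds, "hotspot", excl_hot)
  out$dist_background <- nearest_class_distance(s$x, s$y, ds, "background", excl_bg)
  out
}

#' Lagged-feature fields over all grid cells for one year
#'
#' Grid variant used by the Stage-4 reconstruction: all class monitors act as
#' donors and cell centroids are the targets.
#'
#' @inheritParams monitor_lagged_features
#' @param grid a [grid_spec()].
#' @return `data.table` keyed by `cell_id` with the six lagged/distance
#'   columns.
#' @export
grid_lagged_features <- function(records, sites, grid, year) {
  m <- annual_class_means(records, sites, year)
  cc <- cell_centroids(grid)
  out <- data.table::data.table(cell_id = cc$cell_id, year = as.integer(year))
  out$lag_hotspot_regional <- idw_grid_lagged(m, grid, "hotspot", 1)
  out$lag_background_regional <- idw_grid_lagged(m, grid, "background", 1)
  out$lag_hotspot_local <- idw_grid_lagged(m, grid, "hotspot", 2)
  out$lag_background_local <- idw_grid_lagged(m, grid, "background", 2)
  s <- data.table::as.data.table(sites)
  out$dist_hotspot <- nearest_class_distance(cc$x, cc$y, s, "hotspot")
  out$dist_background <- nearest_class_distance(cc$x, cc$y, s, "background")
  out
}
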