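# Shared constants (collated first).

# wavelengths (um) shared by the satellite and reanalysis AOD products
AOD_WAVELENGTHS <- c(0.47, 0.55, 0.67, 0.865, 1.24)
# sub-day reporting times (hours) of the coarse reanalysis AOD
CAMS_HOURS <- c(3L, 6L, 9L, 12L, 15L, 18L, 21L)
# fixed Angstrom-like multiplicative scaling from the 0.55 um reference
aod_wavelength_factor <- function(wl) (wl / 0.55)^(-1.2)

STATIC_LANDCOVER <- c("lc_urban_fabric", "lc_industrial", "lc_mine_construction",
                      "lc_green_urban", "lc_arable", "lc_pasture", "lc_forest",
                      "lc_natural_open", "lc_water_wetland")

# the 21 static covariates emitted by the world generator
STATIC_COLUMNS <- c(
  "elevation", STATIC_LANDCOVER, "impervious", "night_light",
  "road_dens_highway", "road_dens_secondary", "road_dens_local",
  "road_invdist_highway", "road_invdist_secondary", "road_invdist_local",
  "pop_density", "airport_invdist", "seashore_invdist"
)

# the 6 monitor-derived spatial predictors
LAGGED_COLUMNS <- c("lag_hotspot_regional", "lag_background_regional",
                    "lag_hotspot_local", "lag_background_local",
                    "dist_hotspot", "dist_background")

IDW_DIST_FLOOR <- 0.5  # km; half a cell, prevents infinite IDW weights
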