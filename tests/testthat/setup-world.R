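# Shared small study region reused across test files (16 x 16 km, 30
# monitors, one year). Built once; individual tests must not mutate it.
tw <- generate_world(world_config(grid_nx = 16, grid_ny = 16, n_monitors = 30,
                                  seed = 42))
tw_dedup <- dedupe_colocated(tw$monitors, tw$records)
tw_sites <- tw_dedup$sites
tw_records <- apply_completeness_filters(tw_dedup$records)

# Small noise-free world used by the Stage-1/Stage-3 recovery checks
wlin <- generate_world(world_config(grid_nx = 12, grid_ny = 12, n_monitors = 24,
                                    sigma_pm10_ratio = 0, sigma_resid = 1e-4,
                                    n_duplicate_pairs = 0, seed = 8))
wlin_records <- apply_completeness_filters(wlin$records)

# shared Stage-3 fixture over the common test world (observed PM2.5 rows only)
tw_f47 <- composite_world_aod(tw, 0.47)
tw_f55 <- composite_world_aod(tw, 0.55)
tw_tab2_47 <- build_stage2_table(tw_f47, tw$cams, tw$grid)
tw_tab2_55 <- build_stage2_table(tw_f55, tw$cams, tw$grid)
tw_m47 <- fit_stage2(tw_tab2_47, 2018, 0.47, learner_spec(25, 20))
tw_m55 <- fit_stage2(tw_tab2_55, 2018, 0.55, learner_spec(25, 20))
tw_inputs <- stage3_inputs(tw, impute_aod(tw_m47, tw_f47, tw_tab2_47),
                           impute_aod(tw_m55, tw_f55, tw_tab2_55))
tw_lagged <- monitor_lagged_features(tw_records, tw_sites, 2018)
tw_keys <- merge(tw_records[!is.na(tw_records$pm25), c("monitor_id", "date", "pm25")],
                 tw_sites[, c("monitor_id", "cell_id")], by = "monitor_id")
tw_tab3 <- build_stage3_table(tw_keys[, c("monitor_id", "cell_id", "date")],
                              tw_inputs, tw_lagged)

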