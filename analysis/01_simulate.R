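#!/usr/bin/env Rscript
# Step 1 — simulate the study region.
#
# Builds the default synthetic world: a 40 x 40 km grid observed for one year
# by 120 monitors (about a third also measuring PM2.5), with ~90% of
# satellite-AOD cell-days lost to cloud. Exports the plain-text products and
# stashes the full object for the later steps.

library(pm25grid)

seed <- 1L
world <- generate_world(world_config(seed = seed))
print(world)

dir.create("results", showWarnings = FALSE)
export_world(world, "results/world")
saveRDS(world, "results/world.rds")

miss <- pm25grid:::realized_aod_missing(world)
cat(sprintf("monitors: %d (%d measuring PM2.5, plus 1 injected duplicate)\n",
            nrow(world$monitors), sum(world$monitors$measures_pm25)))
cat(sprintf("realized satellite-AOD missingness: %.1f%% (target 90%%)\n", 100 * miss))
cat(sprintf("truth PM2.5: mean %.2f ug/m3, range %.2f-%.2f\n",
            mean(world$truth_pm25), min(world$truth_pm25), max(world$truth_pm25)))
cat("wrote results/world/ (CSV + JSON) and results/world.rds\n")
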