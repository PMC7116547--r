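#!/usr/bin/env Rscript
# Step 2 — monitor network quality control.
#
# Drops cross-network duplicates (identical series within 0.1 km), then
# applies the completeness filters: < 18 observed hours removes the
# monitor-day, < 30 surviving days removes the monitor-year.

library(pm25grid)

world <- readRDS("results/world.rds")
dd <- dedupe_colocated(world$monitors, world$records)
records <- apply_completeness_filters(dd$records)

cat(sprintf("monitors: %d -> %d after deduplication\n",
            nrow(world$monitors), nrow(dd$sites)))
cat(sprintf("monitor-day rows: %d -> %d after completeness filters\n",
            nrow(world$records), nrow(records)))
cat(sprintf("  PM2.5 days kept: %d; PM10 days kept: %d\n",
            sum(!is.na(records$pm25)), sum(!is.na(records$pm10))))

data.table::fwrite(dd$sites, "results/sites.csv")
data.table::fwrite(records, "results/records_filtered.csv")
saveRDS(list(sites = dd$sites, records = records), "results/preprocessed.rds")
cat("wrote results/sites.csv, results/records_filtered.csv\n")
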