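#!/usr/bin/env Rscript
# Step 5 — Stage-3: the monitor-level log-PM2.5 prediction model.
#
# Assembles the 15 spatio-temporal + 27 spatial predictor table at the
# monitors (targets = observed or Stage-1 PM2.5), fits the per-year
# log-scale random forest, and ranks predictor importance.

library(pm25grid)

world <- readRDS("results/world.rds")
prep <- readRDS("results/preprocessed.rds")
s1 <- readRDS("results/stage1.rds")
filled <- readRDS("results/stage2_filled.rds")
year <- unique(as.integer(format(world$dates, "%Y")))[1]

inputs <- stage3_inputs(world, filled[["0.47"]], filled[["0.55"]])
lagged <- monitor_lagged_features(prep$records, prep$sites, year)
keys <- merge(s1$augmented, prep$sites[, c("monitor_id", "cell_id")],
              by = "monitor_id")
tab <- build_stage3_table(keys[, c("monitor_id", "cell_id", "date")],
                          inputs, lagged)
tgt <- merge(tab[, c("monitor_id", "date")], s1$augmented,
             by = c("monitor_id", "date"), sort = FALSE)$pm25
model <- fit_stage3(tab, tgt, year, learner_spec(100, 20))

st <- performance_stats(model$oob, model$y_train, method = "OOB_log", year = year)
cat(sprintf("Stage-3 table: %d monitor-days x %d predictors\n",
            nrow(tab), length(model$schema)))
cat(sprintf("Stage-3 OOB (log scale): R2 %.3f, RMSE %.3f\n", st$r2, st$rmse))

imp <- importance_table(model)
cat("top predictors by split-impurity importance:\n")
print(utils::head(as.data.frame(imp), 8), row.names = FALSE)

data.table::fwrite(imp, "results/stage3_importance.csv")
data.table::fwrite(st, "results/stage3_oob.csv")
saveRDS(list(model = model, table = tab, targets = tgt, inputs = inputs,
             lagged = lagged), "results/stage3.rds")
cat("wrote results/stage3_importance.csv, results/stage3_oob.csv\n")
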