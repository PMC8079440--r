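#!/usr/bin/env Rscript
# Stage 2: Monte-Carlo cross-validated age prediction on the
# cross-sectional cohort, compared between the two measurement pipelines.
# Each resplit trains a random forest AGE ~ VOLUME + GENDER + 62 regional
# thickness values on a stratified 80% of subjects and scores RMSE (years)
# on the held-out 20%.

suppressPackageStartupMessages(library(cortexeval))

dir.create("results", showWarnings = FALSE)
a <- read_thickness_table("results/data/cross_sectional_A.csv")
b <- read_thickness_table("results/data/cross_sectional_B.csv")

cfg <- age_prediction_config(n_permutations = 50, n_trees = 200, seed = 42L)
message("pipeline A ...")
res_a <- run_age_prediction(a, cfg, pipeline_label = "A")
message("pipeline B ...")
res_b <- run_age_prediction(b, cfg, pipeline_label = "B")

cmp <- compare_pipeline_rmse(res_a, res_b)
message(sprintf("mean RMSE: A = %.2f years, B = %.2f years (B - A = %+.2f)",
                cmp$rmse_mean_a, cmp$rmse_mean_b, cmp$mean_difference))
message(sprintf("B worse than A in %d of %d resplits",
                sum(cmp$differences > 0), length(cmp$differences)))

out <- data.frame(
  pipeline = rep(c("A", "B"), each = cfg$n_permutations),
  permutation = rep(seq_len(cfg$n_permutations), 2),
  rmse_years = c(res_a$rmse_per_permutation, res_b$rmse_per_permutation))
write.csv(out, "results/age_prediction_rmse.csv", row.names = FALSE)
message("wrote results/age_prediction_rmse.csv")
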