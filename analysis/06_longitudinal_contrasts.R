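#!/usr/bin/env Rscript
# Stage 6: the supervised longitudinal criterion. Per region, change from
# baseline is modeled with baseline covariates, diagnosis-specific
# trajectory slopes and crossed subject/site random intercepts; the
# LMCI-CN, AD-LMCI and AD-CN trajectory contrasts get Tukey p-values,
# FDR-adjusted across regions within each contrast.

suppressPackageStartupMessages(library(cortexeval))

for (pl in c("A", "B")) {
  message("pipeline ", pl, " ...")
  tab <- read_thickness_table(sprintf("results/data/longitudinal_%s.csv", pl))
  res <- run_longitudinal_evaluation(tab)
  write.csv(res, sprintf("results/longitudinal_contrasts_%s.csv", pl),
            row.names = FALSE)
  for (ct in unique(res$contrast)) {
    sub <- res[res$contrast == ct, ]
    message(sprintf("  %-8s: %2d/62 regions FDR-significant, median log10 p = %.2f",
                    ct, sum(sub$p_fdr < 0.05), median(sub$log10_p_fdr)))
  }
}
message("wrote results/longitudinal_contrasts_{A,B}.csv")
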