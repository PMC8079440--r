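#!/usr/bin/env Rscript
# Stage 4: scan-rescan repeatability. Two-way random-effects,
# average-measures intraclass correlation (ICC(2,k), k = 2) per region and
# pipeline, from the subject x acquisition ANOVA mean squares.

suppressPackageStartupMessages(library(cortexeval))

res <- do.call(rbind, lapply(c("A", "B"), function(pl) {
  tab <- read_thickness_table(sprintf("results/data/scan_rescan_%s.csv", pl))
  cbind(pipeline = pl, compute_icc(tab))
}))

for (pl in c("A", "B")) {
  x <- res$icc[res$pipeline == pl]
  message(sprintf("pipeline %s: median ICC %.3f (range %.3f-%.3f)",
                  pl, median(x), min(x), max(x)))
}
write.csv(res, "results/icc.csv", row.names = FALSE)
message("wrote results/icc.csv")
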