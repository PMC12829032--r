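#!/usr/bin/env Rscript
# Step 5: relative ONECUT2 expression from the simulated qPCR plate.
#
# Per-target standard curves (Cq vs log10 input) are fitted from the
# dilution series, absolute quantities computed per well, normalised to
# HPRT1 per replicate, summarised as mean +/- SD, and scaled to the LNCaP
# calibrator (= 1). Reference wells with Cq > 35 are excluded.

library(epihap)
library(jsonlite)

truth <- read_json("scratch/cohort/truth.json", simplifyVector = TRUE)$samples
plate <- simulate_qpcr_plate(truth, seed = 2L)
write.csv(plate, "scratch/qpcr_plate.csv", row.names = FALSE)

qp <- quantify_plate(plate)
write.csv(qp$results, "results/expression.csv", row.names = FALSE)

cat("control wells:", if (qp$controls$pass) "clean (no amplification)"
    else "CONTAMINATED", "\n")
for (cv in qp$curves) print(cv)
n_ok <- sum(!qp$results$excluded)
cat(sprintf("quantified %d samples (%d excluded on reference QC)\n",
            n_ok, sum(qp$results$excluded)))
m <- merge(qp$results, truth, by.x = "sample_id", by.y = "sample_id")
cat(sprintf("recovered vs true relative expression: r = %.3f\n",
            cor(m$relative, m$rel_expr_true, use = "complete.obs")))
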