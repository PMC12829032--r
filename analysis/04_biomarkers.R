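#!/usr/bin/env Rscript
# Step 4: biomarker evaluation across the clinicopathological dichotomies.
#
# Mann-Whitney U and ROC/AUC for the 7-8-CpG score: adjacent-normal vs
# cancer over all cores, then (within cancer cores) Gleason grade group
# 1-2 vs 3-5, T2 vs T3, EPE, SV invasion and LN metastasis.

library(epihap)

scores <- read.csv("results/scores.csv")
metadata <- read.csv("scratch/cohort/metadata.csv")

panel <- cohort_biomarkers(scores, metadata)
write.csv(panel, "results/biomarkers.csv", row.names = FALSE)

md <- merge(scores, metadata, by = "sample_id")
roc <- roc_auc(md$score, md$lesion == "cancer")
write.csv(roc$roc, "results/roc_lesion.csv", row.names = FALSE)

cat("biomarker panel (7-8 CpG highly-methylated-strand score):\n")
print(panel, digits = 3)
cat(sprintf("\nlesion ROC written (%d points), AUC = %.3f\n",
            nrow(roc$roc), roc$auc))
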