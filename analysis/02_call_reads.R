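#!/usr/bin/env Rscript
# Step 2: classify every read of every core.
#
# Each read is screened for primer-dimer length, compared to the
# bisulfite-converted reference in both orientations, filtered on
# mismatch fraction (off-target) and non-CpG cytosine conversion rate,
# and its 8-CpG methylation pattern is called. Per-read call tables are
# written per sample (scratch/), the cohort QC summary to results/.

library(epihap)

spec <- default_amplicon()
run <- cohort_run("scratch/cohort/manifest.csv", spec)

dir.create("scratch/calls", showWarnings = FALSE, recursive = TRUE)
for (id in names(run$tables)) {
  write.table(run$tables[[id]]$calls,
              file.path("scratch/calls", paste0(id, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
write.csv(run$qc_report, "results/qc_report.csv", row.names = FALSE)

tot <- colSums(run$qc_report[, c("retained", "dimer", "off_target",
                                 "low_conversion", "ambiguous_cpg")])
cat("cohort read classification totals:\n")
print(tot)
cat(sprintf("retained fraction: %.3f; cores excluded (<20 retained): %d\n",
            tot[["retained"]] / sum(tot), sum(run$qc_report$excluded)))
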