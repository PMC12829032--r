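#!/usr/bin/env Rscript
# Step 1: generate the synthetic biopsy cohort.
#
# 70 adjacent-normal + 35 cancer cores, ~3,000 targeted bisulfite reads
# each (the assay context is roughly 1000x coverage of a 126 bp amplicon),
# with per-core epiallele mixtures drawn from the group Beta laws and
# clinical labels linked to the true highly-methylated fraction. Reads go
# to scratch/ (large, regenerable); small tables go to results/.

library(epihap)

seed <- 1L
dir.create("results", showWarnings = FALSE)
co <- simulate_cohort(n_normal = 70, n_cancer = 35, seed = seed,
                      out_dir = "scratch/cohort")

write.csv(co$truth$samples, "results/truth_samples.csv", row.names = FALSE)
cat(sprintf("simulated %d cores (%d normal, %d cancer), %d reads each\n",
            nrow(co$metadata), sum(co$metadata$lesion == "normal"),
            sum(co$metadata$lesion == "cancer"), nrow(co$reads[[1]])))
cat(sprintf("true highly-methylated fraction: normal median %.3f, cancer median %.3f\n",
            median(co$truth$samples$high_meth_true[co$truth$samples$group == "normal"]),
            median(co$truth$samples$high_meth_true[co$truth$samples$group == "cancer"])))
cat("FASTQ + metadata + truth written under scratch/cohort/\n")
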