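#!/usr/bin/env Rscript
# Step 6: COBRA digestion-rate methylation estimates over a
# demethylation-recovery course.
#
# A constructed decitabine-course Cq table (two cell lines, two CpG
# sites, days 0/5/45) is converted to cut fractions via the exponential
# Cq model: intact = f^-(Cq_digested - Cq_undigested), methylation = cut.
# A methylated line shows the dip-and-recover trajectory; an unmethylated
# line stays flat near zero.

library(epihap)

# day-5 demethylation and day-45 restoration in the methylated line;
# near-zero digestion throughout in the unmethylated line
course <- rbind(
  data.frame(sample = "PC3",   site = "cg10835584",
             timepoint = c("d0", "d5", "d45"),
             cq_digested = c(28.1, 25.7, 28.0), cq_undigested = 25),
  data.frame(sample = "PC3",   site = "cg24771804",
             timepoint = c("d0", "d5", "d45"),
             cq_digested = c(27.6, 25.9, 27.4), cq_undigested = 25),
  data.frame(sample = "RWPE1", site = "cg10835584",
             timepoint = c("d0", "d5", "d45"),
             cq_digested = c(25.1, 25.05, 25.1), cq_undigested = 25))
write.csv(course, "scratch/cobra_course.csv", row.names = FALSE)

levels <- read_cobra_csv("scratch/cobra_course.csv")
write.csv(levels, "results/cobra_course.csv", row.names = FALSE)
cat("COBRA methylation levels (cut fractions):\n")
print(levels, digits = 3)

for (s in unique(course$site[course$sample == "PC3"])) {
  d <- course[course$sample == "PC3" & course$site == s, ]
  mk <- function(tp) cobra_measurement("PC3", s,
                                       d$cq_digested[d$timepoint == tp],
                                       d$cq_undigested[d$timepoint == tp])
  ratios <- c(d0 = 1,
              d5 = relative_methylation(mk("d0"), mk("d5"))$ratio,
              d45 = relative_methylation(mk("d0"), mk("d45"))$ratio)
  cat(sprintf("%s relative methylation vs day 0: d5 = %.2f, d45 = %.2f\n",
              s, ratios["d5"], ratios["d45"]))
}
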