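test_that("sample config rejects invalid parameters", {
  mix <- rep(1 / 9, 9)
  expect_error(sim_sample_config("s", n_reads = 0, epiallele_mix = mix),
               "positive")
  expect_error(sim_sample_config("s", epiallele_mix = rep(0.2, 9)),
               "sum to 1")
  expect_error(sim_sample_config("s", epiallele_mix = mix,
                                 conv_failure = 1.5), "\\[0,1\\]")
})

test_that("noise-free point-mass sample classifies fully methylated", {
  spec <- default_amplicon()
  K <- n_cpg_sites(spec)
  cfg <- sim_sample_config("S", n_reads = 300,
                           epiallele_mix = c(rep(0, K), 1),
                           conv_failure = 0, inappropriate_conv = 0,
                           seq_error = 0, frac_dimer = 0,
                           frac_offtarget = 0, seed = 2)
  sim <- simulate_sample_reads(cfg, spec)
  calls <- classify_reads(setNames(sim$reads$seq, sim$reads$read_id), spec)
  expect_true(all(calls$status == "retained"))
  expect_true(all(calls$n_methylated == K))
  expect_true(all(calls$pattern == strrep("M", K)))
})

test_that("contaminant fractions behave as configured", {
  spec <- default_amplicon()
  mix <- rep(1 / 9, 9)
  all_dimer <- simulate_sample_reads(
    sim_sample_config("S", n_reads = 100, epiallele_mix = mix,
                      frac_dimer = 1, frac_offtarget = 0, seed = 3), spec)
  calls <- classify_reads(all_dimer$reads$seq, spec)
  expect_true(all(calls$status == "dimer"))
  sim <- simulate_sample_reads(
    sim_sample_config("S", n_reads = 4000, epiallele_mix = mix, seed = 4),
    spec)
  frac <- table(sim$truth$contaminant) / 4000
  expect_lt(abs(frac[["dimer"]] - 0.02), 3 * sqrt(0.02 * 0.98 / 4000))
  expect_lt(abs(frac[["offtarget"]] - 0.03), 3 * sqrt(0.03 * 0.97 / 4000))
})

test_that("seeded runs are byte-identical", {
  spec <- default_amplicon()
  cfg <- sim_sample_config("S", n_reads = 200, epiallele_mix = rep(1 / 9, 9),
                           seed = 7)
  a <- simulate_sample_reads(cfg, spec)
  b <- simulate_sample_reads(cfg, spec)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".fastq")
  fb <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(a$reads, fa); write_fastq(b$reads, fb)
  expect_identical(readLines(fa), readLines(fb))
  co1 <- simulate_cohort(3, 3, n_reads = 100, seed = 9)
  co2 <- simulate_cohort(3, 3, n_reads = 100, seed = 9)
  expect_identical(co1$reads, co2$reads)
  expect_identical(co1$metadata, co2$metadata)
})

test_that("truth table matches the noiseless pipeline exactly", {
  spec <- default_amplicon()
  K <- n_cpg_sites(spec)
  cfg <- sim_sample_config("S", n_reads = 400,
                           epiallele_mix = epiallele_mix_from_high(0.3, K),
                           conv_failure = 0, inappropriate_conv = 0,
                           seq_error = 0, frac_dimer = 0,
                           frac_offtarget = 0, seed = 13)
  sim <- simulate_sample_reads(cfg, spec)
  calls <- classify_reads(setNames(sim$reads$seq, sim$reads$read_id), spec)
  sp <- build_spectrum(calls, K)
  expect_identical(unname(sp$counts),
                   tabulate(sim$truth$true_m + 1L, nbins = K + 1L))
  expect_equal(high_meth_score(sp), mean(sim$truth$true_m >= K - 1L))
  # every emitted read appears exactly once in the truth table
  expect_identical(sort(sim$truth$read_id), sort(sim$reads$read_id))
})

test_that("cohort generator validates sizes and emits linked metadata", {
  expect_error(simulate_cohort(5, 0, n_reads = 50), "each lesion group")
  co <- simulate_cohort(6, 4, n_reads = 60, seed = 21)
  expect_identical(nrow(co$metadata), 10L)
  expect_identical(sum(co$metadata$lesion == "cancer"), 4L)
  expect_true(all(is.na(co$metadata$gleason_group[co$metadata$lesion ==
                                                   "normal"])))
  expect_true(all(co$metadata$gleason_group[co$metadata$lesion ==
                                              "cancer"] %in% 1:5))
  expect_identical(names(co$reads), co$metadata$sample_id)
  # truth rows align with mixes
  expect_equal(unname(rowSums(co$truth$mixes)), rep(1, 10))
  expect_equal(unname(co$truth$mixes[, 8] + co$truth$mixes[, 9]),
               co$truth$samples$high_meth_true)
})

test_that("null effect gives a chance-level cohort AUC", {
  eff <- effect_config(normal_beta = c(2, 38), cancer_beta = c(2, 38))
  set.seed(31)
  co <- simulate_cohort(50, 50, effect = eff, n_reads = 60, seed = 31)
  auc <- roc_auc(co$truth$samples$high_meth_true,
                 co$truth$samples$group == "cancer")$auc
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})

test_that("qpcr plate simulation is exact at zero noise", {
  truth <- data.frame(sample_id = c("a", "b", "c"),
                      rel_expr_true = c(0.5, 1.2, 3.1))
  expect_error(simulate_qpcr_plate(truth, noise_sd = -1), ">= 0")
  plate <- simulate_qpcr_plate(truth, noise_sd = 0, seed = 5)
  std <- plate[plate$well_type == "standard" & plate$target == "ONECUT2", ]
  cv <- fit_standard_curve(std$log10_input, std$Cq, "ONECUT2")
  expect_equal(cv$slope, -3.30, tolerance = 1e-12)
  expect_equal(cv$intercept, 28, tolerance = 1e-12)
  # quantity 1 amplifies at exactly the intercept cycle
  expect_equal(absolute_quantity(cv$intercept, cv), 1, tolerance = 1e-12)
  res <- quantify_plate(plate)$results
  got <- res$relative[match(truth$sample_id, res$sample_id)]
  expect_equal(got, truth$rel_expr_true, tolerance = 1e-9)
})
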