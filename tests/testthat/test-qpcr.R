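test_that("standard-curve fit recovers exact lines and efficiencies", {
  x <- 0:-4
  cv <- fit_standard_curve(x, -3.321928 * x + 30, "t")
  expect_equal(cv$slope, -3.321928, tolerance = 1e-9)
  expect_equal(cv$intercept, 30, tolerance = 1e-9)
  expect_equal(cv$r2, 1)
  expect_equal(cv$efficiency_pct, 100, tolerance = 1e-4)
  expect_equal(pcr_efficiency(-3), (10^(1 / 3) - 1) * 100, tolerance = 1e-12)
  # exactly 100% at the ideal-doubling slope
  expect_identical(pcr_efficiency(-1 / log10(2)), 100)
  expect_error(fit_standard_curve(c(0, -1), c(30, 33)), ">= 3 distinct")
  expect_error(fit_standard_curve(rep(0, 5), rnorm(5)), ">= 3 distinct")
})

test_that("absolute quantity follows the log-linear Cq model", {
  cv <- fit_standard_curve(0:-4, -3.321928 * (0:-4) + 30, "t")
  expect_equal(absolute_quantity(30, cv), 1, tolerance = 1e-9)
  expect_equal(absolute_quantity(26.678072, cv), 10, tolerance = 1e-6)
  q1 <- absolute_quantity(28, cv)
  expect_equal(absolute_quantity(28 + abs(cv$slope), cv), q1 / 10,
               tolerance = 1e-9)
})

test_that("reference-gene cutoff drops replicates and flags exclusions", {
  cvs <- list(
    ONECUT2 = fit_standard_curve(0:-3, -3.3 * (0:-3) + 28, "ONECUT2"),
    HPRT1 = fit_standard_curve(0:-3, -3.3 * (0:-3) + 25, "HPRT1"))
  rows <- data.frame(
    sample = "s", target = rep(c("ONECUT2", "HPRT1"), each = 2),
    replicate = c(1, 2, 1, 2), Cq = c(29, 29.2, 26, 36),
    well_type = "unknown")
  q <- quantify_sample(rows, cvs, calibrator_norm = 1)
  expect_identical(q$n_replicates_used, 1L)
  expect_true(any(grepl("ref_failed_replicate_2", q$flags)))
  rows$Cq[3:4] <- c(36, 37)
  q2 <- quantify_sample(rows, cvs, calibrator_norm = 1)
  expect_true("excluded" %in% q2$flags)
  expect_true(is.na(q2$relative))
  expect_error(quantify_sample(rows, cvs["HPRT1"], calibrator_norm = 1),
               "missing standard curve")
})

test_that("a sample matching the calibrator has relative expression 1", {
  truth <- data.frame(sample_id = "twin", rel_expr_true = 1)
  plate <- simulate_qpcr_plate(truth, noise_sd = 0, seed = 2)
  res <- quantify_plate(plate)$results
  expect_equal(res$relative[res$sample_id == "twin"], 1, tolerance = 1e-9)
  expect_equal(res$relative[res$sample_id == "LNCaP"], 1, tolerance = 1e-12)
})

test_that("relative expression is invariant to a global input rescaling", {
  truth <- data.frame(sample_id = c("a", "b"), rel_expr_true = c(0.4, 2.5))
  plate <- simulate_qpcr_plate(truth, noise_sd = 0, seed = 3)
  res1 <- quantify_plate(plate)$results
  shifted <- plate
  unk <- shifted$well_type == "unknown"
  # a 10x input increase advances every unknown well by one log-dilution
  shifted$Cq[unk] <- shifted$Cq[unk] - 3.30
  res2 <- quantify_plate(shifted)$results
  expect_equal(res2$relative, res1$relative, tolerance = 1e-9)
})

test_that("replicate order does not change quantification", {
  truth <- data.frame(sample_id = c("a", "b"), rel_expr_true = c(0.4, 2.5))
  plate <- simulate_qpcr_plate(truth, noise_sd = 0.2, seed = 4)
  res1 <- quantify_plate(plate)$results
  res2 <- quantify_plate(plate[rev(seq_len(nrow(plate))), ])$results
  m <- match(res1$sample_id, res2$sample_id)
  expect_equal(res2$relative[m], res1$relative)
})

test_that("contaminated control wells fail exactly their target", {
  truth <- data.frame(sample_id = "a", rel_expr_true = 1)
  plate <- simulate_qpcr_plate(truth, noise_sd = 0, seed = 6)
  expect_true(control_check(plate)$pass)
  bad <- plate
  i <- which(bad$well_type == "ntc" & bad$target == "ONECUT2")
  bad$Cq[i] <- 32
  chk <- control_check(bad)
  expect_false(chk$pass)
  expect_false(chk$pass_by_target[["ONECUT2"]])
  expect_true(chk$pass_by_target[["HPRT1"]])
  # a late drift above the max cycle count is not amplification
  bad$Cq[i] <- 41
  expect_true(control_check(bad)$pass)
})

test_that("Cq tables round-trip through CSV with empty wells as NA", {
  truth <- data.frame(sample_id = "a", rel_expr_true = 2)
  plate <- simulate_qpcr_plate(truth, noise_sd = 0, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(plate, path, row.names = FALSE)
  back <- read_cq_table(path)
  expect_equal(back$Cq, plate$Cq)
  expect_identical(back$well_type, plate$well_type)
  expect_error(read_cq_table({
    p2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p2, row.names = FALSE); p2
  }), "missing columns")
})
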