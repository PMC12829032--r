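test_that("digestion rate follows the exponential Cq model", {
  m0 <- cobra_measurement("s", "cg10835584", 25, 25)
  expect_equal(digestion_rate(m0)$cut_fraction, 0)
  m1 <- cobra_measurement("s", "cg10835584", 26, 25)
  r1 <- digestion_rate(m1)
  expect_equal(r1$intact_fraction, 0.5)
  expect_equal(r1$cut_fraction, 0.5)
  expect_equal(r1$methylation_level, 0.5)
  m2 <- cobra_measurement("s", "cg24771804", 25 + 3.321928, 25)
  expect_equal(digestion_rate(m2)$cut_fraction, 0.9, tolerance = 1e-6)
  expect_error(cobra_measurement("s", "x", 25, 25,
                                 amplification_factor = 1), "> 1")
})

test_that("cut fraction is monotone in delta-Cq and shift-invariant", {
  deltas <- seq(0, 6, by = 0.5)
  cuts <- vapply(deltas, function(d)
    digestion_rate(cobra_measurement("s", "x", 25 + d, 25))$cut_fraction,
    numeric(1))
  expect_true(all(diff(cuts) > 0))
  shifted <- vapply(deltas, function(d)
    digestion_rate(cobra_measurement("s", "x", 30 + d, 30))$cut_fraction,
    numeric(1))
  expect_equal(shifted, cuts)
})

test_that("a 100%-efficiency curve factor reproduces the factor-2 model", {
  f <- 1 + pcr_efficiency(-1 / log10(2)) / 100
  a <- digestion_rate(cobra_measurement("s", "x", 27.3, 25,
                                        amplification_factor = f))
  b <- digestion_rate(cobra_measurement("s", "x", 27.3, 25))
  expect_identical(a$cut_fraction, b$cut_fraction)
})

test_that("inconsistent Cq pairs are flagged, not crashed", {
  m <- cobra_measurement("s", "x", 24, 25)   # digested amplifies earlier
  r <- digestion_rate(m)
  expect_identical(r$flags, "assay_inconsistent")
  expect_equal(r$cut_fraction, 0)   # intact clamped to 1
  ok <- digestion_rate(cobra_measurement("s", "x", 24.8, 25))
  expect_identical(ok$flags, character(0))
})

test_that("relative methylation tracks a demethylation-recovery course", {
  day0 <- cobra_measurement("pc3", "cg10835584", 28.3, 25, timepoint = "d0")
  day5 <- cobra_measurement("pc3", "cg10835584", 25.6, 25, timepoint = "d5")
  day45 <- cobra_measurement("pc3", "cg10835584", 28.2, 25,
                             timepoint = "d45")
  expect_equal(relative_methylation(day0, day0)$ratio, 1)
  series <- c(relative_methylation(day0, day0)$ratio,
              relative_methylation(day0, day5)$ratio,
              relative_methylation(day0, day45)$ratio)
  expect_lt(series[2], 0.5)          # strong drop after treatment
  expect_gt(series[3], 0.9)          # near-complete restoration
  expect_lt(abs(series[3] - 1), 0.1)
  expect_error(relative_methylation(
    day0, cobra_measurement("pc3", "othersite", 26, 25)), "same site")
  # undefined when the baseline is uncut
  uncut <- cobra_measurement("rwpe1", "cg10835584", 25, 25)
  r <- relative_methylation(uncut, day5)
  expect_true(is.na(r$ratio))
  expect_true("undefined_ratio" %in% r$flags)
})

test_that("a halved cut fraction gives ratio one half", {
  before <- cobra_measurement("s", "x", 26, 25)            # cut 0.5
  after <- cobra_measurement("s", "x", 25 + log2(4 / 3), 25)  # cut 0.25
  expect_equal(relative_methylation(before, after)$ratio, 0.5,
               tolerance = 1e-9)
})

test_that("COBRA CSV input averages replicates per sample/site/timepoint", {
  d <- data.frame(
    sample = "pc3", site = "cg10835584", timepoint = c("d0", "d0", "d5"),
    cq_digested = c(26, 26.2, 25.3), cq_undigested = c(25, 25, 25))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  out <- read_cobra_csv(path)
  expect_identical(nrow(out), 2L)
  d0 <- out[out$timepoint == "d0", ]
  expect_identical(d0$n_replicates, 2L)
  expect_equal(d0$cut_fraction,
               mean(c(1 - 2^-1, 1 - 2^-1.2)), tolerance = 1e-12)
})
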