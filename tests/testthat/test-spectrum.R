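fake_calls <- function(n_meth, extra_status = character()) {
  rbind(
    data.frame(status = rep("retained", length(n_meth)),
               n_methylated = as.integer(n_meth),
               pattern = rep(NA_character_, length(n_meth))),
    data.frame(status = extra_status,
               n_methylated = rep(NA_integer_, length(extra_status)),
               pattern = rep(NA_character_, length(extra_status))))
}

test_that("spectrum counts retained reads per bin and totals every call", {
  calls <- fake_calls(c(8, 8, 7, 3, 0), c("dimer", "dimer", "off_target"))
  sp <- build_spectrum(calls, 8, "s1")
  expect_identical(unname(sp$counts),
                   c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 2L))
  expect_identical(unname(sp$totals[c("retained", "dimer", "off_target")]),
                   c(5L, 2L, 1L))
  expect_identical(sum(sp$totals), nrow(calls))
  empty <- build_spectrum(fake_calls(integer()), 8)
  expect_true(all(empty$counts == 0L))
  expect_error(build_spectrum(fake_calls(9), 8), "outside 0..K")
})

test_that("the highly-methylated-strand score is a simple bin fraction", {
  sp <- build_spectrum(fake_calls(c(rep(8, 10), rep(7, 10), rep(0, 80))), 8)
  expect_equal(high_meth_score(sp), 0.20)
  expect_equal(high_meth_score(sp, min_sites = 8), 0.10)
  all8 <- build_spectrum(fake_calls(rep(8, 5)), 8)
  expect_equal(high_meth_score(all8), 1.0)
  expect_equal(mean_meth_level(all8), 1.0)
  none <- build_spectrum(fake_calls(integer()), 8)
  flagged <- high_meth_score(none)
  expect_true(is.na(flagged))
  expect_identical(attr(flagged, "flag"), "no_retained_reads")
})

test_that("the score is invariant to read order and duplication", {
  n_meth <- c(0, 3, 7, 8, 8, 5, 2)
  base <- high_meth_score(build_spectrum(fake_calls(n_meth), 8))
  shuf <- high_meth_score(build_spectrum(fake_calls(sample(n_meth)), 8))
  dup <- high_meth_score(build_spectrum(fake_calls(rep(n_meth, 4)), 8))
  expect_equal(shuf, base)
  expect_equal(dup, base)
})

test_that("single-site rates come from the retained patterns", {
  calls <- data.frame(
    status = "retained", n_methylated = c(8L, 0L),
    pattern = c("MMMMMMMM", "UUUUUUUU"))
  for (k in 1:8) expect_equal(single_site_rate(calls, k), 0.5)
  alt <- data.frame(status = "retained", n_methylated = c(4L, 4L),
                    pattern = c("MUMUMUMU", "UMUMUMUM"))
  for (k in 1:8) expect_equal(single_site_rate(alt, k), 0.5)
  expect_error(single_site_rate(calls, 9), "out of")
})

test_that("spectrum matrix rows are normalised, NA when unscored", {
  s1 <- build_spectrum(fake_calls(c(8, 8, 0, 0)), 8, "s1")
  s2 <- build_spectrum(fake_calls(c(8, 8, 0, 0)), 8, "s2")
  s3 <- build_spectrum(fake_calls(integer()), 8, "s3")
  mat <- spectrum_matrix(list(s1, s2, s3))
  expect_equal(unname(mat["s1", ]), c(0.5, rep(0, 7), 0.5))
  expect_equal(mat["s1", ], mat["s2", ])
  expect_true(all(is.na(mat["s3", ])))
  expect_identical(attr(mat, "flagged"), "s3")
  expect_equal(unname(rowSums(mat[1:2, ])), c(1, 1))
})

test_that("cohort spectra recover the generating mixtures", {
  spec <- default_amplicon()
  K <- n_cpg_sites(spec)
  co <- simulate_cohort(5, 5, n_reads = 1200, seed = 17)
  run <- cohort_run(co$reads, spec)
  mat <- spectrum_matrix(run$spectra)
  expect_identical(rownames(mat), rownames(co$truth$mixes))
  err <- abs(mat - co$truth$mixes)
  expect_lt(max(err), 0.06)
})

test_that("per-bin group tests mark the discriminating bins", {
  set.seed(23)
  n <- 20
  # two groups differing only in the top-two-bin mass
  mk <- function(h) {
    low <- 0.5^(0:6); low <- low / sum(low) * (1 - h)
    c(low, h / 2, h / 2)
  }
  mat <- rbind(
    t(vapply(rbeta(n, 2, 38), mk, numeric(9))),
    t(vapply(rbeta(n, 8, 12), mk, numeric(9))))
  colnames(mat) <- paste0("m", 0:8)
  rownames(mat) <- sprintf("s%02d", 1:(2 * n))
  res <- spectrum_bin_tests(mat, rep(c(FALSE, TRUE), each = n))
  expect_identical(res$bin[nrow(res)], "pooled_top2")
  expect_lt(res$p[res$bin == "pooled_top2"], 1e-4)
  expect_lt(res$p[res$bin == "m8"], 1e-3)
  adj <- spectrum_bin_tests(mat, rep(c(FALSE, TRUE), each = n),
                            adjust = "BH")
  expect_true(all(adj$p_adj >= adj$p - 1e-15))
})
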