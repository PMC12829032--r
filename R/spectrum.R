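#' Build the epiallele spectrum of a sample
#'
#' Aggregates per-read classification calls into the spectrum of 0..K
#' methylated sites per DNA strand: `counts[m+1]` is the number of
#' retained reads carrying exactly m methylated CpGs, without regard to
#' which sites they are. Non-retained reads (dimer, off-target,
#' low-conversion, ambiguous) are tallied in `totals` but never counted in
#' the spectrum.
#'
#' @param calls data.frame from [classify_reads()] (columns `status`,
#'   `n_methylated`), all reads of one sample.
#' @param K number of CpG sites.
#' @param sample_id sample label carried into the result.
#' @return an `epiallele_spectrum`: list with `sample_id`, `counts`
#'   (named integer vector, bins `m0`..`mK`), `totals` (reads per status),
#'   `K`.
#' @export
build_spectrum <- function(calls, K, sample_id = "sample") {
  stopifnot(all(c("status", "n_methylated") %in% names(calls)))
  ret <- calls$n_methylated[calls$status == "retained"]
  if (length(ret) && (anyNA(ret) || any(ret < 0L | ret > K)))
    stop("retained call with n_methylated outside 0..K")
  counts <- tabulate(ret + 1L, nbins = K + 1L)
  names(counts) <- paste0("m", 0:K)
  statuses <- c("retained", "dimer", "off_target", "low_conversion",
                "ambiguous_cpg")
  totals <- vapply(statuses, function(s) sum(calls$status == s), integer(1))
  stopifnot(sum(totals) == nrow(calls))
  structure(list(sample_id = sample_id, counts = counts, totals = totals,
                 K = as.integer(K)),
            class = "epiallele_spectrum")
}

#' @export
print.epiallele_spectrum <- function(x, ...) {
  cat(sprintf("epiallele_spectrum '%s': %d retained reads over %d bins\n",
              x$sample_id, sum(x$counts), x$K + 1L))
  print(x$counts)
  cat("status totals:\n"); print(x$totals)
  invisible(x)
}

#' Highly-methylated-strand biomarker score
#'
#' Fraction of retained reads carrying at least `min_sites` methylated
#' CpGs; with the default `min_sites = K - 1` this is the 7-8-of-8
#' highly-methylated-strand score used as the biopsy biomarker. A sample
#' with no retained reads yields `NA` with attribute `flag =
#' "no_retained_reads"` rather than a silent 0.
#'
#' @param spectrum an [build_spectrum()] result.
#' @param min_sites minimum methylated-site count included in the score.
#' @return fraction in `[0, 1]`, or flagged `NA`.
#' @export
high_meth_score <- function(spectrum, min_sites = spectrum$K - 1L) {
  stopifnot(inherits(spectrum, "epiallele_spectrum"),
            min_sites >= 0L, min_sites <= spectrum$K)
  tot <- sum(spectrum$counts)
  if (tot == 0L) {
    out <- NA_real_
    attr(out, "flag") <- "no_retained_reads"
    return(out)
  }
  sum(spectrum$counts[(min_sites + 1L):(spectrum$K + 1L)]) / tot
}

#' Mean per-read methylation level
#'
#' Mean over retained reads of (methylated sites) / K — the per-sample
#' "mean methylation level" used as the regressor in the
#' methylation-expression association.
#'
#' @param spectrum an [build_spectrum()] result.
#' @return fraction in `[0, 1]`, or flagged `NA` for zero retained reads.
#' @export
mean_meth_level <- function(spectrum) {
  stopifnot(inherits(spectrum, "epiallele_spectrum"))
  tot <- sum(spectrum$counts)
  if (tot == 0L) {
    out <- NA_real_
    attr(out, "flag") <- "no_retained_reads"
    return(out)
  }
  sum((0:spectrum$K) * spectrum$counts) / (spectrum$K * tot)
}

#' Single-CpG methylation rate
#'
#' Fraction of retained reads methylated at one given site — the
#' single-site read-out an array probe would give, provided for comparison
#' against the strand-level score.
#'
#' @param calls data.frame from [classify_reads()] (needs `status` and
#'   `pattern`).
#' @param site_index CpG site index, 1..K.
#' @return fraction in `[0, 1]`, or flagged `NA` for zero retained reads.
#' @export
single_site_rate <- function(calls, site_index) {
  stopifnot(all(c("status", "pattern") %in% names(calls)))
  pat <- calls$pattern[calls$status == "retained"]
  if (!length(pat)) {
    out <- NA_real_
    attr(out, "flag") <- "no_retained_reads"
    return(out)
  }
  K <- nchar(pat[1L])
  if (site_index < 1L || site_index > K) stop("site_index out of 1..K")
  mean(substr(pat, site_index, site_index) == "M")
}

#' Cohort spectrum matrix
#'
#' Row-normalised samples-by-bins proportion matrix (the matrix behind the
#' cohort methylation-pattern heatmap). Rows of samples with retained
#' reads sum to 1; zero-read samples are emitted as all-`NA` rows and
#' listed in the `flagged` attribute.
#'
#' @param spectra list of [build_spectrum()] results.
#' @return numeric matrix, one row per sample, columns `m0`..`mK`.
#' @export
spectrum_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  K <- spectra[[1L]]$K
  mat <- t(vapply(spectra, function(s) {
    stopifnot(s$K == K)
    tot <- sum(s$counts)
    if (tot == 0L) rep(NA_real_, K + 1L) else s$counts / tot
  }, numeric(K + 1L)))
  rownames(mat) <- unname(vapply(spectra, `[[`, character(1), "sample_id"))
  colnames(mat) <- paste0("m", 0:K)
  attr(mat, "flagged") <- rownames(mat)[is.na(mat[, 1L])]
  mat
}

#' Per-bin group comparison across the spectrum
#'
#' For each bin of the spectrum matrix (and, optionally, for the pooled
#' top-two-bins score) compares the per-sample proportions between two
#' groups with the Mann-Whitney U test — the per-bin significance row of
#' the cohort heatmap. P-values are reported raw by default, matching the
#' primary analysis; Benjamini-Hochberg adjustment is available.
#'
#' @param mat matrix from [spectrum_matrix()].
#' @param labels logical/two-level vector over rows (positive group =
#'   `TRUE` / second level).
#' @param pool_top if `TRUE`, append a pooled `m(K-1)+mK` row.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `bin`, `U`, `p` (and `p_adj` when adjusted).
#' @export
spectrum_bin_tests <- function(mat, labels, pool_top = TRUE,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(mat), !anyNA(labels))
  keep <- !is.na(mat[, 1L])
  mat <- mat[keep, , drop = FALSE]; labels <- labels[keep]
  cols <- colnames(mat)
  vals <- lapply(seq_along(cols), function(j) mat[, j])
  names(vals) <- cols
  if (pool_top) {
    K1 <- ncol(mat) - 1L
    vals$pooled_top2 <- mat[, K1] + mat[, K1 + 1L]
  }
  res <- lapply(vals, function(v)
    mann_whitney(v[labels], v[!labels]))
  out <- data.frame(bin = names(vals),
                    U = vapply(res, `[[`, numeric(1), "U"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
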