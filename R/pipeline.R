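#' Classify every read of one sample
#'
#' Streams a sample's FASTQ through [classify_reads()] and summarises QC:
#' read counts per status, conversion-rate quantiles over reads that
#' reached conversion assessment, and the retained-read count.
#'
#' @param fastq path to the sample FASTQ, or a data.frame with `read_id`
#'   and `seq` (as returned by the simulator) to skip file I/O.
#' @param spec an [amplicon_spec()].
#' @param qc a [qc_thresholds()].
#' @param sample_id sample label; defaults to the FASTQ basename.
#' @return a `sample_call_table`: list with `sample_id`, `calls`
#'   (per-read data.frame), `qc_summary` (status counts, conversion-rate
#'   quantiles), `empty` flag.
#' @export
process_sample <- function(fastq, spec, qc = qc_thresholds(),
                           sample_id = NULL) {
  if (is.character(fastq)) {
    if (is.null(sample_id))
      sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
    reads <- read_fastq(fastq)
  } else {
    reads <- fastq
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    if (is.null(sample_id)) sample_id <- "sample"
  }
  if (!nrow(reads)) {
    warning("sample '", sample_id, "': no reads")
    empty_calls <- classify_reads(character(0), spec, qc)
    return(structure(list(sample_id = sample_id, calls = empty_calls,
                          qc_summary = list(status_counts = c(retained = 0L),
                                            n_reads = 0L),
                          empty = TRUE),
                     class = "sample_call_table"))
  }
  calls <- classify_reads(stats::setNames(reads$seq, reads$read_id), spec, qc)
  stopifnot(nrow(calls) == nrow(reads))
  cr <- calls$conversion_rate[!is.na(calls$conversion_rate)]
  qc_summary <- list(
    status_counts = table(factor(calls$status,
                                 levels = c("retained", "dimer",
                                            "off_target", "low_conversion",
                                            "ambiguous_cpg"))),
    conversion_rate_quantiles =
      if (length(cr)) stats::quantile(cr, c(0.05, 0.25, 0.5, 0.75, 0.95))
      else NULL,
    n_reads = nrow(calls))
  structure(list(sample_id = sample_id, calls = calls,
                 qc_summary = qc_summary, empty = FALSE),
            class = "sample_call_table")
}

#' Run read classification over a cohort
#'
#' Processes every sample of a manifest (or an in-memory read-set list),
#' builds per-sample epiallele spectra, and assembles a cohort QC table.
#' Samples with fewer retained reads than `min_retained` are flagged
#' excluded (mirroring the exclusion of poor-quality cores) but their
#' spectra are still returned.
#'
#' @param manifest data.frame with `sample_id` and `fastq` columns, path
#'   to such a CSV, or a named list of read data.frames.
#' @param spec an [amplicon_spec()].
#' @param qc a [qc_thresholds()].
#' @param min_retained minimum retained reads for a core to be scored.
#' @return list with `tables` (named list of `sample_call_table`s),
#'   `spectra` (named list of `epiallele_spectrum`s), and `qc_report`
#'   (data.frame: per-status counts, `retained`, `excluded`).
#' @export
cohort_run <- function(manifest, spec, qc = qc_thresholds(),
                       min_retained = 20L) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (is.data.frame(manifest)) {
    stopifnot(all(c("sample_id", "fastq") %in% names(manifest)))
    ids <- manifest$sample_id
    sources <- as.list(manifest$fastq)
  } else {
    ids <- names(manifest)
    sources <- manifest
  }
  if (anyDuplicated(ids)) stop("duplicate sample_id in manifest")
  K <- n_cpg_sites(spec)
  tables <- vector("list", length(ids)); names(tables) <- ids
  spectra <- vector("list", length(ids)); names(spectra) <- ids
  for (i in seq_along(ids)) {
    tables[[i]] <- process_sample(sources[[i]], spec, qc,
                                  sample_id = ids[i])
    spectra[[i]] <- build_spectrum(tables[[i]]$calls, K,
                                   sample_id = ids[i])
  }
  qc_report <- do.call(rbind, lapply(spectra, function(s)
    data.frame(sample_id = s$sample_id, t(as.matrix(s$totals)),
               n_reads = sum(s$totals),
               excluded = s$totals[["retained"]] < min_retained,
               stringsAsFactors = FALSE)))
  row.names(qc_report) <- NULL
  list(tables = tables, spectra = spectra, qc_report = qc_report)
}

#' Per-sample biomarker score table
#'
#' @param spectra named list of `epiallele_spectrum`s.
#' @param min_retained samples with fewer retained reads get `NA` scores.
#' @return data.frame: `sample_id`, `retained`, `high_meth` (top-two-bins
#'   score), `mean_meth`, `score` (alias of `high_meth`), `flagged`.
#' @export
score_samples <- function(spectra, min_retained = 20L) {
  rows <- lapply(spectra, function(s) {
    ret <- sum(s$counts)
    flagged <- ret < min_retained
    data.frame(sample_id = s$sample_id, retained = ret,
               high_meth = if (flagged) NA_real_
                           else as.numeric(high_meth_score(s)),
               mean_meth = if (flagged) NA_real_
                           else as.numeric(mean_meth_level(s)),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$score <- out$high_meth
  row.names(out) <- NULL
  out
}

#' Run the full synthetic study
#'
#' End-to-end driver reproducing the analysis shape on synthetic data:
#' simulate a cohort, classify every read, build the epiallele spectra and
#' biomarker scores, run the six clinicopathological comparisons, quantify
#' expression from a simulated qPCR plate, and fit the
#' methylation-expression robust regression. All tunables live in the
#' `config` list; every number in the returned bundle is recomputable from
#' the intermediates it carries.
#'
#' @param config list; recognised entries (with defaults):
#'   `seed` (1), `n_normal` (70), `n_cancer` (35), `n_reads` (3000),
#'   `effect` ([effect_config()]), `spec` ([default_amplicon()]),
#'   `qc` ([qc_thresholds()]), `min_retained` (20), `qpcr_noise_sd`
#'   (0.15), `association_x` ("mean_meth"), `out_dir` (`NULL`: nothing
#'   written).
#' @return list with `scores`, `spectrum_matrix`, `bin_tests`,
#'   `biomarkers`, `expression`, `association`, `qc_report`, `truth`,
#'   `config`.
#' @export
run_study <- function(config = list()) {
  cfg <- utils::modifyList(
    list(seed = 1L, n_normal = 70L, n_cancer = 35L, n_reads = 3000L,
         effect = effect_config(), spec = default_amplicon(),
         qc = qc_thresholds(), min_retained = 20L, qpcr_noise_sd = 0.15,
         association_x = "mean_meth", out_dir = NULL),
    config)
  sim <- simulate_cohort(cfg$n_normal, cfg$n_cancer, effect = cfg$effect,
                         spec = cfg$spec, n_reads = cfg$n_reads,
                         seed = cfg$seed)
  calls <- cohort_run(sim$reads, cfg$spec, cfg$qc,
                      min_retained = cfg$min_retained)
  scores <- score_samples(calls$spectra, min_retained = cfg$min_retained)
  mat <- spectrum_matrix(calls$spectra)
  lesion_pos <- sim$metadata$lesion[match(rownames(mat),
                                          sim$metadata$sample_id)] == "cancer"
  bin_tests <- spectrum_bin_tests(mat, lesion_pos)
  biomarkers <- cohort_biomarkers(scores, sim$metadata)
  plate <- simulate_qpcr_plate(sim$truth$samples,
                               noise_sd = cfg$qpcr_noise_sd,
                               seed = cfg$seed + 1L)
  qp <- quantify_plate(plate)
  expr <- qp$results[qp$results$sample_id %in% scores$sample_id, ]
  assoc <- associate(scores, expr, x_var = cfg$association_x)
  out <- list(scores = scores, spectrum_matrix = mat,
              bin_tests = bin_tests, biomarkers = biomarkers,
              expression = qp, association = assoc,
              qc_report = calls$qc_report, truth = sim$truth,
              metadata = sim$metadata, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(cfg$out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mat),
                     file.path(cfg$out_dir, "spectrum_matrix.csv"))
    utils::write.csv(bin_tests, file.path(cfg$out_dir, "bin_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(biomarkers, file.path(cfg$out_dir, "biomarkers.csv"),
                     row.names = FALSE)
    utils::write.csv(qp$results, file.path(cfg$out_dir, "expression.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(association = assoc$fit[c("slope", "intercept", "r2", "n_used")],
           lambda_x = assoc$lambda_x, lambda_y = assoc$lambda_y,
           biomarkers = biomarkers, seed = cfg$seed),
      file.path(cfg$out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}
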