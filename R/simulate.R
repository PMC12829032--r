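#' Per-sample simulation configuration
#'
#' Describes one synthetic biopsy core: its epiallele mixture (probability
#' of a DNA strand carrying 0..K methylated CpGs), read depth, and noise
#' rates. Defaults emulate the assay context: about 1000x coverage per core
#' (default 3,000 reads, within the observed 68-9,848 per-core range),
#' modest bisulfite conversion failure, and small primer-dimer and
#' off-target contaminant fractions.
#'
#' @param sample_id sample label.
#' @param group lesion label, `"normal"` or `"cancer"`.
#' @param n_reads number of reads to emit (> 0).
#' @param epiallele_mix probability vector over 0..K methylated sites
#'   (length K+1, sums to 1 within 1e-9).
#' @param conv_failure probability an unmethylated cytosine escapes
#'   conversion and is read as C.
#' @param inappropriate_conv probability a methylated CpG cytosine is
#'   (wrongly) converted and read as T.
#' @param seq_error per-base substitution error probability.
#' @param frac_dimer,frac_offtarget contaminant read fractions.
#' @param dimer_max_len maximum primer-dimer length (nt); dimers are drawn
#'   shorter than this.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `sim_sample_config` list.
#' @export
sim_sample_config <- function(sample_id, group = "normal", n_reads = 3000L,
                              epiallele_mix, conv_failure = 0.01,
                              inappropriate_conv = 0.01, seq_error = 0.005,
                              frac_dimer = 0.02, frac_offtarget = 0.03,
                              dimer_max_len = 39L, seed = NULL) {
  if (n_reads <= 0) stop("n_reads must be positive")
  probs <- c(conv_failure, inappropriate_conv, seq_error,
             frac_dimer, frac_offtarget, epiallele_mix)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  if (abs(sum(epiallele_mix) - 1) > 1e-9)
    stop("epiallele_mix must sum to 1 (within 1e-9)")
  structure(list(sample_id = sample_id, group = group,
                 n_reads = as.integer(n_reads),
                 epiallele_mix = as.numeric(epiallele_mix),
                 conv_failure = conv_failure,
                 inappropriate_conv = inappropriate_conv,
                 seq_error = seq_error, frac_dimer = frac_dimer,
                 frac_offtarget = frac_offtarget,
                 dimer_max_len = as.integer(dimer_max_len), seed = seed),
            class = "sim_sample_config")
}

#' Epiallele mixture from a target highly-methylated fraction
#'
#' Places probability `high` on the two top bins (K-1 and K methylated
#' sites, split evenly) and spreads the remaining mass geometrically over
#' bins 0..K-2, with most mass on fully unmethylated strands — the
#' background structure of normal prostate at this locus.
#'
#' @param high fraction of strands with K-1 or K methylated sites.
#' @param K number of CpG sites.
#' @param geom_ratio geometric decay ratio across bins 0..K-2.
#' @param top_split how `high` is split between bins K-1 and K.
#' @return probability vector of length K+1 (bins 0..K).
#' @export
epiallele_mix_from_high <- function(high, K = 8L, geom_ratio = 0.5,
                                    top_split = c(0.5, 0.5)) {
  stopifnot(high >= 0, high <= 1, geom_ratio > 0,
            length(top_split) == 2L, abs(sum(top_split) - 1) < 1e-12)
  low <- geom_ratio^(0:(K - 2L))
  low <- low / sum(low) * (1 - high)
  c(low, high * top_split)
}

#' Simulate reads for one sample
#'
#' Generates targeted bisulfite amplicon reads from a known epiallele
#' mixture. For each genuine read: the number of methylated sites m is
#' drawn from the mixture, m sites are chosen uniformly at random, the
#' bisulfite-converted sequence is built from the amplicon reference,
#' conversion-failure and inappropriate-conversion flips are applied at
#' cytosine positions, and per-base substitution errors are added. Dimer
#' contaminants are short random sequences; off-target contaminants are
#' random DNA of amplicon length. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_sample_config()].
#' @param spec an [amplicon_spec()].
#' @return list with `reads` (data.frame `read_id`, `seq`) and `truth`
#'   (data.frame `read_id`, `contaminant`, `true_m`, `true_pattern`) plus
#'   attribute-level sample truth in `sample_truth` (epiallele mix and
#'   true highly-methylated fraction).
#' @export
simulate_sample_reads <- function(cfg, spec) {
  stopifnot(inherits(cfg, "sim_sample_config"), inherits(spec, "amplicon_spec"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  K <- n_cpg_sites(spec)
  if (length(cfg$epiallele_mix) != K + 1L)
    stop("epiallele_mix must have length K + 1 = ", K + 1L)
  n <- cfg$n_reads
  L <- nchar(spec$ref_seq)
  type <- sample(c("none", "dimer", "offtarget"), n, replace = TRUE,
                 prob = c(1 - cfg$frac_dimer - cfg$frac_offtarget,
                          cfg$frac_dimer, cfg$frac_offtarget))
  n_good <- sum(type == "none")
  bases <- c("A", "C", "G", "T")

  true_m <- rep(NA_integer_, n)
  true_pattern <- rep(NA_character_, n)
  seqs <- character(n)

  if (n_good > 0) {
    template <- strsplit(bisulfite_convert_reference(spec, rep(FALSE, K)),
                         "", fixed = TRUE)[[1L]]
    mat <- matrix(template, nrow = L, ncol = n_good)
    m <- sample(0:K, n_good, replace = TRUE, prob = cfg$epiallele_mix)
    # methylated-site indicator per read: site methylated iff its uniform
    # draw ranks among the m smallest for that read
    u <- matrix(stats::runif(K * n_good), nrow = K)
    rk <- apply(u, 2L, rank, ties.method = "first")
    meth <- rk <= rep(m, each = K)
    # CpG read-out with conversion noise
    flip_inap <- matrix(stats::runif(K * n_good) < cfg$inappropriate_conv,
                        nrow = K)
    flip_fail <- matrix(stats::runif(K * n_good) < cfg$conv_failure,
                        nrow = K)
    cpg_base <- ifelse(meth, ifelse(flip_inap, "T", "C"),
                       ifelse(flip_fail, "C", "T"))
    mat[spec$cpg_positions, ] <- cpg_base
    # non-CpG cytosines escaping conversion
    chars <- strsplit(spec$ref_seq, "", fixed = TRUE)[[1L]]
    ncc <- setdiff(which(chars == "C"), spec$cpg_positions)
    if (length(ncc)) {
      fail <- matrix(stats::runif(length(ncc) * n_good) < cfg$conv_failure,
                     nrow = length(ncc))
      sub <- mat[ncc, , drop = FALSE]
      sub[fail] <- "C"
      mat[ncc, ] <- sub
    }
    # per-base sequencing substitution errors
    err <- which(stats::runif(L * n_good) < cfg$seq_error)
    for (e in err) {
      mat[e] <- sample(setdiff(bases, mat[e]), 1L)
    }
    good_seqs <- apply(mat, 2L, paste, collapse = "")
    idx <- which(type == "none")
    seqs[idx] <- good_seqs
    true_m[idx] <- m
    pat <- matrix("U", nrow = K, ncol = n_good)
    pat[meth] <- "M"
    true_pattern[idx] <- apply(pat, 2L, paste, collapse = "")
  }
  for (i in which(type == "dimer")) {
    len <- sample(10:cfg$dimer_max_len, 1L)
    seqs[i] <- paste(sample(bases, len, replace = TRUE), collapse = "")
  }
  for (i in which(type == "offtarget")) {
    seqs[i] <- paste(sample(bases, L, replace = TRUE), collapse = "")
  }
  ids <- sprintf("%s_read_%05d", cfg$sample_id, seq_len(n))
  high_true <- sum(cfg$epiallele_mix[c(K, K + 1L)])
  list(reads = data.frame(read_id = ids, seq = seqs,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids, contaminant = type,
                          true_m = true_m, true_pattern = true_pattern,
                          stringsAsFactors = FALSE),
       sample_truth = list(sample_id = cfg$sample_id, group = cfg$group,
                           epiallele_mix = cfg$epiallele_mix,
                           high_meth_true = high_true))
}

#' Cohort effect-size configuration
#'
#' Group-level generative parameters for the synthetic cohort. The
#' highly-methylated-strand fraction of a sample is drawn from a Beta law
#' per lesion group; aggressiveness labels are linked to the true fraction
#' through a logistic model; relative expression is an affine function of
#' the true fraction with multiplicative lognormal noise. These effect
#' sizes are configuration, not estimates from patient data.
#'
#' @param normal_beta,cancer_beta Beta shape pairs for the
#'   highly-methylated fraction in normal and cancer cores (defaults give
#'   means 0.05 and 0.40).
#' @param geom_ratio geometric spread of the remaining epiallele mass over
#'   lower bins (see [epiallele_mix_from_high()]).
#' @param label_steepness slope of the logistic link from the true
#'   fraction to aggressiveness-label probabilities.
#' @param label_centers logistic midpoints per aggressiveness label.
#' @param expr_intercept,expr_slope affine map from the true fraction to
#'   relative expression (calibrator = 1 scale).
#' @param expr_sdlog sdlog of the multiplicative lognormal expression
#'   noise.
#' @param recurrence_rate marginal PSA-recurrence probability, independent
#'   of methylation (the assay shows no recurrence association).
#' @return an `effect_config` list.
#' @export
effect_config <- function(normal_beta = c(2, 38), cancer_beta = c(8, 12),
                          geom_ratio = 0.5, label_steepness = 8,
                          label_centers = c(gleason_high = 0.35, t3 = 0.38,
                                            epe = 0.38, sv = 0.45, ln = 0.50),
                          expr_intercept = 0.25, expr_slope = 4.75,
                          expr_sdlog = 0.3, recurrence_rate = 0.25) {
  structure(list(normal_beta = normal_beta, cancer_beta = cancer_beta,
                 geom_ratio = geom_ratio, label_steepness = label_steepness,
                 label_centers = label_centers,
                 expr_intercept = expr_intercept, expr_slope = expr_slope,
                 expr_sdlog = expr_sdlog, recurrence_rate = recurrence_rate),
            class = "effect_config")
}

#' Simulate a biopsy cohort
#'
#' Draws per-sample epiallele mixtures from the group Beta laws, simulates
#' reads for every core, and builds the clinical metadata table with
#' aggressiveness labels correlated to the true highly-methylated fraction
#' via a logistic link. Output is byte-identical for a given seed.
#'
#' @param n_normal,n_cancer core counts per lesion group (both >= 1).
#' @param effect an [effect_config()].
#' @param spec an [amplicon_spec()].
#' @param n_reads reads per core.
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, per-sample FASTQ files, `metadata.csv`,
#'   `manifest.csv` and `truth.json` are written there.
#' @return list with `reads` (named list of per-sample read data.frames),
#'   `metadata` (data.frame), `truth` (list: `samples` data.frame with the
#'   true mixture/fraction/expression, `reads` named list of per-read
#'   truth), `spec`, and (when `out_dir` is given) `paths`.
#' @export
simulate_cohort <- function(n_normal, n_cancer, effect = effect_config(),
                            spec = default_amplicon(), n_reads = 3000L,
                            seed = 1L, out_dir = NULL) {
  if (n_normal < 1L || n_cancer < 1L)
    stop("need at least one core in each lesion group")
  if (n_normal + n_cancer < 2L) stop("cohort must have at least 2 cores")
  set.seed(seed)
  K <- n_cpg_sites(spec)
  n <- n_normal + n_cancer
  group <- rep(c("normal", "cancer"), c(n_normal, n_cancer))
  h <- c(stats::rbeta(n_normal, effect$normal_beta[1], effect$normal_beta[2]),
         stats::rbeta(n_cancer, effect$cancer_beta[1], effect$cancer_beta[2]))
  rel_expr <- (effect$expr_intercept + effect$expr_slope * h) *
    exp(stats::rnorm(n, 0, effect$expr_sdlog))
  sample_id <- sprintf("%s_%03d", ifelse(group == "normal", "N", "T"),
                       seq_len(n))
  seeds <- sample.int(2147483646L, n)

  # aggressiveness labels (cancer cores only), logistic in the true fraction
  lab <- function(center) {
    p <- stats::plogis(effect$label_steepness * (h - center))
    out <- stats::runif(n) < p
    out[group == "normal"] <- NA
    out
  }
  gleason_high <- lab(effect$label_centers[["gleason_high"]])
  t3  <- lab(effect$label_centers[["t3"]])
  epe <- lab(effect$label_centers[["epe"]])
  sv  <- lab(effect$label_centers[["sv"]])
  ln  <- lab(effect$label_centers[["ln"]])
  gleason_group <- ifelse(is.na(gleason_high), NA_integer_,
                          ifelse(gleason_high, sample(3:5, n, replace = TRUE),
                                 sample(1:2, n, replace = TRUE)))
  metadata <- data.frame(
    sample_id = sample_id, core_id = sprintf("core_%03d", seq_len(n)),
    lesion = group, gleason_group = gleason_group,
    t_stage = ifelse(is.na(t3), NA_character_, ifelse(t3, "T3", "T2")),
    epe = epe, sv = sv, ln = ln,
    psa_recurrence = stats::runif(n) < effect$recurrence_rate,
    stringsAsFactors = FALSE)

  reads <- vector("list", n); names(reads) <- sample_id
  truth_reads <- vector("list", n); names(truth_reads) <- sample_id
  mixes <- matrix(NA_real_, nrow = n, ncol = K + 1L,
                  dimnames = list(sample_id, paste0("m", 0:K)))
  for (i in seq_len(n)) {
    mix <- epiallele_mix_from_high(h[i], K = K,
                                   geom_ratio = effect$geom_ratio)
    mixes[i, ] <- mix
    cfg <- sim_sample_config(sample_id[i], group = group[i],
                             n_reads = n_reads, epiallele_mix = mix,
                             seed = seeds[i])
    sim <- simulate_sample_reads(cfg, spec)
    reads[[i]] <- sim$reads
    truth_reads[[i]] <- sim$truth
  }
  truth_samples <- data.frame(
    sample_id = sample_id, group = group, high_meth_true = h,
    rel_expr_true = rel_expr, stringsAsFactors = FALSE)
  out <- list(reads = reads, metadata = metadata,
              truth = list(samples = truth_samples, mixes = mixes,
                           reads = truth_reads),
              spec = spec, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fq <- file.path(out_dir, paste0(sample_id, ".fastq"))
    for (i in seq_len(n)) write_fastq(reads[[i]], fq[i])
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    manifest <- data.frame(sample_id = sample_id, fastq = fq,
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(samples = truth_samples, mixes = as.data.frame(mixes)),
      file.path(out_dir, "truth.json"), digits = NA)
    out$paths <- list(fastq = stats::setNames(fq, sample_id),
                      metadata = file.path(out_dir, "metadata.csv"),
                      manifest = file.path(out_dir, "manifest.csv"),
                      truth = file.path(out_dir, "truth.json"))
  }
  out
}

#' Simulate a multiplex qPCR plate
#'
#' Builds a raw Cq table for a target/reference duplex assay from the
#' cohort truth: per-sample template input varies lognormally, the target
#' quantity is the reference quantity times the sample's true relative
#' expression, and each well's Cq follows the standard-curve model
#' Cq = intercept + slope * log10(quantity) + Normal(0, noise_sd). Two
#' technical replicates per sample and target, a serial-dilution standard
#' series per target, and no-template / no-RT control wells (no
#' amplification, Cq = NA) are included. A calibrator sample with relative
#' expression 1 is appended when absent.
#'
#' @param truth_samples data.frame with `sample_id` and `rel_expr_true`
#'   (e.g. `simulate_cohort(...)$truth$samples`).
#' @param curve_params named list per target of `list(slope=, intercept=)`;
#'   default slopes are -3.30, the assay's reported median.
#' @param noise_sd SD (cycles) of well-level Cq noise; must be >= 0.
#' @param seed integer seed.
#' @param calibrator_id calibrator sample id (appended with relative
#'   expression exactly 1 if not already present).
#' @param dilution_log10 log10 input levels of the standard series.
#' @param n_replicates technical replicates per sample/target.
#' @param input_sdlog sdlog of per-sample template-input variation.
#' @return data.frame with columns `sample`, `target`, `replicate`, `Cq`,
#'   `well_type` (`unknown`/`standard`/`ntc`/`no_rt`), `log10_input`.
#' @export
simulate_qpcr_plate <- function(truth_samples,
                                curve_params = list(
                                  ONECUT2 = list(slope = -3.30, intercept = 28),
                                  HPRT1 = list(slope = -3.30, intercept = 25)),
                                noise_sd = 0.15, seed = 1L,
                                calibrator_id = "LNCaP",
                                dilution_log10 = 0:-4, n_replicates = 2L,
                                input_sdlog = 0.5) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(c("sample_id", "rel_expr_true") %in% names(truth_samples)))
  if (length(curve_params) < 2L)
    stop("need curves for a target and a reference gene")
  set.seed(seed)
  samples <- truth_samples[, c("sample_id", "rel_expr_true")]
  if (!calibrator_id %in% samples$sample_id)
    samples <- rbind(samples,
                     data.frame(sample_id = calibrator_id,
                                rel_expr_true = 1))
  targets <- names(curve_params)
  ref <- if ("HPRT1" %in% targets) "HPRT1" else targets[length(targets)]
  ns <- nrow(samples)
  input <- exp(stats::rnorm(ns, 0, input_sdlog))
  rows <- list()
  for (tg in targets) {
    cp <- curve_params[[tg]]
    q <- if (tg == ref) input else input * samples$rel_expr_true
    for (r in seq_len(n_replicates)) {
      cq <- cp$intercept + cp$slope * log10(q) +
        stats::rnorm(ns, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples$sample_id, target = tg, replicate = r,
        Cq = cq, well_type = "unknown", log10_input = NA_real_,
        stringsAsFactors = FALSE)
    }
    for (r in seq_len(n_replicates)) {
      cq <- cp$intercept + cp$slope * dilution_log10 +
        stats::rnorm(length(dilution_log10), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("std_%s_%d", tg, seq_along(dilution_log10)),
        target = tg, replicate = r, Cq = cq, well_type = "standard",
        log10_input = as.numeric(dilution_log10),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = c("NTC", "noRT"), target = tg, replicate = 1L,
      Cq = NA_real_, well_type = c("ntc", "no_rt"),
      log10_input = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
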