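#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Cq versus log10(input) over a serial
#' dilution, with the PCR efficiency derived from the slope as
#' E = (10^(-1/slope) - 1) * 100%. A perfect doubling assay has slope
#' -1/log10(2) (about -3.32) and efficiency exactly 100%.
#'
#' @param log10_input log10 input amounts of the dilution wells.
#' @param cq measured Cq values.
#' @param target target label carried into the result.
#' @return a `standard_curve`: list with `target`, `slope`, `intercept`,
#'   `r2`, `efficiency_pct`, `n`.
#' @export
fit_standard_curve <- function(log10_input, cq, target = "") {
  keep <- is.finite(log10_input) & is.finite(cq)
  log10_input <- log10_input[keep]; cq <- cq[keep]
  if (length(unique(log10_input)) < 3L)
    stop("standard curve needs >= 3 distinct dilution levels")
  fit <- stats::lm(cq ~ log10_input)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # summary() warns on a perfect (noise-free) fit; that case is legitimate
  r2 <- if (stats::var(cq) == 0) 1 else
    unname(suppressWarnings(summary(fit)$r.squared))
  structure(list(target = target, slope = slope, intercept = intercept,
                 r2 = r2, efficiency_pct = pcr_efficiency(slope),
                 n = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve '%s': Cq = %.4f * log10(input) + %.4f (r2 = %.4f, E = %.2f%%)\n",
    x$target, x$slope, x$intercept, x$r2, x$efficiency_pct))
  invisible(x)
}

#' PCR efficiency from a standard-curve slope
#' @param slope Cq change per log10 input (negative for a valid series).
#' @return efficiency in percent.
#' @export
pcr_efficiency <- function(slope) (10^(-1 / slope) - 1) * 100

#' Absolute quantity from a Cq value
#'
#' Q = 10^((Cq - intercept) / slope): strictly decreasing in Cq for a
#' negative slope, Q = 1 at Cq = intercept, and one unit of |slope| in Cq
#' corresponds to a tenfold quantity change.
#'
#' @param cq Cq value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return quantity on the standard's input scale.
#' @export
absolute_quantity <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Quantify relative expression for one sample
#'
#' Per technical replicate, the target and reference absolute quantities
#' are computed from their standard curves and normalised
#' (Q_target / Q_ref); replicates whose reference Cq exceeds the cutoff
#' (or shows no amplification) are dropped. Replicates are then summarised
#' as mean +/- SD and scaled to the calibrator's normalised value, which
#' defines relative expression 1. A sample whose reference fails in every
#' replicate is flagged `excluded` (and is omitted from downstream
#' association analysis). A target well with no amplification contributes
#' quantity 0 with a flag.
#'
#' @param cq_rows Cq table rows for one sample (columns `target`,
#'   `replicate`, `Cq`).
#' @param curves named list of [fit_standard_curve()] results, one per
#'   target.
#' @param target,ref_target target and reference gene names.
#' @param ref_cutoff maximum acceptable reference Cq (cycles).
#' @param calibrator_norm the calibrator's mean normalised quantity
#'   (compute it first via `quantify_sample(..., calibrator_norm = 1)`).
#' @return list with `normalized` (per-replicate values), `norm_mean`,
#'   `norm_sd`, `relative`, `n_replicates_used`, `flags`.
#' @export
quantify_sample <- function(cq_rows, curves, target = "ONECUT2",
                            ref_target = "HPRT1", ref_cutoff = 35,
                            calibrator_norm = NA_real_) {
  for (tg in c(target, ref_target))
    if (is.null(curves[[tg]]))
      stop("missing standard curve for target '", tg, "'")
  tg_rows <- cq_rows[cq_rows$target == target, ]
  rf_rows <- cq_rows[cq_rows$target == ref_target, ]
  reps <- sort(unique(c(tg_rows$replicate, rf_rows$replicate)))
  flags <- character()
  normalized <- numeric()
  for (r in reps) {
    cq_t <- tg_rows$Cq[tg_rows$replicate == r]
    cq_r <- rf_rows$Cq[rf_rows$replicate == r]
    if (!length(cq_t) || !length(cq_r)) {
      flags <- c(flags, sprintf("missing_replicate_%d", r)); next
    }
    if (is.na(cq_r) || cq_r > ref_cutoff) {
      flags <- c(flags, sprintf("ref_failed_replicate_%d", r)); next
    }
    q_ref <- absolute_quantity(cq_r, curves[[ref_target]])
    q_tg <- if (is.na(cq_t)) {
      flags <- c(flags, sprintf("target_no_amplification_%d", r))
      0
    } else absolute_quantity(cq_t, curves[[target]])
    normalized <- c(normalized, q_tg / q_ref)
  }
  if (!length(normalized)) {
    return(list(normalized = numeric(), norm_mean = NA_real_,
                norm_sd = NA_real_, relative = NA_real_,
                n_replicates_used = 0L,
                flags = unique(c(flags, "excluded"))))
  }
  nm <- mean(normalized)
  list(normalized = normalized, norm_mean = nm,
       norm_sd = stats::sd(normalized),
       relative = nm / calibrator_norm,
       n_replicates_used = length(normalized), flags = unique(flags))
}

#' Quantify a whole plate
#'
#' Fits per-target standard curves from the plate's dilution wells (unless
#' curves are supplied), checks the no-template / no-RT controls, and runs
#' [quantify_sample()] for every unknown sample, scaling to the
#' calibrator.
#'
#' @param cq_table raw Cq table (columns `sample`, `target`, `replicate`,
#'   `Cq`, `well_type`, `log10_input`), e.g. from
#'   [simulate_qpcr_plate()] or [read_cq_table()].
#' @param target,ref_target target and reference gene names.
#' @param calibrator_id calibrator sample id (its relative expression is 1
#'   by construction; it is reported but not meant for group comparisons).
#' @param ref_cutoff maximum acceptable reference Cq.
#' @param curves optional named list of [fit_standard_curve()] results;
#'   fitted from the plate's `standard` wells when `NULL`.
#' @return list with `results` (data.frame: `sample_id`, `norm_mean`,
#'   `norm_sd`, `relative`, `n_replicates_used`, `excluded`, `flags`),
#'   `curves`, `controls` (from [control_check()]).
#' @export
quantify_plate <- function(cq_table, target = "ONECUT2",
                           ref_target = "HPRT1", calibrator_id = "LNCaP",
                           ref_cutoff = 35, curves = NULL) {
  need <- c("sample", "target", "replicate", "Cq", "well_type")
  stopifnot(all(need %in% names(cq_table)))
  if (is.null(curves)) {
    std <- cq_table[cq_table$well_type == "standard", ]
    curves <- lapply(split(std, std$target), function(d)
      fit_standard_curve(d$log10_input, d$Cq, target = d$target[1L]))
  }
  controls <- control_check(cq_table)
  unk <- cq_table[cq_table$well_type == "unknown", ]
  if (!calibrator_id %in% unk$sample)
    stop("calibrator sample '", calibrator_id, "' not found on plate")
  cal <- quantify_sample(unk[unk$sample == calibrator_id, ], curves,
                         target, ref_target, ref_cutoff,
                         calibrator_norm = 1)
  if (is.na(cal$norm_mean))
    stop("calibrator reference gene failed QC; plate cannot be scaled")
  ids <- unique(unk$sample)
  rows <- lapply(ids, function(id) {
    q <- quantify_sample(unk[unk$sample == id, ], curves, target,
                         ref_target, ref_cutoff,
                         calibrator_norm = cal$norm_mean)
    data.frame(sample_id = id, norm_mean = q$norm_mean,
               norm_sd = q$norm_sd, relative = q$relative,
               n_replicates_used = q$n_replicates_used,
               excluded = "excluded" %in% q$flags,
               flags = paste(q$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, rows), curves = curves,
       controls = controls)
}

#' Check no-template and no-RT control wells
#'
#' A control well showing numeric amplification before the maximum cycle
#' count fails its target; any failure flags the plate.
#'
#' @param cq_table raw Cq table (see [quantify_plate()]).
#' @param max_cycles amplification sentinel; the assay runs 40 cycles, so
#'   a numeric control Cq below 40 is genuine amplification.
#' @return list with `pass_by_target` (named logical) and `pass`.
#' @export
control_check <- function(cq_table, max_cycles = 40) {
  ctl <- cq_table[cq_table$well_type %in% c("ntc", "no_rt"), ]
  if (!nrow(ctl))
    return(list(pass_by_target = stats::setNames(logical(0), character(0)),
                pass = TRUE))
  by_tg <- vapply(split(ctl, ctl$target), function(d)
    !any(!is.na(d$Cq) & d$Cq < max_cycles), logical(1))
  list(pass_by_target = by_tg, pass = all(by_tg))
}

#' Read a raw Cq table from CSV
#'
#' Expected columns: `sample`, `target`, `replicate`, `Cq` (empty = no
#' amplification), `well_type` (`unknown`/`standard`/`ntc`/`no_rt`),
#' `log10_input` (standards only).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_cq_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "replicate", "Cq", "well_type")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("Cq table is missing columns: ", paste(miss, collapse = ", "))
  if (!"log10_input" %in% names(out)) out$log10_input <- NA_real_
  out$Cq <- suppressWarnings(as.numeric(out$Cq))
  out
}
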