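#' A COBRA digestion measurement
#'
#' One restriction-digestion readout of a bisulfite PCR amplicon: the
#' qPCR Cq of the digested aliquot against the undigested aliquot at one
#' CpG site. The assayed sites are cg10835584 (BstUI, recognition CG/CG)
#' and cg24771804 (BsiWI, C/GTACG); both recognition sequences survive
#' bisulfite conversion only when their CpG cytosines were methylated, so
#' the digested (cut) fraction is read as the methylated fraction — an
#' explicit, flaggable model assumption.
#'
#' @param sample_id sample label.
#' @param site CpG site / probe id.
#' @param cq_digested,cq_undigested Cq values of the two aliquots.
#' @param amplification_factor per-cycle amplification factor; 2.0 for an
#'   ideal assay, or `1 + E/100` from a fitted standard curve.
#' @param timepoint optional label (e.g. day 0 / 5 / 45 of a treatment
#'   course).
#' @return a `cobra_measurement` list.
#' @export
cobra_measurement <- function(sample_id, site, cq_digested, cq_undigested,
                              amplification_factor = 2,
                              timepoint = NA_character_) {
  stopifnot(is.finite(cq_digested), is.finite(cq_undigested))
  if (amplification_factor <= 1)
    stop("amplification_factor must be > 1")
  structure(list(sample_id = sample_id, site = site,
                 cq_digested = cq_digested, cq_undigested = cq_undigested,
                 amplification_factor = amplification_factor,
                 timepoint = timepoint),
            class = "cobra_measurement")
}

#' Restriction digestion rate (methylation level) from a Cq pair
#'
#' Under the exponential qPCR model, the intact template fraction after
#' digestion is f^(-(Cq_digested - Cq_undigested)) with per-cycle factor
#' f, clamped to (0, 1]; the cut fraction is its complement. With the
#' cut-site-survives-when-methylated orientation, the cut fraction is the
#' site's methylation level. A digested Cq more than `tolerance` cycles
#' *below* the undigested Cq is physically inconsistent and is flagged.
#'
#' @param m a [cobra_measurement()].
#' @param tolerance allowed negative delta-Cq (cycles) before flagging.
#' @return list with `delta_cq`, `intact_fraction`, `cut_fraction`,
#'   `methylation_level` (= cut fraction), `flags`.
#' @export
digestion_rate <- function(m, tolerance = 0.5) {
  stopifnot(inherits(m, "cobra_measurement"))
  delta <- m$cq_digested - m$cq_undigested
  flags <- character()
  if (delta < -tolerance) flags <- "assay_inconsistent"
  intact <- min(m$amplification_factor^(-delta), 1)
  cut <- 1 - intact
  list(delta_cq = delta, intact_fraction = intact, cut_fraction = cut,
       methylation_level = cut, flags = flags)
}

#' Relative methylation between two timepoints
#'
#' Ratio of cut fractions after / before treatment at the same site; a
#' demethylating course shows the ratio dipping below 1 and returning
#' towards 1 as methylation is restored.
#'
#' @param before,after [cobra_measurement()]s at the same site.
#' @return list with `ratio`, `cut_before`, `cut_after`, `flags` (carries
#'   `undefined_ratio` when the baseline cut fraction is 0).
#' @export
relative_methylation <- function(before, after) {
  stopifnot(inherits(before, "cobra_measurement"),
            inherits(after, "cobra_measurement"))
  if (!identical(before$site, after$site))
    stop("measurements must be at the same site")
  db <- digestion_rate(before); da <- digestion_rate(after)
  flags <- unique(c(db$flags, da$flags))
  ratio <- if (db$cut_fraction == 0) {
    flags <- c(flags, "undefined_ratio")
    NA_real_
  } else da$cut_fraction / db$cut_fraction
  list(ratio = ratio, cut_before = db$cut_fraction,
       cut_after = da$cut_fraction, flags = flags)
}

#' Read COBRA Cq pairs from CSV and compute cut fractions
#'
#' Expected columns: `sample`, `site`, `timepoint`, `cq_digested`,
#' `cq_undigested`, optional `amplification_factor` (default 2). Each row
#' is evaluated per-replicate with [digestion_rate()]; replicate rows of
#' the same sample/site/timepoint are averaged after conversion.
#'
#' @param path CSV file.
#' @return data.frame with one row per sample/site/timepoint:
#'   `cut_fraction`, `methylation_level`, `n_replicates`, `flags`.
#' @export
read_cobra_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "site", "timepoint", "cq_digested", "cq_undigested")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("COBRA table is missing columns: ", paste(miss, collapse = ", "))
  if (!"amplification_factor" %in% names(d)) d$amplification_factor <- 2
  key <- interaction(d$sample, d$site, d$timepoint, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    res <- lapply(seq_len(nrow(g)), function(i)
      digestion_rate(cobra_measurement(
        g$sample[i], g$site[i], g$cq_digested[i], g$cq_undigested[i],
        g$amplification_factor[i], g$timepoint[i])))
    cuts <- vapply(res, `[[`, numeric(1), "cut_fraction")
    data.frame(sample = g$sample[1L], site = g$site[1L],
               timepoint = g$timepoint[1L], cut_fraction = mean(cuts),
               methylation_level = mean(cuts), n_replicates = nrow(g),
               flags = paste(unique(unlist(lapply(res, `[[`, "flags"))),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
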