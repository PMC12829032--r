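#' QC thresholds for read classification
#'
#' Thresholds for the noise-eliminating classification of amplicon reads.
#' The published workflow removes primer dimers, off-target alignments and
#' false CpG calls but does not disclose its numeric criteria; the defaults
#' here are conventional bisulfite QC values and are stand-ins, not
#' reconstructions.
#'
#' @param min_read_length reads shorter than this are primer dimers (nt).
#' @param max_mismatch_frac maximum tolerated mismatch fraction against the
#'   converted reference (non-wildcard positions) before a read is called
#'   off-target.
#' @param min_conversion_rate minimum bisulfite conversion rate over
#'   non-CpG reference cytosines.
#' @param min_phred optional Phred cutoff below which bases are masked to N
#'   before calling; `NULL` (default) disables quality masking.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_read_length = 40L, max_mismatch_frac = 0.10,
                          min_conversion_rate = 0.95, min_phred = NULL) {
  stopifnot(min_read_length >= 1, max_mismatch_frac >= 0,
            max_mismatch_frac <= 1, min_conversion_rate >= 0,
            min_conversion_rate <= 1)
  structure(list(min_read_length = as.integer(min_read_length),
                 max_mismatch_frac = max_mismatch_frac,
                 min_conversion_rate = min_conversion_rate,
                 min_phred = min_phred),
            class = "qc_thresholds")
}

# Precomputed per-orientation comparison state: integer-coded reference,
# wildcard mask (reference C positions accept C or T), non-CpG-C mask for
# conversion-rate estimation, and CpG cytosine positions.
.orientation_state <- function(spec) {
  chars <- strsplit(spec$ref_seq, "", fixed = TRUE)[[1L]]
  ref_int <- utf8ToInt(spec$ref_seq)
  is_c <- chars == "C"
  cpg <- spec$cpg_positions
  non_cpg_c <- which(is_c)
  non_cpg_c <- non_cpg_c[!non_cpg_c %in% cpg]
  list(ref_int = ref_int, L = length(chars), wildcard = is_c,
       non_cpg_c = non_cpg_c, cpg = cpg)
}

.C <- utf8ToInt("C"); .T <- utf8ToInt("T")

# Compare one read (integer-coded) to one orientation over their overlap.
# Returns mismatch_frac, conversion_rate and raw CpG base codes.
.compare_read <- function(read_int, st) {
  n <- min(length(read_int), st$L)
  idx <- seq_len(n)
  wc <- st$wildcard[idx]
  cmp_pos <- idx[!wc]
  mm <- sum(read_int[cmp_pos] != st$ref_int[cmp_pos])
  mismatch_frac <- if (length(cmp_pos)) mm / length(cmp_pos) else 0
  ncc <- st$non_cpg_c[st$non_cpg_c <= n]
  conv <- sum(read_int[ncc] == .T)
  unconv <- sum(read_int[ncc] == .C)
  conversion_rate <- if (conv + unconv > 0) conv / (conv + unconv) else NA_real_
  cpg_base <- rep(NA_integer_, length(st$cpg))
  in_read <- st$cpg <= n
  cpg_base[in_read] <- read_int[st$cpg[in_read]]
  list(mismatch_frac = mismatch_frac, conversion_rate = conversion_rate,
       cpg_base = cpg_base)
}

.call_states <- function(cpg_base) {
  states <- rep("N", length(cpg_base))
  states[!is.na(cpg_base) & cpg_base == .C] <- "M"
  states[!is.na(cpg_base) & cpg_base == .T] <- "U"
  states
}

#' Classify a single amplicon read
#'
#' Implements the noise-eliminating read classification: a read is first
#' screened for primer-dimer length, then compared position-by-position to
#' the fully bisulfite-converted reference with every reference cytosine
#' position treated as a wildcard (C and T both acceptable there, since a
#' cytosine's read base depends on its unknown methylation/conversion
#' state). Reads exceeding the mismatch threshold over non-wildcard
#' positions are off-target; the bisulfite conversion rate is then
#' estimated over non-CpG reference cytosines (T = converted,
#' C = unconverted, other bases ignored) and under-converted reads are
#' dropped; finally CpG states are called (C = M, T = U, anything else =
#' N). Reads with any no-call are `ambiguous_cpg`, the rest `retained`.
#' Both strand orientations of the amplicon are tried and the one with the
#' lower mismatch fraction wins; CpG states from the reverse orientation
#' are re-indexed to forward site order. Reads shorter than the amplicon
#' (but above dimer length) are compared over the overlap; sites outside
#' the overlap are no-calls.
#'
#' Primers are matched as part of the full-length wildcard comparison (the
#' degenerate primer bases sit on reference cytosine positions) rather than
#' trimmed, because in this assay two of the CpG sites fall inside the
#' primer-binding regions and must remain callable.
#'
#' @param seq read sequence (character scalar).
#' @param spec an [amplicon_spec()].
#' @param qc a [qc_thresholds()].
#' @param read_id read identifier carried into the result.
#' @return a `read_pattern_call` list: `read_id`, `status` (one of
#'   `retained`, `dimer`, `off_target`, `low_conversion`, `ambiguous_cpg`),
#'   `cpg_states` (length-K character over M/U/N; `NA` when classification
#'   stopped before calling), `n_methylated`, `mismatch_frac`,
#'   `conversion_rate`, `strand`.
#' @export
classify_read <- function(seq, spec, qc = qc_thresholds(), read_id = "read") {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  df <- classify_reads(stats::setNames(seq, read_id), spec, qc)
  states <- if (is.na(df$pattern)) NULL else
    strsplit(df$pattern, "", fixed = TRUE)[[1L]]
  structure(list(read_id = df$read_id, status = df$status,
                 cpg_states = states, n_methylated = df$n_methylated,
                 mismatch_frac = df$mismatch_frac,
                 conversion_rate = df$conversion_rate, strand = df$strand),
            class = "read_pattern_call")
}

#' Classify a set of amplicon reads
#'
#' Vectorised driver for [classify_read()]; identical rules, one row per
#' read. Deterministic and independent of read order.
#'
#' @param seqs character vector of read sequences; names (if present) are
#'   used as read ids.
#' @param spec an [amplicon_spec()].
#' @param qc a [qc_thresholds()].
#' @return a data.frame with columns `read_id`, `status`, `pattern`
#'   (M/U/N string, `NA` unless calling was reached), `n_methylated`,
#'   `mismatch_frac`, `conversion_rate`, `strand` (`+`/`-`).
#' @export
classify_reads <- function(seqs, spec, qc = qc_thresholds()) {
  stopifnot(is.character(seqs))
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n))
  fwd <- .orientation_state(spec)
  status <- character(n); pattern <- rep(NA_character_, n)
  n_meth <- rep(NA_integer_, n); mmf <- rep(NA_real_, n)
  convr <- rep(NA_real_, n); strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    if (nchar(s) < qc$min_read_length) { status[i] <- "dimer"; next }
    ri <- utf8ToInt(s)
    # Bisulfite conversion breaks strand complementarity, so the two
    # orientations of a read are handled by reverse-complementing the read
    # and re-comparing against the forward reference (a bottom-strand read
    # of the PCR product is the reverse complement of the converted top
    # strand).
    cf <- .compare_read(ri, fwd)
    cr <- .compare_read(.complement_int(rev(ri)), fwd)
    if (cr$mismatch_frac < cf$mismatch_frac) {
      cmp <- cr; strand[i] <- "-"
    } else {
      cmp <- cf; strand[i] <- "+"
    }
    mmf[i] <- cmp$mismatch_frac
    if (cmp$mismatch_frac > qc$max_mismatch_frac) {
      status[i] <- "off_target"; next
    }
    convr[i] <- cmp$conversion_rate
    if (!is.na(cmp$conversion_rate) &&
        cmp$conversion_rate < qc$min_conversion_rate) {
      status[i] <- "low_conversion"; next
    }
    states <- .call_states(cmp$cpg_base)
    pattern[i] <- paste(states, collapse = "")
    if (any(states == "N")) {
      status[i] <- "ambiguous_cpg"
    } else {
      status[i] <- "retained"
      n_meth[i] <- sum(states == "M")
    }
  }
  data.frame(read_id = ids, status = status, pattern = pattern,
             n_methylated = n_meth, mismatch_frac = mmf,
             conversion_rate = convr, strand = strand,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Base-wise complement on integer-coded sequences; non-ACGT codes map to
# themselves (they will simply mismatch / no-call downstream).
.complement_int <- local({
  map <- seq_len(255L)
  map[utf8ToInt("A")] <- utf8ToInt("T"); map[utf8ToInt("T")] <- utf8ToInt("A")
  map[utf8ToInt("C")] <- utf8ToInt("G"); map[utf8ToInt("G")] <- utf8ToInt("C")
  function(x) map[x]
})

#' Match the primer pair against a read (orientation screen)
#'
#' IUPAC-aware (R/Y) match of the forward primer at the 5' end and the
#' reverse-complemented reverse primer at the 3' end, in either read
#' orientation. Used as a cheap orientation/identity screen; reads failing
#' both orientations fall through to off-target scoring in
#' [classify_read()].
#'
#' @param seq read sequence.
#' @param spec an [amplicon_spec()].
#' @param max_mismatch allowed mismatches per primer.
#' @return `"+"`, `"-"`, or `NA` if neither orientation matches both
#'   primers.
#' @export
match_primers <- function(seq, spec, max_mismatch = 2L) {
  ok <- function(s, p, at_end = FALSE) {
    if (!nzchar(p) || nchar(s) < nchar(p)) return(FALSE)
    sub <- if (at_end) substr(s, nchar(s) - nchar(p) + 1L, nchar(s))
           else substr(s, 1L, nchar(p))
    pc <- strsplit(p, "")[[1L]]; sc <- strsplit(sub, "")[[1L]]
    match1 <- sc == pc |
      (pc == "Y" & sc %in% c("C", "T")) |
      (pc == "R" & sc %in% c("A", "G"))
    sum(!match1) <= max_mismatch
  }
  fwd_p <- spec$primer_fwd
  rev_rc <- if (nzchar(spec$primer_rev)) revcomp(spec$primer_rev) else ""
  if (ok(seq, fwd_p) && ok(seq, rev_rc, at_end = TRUE)) return("+")
  rs <- revcomp(seq)
  if (ok(rs, fwd_p) && ok(rs, rev_rc, at_end = TRUE)) return("-")
  NA_character_
}
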