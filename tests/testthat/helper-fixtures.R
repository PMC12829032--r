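# Small fixtures shared across test files; everything is built in code.

# A short amplicon (60 nt) with every CG listed and several non-CpG
# cytosines, so classification and conversion-rate logic are exercised
# quickly.
tiny_spec <- function() {
  ref <- "GGAATTGGAACGTTAATTGGACGTTAATTCAGGTTAACCATTCGGTTAATTTGGAACCTT"
  cg <- as.integer(gregexpr("CG", ref, fixed = TRUE)[[1L]])
  amplicon_spec("tiny", "chr1", 101L, 100L + nchar(ref), ref, cg)
}

# Perfectly converted reads for a list of methylation patterns (logical
# vectors of length K): the zero-noise sequencer.
pattern_reads <- function(spec, patterns) {
  vapply(patterns, function(p) bisulfite_convert_reference(spec, p),
         character(1))
}

# All 2^K methylation patterns of an amplicon, as a list of logicals.
all_patterns <- function(K) {
  lapply(0:(2^K - 1L), function(i) as.logical(bitwAnd(i, 2^(0:(K - 1L))) > 0))
}

# Enumeration oracle for the exact two-sided Mann-Whitney p-value
# (no ties): the permutation distribution of U over all label
# reassignments, with R's two-sided doubling convention.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(sel) {
    xs <- pool[sel]; ys <- pool[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_dist <- apply(idx, 2L, u_of)
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * n2 / 2
  p <- if (u_obs > mid) 2 * mean(u_dist >= u_obs) else
    2 * mean(u_dist <= u_obs)
  list(U = u_obs, p = min(p, 1))
}
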