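#' Define a targeted bisulfite amplicon
#'
#' An `amplicon_spec` describes a single PCR amplicon on the forward genomic
#' strand: its reference sequence, the positions of the CpG dinucleotides
#' whose methylation is read out, and the (bisulfite-design) primer pair.
#' Primers may contain the IUPAC degenerate codes `R` (G/A) and `Y` (C/T),
#' which are required wherever a primer has to span a CpG position.
#'
#' @param name locus label.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic coordinates of the amplicon;
#'   `end - start + 1` must equal `nchar(ref_seq)`.
#' @param ref_seq uppercase forward-strand reference sequence (A/C/G/T only).
#' @param cpg_positions strictly increasing 1-based positions into `ref_seq`
#'   at which a `CG` dinucleotide begins.
#' @param primer_fwd,primer_rev primer sequences, A/C/G/T plus `R`/`Y`.
#' @param named_sites named integer vector mapping probe ids
#'   (e.g. `cg10835584`) to indices into `cpg_positions`.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, chrom, start, end, ref_seq, cpg_positions,
                          primer_fwd = "", primer_rev = "",
                          named_sites = integer()) {
  ref_seq <- toupper(ref_seq)
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L, nzchar(ref_seq))
  if (grepl("[^ACGT]", ref_seq))
    stop("ref_seq must contain only A/C/G/T")
  if (end - start + 1L != nchar(ref_seq))
    stop("end - start + 1 must equal nchar(ref_seq)")
  cpg_positions <- as.integer(cpg_positions)
  if (is.unsorted(cpg_positions, strictly = TRUE))
    stop("cpg_positions must be strictly increasing")
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  if (any(cpg_positions < 1L | cpg_positions >= length(chars)))
    stop("cpg_positions out of range")
  ok <- chars[cpg_positions] == "C" & chars[cpg_positions + 1L] == "G"
  if (!all(ok))
    stop("every cpg_position must point at a CG dinucleotide")
  all_cg <- gregexpr("CG", ref_seq, fixed = TRUE)[[1L]]
  if (all_cg[1L] != -1L && !setequal(as.integer(all_cg), cpg_positions))
    warning("ref_seq contains CG dinucleotides not listed in cpg_positions; ",
            "they will be treated as always-converted cytosines")
  for (p in c(primer_fwd, primer_rev))
    if (nzchar(p) && grepl("[^ACGTRY]", toupper(p)))
      stop("primers may contain only A/C/G/T/R/Y")
  named_sites <- as.integer(named_sites) |> stats::setNames(names(named_sites))
  if (length(named_sites) &&
      any(named_sites < 1L | named_sites > length(cpg_positions)))
    stop("named_sites indices out of range")
  structure(
    list(name = name, chrom = chrom, start = as.integer(start),
         end = as.integer(end), ref_seq = ref_seq,
         cpg_positions = cpg_positions,
         primer_fwd = toupper(primer_fwd), primer_rev = toupper(primer_rev),
         named_sites = named_sites),
    class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("amplicon_spec '%s' %s:%d-%d (%d bp, K = %d CpG sites)\n",
              x$name, x$chrom, x$start, x$end, nchar(x$ref_seq),
              length(x$cpg_positions)))
  cat(" CpG positions:", paste(x$cpg_positions, collapse = ", "), "\n")
  if (length(x$named_sites))
    cat(" named sites:",
        paste(sprintf("%s=site %d", names(x$named_sites), x$named_sites),
              collapse = ", "), "\n")
  invisible(x)
}

#' Number of CpG sites in an amplicon
#' @param spec an `amplicon_spec`.
#' @return integer K.
#' @export
n_cpg_sites <- function(spec) length(spec$cpg_positions)

#' The packaged ONECUT2 gene-body amplicon (synthetic reference)
#'
#' The 126 bp gene-body amplicon at chr18:55107668-55107793 carrying 8 CpG
#' sites, with the published bisulfite primer pair. The interior reference
#' sequence is *synthetic*: the true genomic sequence is not distributed
#' with this package, so a stand-in was constructed that (i) is consistent
#' with both primers before bisulfite conversion (each primer `Y`/`R`
#' degenerate base sits on a CpG cytosine, as in the published design),
#' (ii) contains exactly 8 CpG dinucleotides, and (iii) carries non-CpG
#' cytosines so the bisulfite conversion-rate filter is informative. Probe
#' ids cg10835584 and cg24771804 are assigned to two interior sites; the
#' published assay does not state which of the 8 sites they are.
#'
#' @return An `amplicon_spec` with K = 8.
#' @export
default_amplicon <- function() {
  amplicon_spec(
    name = "ONECUT2_gene_body_synthetic",
    chrom = "chr18", start = 55107668L, end = 55107793L,
    ref_seq = paste0(
      "GGTTTTTTTTGGGTTTTCGGGGT",
      "ATTCAGCTACGTTCAATGGACGATCCTAGGTACGGATTCAACTTCGTAAGGATCACGTTAGGCTTCAACGTAT",
      "GTAGAGTTTTTAGCGTAAGTATTTGGTTTT"),
    cpg_positions = c(18L, 33L, 44L, 56L, 68L, 79L, 92L, 110L),
    primer_fwd = "GGTTTTTTTTGGGTTTTYGGGGT",
    primer_rev = "AAAACCAAATACTTACRCTAAAAACTCTAC",
    named_sites = c(cg10835584 = 4L, cg24771804 = 6L))
}

#' In-silico bisulfite conversion of the amplicon reference
#'
#' Models the chemistry underlying the assay: unmethylated cytosines
#' deaminate to uracil and are read as T, while methylated CpG cytosines
#' are protected and stay C. Every non-CpG cytosine is converted; the
#' cytosine of CpG site i is converted iff `methylated[i]` is `FALSE`.
#' Guanines (cytosines of the opposite strand) are untouched.
#'
#' @param spec an `amplicon_spec`.
#' @param methylated logical vector of length K: methylation flag per CpG
#'   site.
#' @return the converted sequence (character scalar).
#' @export
bisulfite_convert_reference <- function(spec, methylated) {
  K <- n_cpg_sites(spec)
  methylated <- as.logical(methylated)
  if (length(methylated) != K || anyNA(methylated))
    stop(sprintf("'methylated' must be a logical vector of length K = %d", K))
  chars <- strsplit(spec$ref_seq, "", fixed = TRUE)[[1L]]
  is_c <- chars == "C"
  chars[is_c] <- "T"
  chars[spec$cpg_positions[methylated]] <- "C"
  paste(chars, collapse = "")
}

#' Reverse-strand view of an amplicon
#'
#' Both strands of the PCR product can be sequenced; this returns the
#' reverse-complement amplicon with CpG positions remapped (CpG is its own
#' reverse complement, so site i on the forward spec is site K+1-i on the
#' reverse spec) and the primer roles swapped. Applying the operation twice
#' returns the original spec.
#'
#' @param spec an `amplicon_spec`.
#' @return the reverse-strand `amplicon_spec`.
#' @export
reverse_strand_variant <- function(spec) {
  L <- nchar(spec$ref_seq)
  rc <- revcomp(spec$ref_seq)
  new_pos <- rev(L - spec$cpg_positions)
  ns <- spec$named_sites
  if (length(ns)) ns[] <- length(spec$cpg_positions) + 1L - ns
  amplicon_spec(
    name = spec$name, chrom = spec$chrom, start = spec$start, end = spec$end,
    ref_seq = rc, cpg_positions = new_pos,
    primer_fwd = spec$primer_rev, primer_rev = spec$primer_fwd,
    named_sites = ns)
}

#' Reverse complement of a DNA string (IUPAC R/Y aware)
#' @param seq character scalar.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Serialize / read an amplicon spec as JSON
#' @param spec an `amplicon_spec`.
#' @param path file path.
#' @return `read_amplicon_json` returns an `amplicon_spec`.
#' @export
write_amplicon_json <- function(spec, path) {
  obj <- unclass(spec)
  obj$named_sites <- as.list(obj$named_sites)  # keep probe-id names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_amplicon_json
#' @export
read_amplicon_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  amplicon_spec(x$name, x$chrom, x$start, x$end, x$ref_seq,
                x$cpg_positions, x$primer_fwd, x$primer_rev,
                unlist(x$named_sites))
}
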