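#' Read a FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a plain
#' data.frame. Qualities are parsed but not used for base masking by
#' default (see [qc_thresholds()]).
#'
#' @param path FASTQ file (4-line records, Phred+33).
#' @return data.frame with columns `read_id`, `seq`. Zero rows (with
#'   attribute `empty = TRUE`) for an empty file.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L) {
    out <- data.frame(read_id = character(), seq = character(),
                      stringsAsFactors = FALSE)
    attr(out, "empty") <- TRUE
    return(out)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  data.frame(read_id = names(set), seq = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with columns `read_id` and `seq` (as produced by
#'   [simulate_sample_reads()]).
#' @param path output file.
#' @param qual_char constant Phred+33 quality character used for every base
#'   (the simulator carries no per-base quality model).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  quals <- vapply(nchar(reads$seq), function(n)
    paste(rep(qual_char, n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", quals))
  writeLines(lines, path)
  invisible(path)
}
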