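#' Read a multi-record FASTA file into a sequence set
#'
#' Reading goes through [Biostrings::readBStringSet()]; a light pre-scan adds
#' line-numbered diagnostics for the malformed inputs Biostrings reports
#' without location (sequence data before the first header, headers with no
#' sequence).  At least two records are required.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"`, `"protein"`, `"auto"` (default) or an
#'   [mlcs_alphabet()].
#' @return An [sequence_set()] with record order preserved and residues
#'   uppercased.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "AC"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    mlcs_stop(sprintf("input file not found: %s", path), "mlcs_input_error")
  if (file.size(path) == 0L)
    mlcs_stop(sprintf("input file is empty: %s", path), "mlcs_input_error")
  scan_fasta_syntax(path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    mlcs_stop(sprintf("malformed FASTA in %s: %s", path,
                                      conditionMessage(e)),
                              c("mlcs_parse_error", "mlcs_input_error")))
  if (length(set) < 2L)
    mlcs_stop(sprintf("FASTA file has %d record(s); at least 2 are required",
                      length(set)),
              c("mlcs_cardinality_error", "mlcs_input_error"),
              count = length(set))
  ids <- sub("\\s.*$", "", names(set))
  sequence_set(as.character(set), ids = ids, alphabet = alphabet)
}

# minimal structural scan, only to attach line numbers to parse errors
scan_fasta_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    mlcs_stop(sprintf("input file is empty: %s", path), "mlcs_input_error")
  if (!startsWith(trimws(lines[[nonblank[[1L]]]]), ">"))
    mlcs_stop(sprintf("%s line %d: sequence data before the first '>' header",
                      path, nonblank[[1L]]),
              c("mlcs_parse_error", "mlcs_input_error"))
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    nxt <- nonblank[nonblank > h]
    if (!length(nxt) || startsWith(trimws(lines[[nxt[[1L]]]]), ">"))
      mlcs_stop(sprintf("%s line %d: header '%s' has no sequence lines",
                        path, h, trimws(lines[[h]])),
                c("mlcs_parse_error", "mlcs_input_error"))
  }
  invisible(TRUE)
}

#' Write a sequence set as FASTA
#'
#' @param seqs an [sequence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "mlcs_seqset"))
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- seqs$ids
  tryCatch(Biostrings::writeXStringSet(set, path),
           error = function(e)
             mlcs_stop(sprintf("cannot write %s: %s", path,
                               conditionMessage(e)), "mlcs_io_error"))
  invisible(path)
}
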