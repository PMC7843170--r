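#' Build a sequence set
#'
#' The algorithm's input container: an ordered collection of `n >= 2`
#' sequences tagged with a common alphabet.  Residues are uppercased on
#' construction; no other normalization (no `U` to `T`, no ambiguity-code
#' repair) is performed — legality is checked, not fixed, by
#' [validate_sequences()].  Positions throughout the package are 1-based;
#' position 0 is the virtual "before start" coordinate used by the search's
#' source point.
#'
#' @param residues character vector of sequences (one string each).
#' @param ids record identifiers; defaults to `seq1, seq2, ...`.
#' @param alphabet `"dna"`, `"protein"`, `"auto"` or an [mlcs_alphabet()].
#'   With `"auto"`, dna is chosen iff every residue is one of A/C/G/T,
#'   otherwise protein.
#' @return An object of class `"mlcs_seqset"`: list with `alphabet`, `ids`,
#'   `residues`, `n` and `lengths`.
#' @examples
#' sequence_set(c("ACGT", "GATTACA"))
#' @export
sequence_set <- function(residues, ids = NULL, alphabet = "auto") {
  residues <- as.character(residues)
  if (length(residues) < 2L)
    mlcs_stop(sprintf("a sequence set needs at least 2 sequences, got %d",
                      length(residues)),
              c("mlcs_cardinality_error", "mlcs_input_error"),
              count = length(residues))
  if (any(is.na(residues)))
    mlcs_stop("residues must not contain NA", "mlcs_parameter_error")
  residues <- toupper(residues)
  if (any(nchar(residues) < 1L))
    mlcs_stop("every sequence must have length >= 1", "mlcs_parameter_error")
  if (is.null(ids)) ids <- paste0("seq", seq_along(residues))
  ids <- as.character(ids)
  if (length(ids) != length(residues) || anyDuplicated(ids))
    mlcs_stop("ids must be unique and match the number of sequences",
              "mlcs_parameter_error")
  alphabet <- as_alphabet(alphabet)
  if (identical(alphabet, "auto")) alphabet <- detect_alphabet(residues)
  structure(list(alphabet = alphabet, ids = ids, residues = residues,
                 n = length(residues), lengths = nchar(residues)),
            class = "mlcs_seqset")
}

#' @export
print.mlcs_seqset <- function(x, ...) {
  cat(sprintf("<mlcs_seqset> %d %s sequences (lengths %s)\n",
              x$n, x$alphabet$name,
              paste(x$lengths, collapse = ", ")))
  shown <- ifelse(x$lengths > 60L,
                  paste0(substr(x$residues, 1L, 57L), "..."), x$residues)
  cat(sprintf("  %s: %s\n", format(x$ids), shown), sep = "")
  invisible(x)
}

# per-sequence integer codes (1..K into alphabet$symbols, NA outside)
seqset_codes <- function(seqs) {
  lapply(strsplit(seqs$residues, "", fixed = TRUE),
         match, table = seqs$alphabet$symbols)
}

#' Check sequence legality against the alphabet
#'
#' Every residue of every sequence must belong to the declared alphabet.
#' Violations are returned as data, not raised as errors, so a caller can
#' report all offending positions at once.
#'
#' @param seqs an [sequence_set()].
#' @return A list of class `"mlcs_validation"` with `pass` (logical) and
#'   `violations`, a data frame with columns `id`, `position` (1-based) and
#'   `symbol`.
#' @examples
#' v <- validate_sequences(sequence_set(c("ACGU", "TTGA"), alphabet = "dna"))
#' v$pass
#' v$violations
#' @export
validate_sequences <- function(seqs) {
  stopifnot(inherits(seqs, "mlcs_seqset"))
  codes <- seqset_codes(seqs)
  viol <- lapply(seq_len(seqs$n), function(i) {
    bad <- which(is.na(codes[[i]]))
    if (!length(bad)) return(NULL)
    data.frame(id = seqs$ids[[i]], position = bad,
               symbol = substring(seqs$residues[[i]], bad, bad),
               stringsAsFactors = FALSE)
  })
  viol <- do.call(rbind, viol)
  if (is.null(viol))
    viol <- data.frame(id = character(), position = integer(),
                       symbol = character(), stringsAsFactors = FALSE)
  structure(list(pass = nrow(viol) == 0L, violations = viol),
            class = "mlcs_validation")
}

#' @export
print.mlcs_validation <- function(x, ...) {
  if (x$pass) cat("<mlcs_validation> pass\n")
  else {
    cat(sprintf("<mlcs_validation> %d violation(s)\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

# stop unless the set validates; used by the pipeline entry points
assert_valid <- function(seqs) {
  v <- validate_sequences(seqs)
  if (!v$pass) {
    head_v <- utils::head(v$violations, 3L)
    mlcs_stop(sprintf(
      "%d residue(s) outside the %s alphabet (first: %s position %d '%s')",
      nrow(v$violations), seqs$alphabet$name,
      head_v$id[[1L]], head_v$position[[1L]], head_v$symbol[[1L]]),
      "mlcs_input_error")
  }
  invisible(seqs)
}

#' Generate a seeded random sequence set
#'
#' Draws `n` independent sequences of uniform-random residues over the
#' alphabet.  Identical `(n, length, alphabet, seed)` give byte-identical
#' output; the caller's global random stream is left untouched.
#'
#' @param n number of sequences (>= 2).
#' @param length residues per sequence (>= 1); recycled to length `n`, so
#'   unequal lengths may be requested.
#' @param alphabet `"dna"`, `"protein"` or an [mlcs_alphabet()].
#' @param seed integer seed.
#' @return An [sequence_set()].
#' @examples
#' generate_random_sequences(3, 10, "dna", seed = 1)
#' @export
generate_random_sequences <- function(n, length, alphabet = "dna", seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L)
    mlcs_stop("n must be a single integer >= 2", "mlcs_parameter_error")
  if (!is.numeric(length) || any(length < 1L))
    mlcs_stop("length must be >= 1", "mlcs_parameter_error")
  alphabet <- as_alphabet(alphabet)
  if (identical(alphabet, "auto"))
    mlcs_stop("alphabet 'auto' is not meaningful for generation",
              "mlcs_parameter_error")
  n <- as.integer(n)
  lens <- rep_len(as.integer(length), n)
  residues <- with_preserved_seed(seed, {
    vapply(lens, function(L)
      paste(sample(alphabet$symbols, L, replace = TRUE), collapse = ""),
      character(1))
  })
  sequence_set(residues, alphabet = alphabet)
}

# evaluate expr under set.seed(seed) without disturbing the caller's stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
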