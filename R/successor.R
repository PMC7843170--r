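#' Build the successor table of one sequence
#'
#' Per-sequence next-occurrence index: for every symbol `c` of the alphabet
#' and every position `j` in `0..length`, the smallest position strictly
#' greater than `j` whose residue is `c` (or `NA` when no such position
#' exists).  Position 0 is the virtual pre-sequence coordinate, so
#' `next_occ[c, 0]` is the first occurrence of `c`.  This is the
#' preprocessing structure that makes match-point generation O(1) per
#' symbol.  Tables are built once and treated as immutable.
#'
#' @param residues a single sequence string (or an [sequence_set()], in which
#'   case its first sequence is used — prefer [build_successor_tables()] for
#'   whole sets).
#' @param alphabet an [mlcs_alphabet()] or alphabet name.
#' @param id sequence identifier carried along for diagnostics.
#' @return Object of class `"mlcs_successor_table"`: list with
#'   `sequence_id`, `alphabet` and `next_occ`, an `(length+1) x |alphabet|`
#'   integer matrix whose rows are positions `0..length` (row `j+1` holds
#'   position `j`) and whose columns are the alphabet symbols.
#' @examples
#' st <- build_successor_table("TACGT", "dna")
#' successor_next(st, "A", 0)  # 2
#' successor_next(st, "T", 1)  # 5
#' successor_next(st, "G", 4)  # NA
#' @export
build_successor_table <- function(residues, alphabet, id = "seq") {
  alphabet <- as_alphabet(alphabet)
  if (identical(alphabet, "auto")) alphabet <- detect_alphabet(residues)
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  codes <- match(strsplit(residues, "", fixed = TRUE)[[1L]],
                 alphabet$symbols)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[[1L]]
    mlcs_stop(sprintf("symbol '%s' at position %d of '%s' is outside the %s alphabet",
                      substring(residues, bad, bad), bad, id, alphabet$name),
              "mlcs_input_error")
  }
  L <- length(codes)
  K <- length(alphabet$symbols)
  next_occ <- matrix(NA_integer_, nrow = L + 1L, ncol = K,
                     dimnames = list(NULL, alphabet$symbols))
  for (k in seq_len(K)) {
    occ <- which(codes == k)
    if (length(occ)) {
      idx <- findInterval(0:L, occ) + 1L  # first occurrence strictly after j
      vals <- occ[idx]                    # NA past the last occurrence
      next_occ[, k] <- vals
    }
  }
  structure(list(sequence_id = id, alphabet = alphabet, next_occ = next_occ,
                 length = L),
            class = "mlcs_successor_table")
}

#' Build successor tables for every sequence of a set
#'
#' @param seqs an [sequence_set()].
#' @return List of [build_successor_table()] objects, one per sequence.
#' @export
build_successor_tables <- function(seqs) {
  stopifnot(inherits(seqs, "mlcs_seqset"))
  lapply(seq_len(seqs$n), function(i)
    build_successor_table(seqs$residues[[i]], seqs$alphabet,
                          id = seqs$ids[[i]]))
}

#' Query a successor table
#'
#' @param table an `"mlcs_successor_table"`.
#' @param symbol a single alphabet symbol.
#' @param position integer position in `0..length` (0 = virtual start).
#' @return The next position strictly after `position` carrying `symbol`, or
#'   `NA` if none.
#' @export
successor_next <- function(table, symbol, position) {
  stopifnot(inherits(table, "mlcs_successor_table"))
  if (!symbol %in% colnames(table$next_occ))
    mlcs_stop(sprintf("symbol '%s' is outside the alphabet", symbol),
              "mlcs_parameter_error")
  if (position < 0L || position > table$length)
    mlcs_stop("position must lie in 0..length", "mlcs_parameter_error")
  table$next_occ[position + 1L, symbol]
}

#' @export
print.mlcs_successor_table <- function(x, ...) {
  cat(sprintf("<mlcs_successor_table> '%s' (%s, length %d)\n",
              x$sequence_id, x$alphabet$name, x$length))
  invisible(x)
}

#' Dump a successor table as tab-separated text
#'
#' Debug helper: rows are positions 0..length, columns the alphabet symbols.
#'
#' @param table an `"mlcs_successor_table"`.
#' @param path output path, or `NULL` to return the lines.
#' @return The TSV lines (invisibly when written to `path`).
#' @export
dump_successor_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "mlcs_successor_table"))
  header <- paste(c("position", colnames(table$next_occ)), collapse = "\t")
  rows <- apply(cbind(0:table$length, table$next_occ), 1L,
                function(r) paste(ifelse(is.na(r), "-", r), collapse = "\t"))
  lines <- c(header, rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Build suffix symbol-count tables
#'
#' For every sequence, symbol and position `j` in `0..length`: the number of
#' occurrences of the symbol strictly after `j`.  Satisfies
#' `count(c, length) = 0` and
#' `count(c, j) = count(c, j+1) + [residue(j+1) == c]`.  Used by the
#' admissible upper bound of the heuristic (hf) pruning mode.
#'
#' @param seqs an [sequence_set()].
#' @return Object of class `"mlcs_suffix_counts"`: list of
#'   `(length+1) x |alphabet|` integer matrices (row `j+1` = position `j`).
#' @examples
#' sc <- build_suffix_counts(sequence_set(c("AB", "BA"), alphabet = "protein"))
#' sc$counts[[1]]["1", "A"]  # occurrences of A after position 1 of "AB": 0
#' @export
build_suffix_counts <- function(seqs) {
  stopifnot(inherits(seqs, "mlcs_seqset"))
  assert_valid(seqs)
  symbols <- seqs$alphabet$symbols
  codes <- seqset_codes(seqs)
  counts <- lapply(codes, function(cd) {
    L <- length(cd)
    m <- matrix(0L, nrow = L + 1L, ncol = length(symbols),
                dimnames = list(as.character(0:L), symbols))
    for (k in seq_along(symbols)) {
      ind <- as.integer(cd == k)
      # count strictly after position j = total from j+1 onwards
      m[, k] <- c(rev(cumsum(rev(ind))), 0L)
    }
    m
  })
  structure(list(alphabet = seqs$alphabet, counts = counts),
            class = "mlcs_suffix_counts")
}

#' Candidate match points reachable from a point in one step
#'
#' For each alphabet symbol `c`, looks up the next occurrence of `c` after
#' the point's coordinate in every sequence.  The symbol maps to the
#' resulting position vector iff the lookup succeeds in *every* sequence;
#' each returned vector is then a match point (all sequences carry `c` at
#' those positions) and exceeds the input point in every coordinate.
#'
#' @param point integer vector with one coordinate per sequence, each in
#'   `0..length_i` (all zeros = virtual source).
#' @param tables list of successor tables from [build_successor_tables()].
#' @return Named list mapping each reachable symbol to its position vector.
#' @examples
#' s <- sequence_set(c("AB", "BA"), alphabet = "protein")
#' tabs <- build_successor_tables(s)
#' successor_match_points(c(0, 0), tabs)  # A -> (1,2), B -> (2,1)
#' @export
successor_match_points <- function(point, tables) {
  n <- length(tables)
  if (length(point) != n)
    mlcs_stop("point must have one coordinate per sequence",
              "mlcs_parameter_error")
  lens <- vapply(tables, `[[`, integer(1), "length")
  if (any(point < 0L) || any(point > lens))
    mlcs_stop("point coordinates must lie in 0..length of each sequence",
              "mlcs_parameter_error")
  symbols <- colnames(tables[[1L]]$next_occ)
  # K x n matrix of candidate coordinates
  cand <- vapply(seq_len(n), function(i)
    tables[[i]]$next_occ[point[[i]] + 1L, ], integer(length(symbols)))
  if (length(symbols) == 1L) cand <- matrix(cand, nrow = 1L)
  ok <- !apply(is.na(cand), 1L, any)
  out <- lapply(which(ok), function(r) unname(cand[r, ]))
  names(out) <- symbols[ok]
  out
}
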