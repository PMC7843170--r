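# Pairwise dynamic-programming baselines and an exponential n-dimensional
# brute-force oracle.  The oracle deliberately shares no code with the
# dominant-point engine (no successor tables, no pruning): it fills the full
# position lattice, so it cannot share the engine's bugs.

codes_of <- function(s, alphabet = NULL) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  if (is.null(alphabet)) return(ch)
  match(ch, alphabet$symbols)
}

#' Full pairwise LCS dynamic-programming matrix
#'
#' Cell `[i+1, j+1]` holds the LCS length of the prefixes `s1[1..i]`,
#' `s2[1..j]`; row/column 1 are the zero base cases.  Rows are filled with
#' the vectorized recurrence
#' `L[i,j] = max(L[i-1,j], L[i,j-1], L[i-1,j-1] + [s1(i)=s2(j)])`
#' (a running maximum along the row).
#'
#' @param s1,s2 sequence strings (or single-sequence character vectors).
#' @return Integer matrix of dimensions `(nchar(s1)+1) x (nchar(s2)+1)`.
#' @export
dp_lcs_matrix <- function(s1, s2) {
  a <- codes_of(s1)
  b <- codes_of(s2)
  m <- length(a); n2 <- length(b)
  L <- matrix(0L, m + 1L, n2 + 1L)
  for (i in seq_len(m)) {
    prev <- L[i, ]
    mt <- c(0L, as.integer(b == a[[i]]))
    d <- pmax(prev, c(0L, prev[seq_len(n2)]) + mt)
    L[i + 1L, ] <- cummax(d)
  }
  L
}

#' Pairwise LCS length (full-matrix dynamic programming)
#'
#' The `normal` dynamic-programming mode: fills the complete scoring matrix.
#'
#' @inheritParams dp_lcs_matrix
#' @return Integer LCS length.
#' @examples
#' dp_lcs_length("ABCBDAB", "BDCABA")  # 4
#' @export
dp_lcs_length <- function(s1, s2) {
  L <- dp_lcs_matrix(s1, s2)
  L[nrow(L), ncol(L)]
}

#' Pairwise LCS length in linear space
#'
#' The `space_opti` dynamic-programming mode: identical recurrence, but only
#' the current and previous matrix rows are kept (the Hirschberg-style
#' length computation).  Always equals [dp_lcs_length()].
#'
#' @inheritParams dp_lcs_matrix
#' @return Integer LCS length.
#' @export
space_opt_lcs_length <- function(s1, s2) {
  a <- codes_of(s1)
  b <- codes_of(s2)
  n2 <- length(b)
  prev <- integer(n2 + 1L)
  for (i in seq_along(a)) {
    mt <- c(0L, as.integer(b == a[[i]]))
    prev <- cummax(pmax(prev, c(0L, prev[seq_len(n2)]) + mt))
  }
  prev[[n2 + 1L]]
}

# last occurrence of each symbol at or before position j (0 = none);
# matrix (length+1) x K, row j+1 = position j
last_occurrence_table <- function(codes, K) {
  L <- length(codes)
  m <- matrix(0L, L + 1L, K)
  for (k in seq_len(K)) {
    x <- ifelse(codes == k, seq_len(L), 0L)
    m[, k] <- c(0L, cummax(x))
  }
  m
}

#' Enumerate all distinct LCS strings of a pair
#'
#' Memoized backtracking over the full DP matrix: for each candidate final
#' symbol the rightmost occurrence at or before the current cell is taken,
#' and the recursion continues iff the remaining prefix pair still admits an
#' LCS one shorter.  Serves as the exact oracle for the two-sequence case.
#'
#' @inheritParams dp_lcs_matrix
#' @param alphabet an [mlcs_alphabet()] or name; `"auto"` (default) detects
#'   it from the two sequences.
#' @param budget maximum number of (string x cell) expansions before a
#'   resource error.
#' @return Sorted character vector of all distinct LCS strings (empty when
#'   the sequences share no symbol).
#' @examples
#' dp_enumerate_all_lcs("ABCBDAB", "BDCABA")  # BCAB BCBA BDAB
#' @export
dp_enumerate_all_lcs <- function(s1, s2, alphabet = "auto", budget = 1e6) {
  alphabet <- as_alphabet(alphabet)
  if (identical(alphabet, "auto"))
    alphabet <- detect_alphabet(c(toupper(s1), toupper(s2)))
  a <- codes_of(s1, alphabet)
  b <- codes_of(s2, alphabet)
  K <- length(alphabet$symbols)
  L <- dp_lcs_matrix(s1, s2)
  last1 <- last_occurrence_table(a, K)
  last2 <- last_occurrence_table(b, K)
  memo <- new.env(parent = emptyenv())
  work <- 0
  rec <- function(i, j) {
    k <- L[i + 1L, j + 1L]
    if (k == 0L) return("")
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- character()
    for (cc in seq_len(K)) {
      i2 <- last1[i + 1L, cc]
      j2 <- last2[j + 1L, cc]
      if (i2 == 0L || j2 == 0L) next
      if (L[i2, j2] == k - 1L)
        out <- c(out, paste0(rec(i2 - 1L, j2 - 1L), alphabet$symbols[[cc]]))
    }
    out <- unique(out)
    work <<- work + length(out)
    if (work > budget)
      mlcs_stop(sprintf("enumeration budget (%g) exceeded", budget),
                "mlcs_resource_error")
    memo[[key]] <- out
    out
  }
  res <- rec(length(a), length(b))
  if (identical(res, "")) return(character())
  sort(res, method = "radix")
}

# ---- n-dimensional brute-force oracle ---------------------------------------

# shift an array (or vector) by +1 in every dimension, zero-filling the border
shift_all_dims <- function(B, dims) {
  if (length(dims) == 1L) return(c(0L, B[seq_len(dims - 1L)]))
  Z <- array(0L, dims)
  if (any(dims < 2L)) return(Z)
  from <- lapply(dims, function(d) seq_len(d - 1L))
  to <- lapply(dims, function(d) 2:d)
  block <- do.call(`[`, c(list(B), from, list(drop = FALSE)))
  do.call(`[<-`, c(list(Z), to, list(block)))
}

# running maximum over every lower-or-equal index (separable prefix max)
cummax_all_dims <- function(d, dims) {
  if (length(dims) == 1L) return(cummax(d))
  for (k in seq_along(dims)) {
    perm <- c(k, seq_along(dims)[-k])
    dp <- aperm(array(d, dims), perm)
    m <- matrix(dp, dims[[k]], prod(dims[-k]))
    m <- apply(m, 2L, cummax)
    if (dims[[k]] == 1L) m <- matrix(m, 1L)
    d <- aperm(array(m, dims[perm]), order(perm))
  }
  d
}

#' Exact brute-force MLCS oracle over the full position lattice
#'
#' Generalizes the pairwise dynamic program to `n` sequences: the complete
#' `(len_1+1) x ... x (len_n+1)` scoring lattice is filled (no pruning, no
#' successor structure), then all distinct MLCS strings are recovered by
#' memoized backtracking over rightmost symbol occurrences.  Exponential in
#' `n` — this is the ground-truth oracle for small instances, not a general
#' solver.
#'
#' @param seqs an [sequence_set()].
#' @param budget maximum lattice size `prod(lengths + 1)`; larger inputs
#'   raise a resource error.
#' @return An [result_report()] (algorithm `"brute"`).
#' @examples
#' brute_force_mlcs(sequence_set(c("AC", "CA", "AA"), alphabet = "dna"))
#' @export
brute_force_mlcs <- function(seqs, budget = 1e6) {
  stopifnot(inherits(seqs, "mlcs_seqset"))
  assert_valid(seqs)
  lens <- seqs$lengths
  if (prod(lens + 1) > budget)
    mlcs_stop(sprintf(
      "lattice size %g exceeds the brute-force budget (%g)",
      prod(lens + 1), budget), "mlcs_resource_error")
  codes <- seqset_codes(seqs)
  K <- length(seqs$alphabet$symbols)
  n <- seqs$n
  dims2 <- lens[-1L] + 1L          # lattice dims for sequences 2..n
  # slabs[[i1+1]] = scoring values with first coordinate fixed at i1
  slabs <- vector("list", lens[[1L]] + 1L)
  zero <- if (length(dims2) == 1L) integer(dims2) else array(0L, dims2)
  slabs[[1L]] <- zero
  for (i1 in seq_len(lens[[1L]])) {
    c1 <- codes[[1L]][[i1]]
    ind <- lapply(2:n, function(j) c(0L, as.integer(codes[[j]] == c1)))
    mt <- Reduce(function(x, y) outer(x, y), ind)
    prev <- slabs[[i1]]
    d <- pmax(prev, shift_all_dims(prev, dims2) + mt)
    slabs[[i1 + 1L]] <- cummax_all_dims(d, dims2)
  }
  strides2 <- cumprod(c(1L, dims2[-length(dims2)]))
  value_at <- function(P) {
    slabs[[P[[1L]] + 1L]][[1L + sum(P[-1L] * strides2)]]
  }
  Lmax <- value_at(lens)
  if (Lmax == 0L)
    return(result_report(character(), 0L, algorithm = "brute"))
  last <- lapply(codes, last_occurrence_table, K = K)
  memo <- new.env(parent = emptyenv())
  work <- 0
  rec <- function(P) {
    k <- value_at(P)
    if (k == 0L) return("")
    key <- paste(P, collapse = ".")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- character()
    for (cc in seq_len(K)) {
      M <- vapply(seq_len(n), function(i) last[[i]][P[[i]] + 1L, cc],
                  integer(1))
      if (any(M == 0L)) next
      if (value_at(M - 1L) == k - 1L)
        out <- c(out, paste0(rec(M - 1L), seqs$alphabet$symbols[[cc]]))
    }
    out <- unique(out)
    work <<- work + length(out)
    if (work > budget)
      mlcs_stop(sprintf("enumeration budget (%g) exceeded", budget),
                "mlcs_resource_error")
    memo[[key]] <- out
    out
  }
  strings <- rec(lens)
  result_report(strings, Lmax, algorithm = "brute")
}
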