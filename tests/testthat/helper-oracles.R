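# Independent oracles used across the suite.  Each re-derives the quantity
# with the most literal method available (linear scans, all-pairs checks,
# exhaustive subsequence enumeration) so it cannot share bugs with the
# package's optimized paths.

# worked example pair: LCS length 4, strings BCAB/BCBA/BDAB (frozen from the
# DP-backtrack oracle, cross-checked by naive_all_lcs below)
worked_pair <- c("ABCBDAB", "BDCABA")
worked_alphabet <- mlcs_alphabet("protein", extra = "B")
worked_strings <- c("BCAB", "BCBA", "BDAB")

# next occurrence of `symbol` strictly after `pos` by left-to-right scan
naive_next_occ <- function(s, symbol, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (j in seq_along(ch)) if (j > pos && ch[[j]] == symbol) return(j)
  NA_integer_
}

naive_suffix_count <- function(s, symbol, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  sum(ch[seq_along(ch) > pos] == symbol)
}

# exhaustive all-LCS for tiny inputs: enumerate every subsequence of the
# shortest sequence, longest first
naive_all_lcs <- function(residues) {
  s0 <- residues[[which.min(nchar(residues))]]
  ch <- strsplit(s0, "", fixed = TRUE)[[1L]]
  is_sub <- function(w, s) {
    if (!nchar(w)) return(TRUE)
    wc <- strsplit(w, "", fixed = TRUE)[[1L]]
    sc <- strsplit(s, "", fixed = TRUE)[[1L]]
    j <- 1L
    for (x in sc) {
      if (x == wc[[j]]) { j <- j + 1L; if (j > length(wc)) return(TRUE) }
    }
    FALSE
  }
  for (r in rev(seq_len(length(ch)))) {
    found <- character()
    for (pick in utils::combn(length(ch), r, simplify = FALSE)) {
      w <- paste(ch[pick], collapse = "")
      if (w %in% found) next
      if (all(vapply(residues, function(s) is_sub(w, s), logical(1))))
        found <- c(found, w)
    }
    if (length(found))
      return(list(length = r, strings = sort(unique(found), method = "radix")))
  }
  list(length = 0L, strings = character())
}

# all-pairs dominance minima by the literal definition
naive_strong_minima <- function(pts) {
  keep <- rep(TRUE, nrow(pts))
  for (p in seq_len(nrow(pts)))
    for (q in seq_len(nrow(pts)))
      if (q != p && all(pts[q, ] < pts[p, ])) keep[[p]] <- FALSE
  pts[keep, , drop = FALSE]
}

# path counting by explicit path enumeration over the graph structure
naive_count_paths <- function(graph) {
  if (graph$L == 0L) return(0)
  total <- 0
  walk <- function(k, node) {
    if (k == 0L) { total <<- total + 1; return(invisible()) }
    for (p in graph$levels[[k + 1L]]$parents[[node]]) walk(k - 1L, p)
  }
  for (s in seq_len(nrow(graph$levels[[graph$L + 1L]]$points)))
    walk(graph$L, s)
  total
}

random_set <- function(seed, n = NULL, len = NULL, alphabet = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:4, 1L)
  if (is.null(len)) len <- sample(4:12, 1L)
  if (is.null(alphabet)) alphabet <- sample(c("dna", "protein"), 1L)
  generate_random_sequences(n, len, alphabet, seed = seed + 7L)
}
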