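#' Coordinatewise dominance between points
#'
#' `P` weakly dominates `Q` when every coordinate of `P` is `<=` the
#' corresponding coordinate of `Q`; strong dominance requires strict `<` in
#' every coordinate.  Weak dominance defines the classical k-dominant point
#' (the level-k Pareto frontier); the search engine prunes with *strong*
#' dominance so that every distinct MLCS string survives (see the package
#' vignette for why the weaker rule loses solutions).
#'
#' @param P,Q integer position vectors of equal length.
#' @return Named logical vector `c(weak = , strict = )`.
#' @examples
#' dominates(c(1, 2), c(2, 2))  # weak TRUE, strict FALSE
#' dominates(c(1, 2), c(2, 1))  # incomparable
#' @export
dominates <- function(P, Q) {
  if (length(P) != length(Q))
    mlcs_stop("points must have the same dimension", "mlcs_parameter_error")
  c(weak = all(P <= Q), strict = all(P < Q))
}

#' Prune options for the dominant-point search
#'
#' `pf` is plain dominance pruning.  `hf` additionally discards candidates
#' whose admissible upper bound proves they cannot reach a greedy lower
#' bound on the MLCS length; because the bound never underestimates, the
#' result set is identical to `pf`.
#'
#' @param mode `"pf"` or `"hf"`.
#' @param lower_bound optional integer `>= 0` used only by `hf`; when `NULL`
#'   the search computes a greedy common-subsequence length itself.
#' @return Object of class `"mlcs_prune_options"`.
#' @export
prune_options <- function(mode = c("pf", "hf"), lower_bound = NULL) {
  mode <- match.arg(mode)
  if (!is.null(lower_bound)) {
    if (!is.numeric(lower_bound) || length(lower_bound) != 1L || lower_bound < 0)
      mlcs_stop("lower_bound must be a single integer >= 0",
                "mlcs_parameter_error")
    lower_bound <- as.integer(lower_bound)
  }
  structure(list(mode = mode, lower_bound = lower_bound),
            class = "mlcs_prune_options")
}

#' A level set of match points
#'
#' Container for the points retained at one level `k` of the search:
#' an `m x n` coordinate matrix, the matched symbol of each point, and for
#' each point the row indices of its parents in the level-`(k-1)` set.
#'
#' @param points integer matrix, one row per point.
#' @param k level (`>= 0`; the all-zero source is the only level-0 point).
#' @param symbols character vector of matched symbols (`NA` for the source).
#' @param parents list of integer vectors of parent row indices.
#' @return Object of class `"mlcs_levelset"`.
#' @export
level_set <- function(points, k, symbols = NULL, parents = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "integer"
  m <- nrow(points)
  if (is.null(symbols)) symbols <- rep(NA_character_, m)
  if (is.null(parents)) parents <- rep(list(integer()), m)
  if (length(symbols) != m || length(parents) != m)
    mlcs_stop("symbols and parents must have one entry per point",
              "mlcs_parameter_error")
  structure(list(k = as.integer(k), points = points,
                 symbols = as.character(symbols), parents = parents),
            class = "mlcs_levelset")
}

#' @export
print.mlcs_levelset <- function(x, ...) {
  cat(sprintf("<mlcs_levelset> level %d: %d point(s)\n", x$k, nrow(x$points)))
  invisible(x)
}

point_keys <- function(pts) {
  if (!nrow(pts)) return(character())
  do.call(paste, c(as.data.frame(pts), sep = "."))
}

# Strong-dominance minima on a coordinate matrix (rows = points, assumed
# duplicate-free).  Returns logical keep-vector.  O(m^2 n) via outer
# comparisons; level sets are small at the scales this engine targets.
strong_minima_keep <- function(pts) {
  m <- nrow(pts)
  if (m <= 1L) return(rep(TRUE, m))
  dom <- matrix(TRUE, m, m)
  for (j in seq_len(ncol(pts)))
    dom <- dom & outer(pts[, j], pts[, j], `<`)
  # dom[q, p]: point q strongly dominates point p
  !apply(dom, 2L, any)
}

#' Prune a candidate level set to its retained points
#'
#' Duplicate coordinate vectors are first collapsed to one representative
#' whose parent set is the union of the duplicates' parents (distinct paths
#' may reach the same point, and all their spelled prefixes must survive).
#' Then any point strongly dominated by a different candidate — strictly
#' larger in *every* coordinate — is deleted as redundant: whatever extends
#' it extends the dominating point to at least the same length, and with the
#' same continuation symbols.
#'
#' @param candidates an [level_set()] (all points at one level; mixing
#'   levels is a precondition error, so a list of level sets is rejected).
#' @return A pruned [level_set()] at the same level.
#' @examples
#' ls <- level_set(rbind(c(1, 2), c(2, 3), c(2, 2)), k = 1,
#'                 symbols = c("A", "B", "C"))
#' prune_minima(ls)  # (2,3) is strongly dominated by (1,2)
#' @export
prune_minima <- function(candidates) {
  if (is.list(candidates) && !inherits(candidates, "mlcs_levelset")) {
    ks <- unique(vapply(candidates, function(l) l$k, integer(1)))
    if (length(ks) > 1L)
      mlcs_stop("candidates must all be at the same level",
                "mlcs_parameter_error")
    mlcs_stop("pass a single level_set of candidates", "mlcs_parameter_error")
  }
  stopifnot(inherits(candidates, "mlcs_levelset"))
  pts <- candidates$points
  if (!nrow(pts)) return(candidates)
  keys <- point_keys(pts)
  first <- !duplicated(keys)
  if (any(!first)) {
    groups <- split(seq_along(keys), keys)
    reps <- which(first)
    parents <- lapply(keys[reps], function(kk)
      sort(unique(unlist(candidates$parents[groups[[kk]]], use.names = FALSE))))
    pts <- pts[reps, , drop = FALSE]
    symbols <- candidates$symbols[reps]
  } else {
    parents <- candidates$parents
    symbols <- candidates$symbols
  }
  keep <- strong_minima_keep(pts)
  level_set(pts[keep, , drop = FALSE], candidates$k,
            symbols[keep], parents[keep])
}

#' Admissible upper bound on the extension of a point
#'
#' For a point `P`, sums over the alphabet the minimum (over sequences) of
#' the number of occurrences of each symbol strictly after `P`'s
#' coordinate.  No common subsequence extending `P` can be longer: each of
#' its characters consumes one occurrence of its symbol in every suffix.
#' Used by the `hf` prune mode; admissibility makes that pruning lossless.
#'
#' @param point integer position vector (one coordinate per sequence).
#' @param counts an [build_suffix_counts()] object.
#' @return Integer upper bound (0 at the sequence ends).
#' @examples
#' s <- sequence_set(c("AB", "BA"), alphabet = "protein")
#' extension_upper_bound(c(0, 0), build_suffix_counts(s))  # 2
#' @export
extension_upper_bound <- function(point, counts) {
  stopifnot(inherits(counts, "mlcs_suffix_counts"))
  if (length(point) != length(counts$counts))
    mlcs_stop("point must have one coordinate per sequence",
              "mlcs_parameter_error")
  rows <- lapply(seq_along(point), function(i)
    counts$counts[[i]][point[[i]] + 1L, ])
  sum(Reduce(pmin, rows))
}

# vectorized bound for an m x n candidate matrix
extension_upper_bound_rows <- function(pts, counts) {
  mins <- NULL
  for (i in seq_len(ncol(pts))) {
    rows <- counts$counts[[i]][pts[, i] + 1L, , drop = FALSE]
    mins <- if (is.null(mins)) rows else pmin(mins, rows)
  }
  as.integer(rowSums(mins))
}

#' Expand one level of the dominant-point search
#'
#' Generates every one-step successor match point of the current level's
#' points (recording the generating parents), optionally applies the `hf`
#' bound filter, and prunes the candidates with [prune_minima()].  The
#' number of raw candidates is attached as attribute `"n_candidates"`.
#'
#' @param current an [level_set()] at level `k`.
#' @param tables successor tables from [build_successor_tables()].
#' @param opts an [prune_options()].
#' @param counts suffix counts, required when `opts$mode == "hf"`.
#' @return The retained [level_set()] at level `k + 1` (possibly empty).
#' @export
expand_level <- function(current, tables, opts = prune_options("pf"),
                         counts = NULL) {
  stopifnot(inherits(current, "mlcs_levelset"))
  if (opts$mode == "hf" && is.null(counts))
    mlcs_stop("hf mode requires suffix counts", "mlcs_config_error")
  n <- length(tables)
  pts <- current$points
  m <- nrow(pts)
  symbols <- colnames(tables[[1L]]$next_occ)
  empty <- level_set(matrix(integer(), 0L, n), current$k + 1L)
  if (!m) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  cand_pts <- vector("list", length(symbols))
  cand_par <- vector("list", length(symbols))
  cand_sym <- vector("list", length(symbols))
  for (s in seq_along(symbols)) {
    succ <- matrix(NA_integer_, m, n)
    for (i in seq_len(n))
      succ[, i] <- tables[[i]]$next_occ[pts[, i] + 1L, s]
    ok <- !rowAnyNA(succ)
    if (any(ok)) {
      cand_pts[[s]] <- succ[ok, , drop = FALSE]
      cand_par[[s]] <- which(ok)
      cand_sym[[s]] <- rep(symbols[[s]], sum(ok))
    }
  }
  cpts <- do.call(rbind, cand_pts)
  if (is.null(cpts) || !nrow(cpts)) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  cpar <- as.list(unlist(cand_par, use.names = FALSE))
  csym <- unlist(cand_sym, use.names = FALSE)
  n_cand <- nrow(cpts)
  if (opts$mode == "hf") {
    lb <- opts$lower_bound
    if (is.null(lb)) lb <- 0L
    ub <- extension_upper_bound_rows(cpts, counts)
    keep <- (current$k + 1L) + ub >= lb
    cpts <- cpts[keep, , drop = FALSE]
    cpar <- cpar[keep]
    csym <- csym[keep]
    if (!nrow(cpts)) {
      attr(empty, "n_candidates") <- n_cand
      return(empty)
    }
  }
  out <- prune_minima(level_set(cpts, current$k + 1L, csym, cpar))
  attr(out, "n_candidates") <- n_cand
  out
}

rowAnyNA <- function(m) rowSums(is.na(m)) > 0L

#' Greedy common-subsequence lower bound
#'
#' Repeatedly takes, among the one-step successor candidates of the current
#' point, the symbol whose candidate minimizes the coordinate sum (ties
#' broken by alphabet order), until no symbol remains.  The resulting chain
#' is a common subsequence, so its length is a valid lower bound on the MLCS
#' length for `hf` pruning.
#'
#' @param tables successor tables from [build_successor_tables()].
#' @return Integer lower bound.
#' @export
greedy_lower_bound <- function(tables) {
  n <- length(tables)
  point <- rep(0L, n)
  len <- 0L
  repeat {
    cand <- successor_match_points(point, tables)
    if (!length(cand)) break
    sums <- vapply(cand, sum, numeric(1))
    point <- cand[[which.min(sums)]]  # which.min keeps alphabet order on ties
    len <- len + 1L
  }
  len
}

#' Run the level-wise dominant-point search
#'
#' Starting from the all-zero virtual source, repeatedly applies
#' [expand_level()] until the level set is empty.  The last non-empty level
#' is the MLCS length `L`.  Retained points that cannot reach level `L` are
#' then trimmed away so that every source-to-sink path in the returned graph
#' has exactly `L` edges.  In `hf` mode the greedy lower bound is computed
#' first; because the bound filter is admissible, the resulting MLCS set is
#' identical to `pf` mode.
#'
#' @param seqs a validated [sequence_set()] (`n >= 2`).
#' @param opts an [prune_options()].
#' @param node_budget maximum total number of retained points (guards
#'   against exponential blow-up on adversarial inputs); exceeding it raises
#'   a resource error naming the level reached.
#' @return An `"mlcs_graph"` object; see [backtrack_enumerate()].
#' @examples
#' g <- run_dominant_point_search(
#'   sequence_set(c("ABCBDAB", "BDCABA"), alphabet = "protein"))
#' g$L  # 4
#' @export
run_dominant_point_search <- function(seqs, opts = prune_options("pf"),
                                      node_budget = 1e6) {
  stopifnot(inherits(seqs, "mlcs_seqset"))
  if (seqs$n < 2L)
    mlcs_stop("the dominant-point search needs at least 2 sequences",
              c("mlcs_cardinality_error", "mlcs_input_error"))
  assert_valid(seqs)
  stopifnot(inherits(opts, "mlcs_prune_options"))
  tables <- build_successor_tables(seqs)
  counts <- NULL
  if (opts$mode == "hf") {
    counts <- build_suffix_counts(seqs)
    if (is.null(opts$lower_bound))
      opts$lower_bound <- greedy_lower_bound(tables)
  }
  n <- seqs$n
  levels <- list(level_set(matrix(0L, 1L, n), 0L))
  stats <- list(data.frame(level = 0L, candidates = NA_integer_, retained = 1L))
  total <- 1L
  k <- 0L
  repeat {
    nxt <- expand_level(levels[[k + 1L]], tables, opts, counts)
    if (!nrow(nxt$points)) break
    k <- k + 1L
    levels[[k + 1L]] <- nxt
    stats[[k + 1L]] <- data.frame(level = k,
                                  candidates = attr(nxt, "n_candidates"),
                                  retained = nrow(nxt$points))
    total <- total + nrow(nxt$points)
    if (total > node_budget)
      mlcs_stop(sprintf(
        "node budget (%g points) exceeded at level %d; raise node_budget",
        node_budget, k), "mlcs_resource_error", level = k)
  }
  graph <- trim_to_graph(levels, k)
  structure(list(levels = graph, L = k, n = n, alphabet = seqs$alphabet,
                 seq_ids = seqs$ids, prune = opts$mode,
                 stats = do.call(rbind, stats)),
            class = "mlcs_graph")
}

# keep only nodes from which a level-L sink is reachable, reindexing parents
trim_to_graph <- function(levels, L) {
  if (L == 0L) return(levels[1L])
  keep <- vector("list", L + 1L)
  keep[[L + 1L]] <- seq_len(nrow(levels[[L + 1L]]$points))
  for (k in L:1) {
    used <- sort(unique(unlist(levels[[k + 1L]]$parents[keep[[k + 1L]]],
                               use.names = FALSE)))
    keep[[k]] <- used
  }
  # the source always survives (level 1 parents reference it)
  out <- vector("list", L + 1L)
  for (k in 0:L) {
    ls <- levels[[k + 1L]]
    idx <- keep[[k + 1L]]
    remap <- if (k > 0L) match(seq_len(nrow(levels[[k]]$points)), keep[[k]])
    parents <- if (k == 0L) list(integer())
               else lapply(ls$parents[idx], function(p)
                 sort(remap[p[p %in% keep[[k]]]]))
    out[[k + 1L]] <- level_set(ls$points[idx, , drop = FALSE], k,
                               ls$symbols[idx], parents)
  }
  out
}
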