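#' @export
print.mlcs_graph <- function(x, ...) {
  nodes <- sum(vapply(x$levels, function(l) nrow(l$points), integer(1)))
  cat(sprintf("<mlcs_graph> L = %d, %d node(s) over %d level(s), prune = %s\n",
              x$L, nodes, length(x$levels), x$prune))
  invisible(x)
}

# structural checks; tampered graphs raise an integrity error
validate_graph <- function(graph) {
  if (!inherits(graph, "mlcs_graph") || !length(graph$levels))
    mlcs_stop("not an mlcs_graph", "mlcs_integrity_error")
  L <- graph$L
  if (length(graph$levels) != L + 1L)
    mlcs_stop("graph has a level gap", "mlcs_integrity_error")
  if (nrow(graph$levels[[1L]]$points) != 1L ||
      any(graph$levels[[1L]]$points != 0L))
    mlcs_stop("graph source must be the single all-zero point",
              "mlcs_integrity_error")
  if (L == 0L) return(invisible(TRUE))
  for (k in seq_len(L)) {
    ls <- graph$levels[[k + 1L]]
    if (ls$k != k || !nrow(ls$points))
      mlcs_stop(sprintf("level %d is missing or mislabelled", k),
                "mlcs_integrity_error")
    prev_m <- nrow(graph$levels[[k]]$points)
    for (j in seq_len(nrow(ls$points))) {
      par <- ls$parents[[j]]
      if (!length(par) || any(par < 1L) || any(par > prev_m))
        mlcs_stop(sprintf("node %d at level %d is unreachable", j, k),
                  "mlcs_integrity_error")
      prev <- graph$levels[[k]]$points[par, , drop = FALSE]
      if (any(prev >= matrix(ls$points[j, ], nrow(prev), ncol(prev),
                             byrow = TRUE)))
        mlcs_stop("edge does not increase every coordinate",
                  "mlcs_integrity_error")
    }
  }
  invisible(TRUE)
}

# children[[k]][[i]] = rows of level k+1 whose parents include row i of
# level k, sorted by (symbol, positions) of the child (or permuted when
# order = "random", used only to demonstrate traversal-order invariance)
graph_children <- function(graph, order = c("lex", "random"), seed = NULL) {
  order <- match.arg(order)
  L <- graph$L
  if (L == 0L) return(list())
  children <- vector("list", L)
  for (k in 0:(L - 1L)) {
    cur_m <- nrow(graph$levels[[k + 1L]]$points)
    nxt <- graph$levels[[k + 2L]]
    ord <- do.call(base::order,
                   c(list(nxt$symbols),
                     lapply(seq_len(ncol(nxt$points)),
                            function(j) nxt$points[, j])))
    rank <- match(seq_along(ord), ord)
    ch <- rep(list(integer()), cur_m)
    for (j in seq_len(nrow(nxt$points)))
      for (p in nxt$parents[[j]])
        ch[[p]] <- c(ch[[p]], j)
    ch <- lapply(ch, function(v) v[base::order(rank[v])])
    if (order == "random")
      ch <- with_preserved_seed(if (is.null(seed)) 1L else seed,
                                lapply(ch, function(v) v[sample.int(length(v))]))
    children[[k + 1L]] <- ch
  }
  children
}

#' Enumerate all MLCS by depth-first backtracking over the graph
#'
#' Traverses every source-to-sink path of the dominant-point graph
#' depth-first, spelling one string per path from the matched symbols in
#' level order.  Children are visited in lexicographic (symbol, positions)
#' order so repeated runs are byte-identical; the distinct string set is
#' invariant under any traversal order.
#'
#' @param graph an `"mlcs_graph"` from [run_dominant_point_search()].
#' @param enum_budget maximum number of paths to traverse before raising a
#'   resource error.
#' @param child_order `"lex"` (default) or `"random"` (traversal-order
#'   robustness testing only).
#' @param seed seed for `child_order = "random"`.
#' @return An [result_report()] with the sorted distinct strings, the
#'   length `L`, the distinct-string count and the raw path count.
#' @examples
#' g <- run_dominant_point_search(
#'   sequence_set(c("ABCBDAB", "BDCABA"), alphabet = "protein"))
#' backtrack_enumerate(g)
#' @export
backtrack_enumerate <- function(graph, enum_budget = 1e6,
                                child_order = c("lex", "random"),
                                seed = NULL) {
  validate_graph(graph)
  child_order <- match.arg(child_order)
  L <- graph$L
  if (L == 0L)
    return(result_report(character(), 0L, path_count = 0,
                         algorithm = paste0("dominant/", graph$prune)))
  children <- graph_children(graph, child_order, seed)
  symbols <- lapply(graph$levels, `[[`, "symbols")
  strings <- new.env(parent = emptyenv())
  paths <- 0
  buf <- character(L)
  dfs <- function(k, node) {
    if (k == L) {
      paths <<- paths + 1
      if (paths > enum_budget)
        mlcs_stop(sprintf("enumeration budget (%g paths) exceeded",
                          enum_budget), "mlcs_resource_error")
      assign(paste(buf, collapse = ""), TRUE, envir = strings)
      return(invisible())
    }
    for (ch in children[[k + 1L]][[node]]) {
      buf[k + 1L] <<- symbols[[k + 2L]][[ch]]
      dfs(k + 1L, ch)
    }
  }
  dfs(0L, 1L)
  result_report(ls(strings), L, path_count = paths,
                algorithm = paste0("dominant/", graph$prune))
}

#' Count source-to-sink longest paths by per-node memoization
#'
#' Independent of the depth-first enumeration: the number of paths reaching
#' each node is the sum over its parents, accumulated level by level; the
#' total is the sum over the level-`L` sinks.  Agreement with the path count
#' reported by [backtrack_enumerate()] is a consistency check on the graph.
#'
#' @param graph an `"mlcs_graph"`.
#' @return Numeric path count (0 when `L = 0`).
#' @export
count_paths <- function(graph) {
  validate_graph(graph)
  L <- graph$L
  if (L == 0L) return(0)
  cnt <- 1
  for (k in seq_len(L)) {
    ls <- graph$levels[[k + 1L]]
    cnt <- vapply(ls$parents, function(p) sum(cnt[p]), numeric(1))
  }
  sum(cnt)
}

#' Export the dominant-point graph as DOT text
#'
#' Node labels are `positions:level`; one edge per recorded parent link.
#'
#' @param graph an `"mlcs_graph"`.
#' @param path output path, or `NULL` to return the lines.
#' @return Character vector of DOT lines (invisibly when written).
#' @export
graph_to_dot <- function(graph, path = NULL) {
  validate_graph(graph)
  node_id <- function(k, j) sprintf("n%d_%d", k, j)
  lines <- c("digraph mlcs {", "  rankdir=LR;")
  for (k in 0:graph$L) {
    ls <- graph$levels[[k + 1L]]
    for (j in seq_len(nrow(ls$points))) {
      lab <- sprintf("%s:%d", paste(ls$points[j, ], collapse = ","), k)
      if (!is.na(ls$symbols[[j]]))
        lab <- sprintf("%s %s", ls$symbols[[j]], lab)
      lines <- c(lines, sprintf("  %s [label=\"%s\"];", node_id(k, j), lab))
      if (k > 0L)
        lines <- c(lines, sprintf("  %s -> %s;",
                                  vapply(ls$parents[[j]],
                                         function(p) node_id(k - 1L, p),
                                         character(1)),
                                  node_id(k, j)))
    }
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
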