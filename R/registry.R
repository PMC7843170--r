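# The component registry: algorithm variants are assembled by looking up
# implementations by (slot, name) rather than by hard-coded branches, so a
# new variant is added by registration, not by editing the pipeline.
# Slots mirror the feature structure of the algorithm family:
#   dp_mode     pairwise DP length computation (normal | space_opti)
#   prune_mode  dominant-point pruning behaviour (pf | hf)
#   domi_mode   the level-wise dominant-point engine
#   result_op   turning a graph into a report (backtrack)
#   algorithm   complete end-to-end paths (dominant | dp2 | brute)

.mlcs_registry <- new.env(parent = emptyenv())

registry_key <- function(slot, name) paste(slot, name, sep = "/")

#' Register an algorithm component
#'
#' @param slot one of `"dp_mode"`, `"prune_mode"`, `"domi_mode"`,
#'   `"result_op"`, `"algorithm"`.
#' @param name component name within the slot.
#' @param fun the implementing function.
#' @return `fun`, invisibly.
#' @export
register_mlcs_component <- function(slot, name, fun) {
  slots <- c("dp_mode", "prune_mode", "domi_mode", "result_op", "algorithm")
  if (!slot %in% slots)
    mlcs_stop(sprintf("unknown registry slot '%s'", slot),
              "mlcs_parameter_error")
  if (!is.function(fun))
    mlcs_stop("component must be a function", "mlcs_parameter_error")
  assign(registry_key(slot, name), fun, envir = .mlcs_registry)
  invisible(fun)
}

#' Look up a registered component
#'
#' @inheritParams register_mlcs_component
#' @return The registered function.
#' @export
mlcs_component <- function(slot, name) {
  key <- registry_key(slot, name)
  if (!exists(key, envir = .mlcs_registry, inherits = FALSE))
    mlcs_stop(sprintf("no component registered for %s", key),
              "mlcs_config_error")
  get(key, envir = .mlcs_registry, inherits = FALSE)
}

#' List registered components
#'
#' @return Data frame with columns `slot` and `name`.
#' @export
mlcs_components <- function() {
  keys <- sort(ls(.mlcs_registry))
  parts <- strsplit(keys, "/", fixed = TRUE)
  data.frame(slot = vapply(parts, `[[`, character(1), 1L),
             name = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

register_builtin_components <- function() {
  register_mlcs_component("dp_mode", "normal", dp_lcs_length)
  register_mlcs_component("dp_mode", "space_opti", space_opt_lcs_length)
  register_mlcs_component("prune_mode", "pf",
                          function(...) prune_options("pf", ...))
  register_mlcs_component("prune_mode", "hf",
                          function(...) prune_options("hf", ...))
  register_mlcs_component("domi_mode", "dominant", run_dominant_point_search)
  register_mlcs_component("result_op", "backtrack", backtrack_enumerate)
  register_mlcs_component("algorithm", "dominant",
                          function(seqs, config) {
    opts <- mlcs_component("prune_mode", config$prune)()
    graph <- mlcs_component("domi_mode", "dominant")(
      seqs, opts, node_budget = config$node_budget)
    rep <- mlcs_component("result_op", "backtrack")(
      graph, enum_budget = config$enum_budget)
    rep$stats <- graph$stats
    rep$graph <- graph
    rep
  })
  register_mlcs_component("algorithm", "dp2",
                          function(seqs, config) {
    if (seqs$n != 2L)
      mlcs_stop(sprintf("algorithm 'dp2' needs exactly 2 sequences, got %d",
                        seqs$n), "mlcs_config_error")
    len <- mlcs_component("dp_mode", config$dp_mode)(
      seqs$residues[[1L]], seqs$residues[[2L]])
    strings <- dp_enumerate_all_lcs(seqs$residues[[1L]], seqs$residues[[2L]],
                                    alphabet = seqs$alphabet,
                                    budget = config$enum_budget)
    result_report(strings, len, algorithm = paste0("dp2/", config$dp_mode))
  })
  register_mlcs_component("algorithm", "brute",
                          function(seqs, config)
    brute_force_mlcs(seqs, budget = config$enum_budget))
}

# populated at load so user re-registration survives; idempotent
.onLoad <- function(libname, pkgname) {
  register_builtin_components()
}

#' Build a run configuration
#'
#' The full configuration of one end-to-end run, as used by
#' [assemble_and_run()] and the command-line front end.
#'
#' @param input input FASTA path, [sequence_set()] or character vector of
#'   sequences.
#' @param out optional report output path.
#' @param algorithm `"dominant"`, `"dp2"` or `"brute"`.
#' @param prune `"pf"` or `"hf"`.
#' @param alphabet `"dna"`, `"protein"` or `"auto"`.
#' @param extend optional extra symbols admitted into the alphabet (a string
#'   such as `"B"` or `"B,Z"`); the explicit extension mechanism for
#'   ambiguity codes, which are otherwise validation violations.
#' @param dp_mode `"normal"` or `"space_opti"`.
#' @param seed integer seed (recorded; the exact paths are deterministic,
#'   so it only matters for auxiliary randomized checks).
#' @param node_budget,enum_budget resource limits.
#' @param stats optional path for the per-level statistics TSV.
#' @param dot optional path for a DOT export of the graph.
#' @param verbose print progress to standard error.
#' @return Object of class `"mlcs_config"`.
#' @export
run_config <- function(input, out = NULL,
                       algorithm = c("dominant", "dp2", "brute"),
                       prune = c("pf", "hf"),
                       alphabet = c("auto", "dna", "protein"),
                       extend = NULL,
                       dp_mode = c("normal", "space_opti"),
                       seed = 1L, node_budget = 1e6, enum_budget = 1e6,
                       stats = NULL, dot = NULL, verbose = FALSE) {
  extend <- if (is.null(extend)) character()
            else unlist(strsplit(gsub(",", "", toupper(as.character(extend))),
                                 "", fixed = TRUE), use.names = FALSE)
  extend <- unique(extend[nzchar(extend)])
  structure(list(input = input, out = out,
                 algorithm = match.arg(algorithm),
                 prune = match.arg(prune),
                 alphabet = match.arg(alphabet),
                 extend = extend,
                 dp_mode = match.arg(dp_mode),
                 seed = as.integer(seed),
                 node_budget = node_budget, enum_budget = enum_budget,
                 stats = stats, dot = dot, verbose = isTRUE(verbose)),
            class = "mlcs_config")
}

#' Assemble an algorithm from registered components and run it
#'
#' Executes the canonical pipeline — read, legality check, preprocessing,
#' search, backtrack, report — with every stage resolved through the
#' component registry.  Identical configuration and input give a
#' byte-identical report file.
#'
#' @param config an [run_config()].
#' @return The [result_report()], invisibly when a report file was written.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ABCBDAB", ">s2", "BDCABA"), f)
#' assemble_and_run(run_config(f, alphabet = "protein"))
#' @export
assemble_and_run <- function(config) {
  stopifnot(inherits(config, "mlcs_config"))
  note <- function(...) if (config$verbose) message(sprintf(...))
  seqs <- as_seqset(config$input, config$alphabet)
  if (length(config$extend))
    seqs <- sequence_set(seqs$residues, seqs$ids,
                         mlcs_alphabet(seqs$alphabet$name,
                                       extra = config$extend))
  note("read %d %s sequences", seqs$n, seqs$alphabet$name)
  assert_valid(seqs)
  runner <- mlcs_component("algorithm", config$algorithm)
  res <- runner(seqs, config)
  note("MLCS length %d, %d distinct string(s)", res$length, res$count)
  if (!is.null(config$stats) && !is.null(res$stats))
    utils::write.table(res$stats, config$stats, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(config$dot) && !is.null(res$graph))
    graph_to_dot(res$graph, config$dot)
  res$graph <- NULL
  res$n <- seqs$n
  res$alphabet <- seqs$alphabet$name
  if (!is.null(config$out)) {
    write_report(res, config$out)
    note("report written to %s", config$out)
    return(invisible(res))
  }
  res
}
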