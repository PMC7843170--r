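#' Construct a result report
#'
#' The common output surface of every algorithm path: all distinct MLCS
#' strings (lexicographically sorted), their shared length `L`, their count,
#' and the number of distinct source-to-sink longest paths in the dominant
#' point graph.  Distinct paths may spell identical strings; the headline
#' "number of MLCS" is the distinct-string count, while `path_count` keeps
#' the raw traversal count (always `>= count`; equal to `count` for
#' algorithm paths that have no graph, such as the brute-force oracle).
#'
#' @param strings character vector of MLCS strings (sorted and deduplicated
#'   internally).
#' @param length_L common length of the strings; must be 0 when `strings` is
#'   empty.
#' @param path_count number of distinct longest paths; defaults to the
#'   distinct-string count.
#' @param algorithm label of the producing algorithm path.
#' @return Object of class `"mlcs_result"`.
#' @export
result_report <- function(strings, length_L, path_count = NULL,
                          algorithm = NA_character_) {
  strings <- sort(unique(as.character(strings)), method = "radix")
  length_L <- as.integer(length_L)
  if (length(strings) && any(nchar(strings) != length_L))
    mlcs_stop("every MLCS string must have length length_L",
              "mlcs_parameter_error")
  if (!length(strings) && length_L != 0L)
    mlcs_stop("an empty string set implies length_L = 0",
              "mlcs_parameter_error")
  count <- length(strings)
  if (is.null(path_count)) path_count <- count
  path_count <- as.numeric(path_count)
  if (path_count < count)
    mlcs_stop("path_count cannot be smaller than the distinct-string count",
              "mlcs_parameter_error")
  structure(list(strings = strings, length = length_L, count = count,
                 path_count = path_count, algorithm = algorithm),
            class = "mlcs_result")
}

#' @export
print.mlcs_result <- function(x, max_show = 20L, ...) {
  cat("Multiple longest common subsequence result\n")
  if (!is.na(x$algorithm)) cat(sprintf("  algorithm: %s\n", x$algorithm))
  cat(sprintf("  MLCS length: %d\n  distinct MLCS: %d\n", x$length, x$count))
  if (x$path_count != x$count)
    cat(sprintf("  longest paths: %s\n", format(x$path_count)))
  if (x$count) {
    shown <- utils::head(x$strings, max_show)
    cat(paste0("  ", shown, "\n"), sep = "")
    if (x$count > max_show)
      cat(sprintf("  ... and %d more\n", x$count - max_show))
  }
  invisible(x)
}

#' @export
summary.mlcs_result <- function(object, ...) {
  print(object, max_show = object$count)
  invisible(object)
}

#' Write a result report to a plain-text file
#'
#' One sorted MLCS string per line, followed by `length:` and `count:`
#' lines.  Output is deterministic: the same report always produces a
#' byte-identical file.
#'
#' @param report an [result_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' r <- result_report(c("BDAB", "BCAB", "BCBA"), 4)
#' f <- tempfile()
#' write_report(r, f)
#' readLines(f)
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mlcs_result"))
  lines <- c(report$strings,
             sprintf("length: %d", report$length),
             sprintf("count: %d", report$count))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    mlcs_stop(sprintf("cannot write %s: %s", path,
                                      conditionMessage(e)), "mlcs_io_error"),
                  warning = function(w)
                    mlcs_stop(sprintf("cannot write %s: %s", path,
                                      conditionMessage(w)), "mlcs_io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Independently verify a result report against its input sequences
#'
#' Confirms with a plain two-pointer subsequence scan — sharing no code with
#' the search engine — that every reported string has length `L` and is a
#' subsequence of every input sequence.
#'
#' @param report an [result_report()].
#' @param seqs the [sequence_set()] the report was computed from.
#' @return List with `pass` and a data frame `violations`
#'   (`string`, `id`, `reason`).
#' @export
verify_result <- function(report, seqs) {
  stopifnot(inherits(report, "mlcs_result"), inherits(seqs, "mlcs_seqset"))
  viols <- list()
  for (w in report$strings) {
    if (nchar(w) != report$length)
      viols[[length(viols) + 1L]] <-
        data.frame(string = w, id = NA_character_,
                   reason = "length differs from L", stringsAsFactors = FALSE)
    for (i in seq_len(seqs$n)) {
      if (!is_subsequence(w, seqs$residues[[i]]))
        viols[[length(viols) + 1L]] <-
          data.frame(string = w, id = seqs$ids[[i]],
                     reason = "not a subsequence", stringsAsFactors = FALSE)
    }
  }
  viols <- if (length(viols)) do.call(rbind, viols)
           else data.frame(string = character(), id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  list(pass = nrow(viols) == 0L, violations = viols)
}

# two-pointer scan: is w an (ordered, not necessarily contiguous)
# subsequence of s?
is_subsequence <- function(w, s) {
  if (!nchar(w)) return(TRUE)
  wc <- strsplit(w, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  j <- 1L
  for (ch in sc) {
    if (ch == wc[[j]]) {
      j <- j + 1L
      if (j > length(wc)) return(TRUE)
    }
  }
  FALSE
}
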