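#' Sequence alphabets
#'
#' Construct the residue alphabet against which sequences are validated and
#' over which match points are generated.  Two built-in alphabets are
#' provided: `"dna"` (A, C, G, T) and `"protein"` (the 20 standard amino-acid
#' one-letter codes).  Dominant-point matching assumes exact symbol equality,
#' so IUPAC ambiguity codes are *not* part of either alphabet; they can be
#' admitted explicitly through `extra` (e.g. `extra = "N"`), which extends the
#' symbol set rather than repairing the input.
#'
#' @param name `"dna"` or `"protein"`.
#' @param extra optional character vector of additional single-character
#'   symbols to admit (uppercased, deduplicated).
#' @return An object of class `"mlcs_alphabet"`: a list with `name` and
#'   `symbols` (ordered character vector).
#' @examples
#' mlcs_alphabet("dna")
#' mlcs_alphabet("dna", extra = "N")
#' @export
mlcs_alphabet <- function(name = c("dna", "protein"), extra = character()) {
  name <- match.arg(name)
  symbols <- switch(name,
    dna     = c("A", "C", "G", "T"),
    protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  if (length(extra)) {
    extra <- toupper(as.character(extra))
    if (any(nchar(extra) != 1L))
      mlcs_stop("extra alphabet symbols must be single characters",
                "mlcs_parameter_error")
    symbols <- unique(c(symbols, extra))
  }
  structure(list(name = name, symbols = symbols), class = "mlcs_alphabet")
}

# Accept an mlcs_alphabet, a name string, or "auto"; "auto" is resolved later
# against the residues themselves.
as_alphabet <- function(x) {
  if (inherits(x, "mlcs_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (identical(x, "auto")) return("auto")
    return(mlcs_alphabet(x))
  }
  mlcs_stop("alphabet must be 'dna', 'protein', 'auto' or an mlcs_alphabet",
            "mlcs_parameter_error")
}

# dna iff every residue of every sequence is in {A,C,G,T}, else protein
detect_alphabet <- function(residues) {
  chars <- unique(unlist(strsplit(residues, "", fixed = TRUE), use.names = FALSE))
  if (all(chars %in% c("A", "C", "G", "T"))) mlcs_alphabet("dna")
  else mlcs_alphabet("protein")
}

#' @export
print.mlcs_alphabet <- function(x, ...) {
  cat(sprintf("<mlcs_alphabet> %s: %s\n", x$name,
              paste(x$symbols, collapse = "")))
  invisible(x)
}
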