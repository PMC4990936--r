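# Internal helpers shared across modules.

# IUPAC nucleotide codes mapped to the set of plain bases each one matches.
# N is handled separately by the motif scanner (pure spacer, never a mismatch).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of a nucleotide string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x A single nucleotide string (A/C/G/T plus IUPAC codes).
#' @return A character scalar.
#' @keywords internal
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Random A/C/G/T string (uses the current RNG stream).
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Write a data.frame as TSV with optional '#'-prefixed header comment lines.
writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
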