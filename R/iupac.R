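# IUPAC nucleotide ambiguity codes: each code denotes a set of plain bases.
# Sets are stored sorted so degenerate expansion is lexicographic.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# set (sorted base vector) -> minimal IUPAC code
IUPAC_CODE <- local({
  keys <- vapply(IUPAC_SETS, paste, "", collapse = "")
  stats::setNames(names(IUPAC_SETS), keys)
})

iupac_set <- function(char) {
  s <- IUPAC_SETS[[char]]
  if (is.null(s)) stop("invalid IUPAC character: '", char, "'", call. = FALSE)
  s
}

iupac_collapse <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_CODE[[key]]
  if (is.null(code)) stop("no IUPAC code for base set {", key, "}", call. = FALSE)
  code
}

#' Number of plain sequences a degenerate primer denotes
#'
#' The degeneracy of an IUPAC string is the product of the per-position
#' ambiguity-set sizes; a plain ACGT sequence has degeneracy 1.
#'
#' @param sequence IUPAC nucleotide string.
#' @return Integer degeneracy.
#' @export
#' @examples
#' degeneracy("AYGT")  # 2
degeneracy <- function(sequence) {
  chars <- seq_chars(sequence)
  prod(vapply(chars, function(ch) length(iupac_set(ch)), integer(1)))
}

#' Expand a degenerate primer into plain sequences
#'
#' Cartesian expansion of all IUPAC ambiguity positions, returned in
#' lexicographic order.
#'
#' @param sequence IUPAC nucleotide string.
#' @param cap Maximum admissible degeneracy (default 64); above it the
#'   primer should be redesigned rather than expanded.
#' @return Character vector of plain ACGT sequences.
#' @export
#' @examples
#' expand_degenerate("AY")  # "AC" "AT"
expand_degenerate <- function(sequence, cap = 64) {
  d <- degeneracy(sequence)
  if (d > cap) {
    stop("degeneracy ", d, " exceeds cap ", cap,
         "; redesign the primer with fewer degenerate positions", call. = FALSE)
  }
  out <- ""
  for (ch in seq_chars(sequence)) {
    out <- as.vector(t(outer(out, sort(iupac_set(ch)), paste0)))
  }
  out
}

#' IUPAC-aware reverse complement
#'
#' Complements every base including ambiguity codes (Y<->R, S<->S,
#' D<->H, N<->N, ...) and reverses the sequence. U is normalized to T
#' first.
#'
#' @param sequence IUPAC nucleotide string.
#' @return The reverse complement, same alphabet.
#' @export
#' @examples
#' reverse_complement("AYG")  # "CRT"
reverse_complement <- function(sequence) {
  x <- normalize_residues(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# TRUE where the bases that `a` can be intersect the bases `b` can be
iupac_compatible <- function(a, b) {
  mapply(function(x, y) length(intersect(iupac_set(x), iupac_set(y))) > 0, a, b,
         USE.NAMES = FALSE)
}

seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  gsub(".", "-", x, fixed = TRUE)
}
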