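# Codon-table base order (first position slowest): U < C < A < G.
CODON_BASES <- c("U", "C", "A", "G")

#' All 64 codons in codon-table order
#'
#' Codons are ordered with bases ranked U < C < A < G at each position and
#' the first position varying slowest, the convention used in printed codon
#' tables (UUU, UUC, UUA, UUG, UCU, ...).
#'
#' @return Character vector of 64 RNA codons.
#' @export
codon_levels <- function() {
  grid <- expand.grid(p3 = CODON_BASES, p2 = CODON_BASES, p1 = CODON_BASES,
                      stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3)
}

#' Normalize nucleotide strings to the internal RNA alphabet
#'
#' Upper-cases and maps T to U. The transformation is idempotent; [as_dna()]
#' inverts it for writers that emit DNA.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector in the RNA alphabet.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

third_nt <- function(codon) substr(codon, 3L, 3L)

# Round half away from zero (printed-table convention); base round() is
# banker's rounding.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

# 0-based half-open <-> 1-based inclusive conversion lives here and nowhere
# else; all internal arithmetic is 0-based half-open.
to_zero_based <- function(start, end, style = c("1-based", "0-based")) {
  style <- match.arg(style)
  if (style == "1-based") list(start = start - 1L, end = end) else list(start = start, end = end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
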