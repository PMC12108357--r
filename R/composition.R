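#' Nucleotide composition, AT/GC content and skew
#'
#' Counts unambiguous bases and computes AT/GC content and the strand
#' asymmetry skews
#' \deqn{AT\mbox{-}skew = (A - T)/(A + T), \quad GC\mbox{-}skew = (G - C)/(G + C),}
#' where A, T, G, C are base counts. A zero denominator yields a missing
#' skew, not 0. On a CDS tibble the summary is computed per record and gene;
#' on a character vector, per element.
#'
#' @param x A CDS tibble (with columns `record_id`, `gene`, `seq`) or a
#'   character vector of nucleotide sequences.
#' @param ... Unused.
#' @return A tibble with counts `a`, `u`, `g`, `c`, `n_ambiguous`, contents
#'   `at_content`, `gc_content` (fractions; `*_pct` in percent) and
#'   `at_skew`, `gc_skew`.
#' @export
composition <- function(x, ...) UseMethod("composition")

#' @export
composition.character <- function(x, ...) {
  if (any(!nzchar(x))) stop("Empty sequence", call. = FALSE)
  seqs <- as_rna(x)
  count1 <- function(s, b) nchar(s) - nchar(gsub(b, "", s, fixed = TRUE))
  a <- count1(seqs, "A"); u <- count1(seqs, "U")
  g <- count1(seqs, "G"); c_ <- count1(seqs, "C")
  tot <- a + u + g + c_
  skew <- function(p, q) ifelse(p + q == 0, NA_real_, (p - q) / (p + q))
  tibble::tibble(
    a = a, u = u, g = g, c = c_,
    n_ambiguous = nchar(seqs) - tot,
    at_content = (a + u) / tot,
    gc_content = (g + c_) / tot,
    at_content_pct = 100 * (a + u) / tot,
    gc_content_pct = 100 * (g + c_) / tot,
    at_skew = skew(a, u),
    gc_skew = skew(g, c_)
  )
}

#' @export
composition.data.frame <- function(x, ...) {
  stopifnot(all(c("record_id", "gene", "seq") %in% names(x)))
  dplyr::bind_cols(dplyr::select(x, "record_id", "gene"), composition.character(x$seq))
}

#' Genome-level composition of the records behind a CDS tibble
#'
#' Computed on the annotated plus (heavy) strand of each full genome
#' sequence, as carried in the `"genomes"` attribute of [read_genbank()] /
#' [read_fasta_cds()] output.
#'
#' @param cds A CDS tibble carrying a `"genomes"` attribute.
#' @return One composition row per genome record.
#' @export
genome_composition <- function(cds) {
  genomes <- attr(cds, "genomes")
  if (is.null(genomes)) stop("No genome sequences attached to this CDS table", call. = FALSE)
  dplyr::bind_cols(
    dplyr::select(genomes, "record_id", "length"),
    composition.character(genomes$seq)
  )
}

#' Per-gene skewness plot coordinates
#'
#' For each gene (and record), the (x = content in percent, y = skew) pairs
#' for the two skewness-plot variants: AT-skew against AT content and
#' GC-skew against GC content.
#'
#' @param cds A CDS tibble.
#' @return A tibble of class `skew_points` with columns `record_id`, `gene`,
#'   `variant` (`"AT"`/`"GC"`), `content_pct`, `skew`.
#' @export
skew_points <- function(cds) {
  comp <- composition(cds)
  out <- dplyr::bind_rows(
    dplyr::transmute(comp, .data$record_id, .data$gene, variant = "AT",
                     content_pct = .data$at_content_pct, skew = .data$at_skew),
    dplyr::transmute(comp, .data$record_id, .data$gene, variant = "GC",
                     content_pct = .data$gc_content_pct, skew = .data$gc_skew)
  )
  class(out) <- c("skew_points", class(out))
  out
}
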