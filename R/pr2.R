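#' Extract four-fold degenerate codons from coding sequences
#'
#' Order-preserving sublist of each gene's codons that belong to
#' degeneracy-4 synonymous families (24 codons of Ala, Arg, Gly, Pro, Thr
#' and Val under the vertebrate mitochondrial code).
#'
#' @param x A CDS tibble or a codonized tibble from [codonize()].
#' @param code A [genetic_code()] object.
#' @param stop_policy Passed to [codonize()] when `x` is a CDS tibble.
#' @return The codonized tibble restricted to four-fold degenerate codons.
#' @export
extract_fourfold <- function(x, code = genetic_code(),
                             stop_policy = "drop-partial") {
  codons <- if ("codon" %in% names(x)) x else codonize(x, code, stop_policy)
  dplyr::filter(codons, .data$codon %in% fourfold_codons(code))
}

#' Parity-rule-2 (PR2) bias at third positions of four-fold codons
#'
#' Under strand-symmetric mutation and selection, A is expected to match T
#' and G to match C within a strand (parity rule 2), so third positions of
#' four-fold degenerate codons — where any base is synonymous — should show
#' AT-bias = A3/(A3+T3) = 0.5 and GC-bias = G3/(G3+C3) = 0.5. Deviations
#' locate each gene in a quadrant of the PR2 plot, drawn here with
#' x = GC-bias and y = AT-bias: quadrant I (x > 0.5, y > 0.5, G and A
#' preferred), II (x < 0.5, y > 0.5, C and A), III (x < 0.5, y < 0.5, C and
#' T), IV (x > 0.5, y < 0.5, G and T). A coordinate exactly at 0.5 is
#' labelled `on-axis`. Counts are pooled per gene across records by default.
#'
#' @param cds A CDS tibble.
#' @param code A [genetic_code()] object.
#' @param by `"gene"` (pooled across individuals, default) or
#'   `"record_gene"` (per individual).
#' @param stop_policy Passed to [codonize()].
#' @param min_codons Four-fold codon count below which a gene is flagged
#'   `low_support` (default 10).
#' @return A tibble of class `pr2_points`: grouping columns, counts `a3`,
#'   `t3`, `g3`, `c3`, `n_fourfold`, `at_bias`, `gc_bias`, `quadrant`,
#'   `low_support`.
#' @export
pr2_points <- function(cds, code = genetic_code(),
                       by = c("gene", "record_gene"),
                       stop_policy = "drop-partial", min_codons = 10L) {
  by <- match.arg(by)
  keys <- if (by == "gene") "gene" else c("record_id", "gene")
  ff <- extract_fourfold(cds, code, stop_policy)
  out <- ff %>%
    dplyr::mutate(nt3 = third_nt(.data$codon)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      a3 = sum(.data$nt3 == "A"), t3 = sum(.data$nt3 == "U"),
      g3 = sum(.data$nt3 == "G"), c3 = sum(.data$nt3 == "C"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      n_fourfold = .data$a3 + .data$t3 + .data$g3 + .data$c3,
      at_bias = dplyr::if_else(.data$a3 + .data$t3 > 0,
                               .data$a3 / (.data$a3 + .data$t3), NA_real_),
      gc_bias = dplyr::if_else(.data$g3 + .data$c3 > 0,
                               .data$g3 / (.data$g3 + .data$c3), NA_real_),
      quadrant = pr2_quadrant(.data$gc_bias, .data$at_bias),
      low_support = .data$n_fourfold < min_codons
    )
  class(out) <- c("pr2_points", class(out))
  out
}

pr2_quadrant <- function(x, y) {
  dplyr::case_when(
    is.na(x) | is.na(y) ~ NA_character_,
    x == 0.5 | y == 0.5 ~ "on-axis",
    x > 0.5 & y > 0.5 ~ "I",
    x < 0.5 & y > 0.5 ~ "II",
    x < 0.5 & y < 0.5 ~ "III",
    TRUE ~ "IV"
  )
}
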