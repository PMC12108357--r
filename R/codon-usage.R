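#' Count codon usage per gene
#'
#' Counts all 64 codons over the codonized CDS (initiator and, when
#' complete, terminal stop codon included by default; a 1-2 nt partial stop
#' can never be counted). Every codon key is present, zeros allowed.
#'
#' @param cds A CDS tibble.
#' @param code A [genetic_code()] object.
#' @param stop_policy Passed to [codonize()].
#' @param by Counting unit: `"record_gene"` (default; one table per record
#'   and gene), `"gene"` (pooled across records), `"record"` (concatenated 13
#'   PCGs per record) or `"all"` (one pooled table, `unit_id = "all"`).
#' @param include_initiator,include_terminal_stop Drop the first / final
#'   (complete stop) codon before counting when `FALSE`.
#' @return A tibble of class `codon_counts` with grouping columns
#'   (`record_id` and/or `gene`), `codon`, `count`.
#' @export
count_codons <- function(cds, code = genetic_code(),
                         stop_policy = c("drop-partial", "polyadenylate"),
                         by = c("record_gene", "gene", "record", "all"),
                         include_initiator = TRUE, include_terminal_stop = TRUE) {
  by <- match.arg(by)
  codons <- codonize(cds, code, stop_policy)
  if (!include_initiator) {
    codons <- dplyr::filter(codons, .data$codon_index > 1L)
  }
  if (!include_terminal_stop) {
    codons <- codons %>%
      dplyr::group_by(.data$record_id, .data$gene) %>%
      dplyr::filter(!(.data$codon_index == max(.data$codon_index) &
                        .data$codon %in% code$stop_codons)) %>%
      dplyr::ungroup()
  }
  keys <- switch(by,
    record_gene = c("record_id", "gene"),
    gene = "gene",
    record = "record_id",
    all = character()
  )
  if (by == "all") codons$unit_id <- "all"
  if (by == "all") keys <- "unit_id"
  out <- codons %>%
    dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$codon, name = "count") %>%
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      codon = codon_levels(),
      fill = list(count = 0L)
    ) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), match(.data$codon, codon_levels()))
  class(out) <- c("codon_counts", class(out))
  out
}

count_keys <- function(counts) setdiff(names(counts), c("codon", "count"))

#' Pool codon counts over records and/or genes
#'
#' @param counts A `codon_counts` tibble.
#' @param by Remaining grouping columns, e.g. `"gene"` to pool across
#'   records; `character()` pools everything into `unit_id = "all"`.
#' @return A `codon_counts` tibble.
#' @export
pool_counts <- function(counts, by = "gene") {
  if (length(by) == 0L) {
    counts$unit_id <- "all"
    by <- "unit_id"
  }
  out <- counts %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$codon) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(by)), match(.data$codon, codon_levels()))
  class(out) <- c("codon_counts", class(out))
  out
}

# family table incl. the degeneracy-4 stop pseudo-family (RSCU only)
rscu_families <- function(code, include_stops = TRUE) {
  fam <- dplyr::select(code$families, "codon", "amino_acid", "family", "degeneracy")
  if (include_stops) {
    fam <- dplyr::bind_rows(fam, tibble::tibble(
      codon = code$stop_codons, amino_acid = "*", family = "*",
      degeneracy = length(code$stop_codons)
    ))
  }
  fam
}

#' Relative synonymous codon usage with CUP classification
#'
#' For codon j in a synonymous family of size k with family total N > 0,
#' RSCU = k n_j / N: the observed count relative to the uniform-usage
#' expectation, independent of gene length and amino-acid composition.
#' Codon usage patterns (CUP) are classified per codon: `unused` (RSCU = 0),
#' `under` (0 < RSCU < 0.6), `over` (RSCU > 1.6), `unbiased` otherwise. Stop
#' codons are treated as one 4-member pseudo-family so that stop-codon
#' preference is visible alongside sense codons. Members of families with no
#' observations carry a missing RSCU and `family_observed = FALSE`; they are
#' classified `unused` by default since their usage count is zero.
#'
#' @param counts A `codon_counts` tibble.
#' @param code A [genetic_code()] object.
#' @param include_stops Include the stop pseudo-family (default `TRUE`).
#' @param classify_absent Classify members of unobserved families as
#'   `unused` (default) instead of `NA`.
#' @return A tibble of class `rscu_tbl`: grouping columns, `codon`,
#'   `amino_acid`, `degeneracy`, `count`, `rscu`, `family_observed`,
#'   `cup_class`, `third_nt`.
#' @export
rscu <- function(counts, code = genetic_code(), include_stops = TRUE,
                 classify_absent = TRUE) {
  keys <- count_keys(counts)
  fam <- rscu_families(code, include_stops)
  out <- counts %>%
    dplyr::inner_join(fam, by = "codon") %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$family) %>%
    dplyr::mutate(
      family_total = sum(.data$count),
      family_observed = .data$family_total > 0L,
      rscu = dplyr::if_else(.data$family_observed,
                            .data$degeneracy * .data$count / .data$family_total,
                            NA_real_)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      cup_class = classify_cup(.data$rscu, classify_absent),
      third_nt = third_nt(.data$codon)
    ) %>%
    dplyr::select(dplyr::all_of(keys), "codon", "amino_acid", "degeneracy",
                  "count", "rscu", "family_observed", "cup_class", "third_nt") %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), match(.data$codon, codon_levels()))
  class(out) <- c("rscu_tbl", class(out))
  out
}

CUP_LEVELS <- c("unused", "under", "unbiased", "over")

classify_cup <- function(rscu, classify_absent = TRUE) {
  v <- rscu
  if (classify_absent) v[is.na(v)] <- 0
  cls <- dplyr::case_when(
    is.na(v) ~ NA_character_,
    v == 0 ~ "unused",
    v < 0.6 ~ "under",
    v > 1.6 ~ "over",
    TRUE ~ "unbiased"
  )
  factor(cls, levels = CUP_LEVELS)
}

#' Mean RSCU across individuals
#'
#' Arithmetic mean of per-individual RSCU values for each gene and codon,
#' with CUP classification applied to the means. Missing per-individual
#' values (unobserved families) enter the mean as 0 by default, so every
#' codon stays classifiable.
#'
#' @param rscu_tbl An `rscu_tbl` with a `record_id` column.
#' @param na_as_zero Treat unobserved-family RSCU as 0 (default).
#' @return An `rscu_tbl` keyed by the remaining grouping columns, with
#'   columns `rscu` (mean), `n_records`, `cup_class`, `third_nt`.
#' @export
mean_rscu <- function(rscu_tbl, na_as_zero = TRUE) {
  keys <- setdiff(
    names(rscu_tbl),
    c("record_id", "codon", "amino_acid", "degeneracy", "count", "rscu",
      "family_observed", "cup_class", "third_nt")
  )
  keys <- unique(c(intersect(names(rscu_tbl), c("gene", "unit_id")), keys))
  if (!"record_id" %in% names(rscu_tbl)) {
    stop("mean_rscu expects per-record RSCU tables (a 'record_id' column)", call. = FALSE)
  }
  out <- rscu_tbl %>%
    dplyr::mutate(rscu_eff = if (na_as_zero) dplyr::coalesce(.data$rscu, 0) else .data$rscu) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$codon,
                    .data$amino_acid, .data$degeneracy) %>%
    dplyr::summarise(
      rscu = mean(.data$rscu_eff),
      n_records = dplyr::n(),
      family_observed = any(.data$family_observed),
      .groups = "drop"
    ) %>%
    dplyr::mutate(cup_class = classify_cup(.data$rscu),
                  third_nt = third_nt(.data$codon)) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), match(.data$codon, codon_levels()))
  class(out) <- c("rscu_tbl", class(out))
  out
}

#' RSCU-interval by codon-ending summary
#'
#' Cross-classifies every (gene, codon) pair by RSCU interval (0, 0-0.6,
#' 0.6-1.6, >1.6) and by the codon's third nucleotide, with row totals and
#' percentages of the grand total (number of genes x 64). The arithmetic on
#' a prepared count table is exposed as [interval_percentages()].
#'
#' @param mean_tbl A per-gene `rscu_tbl` (typically from [mean_rscu()]).
#' @return A tibble of class `interval_summary`: `cup_class`, counts `A`,
#'   `G`, `U`, `C`, `total`, `percentage`.
#' @export
interval_summary <- function(mean_tbl) {
  counts <- mean_tbl %>%
    dplyr::count(.data$cup_class, .data$third_nt) %>%
    tidyr::complete(cup_class = factor(CUP_LEVELS, levels = CUP_LEVELS),
                    third_nt = c("A", "G", "U", "C"), fill = list(n = 0L)) %>%
    tidyr::pivot_wider(names_from = "third_nt", values_from = "n") %>%
    dplyr::select("cup_class", "A", "G", "U", "C")
  interval_percentages(counts)
}

#' @rdname interval_summary
#' @param counts A tibble with columns `cup_class` and ending-nucleotide
#'   counts `A`, `G`, `U`, `C` (one row per RSCU interval).
#' @export
interval_percentages <- function(counts) {
  out <- counts %>%
    dplyr::mutate(total = .data$A + .data$G + .data$U + .data$C) %>%
    dplyr::mutate(percentage = round_half_up(100 * .data$total / sum(.data$total), 2))
  class(out) <- c("interval_summary", class(out))
  out
}

#' Derived shares of an interval summary
#'
#' Headline percentages: the non-random share (unused + under + over), and
#' within-interval ending-nucleotide shares (e.g. the G-ending share of
#' unused codons). All values round half up to 2 decimals.
#'
#' @param summary An `interval_summary`.
#' @return A named list of percentages.
#' @export
interval_shares <- function(summary) {
  s <- as.data.frame(summary)
  rownames(s) <- as.character(s$cup_class)
  grand <- sum(s$total)
  pct <- function(x) round_half_up(100 * x, 2)
  list(
    nonrandom_pct = pct((grand - s["unbiased", "total"]) / grand),
    unused_pct = s["unused", "percentage"],
    under_pct = s["under", "percentage"],
    unbiased_pct = s["unbiased", "percentage"],
    over_pct = s["over", "percentage"],
    unused_g_ending_pct = pct(s["unused", "G"] / s["unused", "total"]),
    over_a_ending_pct = pct(s["over", "A"] / s["over", "total"]),
    unbiased_uc_ending_pct = pct((s["unbiased", "U"] + s["unbiased", "C"]) / s["unbiased", "total"])
  )
}

#' Codon aversion motif (CAM)
#'
#' The set of codons a gene never uses: RSCU = 0, including members of
#' wholly unobserved families by default (their usage count is zero).
#'
#' @param rscu_tbl An `rscu_tbl`.
#' @param include_absent Include unobserved-family members (default `TRUE`).
#' @return A tibble of (grouping columns, `codon`) rows, codon-table order.
#' @export
cam <- function(rscu_tbl, include_absent = TRUE) {
  keys <- intersect(names(rscu_tbl), c("record_id", "gene", "unit_id"))
  rscu_tbl %>%
    dplyr::filter(dplyr::coalesce(.data$rscu, 0) == 0,
                  include_absent | .data$family_observed) %>%
    dplyr::select(dplyr::all_of(keys), "codon") %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), match(.data$codon, codon_levels()))
}

#' @rdname cam
#' @return For `cam_matrix()`: a wide 0/1 tibble, one row per codon and one
#'   column per gene, 1 marking CAM membership.
#' @export
cam_matrix <- function(rscu_tbl, include_absent = TRUE) {
  members <- cam(rscu_tbl, include_absent)
  keys <- setdiff(names(members), "codon")
  if (length(keys) != 1L) stop("cam_matrix expects exactly one grouping column", call. = FALSE)
  units <- unique(rscu_tbl[[keys]])
  members %>%
    dplyr::mutate(member = 1L) %>%
    tidyr::complete(codon = codon_levels(),
                    !!rlang::sym(keys) := units,
                    fill = list(member = 0L)) %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(keys), values_from = "member") %>%
    dplyr::arrange(match(.data$codon, codon_levels()))
}

#' Published interval-by-ending codon classification counts
#'
#' A reference cross-classification of the 832 (gene, codon) pairs of a
#' 13-PCG cervid mitogenome survey into RSCU intervals by ending nucleotide,
#' shipped as a worked-example input for [interval_percentages()].
#'
#' @return A tibble with columns `cup_class`, `A`, `G`, `U`, `C`.
#' @export
reference_interval_counts <- function() {
  path <- system.file("extdata", "interval_counts_reference.tsv", package = "mitocub")
  out <- readr::read_tsv(path, col_types = "ciiii")
  out$cup_class <- factor(out$cup_class, levels = CUP_LEVELS)
  out
}
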