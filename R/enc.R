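#' GC content at third codon positions (GC3)
#'
#' Fraction of counted codons whose third nucleotide is G or C. Stop codons
#' are excluded by default: synonymity at the third position is undefined
#' for the stop pseudo-family. A `"synonymous-only"` variant restricts the
#' tally to codons of families with degeneracy > 1 (under the mitochondrial
#' code all sense codons qualify, so the default matches CodonW's GC3s).
#'
#' @param counts A `codon_counts` tibble.
#' @param code A [genetic_code()] object.
#' @param include_stops Count stop codons too (default `FALSE`).
#' @param synonymous_only Restrict to synonymous families of size > 1.
#' @return Tibble of grouping columns plus `gc3`.
#' @export
gc3 <- function(counts, code = genetic_code(), include_stops = FALSE,
                synonymous_only = FALSE) {
  keys <- count_keys(counts)
  keep <- if (include_stops) counts$codon else setdiff(counts$codon, code$stop_codons)
  if (synonymous_only) {
    syn <- code$families$codon[code$families$degeneracy > 1L]
    keep <- intersect(keep, c(syn, if (include_stops) code$stop_codons))
  }
  out <- counts %>%
    dplyr::filter(.data$codon %in% keep) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      gc3 = {
        tot <- sum(.data$count)
        if (tot == 0L) stop("gc3: no countable codons", call. = FALSE)
        sum(.data$count[third_nt(.data$codon) %in% c("G", "C")]) / tot
      },
      .groups = "drop"
    )
  out
}

#' Expected ENC under mutation pressure alone
#'
#' The ENC-plot standard curve:
#' \deqn{ENC = 2 + GC3 + 29 / [GC3^2 + (1 - GC3)^2].}
#' Genes whose codon usage is shaped only by mutation pressure at the third
#' position are expected to lie on this curve; points far below it indicate
#' selection on codon usage.
#'
#' @param gc3 Numeric vector of GC3 fractions in \[0, 1\].
#' @return Expected ENC values.
#' @export
expected_enc <- function(gc3) {
  if (any(gc3 < 0 | gc3 > 1, na.rm = TRUE)) {
    stop("gc3 must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' The ENC-plot standard curve on a GC3 grid
#'
#' @param step Grid spacing in (0, 0.5\]; the default 0.001 gives the
#'   conventional 1001-point curve on the inclusive grid \[0, 1\].
#' @return Tibble with columns `gc3`, `expected_enc`.
#' @export
enc_standard_curve <- function(step = 0.001) {
  stopifnot(step > 0, step <= 0.5)
  grid <- seq(0, 1, by = step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  tibble::tibble(gc3 = grid, expected_enc = expected_enc(grid))
}

# Wright's homozygosity per observed family with n >= 2:
#   F = (n * sum(p_j^2) - 1) / (n - 1)
family_F <- function(counts, code) {
  fam <- dplyr::select(code$families, "codon", "family", "degeneracy")
  counts %>%
    dplyr::inner_join(fam, by = "codon") %>%
    dplyr::group_by(.data$family, .data$degeneracy) %>%
    dplyr::summarise(
      n = sum(.data$count),
      F = if (sum(.data$count) >= 2L) {
        p <- .data$count / sum(.data$count)
        (sum(.data$count) * sum(p^2) - 1) / (sum(.data$count) - 1)
      } else NA_real_,
      .groups = "drop"
    )
}

# class counts for the standard-compat mode (Wright's formulation for the
# universal code: 2 single-codon amino acids, 9/1/5/3 families of size 2/3/4/6)
STANDARD_CLASSES <- c(`2` = 9L, `3` = 1L, `4` = 5L, `6` = 3L)
STANDARD_SINGLES <- 2L

#' Wright's effective number of codons (ENC)
#'
#' Per observed synonymous family with n >= 2 codons, the codon
#' homozygosity is estimated as F = (n \eqn{\sum p_j^2} - 1)/(n - 1); class
#' averages over families of equal degeneracy give
#' \deqn{ENC = n_{single} + \sum_s N_s / \bar F_s,}
#' with N_s the number of families of size s in the code. Two modes:
#'
#' * `"code-derived"` (default): class structure taken from the supplied
#'   code. For the vertebrate mitochondrial code (12 two-fold, 6 four-fold,
#'   2 six-fold families, no single-codon amino acids) the theoretical range
#'   is \[20, 60\].
#' * `"standard-compat"`: the universal-code formulation
#'   ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 applied to the observed class
#'   averages, mimicking codon-usage software whose printed range reaches
#'   61 regardless of the code.
#'
#' Families with F <= 0 or n < 2 are excluded from their class average. A
#' class with no estimable family is interpolated — the three-fold class as
#' (F2 + F4)/2, otherwise the mean of the observed class averages — and the
#' gene is flagged. Results are capped to the mode's theoretical range.
#'
#' @param counts A `codon_counts` tibble.
#' @param code A [genetic_code()] object.
#' @param mode `"code-derived"` or `"standard-compat"`.
#' @return Tibble of grouping columns plus `enc`, `gc3`, `mode`, `quality`
#'   (`"ok"`/`"interpolated"`) and a `family_F` list-column of per-family
#'   homozygosity tables.
#' @export
enc <- function(counts, code = genetic_code(),
                mode = c("code-derived", "standard-compat")) {
  mode <- match.arg(mode)
  keys <- count_keys(counts)
  g3 <- gc3(counts, code)
  nested <- tidyr::nest(counts, data = -dplyr::all_of(keys))
  res <- purrr::map(nested$data, function(d) enc_one(d, code, mode))
  out <- nested %>%
    dplyr::select(-"data") %>%
    dplyr::mutate(
      enc = purrr::map_dbl(res, "enc"),
      mode = mode,
      quality = purrr::map_chr(res, "quality"),
      family_F = purrr::map(res, "family_F")
    )
  if (length(keys)) out <- dplyr::left_join(out, g3, by = keys) else out$gc3 <- g3$gc3
  dplyr::relocate(out, "gc3", .after = "enc")
}

enc_one <- function(counts, code, mode) {
  ff <- family_F(counts, code)
  est <- ff %>%
    dplyr::filter(!is.na(.data$F), .data$F > 0) %>%
    dplyr::group_by(.data$degeneracy) %>%
    dplyr::summarise(F_bar = mean(.data$F), n_fam = dplyr::n(), .groups = "drop")
  if (nrow(est) == 0L) stop("enc: no estimable synonymous family", call. = FALSE)
  F_bar <- setNames(est$F_bar, est$degeneracy)

  if (mode == "code-derived") {
    classes <- family_class_counts(code)
    classes <- classes[names(classes) != "1"]
    singles <- sum(code$families$degeneracy == 1L)
  } else {
    classes <- STANDARD_CLASSES
    singles <- STANDARD_SINGLES
  }

  quality <- "ok"
  need <- names(classes)
  for (s in need) {
    if (!s %in% names(F_bar)) {
      quality <- "interpolated"
      F_bar[[s]] <- if (s == "3" && all(c("2", "4") %in% names(F_bar))) {
        (F_bar[["2"]] + F_bar[["4"]]) / 2
      } else {
        mean(F_bar[names(F_bar) %in% need])
      }
    }
  }
  enc_val <- singles + sum(classes / F_bar[need])
  max_enc <- singles + sum(classes * as.integer(need))
  list(enc = min(max(enc_val, 20), max_enc), quality = quality, family_F = ff)
}

#' ENC-plot coordinates
#'
#' Per gene, (x = GC3, y = ENC) together with the expected ENC at that GC3
#' and a below-curve flag (`enc < expected_enc(gc3) - margin`). The standard
#' curve is attached as attribute `"curve"` for plotting.
#'
#' @inheritParams enc
#' @param margin Tolerance below the curve before a gene is flagged
#'   (default 0).
#' @param curve_step Grid spacing of the attached standard curve.
#' @return A tibble of class `enc_points`.
#' @export
enc_plot_points <- function(counts, code = genetic_code(),
                            mode = c("code-derived", "standard-compat"),
                            margin = 0, curve_step = 0.001) {
  out <- enc(counts, code, mode) %>%
    dplyr::mutate(
      expected = expected_enc(.data$gc3),
      below_curve = .data$enc < .data$expected - margin
    ) %>%
    dplyr::select(-"family_F")
  attr(out, "curve") <- enc_standard_curve(curve_step)
  class(out) <- c("enc_points", class(out))
  out
}
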