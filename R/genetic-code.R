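CODE_ALIASES <- c(
  "vertebrate-mito" = "2", "vertebrate mitochondrial" = "2", "2" = "2",
  "standard" = "1", "1" = "1"
)

#' Load a genetic code with derived synonymous-family structure
#'
#' Builds the single source of truth for codon degeneracy used by every
#' downstream statistic: the codon-to-amino-acid map, the partition of sense
#' codons into synonymous families, the four-fold degenerate codon set, and
#' the stop and initiation codon sets. The vertebrate mitochondrial code
#' (NCBI translation table 2) is the default: 60 sense codons, 4 stop codons
#' (UAA, UAG, AGA, AGG), AUA read as Met and UGA as Trp, giving 12 two-fold,
#' 6 four-fold and 2 six-fold families.
#'
#' @param name Code identifier: `"vertebrate-mito"` (alias `"2"`) or
#'   `"standard"` (alias `"1"`).
#' @param split_sixfold If `TRUE`, six-fold families (Leu, Ser) are split at
#'   the first two codon positions into a four-fold and a two-fold
#'   sub-family, the convention of some codon-usage software. Default
#'   `FALSE`: families follow the code strictly.
#' @return An object of class `genetic_code`: a list with elements `name`,
#'   `table_id`, `codons` (all 64, codon-table order), `aa` (named map,
#'   `"*"` for stop), `stop_codons`, `sense_codons`, `start_codons`,
#'   `families` (tibble: codon, amino_acid, family, degeneracy) and
#'   `degeneracy` (named integer per sense codon).
#' @examples
#' code <- genetic_code("vertebrate-mito")
#' code$aa[["AUA"]] # "M"
#' fourfold_codons(code)
#' @export
genetic_code <- function(name = "vertebrate-mito", split_sixfold = FALSE) {
  key <- tolower(name)
  if (!key %in% names(CODE_ALIASES)) {
    stop("Unknown genetic code '", name, "'. Supported: ",
         paste(sort(unique(names(CODE_ALIASES))), collapse = ", "), call. = FALSE)
  }
  id <- CODE_ALIASES[[key]]
  tab <- Biostrings::getGeneticCode(id)
  codons <- as_rna(names(tab))
  aa <- setNames(as.character(tab), codons)
  ord <- codon_levels()
  aa <- aa[ord]

  stops <- names(aa)[aa == "*"]
  sense <- names(aa)[aa != "*"]

  fam_key <- if (split_sixfold) {
    # split six-fold families by their first two positions
    ifelse(aa[sense] %in% names(which(table(aa[sense]) == 6)),
           paste0(aa[sense], "-", substr(sense, 1, 2)), aa[sense])
  } else {
    aa[sense]
  }
  families <- tibble::tibble(codon = sense, amino_acid = unname(aa[sense]),
                             family = unname(fam_key)) %>%
    dplyr::group_by(.data$family) %>%
    dplyr::mutate(degeneracy = dplyr::n()) %>%
    dplyr::ungroup()

  alt_init <- as_rna(attr(tab, "alt_init_codons") %||% character())
  met <- names(aa)[aa == "M"]
  start_codons <- sort(unique(c("AUG", alt_init, met)))

  structure(list(
    name = name,
    table_id = id,
    split_sixfold = split_sixfold,
    codons = ord,
    aa = aa,
    stop_codons = stops,
    sense_codons = sense,
    start_codons = start_codons,
    families = families,
    degeneracy = setNames(families$degeneracy, families$codon)
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cls <- table(tapply(x$families$degeneracy, x$families$family, unique))
  cat("<genetic_code> ", x$name, " (NCBI table ", x$table_id, ")\n", sep = "")
  cat("  sense codons: ", length(x$sense_codons),
      "; stop codons: ", paste(x$stop_codons, collapse = " "), "\n", sep = "")
  cat("  families: ",
      paste(sprintf("%s-fold x %d", names(cls), cls), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Four-fold degenerate codons of a genetic code
#'
#' Codons belonging to synonymous families of degeneracy exactly 4. Under the
#' vertebrate mitochondrial code these are the 24 codons of Ala, Arg, Gly,
#' Pro, Thr and Val; six-fold families (Leu, Ser) are excluded even though
#' their third position is also free.
#'
#' @param code A [genetic_code()] object.
#' @return Character vector of codons, codon-table order.
#' @export
fourfold_codons <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  fam <- code$families
  out <- fam$codon[fam$degeneracy == 4L]
  out[order(match(out, code$codons))]
}

#' Synonymous family containing a codon
#'
#' @param code A [genetic_code()] object.
#' @param codon A single sense codon (RNA or DNA alphabet).
#' @return A list with `amino_acid`, `codons` (codon-table order) and
#'   `degeneracy`. Stop codons are refused: they form their own pseudo-family
#'   used only for RSCU (see [rscu()]).
#' @export
codon_family <- function(code, codon) {
  stopifnot(inherits(code, "genetic_code"), length(codon) == 1L)
  codon <- as_rna(codon)
  if (!codon %in% code$codons) stop("'", codon, "' is not a codon", call. = FALSE)
  if (codon %in% code$stop_codons) {
    stop("'", codon, "' is a stop codon: stop codons form their own pseudo-family ",
         "(used only for RSCU), not a synonymous family", call. = FALSE)
  }
  fam <- code$families
  key <- fam$family[fam$codon == codon]
  members <- fam$codon[fam$family == key]
  list(
    amino_acid = fam$amino_acid[fam$codon == codon],
    codons = members[order(match(members, code$codons))],
    degeneracy = length(members)
  )
}

#' Export a genetic code table as JSON
#'
#' @param code A [genetic_code()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_code_json <- function(code, path) {
  stopifnot(inherits(code, "genetic_code"))
  jsonlite::write_json(
    list(name = code$name, table_id = code$table_id,
         codon_to_aa = as.list(code$aa),
         start_codons = code$start_codons,
         stop_codons = code$stop_codons),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

# family sizes + counts per degeneracy class, e.g. c(`2` = 12, `4` = 6, `6` = 2)
family_class_counts <- function(code) {
  fam <- dplyr::distinct(code$families, .data$family, .data$degeneracy)
  tab <- table(fam$degeneracy)
  setNames(as.integer(tab), names(tab))
}
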