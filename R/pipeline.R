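#' Validate pipeline inputs
#'
#' Dry-run diagnostics on a CDS table: per-record gene coverage against the
#' 13 canonical PCGs, CDS lengths that are not a multiple of 3 despite a
#' complete annotated stop, ambiguity content, and internal stop codons
#' (error-level, named by gene). Diagnostics only; nothing aborts.
#'
#' @param cds A CDS tibble.
#' @param code A [genetic_code()] object.
#' @return A tibble with columns `level` (`"info"`/`"warning"`/`"error"`),
#'   `record_id`, `gene`, `message`.
#' @export
validate_inputs <- function(cds, code = genetic_code()) {
  diags <- list()
  add <- function(level, record_id, gene, message) {
    diags[[length(diags) + 1L]] <<-
      tibble::tibble(level = level, record_id = record_id, gene = gene, message = message)
  }
  for (id in unique(cds$record_id)) {
    missing <- setdiff(PCG_ORDER, cds$gene[cds$record_id == id])
    for (g in missing) add("warning", id, g, "gene missing from record")
  }
  for (i in seq_len(nrow(cds))) {
    row <- cds[i, ]
    if (row$length %% 3L != 0L && row$complete_stop) {
      add("warning", row$record_id, row$gene,
          "CDS length not a multiple of 3 despite complete stop")
    }
    n_amb <- nchar(gsub("[ACGU]", "", row$seq))
    if (n_amb > 0L) {
      add("info", row$record_id, row$gene,
          paste0(n_amb, " ambiguous base(s); affected codons will be dropped"))
    }
    res <- tryCatch(codonize(row, code), error = function(e) conditionMessage(e))
    if (is.character(res)) add("error", row$record_id, row$gene, res)
  }
  if (length(diags) == 0L) {
    return(tibble::tibble(level = character(), record_id = character(),
                          gene = character(), message = character()))
  }
  dplyr::bind_rows(diags)
}

#' Run the full mitochondrial PCG characterization pipeline
#'
#' Reads annotated mitogenomes, extracts mRNA-sense CDS and emits the
#' complete analysis bundle as deterministic TSV/Newick/JSON files:
#' genome-level and per-gene composition, skewness-plot points, per-gene
#' mean RSCU matrix, CAM membership matrix, the RSCU-interval summary, ENC
#' table with the standard curve, PR2 table, the RSCU dendrogram, and a JSON
#' manifest (package version, configuration, input checksums, run id). The
#' bundle is a pure function of (inputs, configuration).
#'
#' @param input Path to a GenBank flat file or FASTA genome file, or a CDS
#'   tibble (e.g. from [simulate_mitogenomes()]).
#' @param out_dir Output directory (created if needed).
#' @param format `"auto"` (by file extension), `"genbank"` or `"fasta"`.
#' @param coords Coordinate TSV path (required for FASTA input).
#' @param code_name Genetic code identifier (see [genetic_code()]).
#' @param stop_policy Passed to [codonize()].
#' @param enc_mode Passed to [enc()].
#' @param distance,linkage,k Passed to [cluster_rscu()].
#' @return Invisibly, a named list of output paths plus the manifest.
#' @export
run_pipeline <- function(input, out_dir, format = c("auto", "genbank", "fasta"),
                         coords = NULL, code_name = "vertebrate-mito",
                         stop_policy = "drop-partial",
                         enc_mode = "code-derived",
                         distance = "euclidean", linkage = "average", k = NULL) {
  format <- match.arg(format)
  code <- genetic_code(code_name)

  checksums <- character()
  if (is.character(input)) {
    if (format == "auto") {
      format <- if (grepl("\\.(gb|gbk|genbank)$", input, ignore.case = TRUE)) "genbank" else "fasta"
    }
    checksums <- unname(tools::md5sum(c(input, coords)))
    cds <- if (format == "genbank") {
      read_genbank(input, code)
    } else {
      if (is.null(coords)) stop("FASTA input requires a coordinate table", call. = FALSE)
      read_fasta_cds(input, coords, code = code)
    }
  } else {
    cds <- input
  }

  config <- list(code = code_name, stop_policy = stop_policy,
                 enc_mode = enc_mode, distance = distance, linkage = linkage,
                 k = k, package_version = as.character(utils::packageVersion("mitocub")))
  run_id <- substr(digest_chr(c(unlist(config), checksums,
                                cds$record_id, cds$gene, cds$seq)), 1, 12)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(out_dir, name)
  paths <- list()

  if (!is.null(attr(cds, "genomes"))) {
    paths$genome_composition <- write_result(genome_composition(cds),
                                             p("genome_composition.tsv"), run_id)
  }
  paths$gene_composition <- write_result(composition(cds), p("gene_composition.tsv"), run_id)
  paths$skew_points <- write_result(skew_points(cds), p("skew_points.tsv"), run_id)

  counts <- count_codons(cds, code, stop_policy)
  per_gene_rscu <- rscu(counts, code)
  mean_tbl <- mean_rscu(per_gene_rscu)
  paths$mean_rscu <- write_result(
    tidyr::pivot_wider(
      dplyr::select(mean_tbl, "gene", "codon", "rscu"),
      names_from = "gene", values_from = "rscu"
    ),
    p("mean_rscu.tsv"), run_id
  )
  paths$cam <- write_result(cam_matrix(mean_tbl), p("cam_matrix.tsv"), run_id)
  paths$interval_summary <- write_result(interval_summary(mean_tbl),
                                         p("interval_summary.tsv"), run_id)

  pooled <- pool_counts(counts, "gene")
  enc_pts <- enc_plot_points(pooled, code, enc_mode)
  paths$enc <- write_result(enc_pts, p("enc.tsv"), run_id)
  paths$enc_curve <- write_result(attr(enc_pts, "curve"), p("enc_curve.tsv"), run_id)
  paths$pr2 <- write_result(pr2_points(cds, code, stop_policy = stop_policy),
                            p("pr2.tsv"), run_id)

  clust <- cluster_rscu(mean_tbl, k = k, distance = distance, linkage = linkage)
  paths$dendrogram <- write_newick(clust, p("rscu_dendrogram.nwk"))

  manifest <- list(run_id = run_id, config = config,
                   inputs = if (length(checksums)) checksums else "in-memory",
                   n_records = length(unique(cds$record_id)),
                   n_genes = length(unique(cds$gene)),
                   outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- p("manifest.json")

  invisible(c(paths, list(run_id = run_id, manifest = manifest)))
}

# dependency-free content hash (md5 over a serialized character vector)
digest_chr <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}
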