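GENE_SYNONYMS <- c(
  NAD1 = "ND1", NAD2 = "ND2", NAD3 = "ND3", NAD4 = "ND4", NAD4L = "ND4L",
  NAD5 = "ND5", NAD6 = "ND6", NADH1 = "ND1", NADH2 = "ND2", NADH3 = "ND3",
  NADH4 = "ND4", NADH4L = "ND4L", NADH5 = "ND5", NADH6 = "ND6",
  COB = "CYTB", CYB = "CYTB", CYTB = "CYTB", MTCYB = "CYTB",
  COI = "COX1", COII = "COX2", COIII = "COX3",
  CO1 = "COX1", CO2 = "COX2", CO3 = "COX3",
  COX1 = "COX1", COX2 = "COX2", COX3 = "COX3",
  ATPASE6 = "ATP6", ATPASE8 = "ATP8", ATP6 = "ATP6", ATP8 = "ATP8",
  ND1 = "ND1", ND2 = "ND2", ND3 = "ND3", ND4 = "ND4", ND4L = "ND4L",
  ND5 = "ND5", ND6 = "ND6"
)

#' Normalize mitochondrial gene symbols
#'
#' Maps common annotation synonyms (`NAD1`, `COB`, `COI`, ...) onto the 13
#' canonical PCG symbols. Unrecognized symbols are returned upper-cased,
#' unchanged. The mapping is idempotent.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_gene_symbol <- function(x) {
  key <- gsub("[ _-]", "", toupper(x))
  out <- unname(GENE_SYNONYMS[key])
  ifelse(is.na(out), key, out)
}

# Build the per-gene CDS tibble from mRNA-sense sequences.
new_cds_tbl <- function(record_id, gene, strand, seq, code = genetic_code()) {
  seq <- as_rna(seq)
  len <- nchar(seq)
  tail_len <- len %% 3L
  last_codon <- ifelse(len >= 3L & tail_len == 0L, substr(seq, len - 2L, len), NA_character_)
  complete <- !is.na(last_codon) & last_codon %in% code$stop_codons
  stop_str <- ifelse(complete, last_codon,
                     ifelse(tail_len > 0L, substr(seq, len - tail_len + 1L, len), last_codon))
  tibble::tibble(
    record_id = record_id,
    gene = normalize_gene_symbol(gene),
    strand = strand,
    length = len,
    start_codon = substr(seq, 1L, 3L),
    stop_codon = stop_str,
    complete_stop = complete,
    seq = seq
  )
}

parse_gb_location <- function(loc) {
  comp <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|^join\\(|\\)+$", "", loc)
  inner <- gsub("^complement\\(|^join\\(", "", inner) # nested complement(join(...))
  parts <- strsplit(inner, ",")[[1]]
  m <- regmatches(parts, regexec("[<>]?(\\d+)\\.\\.[<>]?(\\d+)", parts))
  ranges <- do.call(rbind, lapply(m, function(g) as.integer(g[2:3])))
  if (is.null(ranges)) return(NULL)
  list(complement = comp, start = ranges[, 1], end = ranges[, 2])
}

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses one or more LOCUS records, extracts CDS features, normalizes gene
#' symbols via a synonym table, and returns every CDS in mRNA sense:
#' minus-strand features (e.g. ND6) are reverse-complemented on load.
#' `complement()` and simple `join()` locations are supported. CDS features
#' whose gene symbol cannot be resolved from `/gene` or `/product` are
#' skipped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @param code Genetic code used to judge stop-codon completeness.
#' @return A tibble with one row per CDS (`record_id`, `gene`, `strand`,
#'   `length`, `start_codon`, `stop_codon`, `complete_stop`, `seq`), with the
#'   per-record genome table (id, length, full sequence) in attribute
#'   `"genomes"`.
#' @export
read_genbank <- function(path, code = genetic_code()) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) stop("No LOCUS records found in ", path, call. = FALSE)
  bounds <- c(locus_idx, length(lines) + 1L)

  cds_rows <- list()
  genome_rows <- list()
  for (i in seq_along(locus_idx)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    acc_line <- grep("^(VERSION|ACCESSION)", block, value = TRUE)
    id <- if (length(acc_line)) strsplit(trimws(sub("^\\S+", "", acc_line[1])), "\\s+")[[1]][1]
          else strsplit(block[1], "\\s+")[[1]][2]

    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0L) stop("Record ", id, " has no ORIGIN section", call. = FALSE)
    seq_lines <- block[(ori[1] + 1L):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    full <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    full <- as_rna(full)
    genome_rows[[i]] <- tibble::tibble(record_id = id, length = nchar(full), seq = full)

    feat_start <- grep("^FEATURES", block)
    if (length(feat_start) == 0L) next
    feats <- block[(feat_start[1] + 1L):(ori[1] - 1L)]
    key_idx <- grep("^ {5}\\S", feats)
    key_bounds <- c(key_idx, length(feats) + 1L)
    for (j in seq_along(key_idx)) {
      fl <- feats[key_idx[j]]
      key <- sub("^ +(\\S+).*", "\\1", fl)
      if (key != "CDS") next
      body <- feats[key_idx[j]:(key_bounds[j + 1L] - 1L)]
      # location may wrap onto continuation lines before the first qualifier
      qual_start <- grep("^ +/", body)
      loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(body)
      loc <- gsub("\\s", "", paste(c(sub("^ +CDS +", "", body[1]),
                                     trimws(body[seq_len(loc_end)][-1])), collapse = ""))
      parsed <- parse_gb_location(loc)
      if (is.null(parsed)) next
      quals <- paste(body, collapse = " ")
      gene <- stringr::str_match(quals, '/gene="([^"]+)"')[, 2]
      if (is.na(gene)) gene <- stringr::str_match(quals, '/product="([^"]+)"')[, 2]
      if (is.na(gene)) {
        warning("Skipping CDS at ", loc, " in record ", id,
                ": no /gene or /product qualifier", call. = FALSE)
        next
      }
      pieces <- substring(full, parsed$start, parsed$end)
      cds_seq <- paste(pieces, collapse = "")
      strand <- "+"
      if (parsed$complement) {
        cds_seq <- revcomp(cds_seq)
        strand <- "-"
      }
      cds_rows[[length(cds_rows) + 1L]] <-
        new_cds_tbl(id, gene, strand, cds_seq, code)
    }
  }
  out <- dplyr::bind_rows(cds_rows)
  genomes <- dplyr::bind_rows(genome_rows)
  validate_record_genes(out)
  attr(out, "genomes") <- genomes
  class(out) <- c("cds_tbl", class(out))
  out
}

validate_record_genes <- function(cds) {
  if (nrow(cds) == 0L) return(invisible(cds))
  dup <- cds %>% dplyr::count(.data$record_id, .data$gene) %>% dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("Duplicate gene symbols within a record: ",
         paste(unique(dup$gene), collapse = ", "), call. = FALSE)
  }
  n_genes <- cds %>% dplyr::count(.data$record_id)
  low <- n_genes$record_id[n_genes$n < 13L]
  if (length(low)) {
    warning("Records with fewer than 13 protein-coding genes: ",
            paste(utils::head(low, 5), collapse = ", "), call. = FALSE)
  }
  invisible(cds)
}

#' Read CDS from a FASTA genome plus a gene-coordinate table
#'
#' @param fasta Path to a FASTA file of genome sequences.
#' @param coords Path to a TSV with columns `gene`, `start`, `end`, `strand`
#'   and optionally `record_id` (absent: coordinates apply to every FASTA
#'   record). Coordinates are 1-based inclusive by default.
#' @param coord_style `"1-based"` (inclusive, GenBank convention, default) or
#'   `"0-based"` (half-open).
#' @param code Genetic code used to judge stop-codon completeness.
#' @return Same shape as [read_genbank()].
#' @export
read_fasta_cds <- function(fasta, coords, coord_style = c("1-based", "0-based"),
                           code = genetic_code()) {
  coord_style <- match.arg(coord_style)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  genomes <- tibble::tibble(record_id = ids, length = Biostrings::width(seqs),
                            seq = unname(as_rna(as.character(seqs))))
  tab <- readr::read_tsv(coords, show_col_types = FALSE, comment = "#")
  req <- c("gene", "start", "end", "strand")
  if (!all(req %in% names(tab))) {
    stop("Coordinate table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"record_id" %in% names(tab)) {
    tab <- tidyr::crossing(record_id = genomes$record_id, tab)
  }
  out <- purrr::pmap(tab, function(record_id, gene, start, end, strand, ...) {
    g <- genomes[genomes$record_id == record_id, ]
    if (nrow(g) == 0L) stop("Coordinate row refers to unknown record '", record_id, "'", call. = FALSE)
    z <- to_zero_based(start, end, coord_style)
    if (z$start < 0L || z$end > g$length || z$end <= z$start) {
      stop("Out-of-range or empty coordinates for gene ", gene, " in ", record_id,
           " (", start, "..", end, " on a ", g$length, " bp genome)", call. = FALSE)
    }
    s <- substr(g$seq, z$start + 1L, z$end)
    if (strand == "-") s <- revcomp(s)
    new_cds_tbl(record_id, gene, strand, s, code)
  }) %>% dplyr::bind_rows()
  validate_record_genes(out)
  attr(out, "genomes") <- genomes
  class(out) <- c("cds_tbl", class(out))
  out
}

#' Split coding sequences into codons
#'
#' Splits each CDS into consecutive triplets from position 1. A trailing 1-2
#' nt partial stop codon (post-transcriptionally polyadenylated in the
#' transcript, e.g. ND4's "T--") is excluded under the default
#' `"drop-partial"` policy, or completed with A's to a stop codon and
#' included under `"polyadenylate"`. Codons containing ambiguity codes are
#' dropped with a tallied message. An internal stop codon before the final
#' position is an annotation error and aborts.
#'
#' @param cds A CDS tibble from [read_genbank()], [read_fasta_cds()] or
#'   [simulate_mitogenomes()].
#' @param code A [genetic_code()] object.
#' @param stop_policy `"drop-partial"` (default) or `"polyadenylate"`.
#' @return A tibble with columns `record_id`, `gene`, `codon_index`, `codon`.
#' @export
codonize <- function(cds, code = genetic_code(),
                     stop_policy = c("drop-partial", "polyadenylate")) {
  stop_policy <- match.arg(stop_policy)
  n_ambig <- 0L
  rows <- purrr::pmap(
    list(cds$record_id, cds$gene, cds$seq),
    function(record_id, gene, seq) {
      len <- nchar(seq)
      if (len < 6L) stop("CDS for gene ", gene, " is shorter than 6 nt", call. = FALSE)
      n_full <- len %/% 3L
      tail_len <- len %% 3L
      starts <- seq(1L, by = 3L, length.out = n_full)
      codons <- substring(seq, starts, starts + 2L)
      if (tail_len > 0L && stop_policy == "polyadenylate") {
        padded <- paste0(substr(seq, len - tail_len + 1L, len),
                         strrep("A", 3L - tail_len))
        if (padded %in% code$stop_codons) {
          codons <- c(codons, padded)
        } else {
          warning("Polyadenylated tail of gene ", gene, " ('", padded,
                  "') is not a stop codon; tail dropped", call. = FALSE)
        }
      }
      internal <- which(codons %in% code$stop_codons)
      internal <- internal[internal < length(codons)]
      if (length(internal)) {
        stop("Internal stop codon in gene ", gene, " (record ", record_id,
             ") at codon ", internal[1],
             ": likely misannotation", call. = FALSE)
      }
      keep <- grepl("^[ACGU]{3}$", codons)
      n_ambig <<- n_ambig + sum(!keep)
      tibble::tibble(record_id = record_id, gene = gene,
                     codon_index = seq_along(codons)[keep], codon = codons[keep])
    }
  )
  if (n_ambig > 0L) {
    rlang::inform(paste0("codonize: dropped ", n_ambig, " codon(s) containing ambiguity codes"))
  }
  dplyr::bind_rows(rows)
}

#' Write a result table as TSV with deterministic row order
#'
#' Rows are ordered by gene (canonical genome order first, others
#' alphabetical) and codon (codon-table order) where those columns exist. An
#' optional run identifier is carried as a leading `#` comment line, which
#' [read_result()] skips.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param run_id Optional run identifier written as a comment header.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, run_id = NULL) {
  x <- dplyr::as_tibble(x)
  ord <- list()
  if ("gene" %in% names(x)) {
    ord <- c(ord, list(match(x$gene, c(PCG_ORDER, sort(setdiff(unique(x$gene), PCG_ORDER))))))
  }
  if ("record_id" %in% names(x)) ord <- c(ord, list(x$record_id))
  if ("codon" %in% names(x)) ord <- c(ord, list(match(x$codon, codon_levels())))
  if (length(ord)) x <- x[do.call(order, ord), , drop = FALSE]
  if (!is.null(run_id)) {
    writeLines(paste0("# run_id: ", run_id), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
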