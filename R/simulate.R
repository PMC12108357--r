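# Canonical gene plan: the 13 vertebrate mitochondrial PCGs with typical
# cervid lengths, strands, start/stop codons; ND6 minus-strand, ND4 with an
# incomplete stop (single U, polyadenylated in the transcript). COX1 is set
# to 513 codons (1539 bp).
default_gene_plan <- function() {
  tibble::tribble(
    ~gene,  ~length_bp, ~strand, ~start_codon, ~stop_codon,
    "ND1",    957L, "+", "AUG", "UAA",
    "ND2",   1044L, "+", "AUA", "UAG",
    "COX1",  1539L, "+", "AUG", "UAA",
    "COX2",   684L, "+", "AUG", "UAA",
    "ATP8",   201L, "+", "AUG", "UAA",
    "ATP6",   681L, "+", "AUG", "UAA",
    "COX3",   804L, "+", "AUG", "UAG",
    "ND3",    357L, "+", "AUA", "UAG",
    "ND4L",   297L, "+", "AUG", "UAA",
    "ND4",   1378L, "+", "AUG", "U",
    "ND5",   1821L, "+", "AUA", "UAA",
    "ND6",    528L, "-", "AUG", "UAA",
    "CYTB",  1140L, "+", "AUG", "AGA"
  )
}

# Mammalian-mitochondrial-like amino-acid frequencies (hydrophobic-rich:
# membrane subunits of the OXPHOS complexes); normalized on use.
MITO_AA_FREQS <- c(
  L = 0.155, I = 0.090, T = 0.085, A = 0.070, S = 0.070, F = 0.060,
  M = 0.055, G = 0.055, N = 0.050, P = 0.050, V = 0.050, Y = 0.035,
  W = 0.030, K = 0.030, H = 0.025, Q = 0.025, E = 0.025, D = 0.020,
  R = 0.020, C = 0.010
)

# Third-position base preference of the plus (heavy) strand under the
# A/C-rich regime typical of mammalian mitogenomes.
AC_RICH_WEIGHTS <- c(A = 0.45, C = 0.32, U = 0.15, G = 0.08)

complement_weights <- function(w) {
  setNames(unname(w[c("U", "G", "A", "C")]), c("A", "C", "U", "G"))
}

#' Build a synthetic mitogenome generator specification
#'
#' Resolves a preset into a fully reproducible generator spec: a per-gene
#' codon-probability vector over the sense codons (amino-acid marginals from
#' a fixed composition plan, within-family weights drawn from a Dirichlet
#' distribution whose concentration `alpha` controls bias strength), a gene
#' plan (13 PCGs with canonical lengths, ND6 on the minus strand, ND4 with
#' an incomplete stop), a population size and a per-site substitution rate.
#'
#' Presets:
#' * `"kansuensis-like"`: AT-rich, A/C-preferring third positions on the
#'   plus strand (complemented for minus-strand genes), emulating the
#'   composition regime of cervid mitogenomes.
#' * `"neutral"`: uniform within-family probabilities (strand-symmetric; no
#'   Dirichlet noise).
#' * `"extreme-bias"`: probability 1 on a single codon per family.
#'
#' @param preset One of `"kansuensis-like"`, `"neutral"`, `"extreme-bias"`.
#' @param seed Integer seed; the spec is a pure function of
#'   `(preset, seed, overrides)`.
#' @param overrides Named list overriding `n_individuals` (default 89), `mu`
#'   (per-site substitution rate, default 0.001, must lie in \[0, 0.05\]),
#'   `alpha` (Dirichlet concentration, default 12), `gene_plan`,
#'   `third_weights`, `aa_freqs`, `messy` (allow nonsynonymous divergence,
#'   default `FALSE`).
#' @param code A [genetic_code()] object.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(preset = c("kansuensis-like", "neutral", "extreme-bias"),
                     seed = 1L, overrides = list(), code = genetic_code()) {
  preset <- match.arg(preset)
  opts <- list(
    n_individuals = 89L,
    mu = 0.001,
    alpha = 12,
    gene_plan = default_gene_plan(),
    third_weights = AC_RICH_WEIGHTS,
    aa_freqs = MITO_AA_FREQS,
    messy = FALSE
  )
  unknown <- setdiff(names(overrides), names(opts))
  if (length(unknown)) {
    stop("Unknown override(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  opts[names(overrides)] <- overrides
  stopifnot(opts$mu >= 0, opts$mu <= 0.05,
            all(opts$gene_plan$length_bp >= 6L))
  aa_freqs <- opts$aa_freqs / sum(opts$aa_freqs)

  fams <- split(code$families$codon, code$families$family)
  set.seed(as.integer(seed))
  codon_probs <- purrr::pmap(
    opts$gene_plan[, c("gene", "strand")],
    function(gene, strand) {
      w3 <- if (strand == "-") complement_weights(opts$third_weights) else opts$third_weights
      p <- unlist(lapply(names(fams), function(f) {
        members <- fams[[f]]
        aa <- code$aa[[members[1]]]
        within <- switch(preset,
          "neutral" = rep(1 / length(members), length(members)),
          "extreme-bias" = {
            v <- numeric(length(members)); v[1] <- 1; v
          },
          "kansuensis-like" = {
            base <- w3[third_nt(members)]
            base <- base / sum(base)
            g <- stats::rgamma(length(members), shape = opts$alpha * base)
            if (sum(g) == 0) base else g / sum(g)
          }
        )
        setNames(aa_freqs[[aa]] * within, members)
      }))
      p[code$sense_codons] / sum(p)
    }
  )
  names(codon_probs) <- opts$gene_plan$gene

  structure(c(list(preset = preset, seed = as.integer(seed),
                   code_name = code$name, codon_probs = codon_probs),
              opts[c("n_individuals", "mu", "alpha", "gene_plan",
                     "third_weights", "messy")]),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec> preset '", x$preset, "', seed ", x$seed, "\n", sep = "")
  cat("  ", nrow(x$gene_plan), " genes, ", x$n_individuals,
      " individuals, mu = ", x$mu, ", alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

# expected RSCU implied by a codon-probability vector
probs_to_rscu <- function(p, code) {
  fam <- code$families
  tibble::tibble(codon = names(p), p = unname(p)) %>%
    dplyr::inner_join(fam, by = "codon") %>%
    dplyr::group_by(.data$family) %>%
    dplyr::mutate(rscu = .data$degeneracy * .data$p / sum(.data$p)) %>%
    dplyr::ungroup() %>%
    dplyr::select("codon", "rscu")
}

#' Generate a synthetic mitogenome population
#'
#' Draws one ancestral mitogenome from the spec's per-gene codon
#' probabilities (codons i.i.d.; start/stop codons fixed by the gene plan;
#' ND4 carries its 1 nt partial stop), then derives each individual by
#' Poisson(mu x gene length) substitutions at randomly chosen internal
#' codons — synonymous by default (resampled within the codon's family), or
#' unconstrained under the spec's `messy` flag. Minus-strand genes are
#' stored mRNA-sense in the CDS table and reverse-complemented in the
#' assembled genome. Fully deterministic given the spec.
#'
#' @param spec A [sim_spec()] object.
#' @return A CDS tibble (class `cds_tbl`) of all individuals, with
#'   attributes `"genomes"` (assembled genome per record), `"coords"`
#'   (1-based inclusive gene coordinates) and `"truth"` (generator truth:
#'   `codon_probs`, distributional `expected_rscu` and `expected_gc3` per
#'   gene, realized `ancestral_rscu` and `ancestral_counts`, and the spec).
#' @export
simulate_mitogenomes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  code <- genetic_code(spec$code_name)
  set.seed(spec$seed + 1L)
  plan <- spec$gene_plan

  ancestor <- purrr::pmap(plan, function(gene, length_bp, strand, start_codon, stop_codon, ...) {
    n_codons <- length_bp %/% 3L
    tail_nt <- if (nchar(stop_codon) < 3L) stop_codon else ""
    has_stop <- nchar(stop_codon) == 3L
    n_internal <- n_codons - 1L - as.integer(has_stop)
    p <- spec$codon_probs[[gene]]
    internal <- sample(names(p), n_internal, replace = TRUE, prob = p)
    list(gene = gene, strand = strand,
         codons = c(start_codon, internal, if (has_stop) stop_codon),
         tail = tail_nt, n_internal = n_internal, has_stop = has_stop)
  })
  names(ancestor) <- plan$gene

  fam_of <- setNames(code$families$family, code$families$codon)
  fams <- split(code$families$codon, code$families$family)

  ids <- sprintf("SYN%03d", seq_len(spec$n_individuals))
  records <- purrr::map(ids, function(id) {
    genes <- purrr::map(ancestor, function(g) {
      codons <- g$codons
      n_sub <- stats::rpois(1L, spec$mu * (g$n_internal * 3L))
      n_sub <- min(n_sub, g$n_internal)
      if (n_sub > 0L) {
        pos <- 1L + sample.int(g$n_internal, n_sub)
        p <- spec$codon_probs[[g$gene]]
        for (i in pos) {
          if (spec$messy) {
            codons[i] <- sample(names(p), 1L, prob = p)
          } else {
            members <- fams[[fam_of[[codons[i]]]]]
            pm <- p[members]
            codons[i] <- sample(members, 1L, prob = pm / sum(pm))
          }
        }
      }
      paste0(paste(codons, collapse = ""), g$tail)
    })
    tibble::tibble(record_id = id, gene = plan$gene, strand = plan$strand,
                   seq = unname(unlist(genes)))
  })

  spacer <- "AAUCCUAAUGGCAUCAAUUCAUCGAAUCCA" # fixed 30 nt intergenic filler
  genome_rows <- list(); coord_rows <- list(); cds_rows <- list()
  for (r in records) {
    pos <- nchar(spacer)
    segs <- spacer
    starts <- integer(nrow(r)); ends <- integer(nrow(r))
    for (i in seq_len(nrow(r))) {
      s <- r$seq[i]
      emitted <- if (r$strand[i] == "-") revcomp(s) else s
      starts[i] <- pos + 1L
      ends[i] <- pos + nchar(emitted)
      pos <- ends[i] + nchar(spacer)
      segs <- c(segs, emitted, spacer)
    }
    full <- paste(segs, collapse = "")
    genome_rows[[length(genome_rows) + 1L]] <-
      tibble::tibble(record_id = r$record_id[1], length = nchar(full), seq = full)
    coord_rows[[length(coord_rows) + 1L]] <-
      tibble::tibble(record_id = r$record_id[1], gene = r$gene,
                     start = starts, end = ends, strand = r$strand)
    cds_rows[[length(cds_rows) + 1L]] <-
      new_cds_tbl(r$record_id, r$gene, r$strand, r$seq, code)
  }

  anc_counts <- purrr::imap(ancestor, function(g, gene) {
    tab <- table(factor(g$codons, levels = codon_levels()))
    tibble::tibble(gene = gene, codon = names(tab), count = as.integer(tab))
  }) %>% dplyr::bind_rows()
  class(anc_counts) <- c("codon_counts", class(anc_counts))
  anc_rscu <- rscu(anc_counts, code)

  truth <- list(
    codon_probs = spec$codon_probs,
    expected_rscu = purrr::imap(spec$codon_probs, function(p, gene) {
      dplyr::mutate(probs_to_rscu(p, code), gene = gene, .before = 1)
    }) %>% dplyr::bind_rows(),
    expected_gc3 = purrr::imap(spec$codon_probs, function(p, gene) {
      tibble::tibble(gene = gene,
                     gc3 = sum(p[third_nt(names(p)) %in% c("G", "C")]))
    }) %>% dplyr::bind_rows(),
    ancestral_counts = anc_counts,
    ancestral_rscu = anc_rscu,
    spec = spec
  )

  out <- dplyr::bind_rows(cds_rows)
  attr(out, "genomes") <- dplyr::bind_rows(genome_rows)
  attr(out, "coords") <- dplyr::bind_rows(coord_rows)
  attr(out, "truth") <- truth
  class(out) <- c("cds_tbl", class(out))
  out
}

#' Write a simulated population as fixture files
#'
#' Emits files readable by [read_genbank()] / [read_fasta_cds()], plus the
#' generator truth as JSON. Sequences are written in the DNA alphabet.
#'
#' @param sim Output of [simulate_mitogenomes()].
#' @param dir Output directory (created if needed).
#' @param format `"genbank"` or `"fasta"` (FASTA genome + coordinate TSV).
#' @param truth Also write `truth.json` (default `TRUE`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, dir, format = c("genbank", "fasta"), truth = TRUE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- attr(sim, "genomes")
  coords <- attr(sim, "coords")
  files <- character()

  if (format == "genbank") {
    path <- file.path(dir, "mitogenomes.gb")
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    for (i in seq_len(nrow(genomes))) {
      id <- genomes$record_id[i]
      seq_dna <- tolower(as_dna(genomes$seq[i]))
      len <- genomes$length[i]
      writeLines(sprintf("LOCUS       %s %d bp    DNA     circular VRT", id, len), con)
      writeLines(sprintf("DEFINITION  synthetic mitochondrial genome %s.", id), con)
      writeLines(sprintf("ACCESSION   %s", id), con)
      writeLines("FEATURES             Location/Qualifiers", con)
      writeLines(sprintf("     source          1..%d", len), con)
      cc <- coords[coords$record_id == id, ]
      for (j in seq_len(nrow(cc))) {
        loc <- sprintf("%d..%d", cc$start[j], cc$end[j])
        if (cc$strand[j] == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     CDS             %s", loc), con)
        writeLines(sprintf('                     /gene="%s"', cc$gene[j]), con)
      }
      writeLines("ORIGIN", con)
      starts <- seq(1L, len, by = 60L)
      for (s in starts) {
        chunk <- substr(seq_dna, s, min(s + 59L, len))
        groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                            pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
        writeLines(sprintf("%9d %s", s, paste(groups, collapse = " ")), con)
      }
      writeLines("//", con)
    }
    files["genbank"] <- path
  } else {
    fasta <- file.path(dir, "genomes.fasta")
    dna <- Biostrings::DNAStringSet(as_dna(genomes$seq))
    names(dna) <- genomes$record_id
    Biostrings::writeXStringSet(dna, fasta)
    coords_path <- file.path(dir, "coords.tsv")
    readr::write_tsv(coords, coords_path)
    files[c("fasta", "coords")] <- c(fasta, coords_path)
  }

  if (truth) {
    tr <- attr(sim, "truth")
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(preset = tr$spec$preset, seed = tr$spec$seed,
           n_individuals = tr$spec$n_individuals, mu = tr$spec$mu,
           codon_probs = tr$codon_probs,
           expected_rscu = tr$expected_rscu,
           expected_gc3 = tr$expected_gc3),
      truth_path, auto_unbox = TRUE, digits = NA
    )
    files["truth"] <- truth_path
  }
  invisible(files)
}
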