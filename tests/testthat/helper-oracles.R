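# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the package's own code paths: family structure is
# re-derived from a hard-coded amino-acid map where needed.

# The 24 four-fold degenerate codons of the vertebrate mitochondrial code,
# written out explicitly (Ala, Pro, Thr, Val, Arg, Gly).
FOURFOLD_24 <- c(
  "GCU", "GCC", "GCA", "GCG", "CCU", "CCC", "CCA", "CCG",
  "ACU", "ACC", "ACA", "ACG", "GUU", "GUC", "GUA", "GUG",
  "CGU", "CGC", "CGA", "CGG", "GGU", "GGC", "GGA", "GGG"
)

MITO_STOPS <- c("UAA", "UAG", "AGA", "AGG")

# amino-acid map for the oracle, independent of the package's code object
oracle_aa_map <- function() {
  bases <- c("U", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- unname(vapply(codons, function(cd) {
    # vertebrate mito translation spelled out by family
    if (cd %in% MITO_STOPS) return("*")
    if (cd %in% c("UUU", "UUC")) return("F")
    if (cd %in% c("UUA", "UUG", "CUU", "CUC", "CUA", "CUG")) return("L")
    if (cd %in% c("AUU", "AUC")) return("I")
    if (cd %in% c("AUA", "AUG")) return("M")
    if (substr(cd, 1, 2) == "GU") return("V")
    if (substr(cd, 1, 2) == "UC" || cd %in% c("AGU", "AGC")) return("S")
    if (substr(cd, 1, 2) == "CC") return("P")
    if (substr(cd, 1, 2) == "AC") return("T")
    if (substr(cd, 1, 2) == "GC") return("A")
    if (cd %in% c("UAU", "UAC")) return("Y")
    if (cd %in% c("CAU", "CAC")) return("H")
    if (cd %in% c("CAA", "CAG")) return("Q")
    if (cd %in% c("AAU", "AAC")) return("N")
    if (cd %in% c("AAA", "AAG")) return("K")
    if (cd %in% c("GAU", "GAC")) return("D")
    if (cd %in% c("GAA", "GAG")) return("E")
    if (cd %in% c("UGU", "UGC")) return("C")
    if (cd %in% c("UGA", "UGG")) return("W")
    if (substr(cd, 1, 2) == "CG") return("R")
    if (substr(cd, 1, 2) == "GG") return("G")
    stop("unmapped codon ", cd)
  }, character(1)))
  stats::setNames(aa, codons)
}

ORACLE_AA <- oracle_aa_map()

# RSCU by direct per-family evaluation of k * n_j / N
oracle_rscu <- function(counts_named, include_stops = TRUE) {
  aa <- ORACLE_AA
  fams <- split(names(aa), aa)
  if (!include_stops) fams[["*"]] <- NULL
  out <- c()
  for (f in names(fams)) {
    members <- fams[[f]]
    n <- counts_named[members]
    N <- sum(n)
    k <- length(members)
    vals <- if (N > 0) k * n / N else rep(NA_real_, k)
    out[members] <- vals
  }
  out
}

# Wright's per-family F from an expanded codon list
oracle_family_F <- function(codon_list) {
  aa <- ORACLE_AA
  sense <- codon_list[!(aa[codon_list] %in% "*")]
  out <- list()
  for (f in setdiff(unique(aa), "*")) {
    members <- names(aa)[aa == f]
    obs <- sense[sense %in% members]
    n <- length(obs)
    if (n < 2) next
    p <- as.vector(table(factor(obs, levels = members))) / n
    out[[f]] <- list(F = (n * sum(p^2) - 1) / (n - 1), n = n,
                     degeneracy = length(members))
  }
  out
}

# ENC recomputed from an expanded codon list (vertebrate mito classes)
oracle_enc_mito <- function(codon_list) {
  ff <- oracle_family_F(codon_list)
  keep <- Filter(function(x) x$F > 0, ff)
  degs <- vapply(keep, function(x) x$degeneracy, numeric(1))
  Fs <- vapply(keep, function(x) x$F, numeric(1))
  F_bar <- tapply(Fs, degs, mean)
  classes <- c(`2` = 12, `4` = 6, `6` = 2)
  if (!all(names(classes) %in% names(F_bar))) return(NA_real_)
  min(max(sum(classes / F_bar[names(classes)]), 20), 60)
}

# Agglomerative clustering oracle: recompute all inter-cluster distances at
# each merge (average linkage = mean pairwise distance); returns the
# cophenetic matrix.
oracle_average_linkage_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# random instances -----------------------------------------------------------

random_counts_tbl <- function(n_units, seed, lambda = 4) {
  set.seed(seed)
  tbl <- tidyr::crossing(unit_id = sprintf("u%03d", seq_len(n_units)),
                         codon = codon_levels())
  tbl$count <- stats::rpois(nrow(tbl), lambda)
  class(tbl) <- c("codon_counts", class(tbl))
  tbl
}

# random CDS: start + random sense codons + stop, wrapped as a cds tibble
random_cds <- function(n_codons, seed, gene = "ND1", record_id = "R1") {
  set.seed(seed)
  sense <- setdiff(names(ORACLE_AA), MITO_STOPS)
  body <- sample(sense, n_codons, replace = TRUE)
  seq <- paste0("AUG", paste(body, collapse = ""), "UAA")
  tibble::tibble(record_id = record_id, gene = gene, strand = "+", seq = seq)
}

expand_counts <- function(counts_tbl) rep(counts_tbl$codon, counts_tbl$count)
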