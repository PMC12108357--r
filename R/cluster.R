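#' Hierarchical clustering of per-gene RSCU profiles
#'
#' Agglomerative clustering of genes on their 64-dimensional RSCU vectors,
#' the analysis behind RSCU heatmap dendrograms. Missing values (unobserved
#' families) are imputed as 0 with a message. Deterministic given inputs;
#' the dendrogram is exportable as Newick text.
#'
#' @param mean_tbl A per-gene `rscu_tbl` (one row per gene and codon).
#' @param k Optional number of clusters to cut the tree at.
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `rscu_clust`: list with the `hclust` fit, the
#'   gene-by-codon `matrix`, `newick` text, and `clusters` (named integer
#'   vector) when `k` is given. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
cluster_rscu <- function(mean_tbl, k = NULL, distance = "euclidean",
                         linkage = "average") {
  key <- intersect(names(mean_tbl), c("gene", "unit_id"))[1]
  wide <- mean_tbl %>%
    dplyr::select(dplyr::all_of(key), "codon", "rscu") %>%
    tidyr::pivot_wider(names_from = "codon", values_from = "rscu")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide[[key]]
  m <- m[, intersect(codon_levels(), colnames(m)), drop = FALSE]
  if (nrow(m) < 2L) stop("Clustering needs at least 2 genes", call. = FALSE)
  if (!is.null(k) && k > nrow(m)) stop("k exceeds the number of genes", call. = FALSE)
  if (anyNA(m)) {
    rlang::inform(paste0("cluster_rscu: imputing ", sum(is.na(m)), " missing RSCU value(s) as 0"))
    m[is.na(m)] <- 0
  }
  hc <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  phy <- ape::as.phylo(hc)
  out <- list(
    hclust = hc,
    matrix = m,
    distance = distance,
    linkage = linkage,
    newick = ape::write.tree(phy),
    clusters = if (!is.null(k)) stats::cutree(hc, k = k)
  )
  class(out) <- "rscu_clust"
  out
}

#' @export
print.rscu_clust <- function(x, ...) {
  cat("<rscu_clust> ", nrow(x$matrix), " genes, ", x$distance, " distance, ",
      x$linkage, " linkage\n", sep = "")
  if (!is.null(x$clusters)) {
    cat("  clusters:", paste(names(x$clusters), x$clusters, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rscu_clust <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_along(hc$height),
    height = hc$height,
    merge1 = hc$merge[, 1],
    merge2 = hc$merge[, 2]
  )
}

#' @exportS3Method generics::glance
glance.rscu_clust <- function(x, ...) {
  coph <- stats::cophenetic(x$hclust)
  tibble::tibble(
    n_genes = nrow(x$matrix),
    distance = x$distance,
    linkage = x$linkage,
    cophenetic_cor = stats::cor(stats::dist(x$matrix, method = x$distance), coph),
    k = if (is.null(x$clusters)) NA_integer_ else length(unique(x$clusters))
  )
}

#' Export a clustering dendrogram as Newick text
#'
#' @param x An `rscu_clust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "rscu_clust"))
  writeLines(x$newick, path)
  invisible(path)
}
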