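code <- genetic_code()

counts_from_named <- function(x, unit_id = "g1") {
  tbl <- tibble::tibble(unit_id = unit_id, codon = codon_levels(),
                        count = as.integer(x[codon_levels()] %0% 0))
  class(tbl) <- c("codon_counts", class(tbl))
  tbl
}
`%0%` <- function(a, b) { a[is.na(a)] <- b; a }

named_counts <- function(...) {
  v <- c(...)
  out <- stats::setNames(rep(0L, 64), codon_levels())
  out[names(v)] <- as.integer(v)
  out
}

test_that("count_codons matches a brute-force sliding-triplet tally and adds", {
  cds <- tibble::tibble(record_id = "R1", gene = "ND1", strand = "+",
                        seq = "AUGAAAUAA")
  out <- count_codons(cds, code)
  expect_identical(sum(out$count), 3L)
  expect_identical(out$count[out$codon %in% c("AUG", "AAA", "UAA")], rep(1L, 3))

  # random CDS vs independent triplet count
  for (seed in 1:10) {
    cds <- random_cds(60, seed)
    out <- count_codons(cds, code)
    s <- cds$seq
    trips <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    brute <- table(factor(trips, levels = codon_levels()))
    expect_identical(out$count[match(codon_levels(), out$codon)],
                     as.integer(brute))
  }

  # additivity under concatenation of two genes
  cds2 <- dplyr::bind_rows(
    tibble::tibble(record_id = "R1", gene = "ND1", strand = "+", seq = "AUGAAAUAA"),
    tibble::tibble(record_id = "R1", gene = "ND2", strand = "+", seq = "AUGCCCUAA")
  )
  pooled <- count_codons(cds2, code, by = "record")
  separate <- count_codons(cds2, code)
  added <- separate %>% dplyr::group_by(codon) %>%
    dplyr::summarise(count = sum(count))
  expect_identical(pooled$count[match(added$codon, pooled$codon)], added$count)
})

test_that("rscu evaluates the definition, including extremes and stop pseudo-family", {
  # Met family {AUA, AUG} with counts 3:1
  r <- rscu(counts_from_named(named_counts(AUA = 3, AUG = 1)), code)
  expect_equal(r$rscu[r$codon == "AUA"], 1.5)
  expect_equal(r$rscu[r$codon == "AUG"], 0.5)

  # uniform usage in every family -> RSCU 1 everywhere
  uni <- counts_from_named(stats::setNames(rep(2L, 64), codon_levels()))
  ru <- rscu(uni, code)
  expect_true(all(abs(ru$rscu - 1) < 1e-12))

  # all mass on one codon of a 4-fold family -> 4 and three CAM siblings
  r4 <- rscu(counts_from_named(named_counts(GCU = 10, AAA = 1)), code)
  expect_equal(r4$rscu[r4$codon == "GCU"], 4)
  expect_equal(r4$rscu[r4$codon %in% c("GCC", "GCA", "GCG")], rep(0, 3))

  # stop codons form a 4-member pseudo-family
  rs <- rscu(counts_from_named(named_counts(UAA = 3, AGA = 1)), code)
  expect_equal(rs$rscu[rs$codon == "UAA"], 3)
  expect_equal(rs$degeneracy[rs$codon == "UAA"], 4L)

  # unobserved families are flagged, not zeroed
  expect_true(all(is.na(r$rscu[r$codon %in% c("UUU", "UUC")])))
  expect_false(any(r$family_observed[r$codon %in% c("UUU", "UUC")]))
  expect_identical(as.character(r$cup_class[r$codon == "UUU"]), "unused")
})

test_that("family sums equal family size and RSCU ignores sequence duplication", {
  for (seed in 1:25) {
    tbl <- random_counts_tbl(1, seed)
    r <- rscu(tbl, code)
    sums <- r %>%
      dplyr::filter(family_observed) %>%
      dplyr::group_by(amino_acid, degeneracy,
                      fam = paste(amino_acid, degeneracy)) %>%
      dplyr::summarise(s = sum(rscu), k = degeneracy[1], .groups = "drop")
    expect_true(all(abs(sums$s - sums$k) < 1e-9))
  }
  # duplicating the sequence (doubling every count) leaves RSCU unchanged
  tbl <- random_counts_tbl(1, 99)
  doubled <- dplyr::mutate(tbl, count = 2L * count)
  class(doubled) <- class(tbl)
  expect_equal(rscu(tbl, code)$rscu, rscu(doubled, code)$rscu)
})

test_that("rscu matches the brute-force oracle on seeded random tables", {
  for (seed in 1:30) {
    tbl <- random_counts_tbl(1, seed)
    r <- rscu(tbl, code)
    named <- stats::setNames(tbl$count, tbl$codon)
    o <- oracle_rscu(named)
    expect_equal(r$rscu[match(names(o), r$codon)], unname(o), tolerance = 1e-12)
  }
})

test_that("mean_rscu is idempotent on identical tables and averages linearly", {
  tbl <- dplyr::bind_rows(
    dplyr::mutate(random_counts_tbl(1, 7), record_id = "a", gene = "ND1"),
    dplyr::mutate(random_counts_tbl(1, 7), record_id = "b", gene = "ND1")
  ) %>% dplyr::select(record_id, gene, codon, count)
  class(tbl) <- c("codon_counts", class(tbl))
  r <- rscu(tbl, code)
  m <- mean_rscu(r)
  one <- rscu(dplyr::filter(tbl, record_id == "a") %>% dplyr::select(-record_id), code)
  expect_equal(m$rscu, dplyr::coalesce(one$rscu, 0))

  # mean of 0 and 2 is 1
  t0 <- counts_from_named(named_counts(GCU = 0, GCC = 5), "x") %>%
    dplyr::mutate(record_id = "a", gene = "ND1") %>% dplyr::select(record_id, gene, codon, count)
  t2 <- counts_from_named(named_counts(GCU = 5, GCC = 5), "x") %>%
    dplyr::mutate(record_id = "b", gene = "ND1") %>% dplyr::select(record_id, gene, codon, count)
  both <- dplyr::bind_rows(t0, t2)
  class(both) <- c("codon_counts", class(both))
  m2 <- mean_rscu(rscu(both, code))
  expect_equal(m2$rscu[m2$codon == "GCU"], 1) # (0 + 2)/2
})

test_that("interval percentages reproduce the reference worked example exactly", {
  ref <- reference_interval_counts()
  s <- interval_percentages(ref)
  expect_identical(sum(s$total), 832L) # 13 genes x 64 codons
  expect_equal(s$percentage, c(25.48, 15.02, 36.18, 23.32))
  shares <- interval_shares(s)
  expect_equal(shares$nonrandom_pct, 63.82)
  expect_equal(shares$unused_g_ending_pct, 53.30)
  expect_equal(shares$over_a_ending_pct, 68.04)
  expect_equal(shares$unbiased_uc_ending_pct, 76.41)
})

test_that("interval_summary classifies all 64 codons per gene", {
  # uniform usage in 13 toy genes -> every pair unbiased
  uni <- tidyr::crossing(record_id = "R1", gene = PCG_ORDER,
                         codon = codon_levels()) %>%
    dplyr::mutate(count = 2L)
  class(uni) <- c("codon_counts", class(uni))
  m <- mean_rscu(rscu(uni, code))
  s <- interval_summary(m)
  expect_identical(sum(s$total), 13L * 64L)
  expect_identical(s$total[s$cup_class == "unbiased"], 13L * 64L)
  expect_equal(sum(s$percentage), 100, tolerance = 0.02)

  # one codon per family -> unused + over only
  one <- counts_from_named(named_counts(
    UUU = 1, CUU = 1, AUU = 1, AUG = 1, GUU = 1, UCU = 1, CCU = 1, ACU = 1,
    GCU = 1, UAU = 1, CAU = 1, CAA = 1, AAU = 1, AAA = 1, GAU = 1, GAA = 1,
    UGU = 1, UGA = 1, CGU = 1, GGU = 1, UAA = 1
  ))
  s1 <- interval_summary(rscu(one, code) %>% dplyr::rename(gene = unit_id))
  expect_identical(s1$total[s1$cup_class %in% c("under", "unbiased")], c(0L, 0L))
})

test_that("cam collects exactly the unused codons", {
  # gene using all 64 codons: empty CAM
  full <- counts_from_named(stats::setNames(rep(1L, 64), codon_levels()))
  expect_identical(nrow(cam(rscu(full, code))), 0L)

  # toy gene with 3 codons: all other 61 are averse
  toy <- counts_from_named(named_counts(AUG = 1, AAA = 1, UAA = 1))
  members <- cam(rscu(toy, code))
  expect_identical(nrow(members), 61L)
  expect_false(any(c("AUG", "AAA", "UAA") %in% members$codon))
  # excluding unobserved families shrinks the motif to observed-family zeros
  strict <- cam(rscu(toy, code), include_absent = FALSE)
  expect_setequal(strict$codon, c("AUA", "AAG", "UAG", "AGA", "AGG"))

  m <- cam_matrix(rscu(toy, code) %>% dplyr::rename(gene = unit_id))
  expect_identical(dim(m), c(64L, 2L))
  expect_identical(sum(m[[2]]), 61L)
})
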