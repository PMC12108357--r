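code <- genetic_code()

test_that("gc3 tallies third positions, excluding stops by default", {
  mk <- function(x) {
    out <- tidyr::crossing(unit_id = "g", codon = codon_levels()) %>%
      dplyr::mutate(count = as.integer(x[codon] %|0|% 0))
    class(out) <- c("codon_counts", class(out))
    out
  }
  `%|0|%` <- function(a, b) { a[is.na(a)] <- b; a }
  expect_equal(gc3(mk(c(AAA = 10)), code)$gc3, 0)
  expect_equal(gc3(mk(c(GCG = 5, GCA = 5)), code)$gc3, 0.5)
  # stop codons do not enter the denominator
  expect_equal(gc3(mk(c(GCG = 5, GCA = 5, UAG = 100)), code)$gc3, 0.5)

  # random table vs expansion oracle
  for (seed in 1:10) {
    tbl <- random_counts_tbl(1, seed)
    expanded <- expand_counts(tbl)
    expanded <- expanded[!expanded %in% MITO_STOPS]
    brute <- mean(substr(expanded, 3, 3) %in% c("G", "C"))
    expect_equal(gc3(tbl, code)$gc3, brute)
  }
})

test_that("the expected-ENC curve evaluates exactly and is symmetric", {
  expect_identical(expected_enc(0), 31)
  expect_identical(expected_enc(0.5), 60.5)
  expect_identical(expected_enc(1), 32)
  expect_error(expected_enc(1.2), "0, 1")

  x <- seq(0, 1, by = 0.01)
  expect_equal(expected_enc(x) - x, expected_enc(1 - x) - (1 - x))
  curve <- enc_standard_curve()
  expect_identical(nrow(curve), 1001L)
  expect_equal(curve$expected_enc[curve$gc3 == 0.5], 60.5)
  expect_true(all(diff(curve$gc3) > 0))
  small <- enc_standard_curve(0.5)
  expect_equal(small$expected_enc, c(31, 60.5, 32))
})

test_that("ENC hits its analytic limits", {
  # one codon per family -> maximal bias, ENC = 20
  one_per_family <- code$families %>%
    dplyr::group_by(family) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(unit_id = "g", codon, count = 50L) %>%
    tidyr::complete(unit_id = "g", codon = codon_levels(), fill = list(count = 0L))
  class(one_per_family) <- c("codon_counts", class(one_per_family))
  expect_equal(enc(one_per_family, code)$enc, 20)

  # uniform usage with large counts -> near the mode's theoretical maximum
  uni <- tidyr::crossing(unit_id = "g", codon = codon_levels()) %>%
    dplyr::mutate(count = 500L)
  class(uni) <- c("codon_counts", class(uni))
  expect_gt(enc(uni, code)$enc, 59.5)
  expect_lte(enc(uni, code)$enc, 60)
  expect_gt(enc(uni, code, mode = "standard-compat")$enc, 60)
  expect_lte(enc(uni, code, mode = "standard-compat")$enc, 61)
})

test_that("ENC and family F match the brute-force oracle on random genes", {
  for (seed in 1:20) {
    tbl <- random_counts_tbl(1, seed, lambda = 3)
    fit <- enc(tbl, code)
    expect_equal(fit$enc, oracle_enc_mito(expand_counts(tbl)), tolerance = 1e-10)

    ff <- fit$family_F[[1]]
    o <- oracle_family_F(expand_counts(tbl))
    for (f in names(o)) {
      got <- ff$F[ff$family == f]
      expect_equal(got, o[[f]]$F, tolerance = 1e-12)
    }
  }
})

test_that("ENC stays within the mode's range and F within (0, 1] after exclusion", {
  for (seed in 1:200) {
    tbl <- random_counts_tbl(1, seed, lambda = stats::runif(1, 0.2, 6))
    fit <- enc(tbl, code)
    expect_gte(fit$enc, 20)
    expect_lte(fit$enc, 60)
    ff <- fit$family_F[[1]]
    est <- ff$F[!is.na(ff$F) & ff$F > 0]
    expect_true(all(est <= 1 + 1e-12))
  }
  # asymptotically F >= 1/k
  big <- random_counts_tbl(1, 1, lambda = 500)
  ff <- enc(big, code)$family_F[[1]]
  expect_true(all(ff$F >= 1 / ff$degeneracy - 1e-3))
})

test_that("enc_plot_points flags genes relative to the standard curve", {
  uni <- tidyr::crossing(gene = "ND1", codon = codon_levels()) %>%
    dplyr::mutate(count = 500L)
  class(uni) <- c("codon_counts", class(uni))
  pts <- enc_plot_points(uni, code, margin = 1)
  # uniform usage sits at gc3 = 0.5: 60 vs expected 60.5, within margin 1
  expect_equal(pts$gc3, 0.5)
  expect_false(pts$below_curve)
  expect_false(is.null(attr(pts, "curve")))

  biased <- code$families %>%
    dplyr::group_by(family) %>% dplyr::slice(1) %>% dplyr::ungroup() %>%
    dplyr::transmute(gene = "ND2", codon, count = 50L) %>%
    tidyr::complete(gene = "ND2", codon = codon_levels(), fill = list(count = 0L))
  class(biased) <- c("codon_counts", class(biased))
  pts2 <- enc_plot_points(biased, code)
  expect_true(pts2$below_curve) # ENC 20 is far below any expected value

  # mutation-only gene: third position i.i.d. -> close to the curve
  set.seed(77)
  fams <- split(code$families$codon, code$families$family)
  w <- 0.35 # one GC3 regime shared by every family
  draw <- unlist(lapply(fams, function(members) {
    p3 <- ifelse(substr(members, 3, 3) %in% c("G", "C"),
                 w / sum(substr(members, 3, 3) %in% c("G", "C")),
                 (1 - w) / sum(!substr(members, 3, 3) %in% c("G", "C")))
    sample(members, 3000, replace = TRUE, prob = p3 / sum(p3))
  }))
  tab <- table(factor(draw, levels = codon_levels()))
  mut <- tibble::tibble(gene = "ND3", codon = names(tab), count = as.integer(tab))
  class(mut) <- c("codon_counts", class(mut))
  pts3 <- enc_plot_points(mut, code)
  expect_lt(abs(pts3$enc - pts3$expected), 3)
})
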