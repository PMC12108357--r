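test_that("specs are pure functions of preset and seed", {
  a <- sim_spec("kansuensis-like", seed = 7)
  b <- sim_spec("kansuensis-like", seed = 7)
  expect_identical(a, b)
  c_ <- sim_spec("kansuensis-like", seed = 8)
  expect_false(identical(a$codon_probs, c_$codon_probs))

  sim1 <- simulate_mitogenomes(sim_spec("neutral", 3, list(n_individuals = 2)))
  sim2 <- simulate_mitogenomes(sim_spec("neutral", 3, list(n_individuals = 2)))
  expect_identical(as.data.frame(sim1), as.data.frame(sim2))
})

test_that("preset probability structure is as declared", {
  code <- genetic_code()
  neutral <- sim_spec("neutral", 1)
  p <- neutral$codon_probs[["ND1"]]
  fams <- split(code$families$codon, code$families$family)
  for (f in fams) {
    expect_equal(stats::sd(p[f]), 0) # uniform within each family
  }
  extreme <- sim_spec("extreme-bias", 1)
  pe <- extreme$codon_probs[["ND1"]]
  for (f in fams) {
    expect_identical(sum(pe[f] > 0), 1L) # single codon carries the family
  }
  expect_error(sim_spec("klingon"), "arg")
})

test_that("the gene plan shapes every generated record", {
  spec <- sim_spec("kansuensis-like", 13, list(n_individuals = 2))
  sim <- simulate_mitogenomes(spec)
  expect_identical(nrow(sim), 26L)
  plan <- spec$gene_plan
  merged <- dplyr::inner_join(as.data.frame(sim), plan, by = "gene",
                              suffix = c("", "_plan"))
  expect_identical(merged$length, merged$length_bp)
  expect_identical(merged$strand, merged$strand_plan)
  expect_identical(merged$start_codon, merged$start_codon_plan)
  # ND4 carries the 1 nt partial stop; everything else a complete stop
  expect_false(any(merged$complete_stop[merged$gene == "ND4"]))
  expect_identical(unique(merged$stop_codon[merged$gene == "ND4"]), "U")
  expect_true(all(merged$complete_stop[merged$gene != "ND4"]))
  # ND6 is reverse-complemented in the assembled genome
  coords <- attr(sim, "coords")
  genomes <- attr(sim, "genomes")
  nd6 <- coords[coords$gene == "ND6" & coords$record_id == "SYN001", ]
  g <- genomes$seq[genomes$record_id == "SYN001"]
  emitted <- substr(g, nd6$start, nd6$end)
  mrna <- sim$seq[sim$gene == "ND6" & sim$record_id == "SYN001"]
  expect_identical(emitted, revcomp(mrna))
})

test_that("zero divergence gives identical individuals; mu controls spread", {
  frozen <- simulate_mitogenomes(sim_spec("kansuensis-like", 5,
                                          list(n_individuals = 5, mu = 0)))
  seqs <- split(frozen$seq, frozen$record_id)
  expect_true(all(vapply(seqs[-1], identical, logical(1), seqs[[1]])))

  diverged <- simulate_mitogenomes(sim_spec("kansuensis-like", 5,
                                            list(n_individuals = 5, mu = 0.01)))
  seqs2 <- split(diverged$seq, diverged$record_id)
  expect_false(all(vapply(seqs2[-1], identical, logical(1), seqs2[[1]])))
  # synonymous-only divergence: translated protein identical across individuals
  code <- genetic_code()
  aa_of <- function(s) paste(code$aa[codonize(
    tibble::tibble(record_id = "x", gene = "ND1", strand = "+", seq = s),
    code)$codon], collapse = "")
  prots <- vapply(seqs2, function(x) aa_of(x[[1]]), character(1))
  expect_identical(length(unique(prots)), 1L)
})

test_that("extreme bias forces ENC = 20 and the full aversion motif", {
  sim <- simulate_mitogenomes(sim_spec("extreme-bias", 2, list(n_individuals = 1)))
  code <- genetic_code()
  # initiator excluded: the fixed AUG start would otherwise add a second
  # Met codon on top of the preset's single one
  counts <- count_codons(sim, code, by = "gene", include_initiator = FALSE)
  fit <- enc(dplyr::filter(counts, gene == "COX1"), code)
  expect_equal(fit$enc, 20)
  r <- rscu(dplyr::filter(counts, gene == "COX1"), code)
  used <- sum(r$count > 0)
  motif <- cam(r)
  expect_identical(nrow(motif), 64L - used)
})

test_that("neutral sampling recovers RSCU 1 and truth matches at large n", {
  # one long gene: every family-class sees thousands of codons
  plan <- tibble::tibble(gene = "ND1", length_bp = 1500000L, strand = "+",
                         start_codon = "AUG", stop_codon = "UAA")
  sim <- simulate_mitogenomes(sim_spec("neutral", 31,
                                       list(n_individuals = 1, gene_plan = plan)))
  r <- rscu(count_codons(sim, by = "gene"), genetic_code(), include_stops = FALSE)
  expect_true(all(abs(r$rscu[r$family_observed] - 1) < 0.1))

  # kansuensis-like: empirical RSCU within +-0.1 of the spec's expectation
  sim2 <- simulate_mitogenomes(sim_spec("kansuensis-like", 31,
                                        list(n_individuals = 1, gene_plan = plan)))
  r2 <- rscu(count_codons(sim2, by = "gene"), genetic_code(), include_stops = FALSE)
  truth <- attr(sim2, "truth")$expected_rscu
  j <- dplyr::inner_join(r2, truth, by = c("gene", "codon"),
                         suffix = c("", "_truth"))
  expect_true(all(abs(j$rscu - j$rscu_truth) < 0.1, na.rm = TRUE))
  # and GC3 close to its expectation
  g3 <- gc3(count_codons(sim2, by = "gene"), genetic_code())
  expect_equal(g3$gc3, attr(sim2, "truth")$expected_gc3$gc3, tolerance = 0.02)
})

test_that("fixtures round-trip in both formats with truth attached", {
  sim <- simulate_mitogenomes(sim_spec("kansuensis-like", 9, list(n_individuals = 2)))
  dir <- withr::local_tempdir()
  f <- write_fixture(sim, dir, "fasta")
  expect_true(file.exists(f[["truth"]]))
  truth <- jsonlite::read_json(f[["truth"]])
  expect_identical(truth$preset, "kansuensis-like")
  back <- read_fasta_cds(f[["fasta"]], f[["coords"]])
  key <- function(d) dplyr::arrange(as.data.frame(d)[c("record_id", "gene", "seq")],
                                    record_id, gene)
  expect_identical(key(back), key(sim))
})
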