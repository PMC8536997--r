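test_that("generated alleles carry both flanks and a faithful encoding", {
  set.seed(61)
  ny <- 0
  reps <- 300
  mid_len <- 0
  for (i in seq_len(reps)) {
    al <- generate_allele()
    expect_match(al$peptide, "^KIIS")
    expect_match(al$peptide, "IEQIP$")
    expect_true(nchar(al$peptide) >= 35 && nchar(al$peptide) <= 53)
    expect_equal(csdhoney:::translate_dna(al$dna), al$peptide)
    mid <- substr(al$peptide, 5, nchar(al$peptide) - 5)
    ny <- ny + lengths(regmatches(mid, gregexpr("[NY]", mid)))
    mid_len <- mid_len + nchar(mid)
  }
  expect_equal(ny / mid_len, 0.75, tolerance = 0.05)
  expect_error(generate_allele(length_range = c(10, 20)))
  expect_error(generate_allele(weights = c(N = 2)), "invalid")
})

test_that("colonies have distinct queen alleles and unit total abundance", {
  set.seed(67)
  for (i in 1:5) {
    np <- sample(7:20, 1)
    tr <- simulate_colony("S1", n_patrilines = np)
    expect_length(tr$queen_alleles, 2L)
    expect_false(tr$queen_alleles[1] == tr$queen_alleles[2])
    expect_equal(sum(tr$abundance), 1, tolerance = 1e-12)
    expect_lte(length(tr$abundance), 2L + np + length(tr$drift_alleles))
    expect_lt(sum(tr$abundance[tr$drift_alleles]), 0.05)
    expect_false(any(duplicated(names(tr$abundance))))
    for (p in names(tr$dna))
      expect_equal(csdhoney:::translate_dna(tr$dna[[p]]), p)
  }
})

test_that("a fixed seed reproduces the colony and its reads exactly", {
  set.seed(71); tr1 <- simulate_colony("S1", n_patrilines = 5)
  set.seed(71); tr2 <- simulate_colony("S1", n_patrilines = 5)
  expect_identical(tr1, tr2)
  set.seed(72); r1 <- simulate_reads(tr1, 100, error_model())
  set.seed(72); r2 <- simulate_reads(tr1, 100, error_model())
  expect_identical(r1, r2)
})

test_that("read abundances follow the multinomial and zero never samples", {
  truth <- structure(list(
    sample_id = "T", queen_alleles = c("KIISNNIEQIP", "KIISYYIEQIP"),
    patriline_alleles = "KIISSSIEQIP", drift_alleles = character(),
    abundance = c(KIISNNIEQIP = 0.7, KIISYYIEQIP = 0.3, KIISSSIEQIP = 0),
    dna = c(KIISNNIEQIP = rev_translate("KIISNNIEQIP"),
            KIISYYIEQIP = rev_translate("KIISYYIEQIP"),
            KIISSSIEQIP = rev_translate("KIISSSIEQIP"))),
    class = "colony_truth")
  set.seed(73)
  reads <- simulate_reads(truth, 10000, no_error())
  pr <- process_reads(reads, default_pattern_pair(), min_cluster = 1)
  tab <- tabulate_alleles(pr$clusters, "T")
  expect_false("KIISSSIEQIP" %in% tab$peptide)
  p_hat <- tab$rel_abundance[tab$peptide == "KIISNNIEQIP"]
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(p_hat - 0.7), 3 * se)
})

test_that("raising the homopolymer indel rate raises frame rejections", {
  frac_frame <- function(rate) {
    set.seed(79)
    tr <- toy_colony(n_pat = 3)
    em <- error_model(substitution_rate = 0, hp_indel_rate = rate)
    reads <- simulate_reads(tr, 600, em)
    pr <- process_reads(reads, default_pattern_pair(), min_cluster = 1)
    bad <- pr$clusters$member_count[!is.na(pr$clusters$reason) &
                                      pr$clusters$reason == "frame"]
    sum(bad) / sum(pr$clusters$member_count)
  }
  f <- vapply(c(0, 0.005, 0.05), frac_frame, 0)
  expect_equal(f[1], 0)
  expect_true(f[2] > 0)
  expect_true(f[3] > f[2])
})

test_that("ground truth round-trips through the manifest", {
  set.seed(83)
  truths <- list(S1 = toy_colony("S1", 3), S2 = toy_colony("S2", 4))
  truths$S2$drift_alleles <- character()  # empty field serialization
  dir <- withr::local_tempdir()
  paths <- write_truth(truths, dir)
  expect_true(all(file.exists(paths)))
  back <- read_truth(paths["manifest"])
  expect_length(back, 2L)
  expect_equal(back[[1]]$queen_alleles, truths$S1$queen_alleles)
  expect_equal(back[[2]]$drift_alleles, character())
  expect_equal(back[[1]]$abundance, truths$S1$abundance,
               tolerance = 1e-9)
  fa <- Biostrings::readAAStringSet(paths["fasta"])
  expect_length(fa, length(truths$S1$abundance) + length(truths$S2$abundance))
})

test_that("shared-pool simulation produces multi-sample alleles", {
  ds <- simulate_dataset(n_samples = 3, n_reads = 50, pool_size = 6,
                         seed = 89, n_patrilines = 6)
  peps <- lapply(ds$truths, function(t) names(t$abundance))
  shared <- intersect(peps[[1]], union(peps[[2]], peps[[3]]))
  expect_gt(length(shared), 0L)
  expect_named(ds$reads, c("S01", "S02", "S03"))
})
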