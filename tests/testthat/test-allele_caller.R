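mk_table <- function(sample_id, peptides, counts) {
  data.frame(sample_id = sample_id, peptide = peptides,
             read_count = as.integer(counts),
             rel_abundance = counts / sum(counts),
             stringsAsFactors = FALSE)
}

test_that("tabulate_alleles merges synonymous encodings", {
  cl <- data.frame(bases = c("x", "y", "z"),
                   member_count = c(60L, 40L, 100L),
                   peptide = c("KIISAIEQIP", "KIISAIEQIP", "KIISCIEQIP"),
                   reason = NA_character_)
  tab <- tabulate_alleles(cl, "S1")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$read_count[tab$peptide == "KIISAIEQIP"], 100L)
  expect_equal(sort(tab$rel_abundance), c(0.5, 0.5))
  expect_equal(sum(tab$rel_abundance), 1, tolerance = 1e-12)

  single <- tabulate_alleles(cl[3, ], "S2")
  expect_equal(single$rel_abundance, 1)
  expect_error(tabulate_alleles(cl[0, ], "S3"), "no translated")
})

test_that("derive_threshold is the median of multi-sample minima, with fallback", {
  tabs <- rbind(mk_table("S1", c("X", "Y"), c(10, 2)) ,  # X .833, Y .167
                mk_table("S2", "X", 1),
                mk_table("S3", "Y", 1))
  # hand fixture with explicit abundances
  tabs <- data.frame(
    sample_id = c("S1", "S2", "S1", "S3", "S1"),
    peptide = c("X", "X", "Y", "Y", "Z"),
    read_count = 1L,
    rel_abundance = c(0.10, 0.05, 0.02, 0.50, 0.33))
  expect_equal(derive_threshold(tabs), median(c(0.05, 0.02)))  # 0.035

  lonely <- mk_table("S1", c("A", "B"), c(3, 1))
  expect_equal(derive_threshold(lonely), 0.0164)

  same <- data.frame(sample_id = c("S1", "S2", "S1", "S2"),
                     peptide = c("X", "X", "Y", "Y"), read_count = 1L,
                     rel_abundance = c(0.05, 0.9, 0.05, 0.9))
  expect_equal(derive_threshold(same), 0.05)
})

test_that("apply_qc enforces the retention criteria at their boundaries", {
  tabs <- data.frame(
    sample_id = c("S1", "S2", "S3", "S3", "S4"),
    peptide = c("KIISAIEQIP", "KIISAIEQIP",     # two samples, tiny abundance
                "KIISCIEQIP",                   # private, above threshold
                "KIISDIEQIP",                   # private, exactly at threshold
                "KIISEIEQIP"),                  # private, below threshold
    read_count = 1L,
    rel_abundance = c(0.001, 0.001, 0.0200, 0.0164, 0.0100))
  qc <- apply_qc(tabs, 0.0164)
  expect_setequal(qc$alleles$peptide, c("KIISAIEQIP", "KIISCIEQIP"))
  expect_false(qc$alleles$is_private[qc$alleles$peptide == "KIISAIEQIP"])
  expect_true(qc$alleles$is_private[qc$alleles$peptide == "KIISCIEQIP"])
})

test_that("criterion (i) rejects stop symbols and motif-less peptides", {
  pair <- default_pattern_pair()
  tabs <- data.frame(sample_id = "S1",
                     peptide = c("KIISNNYIEQIP", "KIISNN*IEQIP", "AAANNYCCC"),
                     read_count = 1L, rel_abundance = c(0.5, 0.3, 0.2))
  qc <- apply_qc(tabs, 0.0164, patterns = pair)
  expect_equal(qc$alleles$peptide, "KIISNNYIEQIP")
})

test_that("raising the threshold never enlarges the retained set", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    tabs <- do.call(rbind, lapply(1:4, function(s) {
      peps <- sample(paste0("KIIS", LETTERS[1:n], "IEQIP"), 12)
      mk_table(paste0("S", s), peps, rpois(12, 40) + 1L)
    }))
    prev <- NULL
    for (thr in c(0.005, 0.02, 0.08, 0.3)) {
      cur <- apply_qc(tabs, thr)$alleles$peptide
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("privacy counts decompose the per-sample allele totals", {
  set.seed(23)
  tabs <- do.call(rbind, lapply(1:5, function(s) {
    peps <- sample(paste0("KIIS", LETTERS[1:20], "IEQIP"), 10)
    mk_table(paste0("S", s), peps, rpois(10, 60) + 1L)
  }))
  qc <- apply_qc(tabs, 0.0164)
  per_sample_total <- nrow(qc$tables)
  expect_equal(sum(qc$alleles$n_samples), per_sample_total)
  expect_equal(sum(qc$alleles$is_private) +
                 sum(qc$alleles$n_samples[!qc$alleles$is_private]),
               per_sample_total)
})

test_that("novelty is exact membership in the known set", {
  al <- data.frame(peptide = c("KIISAIEQIP", "KIISCIEQIP"),
                   stringsAsFactors = FALSE)
  out <- classify_novelty(al, known = "KIISAIEQIP")
  expect_equal(out$is_novel, c(FALSE, TRUE))
  expect_true(all(classify_novelty(al, character())$is_novel))
  expect_true(all(classify_novelty(al, NULL)$is_novel))

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">k1", "KIISCIEQIP"), fa)
  expect_equal(classify_novelty(al, fa)$is_novel, c(TRUE, FALSE))
})

test_that("rarefaction is exact at 100%, constant for one allele, and seeded", {
  one <- rarefy(rep("A", 500), percents = c(10, 50, 100), replicates = 20)
  expect_true(all(one$mean_alleles == 1))

  labels <- c(rep("A", 200), rep("B", 200))
  rc <- rarefy(labels, percents = c(50, 100), replicates = 100, seed = 9)
  expect_equal(rc$mean_alleles[rc$percent == 100], 2)
  expect_equal(rc$mean_alleles[rc$percent == 50], 2)  # miss prob ~ 1e-120
  rc2 <- rarefy(labels, percents = c(50, 100), replicates = 100, seed = 9)
  expect_identical(rc, rc2)
  expect_error(rarefy(character()), "empty")
})

test_that("rarefaction means are non-decreasing within Monte-Carlo tolerance", {
  set.seed(31)
  labels <- sample(LETTERS[1:8], 2000, replace = TRUE,
                   prob = c(40, 20, 10, 5, 3, 1, 0.5, 0.5))
  rc <- rarefy(labels, percents = seq(5, 100, by = 5), replicates = 50,
               seed = 2)
  expect_true(all(diff(rc$mean_alleles) > -0.25))
  expect_equal(rc$mean_alleles[rc$percent == 100],
               attr(rc, "total_alleles"))
})
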