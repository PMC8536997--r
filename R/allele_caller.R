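# Allele-level quality control: per-sample allele tables, the data-derived
# relative-abundance threshold, retention criteria, novelty classification
# and rarefaction of allele richness.
#
# A peptide is retained as a functional allele iff
#   (i)   it carries both flank motifs and no stop symbol,
#   (ii)  if seen in a single sample, its within-sample relative abundance
#         strictly exceeds the threshold, and
#   (iii) if seen in two or more samples, it is kept regardless of
#         abundance.
# The threshold is the median over multi-sample peptides of each peptide's
# minimum within-sample relative abundance, with 0.0164 as the fallback
# when no peptide is shared between samples.

#' Aggregate translated clusters of one sample into an allele table
#'
#' Clusters whose DNA differs but translates to the same peptide
#' (synonymous encodings) are merged by summing read counts.  Relative
#' abundance is computed over the reads coding for alleles within the
#' sample, i.e. reads surviving cluster filtering and translation.
#'
#' @param clusters translated cluster data.frame ([translate_cluster()])
#' @param sample_id sample identifier
#' @return data.frame `sample_id`, `peptide`, `read_count`,
#'   `rel_abundance`, ordered by decreasing count
#' @export
tabulate_alleles <- function(clusters, sample_id) {
  ok <- clusters[!is.na(clusters$peptide), , drop = FALSE]
  if (nrow(ok) == 0L) stop("sample '", sample_id, "' has no translated clusters")
  cnt <- tapply(ok$member_count, ok$peptide, sum)
  tab <- data.frame(sample_id = sample_id,
                    peptide = names(cnt),
                    read_count = as.integer(cnt),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$rel_abundance <- tab$read_count / sum(tab$read_count)
  tab <- tab[order(-tab$read_count, tab$peptide), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Derive the single-sample abundance threshold from multi-sample alleles
#'
#' For every peptide present in at least two samples, take its minimum
#' within-sample relative abundance; the threshold is the median of those
#' minima.  When no peptide is shared between samples the data-derived
#' statistic is undefined and the fixed fallback (0.0164, the value of the
#' statistic in the original 12-sample honey survey) is returned.
#'
#' @param tables allele tables of all samples, row-bound
#'   ([tabulate_alleles()])
#' @param fallback threshold used when no multi-sample peptide exists
#' @return numeric threshold in (0, 1)
#' @export
derive_threshold <- function(tables, fallback = 0.0164) {
  ns <- tapply(tables$sample_id, tables$peptide,
               function(s) length(unique(s)))
  multi <- names(ns)[ns >= 2L]
  if (length(multi) == 0L) return(fallback)
  minima <- tapply(tables$rel_abundance[tables$peptide %in% multi],
                   tables$peptide[tables$peptide %in% multi], min)
  stats::median(as.numeric(minima))
}

#' Apply the allele retention criteria
#'
#' @param tables row-bound allele tables of all samples
#' @param threshold single-sample abundance threshold (strict inequality);
#'   typically [derive_threshold()]
#' @param patterns optional `motif_pattern_pair`; when supplied, criterion
#'   (i) is re-checked at the peptide level (flank motifs present, no stop
#'   symbol).  Fragments trimmed by [scan_and_trim()] satisfy it by
#'   construction, so this is a belt-and-braces check for externally
#'   supplied tables.
#' @return list with `alleles` (data.frame `peptide`, `length_residues`,
#'   `n_samples`, `samples`, `is_private`, `max_abundance`) and `tables`
#'   (the input restricted to retained peptides)
#' @export
apply_qc <- function(tables, threshold, patterns = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  keep_i <- rep(TRUE, nrow(tables))
  if (!is.null(patterns)) {
    keep_i <- grepl(patterns$peptide5_regex, tables$peptide, perl = TRUE) &
      grepl(patterns$peptide3_regex, tables$peptide, perl = TRUE)
  }
  keep_i <- keep_i & !grepl("\\*", tables$peptide, fixed = FALSE)
  tab <- tables[keep_i, , drop = FALSE]

  sp <- split(seq_len(nrow(tab)), tab$peptide)
  retained <- vapply(sp, function(ix) {
    ns <- length(unique(tab$sample_id[ix]))
    ns >= 2L || any(tab$rel_abundance[ix] > threshold)
  }, NA)
  peps <- names(sp)[retained]
  # first-seen order of retained peptides
  peps <- tab$peptide[!duplicated(tab$peptide)]
  peps <- peps[peps %in% names(sp)[retained]]

  alleles <- data.frame(
    peptide = peps,
    length_residues = nchar(peps),
    n_samples = vapply(peps, function(p)
      length(unique(tab$sample_id[tab$peptide == p])), 0L),
    samples = vapply(peps, function(p)
      paste(sort(unique(tab$sample_id[tab$peptide == p])), collapse = ","),
      ""),
    max_abundance = vapply(peps, function(p)
      max(tab$rel_abundance[tab$peptide == p]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  alleles$is_private <- alleles$n_samples == 1L
  list(alleles = alleles,
       tables = tab[tab$peptide %in% peps, , drop = FALSE])
}

#' Flag alleles absent from a known-allele reference
#'
#' Novelty is defined as exact peptide absence from a user-supplied
#' reference set (a local stand-in for a database search).  With no
#' reference, every allele is novel.
#'
#' @param alleles allele data.frame from [apply_qc()]
#' @param known character vector of known peptides, or path to a protein
#'   FASTA of known alleles, or NULL
#' @return `alleles` with a logical `is_novel` column
#' @export
classify_novelty <- function(alleles, known = NULL) {
  if (is.character(known) && length(known) == 1L && file.exists(known))
    known <- as.character(Biostrings::readAAStringSet(known))
  alleles$is_novel <- !(alleles$peptide %in% known)
  alleles
}

#' Rarefaction of allele richness against sequencing effort
#'
#' Subsamples a sample's allele-coding reads without replacement at each
#' percentage of the grid and averages the number of distinct retained
#' alleles over replicates.  Allele labels are fixed by the full-data call;
#' clustering is not re-run within subsamples.
#'
#' @param labels per-read allele labels (character vector, one element per
#'   retained-allele-coding read of the sample)
#' @param percents percentage grid in (0, 100]
#' @param replicates resampling replicates per grid point
#' @param seed optional integer seed (local to this call)
#' @return data.frame `percent`, `mean_alleles`; attributes `replicates`,
#'   `seed`, `total_alleles` and `plateau_percent` (smallest grid percent at
#'   which the mean equals the sample's full allele count)
#' @export
rarefy <- function(labels, percents = 1:100, replicates = 100L, seed = NULL) {
  n <- length(labels)
  if (n == 0L) stop("empty sample")
  stopifnot(replicates >= 1L, all(percents > 0), all(percents <= 100))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  codes <- as.integer(factor(labels))
  total <- length(unique(codes))
  means <- vapply(percents, function(p) {
    k <- max(1L, floor(p * n / 100))
    mean(vapply(seq_len(replicates), function(r)
      length(unique(codes[sample.int(n, k)])), 0L))
  }, 0)
  out <- data.frame(percent = percents, mean_alleles = means)
  plateau <- percents[means >= total - 1e-12]
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  attr(out, "total_alleles") <- total
  attr(out, "plateau_percent") <- if (length(plateau)) min(plateau) else NA
  out
}

#' Expand an allele table into per-read labels
#' @param table one sample's allele table (rows restricted to retained
#'   alleles)
#' @return character vector with one peptide label per read
#' @export
read_labels <- function(table) rep(table$peptide, table$read_count)
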