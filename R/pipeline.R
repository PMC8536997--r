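# End-to-end workflow: reads -> alleles -> diversity -> similarity, with
# per-sample summary tables, the abundant-allele table, and the
# correlation panel relating sequencing effort to allele counts.

#' Pearson correlation panel of a per-sample summary table
#'
#' Correlates the number of sequenced reads, retained reads, private
#' alleles and novel alleles with the total allele count per sample
#' (sample, n-1, convention).
#'
#' @param summary per-sample summary data.frame with columns `n_reads`,
#'   `n_retained`, `n_alleles`, `n_private`, `n_novel`
#' @return named numeric vector `r_reads_alleles`, `r_retained_alleles`,
#'   `r_private_total`, `r_novel_total`
#' @export
correlation_panel <- function(summary) {
  r <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  c(r_reads_alleles = r(summary$n_reads, summary$n_alleles),
    r_retained_alleles = r(summary$n_retained, summary$n_alleles),
    r_private_total = r(summary$n_private, summary$n_alleles),
    r_novel_total = r(summary$n_novel, summary$n_alleles))
}

.log_stage <- function(verbose, ...) if (verbose) message(...)

#' Run the full honey eDNA allele pipeline
#'
#' Processes per-sample reads through motif-anchored trimming, quality and
#' cluster filtering, translation, allele QC, novelty classification,
#' rarefaction, allele diversity and sample-similarity analyses.
#'
#' @param reads named list of reads data.frames (sample id -> reads), or a
#'   named character vector of FASTQ paths
#' @param patterns `motif_pattern_pair` (default: exemplar KIIS/IEQIP)
#' @param known known-allele reference for novelty (vector, FASTA path or
#'   NULL = all novel)
#' @param threshold `"auto"` (data-derived median-of-minima with 0.0164
#'   fallback) or a fixed numeric value
#' @param qmin,min_cluster read-level filter parameters
#' @param abundant_cutoff within-sample relative abundance above which an
#'   allele enters the abundant-allele table (strict inequality)
#' @param rarefaction NULL to skip, or a list with `percents`,
#'   `replicates`, `seed`
#' @param scoring `diversity_scoring` for allele diversity (NULL skips the
#'   diversity stage)
#' @param k,m similarity embedding dimension and logistic-PCA scale
#' @param out_dir optional directory to write TSV outputs into
#' @param verbose log per-stage attrition to stderr
#' @return list of class `csd_pipeline`: `summary`, `threshold`,
#'   `alleles`, `tables`, `abundant`, `correlations`, `rarefaction`,
#'   `diversity`, `similarity`, `tallies`
#' @export
run_pipeline <- function(reads, patterns = default_pattern_pair(),
                         known = NULL, threshold = "auto", qmin = 6L,
                         min_cluster = 10L, abundant_cutoff = 0.05,
                         rarefaction = list(percents = 1:100,
                                            replicates = 100L, seed = 1L),
                         scoring = diversity_scoring(), k = 2L, m = 4,
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(reads))
    reads <- stats::setNames(lapply(reads, read_fastq),
                             if (is.null(names(reads)))
                               sub("\\.(fastq|fq)(\\.gz)?$", "",
                                   basename(reads)) else names(reads))
  sample_ids <- names(reads)
  stopifnot(length(sample_ids) > 0L, !is.null(sample_ids))

  processed <- lapply(sample_ids, function(s) {
    pr <- process_reads(reads[[s]], patterns, qmin = qmin,
                        min_cluster = min_cluster)
    .log_stage(verbose, sprintf(
      "[reads] %s: %d in, %d trimmed, %d quality-passed, %d in clusters, %d translated",
      s, pr$tallies["input"], pr$tallies["trimmed"],
      pr$tallies["quality_passed"], pr$tallies["clustered_reads"],
      pr$tallies["translated_reads"]))
    pr
  })
  names(processed) <- sample_ids

  tables <- do.call(rbind, lapply(sample_ids, function(s)
    tabulate_alleles(processed[[s]]$clusters, s)))
  thr <- if (identical(threshold, "auto")) derive_threshold(tables)
         else as.numeric(threshold)
  .log_stage(verbose, sprintf("[alleles] threshold = %.6g", thr))
  qc <- apply_qc(tables, thr, patterns = patterns)
  alleles <- classify_novelty(qc$alleles, known)
  ret <- qc$tables

  summary <- do.call(rbind, lapply(sample_ids, function(s) {
    st <- ret[ret$sample_id == s, , drop = FALSE]
    al <- alleles[alleles$peptide %in% st$peptide, , drop = FALSE]
    n_reads <- nrow(reads[[s]])
    n_ret <- sum(st$read_count)
    data.frame(sample_id = s, n_reads = n_reads, n_retained = n_ret,
               pct_retained = round(100 * n_ret / n_reads, 1),
               n_alleles = nrow(st),
               n_private = sum(al$is_private),
               pct_private = round(100 * sum(al$is_private) /
                                     max(1L, nrow(st)), 1),
               n_novel = sum(al$is_novel),
               stringsAsFactors = FALSE)
  }))

  abundant <- ret[ret$rel_abundance > abundant_cutoff, , drop = FALSE]
  abundant <- abundant[order(abundant$sample_id, -abundant$rel_abundance), ]
  abundant$abundance_pct <- round(100 * abundant$rel_abundance, 1)
  abundant$is_novel <- alleles$is_novel[match(abundant$peptide,
                                              alleles$peptide)]
  rownames(abundant) <- NULL

  rare <- NULL
  if (!is.null(rarefaction)) {
    rare <- lapply(sample_ids, function(s)
      rarefy(read_labels(ret[ret$sample_id == s, , drop = FALSE]),
             percents = rarefaction$percents,
             replicates = rarefaction$replicates,
             seed = rarefaction$seed))
    names(rare) <- sample_ids
  }

  sample_sets <- split(ret$peptide, ret$sample_id)[sample_ids]
  div <- if (!is.null(scoring))
    summarize_diversity(alleles$peptide, sample_sets, scoring) else NULL
  sim <- if (length(sample_sets) >= 2L)
    sample_similarity(sample_sets, k = k, m = m) else NULL

  out <- structure(list(
    summary = summary, threshold = thr, alleles = alleles, tables = ret,
    abundant = abundant,
    correlations = round(correlation_panel(summary), 2),
    rarefaction = rare, diversity = div, similarity = sim,
    tallies = lapply(processed, `[[`, "tallies")), class = "csd_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.csd_pipeline <- function(x, ...) {
  cat("<csd_pipeline> ", nrow(x$summary), " samples, ",
      nrow(x$alleles), " unique alleles (",
      sum(x$alleles$is_private), " private, ",
      sum(x$alleles$is_novel), " novel), threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs as TSV/FASTA files
#' @param result a `csd_pipeline`
#' @param dir output directory
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(result$summary, "sample_summary.tsv")
  w(result$alleles, "alleles.tsv")
  w(result$tables, "allele_tables.tsv")
  w(result$abundant, "abundant_alleles.tsv")
  writeLines(c(rbind(sprintf(">allele%03d|samples=%s|private=%d|novel=%d",
                             seq_len(nrow(result$alleles)),
                             result$alleles$samples,
                             result$alleles$is_private,
                             result$alleles$is_novel),
                     result$alleles$peptide)),
             file.path(dir, "alleles.fasta"))
  if (!is.null(result$rarefaction)) {
    rc <- do.call(rbind, lapply(names(result$rarefaction), function(s)
      cbind(sample_id = s, result$rarefaction[[s]])))
    w(rc, "rarefaction.tsv")
  }
  if (!is.null(result$diversity)) w(result$diversity, "diversity_summary.tsv")
  if (!is.null(result$similarity)) {
    jm <- result$similarity$jaccard
    w(data.frame(sample_id = rownames(jm), jm, check.names = FALSE),
      "jaccard.tsv")
    w(result$similarity$single$merges, "linkage_single.tsv")
    w(result$similarity$complete$merges, "linkage_complete.tsv")
    co <- result$similarity$mds
    w(data.frame(sample_id = rownames(co), co, check.names = FALSE),
      "mds_coords.tsv")
    sc <- result$similarity$lpca$scores
    w(data.frame(sample_id = rownames(sc), sc, check.names = FALSE),
      "lpca_scores.tsv")
  }
  jsonlite::write_json(list(threshold = result$threshold,
                            correlations = as.list(result$correlations)),
                       file.path(dir, "run_stats.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
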