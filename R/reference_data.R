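# Bundled reference tables from a published 12-sample honey eDNA survey of
# csd HVR diversity (12 colonies, Emilia-Romagna, 2020): the per-sample
# sequencing/allele summary and the abundant-allele (>5%) table.  They are
# used as printed-number inputs by the acceptance checks and as worked
# examples.

#' Per-sample summary of the bundled 12-sample honey survey
#'
#' Columns: `sample_id`, `province`, `n_reads` (sequenced), `n_retained`
#' (reads coding for valid alleles), `pct_retained`, `n_alleles` (valid
#' protein alleles), `n_private`, `pct_private`, `n_novel`,
#' `n_novel_private`.
#'
#' @return data.frame with 12 rows
#' @export
honey_survey_summary <- function() {
  utils::read.table(system.file("extdata", "honey12_summary.tsv",
                                package = "csdhoney"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Abundant alleles (>5% within-sample) of the bundled honey survey
#'
#' Columns: `sample_id`, `peptide`, `abundance_pct`, `is_novel`.  Alleles
#' shared between samples appear as identical peptide strings on several
#' rows.
#'
#' @return data.frame, one row per (sample, abundant allele)
#' @export
honey_survey_abundant <- function() {
  utils::read.table(system.file("extdata", "honey12_abundant.tsv",
                                package = "csdhoney"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
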