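# Pairwise allele diversity: length difference plus amino-acid
# substitutions (delta-L + N_SAP) over globally aligned allele pairs.

#' Alignment scoring parameters for pairwise allele comparison
#'
#' Global (end-to-end) protein alignment under BLOSUM62 with affine gaps,
#' mirroring the default pairwise parameters of common interactive
#' alignment viewers.  Penalties are positive costs.
#'
#' @param matrix substitution matrix name (a matrix bundled with
#'   Biostrings) or an actual scoring matrix
#' @param gap_open gap opening cost
#' @param gap_ext gap extension cost (per gapped position)
#' @return list of class `diversity_scoring`
#' @export
diversity_scoring <- function(matrix = "BLOSUM62", gap_open = 12,
                              gap_ext = 2) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(ls(e)[1], envir = e)
  }
  structure(list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext),
            class = "diversity_scoring")
}

#' Length-plus-substitution diversity of one allele pair
#'
#' Aligns the two peptides globally and reports `delta_L`, the absolute
#' residue-length difference (alignment-independent), `n_sap`, the number
#' of aligned columns where both symbols are residues and differ (gapped
#' columns never count -- the length difference is captured once, via
#' `delta_L`), and their sum `total`.
#'
#' @param a,b peptide strings
#' @param scoring a `diversity_scoring` (defaults to BLOSUM62, 12/2)
#' @return list `delta_L`, `n_sap`, `total`
#' @export
pair_diversity <- function(a, b, scoring = diversity_scoring()) {
  stopifnot(nzchar(a), nzchar(b))
  delta_L <- abs(nchar(a) - nchar(b))
  if (a == b)
    return(list(delta_L = 0L, n_sap = 0L, total = 0L))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
    type = "global")
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  n_sap <- sum(pa != "-" & pb != "-" & pa != pb)
  list(delta_L = as.integer(delta_L), n_sap = as.integer(n_sap),
       total = as.integer(delta_L + n_sap))
}

#' Remove redundant (identical) peptides, preserving first-seen order
#' @param peptides character vector
#' @return character vector of unique peptides
#' @export
deduplicate <- function(peptides) unique(peptides)

#' All-pairs diversity within a set of alleles
#'
#' @param peptides character vector of unique peptides (deduplicated first
#'   if not)
#' @param scoring a `diversity_scoring`
#' @return long-format data.frame `a`, `b`, `delta_L`, `n_sap`, `total`
#'   over all C(n, 2) unordered pairs
#' @export
diversity_pairs <- function(peptides, scoring = diversity_scoring()) {
  peptides <- deduplicate(peptides)
  n <- length(peptides)
  if (n < 2L)
    return(data.frame(a = character(), b = character(), delta_L = integer(),
                      n_sap = integer(), total = integer()))
  # batch alignments per subject: all earlier peptides against peptide j
  blocks <- lapply(2:n, function(j) {
    pats <- peptides[seq_len(j - 1L)]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pats), Biostrings::AAString(peptides[j]),
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      type = "global")
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")
    pb <- strsplit(as.character(Biostrings::subject(aln)), "")
    n_sap <- mapply(function(x, y) sum(x != "-" & y != "-" & x != y),
                    pa, pb)
    dl <- abs(nchar(pats) - nchar(peptides[j]))
    data.frame(a = pats, b = peptides[j], delta_L = as.integer(dl),
               n_sap = as.integer(n_sap),
               total = as.integer(dl + n_sap), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

.summary_row <- function(scope, x_total, x_dl, n_alleles) {
  data.frame(scope = scope, n_alleles = n_alleles,
             n_pairs = length(x_total),
             mean_total = mean(x_total), sd_total = stats::sd(x_total),
             median_total = stats::median(x_total),
             min_total = min(x_total), max_total = max(x_total),
             mean_delta_L = mean(x_dl), sd_delta_L = stats::sd(x_dl),
             median_delta_L = stats::median(x_dl),
             stringsAsFactors = FALSE)
}

#' Global and within-sample diversity summaries
#'
#' Computes all-pairs diversity over the global unique allele set and,
#' separately, within each sample's own allele set.  Scopes with fewer
#' than two alleles yield a row of NA statistics (`undefined = TRUE`).
#'
#' @param peptides global unique peptide vector
#' @param sample_sets optional named list mapping sample id to its peptide
#'   vector
#' @param scoring a `diversity_scoring`
#' @return data.frame with one row per scope (`"global"` first)
#' @export
summarize_diversity <- function(peptides, sample_sets = NULL,
                                scoring = diversity_scoring()) {
  one_scope <- function(scope, peps) {
    peps <- deduplicate(peps)
    if (length(peps) < 2L) {
      row <- .summary_row(scope, NA_real_, NA_real_, length(peps))
      row$n_pairs <- 0L
      row$undefined <- TRUE
      return(row)
    }
    pd <- diversity_pairs(peps, scoring)
    row <- .summary_row(scope, pd$total, pd$delta_L, length(peps))
    row$undefined <- FALSE
    row
  }
  out <- one_scope("global", peptides)
  if (!is.null(sample_sets))
    for (s in names(sample_sets))
      out <- rbind(out, one_scope(s, sample_sets[[s]]))
  rownames(out) <- NULL
  out
}
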