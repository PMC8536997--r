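# Read-level processing: motif-anchored extraction, orientation
# normalization, trimming, per-base quality filtering, exact-identity
# clustering with a minimum-cluster-size filter, and translation.
#
# Reads are plain data frames (id, bases, quals) with qualities kept as
# Phred+33 strings; see read_fastq()/write_fastq().

#' Read a FASTQ file into a reads data frame
#'
#' Transparent to gzip.  Qualities are kept as Phred+33 encoded strings.
#'
#' @param path FASTQ file
#' @return data.frame with columns `id`, `bases`, `quals`
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = unname(names(x)),
             bases = unname(as.character(x)),
             quals = unname(as.character(S4Vectors::mcols(x)$qualities)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a reads data frame as FASTQ
#' @param reads data.frame with `id`, `bases`, `quals`
#' @param path output file (".gz" suffix gzips)
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$bases, "\n+\n", reads$quals),
             con, sep = "\n")
  invisible(path)
}

#' Phred scores of a quality string
#' @param quals Phred+33 string
#' @return integer vector of per-base scores
#' @export
phred_scores <- function(quals) utf8ToInt(quals) - 33L

#' Encode integer Phred scores as a quality string
#' @param scores integer vector
#' @keywords internal
phred_string <- function(scores) intToUtf8(scores + 33L)

.reverse_chr <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# leftmost 5' match and rightmost downstream (non-overlapping) 3' match,
# vectorized over sequences; NA where no ordered pair of anchors exists
.find_span <- function(seqs, p5, p3) {
  n <- length(seqs)
  out_s <- rep(NA_integer_, n)
  out_e <- rep(NA_integer_, n)
  m5 <- regexpr(p5, seqs, perl = TRUE)
  s5 <- as.integer(m5)
  l5 <- attr(m5, "match.length")
  hit <- which(s5 > 0L)
  if (length(hit)) {
    g3 <- gregexpr(p3, seqs[hit], perl = TRUE)
    for (k in seq_along(hit)) {
      i <- hit[k]
      s3 <- as.integer(g3[[k]])
      if (s3[1] == -1L) next
      e3 <- s3 + attr(g3[[k]], "match.length") - 1L
      ok <- s3 >= s5[i] + l5[i]
      if (any(ok)) {
        out_s[i] <- s5[i]
        out_e[i] <- max(e3[ok])
      }
    }
  }
  list(start = out_s, end = out_e)
}

#' Motif-anchored extraction and trimming of HVR-spanning reads
#'
#' Searches each read for a 5'-motif DNA match followed downstream by a
#' 3'-motif match, first in forward orientation, then (for reads without a
#' forward hit) in reverse complement.  Matching reads are trimmed from the
#' first base of the leftmost 5' match through the last base of the
#' rightmost downstream 3' match, motif codons included, with qualities
#' trimmed in register.  Reverse-complement hits are orientation-normalized
#' so all fragments read 5'->3' across the HVR.
#'
#' @param reads data.frame (`id`, `bases`, `quals`) as from [read_fastq()]
#' @param patterns a `motif_pattern_pair`
#' @return data.frame of fragments: `source_id`, `bases`, `quals`,
#'   `orientation` (`"forward"` or `"revcomp"`); zero rows if nothing matches
#' @export
scan_and_trim <- function(reads, patterns) {
  stopifnot(inherits(patterns, "motif_pattern_pair"))
  if (nrow(reads) == 0L)
    return(data.frame(source_id = character(), bases = character(),
                      quals = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  fw <- .find_span(reads$bases, patterns$pattern5_fwd, patterns$pattern3_fwd)
  fwd_hit <- which(!is.na(fw$start))
  frag_f <- data.frame(
    source_id = reads$id[fwd_hit],
    bases = substr(reads$bases[fwd_hit], fw$start[fwd_hit], fw$end[fwd_hit]),
    quals = substr(reads$quals[fwd_hit], fw$start[fwd_hit], fw$end[fwd_hit]),
    orientation = rep("forward", length(fwd_hit)),
    stringsAsFactors = FALSE)

  miss <- setdiff(seq_len(nrow(reads)), fwd_hit)
  frag_r <- NULL
  if (length(miss)) {
    rc_bases <- .revcomp_chr(reads$bases[miss])
    rc_quals <- .reverse_chr(reads$quals[miss])
    rv <- .find_span(rc_bases, patterns$pattern5_fwd, patterns$pattern3_fwd)
    rc_hit <- which(!is.na(rv$start))
    if (length(rc_hit))
      frag_r <- data.frame(
        source_id = reads$id[miss][rc_hit],
        bases = substr(rc_bases[rc_hit], rv$start[rc_hit], rv$end[rc_hit]),
        quals = substr(rc_quals[rc_hit], rv$start[rc_hit], rv$end[rc_hit]),
        orientation = rep("revcomp", length(rc_hit)),
        stringsAsFactors = FALSE)
  }
  out <- rbind(frag_f, frag_r)
  out[order(match(out$source_id, reads$id)), , drop = FALSE]
}

#' Per-base quality filter on trimmed fragments
#'
#' A fragment passes iff every position of its trimmed span has Phred
#' quality >= `qmin`.  The default Q >= 6 corresponds to a per-base error
#' probability below 25%.
#'
#' @param fragments fragment data.frame from [scan_and_trim()], or a single
#'   quality string
#' @param qmin minimum Phred score (inclusive)
#' @return logical vector, one element per fragment
#' @export
quality_pass <- function(fragments, qmin = 6L) {
  quals <- if (is.character(fragments)) fragments else fragments$quals
  if (any(!nzchar(quals))) stop("empty fragment")
  vapply(quals, function(q) min(utf8ToInt(q)) - 33L >= qmin, NA,
         USE.NAMES = FALSE)
}

#' Exact-identity clustering with a minimum cluster size
#'
#' Groups fragments by exact DNA string identity and discards clusters with
#' fewer than `min_cluster` members (residual low-quality sequences).
#'
#' @param fragments fragment data.frame (quality-passed)
#' @param min_cluster smallest retained cluster size (default 10; clusters
#'   with fewer reads are discarded, 10 itself is kept)
#' @return data.frame of clusters: `bases`, `member_count`, with member ids
#'   in the list column `member_ids`; ordered by decreasing count then bases
#' @export
cluster_and_filter <- function(fragments, min_cluster = 10L) {
  if (nrow(fragments) == 0L)
    return(data.frame(bases = character(), member_count = integer()))
  sp <- split(fragments$source_id, fragments$bases)
  cl <- data.frame(bases = names(sp),
                   member_count = lengths(sp),
                   stringsAsFactors = FALSE, row.names = NULL)
  cl$member_ids <- unname(sp)
  cl <- cl[cl$member_count >= min_cluster, , drop = FALSE]
  cl <- cl[order(-cl$member_count, cl$bases), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Translate a DNA string with the standard genetic code
#' @param bases DNA string over A/C/G/T, length a multiple of 3
#' @return peptide string (stop codons become `*`)
#' @keywords internal
translate_dna <- function(bases) {
  n <- nchar(bases)
  stopifnot(n %% 3L == 0L)
  codons <- substring(bases, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Translate cluster sequences, rejecting frame-shifted or ambiguous ones
#'
#' The motif anchor fixes the reading frame at position 0, so a fragment
#' length that is not a multiple of 3 indicates an indel inside the span
#' (`frame`); any N makes translation ambiguous (`ambiguous_base`); an
#' internal stop codon indicates a disrupted coding sequence (`stop`).
#'
#' @param clusters cluster data.frame from [cluster_and_filter()], or a
#'   character vector of DNA strings
#' @return the input with columns `peptide` (NA when rejected) and `reason`
#'   (`NA`, `"frame"`, `"ambiguous_base"` or `"stop"`)
#' @export
translate_cluster <- function(clusters) {
  if (is.character(clusters))
    clusters <- data.frame(bases = clusters, stringsAsFactors = FALSE)
  one <- function(b) {
    if (nchar(b) %% 3L != 0L) return(c(NA_character_, "frame"))
    if (grepl("[^ACGT]", b)) return(c(NA_character_, "ambiguous_base"))
    pep <- translate_dna(b)
    if (grepl("\\*", pep)) return(c(pep, "stop"))
    c(pep, NA_character_)
  }
  res <- vapply(clusters$bases, one, character(2), USE.NAMES = FALSE)
  clusters$peptide <- ifelse(is.na(res[2, ]) , res[1, ], NA_character_)
  clusters$reason <- res[2, ]
  clusters
}

#' Run the full read-level stage on one sample
#'
#' Chains [scan_and_trim()], [quality_pass()], [cluster_and_filter()] and
#' [translate_cluster()], keeping per-stage attrition tallies.
#'
#' @param reads reads data.frame or path to a FASTQ file
#' @param patterns a `motif_pattern_pair`
#' @param qmin minimum per-base Phred score on the trimmed span
#' @param min_cluster minimum cluster size
#' @return list with `clusters` (translated cluster data.frame),
#'   `tallies` (named counts per stage) and `rejections` (reason tallies)
#' @export
process_reads <- function(reads, patterns, qmin = 6L, min_cluster = 10L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  frags <- scan_and_trim(reads, patterns)
  qc <- if (nrow(frags)) frags[quality_pass(frags, qmin), , drop = FALSE]
        else frags
  cl <- cluster_and_filter(qc, min_cluster)
  cl <- translate_cluster(cl)
  ok <- !is.na(cl$peptide)
  list(
    clusters = cl,
    tallies = c(input = nrow(reads), trimmed = nrow(frags),
                quality_passed = nrow(qc),
                clustered_reads = sum(cl$member_count),
                translated_reads = sum(cl$member_count[ok])),
    rejections = table(factor(cl$reason[!ok],
                              levels = c("frame", "ambiguous_base", "stop")))
  )
}
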