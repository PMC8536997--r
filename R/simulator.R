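# Synthetic honey-eDNA amplicon generator with colony-level ground truth.
#
# A colony contributes the queen's two distinct alleles, one allele per
# patriline (queens mate with many drones; 7-20 patrilines are typical),
# and optionally a few low-abundance alleles from drifted workers.  HVR
# alleles are A/T-rich repeats encoding mostly asparagine (N) and tyrosine
# (Y) between the conserved flanks.  The read error model is
# semiconductor-style: random substitutions plus homopolymer-length indels
# whose probability grows with run length.
#
# All randomness flows from R's RNG stream; top-level entry points accept a
# seed.

#' Residue weights of the HVR repeat region
#'
#' N and Y dominate the repeat region; the remainder is shared by the
#' residues commonly observed between the flanks.
#' @param n,y weights of asparagine and tyrosine
#' @param others residues sharing the remaining mass equally
#' @return named numeric vector summing to 1
#' @export
repeat_weights <- function(n = 0.45, y = 0.30,
                           others = c("S", "K", "H", "T", "C", "Q", "L",
                                      "I", "P")) {
  w <- c(N = n, Y = y, stats::setNames(rep((1 - n - y) / length(others),
                                           length(others)), others))
  if (any(w < 0)) stop("invalid weights")
  w / sum(w)
}

# most A/T-rich codon of a residue, with deterministic tie-break (AAT for
# N, TAT for Y under the standard code)
.at_rich_codon <- function(aa) {
  cod <- codons_for(aa)
  at <- vapply(strsplit(cod, ""), function(x) sum(x %in% c("A", "T")), 0L)
  sort(cod[at == max(at)])[1]
}

#' Generate one synthetic HVR allele (peptide and DNA encoding)
#'
#' The peptide is 5' motif + repeat region + 3' motif; the repeat region is
#' drawn from [repeat_weights()].  The DNA encoding picks, per residue, the
#' most A/T-rich codon with probability `at_bias` and a uniform codon
#' otherwise, reproducing the A/T-rich repeat structure of the locus.
#'
#' @param length_range total peptide length range in residues (inclusive),
#'   within `[30, 60]`
#' @param weights repeat-region residue weights
#' @param motif5,motif3 flank residue strings
#' @param at_bias probability of choosing the most A/T-rich codon
#' @return list `peptide`, `dna`
#' @export
generate_allele <- function(length_range = c(35, 53),
                            weights = repeat_weights(),
                            motif5 = "KIIS", motif3 = "IEQIP",
                            at_bias = 0.8) {
  stopifnot(length_range[1] >= 30, length_range[2] <= 60,
            length_range[1] <= length_range[2])
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("invalid weights")
  flank_len <- nchar(motif5) + nchar(motif3)
  len <- sample(length_range[1]:length_range[2], 1L)
  rep_len <- len - flank_len
  stopifnot(rep_len > 0)
  rep_res <- sample(names(weights), rep_len, replace = TRUE, prob = weights)
  peptide <- paste0(motif5, paste(rep_res, collapse = ""), motif3)
  dna <- vapply(strsplit(peptide, "")[[1]], function(aa) {
    cod <- codons_for(aa)
    if (stats::runif(1) < at_bias) .at_rich_codon(aa)
    else cod[sample.int(length(cod), 1L)]
  }, "")
  list(peptide = peptide, dna = paste(dna, collapse = ""))
}

#' Simulate one colony's allele set and abundances
#'
#' The queen carries two distinct alleles that jointly receive
#' `queen_share` of the abundance (split near-evenly); each patriline
#' contributes one allele, with proportions drawn from a symmetric
#' Dirichlet (low concentration produces the realistic skew of many rare
#' patrilines); drifted-worker alleles, when present, share a small fixed
#' abundance.  Alleles may be drawn from a shared population pool so that
#' colonies overlap, or generated fresh.  All peptides within a colony are
#' distinct.
#'
#' @param sample_id colony/sample identifier
#' @param n_patrilines number of patrilines (default: one draw from 7-20)
#' @param pool optional population pool: list of `generate_allele()`
#'   outputs shared across colonies
#' @param pool_prob probability that an allele is drawn from the pool
#'   rather than generated fresh (ignored without a pool)
#' @param queen_share abundance fraction of the queen's two alleles
#' @param concentration symmetric Dirichlet concentration of patriline
#'   proportions
#' @param n_drift number of drifted-worker alleles (default: 0-2 at random)
#' @param drift_fraction combined abundance of drift alleles (< 0.05)
#' @param ... passed to [generate_allele()]
#' @return object of class `colony_truth`: `sample_id`, `queen_alleles`,
#'   `patriline_alleles`, `drift_alleles` (peptides), `abundance` and `dna`
#'   (named by peptide)
#' @export
simulate_colony <- function(sample_id, n_patrilines = NULL, pool = NULL,
                            pool_prob = 0.5, queen_share = 0.5,
                            concentration = 0.8, n_drift = NULL,
                            drift_fraction = 0.03, ...) {
  if (is.null(n_patrilines)) n_patrilines <- sample(7:20, 1L)
  if (n_patrilines < 1L) stop("n_patrilines must be >= 1")
  if (is.null(n_drift)) n_drift <- sample(0:2, 1L)
  if (n_drift == 0L) drift_fraction <- 0
  stopifnot(drift_fraction < 0.05, queen_share > 0, queen_share < 1)

  seen <- character()
  draw <- function() {
    for (try in 1:50) {
      al <- if (!is.null(pool) && stats::runif(1) < pool_prob)
        pool[[sample.int(length(pool), 1L)]]
      else generate_allele(...)
      if (!(al$peptide %in% seen)) {
        seen <<- c(seen, al$peptide)
        return(al)
      }
    }
    stop("could not draw a distinct allele after 50 attempts")
  }
  queen <- list(draw(), draw())
  pat <- replicate(n_patrilines, draw(), simplify = FALSE)
  drift <- if (n_drift > 0L) replicate(n_drift, draw(), simplify = FALSE)
           else list()

  qsplit <- stats::rbeta(1, 10, 10)
  q_ab <- queen_share * c(qsplit, 1 - qsplit)
  g <- stats::rgamma(n_patrilines, shape = concentration)
  p_ab <- (1 - queen_share - drift_fraction) * g / sum(g)
  d_ab <- if (n_drift > 0L) rep(drift_fraction / n_drift, n_drift)
          else numeric()

  all_alleles <- c(queen, pat, drift)
  peps <- vapply(all_alleles, `[[`, "", "peptide")
  structure(list(
    sample_id = sample_id,
    queen_alleles = peps[1:2],
    patriline_alleles = peps[2L + seq_len(n_patrilines)],
    drift_alleles = if (n_drift > 0L)
      peps[2L + n_patrilines + seq_len(n_drift)] else character(),
    abundance = stats::setNames(c(q_ab, p_ab, d_ab), peps),
    dna = stats::setNames(vapply(all_alleles, `[[`, "", "dna"), peps)
  ), class = "colony_truth")
}

#' @export
print.colony_truth <- function(x, ...) {
  cat("<colony_truth ", x$sample_id, "> ", length(x$abundance),
      " alleles (2 queen, ", length(x$patriline_alleles), " patriline, ",
      length(x$drift_alleles), " drift)\n", sep = "")
  invisible(x)
}

#' Semiconductor-style sequencing error model
#'
#' @param substitution_rate per-base substitution probability
#' @param hp_indel_rate per-homopolymer-run indel probability at run
#'   length 1
#' @param hp_exponent multiplier of the indel probability per extra run
#'   base: a run of length L has indel probability
#'   `min(1, hp_indel_rate * hp_exponent^(L-1))`
#' @param qual_mean,qual_sd Phred score distribution of correct bases
#'   (clipped to 6-40, so error-free reads always pass the default
#'   per-base filter)
#' @param err_qual_mean,err_qual_sd lower-quality distribution used for
#'   erroneous bases (clipped to 2-40)
#' @return list of class `error_model`
#' @export
error_model <- function(substitution_rate = 0.005, hp_indel_rate = 0.005,
                        hp_exponent = 2, qual_mean = 30, qual_sd = 5,
                        err_qual_mean = 10, err_qual_sd = 3) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            hp_indel_rate >= 0, hp_indel_rate < 1)
  structure(as.list(environment()), class = "error_model")
}

.BASES <- c("A", "C", "G", "T")

# apply the error model to n copies of one template; returns list of
# per-read base vectors and quality vectors
.mutate_template <- function(template, n, em) {
  tv <- strsplit(template, "")[[1]]
  L <- length(tv)
  r <- rle(tv)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_p <- pmin(1, em$hp_indel_rate * em$hp_exponent^(r$lengths - 1L))

  reads <- vector("list", n)
  quals <- vector("list", n)
  nsub <- stats::rbinom(n, L, em$substitution_rate)
  hp_mask <- matrix(stats::runif(length(run_p) * n) < run_p,
                    nrow = length(run_p))
  for (i in seq_len(n)) {
    b <- tv
    # correct bases are floored at Q6 (erroneous ones may go down to Q2):
    # a faithfully sequenced base below the retention threshold would make
    # even error-free reads fail the per-base filter
    q <- pmin(40L, pmax(6L, as.integer(round(
      stats::rnorm(L, em$qual_mean, em$qual_sd)))))
    if (nsub[i] > 0L) {
      pos <- sample.int(L, nsub[i])
      b[pos] <- vapply(b[pos], function(x)
        sample(setdiff(.BASES, x), 1L), "")
      q[pos] <- pmin(40L, pmax(2L, as.integer(round(
        stats::rnorm(nsub[i], em$err_qual_mean, em$err_qual_sd)))))
    }
    ev <- which(hp_mask[, i])
    if (length(ev)) {
      lowq <- function(k) pmin(40L, pmax(2L, as.integer(round(
        stats::rnorm(k, em$err_qual_mean, em$err_qual_sd)))))
      for (j in rev(ev)) {                  # right-to-left keeps indices valid
        s <- run_start[j]
        if (stats::runif(1) < 0.5) {        # insertion: duplicate run base
          b <- append(b, b[s], after = s)
          q <- append(q, lowq(1L), after = s)
        } else {                            # deletion of one run base
          b <- b[-s]
          q <- q[-s]
          if (length(q) >= s) q[s] <- lowq(1L)
        }
      }
    }
    reads[[i]] <- b
    quals[[i]] <- q
  }
  list(bases = reads, quals = quals)
}

#' Simulate amplicon reads from a colony
#'
#' Each read draws its source allele from the colony's abundance
#' multinomial, embeds the allele's DNA encoding between short primer
#' context strings, applies the error model, receives per-base qualities
#' (erroneous bases drawn from a lower-quality distribution), and is
#' reverse-complemented with probability 1/2.
#'
#' @param truth a `colony_truth`
#' @param n_reads number of reads
#' @param em an [error_model()]
#' @param context5,context3 fixed flanking context (set `""` for none)
#' @return reads data.frame (`id`, `bases`, `quals`) as accepted by
#'   [process_reads()]
#' @export
simulate_reads <- function(truth, n_reads, em = error_model(),
                           context5 = "GATCACGTTC", context3 = "TGAACGTGAT") {
  stopifnot(inherits(truth, "colony_truth"), n_reads >= 1L)
  peps <- names(truth$abundance)
  src <- sample(seq_along(peps), n_reads, replace = TRUE,
                prob = truth$abundance)
  counts <- tabulate(src, nbins = length(peps))
  bases <- character(n_reads)
  quals <- character(n_reads)
  idx_of <- split(seq_len(n_reads), src)
  for (ai in names(idx_of)) {
    a <- as.integer(ai)
    template <- paste0(context5, truth$dna[[a]], context3)
    mt <- .mutate_template(template, length(idx_of[[ai]]), em)
    bases[idx_of[[ai]]] <- vapply(mt$bases, paste, "", collapse = "")
    quals[idx_of[[ai]]] <- vapply(mt$quals, phred_string, "")
  }
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) {
    bases[flip] <- .revcomp_chr(bases[flip])
    quals[flip] <- .reverse_chr(quals[flip])
  }
  data.frame(
    id = sprintf("%s_read%06d_%s", truth$sample_id, seq_len(n_reads),
                 gsub("[^A-Za-z0-9]", "", substr(peps[src], 5, 10))),
    bases = bases, quals = quals, stringsAsFactors = FALSE)
}

#' Simulate a multi-sample honey dataset with a shared allele pool
#'
#' Builds a population pool of alleles, simulates one colony per sample
#' (drawing from the pool so that alleles recur across samples), and
#' generates reads per colony.
#'
#' @param n_samples number of honey samples/colonies
#' @param n_reads reads per sample (scalar or vector)
#' @param pool_size size of the shared population allele pool
#' @param seed integer seed applied before any randomness
#' @param em an [error_model()]
#' @param ... passed to [simulate_colony()]
#' @return list with `truths` (list of `colony_truth`), `reads` (named
#'   list of reads data.frames) and `pool`
#' @export
simulate_dataset <- function(n_samples = 12L, n_reads = 20000L,
                             pool_size = 40L, seed = NULL,
                             em = error_model(), ...) {
  if (!is.null(seed)) set.seed(seed)
  pool <- replicate(pool_size, generate_allele(), simplify = FALSE)
  ids <- sprintf("S%02d", seq_len(n_samples))
  n_reads <- rep_len(n_reads, n_samples)
  truths <- list()
  reads <- list()
  for (i in seq_len(n_samples)) {
    truths[[ids[i]]] <- simulate_colony(ids[i], pool = pool, ...)
    reads[[ids[i]]] <- simulate_reads(truths[[ids[i]]], n_reads[i], em)
  }
  list(truths = truths, reads = reads, pool = pool)
}

#' Serialize colony ground truth to a manifest TSV and an allele FASTA
#'
#' @param truths list of `colony_truth`
#' @param dir output directory (created if needed)
#' @return paths of the written manifest and FASTA (invisible)
#' @export
write_truth <- function(truths, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(truths, function(tr) data.frame(
    sample_id = tr$sample_id,
    queen_alleles = paste(tr$queen_alleles, collapse = ";"),
    patriline_alleles = paste(tr$patriline_alleles, collapse = ";"),
    drift_alleles = paste(tr$drift_alleles, collapse = ";"),
    abundance = paste(signif(tr$abundance, 10), collapse = ";"),
    stringsAsFactors = FALSE))
  manifest <- file.path(dir, "truth_manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "truth_alleles.fasta")
  lines <- unlist(lapply(truths, function(tr)
    as.vector(rbind(sprintf(">%s|%s|%.6g", tr$sample_id,
                            names(tr$abundance), tr$abundance),
                    names(tr$abundance)))))
  writeLines(lines, fa)
  invisible(c(manifest = manifest, fasta = fa))
}

#' Read a truth manifest back
#' @param path manifest TSV from [write_truth()]
#' @return list of `colony_truth`-shaped lists (without DNA encodings)
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    split_field <- function(x) if (nzchar(x)) strsplit(x, ";")[[1]]
                               else character()
    queen <- split_field(df$queen_alleles[i])
    pat <- split_field(df$patriline_alleles[i])
    drift <- split_field(df$drift_alleles[i])
    ab <- as.numeric(split_field(df$abundance[i]))
    list(sample_id = df$sample_id[i], queen_alleles = queen,
         patriline_alleles = pat, drift_alleles = drift,
         abundance = stats::setNames(ab, c(queen, pat, drift)))
  })
}
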