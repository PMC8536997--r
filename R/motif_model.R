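# Conserved flanking motifs of the csd HVR and their DNA-level search patterns.
#
# The hypervariable region is bracketed by short, highly conserved runs of
# residues (classically "KIIS" upstream and "IEQIP" downstream).  Reads are
# located by searching, at the DNA level, for any codon spelling of those
# residue runs, in both orientations.

#' The twenty standard amino-acid letters
#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.gap_chars <- c("-", ".")

#' Codons of the standard genetic code encoding an amino acid
#' @param aa single upper-case amino-acid letter
#' @return character vector of codons (over A/C/G/T)
#' @keywords internal
codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  cod <- names(gc)[gc == aa]
  if (length(cod) == 0L)
    stop("no codon in the standard genetic code for residue '", aa, "'")
  cod
}

#' Construct a flanking-motif object
#'
#' A `flank_motif` is an ordered list of residue sets: position `i` of the
#' motif may be occupied by any residue in `positions[[i]]`.  Degenerate
#' positions (sets with more than one residue) arise when the reference
#' alignment is polymorphic at a flank column (e.g. KIIS / KITS variants).
#'
#' @param positions list of character vectors, one per motif position; each
#'   a non-empty subset of the 20 standard amino-acid letters
#' @param side `"5prime"` or `"3prime"`
#' @return object of class `flank_motif`
#' @export
flank_motif <- function(positions, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  if (!is.list(positions) || length(positions) < 3L)
    stop("a flank motif needs at least 3 positions")
  positions <- lapply(positions, function(p) {
    p <- unique(toupper(as.character(p)))
    if (length(p) == 0L || !all(p %in% AA_STANDARD))
      stop("each motif position must be a non-empty set of standard residues")
    sort(p)
  })
  structure(list(side = side, positions = positions), class = "flank_motif")
}

#' Build a motif of singleton positions from a peptide string
#' @param peptide residue string, e.g. `"KIIS"`
#' @param side `"5prime"` or `"3prime"`
#' @return `flank_motif`
#' @export
motif_from_string <- function(peptide, side = c("5prime", "3prime")) {
  flank_motif(as.list(strsplit(toupper(peptide), "")[[1]]), match.arg(side))
}

#' @export
print.flank_motif <- function(x, ...) {
  pos <- vapply(x$positions, function(p)
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]"), "")
  cat("<flank_motif ", x$side, "> ", paste(pos, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Motif width in residues
#' @param motif a `flank_motif`
#' @export
motif_width <- function(motif) length(motif$positions)

#' Infer the conserved 5' and 3' flanking motifs from a protein alignment
#'
#' Reads the first `flank_width5` and last `flank_width3` informative
#' (non-gap-majority) columns of a protein multiple alignment, and admits at
#' each position every residue observed in at least `consensus_fraction` of
#' the non-gap rows of that column.  A permissive default fraction keeps
#' genuine low-frequency flank variants (KITS-initial alleles are observed
#' in real data) inside the motif.
#'
#' @param msa an `AAStringSet`, a character vector of equal-length aligned
#'   rows, or the path to an aligned protein FASTA file
#' @param flank_width5,flank_width3 number of motif positions on each side
#' @param consensus_fraction minimum column frequency (over non-gap rows)
#'   for a residue to enter the position's set
#' @param max_gap_fraction columns whose gap fraction exceeds this value are
#'   treated as alignment artifacts and skipped when locating flanks
#' @return list with elements `motif5` and `motif3` (`flank_motif` objects)
#' @examples
#' aln <- rep("KIISNNYIEQIP", 5)
#' m <- infer_flank_motifs(aln, flank_width5 = 4, flank_width3 = 5)
#' m$motif5
#' @export
infer_flank_motifs <- function(msa, flank_width5 = 4L, flank_width3 = 5L,
                               consensus_fraction = 0.05,
                               max_gap_fraction = 0.5) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  rows <- toupper(as.character(msa))
  if (length(rows) == 0L) stop("empty alignment")
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment: rows differ in length")
  if (flank_width5 < 3L || flank_width3 < 3L)
    stop("flank widths must be >= 3")
  mat <- do.call(rbind, strsplit(rows, ""))
  gap_frac <- colMeans(matrix(mat %in% .gap_chars, nrow = nrow(mat)))
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) < flank_width5 + flank_width3)
    stop("alignment has too few informative columns for the requested flanks")

  column_set <- function(j) {
    col <- mat[, j]
    col <- col[!(col %in% .gap_chars)]
    frq <- table(col) / length(col)
    res <- names(frq)[frq >= consensus_fraction]
    res <- res[res %in% AA_STANDARD]
    if (length(res) == 0L)
      stop("no standard residue reaches the consensus fraction in column ", j)
    res
  }
  pos5 <- lapply(keep[seq_len(flank_width5)], column_set)
  pos3 <- lapply(keep[length(keep) - rev(seq_len(flank_width3)) + 1L],
                 column_set)
  list(motif5 = flank_motif(pos5, "5prime"),
       motif3 = flank_motif(pos3, "3prime"))
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Compile a flanking motif into a DNA search pattern
#'
#' Enumerates, per motif position, every standard-genetic-code codon of the
#' position's residue set and joins the positions into a regular expression.
#' A DNA substring matches the forward pattern iff its in-frame translation
#' lies in the motif's residue-set product; the `revcomp` pattern matches
#' reverse-complement encodings (codons reverse-complemented, position order
#' reversed).  Both serine codon boxes (TCN and AGY) are admitted.
#'
#' @param motif a `flank_motif`
#' @param orientation `"forward"` or `"revcomp"`
#' @return single regular-expression string (use with `perl = TRUE`)
#' @examples
#' peptide_motif_to_dna_pattern(motif_from_string("M", "5prime"))
#' @export
peptide_motif_to_dna_pattern <- function(motif,
                                         orientation = c("forward", "revcomp")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(motif, "flank_motif"))
  codon_sets <- lapply(motif$positions, function(res)
    sort(unique(unlist(lapply(res, codons_for)))))
  if (orientation == "revcomp") {
    codon_sets <- rev(lapply(codon_sets, function(cs) sort(.revcomp_chr(cs))))
  }
  groups <- vapply(codon_sets, function(cs)
    paste0("(?:", paste(cs, collapse = "|"), ")"), "")
  paste(groups, collapse = "")
}

#' Compile a motif into a peptide-level regular expression
#' @param motif a `flank_motif`
#' @return regex matching exactly the motif's residue-set product
#' @keywords internal
motif_peptide_regex <- function(motif) {
  paste(vapply(motif$positions, function(p)
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]"), ""),
    collapse = "")
}

#' Build the four compiled search patterns for a motif pair
#'
#' @param motif5,motif3 `flank_motif` objects for the 5' and 3' flank
#' @return object of class `motif_pattern_pair` with DNA patterns
#'   `pattern5_fwd`, `pattern3_fwd`, `pattern5_rc`, `pattern3_rc`, the two
#'   source motifs, and anchored peptide-level regexes used by allele QC
#' @export
build_pattern_pair <- function(motif5, motif3) {
  stopifnot(inherits(motif5, "flank_motif"), inherits(motif3, "flank_motif"))
  structure(list(
    pattern5_fwd = peptide_motif_to_dna_pattern(motif5, "forward"),
    pattern3_fwd = peptide_motif_to_dna_pattern(motif3, "forward"),
    pattern5_rc  = peptide_motif_to_dna_pattern(motif5, "revcomp"),
    pattern3_rc  = peptide_motif_to_dna_pattern(motif3, "revcomp"),
    motif5 = motif5, motif3 = motif3,
    peptide5_regex = paste0("^", motif_peptide_regex(motif5)),
    peptide3_regex = paste0(motif_peptide_regex(motif3), "$")
  ), class = "motif_pattern_pair")
}

#' @export
print.motif_pattern_pair <- function(x, ...) {
  cat("<motif_pattern_pair>\n")
  print(x$motif5); print(x$motif3)
  invisible(x)
}

#' Serialize a motif pattern pair to JSON
#' @param pair a `motif_pattern_pair`
#' @param path output file
#' @export
write_pattern_pair <- function(pair, path) {
  stopifnot(inherits(pair, "motif_pattern_pair"))
  obj <- list(motif5 = pair$motif5$positions, motif3 = pair$motif3$positions)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' Read a motif pattern pair back from JSON
#' @param path JSON file written by [write_pattern_pair()]
#' @return `motif_pattern_pair`
#' @export
read_pattern_pair <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_pattern_pair(flank_motif(as.list(obj$motif5), "5prime"),
                     flank_motif(as.list(obj$motif3), "3prime"))
}

#' The classical csd HVR flank motifs (KIIS / IEQIP)
#'
#' Convenience constructor for the exemplar conserved flanks; real analyses
#' should prefer [infer_flank_motifs()] on a reference alignment so that
#' observed flank variants (e.g. KITS) are admitted.
#' @return `motif_pattern_pair`
#' @export
default_pattern_pair <- function() {
  build_pattern_pair(motif_from_string("KIIS", "5prime"),
                     motif_from_string("IEQIP", "3prime"))
}
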