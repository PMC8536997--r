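# Shared fixtures: deterministic reverse translation, quality strings and
# read construction used across test files.

# one fixed DNA encoding of a peptide (first codon of the standard code)
rev_translate <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(peptide, "")[[1]],
               function(aa) names(gc)[gc == aa][1], ""), collapse = "")
}

# constant-quality string (default Q40)
qual40 <- function(n, q = 40L) strrep(intToUtf8(q + 33L), n)

make_read <- function(id, bases, q = 40L) {
  data.frame(id = id, bases = bases, quals = qual40(nchar(bases), q),
             stringsAsFactors = FALSE)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# random HVR-ish peptide over the repeat alphabet, KIIS/IEQIP flanks
random_peptide <- function(len_mid = sample(3:8, 1)) {
  mid <- paste(sample(c("N", "Y", "S", "K", "I", "T", "H"), len_mid,
                      replace = TRUE), collapse = "")
  paste0("KIIS", mid, "IEQIP")
}

# a small error-free colony with controlled even-ish abundances
toy_colony <- function(sample_id = "S1", n_pat = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_colony(sample_id, n_patrilines = n_pat, queen_share = 0.5,
                  concentration = 5, n_drift = 0)
}

no_error <- function() error_model(substitution_rate = 0, hp_indel_rate = 0)
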