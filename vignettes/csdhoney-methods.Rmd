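---
title: "Calling csd HVR alleles from honey eDNA amplicons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling csd HVR alleles from honey eDNA amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdhoney)
```

## The problem

Honey carries trace DNA of the bees that produced it.  Amplicon sequencing
of the *complementary sex determiner* (*csd*) hypervariable region (HVR)
from this environmental DNA can reveal, in a single assay, most of the
*csd* alleles segregating in a colony: the queen's two alleles, one allele
per patriline (queens mate with on the order of 7–20 drones), and
occasionally alleles from drifted workers.  Because *csd* heterozygosity is
what makes a fertilized egg develop into a female, the number and
distribution of HVR alleles is a direct readout of the sex-locus diversity
that colony viability depends on.

The difficulty is that the HVR is an A/T-rich repeat — it encodes mostly
asparagine (N) and tyrosine (Y) between two conserved flanks — and
semiconductor sequencing chemistry makes homopolymer-length errors exactly
in such regions.  The pipeline in this package is built around that error
structure: it works at the protein level, where frame-disrupting indels
announce themselves as frame shifts and premature stops.

## Pipeline model

1. **Motif anchoring** (`infer_flank_motifs()`, `build_pattern_pair()`).
   The conserved flanks (classically `KIIS` upstream, `IEQIP` downstream)
   are read off a reference protein alignment: the first/last informative
   columns, admitting any residue at frequency ≥ `consensus_fraction`
   (default 0.05).  The permissive default is deliberate — real allele sets
   contain `KITS`-initial variants, and a motif that excluded them would
   silently drop entire alleles.  Each motif is compiled into a DNA regular
   expression enumerating every codon spelling (both serine boxes
   included), in forward and reverse-complement orientation.
2. **Read processing** (`process_reads()`).  Reads are searched in forward
   orientation first, then reverse complement.  Trimming spans the
   leftmost 5′ match through the rightmost downstream 3′ match, motifs
   included — maximal-span trimming is deterministic and favours
   full-length HVRs when the repeat region happens to contain a spurious
   interior match.  Trimmed fragments must have Phred ≥ 6 at every
   position (a ≤ 25% per-base error probability).  Fragments are then
   clustered by exact string identity and clusters with fewer than 10
   reads are discarded; surviving clusters are translated from the motif
   anchor (frame 0), rejecting frame shifts, ambiguous bases and stops.
3. **Allele QC** (`apply_qc()`, `derive_threshold()`).  A peptide is a
   functional allele iff it carries both flanks without a stop, and either
   occurs in ≥ 2 samples (any abundance) or occurs in one sample with
   relative abundance *strictly above* a threshold.  The threshold is
   re-derived from the data — the median over multi-sample alleles of
   their minimum within-sample abundance — because it is defined as a
   statistic of the dataset at hand; 0.0164 (its value in the original
   12-sample survey) is the fallback when no allele is shared, and a fixed
   override is available.  Relative abundance is computed over reads
   coding for alleles (post cluster filter and translation), not raw
   reads.
4. **Rarefaction** (`rarefy()`).  Allele richness versus the percentage of
   reads subsampled without replacement, averaged over 100 replicates.
   Allele labels are fixed by the full-data call; the 10-read cluster
   filter is *not* re-applied within subsamples, because re-running
   clustering at reduced depth would change the meaning of the filter —
   the curve then measures sampling effort, not a depth-dependent QC.
5. **Diversity** (`pair_diversity()`).  For each allele pair, the index is
   ΔL (absolute residue-length difference) plus N_SAP (aligned residue
   pairs that differ), from a global alignment under BLOSUM62 with gap
   open 12 / extend 2 — the default pairwise parameters of the common
   interactive viewer this analysis is usually run in; they are
   configurable because "default parameters" is the only published
   anchor.  Gapped columns never count towards N_SAP: the length
   difference is already captured, once, by ΔL.
6. **Sample similarity** (`sample_similarity()`).  Presence/absence matrix
   over the allele union; Jaccard index J; hierarchical clustering of
   1 − J under single and complete linkage; classical (Torgerson) MDS; and
   logistic PCA for the binary matrix itself.

## Logistic PCA

Binary presence/absence data sit poorly with ordinary PCA, so the package
fits the natural-parameter logistic PCA model: saturated natural
parameters are represented as `m·(2X − 1)`, feature offsets and a rank-k
projection are estimated by minimising the Bernoulli deviance via
majorize–minimize with the quadratic bound 1/4 on the logistic curvature.
The deviance is non-increasing across iterations *by construction* — the
test suite asserts this on random matrices, and a violation would indicate
a bug, not a data property.  The scale `m` is fixed (default 4) rather
than cross-validated: a fixed scale keeps results deterministic, and only
qualitative groupings of samples are interpreted downstream.  Scores are
bounded because the saturated parameters are.

## The simulator's stated world

`simulate_colony()` / `simulate_reads()` encode the biology the pipeline
is meant to face, with defaults chosen once from what is known about
managed colonies:

| parameter | default | rationale |
|---|---|---|
| patrilines per colony | drawn from 7–20 | microsatellite estimates of effective mating number |
| queen-allele share | 0.5, split ~evenly between her 2 alleles | two maternal alleles expected to dominate; amplification bias is emulated by lowering it |
| patriline proportions | symmetric Dirichlet, concentration 0.8 | many patrilines at very low frequency |
| drifted-worker alleles | 0–2, jointly < 5% | drift rates reported for mainland apiaries |
| allele length | 35–53 residues, motifs included | observed HVR length range |
| repeat composition | N 45%, Y 30%, remainder shared | N/Y-dominated repeat with minor residues |
| substitution rate | 0.5%/base | stand-in; the platform's rates are not published for this assay |
| homopolymer indel | 0.5% per run, ×2 per extra run base | semiconductor error growth with run length |
| qualities | correct bases N(30, 5) clipped to [6, 40]; error bases N(10, 3) clipped to [2, 40] | errors carry low quality; a *correct* base below the Q6 retention floor would make error-free reads fail the filter, so the correct-base floor sits at the threshold |

What a green test establishes: that motif anchoring, trimming,
translation-level QC, the threshold rule and the downstream statistics
recover a known allele configuration under this error process.  What it
does not establish: robustness to PCR chimeras, amplification bias
correlated with allele length (observed in real data as single dominant
short alleles), template degradation, or flow-space error correlations —
none of which the simulator models.

Default read depth in examples is thousands of reads per sample, far
below real runs (10³–10⁵); tests scale depth down further.  The
properties tested are depth-independent, and rarefaction behaviour is
asserted qualitatively (plateau before 100%), not at the published
percentages, which depend on real depth.

## Numerical choices and tie-breaks

* **Strictness**: the single-sample abundance criterion is strictly
  greater-than; an allele exactly at the threshold is discarded.  The
  10-read cluster filter discards *fewer than* 10; a 10-read cluster
  survives.  Q ≥ 6 is inclusive.
* **Alignment ties**: co-optimal global alignments can disagree on N_SAP.
  The implementation reports the alignment chosen by its traceback; the
  test suite checks reported values against the *set* of N_SAP values
  over all co-optimal alignments (enumerated independently by dynamic
  programming) and requires exact agreement whenever that set is a
  singleton.  About 2–4% of random short pairs are ambiguous; published
  global means may shift by ±1 under other sensible scorings.
* **Clustering ties**: among pairs at equal minimum distance the
  lexicographically smallest (row, column) pair merges first, making
  dendrograms reproducible; heights match `stats::hclust` on tie-free
  input.
* **Orientation ties**: a read matching in both orientations (pathological)
  uses the forward hit.
* **Ambiguity**: any N inside the trimmed span rejects the cluster at
  translation (`ambiguous_base`); the published procedure is silent on
  ambiguous bases, and admitting them would require degenerate-codon
  translation for no benefit.
* **Degenerate MDS**: an all-zero dissimilarity matrix embeds to all-zero
  coordinates; missing positive eigenvalues zero-pad.

## Known limitations

* Length reporting is motif-inclusive.  The published per-allele range
  (35–53 residues) is mostly consistent with motif-inclusive counting,
  but at least one published abundant allele is 30 residues on that
  convention — the discrepancy is surfaced here rather than resolved, and
  the simulator's default range keeps the published bounds.
* Novelty is exact peptide membership in a user-supplied reference set; a
  remote database search (version-dependent, network-dependent) is out of
  scope, so "novel" means "not in the provided FASTA".
* Exact-identity clustering plus per-base error means retention percent
  falls quickly with read length and error rate; with the default error
  stand-ins, simulated retention sits near 30–40%, below the ~75%
  observed in the real survey — consistent with the real platform's
  effective error rate differing from the stand-ins.  Retention of 100%
  is recovered exactly in the zero-error limit.
* Synthetic allele sets are i.i.d. draws, so their pairwise diversity
  (mean ≈ 22) is higher than in real populations (mean ≈ 12) where
  alleles share descent; tests therefore never assert real-data diversity
  means against simulated sets.
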