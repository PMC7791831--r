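---
title: "Detecting m6A at single-read resolution from segmented nanopore signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting m6A at single-read resolution from segmented nanopore signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Direct RNA nanopore sequencing reads native RNA molecules, so the ionic
current carries the marks of base modifications.  N6-methyladenosine
(m6A) sits almost exclusively in RRACH motifs (R = A/G, H = A/C/U); the
degenerate motif expands to twelve concrete 5-mers.  When the raw
current of a read has been segmented and assigned to reference bases
(re-squiggling), a methylated central A changes the level, spread and
dwell of its segment relative to the unmethylated case.

`nanostoich` turns this into per-read, per-site calls in four steps:

1. **Normalization.**  Every read is normalized on its own pooled raw
   samples by the median shift and the (unscaled) median absolute
   deviation.  The MAD carries no 1.4826 consistency factor — the method
   names the robust scale itself, not a standard-deviation estimate.
   An all-constant read would have MAD 0; it falls back to scale 1 and
   is flagged rather than dropped.
2. **Features.**  For every RRACH window fully contained in a read, the
   five bases contribute four statistics each — mean, median,
   population standard deviation (divide by *n*), and dwell (number of
   raw samples) — giving a 20-dimensional site feature vector.  "Signal
   length", "width" and "dwell time" are treated as one and the same
   quantity, the sample count.
3. **Classification.**  One gradient-boosted tree ensemble per motif
   (twelve models, logistic loss, K = 100 trees, depth 6, learning rate
   0.3 by default) emits the probability that the central A of one read
   is methylated.  Training uses a stratified 4:1 train/test split;
   10-fold cross-validation pools out-of-fold scores before computing a
   single ROC/AUC.  Besides the 20 raw features, the ensemble is fed
   two centre-minus-flank contrasts (centre mean/median minus the mean
   of the four flanking means/medians).  Within one motif all five
   window bases are fixed, so these contrasts cancel the residual
   per-read normalization offset — a rotated decision direction that
   axis-aligned tree splits approximate poorly on their own.  The
   public feature schema is unchanged; the contrasts are derived
   deterministically inside the classifier.
4. **Stoichiometry.**  Per-read probabilities are binarized at 0.5
   (ties count as modified; the cut is configurable) and aggregated per
   `(transcript, position)`: the m6A ratio is modified reads over total
   reads, and a site passes the support filter iff it is backed by at
   least 20 *modified* reads.  The alternative reading of the rule —
   at least 20 reads of total coverage — is exposed as a separate
   option for cross-method comparisons, because the two cutoffs answer
   different questions.

The printed false-positive-rate formula in the source method is the
specificity (TN/(FP+TN)); the standard FPR = FP/(FP+TN) is implemented,
since ROC construction requires it.

## Coordinates, metagene, and APA coupling

Transcript positions are 0-based internally; genomic output is 1-based.
Mapping walks the transcript-to-genome CIGAR per base (M/=/X advance
both, I the transcript only, D/N the genome only); reverse-strand
alignments flip orientation, and positions in insertions are kept as
unmappable rather than silently dropped.

Metagene profiles place each site at `u = tpos/len(5'UTR)`,
`1 + (tpos-s)/len(CDS)` or `2 + (tpos-e)/len(3'UTR)` — three
unit-length regions, 100 bins each by default.  A site exactly at the
stop-codon boundary lands at `u = 2.0`, i.e. in the first 3'UTR bin.
Transcripts lacking a UTR annotation simply contribute no sites to that
region; with per-bin densities over the pooled histogram no per-
transcript denominator is needed.

Poly(A) analysis consumes per-read 3'-end positions and tail lengths
(nanopolish-style; only `qc_tag == "PASS"` records are used).  Read
ends within 24 nt of each other chain into one cluster (stepwise single
linkage, inclusive at exactly 24 nt; a cluster-diameter rule was
considered and rejected as it contradicts common poly(A)-cluster
practice).  The representative end is the modal position, ties broken
toward the most 3' position.  Among clusters with at least 10 reads,
the one nearest the stop codon in transcription direction is proximal
and the farthest distal; genes need both to count as APA.  Genes whose
proximal and distal mean tail lengths differ at least two-fold
(inclusive) are flagged, and the methylation coupling is summarized as
`log2((ratio_D + 0.01) / (ratio_P + 0.01))` — the pseudo-ratio guards
sites with ratio 0.

For the per-cluster m6A ratio, a site qualifies through the
*gene-level pooled* ≥20-modified-read filter keyed by
`(gene, transcript position)`: proximal and distal isoforms share
transcript coordinates 5' of the proximal cut, and pooling prevents an
isoform from being excluded merely because its own coverage falls
under the cutoff while its sibling passes.

## What the generator emulates

The synthetic generator is the package's source of ground truth.  Its
defaults are the study conditions used throughout the tests:

* per-base current levels `A=100, C=90, G=110, T=80` (arbitrary units),
  within-segment noise sd 2, geometric dwell (mean 8 samples, minimum
  3);
* modification effect confined to the central A: +3 raw units of mean
  shift and a 1.5x dwell multiplier (an optional context-spill mode
  perturbs the ±1 neighbours; an optional deterministic 5-mer offset
  table, `kmer_sd`, emulates k-mer-dependent levels and is off by
  default);
* labeled training molecules carry one motif with 48 random flanking
  bases on each side (101 bases).  The flank length was chosen so that
  the per-read median/MAD estimate is about as stable as on full-length
  transcript reads; much shorter molecules make the normalization
  itself the dominant noise source, which belongs to the read-length
  regime, not to the modification signal under study;
* mixtures draw the modified-read count per site from
  `Binomial(depth, ratio)`, with per-site random substreams so one
  site's draws never depend on how many sites or reads are simulated;
* the transcriptome has 100 two-exon genes (5'UTR 30–60, CDS 150–300,
  3'UTR 150–250 nt — compact but structurally complete transcripts),
  3–6 planted RRACH sites per gene with 70% of the mass in the window
  from the last CDS decile into the adjacent 3'UTR, per-gene true
  ratios drawn from 0.5–0.8 (sites surviving a 20-modified-read filter
  skew toward mid-to-high stoichiometry), and depth 100 per isoform
  with log-normal per-gene variation.  Reads are 3'-anchored with
  variable 5' truncation, as direct RNA reads are.  Half the genes get
  a second poly(A) isoform 60 nt upstream, with the distal isoform's
  true m6A ratio set to half the proximal one and tail lengths of
  45 nt (proximal) versus 95 nt (distal);
* replicate counts are scaled down from the original design's 10,000
  mixtures to 200 sites per (ratio, depth) cell; both are exposed.

The generator does **not** model basecalling errors, alignment
artifacts, k-mer-specific modification effects, multiple modification
types sharing a motif, or real pore physics.  Green tests therefore
demonstrate that the pipeline recovers what this generative structure
encodes — motif-conditional level/dwell shifts, binomial site mixtures,
APA-linked methylation — not that the classifier would reach the same
accuracy on any particular real data set.

## Numerical choices and degenerate inputs

* Binarization threshold 0.5; ties to modified.
* MAD = 0 reads: scale 1, flagged, kept.
* Empty segments, empty reads, non-RRACH windows, and windows truncated
  by a read boundary are rejected or skipped with an explicit reason.
* ROC thresholds sweep the distinct scores with ties grouped, making
  the trapezoidal AUC exactly the Mann–Whitney pair statistic.
* Confusion metrics return `NA` on zero denominators rather than
  raising.
* Seeds: every simulation entry point is a pure function of
  `(params, seed)`; splits and folds derive from the training
  configuration's seed; boosting runs single-threaded with a fixed
  seed so persisted bundles reproduce bit-identical probabilities.

## Problem sizes used in the checks

The packaged checks run the classifier conditions at 500 reads per
motif per class (strong-separation regime, shift 5 / noise 1), the
stoichiometry grid at ratios 0–1 in steps of 0.1 with depths 20/50/100
and 200 sites per cell, and one full transcriptome run (100 genes,
depth 100).  These sizes keep every simulated quantity's sampling error
well inside the asserted tolerances while remaining desk-scale.

## Known limitations

* Per-motif models mean a motif absent from training cannot be
  predicted; there is deliberately no pooled fallback.
* The stoichiometry estimate counts every read once; molecules are not
  deduplicated.
* Condition comparison reports descriptive deltas, not significance
  tests.
* Genomic pooling merges transcripts sharing an A; isoform-aware
  analyses must use the transcript-level table (the APA module does).
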