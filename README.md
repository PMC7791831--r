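# nanostoich

Single-base, single-read detection of N6-methyladenosine (m6A) from
segmented nanopore direct RNA sequencing signal, with per-site
stoichiometry and downstream coupling to alternative polyadenylation.

## Who this is for

Direct RNA sequencing pushes native transcripts through a nanopore, so
the ionic current of every read carries the marks of its modifications.
m6A — the most prevalent internal mRNA modification — concentrates in
RRACH motifs (R = A/G, H = A/C/U; twelve concrete 5-mers).  Given
per-read, per-base current segments (the output of a re-squiggle step
such as Tombo's, in a portable TSV), `nanostoich`:

* normalizes each read by its median shift and MAD scale,
* extracts, for every RRACH window on every read, 20 signal features
  (mean, median, population std, dwell for the five window bases),
* classifies each read/site pair with one gradient-boosted tree
  ensemble per motif, giving the probability that the central A is
  methylated,
* aggregates per-read calls into per-site stoichiometry
  `ratio = m6A reads / total reads`, keeping sites supported by at
  least 20 modified reads,
* maps transcript positions to the genome through alignment CIGAR
  strings, profiles sites along scaled metagene coordinates
  (5'UTR | CDS | 3'UTR), and couples per-isoform methylation to
  poly(A)-site choice (24-nt single-linkage clustering of read 3'
  ends, proximal/distal roles, two-fold tail-length screen,
  `log2((ratio_D + 0.01)/(ratio_P + 0.01))`).

A synthetic-data generator (`simulateLabeledEvents`,
`simulateMixture`, `simulateTranscriptome`) produces every input the
pipeline consumes, with known ground truth, and is itself first-class,
tested code.

## Worked example

Train on simulated labeled events (strong-separation regime), then
estimate the stoichiometry of fifty-read mixtures with a true modified
fraction of 0.6:

```r
library(nanostoich)

params   <- simParams(seed = 1, mod_shift = 5, noise_sd = 1)
training <- simulateLabeledEvents(params, n_per_motif_per_class = 100)
labeled  <- attachLabels(extractFeatures(training$events), training$labels)
fit      <- trainBundle(labeled, trainConfig(seed = 1))
sprintf("held-out AUC: %.3f (TPR %.3f, FPR %.3f)",
        fit$report$auc, fit$report$tpr, fit$report$fpr)
#> held-out AUC: 0.990 (TPR 0.983, FPR 0.000)

mix   <- simulateMixture(params, true_ratio = 0.6, depth = 50, n_sites = 40)
calls <- callReads(fit$bundle, extractFeatures(mix$events))
sites <- merge(aggregateSites(calls, min_mod_reads = 20),
               mix$truth[, c("transcript_id", "tpos", "true_ratio")])
head(sites[, c("transcript_id", "tpos", "motif", "n_mod", "n_total",
               "ratio", "pass_filter")], 3)
#>  transcript_id tpos motif n_mod n_total ratio pass_filter
#>       mix00001   50 GAACA    27      50  0.54        TRUE
#>       mix00002   50 AGACT    27      50  0.54        TRUE
#>       mix00003   50 AGACC    28      50  0.56        TRUE
mean(sites$ratio)
#> [1] 0.595
```

Each row is one genomically distinct A: 27 of 50 reads called
modified gives a stoichiometry of 0.54, and the site passes the
20-modified-read support filter; averaged over the forty simulated
sites the estimate recovers the true mixing fraction (0.595 vs 0.600).
Transcript coordinates map to the genome through the alignment's
CIGAR:

```r
mapToGenome(7L, "chr1", 101L, "+", "5M100N5M")
#>   chrom gpos strand mappable
#> 1  chr1  208      +     TRUE
```

A thin command-line front-end over the same functions ships in
`inst/exec/nanostoich.R` (subcommands `simulate`, `train`, `quantify`,
`profile`, `apa`).

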