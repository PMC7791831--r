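# Shared (lazily built, memoised) fixtures.  Everything is generated in
# code at test time; the heavier objects are built once per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# strong-separation regime: large center shift, low noise (the Bayes
# error of the simulated classes is well below 1%)
strongParams <- function(seed = 41L)
  simParams(seed = seed, mod_shift = 5, noise_sd = 1)

strongLabeled <- function() memo("strong_labeled", function() {
  sim <- simulateLabeledEvents(strongParams(), 500L)
  attachLabels(extractFeatures(sim$events), sim$labels)
})

strongBundle <- function() memo("strong_bundle", function() {
  trainBundle(strongLabeled(), trainConfig(seed = 1L))
})

smallLabeled <- function() memo("small_labeled", function() {
  sim <- simulateLabeledEvents(strongParams(seed = 42L), 60L)
  attachLabels(extractFeatures(sim$events), sim$labels)
})

smallBundle <- function() memo("small_bundle", function() {
  trainBundle(smallLabeled(), trainConfig(seed = 2L))
})

defaultBundle <- function() memo("default_bundle", function() {
  sim <- simulateLabeledEvents(simParams(seed = 11L), 300L)
  lf <- attachLabels(extractFeatures(sim$events), sim$labels)
  trainBundle(lf, trainConfig(seed = 7L))
})

# full transcriptome pipeline run at the generator's study conditions
# (100 genes, APA fraction 0.5, depth 100/isoform)
txPipeline <- function() memo("tx_pipeline", function() {
  tx <- simulateTranscriptome(simParams(seed = 21L))
  feats <- extractFeatures(tx$events)
  tx$events <- NULL
  gc(FALSE)
  calls <- callReads(defaultBundle()$bundle, feats)
  sites <- aggregateSites(calls)
  pol <- tx$polya[tx$polya$qc_tag == "PASS", ]
  cl <- clusterPolyaSites(pol)
  roles <- assignProximalDistal(
    cl$clusters, tx$truth$genes[, c("gene_id", "stop_pos")])
  list(tx = tx, calls = calls, sites = sites, polya = pol,
       clusters = cl, roles = roles)
})

toyRead <- function(bases = "GGACT", segs = list(0, 0, c(1, 1), 0, 0),
                    start = 0L)
  EventRead("r1", "tx1", start, bases, segs)
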