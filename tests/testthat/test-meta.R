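modelTable <- function(utr5 = 100L, cds = 300L, utr3 = 200L, id = "t1")
  data.frame(transcript_id = id, utr5_len = utr5, cds_len = cds,
             utr3_len = utr3, tx_len = utr5 + cds + utr3)

test_that("metagene scaling maps region boundaries as specified", {
  m <- modelTable()
  # stop-codon boundary (first 3'UTR base) lands at u = 2.0
  p <- metageneProfile(data.frame(transcript_id = "t1", tpos = 400L),
                       m, bins_per_region = 10L)
  b <- profileBins(p)
  expect_equal(b$count[b$lower == 2.0], 1L)
  # first base of the transcript lands in the first 5'UTR bin
  p0 <- metageneProfile(data.frame(transcript_id = "t1", tpos = 0L),
                        m, bins_per_region = 10L)
  expect_equal(profileBins(p0)$count[1], 1L)
  # first CDS base lands at u = 1.0
  p1 <- metageneProfile(data.frame(transcript_id = "t1", tpos = 100L),
                        m, bins_per_region = 10L)
  expect_equal(profileBins(p1)$count[profileBins(p1)$lower == 1.0], 1L)
  expect_error(metageneProfile(
    data.frame(transcript_id = "t1", tpos = 600L), m), "outside")
})

test_that("metagene conserves mass and densities integrate to one", {
  set.seed(31)
  m <- modelTable()
  sites <- data.frame(transcript_id = "t1",
                      tpos = sample(0:599, 500, TRUE))
  p <- metageneProfile(sites, m, bins_per_region = 25L)
  b <- profileBins(p)
  expect_equal(sum(b$count), 500L)
  expect_equal(profileSites(p), 500L)
  expect_equal(sum(b$density * (b$upper - b$lower)), 1)
})

test_that("uniform site placement gives a flat per-region profile", {
  set.seed(37)
  m <- modelTable(200L, 400L, 400L)
  sites <- data.frame(transcript_id = "t1",
                      tpos = sample(0:999, 10000, TRUE))
  p <- metageneProfile(sites, m, bins_per_region = 20L)
  b <- profileBins(p)
  for (reg in unique(b$region)) {
    cnt <- b$count[b$region == reg]
    expect_gt(stats::chisq.test(cnt)$p.value, 1e-3)
  }
})

test_that("profiles are invariant to rescaling all region lengths", {
  set.seed(41)
  m1 <- modelTable(50L, 120L, 80L)
  m2 <- modelTable(100L, 240L, 160L)
  # sites at matched relative positions within each region
  t1 <- c(0L, 10L, 49L, 50L, 110L, 169L, 170L, 200L, 249L)
  t2 <- 2L * t1
  p1 <- metageneProfile(data.frame(transcript_id = "t1", tpos = t1), m1,
                        bins_per_region = 10L)
  p2 <- metageneProfile(data.frame(transcript_id = "t1", tpos = t2), m2,
                        bins_per_region = 10L)
  expect_identical(profileBins(p1)$count, profileBins(p2)$count)
})

test_that("exon length comparison reports medians and a rank statistic", {
  same <- exonLengthComparison(c(100, 200, 300), c(100, 200, 300))
  expect_equal(same$median_diff, 0)
  up <- exonLengthComparison(c(300, 400), c(100, 200))
  expect_equal(up$median_diff, 200)
  expect_true(is.finite(up$rank_statistic))
  expect_error(exonLengthComparison(numeric(), 1:3), "non-empty")
})

test_that("correlateGenes matches expectations and flags degeneracy", {
  x <- 1:20
  expect_equal(correlateGenes(x, -x)$r, -1)
  set.seed(43)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(correlateGenes(a, b)$r), 0.1)
  z <- correlateGenes(rep(1, 10), rnorm(10))
  expect_true(z$undefined)
  expect_true(is.na(z$r))
  expect_error(correlateGenes(1:2, 2:3), ">= 3")
})

test_that("induced negative expression-methylation coupling is recovered", {
  set.seed(47)
  expr <- rlnorm(400, log(100), 0.6)
  ratio <- pmin(0.95, pmax(0.05, 0.9 - 0.25 * log10(expr) + rnorm(400, 0, 0.05)))
  r <- correlateGenes(log10(expr + 1), ratio)$r
  expect_lt(r, -0.5)
})

test_that("transcript models reconstructed from GTF match the generator", {
  tx <- txPipeline()$tx
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(tx$gtf, gtf)
  models <- transcriptModelsFromGtf(gtf)
  tab <- models$table
  g <- tx$truth$genes
  i <- match(paste0(g$gene_id, ".d"), tab$transcript_id)
  expect_false(anyNA(i))
  expect_equal(tab$utr5_len[i], g$utr5)
  expect_equal(tab$cds_len[i], g$cds)
  expect_equal(tab$utr3_len[i], g$utr3)
  expect_equal(tab$tx_len[i], g$L)
  expect_equal(tab$strand[i], g$strand)
  # proximal isoforms lose exactly the poly(A) offset from the 3'UTR
  pi <- match(paste0(g$gene_id[g$apa], ".p"), tab$transcript_id)
  expect_equal(tab$utr3_len[pi], g$utr3[g$apa] - 60L)
})

test_that("m6A-containing exons are separated from control exons", {
  tx <- txPipeline()$tx
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(tx$gtf, gtf)
  models <- transcriptModelsFromGtf(gtf)
  sites <- annotateSiteGenomics(txPipeline()$sites, tx$alignments)
  le <- m6aExonLengths(sites, models)
  expect_gt(length(le$m6a), 0L)
  expect_gt(length(le$control), 0L)
  cmp <- exonLengthComparison(le$m6a, le$control)
  expect_true(is.finite(cmp$median_diff))
})
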