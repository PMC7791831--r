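test_that("binarize thresholds probabilities with ties going to modified", {
  expect_equal(binarize(c(0.974, 0.003)), c("modified", "unmodified"))
  expect_equal(binarize(0.5, 0.5), "modified")
  expect_equal(binarize(0.49999, 0.5), "unmodified")
  expect_error(binarize(1.2), "\\[0, 1\\]")
  expect_error(binarize(0.5, -1), "\\[0, 1\\]")
})

makeCalls <- function(n_mod, n_unmod, tx = "tx1", tpos = 10L) {
  n <- n_mod + n_unmod
  data.frame(read_id = sprintf("%s_%d_r%03d", tx, tpos, seq_len(n)),
             transcript_id = tx, tpos = tpos, motif = "GGACT",
             probability = rep(c(0.95, 0.02), c(n_mod, n_unmod)),
             call = rep(c("modified", "unmodified"), c(n_mod, n_unmod)))
}

test_that("aggregateSites applies the 20-modified-read support rule", {
  s <- aggregateSites(makeCalls(25, 15))
  expect_equal(s$n_mod, 25L)
  expect_equal(s$n_total, 40L)
  expect_equal(s$ratio, 0.625)
  expect_true(s$pass_filter)

  s2 <- aggregateSites(makeCalls(19, 100))
  expect_equal(round(s2$ratio, 3), 0.160)
  expect_false(s2$pass_filter)

  s3 <- aggregateSites(makeCalls(0, 30))
  expect_equal(s3$ratio, 0)
  expect_false(s3$pass_filter)
})

test_that("aggregateSites conserves reads across sites", {
  calls <- rbind(makeCalls(5, 7, "a", 3L), makeCalls(2, 1, "a", 9L),
                 makeCalls(4, 4, "b", 3L))
  s <- aggregateSites(calls, min_mod_reads = 3L)
  expect_equal(sum(s$n_total), nrow(calls))
  expect_equal(s$pass_filter, c(TRUE, FALSE, TRUE))
})

test_that("mapToGenome walks M, N gaps and reverse strand correctly", {
  expect_equal(mapToGenome(4L, "c", 101L, "+", "10M")$gpos, 105L)
  expect_equal(mapToGenome(7L, "c", 101L, "+", "5M100N5M")$gpos, 208L)
  r <- mapToGenome(0L, "c", 101L, "-", "10M")
  expect_equal(r$gpos, 110L)
  expect_equal(r$strand, "-")
  # insertion positions are unmappable but retained
  ins <- mapToGenome(c(4L, 5L, 7L), "c", 101L, "+", "5M2I5M")
  expect_equal(ins$mappable, c(TRUE, FALSE, TRUE))
  expect_equal(ins$gpos, c(105L, NA, 106L))
  # outside the alignment
  expect_false(mapToGenome(99L, "c", 101L, "+", "10M")$mappable)
})

test_that("mapToGenome equals an exhaustive per-base CIGAR walk", {
  set.seed(23)
  for (i in 1:120) {
    cigar <- randCigar()
    gpos <- sample(1:5000, 1)
    strand <- sample(c("+", "-"), 1)
    qlen <- nrow(refCigarTable(cigar, gpos))
    tpos <- unique(c(0L, qlen - 1L, sample(0:(qlen - 1L), min(8, qlen))))
    got <- mapToGenome(tpos, "c", gpos, strand, cigar)
    want <- vapply(tpos, function(t)
      as.integer(refMapToGenome(t, gpos, strand, cigar)), 1L)
    expect_equal(got$gpos, want)
    expect_equal(got$mappable, !is.na(want))
  }
})

test_that("site tables gain genomic coordinates through alignments", {
  aln <- data.frame(transcript_id = c("a", "b"), chrom = "chr1",
                    gpos = c(101L, 501L), strand = c("+", "-"),
                    cigar = c("20M", "10M5I10M"))
  sites <- data.frame(transcript_id = c("a", "b", "b", "zz"),
                      tpos = c(4L, 0L, 12L, 1L), motif = "GGACT",
                      n_mod = 21L, n_total = 30L, ratio = 0.7,
                      pass_filter = TRUE)
  out <- annotateSiteGenomics(sites, aln)
  expect_equal(out$gpos[1], 105L)
  expect_equal(out$gpos[2], 520L)      # reverse strand, 25-base query
  expect_false(out$mappable[3])        # lands in the insertion
  expect_false(out$mappable[4])        # no alignment for transcript
})

test_that("condition comparison intersects sites and reports deltas", {
  mk <- function(tx, tpos, ratio)
    data.frame(transcript_id = tx, tpos = tpos, motif = "GGACT",
               n_mod = 30L, n_total = 50L, ratio = ratio,
               pass_filter = TRUE)
  a <- rbind(mk("t1", 5L, 0.8), mk("t2", 9L, 0.6))
  b <- rbind(mk("t2", 9L, 0.3), mk("t3", 2L, 0.5))
  cc <- compareConditions(a, b, key = "transcript")
  expect_equal(cc$n_shared, 1L)
  expect_equal(cc$n_a_only, 1L)
  expect_equal(cc$n_b_only, 1L)
  expect_equal(cc$shared$delta, -0.3)
  ident <- compareConditions(a, a, key = "transcript")
  expect_equal(ident$n_shared, 2L)
  expect_true(all(ident$shared$delta == 0))
  expect_error(compareConditions(a, b, key = "genomic"), "genomic")
})

test_that("gene-level m6A is the mean over passing sites", {
  sites <- data.frame(transcript_id = c("t1", "t1", "t2", "t3"),
                      tpos = c(1L, 9L, 4L, 2L), motif = "GGACT",
                      n_mod = c(25L, 30L, 21L, 3L),
                      n_total = c(50L, 50L, 30L, 30L),
                      ratio = c(0.2, 0.6, 0.7, 0.1),
                      pass_filter = c(TRUE, TRUE, TRUE, FALSE))
  t2g <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("g1", "g1", "g2"))
  gl <- geneM6aLevel(sites, t2g)
  expect_equal(gl$m6a_level[gl$gene_id == "g1"], mean(c(0.2, 0.6, 0.7)))
  # g2 has no passing site and is absent
  expect_false("g2" %in% gl$gene_id)
})

test_that("site TSV and BED exports are well-formed", {
  sites <- data.frame(transcript_id = "t1", tpos = 7L, motif = "GGACT",
                      n_mod = 25L, n_total = 40L, ratio = 0.625,
                      pass_filter = TRUE, chrom = "chr1", gpos = 1008L,
                      gstrand = "+", mappable = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeSites(sites, tsv)
  sitesToBed(sites, bed)
  line <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(line[1:3], c("chr1", "1007", "1008"))
  expect_equal(line[5], "625")
  back <- read.delim(tsv)
  expect_equal(back$ratio, 0.625)
  expect_equal(back$pos, 1008L)
})
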