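test_that("single-linkage clustering chains gaps up to the window", {
  expect_equal(clusterEnds(c(100, 110, 150)), c(1L, 1L, 2L))
  expect_equal(clusterEnds(c(100, 124, 148)), c(1L, 1L, 1L))  # 24 inclusive
  expect_equal(clusterEnds(100), 1L)
  expect_equal(clusterEnds(integer()), integer())
  expect_error(clusterEnds(c(5, 1)), "sorted")
})

test_that("clustering equals connected components on the 24-nt graph", {
  set.seed(53)
  for (i in 1:300) {
    n <- sample(1:10, 1)
    pos <- sort(sample(1:300, n))
    expect_identical(clusterEnds(pos), refClusterEnds(pos))
  }
})

test_that("clustering is order-independent and translation-invariant", {
  set.seed(59)
  for (i in 1:30) {
    pos <- sort(sample(1:500, 12, TRUE))
    base <- clusterEnds(pos)
    shuf <- sample(pos)
    expect_identical(clusterEnds(sort(shuf)), base)
    expect_identical(clusterEnds(pos + 1000L), base)
  }
})

polyaToy <- function() {
  data.frame(
    read_id = sprintf("r%02d", 1:9),
    gene_id = rep(c("g1", "g2"), c(6, 3)),
    chrom = "chr1",
    end_pos = c(100L, 101L, 100L, 160L, 161L, 162L, 500L, 505L, 540L),
    strand = rep(c("+", "-"), c(6, 3)),
    polya_length = c(40, 42, 38, 90, 95, 88, 70, 75, 72),
    qc_tag = "PASS")
}

test_that("poly(A) clusters summarize reads, lengths and representatives", {
  cl <- clusterPolyaSites(polyaToy())
  g1 <- cl$clusters[cl$clusters$gene_id == "g1", ]
  expect_equal(nrow(g1), 2L)
  expect_equal(g1$n_reads, c(3L, 3L))
  expect_equal(g1$rep_pos[1], 100L)    # modal end
  expect_equal(g1$polya_mean[1], 40)
  # '-' strand modal tie breaks toward the most 3' (smaller genomic)
  g2 <- cl$clusters[cl$clusters$gene_id == "g2", ]
  expect_equal(nrow(g2), 2L)           # gap 35 splits 540
  expect_equal(g2$rep_pos[1], 500L)
  # every PASS read belongs to exactly one cluster
  expect_equal(nrow(cl$membership), 9L)
  expect_equal(anyDuplicated(cl$membership$read_id), 0L)
})

test_that("proximal/distal roles follow transcription direction", {
  cl <- data.frame(gene_id = "g", strand = "+", cluster = 1:2,
                   n_reads = c(20L, 30L), rep_pos = c(1000L, 1500L),
                   min_pos = c(995L, 1495L), max_pos = c(1005L, 1505L),
                   polya_mean = c(40, 90), polya_median = c(40, 90))
  r <- assignProximalDistal(cl, data.frame(gene_id = "g", stop_pos = 800L))
  expect_equal(r$role[r$rep_pos == 1000L], "proximal")
  expect_equal(r$role[r$rep_pos == 1500L], "distal")

  clm <- cl; clm$strand <- "-"
  rm_ <- assignProximalDistal(clm, data.frame(gene_id = "g", stop_pos = 1700L))
  expect_equal(rm_$role[rm_$rep_pos == 1500L], "proximal")
  expect_equal(rm_$role[rm_$rep_pos == 1000L], "distal")

  cl3 <- rbind(cl, data.frame(gene_id = "g", strand = "+", cluster = 3L,
                              n_reads = 15L, rep_pos = 1250L,
                              min_pos = 1245L, max_pos = 1255L,
                              polya_mean = 60, polya_median = 60))
  r3 <- assignProximalDistal(cl3, data.frame(gene_id = "g", stop_pos = 800L))
  expect_equal(r3$role[r3$rep_pos == 1250L], "other")

  # under-supported clusters disqualify the gene from APA
  weak <- cl; weak$n_reads <- c(5L, 30L)
  rw <- assignProximalDistal(weak, data.frame(gene_id = "g", stop_pos = 800L))
  expect_true(all(is.na(rw$role)))
  expect_error(assignProximalDistal(transform(cl, strand = "*"),
                                    data.frame(gene_id = "g", stop_pos = 1L)),
               "unknown strand")
})

test_that("the two-fold poly(A) length screen is inclusive at 2x", {
  mk <- function(p, d)
    data.frame(gene_id = "g", strand = "+", cluster = 1:2,
               n_reads = 20L, rep_pos = c(100L, 300L),
               min_pos = c(99L, 299L), max_pos = c(101L, 301L),
               polya_mean = c(p, d), polya_median = c(p, d),
               dist_stop = c(50L, 250L), stop_pos = 50L,
               role = c("proximal", "distal"), apa = TRUE)
  expect_true(apaPolyaLengthScreen(mk(40, 90))$flagged)     # 2.25x
  expect_false(apaPolyaLengthScreen(mk(80, 100))$flagged)   # 1.25x
  expect_true(apaPolyaLengthScreen(mk(50, 100))$flagged)    # exactly 2x
  expect_true(is.na(apaPolyaLengthScreen(mk(0, 100))$fold))
})

test_that("methylation fold change uses eps-guarded per-cluster ratios", {
  # two isoforms x 30 reads each; one shared passing site at tpos 10
  mkCalls <- function(tx, n_mod, n) data.frame(
    read_id = sprintf("%s_r%02d", tx, 1:n), transcript_id = tx,
    tpos = 10L, motif = "GGACT",
    probability = rep(c(0.9, 0.1), c(n_mod, n - n_mod)),
    call = rep(c("modified", "unmodified"), c(n_mod, n - n_mod)))
  calls <- rbind(mkCalls("g.p", 16, 40), mkCalls("g.d", 8, 40))
  t2g <- data.frame(transcript_id = c("g.p", "g.d"), gene_id = "g")
  membership <- data.frame(
    read_id = c(sprintf("g.p_r%02d", 1:40), sprintf("g.d_r%02d", 1:40)),
    gene_id = "g", strand = "+", cluster = rep(1:2, each = 40))
  clusters <- data.frame(gene_id = "g", strand = "+", cluster = 1:2,
                         n_reads = 40L, rep_pos = c(100L, 200L),
                         min_pos = 0L, max_pos = 0L, polya_mean = 50,
                         polya_median = 50, dist_stop = c(10L, 110L),
                         stop_pos = 90L, role = c("proximal", "distal"),
                         apa = TRUE)
  fc <- apaMethylationFoldChange(clusters, membership, calls, t2g)
  expect_equal(fc$ratio_proximal, 0.4)
  expect_equal(fc$ratio_distal, 0.2)
  expect_equal(fc$log2fc, log2(0.21 / 0.41))
  # the printed-arithmetic example: 0.19 vs 0.39 -> exactly -1
  expect_equal(log2((0.19 + 0.01) / (0.39 + 0.01)), -1)
})

test_that("poly(A) tables honour the PASS qc filter", {
  d <- polyaToy()
  d$qc_tag[c(2, 7)] <- "ADAPTER"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- readPolyaTable(path)
  expect_equal(nrow(kept), 7L)
  all_ <- readPolyaTable(path, keep_all = TRUE)
  expect_equal(nrow(all_), 9L)
  # nanopolish-style column names through the map
  d2 <- d
  names(d2)[names(d2) == "read_id"] <- "readname"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  mapped <- readPolyaTable(path2, column_map = c(read_id = "readname"))
  expect_equal(mapped$read_id, kept$read_id)
  s <- polyaLengthSummary(kept)
  expect_equal(s$n, 7L)
  expect_true(s$mean > 0 && s$median > 0)
})
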