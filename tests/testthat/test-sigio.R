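test_that("baseFeatures computes mean/median/population std/dwell", {
  f <- baseFeatures(c(2, 4, 6))
  expect_equal(unname(f["mean"]), 4)
  expect_equal(unname(f["median"]), 4)
  expect_equal(unname(f["std"]), sqrt(8 / 3))
  expect_equal(unname(f["dwell"]), 3)
  expect_equal(unname(baseFeatures(5)), c(5, 5, 0, 1))
  expect_equal(unname(baseFeatures(c(1, 1, 1, 1))), c(1, 1, 0, 4))
  expect_error(baseFeatures(numeric()), "empty segment")
})

test_that("normalizeRead applies median shift / MAD scale per read", {
  r <- EventRead("r", "tx", 0L, "ACGTA",
                 list(1, 2, 3, 4, 100))
  p <- normalizationParams(r)
  expect_equal(p$shift, 3)
  expect_equal(p$scale, 1)   # median(|x - 3|) = median(2,1,0,1,97)
  n <- normalizeRead(r)
  expect_equal(signalSegments(n)[[4]], 1.0)

  const <- EventRead("c", "tx", 0L, "AC", list(c(7, 7), 7))
  expect_warning(nc <- normalizeRead(const), "MAD = 0")
  expect_true(all(unlist(signalSegments(nc)) == 0))

  # renormalizing leaves shift at 0 (idempotent up to positive rescale)
  p2 <- normalizationParams(n)
  expect_equal(p2$shift, 0)
  expect_error(normalizationParams(
    new("EventRead", read_id = "x", transcript_id = "t",
        start_pos = 0L, bases = "", segments = list())),
    "empty read")
})

test_that("findRrachSites reports every overlapping motif, skips N", {
  expect_equal(findRrachSites("GGACT"),
               data.frame(center_pos = 2L, motif = "GGACT"))
  expect_equal(findRrachSites("AGGACAT"),
               data.frame(center_pos = 3L, motif = "GGACA"))
  expect_equal(nrow(findRrachSites("CCCCCCC")), 0L)
  expect_equal(nrow(findRrachSites("GGAC")), 0L)          # too short
  expect_equal(nrow(findRrachSites("GGNCT")), 0L)         # N never matches
  expect_equal(findRrachSites("ggacu")$motif, "GGACT")    # case and U
  # overlapping occurrences are all reported
  expect_equal(findRrachSites("AAACAAACA")$center_pos, c(2L, 6L))
})

test_that("findRrachSites matches a brute-force window scan", {
  set.seed(7)
  for (i in 1:60) {
    len <- sample(5:400, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), len, TRUE,
                      prob = c(.3, .2, .3, .19, .01)), collapse = "")
    expect_equal(findRrachSites(s), refFindRrach(s), ignore_attr = TRUE)
  }
})

test_that("extractSiteFeatures concatenates per-base features in order", {
  v <- extractSiteFeatures(toyRead(), 2L)
  expect_equal(v$motif, "GGACT")
  expect_equal(v$mean_c0, 1)
  expect_equal(v$dwell_c0, 2)
  expect_equal(v$mean_m2, 0)
  expect_equal(v$std_p2, 0)
  expect_equal(unlist(v[siteFeatureNames()], use.names = FALSE),
               c(0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 0, 2, 0, 0, 0, 1, 0, 0, 0, 1))

  # window truncated at the read edge is skipped with a reason
  short <- EventRead("r", "tx", 0L, "GACTA", list(0, 0, 0, 0, 0))
  out <- extractSiteFeatures(short, 1L)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "reason"), "edge")
  expect_error(extractSiteFeatures(toyRead("GGCTT"), 2L), "not an RRACH")
})

test_that("feature extraction is invariant to per-read affine transforms", {
  set.seed(11)
  for (i in 1:10) {
    n <- 15L
    bases <- paste(c(sample(c("A", "C", "G", "T"), 5, TRUE), "GGACT",
                     sample(c("A", "C", "G", "T"), 5, TRUE)), collapse = "")
    segs <- lapply(seq_len(n), function(j) rnorm(sample(3:8, 1), 95, 4))
    a <- runif(1, 0.5, 3); b <- runif(1, -20, 20)
    r1 <- normalizeRead(EventRead("r", "t", 0L, bases, segs))
    r2 <- normalizeRead(EventRead("r", "t", 0L, bases,
                                  lapply(segs, function(s) a * s + b)))
    f1 <- readSiteFeatures(r1, normalize = FALSE)
    f2 <- readSiteFeatures(r2, normalize = FALSE)
    fn <- siteFeatureNames()
    expect_equal(as.matrix(f2[fn]), as.matrix(f1[fn]), tolerance = 1e-9)
    expect_identical(f1[grep("dwell", fn)], f2[grep("dwell", fn)])
  }
})

test_that("event tables round-trip through both TSV dialects exactly", {
  sim <- simulateLabeledEvents(strongParams(seed = 5L), 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEvents(sim$events, path)
  back <- readEvents(path)
  expect_equal(attr(back, "dialect"), "raw")
  expect_identical(back$samples, sim$events$samples)
  expect_identical(back$read_id, sim$events$read_id)
  expect_identical(back$position, as.integer(sim$events$position))

  # feature dialect
  reads <- asEventReads(sim$events)
  fb <- do.call(rbind, lapply(reads[1:5], function(r) {
    st <- t(vapply(signalSegments(r), baseFeatures, numeric(4)))
    data.frame(read_id = readId(r), transcript_id = transcriptId(r),
               position = startPos(r) + seq_len(nrow(st)) - 1L,
               base = strsplit(readBases(r), "")[[1]],
               mean = st[, 1], median = st[, 2], std = st[, 3],
               dwell = as.integer(st[, 4]))
  }))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeEvents(fb, path2)
  back2 <- readEvents(path2)
  expect_equal(attr(back2, "dialect"), "feature")
  expect_identical(back2$mean, fb$mean)
  expect_identical(back2$std, fb$std)
  expect_identical(back2$dwell, as.integer(fb$dwell))
})

test_that("bulk extractFeatures equals the per-read path", {
  sim <- simulateLabeledEvents(strongParams(seed = 6L), 4L)
  ev <- sim$events
  bulk <- extractFeatures(ev)
  reads <- asEventReads(ev)
  ref <- do.call(rbind, lapply(reads, readSiteFeatures))
  key <- function(d) paste(d$read_id, d$tpos)
  bulk <- bulk[order(key(bulk)), ]
  ref <- ref[order(key(ref)), ]
  expect_equal(nrow(bulk), nrow(ref))
  expect_equal(bulk$motif, ref$motif)
  fn <- siteFeatureNames()
  expect_equal(as.matrix(bulk[fn]), as.matrix(ref[fn]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("degenerate constant-signal reads are flagged, not dropped", {
  ev <- asEventTable(list(
    EventRead("flat", "tx", 0L, "AGGACTA", as.list(rep(5, 7))),
    EventRead("ok", "tx", 0L, "AGGACTA",
              lapply(1:7, function(i) rnorm(4, 90, 3)))))
  expect_warning(f <- extractFeatures(ev), "constant signal")
  expect_equal(attr(f, "degenerate_reads"), "flat")
  expect_true(all(c("flat", "ok") %in% f$read_id))
})
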