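# Event-table IO, per-read normalization, RRACH scanning and 20-feature
# extraction.  Feature order is fixed: for each window base -2..+2 around
# the central A, (mean, median, std, dwell).

#' Names and order of the 20 site features
#'
#' Four signal statistics (mean, median, population standard deviation,
#' dwell = number of raw samples) for each of the five bases of an RRACH
#' window, ordered 5'->3' (`m2`, `m1`, `c0`, `p1`, `p2`).
#'
#' @return character vector of length 20.
#' @export
siteFeatureNames <- function() {
  off <- c("m2", "m1", "c0", "p1", "p2")
  as.vector(vapply(off, function(o)
    paste0(c("mean", "median", "std", "dwell"), "_", o), character(4L)))
}

.FEATURE_SCHEMA <- "nsf-1"

#' Feature schema identifier
#'
#' Version string recorded in trained bundles and checked at prediction
#' time so that models are never applied to features extracted under a
#' different convention.
#' @return character scalar.
#' @export
featureSchema <- function() .FEATURE_SCHEMA

#' Signal statistics of one base segment
#'
#' Computes the four per-base features from the raw current samples
#' assigned to one reference base: mean, median, population standard
#' deviation (divide by n) and dwell (the number of samples).
#'
#' @param segment non-empty numeric vector of current samples.
#' @return named numeric vector `c(mean, median, std, dwell)`.
#' @examples
#' baseFeatures(c(2, 4, 6))   # std = sqrt(8/3)
#' @export
baseFeatures <- function(segment) {
  segment <- as.numeric(segment)
  if (length(segment) == 0L || anyNA(segment)) stop("empty segment")
  m <- mean(segment)
  c(mean = m, median = median(segment),
    std = sqrt(mean((segment - m)^2)), dwell = length(segment))
}

#' Per-read normalization parameters (median shift, MAD scale)
#'
#' Shift is the median of all raw samples pooled over the read; scale is
#' the unscaled median absolute deviation (no 1.4826 consistency factor)
#' of the same pool.  A read whose MAD is zero (constant signal) gets
#' `scale = 1` and is flagged degenerate.
#'
#' @param read an [EventRead].
#' @return list with `shift`, `scale`, `degenerate`.
#' @export
normalizationParams <- function(read) {
  stopifnot(is(read, "EventRead"))
  pooled <- unlist(read@segments, use.names = FALSE)
  if (length(pooled) == 0L) stop("empty read")
  shift <- median(pooled)
  scale <- median(abs(pooled - shift))
  degenerate <- scale == 0
  if (degenerate) scale <- 1
  list(shift = shift, scale = scale, degenerate = degenerate)
}

#' Normalize a read's current samples in place
#'
#' Every raw sample `x` is replaced by `(x - shift)/scale` with the
#' per-read median shift and MAD scale of [normalizationParams()];
#' segmentation is unchanged.  A constant read (MAD = 0) falls back to
#' `scale = 1` with a warning and is kept, not dropped.
#'
#' @param read an [EventRead].
#' @return the normalized [EventRead].
#' @examples
#' r <- EventRead("r1", "tx", 0L, "AC", list(c(1, 2, 3), c(4, 100)))
#' signalSegments(normalizeRead(r))
#' @export
normalizeRead <- function(read) {
  p <- normalizationParams(read)
  if (p$degenerate)
    warning("read ", read@read_id, ": constant signal (MAD = 0), scale 1 used")
  read@segments <- lapply(read@segments, function(s) (s - p$shift) / p$scale)
  read
}

#' Locate RRACH motifs in a nucleotide sequence
#'
#' Scans for every (possibly overlapping) occurrence of the degenerate
#' motif `[AG][AG]AC[ACT]` (R = A/G, H = A/C/U), with U read as T, and
#' returns the 0-based position of the central A together with the
#' concrete 5-mer.  Windows containing N never match.
#'
#' @param sequence character scalar over A/C/G/T/U/N (case-insensitive).
#' @return data.frame with columns `center_pos` (integer, 0-based) and
#'   `motif` (character); zero rows when the sequence is shorter than 5 or
#'   has no motif.
#' @examples
#' findRrachSites("AGGACAT")   # center_pos 3, motif GGACA
#' @export
findRrachSites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(chartr("Uu", "Tt", sequence))
  empty <- data.frame(center_pos = integer(), motif = character())
  if (nchar(s) < 5L) return(empty)
  m <- gregexpr("(?=[AG][AG]AC[ACT])", s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)                     # 1-based window starts
  data.frame(center_pos = starts + 1L,        # 0-based center = start-1+2
             motif = substring(s, starts, starts + 4L))
}

#' Extract the 20-feature vector of one RRACH site on one read
#'
#' Concatenates [baseFeatures()] of the five bases centred on the A at
#' `center_pos` (transcript coordinates, 0-based).  The read is expected
#' to be normalized already (see [normalizeRead()]); no rescaling happens
#' here.  A window truncated by the read boundary is skipped: the function
#' returns a zero-row frame with attribute `reason = "edge"`.  A window
#' whose 5-mer is not RRACH is an error.
#'
#' @param read a (normalized) [EventRead].
#' @param center_pos 0-based transcript coordinate of the central A.
#' @return one-row data.frame with `read_id`, `transcript_id`, `tpos`,
#'   `motif` and the 20 feature columns of [siteFeatureNames()]; zero rows
#'   (attribute `reason = "edge"`) when the window falls off the read.
#' @export
extractSiteFeatures <- function(read, center_pos) {
  stopifnot(is(read, "EventRead"))
  center_pos <- as.integer(center_pos)
  i <- center_pos - read@start_pos + 1L        # 1-based index into segments
  n <- length(read@segments)
  if (i - 2L < 1L || i + 2L > n) {
    out <- data.frame(read_id = character(), transcript_id = character(),
                      tpos = integer(), motif = character())
    out[siteFeatureNames()] <- lapply(siteFeatureNames(), function(x) numeric())
    attr(out, "reason") <- "edge"
    return(out)
  }
  win <- substring(read@bases, i - 2L, i + 2L)
  if (!grepl("^[AG][AG]AC[ACT]$", win)) stop("not an RRACH site: ", win)
  feats <- unlist(lapply(read@segments[(i - 2L):(i + 2L)], baseFeatures),
                  use.names = FALSE)
  out <- data.frame(read_id = read@read_id,
                    transcript_id = read@transcript_id,
                    tpos = center_pos, motif = win)
  out[siteFeatureNames()] <- as.list(feats)
  out
}

#' All RRACH site feature vectors of one read
#'
#' Normalizes the read (optional) and extracts the feature vector of every
#' RRACH window fully contained in it.
#'
#' @param read an [EventRead].
#' @param normalize normalize the read first (default `TRUE`).
#' @return data.frame as in [extractSiteFeatures()], zero rows when the
#'   read carries no complete RRACH window.
#' @export
readSiteFeatures <- function(read, normalize = TRUE) {
  if (normalize) read <- normalizeRead(read)
  sites <- findRrachSites(read@bases)
  rows <- lapply(sites$center_pos + read@start_pos,
                 function(p) extractSiteFeatures(read, p))
  rows <- rows[vapply(rows, nrow, 1L) > 0L]
  if (!length(rows)) {
    out <- data.frame(read_id = character(), transcript_id = character(),
                      tpos = integer(), motif = character())
    out[siteFeatureNames()] <- lapply(siteFeatureNames(), function(x) numeric())
    return(out)
  }
  do.call(rbind, rows)
}

# ---- event tables (bulk representation) -----------------------------------

.RAW_COLS <- c("read_id", "transcript_id", "position", "base",
               "n_samples", "samples")
.FEAT_COLS <- c("read_id", "transcript_id", "position", "base",
                "mean", "median", "std", "dwell")

#' Read an event table (raw or feature dialect)
#'
#' The raw dialect is a TSV with header `read_id, transcript_id, position
#' (0-based), base, n_samples, samples` where `samples` holds the
#' comma-separated raw current values of the base's segment, one row per
#' base.  The feature dialect replaces the last two columns with
#' precomputed `mean, median, std, dwell`.  The dialect is detected from
#' the header.
#'
#' @param path TSV file.
#' @return data.frame, one row per base; raw dialect carries `samples` as
#'   a list column.  Attribute `dialect` is `"raw"` or `"feature"`.
#' @seealso [writeEvents()]
#' @export
readEvents <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("read_id", "transcript_id", "base")))
  nm <- names(dt)
  if (all(.RAW_COLS %in% nm)) {
    dialect <- "raw"
    dt <- dt[, .RAW_COLS, with = FALSE]
    dt[, samples := lapply(strsplit(samples, ",", fixed = TRUE), as.numeric)]
    if (!all(lengths(dt$samples) == dt$n_samples))
      stop("corrupt event table: n_samples disagrees with samples")
  } else if (all(.FEAT_COLS %in% nm)) {
    dialect <- "feature"
    dt <- dt[, .FEAT_COLS, with = FALSE]
  } else stop("not an event table: unrecognized header in ", path)
  dt[, position := as.integer(position)]
  out <- setDF(dt)
  attr(out, "dialect") <- dialect
  out
}

#' Write an event table
#'
#' Inverse of [readEvents()].  Raw samples and feature values are printed
#' with `%.17g` so that write-then-read reproduces every number exactly.
#'
#' @param events data.frame in either dialect (raw dialect: `samples` list
#'   column or preformatted character).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
  dt <- as.data.table(events)
  fmt <- function(v) vapply(v, function(s)
    paste(sprintf("%.17g", s), collapse = ","), "")
  if ("samples" %in% names(dt)) {
    if (is.list(dt$samples)) {
      dt[, n_samples := lengths(samples)]
      dt[, samples := fmt(samples)]
    }
    dt <- dt[, .RAW_COLS, with = FALSE]
  } else {
    for (cc in c("mean", "median", "std"))
      dt[[cc]] <- sprintf("%.17g", dt[[cc]])
    dt <- dt[, .FEAT_COLS, with = FALSE]
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Convert an event table to a list of EventRead objects
#'
#' @param events raw-dialect event table (as from [readEvents()]).
#' @return named list of [EventRead] objects (names = read ids).
#' @export
asEventReads <- function(events) {
  dt <- as.data.table(events)
  setorder(dt, read_id, position)
  sp <- split(dt, by = "read_id")
  lapply(sp, function(d) {
    if (any(diff(d$position) != 1L))
      stop("read ", d$read_id[1L], ": positions are not contiguous")
    EventRead(d$read_id[1L], d$transcript_id[1L], d$position[1L],
              paste(d$base, collapse = ""), d$samples)
  })
}

#' Convert EventRead objects to a raw-dialect event table
#'
#' @param reads list of [EventRead] objects.
#' @return raw-dialect event table (data.frame with `samples` list column).
#' @export
asEventTable <- function(reads) {
  dt <- rbindlist(lapply(reads, function(r) {
    n <- length(r@segments)
    data.table(read_id = r@read_id, transcript_id = r@transcript_id,
               position = r@start_pos + seq_len(n) - 1L,
               base = strsplit(r@bases, "")[[1L]],
               n_samples = vapply(r@segments, length, 1L),
               samples = r@segments)
  }))
  out <- setDF(dt)
  attr(out, "dialect") <- "raw"
  out
}

#' Extract site feature vectors from a whole event table
#'
#' Bulk equivalent of [normalizeRead()] + [readSiteFeatures()] over every
#' read of an event table, vectorized for large tables.  Raw-dialect input
#' is normalized per read (median shift / MAD scale); feature-dialect
#' input is taken as already carrying per-base statistics on a common
#' scale.  Reads whose MAD is zero fall back to scale 1 and are listed in
#' the `degenerate_reads` attribute of the result.
#'
#' @param events event table in either dialect.
#' @param normalize normalize raw samples per read first (default `TRUE`;
#'   ignored for the feature dialect).
#' @return data.frame with `read_id`, `transcript_id`, `tpos`, `motif` and
#'   the 20 feature columns, one row per complete RRACH window per read.
#' @export
extractFeatures <- function(events, normalize = TRUE) {
  dt <- as.data.table(events)
  dialect <- if ("samples" %in% names(dt)) "raw" else "feature"
  setorder(dt, read_id, transcript_id, position)
  bad <- dt[, any(diff(position) != 1L), by = .(read_id, transcript_id)][V1 == TRUE]
  if (nrow(bad))
    stop("non-contiguous positions for read(s): ",
         paste(head(bad$read_id, 3L), collapse = ", "))
  dt[, row_id := .I]
  dt[, read_idx := .GRP, by = .(read_id, transcript_id)]
  degenerate <- character()

  if (dialect == "raw") {
    # reads are processed in blocks of ~8e6 samples to bound peak memory;
    # normalization is per read, so blocking by read is exact
    ns <- lengths(dt$samples)
    per_read <- dt[, .(tot = sum(lengths(samples))), by = read_idx]
    per_read[, block := pmax(1L, ceiling(cumsum(tot) / 8e6))]
    dt[per_read, block := i.block, on = "read_idx"]
    parts <- vector("list", max(per_read$block))
    for (b in seq_along(parts)) {
      sub <- dt[block == b]
      nss <- lengths(sub$samples)
      long <- data.table(row_id = rep(sub$row_id, nss),
                         read_idx = rep(sub$read_idx, nss),
                         x = unlist(sub$samples, use.names = FALSE))
      if (normalize) {
        # single-statistic grouped passes keep data.table's GForce engaged
        sh <- long[, .(shift = median(x)), by = read_idx]
        long[sh, shift := i.shift, on = "read_idx"]
        long[, x := x - shift]
        long[, shift := abs(x)]
        sc <- long[, .(scale_ = median(shift)), by = read_idx]
        degen_idx <- sc[scale_ == 0, read_idx]
        if (length(degen_idx)) {
          degenerate <- c(degenerate,
                          unique(sub$read_id[sub$read_idx %in% degen_idx]))
          sc[scale_ == 0, scale_ := 1]
        }
        long[sc, scale_ := i.scale_, on = "read_idx"]
        long[, x := x / scale_]
        long[, c("shift", "scale_") := NULL]
      }
      st <- long[, .(mean = mean(x), median = median(x), dwell = .N),
                 by = row_id]
      long[st, mean := i.mean, on = "row_id"]
      long[, mean := (x - mean)^2]
      v <- long[, .(v = mean(mean)), by = row_id]
      st[v, std := sqrt(i.v), on = "row_id"]
      parts[[b]] <- st
    }
    st <- rbindlist(parts)
    fb <- st[dt[, .(row_id, read_idx, read_id, transcript_id, position, base)],
             on = "row_id"]
  } else {
    fb <- dt[, .(row_id, read_idx, read_id, transcript_id, position, base,
                 mean, median, std, dwell)]
  }
  setorder(fb, read_idx, position)
  fb[, idx := .I]

  # per-read sequence scan; centers become global row indices into fb
  seqs <- fb[, .(seq = paste(base, collapse = ""), first = idx[1L],
                 start0 = position[1L], read_id = read_id[1L],
                 transcript_id = transcript_id[1L]), by = read_idx]
  ss <- toupper(chartr("Uu", "Tt", seqs$seq))
  mm <- gregexpr("(?=[AG][AG]AC[ACT])", ss, perl = TRUE)
  nhit <- vapply(mm, function(m) if (m[1L] == -1L) 0L else length(m), 1L)
  ri <- rep(seq_along(ss), nhit)
  starts <- unlist(mm[nhit > 0L], use.names = FALSE)  # 1-based window starts
  hits <- data.table(
    center = seqs$first[ri] + starts + 1L,
    tpos = seqs$start0[ri] + starts + 1L,
    motif = substring(ss[ri], starts, starts + 4L),
    read_id = seqs$read_id[ri], transcript_id = seqs$transcript_id[ri])
  if (!nrow(hits)) {
    out <- data.frame(read_id = character(), transcript_id = character(),
                      tpos = integer(), motif = character())
    out[siteFeatureNames()] <- lapply(siteFeatureNames(), function(x) numeric())
    attr(out, "degenerate_reads") <- degenerate
    return(out)
  }
  blocks <- lapply(-2L:2L, function(off)
    as.matrix(fb[hits$center + off, .(mean, median, std, dwell)]))
  fm <- do.call(cbind, blocks)
  colnames(fm) <- siteFeatureNames()
  out <- data.frame(read_id = hits$read_id,
                    transcript_id = hits$transcript_id,
                    tpos = as.integer(hits$tpos), motif = hits$motif)
  out <- cbind(out, as.data.frame(fm))
  if (length(degenerate))
    warning(length(degenerate), " read(s) with constant signal (MAD = 0)")
  attr(out, "degenerate_reads") <- degenerate
  out
}

#' Read transcript reference sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; RNA (`U`) input is
#' accepted and mapped to DNA alphabet.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readTranscriptFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  Biostrings::DNAStringSet(chartr("Uu", "Tt", as.character(x)))
}
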