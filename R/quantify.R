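# Per-read call binarization, per-site stoichiometry with the >=20
# modified-read support filter, transcript->genome CIGAR mapping, and
# condition comparison.

#' Binarize a per-read modification probability
#'
#' A read/site pair is called modified iff its probability is at least the
#' threshold (ties go to modified).  The default threshold is 0.5.
#'
#' @param probability numeric in `[0, 1]` (vectorized).
#' @param threshold scalar in `[0, 1]`.
#' @return character vector, `"modified"` or `"unmodified"`.
#' @examples
#' binarize(c(0.974, 0.003))
#' @export
binarize <- function(probability, threshold = 0.5) {
  if (any(probability < 0 | probability > 1, na.rm = TRUE) ||
      threshold < 0 || threshold > 1)
    stop("probability and threshold must lie in [0, 1]")
  ifelse(probability >= threshold, "modified", "unmodified")
}

#' Per-read site calls from a bundle and an event table's features
#'
#' Convenience wrapper: predicts every site feature vector and binarizes.
#'
#' @param bundle a [ModelBundle].
#' @param features site feature table ([extractFeatures()]).
#' @param threshold binarization threshold (default 0.5).
#' @return data.frame `read_id, transcript_id, tpos, motif, probability,
#'   call`.
#' @export
callReads <- function(bundle, features, threshold = 0.5) {
  p <- predictSites(bundle, features)
  data.frame(read_id = features$read_id,
             transcript_id = features$transcript_id,
             tpos = features$tpos, motif = features$motif,
             probability = p, call = binarize(p, threshold))
}

#' Aggregate per-read calls into per-site stoichiometry
#'
#' Groups read/site calls by `(transcript_id, tpos)` and computes the
#' modified-read count, total read count and their ratio (the m6A
#' stoichiometry).  A site passes the support filter iff it is backed by
#' at least `min_mod_reads` modified reads (default 20, the
#' "at least 20 modified transcripts" rule).  All sites are returned with
#' the filter recorded; downstream analyses default to passing sites.
#'
#' @param calls data.frame from [callReads()].
#' @param min_mod_reads minimum modified-read support (default 20).
#' @return data.frame `transcript_id, tpos, motif, n_mod, n_total, ratio,
#'   pass_filter`, sorted by transcript and position.
#' @export
aggregateSites <- function(calls, min_mod_reads = 20L) {
  stopifnot(all(c("transcript_id", "tpos", "call") %in% names(calls)))
  dt <- as.data.table(calls)
  out <- dt[, .(motif = motif[1L],
                n_mod = sum(call == "modified"),
                n_total = .N), by = .(transcript_id, tpos)]
  out[, ratio := n_mod / n_total]
  out[, pass_filter := n_mod >= min_mod_reads]
  setorder(out, transcript_id, tpos)
  setDF(out)
}

# ---- transcript -> genome mapping -----------------------------------------

.cigarOps <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  tok <- regmatches(cigar, list(m))[[1L]]
  if (!length(tok) || sum(nchar(tok)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  list(op = substr(tok, nchar(tok), nchar(tok)),
       len = as.integer(substr(tok, 1L, nchar(tok) - 1L)))
}

# genomic coordinate (1-based) for each query base (1-based), NA where the
# query base is inserted/soft-clipped relative to the genome
.queryToGenomeMap <- function(cigar, gpos) {
  cg <- .cigarOps(cigar)
  qlen <- sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")])
  v <- rep(NA_integer_, qlen)
  q <- 0L; g <- as.integer(gpos)
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      v[q + seq_len(len)] <- g + seq_len(len) - 1L
      q <- q + len; g <- g + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      g <- g + len
    }                                        # H/P consume nothing here
  }
  v
}

#' Map transcript coordinates to the genome through a CIGAR alignment
#'
#' Walks the CIGAR of a transcript-to-genome alignment base by base:
#' M/=/X advance both coordinates, I advances the transcript only, D/N
#' advance the genome only.  For reverse-strand alignments the transcript
#' is stored reverse-complemented in the alignment, so transcript
#' position `t` (0-based, 5'->3' on the transcript) corresponds to query
#' base `qlen - t` and the orientation flips.  Positions falling in an
#' insertion or outside the alignment are returned unmappable (`NA`
#' coordinates, `mappable = FALSE`).
#'
#' @param tpos integer vector of 0-based transcript coordinates.
#' @param chrom reference sequence name of the alignment.
#' @param gpos 1-based leftmost genomic position of the alignment.
#' @param strand `"+"` or `"-"`.
#' @param cigar CIGAR string.
#' @return data.frame `chrom, gpos (1-based), strand, mappable`, one row
#'   per input position.
#' @examples
#' mapToGenome(4L, "chr1", 101L, "+", "10M")          # 105
#' mapToGenome(7L, "chr1", 101L, "+", "5M100N5M")     # 208
#' mapToGenome(0L, "chr1", 101L, "-", "10M")          # 110
#' @export
mapToGenome <- function(tpos, chrom, gpos, strand, cigar) {
  stopifnot(strand %in% c("+", "-"), length(cigar) == 1L)
  v <- .queryToGenomeMap(cigar, gpos)
  qlen <- length(v)
  t <- as.integer(tpos)
  q <- if (strand == "+") t + 1L else qlen - t
  ok <- q >= 1L & q <= qlen
  g <- rep(NA_integer_, length(t))
  g[ok] <- v[q[ok]]
  data.frame(chrom = ifelse(is.na(g), NA_character_, as.character(chrom)),
             gpos = g,
             strand = ifelse(is.na(g), NA_character_, strand),
             mappable = !is.na(g))
}

#' Read transcript-to-genome alignments from SAM/BAM
#'
#' SAM input is converted on the fly.  One (primary) record per
#' transcript is expected; the query name is taken as the transcript id.
#'
#' @param path SAM or BAM file.
#' @return data.frame `transcript_id, chrom, gpos, strand, cigar`.
#' @export
readAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  fl <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                               isSecondaryAlignment = FALSE)
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar"), flag = fl))[[1L]]
  data.frame(transcript_id = b$qname, chrom = as.character(b$rname),
             gpos = b$pos, strand = as.character(b$strand),
             cigar = b$cigar)
}

#' Attach genomic coordinates to a site table
#'
#' Maps every site through its transcript's alignment.  Sites on
#' transcripts without an alignment, or falling into insertions, are kept
#' with `mappable = FALSE` and `NA` coordinates.
#'
#' @param sites site table from [aggregateSites()].
#' @param alignments data.frame from [readAlignments()].
#' @return `sites` with added columns `chrom, gpos, gstrand, mappable`.
#' @export
annotateSiteGenomics <- function(sites, alignments) {
  sites$chrom <- NA_character_
  sites$gpos <- NA_integer_
  sites$gstrand <- NA_character_
  sites$mappable <- FALSE
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    w <- which(sites$transcript_id == a$transcript_id)
    if (!length(w)) next
    m <- mapToGenome(sites$tpos[w], a$chrom, a$gpos, a$strand, a$cigar)
    sites$chrom[w] <- m$chrom
    sites$gpos[w] <- m$gpos
    sites$gstrand[w] <- m$strand
    sites$mappable[w] <- m$mappable
  }
  sites
}

#' Pool a transcript-level site table by genomic coordinate
#'
#' Reads from transcripts sharing a genomic A are summed so that
#' genome-level stoichiometry counts every read once per genomic site;
#' the transcript-level table remains the right input for isoform-aware
#' analyses.
#'
#' @param sites annotated site table ([annotateSiteGenomics()]).
#' @param min_mod_reads support filter re-applied to the pooled counts.
#' @return data.frame `chrom, gpos, gstrand, motif, n_mod, n_total,
#'   ratio, pass_filter`.
#' @export
poolSitesByGenome <- function(sites, min_mod_reads = 20L) {
  dt <- as.data.table(sites[sites$mappable, , drop = FALSE])
  out <- dt[, .(motif = motif[1L], n_mod = sum(n_mod),
                n_total = sum(n_total)),
            by = .(chrom, gpos, gstrand)]
  out[, ratio := n_mod / n_total]
  out[, pass_filter := n_mod >= min_mod_reads]
  setorder(out, chrom, gpos)
  setDF(out)
}

#' Compare the m6A site sets of two conditions
#'
#' Intersects two pass-filter site tables on exact coordinates (genomic
#' `(chrom, gpos, strand)` when both carry mappable coordinates,
#' otherwise `(transcript_id, tpos)`) and reports set overlap and
#' per-shared-site stoichiometry deltas (B - A).
#'
#' @param sitesA,sitesB site tables (pass-filter rows are used).
#' @param key `"auto"`, `"genomic"` or `"transcript"`.
#' @return list with `n_a`, `n_b`, `n_shared`, `n_a_only`, `n_b_only`,
#'   `shared` (data.frame `key, ratio_a, ratio_b, delta`) and
#'   `median_delta`.
#' @export
compareConditions <- function(sitesA, sitesB,
                              key = c("auto", "genomic", "transcript")) {
  key <- match.arg(key)
  pick <- function(s) s[!("pass_filter" %in% names(s)) | s$pass_filter, ,
                        drop = FALSE]
  a <- pick(sitesA); b <- pick(sitesB)
  hasg <- function(s) all(c("chrom", "gpos") %in% names(s)) &&
    any(!is.na(s$gpos))
  if (key == "auto") key <- if (hasg(a) && hasg(b)) "genomic" else "transcript"
  if (key == "genomic") {
    if (!hasg(a) || !hasg(b))
      stop("genomic keying requested but a site set lacks genomic ",
           "coordinates; force key = \"transcript\"")
    a <- a[!is.na(a$gpos), ]; b <- b[!is.na(b$gpos), ]
    ka <- paste(a$chrom, a$gpos, a$gstrand)
    kb <- paste(b$chrom, b$gpos, b$gstrand)
  } else {
    ka <- paste(a$transcript_id, a$tpos)
    kb <- paste(b$transcript_id, b$tpos)
  }
  shared_keys <- intersect(ka, kb)
  sh <- data.frame(key = shared_keys,
                   ratio_a = a$ratio[match(shared_keys, ka)],
                   ratio_b = b$ratio[match(shared_keys, kb)])
  sh$delta <- sh$ratio_b - sh$ratio_a
  list(key = key, n_a = length(ka), n_b = length(kb),
       n_shared = length(shared_keys),
       n_a_only = length(ka) - length(shared_keys),
       n_b_only = length(kb) - length(shared_keys),
       shared = sh,
       median_delta = if (nrow(sh)) median(sh$delta) else NA_real_)
}

#' Per-gene m6A level
#'
#' Unweighted mean stoichiometry of the passing sites of each gene; genes
#' without a passing site are absent from the output.
#'
#' @param sites site table ([aggregateSites()]).
#' @param tx2gene data.frame `transcript_id, gene_id`.
#' @return data.frame `gene_id, m6a_level, n_sites`.
#' @export
geneM6aLevel <- function(sites, tx2gene) {
  dt <- as.data.table(sites)[pass_filter == TRUE]
  dt <- merge(dt, as.data.table(tx2gene), by = "transcript_id")
  out <- dt[, .(m6a_level = mean(ratio), n_sites = .N), by = gene_id]
  setorder(out, gene_id)
  setDF(out)
}

#' Write a site table / BED6 export
#'
#' The TSV carries `chrom, pos (1-based), strand, transcript_id, tpos
#' (0-based), motif, n_mod, n_total, ratio, pass_filter`.  The BED6
#' export is 0-based half-open with `score = round(1000 * ratio)`.
#'
#' @param sites annotated site table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSites <- function(sites, path) {
  out <- data.frame(
    chrom = sites$chrom %||% NA, pos = sites$gpos %||% NA,
    strand = sites$gstrand %||% NA,
    transcript_id = sites$transcript_id, tpos = sites$tpos,
    motif = sites$motif, n_mod = sites$n_mod, n_total = sites$n_total,
    ratio = sprintf("%.17g", sites$ratio), pass_filter = sites$pass_filter)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeSites
#' @export
sitesToBed <- function(sites, path) {
  stopifnot(all(c("chrom", "gpos", "gstrand") %in% names(sites)))
  s <- sites[!is.na(sites$gpos), , drop = FALSE]
  bed <- data.frame(chrom = s$chrom, start = s$gpos - 1L, end = s$gpos,
                    name = paste0(s$transcript_id, ":", s$tpos, ":", s$motif),
                    score = round(1000 * s$ratio), strand = s$gstrand)
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
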