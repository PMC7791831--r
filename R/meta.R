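# Transcript models from GTF, scaled metagene profiles, exon-length
# comparison and expression--methylation correlation.

#' Transcript models from a GTF/GFF annotation
#'
#' Reads `exon` and `CDS` features and derives, per transcript, the exon
#' chain and the transcript-coordinate lengths of the 5'UTR, CDS and
#' 3'UTR (which sum to the transcript length).  Transcripts without CDS
#' features are dropped.
#'
#' @param path GTF/GFF3 file (anything [rtracklayer::import()] reads).
#' @return list of class `TranscriptModels`: `table` (data.frame
#'   `transcript_id, gene_id, chrom, strand, tx_len, utr5_len, cds_len,
#'   utr3_len`) and `exons` (a [GenomicRanges::GRanges] with
#'   `transcript_id`, `gene_id` metadata, one range per exon).
#' @export
transcriptModelsFromGtf <- function(path) {
  gr <- rtracklayer::import(path)
  typ <- as.character(gr$type)
  ex <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  if (!length(ex)) stop("no exon features in ", path)
  if (!length(cds)) stop("no CDS features in ", path)

  exl <- split(ex, as.character(ex$transcript_id))
  cdsl <- split(cds, as.character(cds$transcript_id))
  ids <- intersect(names(exl), names(cdsl))
  rows <- lapply(ids, function(id) {
    e <- exl[[id]]
    strand <- as.character(BiocGenerics::strand(e))[1L]
    # order exons in transcription direction
    o <- order(BiocGenerics::start(e),
               decreasing = identical(strand, "-"))
    e <- e[o]
    w <- BiocGenerics::width(e)
    tx_len <- sum(w)
    cd <- cdsl[[id]]
    cds_len <- sum(BiocGenerics::width(cd))
    # transcript coordinate (0-based) of the CDS 5'-most genomic base
    g5 <- if (identical(strand, "-")) max(BiocGenerics::end(cd))
          else min(BiocGenerics::start(cd))
    off <- 0L; utr5 <- NA_integer_
    for (i in seq_along(e)) {
      s <- BiocGenerics::start(e)[i]; en <- BiocGenerics::end(e)[i]
      if (g5 >= s && g5 <= en) {
        utr5 <- off + if (identical(strand, "-")) en - g5 else g5 - s
        break
      }
      off <- off + w[i]
    }
    if (is.na(utr5)) stop("CDS start outside exons for ", id)
    data.frame(transcript_id = id,
               gene_id = as.character(e$gene_id)[1L],
               chrom = as.character(GenomicRanges::seqnames(e))[1L],
               strand = strand, tx_len = tx_len,
               utr5_len = as.integer(utr5), cds_len = as.integer(cds_len),
               utr3_len = as.integer(tx_len - utr5 - cds_len))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, exons = ex), class = "TranscriptModels")
}

#' @export
print.TranscriptModels <- function(x, ...) {
  cat("TranscriptModels:", nrow(x$table), "transcripts,",
      length(x$exons), "exons\n")
  invisible(x)
}

.scaledPosition <- function(tpos, utr5, cds, utr3) {
  # u in [0,3): 5'UTR [0,1), CDS [1,2), 3'UTR [2,3)
  s <- utr5; e <- utr5 + cds
  ifelse(tpos < s, tpos / utr5,
         ifelse(tpos < e, 1 + (tpos - s) / cds, 2 + (tpos - e) / utr3))
}

#' Metagene profile of m6A sites over scaled transcript regions
#'
#' Each site is mapped to the scaled coordinate `u`: `tpos/len(5'UTR)`
#' within the 5'UTR, `1 + (tpos - s)/len(CDS)` within the CDS, and
#' `2 + (tpos - e)/len(3'UTR)` within the 3'UTR, where `s`/`e` are the
#' transcript coordinates of the CDS start/end.  A site exactly at the
#' stop-codon boundary therefore lands at `u = 2.0`, the first 3'UTR bin.
#' The histogram uses `bins_per_region` equal bins per region; densities
#' integrate to one over `[0, 3)`.
#'
#' @param sites data.frame with `transcript_id` and `tpos` (0-based).
#' @param models a `TranscriptModels` ([transcriptModelsFromGtf()]) or a
#'   data.frame with `transcript_id, tx_len, utr5_len, cds_len, utr3_len`.
#' @param bins_per_region bins per region (default 100).
#' @return a [MetageneProfile].
#' @export
metageneProfile <- function(sites, models, bins_per_region = 100L) {
  tab <- if (inherits(models, "TranscriptModels")) models$table else models
  stopifnot(all(c("transcript_id", "utr5_len", "cds_len", "utr3_len")
                %in% names(tab)))
  i <- match(sites$transcript_id, tab$transcript_id)
  if (anyNA(i)) stop("site on transcript without model: ",
                     sites$transcript_id[which(is.na(i))[1L]])
  utr5 <- tab$utr5_len[i]; cds <- tab$cds_len[i]; utr3 <- tab$utr3_len[i]
  tl <- utr5 + cds + utr3
  if (any(sites$tpos < 0L | sites$tpos >= tl))
    stop("site outside transcript bounds")
  u <- .scaledPosition(sites$tpos, utr5, cds, utr3)

  B <- as.integer(bins_per_region)
  edges <- seq(0, 3, length.out = 3L * B + 1L)
  bin <- pmin(findInterval(u, edges), 3L * B)    # left-closed bins
  count <- tabulate(bin, nbins = 3L * B)
  width <- 3 / (3L * B)
  n <- length(u)
  bins <- data.frame(
    bin = seq_len(3L * B),
    region = rep(c("5'UTR", "CDS", "3'UTR"), each = B),
    lower = head(edges, -1L), upper = tail(edges, -1L),
    count = count,
    density = if (n > 0) count / (n * width) else 0)
  new("MetageneProfile", bins = bins, n_sites = as.integer(n),
      bins_per_region = B)
}

#' Compare lengths of m6A-containing exons with control exons
#'
#' Reports the two medians, their difference (m6A minus control) and the
#' Wilcoxon rank-sum statistic, a rank-based location comparison.
#'
#' @param m6a_lengths,control_lengths non-empty numeric vectors of exon
#'   lengths (nt).
#' @return list `median_m6a, median_control, median_diff, rank_statistic`.
#' @export
exonLengthComparison <- function(m6a_lengths, control_lengths) {
  if (!length(m6a_lengths) || !length(control_lengths))
    stop("both exon length lists must be non-empty")
  w <- wilcox.test(m6a_lengths, control_lengths, exact = FALSE)
  list(median_m6a = median(m6a_lengths),
       median_control = median(control_lengths),
       median_diff = median(m6a_lengths) - median(control_lengths),
       rank_statistic = unname(w$statistic))
}

#' Exon lengths partitioned by m6A content
#'
#' Overlaps genomically mapped sites with the annotation's exons and
#' returns the widths of exons containing at least one site versus those
#' containing none.
#'
#' @param sites annotated site table with `chrom, gpos` (passing,
#'   mappable rows are used).
#' @param models a `TranscriptModels`.
#' @return list `m6a`, `control` of exon widths.
#' @export
m6aExonLengths <- function(sites, models) {
  s <- sites[!is.na(sites$gpos), , drop = FALSE]
  if ("pass_filter" %in% names(s)) s <- s[s$pass_filter, , drop = FALSE]
  gr <- GenomicRanges::GRanges(s$chrom,
                               IRanges::IRanges(s$gpos, width = 1L))
  ex <- unique(GenomicRanges::granges(models$exons))
  hit <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(gr, ex, ignore.strand = TRUE)))
  rest <- setdiff(seq_along(ex), hit)
  list(m6a = BiocGenerics::width(ex)[hit],
       control = BiocGenerics::width(ex)[rest])
}

#' Pearson correlation between paired per-gene quantities
#'
#' Used for expression versus m6A level and expression versus poly(A)
#' length.  Requires at least three finite pairs; zero variance in either
#' variable flags the correlation undefined.
#'
#' @param x,y paired numeric vectors.
#' @return list `r, n, undefined`.
#' @export
correlateGenes <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n = length(x), undefined = TRUE))
  list(r = cor(x, y, method = "pearson"), n = length(x), undefined = FALSE)
}

#' Per-gene expression from read counts
#'
#' Gene expression is quantified as the number of direct RNA reads
#' assigned to the gene; `log10(count + 1)` is the scale used for
#' correlations.
#'
#' @param read_tx data.frame `read_id, transcript_id` (one row per read).
#' @param tx2gene data.frame `transcript_id, gene_id`.
#' @return data.frame `gene_id, n_reads, log_expr`.
#' @export
geneExpression <- function(read_tx, tx2gene) {
  dt <- unique(as.data.table(read_tx)[, .(read_id, transcript_id)])
  dt <- merge(dt, as.data.table(tx2gene), by = "transcript_id")
  out <- dt[, .(n_reads = uniqueN(read_id)), by = gene_id]
  out[, log_expr := log10(n_reads + 1)]
  setorder(out, gene_id)
  setDF(out)
}
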