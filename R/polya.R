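# Poly(A)-site clustering (24-nt single linkage), proximal/distal role
# assignment, the two-fold poly(A)-length APA screen, and coupling of
# per-isoform m6A ratios to APA choice.

#' Read a per-read poly(A) table
#'
#' TSV with header `read_id, gene_id, chrom, end_pos (1-based genomic
#' 3'-end), strand, polya_length, qc_tag` (nanopolish-polya-style columns
#' are accepted through `column_map`).  Records whose `qc_tag` is not
#' `"PASS"` are dropped unless `keep_all`.
#'
#' @param path TSV file.
#' @param column_map named character vector mapping the expected column
#'   names to the names found in the file, e.g.
#'   `c(read_id = "readname", polya_length = "polya_length")`.
#' @param keep_all keep non-PASS records (default `FALSE`).
#' @return data.frame with the canonical columns.
#' @export
readPolyaTable <- function(path, column_map = NULL, keep_all = FALSE) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!is.null(column_map))
    setnames(dt, unname(column_map), names(column_map), skip_absent = TRUE)
  need <- c("read_id", "gene_id", "chrom", "end_pos", "strand",
            "polya_length", "qc_tag")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("poly(A) table lacks column(s): ",
                         paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  if (!keep_all) dt <- dt[qc_tag == "PASS"]
  setDF(dt)
}

#' Single-linkage clustering of sorted end positions
#'
#' Chains consecutive positions whose gap is at most `window` (inclusive
#' at exactly `window`); a larger gap starts a new cluster.
#'
#' @param positions sorted (ascending) integer positions.
#' @param window maximum gap joining a cluster (default 24 nt).
#' @return integer cluster ids (1-based, nondecreasing).
#' @examples
#' clusterEnds(c(100, 110, 150))   # 1 1 2
#' clusterEnds(c(100, 124, 148))   # 1 1 1
#' @export
clusterEnds <- function(positions, window = 24L) {
  if (!length(positions)) return(integer())
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  c(1L, cumsum(diff(positions) > window) + 1L)
}

#' Cluster read 3'-ends into poly(A) site clusters
#'
#' Groups reads per gene and strand, sorts their genomic 3'-end
#' positions, and applies [clusterEnds()] stepwise single linkage within
#' `window` nt.  The representative position of a cluster is the modal
#' end; ties are broken toward the most 3' position in transcription
#' direction.
#'
#' @param ends data.frame as from [readPolyaTable()] (PASS records).
#' @param window clustering window (default 24 nt).
#' @return list with `clusters` (data.frame `gene_id, strand, cluster,
#'   n_reads, rep_pos, min_pos, max_pos, polya_mean, polya_median`) and
#'   `membership` (data.frame `read_id, gene_id, strand, cluster`).
#' @export
clusterPolyaSites <- function(ends, window = 24L) {
  dt <- as.data.table(ends)
  setorder(dt, gene_id, strand, end_pos)
  dt[, cluster := clusterEnds(end_pos, window), by = .(gene_id, strand)]
  reppos <- function(p, strand) {
    tb <- table(p)
    modal <- as.integer(names(tb)[tb == max(tb)])
    if (identical(strand, "-")) min(modal) else max(modal)
  }
  cl <- dt[, .(n_reads = .N,
               rep_pos = reppos(end_pos, strand[1L]),
               min_pos = min(end_pos), max_pos = max(end_pos),
               polya_mean = mean(polya_length, na.rm = TRUE),
               polya_median = median(polya_length, na.rm = TRUE)),
           by = .(gene_id, strand, cluster)]
  list(clusters = setDF(cl),
       membership = setDF(dt[, .(read_id, gene_id, strand, cluster)]))
}

#' Assign proximal/distal roles to a gene's poly(A) clusters
#'
#' Among clusters with at least `min_cluster_reads` reads, the cluster
#' whose representative lies nearest the stop codon in transcription
#' direction is proximal and the farthest is distal; any in between are
#' `"other"`.  Genes with fewer than two qualifying clusters are non-APA
#' (`role = NA`).
#'
#' @param clusters cluster table from [clusterPolyaSites()].
#' @param stop_codons data.frame `gene_id, stop_pos` (genomic, 1-based).
#' @param min_cluster_reads qualification threshold (default 10).
#' @return `clusters` with added columns `dist_stop`, `role` and `apa`
#'   (TRUE for genes with both a proximal and a distal cluster).
#' @export
assignProximalDistal <- function(clusters, stop_codons,
                                 min_cluster_reads = 10L) {
  cl <- as.data.table(clusters)
  if (any(!cl$strand %in% c("+", "-"))) stop("unknown strand")
  sc <- as.data.table(stop_codons)
  cl <- merge(cl, sc[, .(gene_id, stop_pos)], by = "gene_id", all.x = TRUE)
  cl[, dist_stop := ifelse(strand == "+", rep_pos - stop_pos,
                           stop_pos - rep_pos)]
  cl[, qual := n_reads >= min_cluster_reads]
  cl[, role := NA_character_]
  cl[qual == TRUE, role := {
    if (.N >= 2L) {
      r <- rep("other", .N)
      r[which.min(dist_stop)] <- "proximal"
      r[which.max(dist_stop)] <- "distal"
      r
    } else NA_character_
  }, by = gene_id]
  cl[, apa := gene_id %in% cl[role == "proximal", gene_id]]
  cl[, qual := NULL]
  setDF(cl)
}

#' Two-fold poly(A)-length APA screen
#'
#' Flags genes whose proximal and distal clusters differ at least
#' two-fold (inclusive) in mean poly(A) tail length.
#'
#' @param clusters role-annotated cluster table
#'   ([assignProximalDistal()]).
#' @return data.frame `gene_id, polya_proximal, polya_distal, fold,
#'   flagged` (fold is `NA`-undefined when a mean length is zero).
#' @export
apaPolyaLengthScreen <- function(clusters) {
  cl <- as.data.table(clusters)
  p <- cl[role == "proximal", .(gene_id, polya_proximal = polya_mean)]
  d <- cl[role == "distal", .(gene_id, polya_distal = polya_mean)]
  out <- merge(p, d, by = "gene_id")
  out[, fold := ifelse(pmin(polya_proximal, polya_distal) <= 0, NA_real_,
                       pmax(polya_proximal, polya_distal) /
                         pmin(polya_proximal, polya_distal))]
  out[, flagged := !is.na(fold) & fold >= 2]
  setDF(out)
}

#' Gene-level pooled site support filter
#'
#' Pools read/site calls of all isoforms of a gene by `(gene_id, tpos)`
#' (isoforms of a gene share transcript coordinates 5' of the proximal
#' poly(A) cut) and keeps positions backed by at least `min_mod_reads`
#' modified reads — the same support rule as [aggregateSites()], applied
#' at the gene level so that an isoform is not dropped just because its
#' own coverage falls under the cutoff.
#'
#' @param read_calls data.frame from [callReads()].
#' @param tx2gene data.frame `transcript_id, gene_id`.
#' @param min_mod_reads support threshold (default 20).
#' @return data.frame `gene_id, tpos, n_mod, n_total, pass_filter`.
#' @export
genePassSites <- function(read_calls, tx2gene, min_mod_reads = 20L) {
  dt <- merge(as.data.table(read_calls), as.data.table(tx2gene),
              by = "transcript_id")
  out <- dt[, .(n_mod = sum(call == "modified"), n_total = .N),
            by = .(gene_id, tpos)]
  out[, pass_filter := n_mod >= min_mod_reads]
  setDF(out)
}

#' Methylation fold change between distal and proximal isoforms
#'
#' For every APA gene, the per-cluster m6A ratio is the fraction of
#' modified read/site calls over the cluster's member reads, restricted
#' to sites passing the gene-level support filter; the reported value is
#' `log2((ratio_distal + eps) / (ratio_proximal + eps))` with a
#' pseudo-ratio `eps` guarding zero ratios.
#'
#' @param clusters role-annotated cluster table
#'   ([assignProximalDistal()]).
#' @param membership read-to-cluster membership ([clusterPolyaSites()]).
#' @param read_calls per-read site calls ([callReads()]).
#' @param tx2gene data.frame `transcript_id, gene_id`.
#' @param pass_sites gene-level passing sites ([genePassSites()]); built
#'   from `read_calls` when `NULL`.
#' @param eps pseudo-ratio (default 0.01).
#' @param min_cluster_reads minimum member read/site calls per isoform
#'   (default 10).
#' @return data.frame `gene_id, ratio_proximal, ratio_distal, n_proximal,
#'   n_distal, log2fc`.
#' @export
apaMethylationFoldChange <- function(clusters, membership, read_calls,
                                     tx2gene, pass_sites = NULL,
                                     eps = 0.01, min_cluster_reads = 10L) {
  if (is.null(pass_sites)) pass_sites <- genePassSites(read_calls, tx2gene)
  ps <- as.data.table(pass_sites)[pass_filter == TRUE, .(gene_id, tpos)]
  rc <- merge(as.data.table(read_calls), as.data.table(tx2gene),
              by = "transcript_id")
  rc <- merge(rc, ps, by = c("gene_id", "tpos"))
  mem <- as.data.table(membership)
  rc <- merge(rc, mem[, .(read_id, gene_id, cluster)],
              by = c("read_id", "gene_id"))
  cr <- rc[, .(ratio = mean(call == "modified"), n = .N),
           by = .(gene_id, cluster)]
  cl <- as.data.table(clusters)[role %in% c("proximal", "distal"),
                                .(gene_id, cluster, role)]
  cr <- merge(cr, cl, by = c("gene_id", "cluster"))
  cr <- cr[n >= min_cluster_reads]
  wide <- data.table::dcast(cr, gene_id ~ role,
                            value.var = c("ratio", "n"))
  need <- c("ratio_proximal", "ratio_distal", "n_proximal", "n_distal")
  if (!all(need %in% names(wide)))
    return(data.frame(gene_id = character(), ratio_proximal = numeric(),
                      ratio_distal = numeric(), n_proximal = integer(),
                      n_distal = integer(), log2fc = numeric()))
  wide <- wide[!is.na(ratio_proximal) & !is.na(ratio_distal)]
  wide[, log2fc := log2((ratio_distal + eps) / (ratio_proximal + eps))]
  setDF(wide[, c(list(gene_id = gene_id), .SD),
             .SDcols = c(need, "log2fc")])
}

#' Poly(A) tail length summary
#'
#' @param polya data.frame with `polya_length` (PASS records).
#' @return list `mean`, `median`, `n`.
#' @export
polyaLengthSummary <- function(polya) {
  x <- polya$polya_length
  x <- x[is.finite(x)]
  list(mean = mean(x), median = median(x), n = length(x))
}
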