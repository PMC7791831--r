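# Synthetic-data generator: labeled training events, known-ratio read
# mixtures, and an annotated transcriptome with APA isoforms.  Every
# generator is a pure function of (params, seed); mixtures use a per-site
# substream so changing the depth of one site never reshuffles another.

#' Simulation parameters
#'
#' Defaults encode the assumed statistical structure of segmented direct
#' RNA signal: motif-dependent current levels, Gaussian segment noise, a
#' geometric dwell distribution, and a modification effect confined to
#' the central A (mean shift `mod_shift` raw units, dwell multiplier
#' `mod_dwell_mult`), optionally spilling into the +-1 neighbours.
#'
#' @param seed integer seed.
#' @param base_means unmodified per-base current means (raw units).
#' @param kmer_sd optional spread (raw units) of a deterministic 5-mer
#'   context offset added to each base's current level, emulating the
#'   k-mer dependence of pore current (default 0: the minimal per-base
#'   level model).
#' @param noise_sd within-segment sample standard deviation.
#' @param dwell_mean,dwell_min geometric dwell distribution (mean number
#'   of raw samples per base, hard minimum).
#' @param mod_shift current mean shift of a modified central A (raw
#'   units, applied before per-read normalization).
#' @param mod_dwell_mult dwell-mean multiplier of a modified central A.
#' @param context_spill apply half the shift to the +-1 neighbours
#'   (default off: minimal per-base effect model).
#' @param read_flank bases flanking the RRACH motif on either side of
#'   labeled/mixture reads (default 48, i.e. 101-base molecules), long
#'   enough for the per-read median/MAD normalization to be about as
#'   stable as on full-length transcript reads.
#' @param depth reads per isoform in the transcriptome generator.
#' @param n_genes,apa_fraction transcriptome size and fraction of genes
#'   with two poly(A) isoforms.
#' @param utr5_range,cds_range,utr3_range transcript region length ranges
#'   (nt; CDS is rounded to a codon multiple).
#' @param sites_per_gene range of planted RRACH sites per gene.
#' @param stop_bias fraction of planted sites drawn from the window
#'   spanning the last CDS decile and the adjacent 3'UTR (the stop-codon
#'   enrichment the profile module is meant to detect).
#' @param ratio_range range of per-gene true m6A ratios (the proximal
#'   isoform's ratio for APA genes; the distal isoform gets half of it).
#' @param apa_offset distance (nt) between proximal and distal poly(A)
#'   sites (>= 50).
#' @param apa_polya_means mean poly(A) tail lengths (nt) of proximal and
#'   distal isoforms of APA genes.
#' @param polya_mean,polya_gene_sd,polya_read_sd poly(A) tail length
#'   model for non-APA genes: per-gene mean drawn around `polya_mean`,
#'   per-read noise `polya_read_sd`.
#' @param expression_sd log-normal spread of per-gene read depth.
#' @param m6a_expr_slope,polya_expr_slope optional couplings of the
#'   per-gene m6A ratio / poly(A) length to log10 expression (negative
#'   values induce the negative correlations seen in real data; default
#'   0, uncoupled).
#' @param pass_rate fraction of poly(A) records with qc tag PASS.
#' @return list of class `simParams`.
#' @export
simParams <- function(seed = 1L,
                      base_means = c(A = 100, C = 90, G = 110, T = 80),
                      kmer_sd = 0,
                      noise_sd = 2.0, dwell_mean = 8, dwell_min = 3L,
                      mod_shift = 3.0, mod_dwell_mult = 1.5,
                      context_spill = FALSE, read_flank = 48L,
                      depth = 100L, n_genes = 100L, apa_fraction = 0.5,
                      utr5_range = c(30L, 60L), cds_range = c(150L, 300L),
                      utr3_range = c(150L, 250L),
                      sites_per_gene = c(3L, 6L), stop_bias = 0.7,
                      ratio_range = c(0.5, 0.8), apa_offset = 60L,
                      apa_polya_means = c(proximal = 45, distal = 95),
                      polya_mean = 90, polya_gene_sd = 15,
                      polya_read_sd = 8,
                      expression_sd = 0.25,
                      m6a_expr_slope = 0, polya_expr_slope = 0,
                      pass_rate = 0.97) {
  stopifnot(noise_sd > 0, dwell_min >= 1L, dwell_mean > dwell_min,
            apa_fraction >= 0, apa_fraction <= 1, apa_offset >= 50L,
            all(utr5_range > 0), all(cds_range > 0), all(utr3_range > 0),
            all(ratio_range >= 0), all(ratio_range <= 1))
  structure(as.list(environment()), class = "simParams")
}

.rdwell <- function(n, mean, min) {
  min + rgeom(n, 1 / (mean - min + 1))
}

# deterministic pseudo-random current offset of a 5-mer context: a fixed
# function of the sequence (like a pore model table), not of the seed
.kmerOffset <- function(kmers, kmer_sd) {
  if (kmer_sd == 0) return(numeric(length(kmers)))
  u <- unique(kmers)
  dig <- matrix(match(strsplit(paste(u, collapse = ""), "")[[1L]],
                      c("A", "C", "G", "T")) - 1L, nrow = 5L)
  idx <- as.integer(colSums(dig * 4L^(0:4)))          # 0..1023
  h <- (idx * 2654435761) %% 4096
  off <- kmer_sd * stats::qnorm((h + 0.5) / 4096)
  off[match(kmers, u)]
}

# per-position 5-mer contexts of a character vector of bases (A-padded
# at the ends)
.contextKmers <- function(bases) {
  n <- length(bases)
  pad <- c("A", "A", bases, "A", "A")
  paste0(pad[1:n], pad[2:(n + 1L)], pad[3:(n + 2L)],
         pad[4:(n + 3L)], pad[5:(n + 4L)])
}

# per-base event generation; base_dt: read_id, transcript_id, position,
# base, mod_center (logical), mod_side (logical).  RNG must be seeded by
# the caller.
.genEvents <- function(base_dt, params) {
  dt <- as.data.table(base_dt)
  mu <- unname(params$base_means[dt$base]) +
    (if ("kmer" %in% names(dt))
       .kmerOffset(dt$kmer, params$kmer_sd %||% 0) else 0) +
    ifelse(dt$mod_center, params$mod_shift, 0) +
    if (params$context_spill)
      ifelse(dt$mod_side, params$mod_shift / 2, 0) else 0
  dmean <- ifelse(dt$mod_center,
                  params$dwell_mean * params$mod_dwell_mult,
                  params$dwell_mean)
  dwell <- params$dwell_min + rgeom(nrow(dt), 1 / (dmean - params$dwell_min + 1))
  x <- rnorm(sum(dwell), rep(mu, dwell), params$noise_sd)
  res <- data.frame(read_id = dt$read_id, transcript_id = dt$transcript_id,
                    position = dt$position, base = dt$base,
                    n_samples = dwell)
  res$samples <- vctrs::vec_chop(x, sizes = dwell)
  attr(res, "dialect") <- "raw"
  res
}

.randBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate labeled training events
#'
#' For each of the twelve RRACH motifs, `n_per_motif_per_class` modified
#' and as many unmodified reads are generated; each read is a short
#' molecule (`read_flank` random bases on either side of the motif) whose
#' central A carries the modification effect when labeled modified.
#'
#' @param params a [simParams()].
#' @param n_per_motif_per_class reads per motif per class.
#' @param dir optional output directory (`events.tsv`, `labels.tsv`).
#' @return list with `events` (raw-dialect event table), `labels`
#'   (data.frame `read_id, transcript_id, tpos, motif, label`).
#' @export
simulateLabeledEvents <- function(params = simParams(),
                                  n_per_motif_per_class = 500L,
                                  dir = NULL) {
  n <- as.integer(n_per_motif_per_class)
  if (n < 1L) stop("n_per_motif_per_class must be >= 1")
  set.seed(params$seed)
  motifs <- enumerateRrachMotifs()
  reads <- data.table(
    motif = rep(motifs, each = 2L * n),
    label = rep(rep(c(1L, 0L), each = n), times = length(motifs)))
  reads[, read_id := sprintf("lab_%s_%s_%05d", motif,
                             ifelse(label == 1L, "mod", "unm"),
                             seq_len(.N)), by = .(motif, label)]
  reads[, transcript_id := paste0("txlab_", motif)]
  N <- nrow(reads)
  fl <- as.integer(params$read_flank)
  rl <- 2L * fl + 5L                       # read length
  ctr <- fl + 2L                           # 0-based center position
  flank <- matrix(.randBases(2L * fl * N), ncol = 2L * fl)
  baseschar <- cbind(flank[, seq_len(fl), drop = FALSE],
                     t(matrix(unlist(strsplit(reads$motif, "")), nrow = 5L)),
                     flank[, fl + seq_len(fl), drop = FALSE])
  pos <- rep(0:(rl - 1L), times = N)
  modv <- rep(reads$label == 1L, each = rl)
  base_dt <- data.table(
    read_id = rep(reads$read_id, each = rl),
    transcript_id = rep(reads$transcript_id, each = rl),
    position = pos,
    base = as.vector(t(baseschar)),
    mod_center = modv & pos == ctr,
    mod_side = modv & pos %in% c(ctr - 1L, ctr + 1L))
  if (params$kmer_sd > 0) {
    P <- cbind("A", "A", baseschar, "A", "A")
    kmermat <- vapply(seq_len(rl), function(j)
      paste0(P[, j], P[, j + 1L], P[, j + 2L], P[, j + 3L], P[, j + 4L]),
      character(N))
    base_dt[, kmer := as.vector(t(kmermat))]
  }
  events <- .genEvents(base_dt, params)
  labels <- data.frame(read_id = reads$read_id,
                       transcript_id = reads$transcript_id,
                       tpos = ctr, motif = reads$motif, label = reads$label)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeEvents(events, file.path(dir, "events.tsv"))
    data.table::fwrite(labels, file.path(dir, "labels.tsv"), sep = "\t")
  }
  list(events = events, labels = labels)
}

#' Attach training labels to extracted features
#'
#' @param features site feature table ([extractFeatures()]).
#' @param labels label table ([simulateLabeledEvents()] or a TSV with
#'   `read_id, tpos, label`).
#' @return `features` with a `label` column (rows without a label are
#'   dropped).
#' @export
attachLabels <- function(features, labels) {
  m <- merge(as.data.table(features),
             as.data.table(labels)[, .(read_id, tpos, label)],
             by = c("read_id", "tpos"))
  setDF(m)
}

#' Simulate a known-ratio read mixture
#'
#' Each of `n_sites` sites is an independent nine-base molecule family:
#' the number of modified reads among `depth` is drawn
#' `Binomial(depth, true_ratio)` and signals are generated accordingly.
#' Each site uses its own RNG substream, so results for one site do not
#' depend on how many other sites or reads are simulated.
#'
#' @param params a [simParams()].
#' @param true_ratio true modified fraction in `[0, 1]`.
#' @param depth reads per site.
#' @param n_sites number of sites.
#' @return list with `events` and `truth` (data.frame `transcript_id,
#'   tpos, motif, true_ratio, n_mod_true, depth`).
#' @export
simulateMixture <- function(params = simParams(), true_ratio, depth,
                            n_sites = 200L) {
  stopifnot(true_ratio >= 0, true_ratio <= 1, depth >= 1L, n_sites >= 1L)
  # per-site substreams derived arithmetically from (seed, site index):
  # site i's draws never depend on how many sites or reads are simulated
  site_seeds <- as.integer((as.double(params$seed) * 1000003 +
                              seq_len(n_sites) * 7919) %% 2147483647)
  motifs <- enumerateRrachMotifs()
  site_motif <- motifs[site_seeds %% 12L + 1L]
  fl <- as.integer(params$read_flank)
  rl <- 2L * fl + 5L
  ctr <- fl + 2L
  ev <- vector("list", n_sites)
  truth <- data.frame(transcript_id = sprintf("mix%05d", seq_len(n_sites)),
                      tpos = ctr, motif = site_motif,
                      true_ratio = true_ratio,
                      n_mod_true = NA_integer_, depth = as.integer(depth))
  for (i in seq_len(n_sites)) {
    set.seed(site_seeds[i])
    n_mod <- rbinom(1L, depth, true_ratio)
    truth$n_mod_true[i] <- n_mod
    lab <- rep(c(TRUE, FALSE), c(n_mod, depth - n_mod))
    rid <- sprintf("%s_r%04d", truth$transcript_id[i], seq_len(depth))
    pos <- rep(0:(rl - 1L), times = depth)
    modv <- rep(lab, each = rl)
    # per-read flanks: normalization noise is then independent across
    # the reads of a site and averages out of the site-level estimate
    mb <- matrix(strsplit(site_motif[i], "")[[1L]], nrow = depth,
                 ncol = 5L, byrow = TRUE)
    fb <- matrix(.randBases(2L * fl * depth), nrow = depth)
    bs <- cbind(fb[, seq_len(fl), drop = FALSE], mb,
                fb[, fl + seq_len(fl), drop = FALSE])
    kmermat <- if (params$kmer_sd > 0) {
      P <- cbind("A", "A", bs, "A", "A")
      vapply(seq_len(rl), function(j)
        paste0(P[, j], P[, j + 1L], P[, j + 2L], P[, j + 3L], P[, j + 4L]),
        character(depth))
    } else NULL
    base_dt <- data.table(
      read_id = rep(rid, each = rl),
      transcript_id = truth$transcript_id[i],
      position = pos,
      base = as.vector(t(bs)),
      mod_center = modv & pos == ctr,
      mod_side = modv & pos %in% c(ctr - 1L, ctr + 1L))
    if (!is.null(kmermat)) base_dt[, kmer := as.vector(t(kmermat))]
    ev[[i]] <- .genEvents(base_dt, params)
  }
  events <- rbindlist(ev)
  events <- setDF(events)
  attr(events, "dialect") <- "raw"
  list(events = events, truth = truth)
}

#' Stoichiometry recovery experiment over a ratio grid and read depths
#'
#' Runs the full per-read pipeline (feature extraction, per-motif
#' prediction, binarization, per-site aggregation) on simulated mixtures
#' for every combination of true ratio and depth, and summarizes recovery
#' per depth: Pearson correlation between true and estimated ratios and
#' mean absolute error.  `n_sites` plays the role of replicates per grid
#' cell (scaled down from the 10,000 mixtures of the original design;
#' configurable).
#'
#' @param bundle trained [ModelBundle].
#' @param params a [simParams()] (its `mod_shift`/`noise_sd` should match
#'   the training conditions of `bundle`).
#' @param ratios grid of true ratios.
#' @param depths read depths.
#' @param n_sites replicate sites per (ratio, depth) cell.
#' @param threshold binarization threshold.
#' @return list with `sites` (per-site table: `depth, true_ratio,
#'   transcript_id, est_ratio, n_mod, n_total`) and `summary` (per depth:
#'   `correlation, mae`; correlation is `NA`-flagged for a degenerate
#'   single-ratio grid).
#' @export
ratioRecoveryExperiment <- function(bundle, params = simParams(),
                                    ratios = seq(0, 1, by = 0.1),
                                    depths = c(20L, 50L, 100L),
                                    n_sites = 200L, threshold = 0.5) {
  if (!is(bundle, "ModelBundle")) stop("a trained ModelBundle is required")
  res <- list()
  for (di in seq_along(depths)) {
    for (ri in seq_along(ratios)) {
      p <- params
      p$seed <- params$seed + 7919L * di + 101L * ri
      sim <- simulateMixture(p, ratios[ri], depths[di], n_sites)
      feats <- extractFeatures(sim$events)
      calls <- callReads(bundle, feats, threshold)
      est <- aggregateSites(calls, min_mod_reads = 1L)
      i <- match(paste(sim$truth$transcript_id, sim$truth$tpos),
                 paste(est$transcript_id, est$tpos))
      res[[length(res) + 1L]] <- data.frame(
        depth = depths[di], true_ratio = ratios[ri],
        transcript_id = sim$truth$transcript_id,
        n_mod_true = sim$truth$n_mod_true,
        est_ratio = est$ratio[i], n_mod = est$n_mod[i],
        n_total = est$n_total[i])
    }
  }
  sites <- do.call(rbind, res)
  sdt <- as.data.table(sites)
  summary <- sdt[, .(
    correlation = if (length(unique(true_ratio)) > 1L)
      cor(true_ratio, est_ratio) else NA_real_,
    mae = mean(abs(est_ratio - true_ratio))), by = depth]
  list(sites = sites, summary = setDF(summary))
}

# ---- annotated transcriptome with APA isoforms ----------------------------

# genomic coordinate (1-based) of a 0-based transcript position, from the
# generator's two-exon gene layout (exon lengths in transcript order)
.txToGenomic <- function(tpos, gstart, e1, e2, intron, strand) {
  L <- e1 + e2
  stopifnot(all(tpos >= 0L & tpos < L))
  if (strand == "+") {
    ifelse(tpos < e1, gstart + tpos, gstart + e1 + intron + (tpos - e1))
  } else {
    # transcript runs right->left; genomic-left exon holds the 3' part
    gend <- gstart + e2 + intron + e1 - 1L
    ifelse(tpos < e1, gend - tpos, gstart + (L - 1L - tpos))
  }
}

.plantSites <- function(L, utr5, cds, k, stop_bias) {
  e <- utr5 + cds                       # first 3'UTR position
  lo <- max(2L, e - as.integer(0.1 * cds))
  hi <- min(L - 3L, e + as.integer(0.3 * (L - e)))
  pos <- integer(0)
  tries <- 0L
  while (length(pos) < k && tries < 200L) {
    tries <- tries + 1L
    cand <- if (runif(1) < stop_bias) sample(lo:hi, 1L)
            else sample(2:(L - 3L), 1L)
    if (all(abs(cand - pos) >= 6L)) pos <- c(pos, cand)
  }
  sort(pos)
}

#' Simulate an annotated transcriptome with APA isoforms
#'
#' Generates `n_genes` two-exon genes (5'UTR/CDS/3'UTR structure, random
#' strand) on one synthetic chromosome, plants RRACH sites with a
#' stop-codon bias, gives a fraction of genes two poly(A) isoforms
#' (`apa_offset` nt apart, distal true m6A ratio half the proximal one,
#' distinct poly(A) tail lengths), and emits mutually consistent signal
#' events, per-read poly(A) records, transcript-to-genome alignments,
#' transcript FASTA and GTF annotation, plus the full ground truth.
#'
#' @param params a [simParams()].
#' @param dir optional output directory (`ref.fa`, `annotation.gtf`,
#'   `events.tsv`, `polya.tsv`, `alignments.sam`, `truth_*.tsv`).
#' @param signal generate signal events (default `TRUE`; turning it off
#'   yields the annotation/poly(A)/truth layers only, much faster).
#' @return list with `events`, `polya`, `alignments`, `sequences`
#'   (named character), `gtf` (lines), `tx2gene`, and `truth` (list
#'   `genes`, `sites`, `reads`).
#' @export
simulateTranscriptome <- function(params = simParams(), dir = NULL,
                                  signal = TRUE) {
  stopifnot(params$n_genes >= 1L)
  set.seed(params$seed)
  ng <- as.integer(params$n_genes)
  chrom <- "chrS"

  genes <- data.table(gene_id = sprintf("gene%04d", seq_len(ng)))
  genes[, strand := sample(c("+", "-"), ng, replace = TRUE)]
  genes[, utr5 := sample(params$utr5_range[1L]:params$utr5_range[2L], ng, TRUE)]
  genes[, cds := 3L * sample((params$cds_range[1L] %/% 3L):
                               (params$cds_range[2L] %/% 3L), ng, TRUE)]
  genes[, utr3 := sample(params$utr3_range[1L]:params$utr3_range[2L], ng, TRUE)]
  genes[, L := utr5 + cds + utr3]
  genes[, e1 := utr5 + as.integer(0.4 * cds)]   # exon 1 length (tx order)
  genes[, e2 := L - e1]
  genes[, intron := sample(150:400, ng, TRUE)]
  genes[, gstart := cumsum(c(1L, head(L + intron + 1000L, -1L)))]
  apa_idx <- sample(ng, round(ng * params$apa_fraction))
  genes[, apa := seq_len(ng) %in% apa_idx]
  genes[, ratio_proximal := runif(ng, params$ratio_range[1L],
                                  params$ratio_range[2L])]
  genes[, n_reads_iso := pmax(5L, as.integer(round(
    params$depth * rlnorm(ng, 0, params$expression_sd))))]
  if (params$m6a_expr_slope != 0) {
    le <- log10(genes$n_reads_iso * ifelse(genes$apa, 2, 1))
    genes[, ratio_proximal := pmin(0.95, pmax(0.05,
      ratio_proximal + params$m6a_expr_slope * (le - mean(le))))]
  }
  genes[, polya_gene_mean := rnorm(ng, params$polya_mean,
                                   params$polya_gene_sd)]
  if (params$polya_expr_slope != 0) {
    le <- log10(genes$n_reads_iso * ifelse(genes$apa, 2, 1))
    genes[, polya_gene_mean := pmax(20,
      polya_gene_mean + params$polya_expr_slope * (le - mean(le)))]
  }

  motifs <- enumerateRrachMotifs()
  seqs <- character(ng)
  site_rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- genes[i]
    k <- sample(params$sites_per_gene[1L]:params$sites_per_gene[2L], 1L)
    s <- .randBases(g$L)
    pos <- .plantSites(g$L, g$utr5, g$cds, k, params$stop_bias)
    mot <- sample(motifs, length(pos), replace = TRUE)
    for (j in seq_along(pos))
      s[(pos[j] - 1L):(pos[j] + 3L)] <- strsplit(mot[j], "")[[1L]]
    seqs[i] <- paste(s, collapse = "")
    site_rows[[i]] <- data.table(gene_id = g$gene_id, tpos = pos,
                                 motif = mot)
  }
  plant <- rbindlist(site_rows)

  # isoforms: distal = full transcript (.d); proximal (.p) truncated in
  # the 3'UTR by apa_offset, APA genes only
  iso <- rbind(
    genes[, .(gene_id, transcript_id = paste0(gene_id, ".d"),
              role = "distal", iso_len = L)],
    genes[apa == TRUE, .(gene_id, transcript_id = paste0(gene_id, ".p"),
                         role = "proximal",
                         iso_len = L - params$apa_offset)])
  iso <- merge(iso, genes, by = "gene_id")
  iso[, true_ratio := ifelse(apa & role == "distal",
                             ratio_proximal / 2, ratio_proximal)]
  iso[, n_reads := n_reads_iso]
  setorder(iso, gene_id, role)

  tx2gene <- setDF(iso[, .(transcript_id, gene_id)])

  # alignments: two-exon CIGAR (intron as N); '-' strand stores the
  # reverse-complemented query, genomic-left exon = transcript 3' part
  aln <- iso[, {
    el1 <- e1; el2 <- iso_len - e1
    if (strand == "+") {
      .(chrom = chrom, gpos = gstart,
        cigar = sprintf("%dM%dN%dM", el1, intron, el2))
    } else {
      .(chrom = chrom, gpos = gstart + (L - iso_len),
        cigar = sprintf("%dM%dN%dM", el2, intron, el1))
    }
  }, by = .(transcript_id, strand)]
  alignments <- setDF(aln[, .(transcript_id, chrom, gpos, strand, cigar)])

  # ground-truth genomics: stop codon (last CDS base) and poly(A) ends
  genes[, stop_tpos := utr5 + cds - 1L]
  genes[, stop_pos := mapply(.txToGenomic, stop_tpos, gstart, e1, e2,
                             intron, strand)]
  iso[, end_tpos := iso_len - 1L]
  iso[, end_pos := mapply(.txToGenomic, end_tpos, gstart, e1, e2,
                          intron, strand)]

  # per-isoform site table (sites beyond the proximal cut exist on the
  # distal isoform only)
  sites <- merge(iso[, .(gene_id, transcript_id, role, iso_len, true_ratio)],
                 plant, by = "gene_id", allow.cartesian = TRUE)
  sites <- sites[tpos <= iso_len - 3L]
  truth_sites <- setDF(sites[, .(gene_id, transcript_id, role, tpos, motif,
                                 true_ratio)])

  # reads: 3'-anchored molecules with variable 5' truncation (half are
  # full length, half start within the 5' half of UTR5+CDS, as direct
  # RNA reads do); per covered site, modified with the isoform's true
  # ratio; poly(A) record per read
  read_rows <- vector("list", nrow(iso))
  polya_rows <- vector("list", nrow(iso))
  for (i in seq_len(nrow(iso))) {
    it <- iso[i]
    n <- it$n_reads
    rid <- sprintf("%s_r%04d", it$transcript_id, seq_len(n))
    smax <- max(1L, as.integer(0.5 * (it$utr5 + it$cds)))
    rstart <- ifelse(runif(n) < 0.5, 0L, sample.int(smax, n, replace = TRUE))
    stab <- sites[transcript_id == it$transcript_id]
    mod <- if (nrow(stab))
      matrix(runif(n * nrow(stab)) < it$true_ratio, nrow = n) else
      matrix(FALSE, nrow = n, ncol = 0L)
    read_rows[[i]] <- list(transcript_id = it$transcript_id,
                           gene_id = it$gene_id, role = it$role,
                           read_id = rid, rstart = rstart,
                           site_tpos = stab$tpos, mod = mod)
    pl_mean <- if (it$apa) unname(params$apa_polya_means[it$role])
               else it$polya_gene_mean
    polya_rows[[i]] <- data.table(
      read_id = rid, gene_id = it$gene_id, chrom = chrom,
      end_pos = it$end_pos + sample(-3:3, n, TRUE) *
        (if (it$strand == "+") 1L else -1L),
      strand = it$strand,
      polya_length = pmax(5, rnorm(n, pl_mean, params$polya_read_sd)),
      qc_tag = ifelse(runif(n) < params$pass_rate, "PASS", "ADAPTER"))
  }
  polya <- setDF(rbindlist(polya_rows))

  truth_reads <- rbindlist(lapply(read_rows, function(r)
    data.table(read_id = r$read_id, transcript_id = r$transcript_id,
               gene_id = r$gene_id, role = r$role, rstart = r$rstart,
               n_mod_sites = if (ncol(r$mod)) rowSums(r$mod) else 0L)))

  events <- NULL
  if (signal) {
    base_dt <- rbindlist(lapply(read_rows, function(r) {
      iso_len <- iso[transcript_id == r$transcript_id, iso_len]
      bases <- strsplit(substr(seqs[match(r$gene_id, genes$gene_id)],
                               1L, iso_len), "")[[1L]]
      n <- length(r$read_id)
      li <- iso_len - r$rstart                 # covered bases per read
      cum <- cumsum(c(0L, li[-n]))
      posn <- sequence(li) - 1L + rep(r$rstart, li)
      d <- data.table(
        read_id = rep(r$read_id, times = li),
        transcript_id = r$transcript_id,
        position = posn,
        base = bases[posn + 1L],
        mod_center = FALSE, mod_side = FALSE)
      if (params$kmer_sd > 0)
        d[, kmer := .contextKmers(bases)[posn + 1L]]
      for (j in seq_along(r$site_tpos)) {
        tp <- r$site_tpos[j]
        hit <- which(r$mod[, j] & r$rstart <= tp)
        if (length(hit)) {
          d[cum[hit] + (tp - r$rstart[hit]) + 1L, mod_center := TRUE]
          left <- hit[r$rstart[hit] <= tp - 1L]
          if (length(left))
            d[cum[left] + (tp - r$rstart[left]), mod_side := TRUE]
          d[cum[hit] + (tp - r$rstart[hit]) + 2L, mod_side := TRUE]
        }
      }
      d
    }))
    events <- .genEvents(base_dt, params)
  }

  gtf <- .makeGtf(iso, genes, chrom)
  truth_genes <- setDF(genes[, .(gene_id, strand, gstart, utr5, cds, utr3,
                                 L, e1, e2, intron, apa, ratio_proximal,
                                 n_reads_iso, polya_gene_mean, stop_tpos,
                                 stop_pos)])
  sequences <- setNames(
    unlist(lapply(seq_len(nrow(iso)), function(i)
      substr(seqs[match(iso$gene_id[i], genes$gene_id)], 1L,
             iso$iso_len[i]))),
    iso$transcript_id)

  out <- list(events = events, polya = polya, alignments = alignments,
              sequences = sequences, gtf = gtf, tx2gene = tx2gene,
              truth = list(genes = truth_genes, sites = truth_sites,
                           reads = setDF(truth_reads)))
  if (!is.null(dir)) .writeTranscriptomeDir(out, dir)
  out
}

# GTF lines for every isoform: transcript/exon/CDS rows.  The generator's
# genes have two exons; the CDS always spans the junction.
.makeGtf <- function(iso, genes, chrom) {
  out <- vector("list", nrow(iso))
  att <- function(g, t)
    sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  row <- function(type, s, e, strand, a)
    sprintf("%s\tnanostoich_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s, e, strand, a)
  for (i in seq_len(nrow(iso))) {
    it <- iso[i]
    el1 <- it$e1; el2 <- it$iso_len - it$e1
    # genomic coordinate of a 0-based transcript position of this isoform
    if (it$strand == "+") {
      ex1 <- c(it$gstart, it$gstart + el1 - 1L)
      ex2 <- c(it$gstart + el1 + it$intron,
               it$gstart + el1 + it$intron + el2 - 1L)
      g_of <- function(t) ifelse(t < el1, it$gstart + t,
                                 ex2[1L] + (t - el1))
    } else {
      g0 <- it$gstart + (it$L - it$iso_len)
      ex2 <- c(g0, g0 + el2 - 1L)                      # transcript 3' part
      ex1 <- c(g0 + el2 + it$intron, g0 + el2 + it$intron + el1 - 1L)
      g_of <- function(t) ifelse(t < el1, ex1[2L] - t,
                                 ex2[2L] - (t - el1))
    }
    a <- att(it$gene_id, it$transcript_id)
    cds_end <- it$utr5 + it$cds - 1L
    cds_tx <- list(c(it$utr5, min(cds_end, el1 - 1L)),
                   c(el1, cds_end))                    # part per exon
    cds_rows <- lapply(cds_tx, function(r) {
      if (r[1L] > r[2L]) return(NULL)
      g <- sort(g_of(r))
      row("CDS", g[1L], g[2L], it$strand, a)
    })
    out[[i]] <- c(
      row("transcript", min(ex1, ex2), max(ex1, ex2), it$strand, a),
      row("exon", ex1[1L], ex1[2L], it$strand, a),
      row("exon", ex2[1L], ex2[2L], it$strand, a),
      unlist(cds_rows))
  }
  unlist(out)
}

.writeTranscriptomeDir <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$sequences),
                              file.path(dir, "ref.fa"))
  writeLines(x$gtf, file.path(dir, "annotation.gtf"))
  if (!is.null(x$events))
    writeEvents(x$events, file.path(dir, "events.tsv"))
  data.table::fwrite(x$polya, file.path(dir, "polya.tsv"), sep = "\t")
  writeSam(x$alignments, x$sequences, file.path(dir, "alignments.sam"))
  data.table::fwrite(x$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t")
  data.table::fwrite(x$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t")
  invisible(dir)
}

#' Write transcript-to-genome alignments as SAM
#'
#' Minimal single-end SAM with one record per transcript; reverse-strand
#' records carry flag 16.  Sequences are omitted (`*`).
#'
#' @param alignments data.frame `transcript_id, chrom, gpos, strand,
#'   cigar`.
#' @param sequences named character (used only to size the `@SQ` header
#'   when `sq_len` is missing).
#' @param path output SAM.
#' @param sq_len optional named vector of reference lengths.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, sequences = NULL, path, sq_len = NULL) {
  if (is.null(sq_len)) {
    cg <- vapply(alignments$cigar, function(c) {
      o <- .cigarOps(c)
      sum(o$len[o$op %in% c("M", "=", "X", "D", "N")])
    }, 1L)
    ends <- alignments$gpos + cg - 1L
    sq_len <- tapply(ends, alignments$chrom, max) + 1000L
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq_len), as.integer(sq_len)))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                 alignments$transcript_id,
                 ifelse(alignments$strand == "-", 16L, 0L),
                 alignments$chrom, alignments$gpos, alignments$cigar)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
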