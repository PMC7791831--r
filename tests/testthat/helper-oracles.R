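# Independent reference implementations used as oracles.  They are kept
# deliberately naive (loops, exhaustive enumeration) and never call the
# package functions they check.

refBaseFeatures <- function(seg) {
  n <- length(seg)
  m <- sum(seg) / n
  sorted <- sort(seg)
  med <- if (n %% 2 == 1) sorted[(n + 1) / 2]
         else (sorted[n / 2] + sorted[n / 2 + 1]) / 2
  v <- 0
  for (s in seg) v <- v + (s - m)^2
  c(mean = m, median = med, std = sqrt(v / n), dwell = n)
}

refFindRrach <- function(seq) {
  s <- strsplit(toupper(chartr("Uu", "Tt", seq)), "")[[1L]]
  out <- list()
  if (length(s) >= 5L) {
    for (i in seq_len(length(s) - 4L)) {
      w <- s[i:(i + 4L)]
      if (w[1] %in% c("A", "G") && w[2] %in% c("A", "G") &&
          w[3] == "A" && w[4] == "C" && w[5] %in% c("A", "C", "T"))
        out[[length(out) + 1L]] <- data.frame(
          center_pos = i + 1L, motif = paste(w, collapse = ""))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(center_pos = integer(), motif = character())
}

# exhaustive per-base CIGAR walk: table of (query 1-based, genome 1-based)
refCigarTable <- function(cigar, gpos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  q <- 0L; g <- gpos
  rows <- list()
  for (tok in ops) {
    len <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
    op <- substr(tok, nchar(tok), nchar(tok))
    for (k in seq_len(len)) {
      if (op %in% c("M", "=", "X")) {
        q <- q + 1L; rows[[length(rows) + 1L]] <- c(q, g); g <- g + 1L
      } else if (op %in% c("I", "S")) {
        q <- q + 1L; rows[[length(rows) + 1L]] <- c(q, NA)
      } else if (op %in% c("D", "N")) {
        g <- g + 1L
      }
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("q", "g")
  m
}

refMapToGenome <- function(tpos, gpos, strand, cigar) {
  tab <- refCigarTable(cigar, gpos)
  qlen <- nrow(tab)
  q <- if (strand == "+") tpos + 1L else qlen - tpos
  if (q < 1L || q > qlen) return(NA_integer_)
  tab[tab[, "q"] == q, "g"]
}

# connected components on the <=window adjacency graph
refClusterEnds <- function(pos, window = 24L) {
  n <- length(pos)
  if (!n) return(integer())
  adj <- abs(outer(pos, pos, "-")) <= window
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(pos)]))
}

# Mann-Whitney pair-counting AUC
refAuc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

randCigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- character(0)
  lens <- integer(0)
  prev <- ""
  for (i in seq_len(n_ops)) {
    op <- sample(c("M", "I", "D", "N"), 1,
                 prob = c(0.6, 0.15, 0.15, 0.1))
    if (op == prev || (i == 1 && op != "M")) op <- "M"
    ops <- c(ops, op); lens <- c(lens, sample(1:30, 1)); prev <- op
  }
  if (ops[length(ops)] != "M") { ops <- c(ops, "M"); lens <- c(lens, 5L) }
  if (runif(1) < 0.3) { ops <- c("S", ops); lens <- c(sample(1:5, 1), lens) }
  paste0(lens, ops, collapse = "")
}
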