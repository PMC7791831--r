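#' EventRead: one sequenced molecule as segmented current signal
#'
#' An `EventRead` holds the ordered per-base current-sample segments of one
#' direct RNA read after signal-to-sequence assignment: for every reference
#' base covered by the read there is one segment (a non-empty numeric vector
#' of raw current samples).  Bases are stored 5'->3' along the transcript
#' and cover the contiguous window `startPos(x) .. startPos(x) + n - 1`
#' (0-based transcript coordinates).
#'
#' @param read_id character scalar, read identifier.
#' @param transcript_id character scalar, reference transcript.
#' @param start_pos 0-based transcript offset of the first segment.
#' @param bases character scalar over A/C/G/T (U is mapped to T).
#' @param segments list of non-empty numeric vectors, one per base.
#'
#' @return An `EventRead` object.
#' @examples
#' r <- EventRead("r1", "tx1", 0L, "GGACT",
#'                list(80, 95, c(100, 102), 91, 84))
#' readBases(r)
#' @export
EventRead <- function(read_id, transcript_id, start_pos, bases, segments) {
  new("EventRead",
      read_id = as.character(read_id),
      transcript_id = as.character(transcript_id),
      start_pos = as.integer(start_pos),
      bases = toupper(chartr("Uu", "Tt", as.character(bases))),
      segments = lapply(segments, as.numeric))
}

setClass("EventRead",
         representation(read_id = "character", transcript_id = "character",
                        start_pos = "integer", bases = "character",
                        segments = "list"))

setValidity("EventRead", function(object) {
  msg <- character()
  if (length(object@bases) != 1L || nchar(object@bases) == 0L)
    msg <- c(msg, "empty read")
  if (nchar(object@bases) != length(object@segments))
    msg <- c(msg, "length(bases) must equal length(segments)")
  if (length(object@segments) &&
      any(vapply(object@segments, length, 1L) == 0L))
    msg <- c(msg, "every segment needs >= 1 sample")
  if (grepl("[^ACGTN]", object@bases))
    msg <- c(msg, "bases must be over {A,C,G,T/U,N}")
  if (is.na(object@start_pos) || object@start_pos < 0L)
    msg <- c(msg, "start_pos must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EventRead", function(object) {
  n <- length(object@segments)
  cat("EventRead", object@read_id, "on", object@transcript_id, "\n",
      " ", n, "bases at transcript positions",
      object@start_pos, "-", object@start_pos + n - 1L, ";",
      sum(vapply(object@segments, length, 1L)), "raw samples\n")
})

#' @rdname EventRead
#' @param x an `EventRead`.
#' @export
readId <- function(x) x@read_id

#' @rdname EventRead
#' @export
transcriptId <- function(x) x@transcript_id

#' @rdname EventRead
#' @export
startPos <- function(x) x@start_pos

#' @rdname EventRead
#' @export
readBases <- function(x) x@bases

#' @rdname EventRead
#' @export
signalSegments <- function(x) x@segments

#' ModelBundle: twelve per-motif gradient-boosted classifiers
#'
#' A `ModelBundle` stores one trained gradient-boosted tree ensemble per
#' RRACH 5-mer (twelve in all), each emitting the probability that the
#' central A of a site feature vector is m6A-modified, together with the
#' feature schema version and the training configuration.  Motifs whose
#' training data lacked one of the two classes are kept as entries flagged
#' untrainable; routing a prediction to them fails loudly.
#'
#' Bundles are created by [trainBundle()] and persisted with
#' [saveBundle()] / [loadBundle()].
#'
#' @param x a `ModelBundle`.
#' @return `bundleMotifs()` returns the motif names; `bundleConfig()` the
#'   training configuration list; `schemaVersion()` the feature schema
#'   string.
#' @name ModelBundle-class
#' @aliases ModelBundle
NULL

setClass("ModelBundle",
         representation(models = "list", schema_version = "character",
                        config = "list"))

setValidity("ModelBundle", function(object) {
  motifs <- enumerateRrachMotifs()
  if (!setequal(names(object@models), motifs))
    return("models must have exactly the 12 RRACH motifs as names")
  if (length(object@schema_version) != 1L)
    return("schema_version must be a single string")
  TRUE
})

setMethod("show", "ModelBundle", function(object) {
  tr <- vapply(object@models, function(m) isTRUE(m$trainable), TRUE)
  cat("ModelBundle:", sum(tr), "of", length(tr),
      "RRACH motif models trained (schema", object@schema_version, ")\n")
  nt <- vapply(object@models, function(m) m$n_train %||% 0L, 1L)
  ns <- vapply(object@models, function(m) m$n_test %||% 0L, 1L)
  cat("  training examples per motif:",
      paste0(range(nt), collapse = "-"),
      " held out:", paste0(range(ns), collapse = "-"), "\n")
})

#' @rdname ModelBundle-class
#' @export
bundleMotifs <- function(x) names(x@models)

#' @rdname ModelBundle-class
#' @export
bundleConfig <- function(x) x@config

#' @rdname ModelBundle-class
#' @export
schemaVersion <- function(x) x@schema_version

#' @rdname ModelBundle-class
#' @param motif a single RRACH 5-mer.
#' @export
motifModel <- function(x, motif) {
  m <- x@models[[motif]]
  if (is.null(m)) stop("no model for motif ", motif)
  m
}

#' MetageneProfile: site density over scaled transcript regions
#'
#' Histogram of m6A sites on the scaled metagene axis `u` in `[0, 3)`:
#' `[0,1)` is the 5'UTR, `[1,2)` the CDS and `[2,3)` the 3'UTR, each
#' stretched to unit length per transcript.  Built by [metageneProfile()].
#'
#' @param x a `MetageneProfile`.
#' @return `profileBins(x)` returns the bin table (columns `bin`, `region`,
#'   `lower`, `upper`, `count`, `density`); `profileSites(x)` the number of
#'   profiled sites.
#' @name MetageneProfile-class
#' @aliases MetageneProfile
NULL

setClass("MetageneProfile",
         representation(bins = "data.frame", n_sites = "integer",
                        bins_per_region = "integer"))

setValidity("MetageneProfile", function(object) {
  if (sum(object@bins$count) != object@n_sites)
    return("bin counts must sum to the number of profiled sites")
  TRUE
})

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile:", object@n_sites, "sites in",
      nrow(object@bins), "bins (", object@bins_per_region, "per region)\n")
  byr <- tapply(object@bins$count, object@bins$region, sum)
  cat("  sites per region:",
      paste(names(byr), byr, sep = "=", collapse = ", "), "\n")
})

#' @rdname MetageneProfile-class
#' @export
profileBins <- function(x) x@bins

#' @rdname MetageneProfile-class
#' @export
profileSites <- function(x) x@n_sites

`%||%` <- function(a, b) if (is.null(a)) b else a
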