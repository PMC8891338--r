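#' @rdname TranscriptSet-class
#' @param sequences named DNAStringSet (or named character vector).
#' @param cds,exons named lists of 2-column integer matrices (start, end;
#'   0-based half-open).
#' @return a validated \code{TranscriptSet}.
#' @export
TranscriptSet <- function(sequences, cds = list(), exons = list()) {
  if (is.list(sequences)) sequences <- unlist(sequences)
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  cds <- lapply(cds, .asIntervalMatrix)
  exons <- lapply(exons, .asIntervalMatrix)
  new("TranscriptSet", sequences = sequences, cds = cds, exons = exons)
}

.asIntervalMatrix <- function(m) {
  m <- matrix(as.integer(as.matrix(m)), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1L]), , drop = FALSE]
}

#' @rdname SiteTable-class
#' @param sites data.frame with at least \code{transcript}, \code{pos},
#'   \code{coverage}, \code{g_count}; \code{el} and annotation columns are
#'   filled in when absent.
#' @param transcripts optional \code{TranscriptSet} used to check the
#'   reference base and annotate frame/recoding.
#' @return a validated \code{SiteTable}.
#' @export
SiteTable <- function(sites, transcripts = NULL) {
  n <- nrow(sites)
  sites$transcript <- as.character(sites$transcript)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$coverage)) sites$coverage <- rep(NA_integer_, n)
  if (is.null(sites$g_count)) sites$g_count <- rep(NA_integer_, n)
  if (is.null(sites$el))
    sites$el <- ifelse(is.na(sites$coverage) | sites$coverage == 0L,
                       NA_real_, sites$g_count / sites$coverage)
  if (is.null(sites$frame_offset)) sites$frame_offset <- rep(NA_integer_, n)
  if (is.null(sites$recoding)) sites$recoding <- rep(NA_character_, n)
  sites <- sites[order(sites$transcript, sites$pos),
                 c("transcript", "pos", "coverage", "g_count", "el",
                   "frame_offset", "recoding")]
  rownames(sites) <- NULL
  if (!is.null(transcripts)) {
    .checkReferenceA(sites, transcripts)
    sites <- annotateSites(sites, transcripts)
  }
  new("SiteTable", sites = sites)
}

.checkReferenceA <- function(sites, transcripts) {
  for (tx in unique(sites$transcript)) {
    sq <- sequencesOf(transcripts)[[tx]]
    if (is.null(sq)) stop("unknown transcript: ", tx)
    p <- sites$pos[sites$transcript == tx]
    if (any(p < 0L | p >= length(sq)))
      stop("site position outside sequence in ", tx)
    b <- strsplit(as.character(sq), "")[[1L]][p + 1L]
    if (any(b != "A"))
      stop("reference base at a site is not A in ", tx,
           " (pos ", paste(p[b != "A"], collapse = ","), ")")
  }
  invisible(TRUE)
}

#' @rdname ReadMatrix-class
#' @param reads,calls data.frames as documented for the slots.
#' @return a validated \code{ReadMatrix}.
#' @export
ReadMatrix <- function(reads, calls) {
  reads$read_id <- as.character(reads$read_id)
  reads$transcript <- as.character(reads$transcript)
  reads$start <- as.integer(reads$start); reads$end <- as.integer(reads$end)
  calls$read_id <- as.character(calls$read_id)
  calls$transcript <- as.character(calls$transcript)
  calls$pos <- as.integer(calls$pos)
  calls$state <- as.character(calls$state)
  rownames(reads) <- rownames(calls) <- NULL
  new("ReadMatrix", reads = reads, calls = calls)
}

#' @rdname PairingProfile-class
#' @param pairing,potential,partner named lists as documented for the slots.
#' @return a validated \code{PairingProfile}.
#' @export
PairingProfile <- function(pairing, potential = list(), partner = list()) {
  new("PairingProfile", pairing = pairing, potential = potential,
      partner = partner)
}

## ---- accessors -------------------------------------------------------------

#' Accessors for the core containers
#'
#' \code{sequencesOf}, \code{cdsOf}, \code{exonsOf} return the slots of a
#' \code{TranscriptSet}; \code{sites} the site data.frame of a
#' \code{SiteTable}; \code{readIntervals}/\code{readCalls} the two tables of
#' a \code{ReadMatrix}; \code{pairingProb}/\code{partnerMap} the profile
#' lists; \code{pairTallies}/\code{pairFrequencies} the tallies and relative
#' frequencies of a \code{PairCounts}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequencesOf", function(x) standardGeneric("sequencesOf"))
#' @rdname accessors
#' @export
setMethod("sequencesOf", "TranscriptSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("cdsOf", function(x) standardGeneric("cdsOf"))
#' @rdname accessors
#' @export
setMethod("cdsOf", "TranscriptSet", function(x) x@cds)

#' @rdname accessors
#' @export
setGeneric("exonsOf", function(x) standardGeneric("exonsOf"))
#' @rdname accessors
#' @export
setMethod("exonsOf", "TranscriptSet", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname accessors
#' @export
setMethod("sites", "SiteTable", function(x) x@sites)

#' @rdname accessors
#' @export
setGeneric("readIntervals", function(x) standardGeneric("readIntervals"))
#' @rdname accessors
#' @export
setMethod("readIntervals", "ReadMatrix", function(x) x@reads)

#' @rdname accessors
#' @export
setGeneric("readCalls", function(x) standardGeneric("readCalls"))
#' @rdname accessors
#' @export
setMethod("readCalls", "ReadMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("pairingProb", function(x) standardGeneric("pairingProb"))
#' @rdname accessors
#' @export
setMethod("pairingProb", "PairingProfile", function(x) x@pairing)

#' @rdname accessors
#' @export
setGeneric("partnerMap", function(x) standardGeneric("partnerMap"))
#' @rdname accessors
#' @export
setMethod("partnerMap", "PairingProfile", function(x) x@partner)

#' @rdname accessors
#' @export
setGeneric("pairTallies", function(x) standardGeneric("pairTallies"))
#' @rdname accessors
#' @export
setMethod("pairTallies", "PairCounts", function(x)
  c(nAA = x@nAA, nAI = x@nAI, nIA = x@nIA, nII = x@nII))

#' @rdname accessors
#' @export
setGeneric("pairFrequencies", function(x) standardGeneric("pairFrequencies"))
#' @rdname accessors
#' @export
setMethod("pairFrequencies", "PairCounts", function(x) {
  n <- pairTallies(x); tot <- sum(n)
  if (tot == 0L) return(c(fAA = NA_real_, fAI = NA_real_,
                          fIA = NA_real_, fII = NA_real_))
  setNames(n / tot, c("fAA", "fAI", "fIA", "fII"))
})

#' @rdname accessors
#' @export
setGeneric("denseClusters", function(x) standardGeneric("denseClusters"))
#' @rdname accessors
#' @export
setMethod("denseClusters", "ClusterSet", function(x) x@denseClusters)

#' @rdname accessors
#' @export
setGeneric("siteCategories", function(x) standardGeneric("siteCategories"))
#' @rdname accessors
#' @export
setMethod("siteCategories", "ClusterSet", function(x) x@categories)

#' @rdname accessors
#' @export
setGeneric("sDistances", function(x) standardGeneric("sDistances"))
#' @rdname accessors
#' @export
setMethod("sDistances", "ClusterSet", function(x) x@sTable)

#' @rdname accessors
#' @export
setGeneric("sStarDistances", function(x) standardGeneric("sStarDistances"))
#' @rdname accessors
#' @export
setMethod("sStarDistances", "ClusterSet", function(x) x@sStarTable)

## ---- show ------------------------------------------------------------------

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object@sequences), "transcripts,",
      sum(lengths(object@cds) > 0), "with CDS annotation\n")
})

setMethod("show", "SiteTable", function(object) {
  s <- object@sites
  cat("SiteTable:", nrow(s), "sites on", length(unique(s$transcript)),
      "transcripts")
  if (any(!is.na(s$el)))
    cat(sprintf("; median EL %.3f", median(s$el, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "ReadMatrix", function(object) {
  cat("ReadMatrix:", nrow(object@reads), "reads,",
      nrow(object@calls), "site-level calls\n")
})

setMethod("show", "PairingProfile", function(object) {
  cat("PairingProfile over", length(object@pairing), "transcripts",
      if (length(object@partner)) "(with partner map)" else "", "\n")
})

setMethod("show", "PairCounts", function(object) {
  n <- pairTallies(object)
  cat(sprintf("PairCounts %s:%d-%d (S=%d) AA=%d AI=%d IA=%d II=%d%s\n",
              object@transcript, object@i, object@j, object@S,
              n[1], n[2], n[3], n[4],
              if (object@informative) "" else " [uninformative]"))
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@denseClusters), "dense clusters;",
      nrow(object@sTable), "S pairs;", nrow(object@sStarTable), "S* pairs\n")
})
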