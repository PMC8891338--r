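#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats rnorm runif rpois rbeta qnorm pnorm dnorm integrate uniroot
#'   wilcox.test ks.test fisher.test chisq.test binom.test cor quantile median
#'   sd var qt pt setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

#' TranscriptSet: transcript sequences with CDS (and optional exon) annotation
#'
#' Holds sense-strand transcript sequences as a \link[Biostrings]{DNAStringSet}
#' together with per-transcript CDS intervals in 0-based half-open transcript
#' coordinates. All downstream coordinates in the package follow the same
#' convention; there is no strand arithmetic.
#'
#' @slot sequences DNAStringSet of transcript sequences (A/C/G/T, uppercase).
#' @slot cds named list; per transcript an integer matrix with columns
#'   \code{start}, \code{end} (0-based half-open), sorted and non-overlapping,
#'   total length divisible by 3. May be empty for non-coding transcripts.
#' @slot exons same convention as \code{cds}; optional.
#' @export
setClass("TranscriptSet",
  slots = c(sequences = "DNAStringSet", cds = "list", exons = "list"))

setValidity("TranscriptSet", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    return("sequences must be uniquely named")
  chk <- function(ivls, what) {
    for (tx in names(ivls)) {
      m <- ivls[[tx]]
      if (!tx %in% ids) return(sprintf("%s for unknown transcript '%s'", what, tx))
      if (nrow(m) == 0L) next
      if (any(m[, 1L] >= m[, 2L])) return(sprintf("empty %s interval in '%s'", what, tx))
      if (any(m[, 1L] < 0L) || any(m[, 2L] > length(object@sequences[[tx]])))
        return(sprintf("%s interval outside sequence in '%s'", what, tx))
      if (is.unsorted(m[, 1L]) || any(m[-1L, 1L] < m[-nrow(m), 2L]))
        return(sprintf("%s intervals unsorted/overlapping in '%s'", what, tx))
    }
    NULL
  }
  err <- chk(object@cds, "CDS")
  if (!is.null(err)) return(err)
  for (tx in names(object@cds)) {
    m <- object@cds[[tx]]
    if (nrow(m) > 0L && sum(m[, 2L] - m[, 1L]) %% 3L != 0L)
      return(sprintf("CDS length not divisible by 3 in '%s'", tx))
  }
  err <- chk(object@exons, "exon")
  if (!is.null(err)) return(err)
  TRUE
})

#' SiteTable: editing-site records
#'
#' One row per editing site: transcript id, 0-based position of an edited
#' adenine, read coverage, G-call count, editing level EL = g_count/coverage
#' (the fraction of mapped reads carrying inosine, read as G), codon frame
#' offset and a recoding flag for CDS sites.
#'
#' @slot sites data.frame with columns \code{transcript}, \code{pos},
#'   \code{coverage}, \code{g_count}, \code{el}, \code{frame_offset}
#'   (0/1/2 or NA for non-coding), \code{recoding} ("synonymous",
#'   "nonsynonymous", "noncoding" or NA when undetermined).
#' @export
setClass("SiteTable", slots = c(sites = "data.frame"))

setValidity("SiteTable", function(object) {
  s <- object@sites
  need <- c("transcript", "pos", "coverage", "g_count", "el",
            "frame_offset", "recoding")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  ok <- is.na(s$g_count) | is.na(s$coverage) | (s$g_count >= 0 & s$g_count <= s$coverage)
  if (!all(ok)) return("g_count must lie in [0, coverage]")
  if (any(!is.na(s$el) & (s$el < 0 | s$el > 1))) return("el must lie in [0, 1]")
  if (anyDuplicated(s[, c("transcript", "pos")])) return("duplicated site")
  TRUE
})

#' ReadMatrix: per-read A/I calls at editing-site positions
#'
#' Sparse representation of the read-level editing states: one table of read
#' intervals and one table of per-read calls restricted to editing-site
#' positions. State "I" means the sequenced base was G at an A reference
#' position; any other non-A base is "other" and is excluded from A/I tallies.
#'
#' @slot reads data.frame: \code{read_id}, \code{transcript}, \code{start},
#'   \code{end} (0-based half-open covered interval).
#' @slot calls data.frame: \code{read_id}, \code{transcript}, \code{pos},
#'   \code{state} in \{"A","I","other"\}.
#' @export
setClass("ReadMatrix", slots = c(reads = "data.frame", calls = "data.frame"))

setValidity("ReadMatrix", function(object) {
  r <- object@reads; cl <- object@calls
  if (!all(c("read_id", "transcript", "start", "end") %in% names(r)))
    return("reads needs read_id/transcript/start/end")
  if (!all(c("read_id", "transcript", "pos", "state") %in% names(cl)))
    return("calls needs read_id/transcript/pos/state")
  if (nrow(cl) > 0L && !all(cl$state %in% c("A", "I", "other")))
    return("call states must be A, I or other")
  if (nrow(r) > 0L && any(r$end <= r$start)) return("empty read interval")
  TRUE
})

#' PairingProfile: per-nucleotide base-pairing probabilities
#'
#' Per transcript, the probability that each nucleotide is paired in the
#' local secondary-structure ensemble (complement of the RNAplfold unpaired
#' probability), an optional structural-potential score, and an optional
#' predicted pairing-partner map used for A-C mismatch analysis.
#'
#' @slot pairing named list of numeric vectors in [0,1]; NA marks missing.
#' @slot potential named list of numeric vectors (e.g. Z-scores); optional.
#' @slot partner named list of integer vectors (0-based partner position,
#'   NA when unpaired); optional.
#' @export
setClass("PairingProfile",
  slots = c(pairing = "list", potential = "list", partner = "list"))

setValidity("PairingProfile", function(object) {
  for (tx in names(object@pairing)) {
    v <- object@pairing[[tx]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      return(sprintf("pairing probabilities outside [0,1] in '%s'", tx))
  }
  TRUE
})

#' PairCounts: joint editing-state tallies for an ordered site pair
#'
#' Read tallies n_AA, n_AI, n_IA, n_II for a pair of editing sites (i
#' upstream, j downstream, S = j - i) over reads covering both positions
#' with informative A/I calls at both.
#'
#' @slot transcript,i,j pair identity (0-based positions, i < j).
#' @slot S integer distance j - i.
#' @slot nAA,nAI,nIA,nII integer tallies (first letter = state at i).
#' @slot informative logical; FALSE when the total tally is below the
#'   caller's minimum.
#' @export
setClass("PairCounts",
  slots = c(transcript = "character", i = "integer", j = "integer",
            S = "integer", nAA = "integer", nAI = "integer",
            nIA = "integer", nII = "integer", informative = "logical"))

setValidity("PairCounts", function(object) {
  if (object@i >= object@j) return("requires i < j")
  if (object@S != object@j - object@i) return("S must equal j - i")
  if (min(object@nAA, object@nAI, object@nIA, object@nII) < 0L)
    return("negative tally")
  TRUE
})

#' ClusterSet: dense-cluster runs, site categories and distance tables
#'
#' @slot denseClusters data.frame: \code{transcript}, \code{start},
#'   \code{end} (0-based inclusive run of consecutive edited adenines),
#'   \code{size} (>= 2).
#' @slot categories data.frame: \code{transcript}, \code{pos},
#'   \code{category} in \{"DC", "clustered", "individual"\}.
#' @slot sTable data.frame of all same-transcript pair distances
#'   (\code{transcript}, \code{i}, \code{j}, \code{S}), regardless of
#'   intervening sites, up to the configured maximum.
#' @slot sStarTable nearest-neighbor subset (no edited adenine between
#'   the pair members).
#' @export
setClass("ClusterSet",
  slots = c(denseClusters = "data.frame", categories = "data.frame",
            sTable = "data.frame", sStarTable = "data.frame"))
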