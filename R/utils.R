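# Internal helpers shared across modules.

.seqChars <- function(transcripts, tx) {
  strsplit(as.character(sequencesOf(transcripts)[[tx]]), "")[[1L]]
}

# 0-based positions of adenines in a transcript
.adeninePositions <- function(transcripts, tx) {
  which(.seqChars(transcripts, tx) == "A") - 1L
}

# Map a 0-based transcript position into concatenated-CDS coordinates;
# NA when outside every CDS interval.
.cdsOffset <- function(cdsIvls, pos) {
  if (is.null(cdsIvls) || nrow(cdsIvls) == 0L) return(NA_integer_)
  off <- 0L
  for (k in seq_len(nrow(cdsIvls))) {
    s <- cdsIvls[k, 1L]; e <- cdsIvls[k, 2L]
    if (pos >= s && pos < e) return(off + (pos - s))
    off <- off + (e - s)
  }
  NA_integer_
}

#' Classify the A-to-G consequence of editing a CDS adenine
#'
#' Translates the codon containing \code{pos} with and without the A-to-G
#' substitution under the standard genetic code.
#'
#' @param transcripts a \code{TranscriptSet} with CDS annotation.
#' @param transcript transcript id.
#' @param pos 0-based transcript position of an adenine.
#' @return one of \code{"synonymous"}, \code{"nonsynonymous"},
#'   \code{"noncoding"}.
#' @export
recodingFlag <- function(transcripts, transcript, pos) {
  cdsIvls <- cdsOf(transcripts)[[transcript]]
  off <- .cdsOffset(cdsIvls, pos)
  if (is.na(off)) return("noncoding")
  chars <- .seqChars(transcripts, transcript)
  cdsSeq <- unlist(lapply(seq_len(nrow(cdsIvls)), function(k)
    chars[(cdsIvls[k, 1L] + 1L):cdsIvls[k, 2L]]))
  codonIdx <- off %/% 3L
  codon <- cdsSeq[(codonIdx * 3L + 1L):(codonIdx * 3L + 3L)]
  if (codon[off %% 3L + 1L] != "A")
    stop("position ", pos, " in ", transcript, " is not an adenine")
  edited <- codon
  edited[off %% 3L + 1L] <- "G"
  gc <- Biostrings::GENETIC_CODE
  if (gc[[paste(codon, collapse = "")]] == gc[[paste(edited, collapse = "")]])
    "synonymous" else "nonsynonymous"
}

# Vectorized frame/recoding annotation for many positions on one
# transcript (codon translation via Biostrings::GENETIC_CODE).
.recodingVector <- function(transcripts, tx, pos) {
  n <- length(pos)
  frame <- rep(NA_integer_, n)
  rec <- rep("noncoding", n)
  cdsIvls <- cdsOf(transcripts)[[tx]]
  if (is.null(cdsIvls) || nrow(cdsIvls) == 0L)
    return(list(frame = frame, recoding = rec))
  gc <- Biostrings::GENETIC_CODE
  chars <- .seqChars(transcripts, tx)
  cdsPos <- unlist(lapply(seq_len(nrow(cdsIvls)), function(k)
    cdsIvls[k, 1L]:(cdsIvls[k, 2L] - 1L)))
  cdsSeq <- chars[cdsPos + 1L]
  off <- match(pos, cdsPos) - 1L         # 0-based CDS offset or NA
  frame <- as.integer(off %% 3L)
  inCds <- which(!is.na(off))
  if (length(inCds)) {
    cIdx <- off[inCds] %/% 3L
    codon <- paste0(cdsSeq[cIdx * 3L + 1L], cdsSeq[cIdx * 3L + 2L],
                    cdsSeq[cIdx * 3L + 3L])
    inFrame <- off[inCds] %% 3L + 1L
    edited <- codon
    substr(edited, inFrame, inFrame) <- "G"
    rec[inCds] <- ifelse(gc[codon] == gc[edited],
                         "synonymous", "nonsynonymous")
  }
  list(frame = frame, recoding = rec)
}

# Fill frame_offset and recoding for every site.
annotateSites <- function(sitesDf, transcripts) {
  if (nrow(sitesDf) == 0L) return(sitesDf)
  for (tx in unique(sitesDf$transcript)) {
    rows <- which(sitesDf$transcript == tx)
    ann <- .recodingVector(transcripts, tx, sitesDf$pos[rows])
    sitesDf$frame_offset[rows] <- ann$frame
    sitesDf$recoding[rows] <- ann$recoding
  }
  sitesDf
}

## ---- bivariate-normal machinery (Gaussian copula calibration) --------------

# P(X <= a, Y <= b) for standard bivariate normal with correlation rho,
# by 1-D quadrature over x of phi(x) * Phi((b - rho x)/sqrt(1 - rho^2)).
.binormOrthant <- function(a, b, rho) {
  if (abs(rho) >= 1 - 1e-9) {
    if (rho > 0) return(pnorm(min(a, b)))
    return(max(0, pnorm(a) + pnorm(b) - 1))
  }
  s <- sqrt(1 - rho^2)
  integrate(function(x) dnorm(x) * pnorm((b - rho * x) / s),
            lower = -8.5, upper = a, rel.tol = 1e-9,
            stop.on.error = FALSE)$value
}

# phi coefficient of the thresholded pair: X < qnorm(p1) marks state I.
.phiFromLatent <- function(rho, p1, p2) {
  p11 <- .binormOrthant(qnorm(p1), qnorm(p2), rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation achieving a target phi for marginals p1, p2; capped at
# +-0.999 when the target is unattainable for these marginals.
.latentFromPhi <- function(phiTarget, p1, p2) {
  if (abs(phiTarget) < 1e-12) return(0)
  hi <- .phiFromLatent(0.999, p1, p2)
  lo <- .phiFromLatent(-0.999, p1, p2)
  if (phiTarget >= hi) return(0.999)
  if (phiTarget <= lo) return(-0.999)
  uniroot(function(r) .phiFromLatent(r, p1, p2) - phiTarget,
          lower = -0.999, upper = 0.999, tol = 1e-6)$root
}

# Memoized calibration on a rounded (phi, p1, p2) grid; calibration is
# smooth so 0.005 rounding is far below read-sampling noise.
.makeLatentCache <- function() {
  cache <- new.env(parent = emptyenv())
  function(phiTarget, p1, p2) {
    key <- paste(round(phiTarget, 3), round(p1, 3), round(p2, 3))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    cache[[key]] <- .latentFromPhi(round(phiTarget, 3),
                                   round(p1, 3), round(p2, 3))
    cache[[key]]
  }
}

## ---- misc ------------------------------------------------------------------

# Largest run of TRUE containing (or bridged around) index `center`.
.runBounds <- function(flags, center) {
  n <- length(flags)
  lo <- center; hi <- center
  while (lo > 1L && flags[lo - 1L]) lo <- lo - 1L
  while (hi < n && flags[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}

.stopifnotProb <- function(x, what) {
  if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]")
  invisible(x)
}
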