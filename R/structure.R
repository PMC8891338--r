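# Structure-conditioned analyses: average pairing profiles and peak
# width, A-C mismatch enrichment, site-vs-control structural comparisons,
# structural pair classification, cooperativity stratified by structure,
# and a desk-scale Nussinov/shuffle pairing scorer.

#' Average pairing probability around editing sites
#'
#' Mean per-offset pairing probability over windows centered at the
#' sites; offsets truncated by transcript ends are averaged over the
#' available data only.
#'
#' @param profiles a \code{PairingProfile}.
#' @param siteTable sites defining the window centers.
#' @param halfwidth window half-width in nt.
#' @return data.frame: offset (-halfwidth..halfwidth), mean, n.
#' @export
averageProfileAroundSites <- function(profiles, siteTable,
                                      halfwidth = 100L) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  offs <- -halfwidth:halfwidth
  acc <- numeric(length(offs)); cnt <- integer(length(offs))
  pp <- pairingProb(profiles)
  for (r in seq_len(nrow(st))) {
    v <- pp[[st$transcript[r]]]
    if (is.null(v)) next
    pos <- st$pos[r] + offs            # 0-based positions per offset
    ok <- pos >= 0L & pos < length(v)
    val <- v[pos[ok] + 1L]
    use <- ok; use[ok] <- !is.na(val)
    acc[use] <- acc[use] + val[!is.na(val)]
    cnt[use] <- cnt[use] + 1L
  }
  data.frame(offset = offs, mean = ifelse(cnt > 0L, acc / cnt, NA_real_),
             n = cnt)
}

#' Background (noise) band of pairing probabilities
#'
#' Central 95\% interval of per-nucleotide pairing probabilities at
#' nucleotides farther than \code{minDist} from every editing site.
#'
#' @param profiles a \code{PairingProfile}.
#' @param siteTable sites to stay away from.
#' @param minDist minimum distance (nt; 200 in the standard analysis).
#' @return numeric c(lo, hi).
#' @export
estimateNoiseBand <- function(profiles, siteTable, minDist = 200L) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  vals <- numeric()
  pp <- pairingProb(profiles)
  for (tx in names(pp)) {
    v <- pp[[tx]]
    p <- st$pos[st$transcript == tx]
    far <- rep(TRUE, length(v))
    for (s in p) {
      lo <- max(0L, s - minDist); hi <- min(length(v) - 1L, s + minDist)
      far[(lo + 1L):(hi + 1L)] <- FALSE
    }
    vals <- c(vals, v[far & !is.na(v)])
  }
  if (!length(vals)) stop("no nucleotides farther than minDist from sites")
  as.numeric(quantile(vals, c(0.025, 0.975)))
}

#' Width of the above-band pairing peak centered at editing sites
#'
#' Length of the maximal contiguous offset interval containing offset 0
#' in which the average profile exceeds the band's upper bound. The
#' central dip (edited adenines are less paired than their flanks) is
#' bridged when flanked by above-band values on both sides; set
#' \code{bridge = FALSE} to disable.
#'
#' @param avgProfile output of \code{averageProfileAroundSites}.
#' @param band numeric c(lo, hi) from \code{estimateNoiseBand}.
#' @param bridge bridge the central below-band dip.
#' @param maxBridge widest central dip (nt) that may be bridged.
#' @return width in nt (0 when the center never rises above the band).
#' @export
estimatePeakWidth <- function(avgProfile, band, bridge = TRUE,
                              maxBridge = 5L) {
  above <- !is.na(avgProfile$mean) & avgProfile$mean > band[2]
  center <- which(avgProfile$offset == 0L)
  if (!length(center)) stop("profile must contain offset 0")
  if (!above[center]) {
    if (!bridge) return(0L)
    # bridge: nearest above-band offsets on both sides within maxBridge
    lhs <- which(above & avgProfile$offset < 0L)
    rhs <- which(above & avgProfile$offset > 0L)
    if (!length(lhs) || !length(rhs)) return(0L)
    l <- max(lhs); r <- min(rhs)
    if (avgProfile$offset[r] - avgProfile$offset[l] - 1L > maxBridge)
      return(0L)
    above[l:r] <- TRUE
  }
  b <- .runBounds(above, center)
  as.integer(avgProfile$offset[b[2L]] - avgProfile$offset[b[1L]] + 1L)
}

#' A-C mismatch enrichment at editing sites
#'
#' 2x2 of \{site, control\} x \{A-across-C, other\} where the control for
#' each site is its nearest non-edited adenine; the partner map of the
#' profile identifies the base across the helix. Fisher's exact test for
#' p; odds ratio with Haldane correction when a margin is zero.
#'
#' @param profiles a \code{PairingProfile} with a partner map.
#' @param siteTable edited sites.
#' @param transcripts a \code{TranscriptSet}.
#' @return list: table, oddsRatio, p.
#' @export
acMismatchEnrichment <- function(profiles, siteTable, transcripts) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  pm <- partnerMap(profiles)
  if (!length(pm)) stop("profiles carry no partner map")
  acrossC <- function(tx, pos, chars) {
    ptn <- pm[[tx]]
    if (is.null(ptn) || pos + 1L > length(ptn)) return(NA)
    q <- ptn[pos + 1L]
    if (is.na(q)) return(FALSE)
    chars[q + 1L] == "C"
  }
  siteAC <- 0L; siteOther <- 0L; ctrlAC <- 0L; ctrlOther <- 0L
  for (tx in unique(st$transcript)) {
    chars <- .seqChars(transcripts, tx)
    aPos <- which(chars == "A") - 1L
    p <- st$pos[st$transcript == tx]
    nonEd <- setdiff(aPos, p)
    for (s in p) {
      a <- acrossC(tx, s, chars)
      if (is.na(a)) next
      if (a) siteAC <- siteAC + 1L else siteOther <- siteOther + 1L
      if (length(nonEd)) {
        ctl <- nonEd[which.min(abs(nonEd - s))]
        b <- acrossC(tx, ctl, chars)
        if (!is.na(b)) {
          if (b) ctrlAC <- ctrlAC + 1L else ctrlOther <- ctrlOther + 1L
        }
      }
    }
  }
  tab <- matrix(c(siteAC, siteOther, ctrlAC, ctrlOther), nrow = 2L,
                byrow = TRUE,
                dimnames = list(c("site", "control"), c("AC", "other")))
  p <- fisher.test(tab)$p.value
  h <- if (any(tab == 0L)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
        ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(table = tab, oddsRatio = or, p = p)
}

#' Paired site-vs-nearest-control structural comparison
#'
#' For each edited adenine, the nearest non-edited adenine on the same
#' transcript serves as its matched control; reports paired differences
#' in pairing probability (and structural potential when present), a
#' Wilcoxon signed-rank p, and EL-stratified summaries.
#'
#' @param siteTable edited sites with ELs.
#' @param profiles a \code{PairingProfile}.
#' @param transcripts a \code{TranscriptSet}.
#' @param elBreaks EL stratification breaks.
#' @return list: \code{pairs} (per-site table), \code{p} (Wilcoxon on
#'   pairing differences), \code{pPotential} (NA without potential),
#'   \code{strata} (per-stratum mean difference).
#' @export
siteVsNearestControl <- function(siteTable, profiles, transcripts,
                                 elBreaks = c(0, 0.1, 0.5, 1)) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  pp <- pairingProb(profiles); pot <- profiles@potential
  rows <- list()
  for (tx in unique(st$transcript)) {
    chars <- .seqChars(transcripts, tx)
    aPos <- which(chars == "A") - 1L
    p <- st$pos[st$transcript == tx]
    el <- st$el[st$transcript == tx]
    nonEd <- setdiff(aPos, p)
    if (!length(nonEd)) next       # no eligible control on this transcript
    v <- pp[[tx]]; w <- pot[[tx]]
    for (k in seq_along(p)) {
      ctl <- nonEd[which.min(abs(nonEd - p[k]))]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx, pos = p[k], control = ctl, el = el[k],
        sitePairing = v[p[k] + 1L], controlPairing = v[ctl + 1L],
        sitePotential = if (!is.null(w)) w[p[k] + 1L] else NA_real_,
        controlPotential = if (!is.null(w)) w[ctl + 1L] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sitePairing = numeric(), controlPairing = numeric())
  d <- pairs$sitePairing - pairs$controlPairing
  pW <- if (length(d) >= 2L)
    suppressWarnings(wilcox.test(pairs$sitePairing, pairs$controlPairing,
                                 paired = TRUE, exact = FALSE)$p.value)
    else NA_real_
  pPot <- if (nrow(pairs) && any(!is.na(pairs$sitePotential)))
    suppressWarnings(wilcox.test(pairs$sitePotential,
                                 pairs$controlPotential, paired = TRUE,
                                 exact = FALSE)$p.value) else NA_real_
  strata <- if (nrow(pairs)) {
    bin <- cut(pairs$el, elBreaks, include.lowest = TRUE)
    agg <- aggregate(d, list(el = bin), mean)
    names(agg) <- c("elStratum", "meanDiff")
    agg
  } else data.frame()
  list(pairs = pairs, p = pW, pPotential = pPot, strata = strata)
}

#' Classify a site pair by the secondary structure between them
#'
#' \code{close_due_to_structure}: an above-band paired segment (a run of
#' at least \code{minRun} consecutive nucleotides with consistent partner
#' mapping) lies between the sites and brings them within
#' \code{spatialCutoff} nt of each other along the structure;
#' \code{distant_unstructured}: no above-band paired run between them;
#' otherwise \code{intermediate}.
#'
#' @param profiles a \code{PairingProfile} with partner map.
#' @param transcript,i,j the pair (0-based, i < j).
#' @param band noise band c(lo, hi).
#' @param minRun minimum run length of above-band paired nucleotides.
#' @param spatialCutoff maximum spatial offset (nt) for "close".
#' @return one of the three labels.
#' @export
classifyPairStructure <- function(profiles, transcript, i, j, band,
                                  minRun = 5L, spatialCutoff = 20L) {
  stopifnot(i < j)
  v <- pairingProb(profiles)[[transcript]]
  ptn <- partnerMap(profiles)[[transcript]]
  between <- (i + 1L):(j - 1L)
  if (j - i < 2L) return("close_due_to_structure")  # adjacent: trivially close
  above <- between[!is.na(v[between + 1L]) & v[between + 1L] > band[2] &
                   !is.na(ptn[between + 1L])]
  if (!length(above)) return("distant_unstructured")
  runs <- split(above, cumsum(c(1L, diff(above) != 1L)))
  best <- Inf
  anyRun <- FALSE
  for (rn in runs) {
    if (length(rn) < minRun) next
    prt <- ptn[rn + 1L]
    consistent <- length(rn) < 2L || all(abs(diff(prt)) == 1L)
    if (!consistent) next
    anyRun <- TRUE
    inside <- prt >= i & prt <= j
    if (!any(inside)) next
    off <- (rn[inside] - i) + (j - prt[inside])
    off2 <- (prt[inside] - i) + (j - rn[inside])
    best <- min(best, abs(off), abs(off2))
  }
  if (!anyRun) return("distant_unstructured")
  if (best <= spatialCutoff) "close_due_to_structure" else "intermediate"
}

#' Cooperativity stratified by structural class, in log2 distance bins
#'
#' Mann-Whitney comparison of r' between structurally close pairs and
#' distant-unstructured controls within powers-of-two S bins
#' (1-2, 2-4, ..., 256-512), Bonferroni-corrected over occupied bins.
#'
#' @param pairDf data.frame with columns \code{S}, \code{rprime},
#'   \code{label} (structural class).
#' @param alpha family-wise level.
#' @return data.frame per bin: n per class, medians, p, significant,
#'   direction.
#' @export
cooperativityByStructure <- function(pairDf, alpha = 0.05) {
  breaks <- 2^(0:9)
  pairDf <- pairDf[!is.na(pairDf$rprime), , drop = FALSE]
  bin <- cut(pairDf$S, breaks, right = FALSE,
             labels = paste(head(breaks, -1L), breaks[-1L], sep = "-"))
  rows <- list()
  for (b in levels(bin)) {
    sel <- which(bin == b)
    a <- pairDf$rprime[sel][pairDf$label[sel] == "close_due_to_structure"]
    c0 <- pairDf$rprime[sel][pairDf$label[sel] == "distant_unstructured"]
    if (length(a) < 2L || length(c0) < 2L) {
      rows[[b]] <- data.frame(bin = b, nStruct = length(a),
                              nControl = length(c0), medStruct = NA_real_,
                              medControl = NA_real_, p = NA_real_,
                              significant = NA, skipped = TRUE)
      next
    }
    p <- suppressWarnings(wilcox.test(a, c0, exact = FALSE)$p.value)
    rows[[b]] <- data.frame(bin = b, nStruct = length(a),
                            nControl = length(c0),
                            medStruct = median(a), medControl = median(c0),
                            p = p, significant = NA, skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  m <- sum(!out$skipped)
  out$significant <- !out$skipped & !is.na(out$p) & out$p < alpha / max(1L, m)
  rownames(out) <- NULL
  out
}

## ---- naive pairing scorer (fallback when no folding output exists) --------

# Nussinov-style maximum base-pair count; minimum hairpin loop 3, GU
# (here TG on the DNA alphabet) allowed.
.maxPairCount <- function(chars) {
  n <- length(chars)
  if (n < 5L) return(0L)
  canPair <- function(a, b)
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  N <- matrix(0L, n, n)
  for (span in 4L:(n - 1L)) {
    for (a in seq_len(n - span)) {
      b <- a + span
      best <- N[a + 1L, b]
      for (k in a:(b - 4L)) {
        if (canPair(chars[k], chars[b])) {
          left <- if (k > a) N[a, k - 1L] else 0L
          mid <- if (k + 1L <= b - 1L) N[k + 1L, b - 1L] else 0L
          best <- max(best, left + mid + 1L)
        }
      }
      N[a, b] <- best
    }
  }
  N[1L, n]
}

# Altschul-Erickson dinucleotide-preserving shuffle.
.shuffleDinucleotides <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(chars)
  letters0 <- unique(chars)
  if (length(letters0) == 1L) return(chars)
  edges <- split(chars[-1L], chars[-n])     # outgoing edges per vertex
  last <- chars[n]
  for (tries in seq_len(200L)) {
    lastEdge <- vapply(names(edges), function(v) {
      if (v == last) return(NA_character_)
      sample(edges[[v]], 1L)
    }, "")
    # the chosen last edges must form a tree rooted at the final vertex
    ok <- TRUE
    for (v in names(lastEdge)) {
      if (is.na(lastEdge[v])) next
      seen <- v; cur <- lastEdge[[v]]
      while (cur != last && !cur %in% seen) {
        if (is.na(lastEdge[cur])) break
        seen <- c(seen, cur); cur <- lastEdge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (!ok) next
    # permute non-last edges, append the chosen last edge
    perm <- lapply(names(edges), function(v) {
      e <- edges[[v]]
      if (!is.na(lastEdge[v])) {
        drop <- match(lastEdge[[v]], e)
        e <- e[-drop]
      }
      c(sample(e), if (!is.na(lastEdge[v])) lastEdge[[v]])
    })
    names(perm) <- names(edges)
    out <- character(n); out[1L] <- chars[1L]
    idx <- setNames(rep(1L, length(perm)), names(perm))
    cur <- chars[1L]
    for (k in 2L:n) {
      nxt <- perm[[cur]][idx[cur]]
      idx[cur] <- idx[cur] + 1L
      out[k] <- nxt
      cur <- nxt
    }
    return(out)
  }
  sample(chars)   # degenerate graphs: plain permutation
}

#' Naive per-window pairing propensity with shuffle Z-scores
#'
#' Desk-scale structural scorer for when no thermodynamic folding output
#' is available: the maximum complementary-pair count (Nussinov counting,
#' minimum loop 3, GU allowed) of the window centered at each requested
#' position, compared against dinucleotide-preserving shuffles of the
#' same window.
#'
#' @param sequence character string (A/C/G/T).
#' @param window window size in nt (must not exceed the sequence length).
#' @param positions 0-based center positions (default: window centers
#'   tiling the sequence every window/2).
#' @param nShuffle shuffles per window.
#' @param seed RNG seed (scores are deterministic given the seed).
#' @return data.frame: pos, score, shuffleMean, shuffleSd, z (0 when the
#'   shuffles are degenerate).
#' @export
naivePairingScore <- function(sequence, window = 60L, positions = NULL,
                              nShuffle = 20L, seed = 1L) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(chars)
  if (window > n) stop("window larger than sequence")
  set.seed(seed)
  half <- window %/% 2L
  if (is.null(positions))
    positions <- seq(half, n - 1L - half, by = max(1L, half))
  rows <- lapply(positions, function(p) {
    lo <- max(0L, p - half); hi <- min(n - 1L, lo + window - 1L)
    lo <- max(0L, hi - window + 1L)
    w <- chars[(lo + 1L):(hi + 1L)]
    sc <- .maxPairCount(w)
    sh <- vapply(seq_len(nShuffle), function(z)
      .maxPairCount(.shuffleDinucleotides(w)), 0L)
    sdv <- sd(sh)
    z <- if (is.na(sdv) || sdv == 0) 0 else (sc - mean(sh)) / sdv
    data.frame(pos = p, score = sc, shuffleMean = mean(sh),
               shuffleSd = sdv, z = z)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
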