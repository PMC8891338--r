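# Dense-cluster detection, context-preserving randomized controls, site
# categorization and EL comparisons, S/S* distance machinery, the
# neighbor-editing-probability window, and the long-range KS analysis.

#' Find dense clusters (maximal runs of consecutive edited adenines)
#'
#' @param siteTable a \code{SiteTable} (or plain data.frame with
#'   \code{transcript}, \code{pos}).
#' @return data.frame: transcript, start, end (0-based inclusive), size;
#'   singleton sites are not dense clusters.
#' @export
findDenseClusters <- function(siteTable) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  out <- list()
  for (tx in unique(st$transcript)) {
    p <- sort(st$pos[st$transcript == tx])
    if (length(p) < 2L) next
    brk <- c(0L, which(diff(p) > 1L), length(p))
    for (k in seq_len(length(brk) - 1L)) {
      run <- p[(brk[k] + 1L):brk[k + 1L]]
      if (length(run) >= 2L)
        out[[length(out) + 1L]] <- data.frame(
          transcript = tx, start = run[1L], end = run[length(run)],
          size = length(run), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(transcript = character(), start = integer(),
                      end = integer(), size = integer()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' All-pairs (S) and nearest-neighbor (S*) distance tables
#'
#' S values are nucleotide distances between edited adenines on one
#' transcript regardless of intervening sites (up to \code{maxS}); S*
#' values are the subset of pairs with no edited adenine between them.
#'
#' @param siteTable a \code{SiteTable} or site data.frame.
#' @param maxS cap on the all-pairs table (default 1000 nt).
#' @return a \code{ClusterSet} with distance tables and dense clusters;
#'   categories are filled by \code{categorizeSites}.
#' @export
computeDistances <- function(siteTable, maxS = 1000L) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  sTab <- .sitePairs(st, maxS)
  starL <- list()
  for (tx in unique(st$transcript)) {
    p <- sort(st$pos[st$transcript == tx])
    if (length(p) < 2L) next
    starL[[tx]] <- data.frame(transcript = tx, i = p[-length(p)],
                              j = p[-1L], S = diff(p),
                              stringsAsFactors = FALSE)
  }
  sStar <- if (length(starL)) do.call(rbind, starL) else
    data.frame(transcript = character(), i = integer(), j = integer(),
               S = integer())
  rownames(sStar) <- NULL
  new("ClusterSet", denseClusters = findDenseClusters(st),
      categories = categorizeSites(st),
      sTable = sTab, sStarTable = sStar)
}

#' Categorize sites as DC / clustered / individual
#'
#' DC: member of a run of consecutive edited adenines; clustered: nearest
#' edited neighbor closer than \code{cutoff} (100 nt, the standard
#' threshold) but not in a dense run; individual: no edited adenine within
#' the cutoff.
#'
#' @param siteTable a \code{SiteTable} or site data.frame.
#' @param cutoff clustered/individual distance threshold (nt).
#' @return data.frame: transcript, pos, category.
#' @export
categorizeSites <- function(siteTable, cutoff = 100L) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  out <- list()
  for (tx in unique(st$transcript)) {
    p <- sort(st$pos[st$transcript == tx])
    nn <- if (length(p) > 1L)
      pmin(c(Inf, diff(p)), c(diff(p), Inf)) else rep(Inf, length(p))
    cat <- ifelse(nn == 1L, "DC",
                  ifelse(nn < cutoff, "clustered", "individual"))
    out[[tx]] <- data.frame(transcript = tx, pos = p, category = cat,
                            stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript = character(), pos = integer(),
               category = character())
  rownames(df) <- NULL
  df
}

#' Randomized control site sets
#'
#' Draws, per transcript, the real number of sites from the transcript's
#' adenines, either uniformly or stratified by the (-1, +1) flanking
#' context of the real sites (the site base is always A). Per-transcript
#' site counts are preserved exactly in every replicate. Strata with too
#' few eligible adenines fall back to uniform sampling within the
#' transcript; the number of such events is recorded in the
#' \code{"fallbacks"} attribute.
#'
#' @param transcripts a \code{TranscriptSet}.
#' @param siteTable the real \code{SiteTable}.
#' @param mode \code{"uniform_adenine"} or \code{"trinucleotide"}.
#' @param nReps number of control replicates.
#' @param seed RNG seed.
#' @return list of site data.frames (transcript, pos), one per replicate.
#' @export
randomizeSites <- function(transcripts, siteTable,
                           mode = c("uniform_adenine", "trinucleotide"),
                           nReps = 100L, seed = 1L) {
  mode <- match.arg(mode)
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  set.seed(seed)
  txs <- unique(st$transcript)
  # precompute per-transcript adenine positions and contexts
  prep <- lapply(txs, function(tx) {
    chars <- .seqChars(transcripts, tx)
    aPos <- which(chars == "A") - 1L
    up <- ifelse(aPos - 1L >= 0L, chars[aPos], "N")
    dn <- ifelse(aPos + 1L < length(chars), chars[aPos + 2L], "N")
    list(aPos = aPos, ctx = paste0(up, dn),
         real = sort(st$pos[st$transcript == tx]))
  })
  names(prep) <- txs
  fallbacks <- 0L
  reps <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    rows <- lapply(txs, function(tx) {
      pp <- prep[[tx]]
      n <- length(pp$real)
      if (n == 0L) return(NULL)
      if (length(pp$aPos) < n)
        stop("transcript ", tx, " has fewer adenines than sites")
      if (mode == "uniform_adenine") {
        pos <- pp$aPos[sample.int(length(pp$aPos), n)]
      } else {
        realCtx <- pp$ctx[match(pp$real, pp$aPos)]
        want <- table(realCtx)
        pos <- integer()
        short <- 0L
        for (cx in names(want)) {
          pool <- pp$aPos[pp$ctx == cx]
          k <- want[[cx]]
          if (length(pool) >= k) {
            pos <- c(pos, pool[sample.int(length(pool), k)])
          } else {
            pos <- c(pos, pool)
            short <- short + (k - length(pool))
          }
        }
        if (short > 0L) {
          fallbacks <<- fallbacks + 1L
          pool <- setdiff(pp$aPos, pos)
          pos <- c(pos, pool[sample.int(length(pool), short)])
        }
      }
      data.frame(transcript = tx, pos = sort(pos),
                 stringsAsFactors = FALSE)
    })
    reps[[r]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    rownames(reps[[r]]) <- NULL
  }
  attr(reps, "fallbacks") <- fallbacks
  reps
}

#' Dense-cluster overrepresentation versus randomized controls
#'
#' Per cluster size: real count, control mean and sd across replicates,
#' and the empirical p-value (1 + #replicates >= real)/(R + 1). An
#' overall row ("total") uses the total number of DC-resident sites.
#'
#' @param siteTable the real sites.
#' @param controls list of control site data.frames
#'   (from \code{randomizeSites}).
#' @param maxSize sizes >= maxSize are pooled into one class.
#' @return data.frame: size, real, controlMean, controlSd, empiricalP.
#' @export
dcOverrepresentation <- function(siteTable, controls, maxSize = 8L) {
  countBySize <- function(s) {
    dc <- findDenseClusters(s)
    sz <- pmin(dc$size, maxSize)
    c(vapply(2:maxSize, function(k) sum(sz == k), 0L),
      total = sum(dc$size))
  }
  real <- countBySize(siteTable)
  ctrl <- vapply(controls, countBySize, real)
  R <- length(controls)
  data.frame(
    size = c(as.character(2:maxSize), "total"),
    real = as.integer(real),
    controlMean = rowMeans(ctrl),
    controlSd = apply(ctrl, 1L, sd),
    empiricalP = (1 + rowSums(ctrl >= real)) / (R + 1))
}

#' Editing-level comparisons between site categories
#'
#' All three pairwise comparisons between DC, clustered (non-DC) and
#' individual sites: fold change of mean EL, Mann-Whitney p, and the
#' heavy-edited (EL > 0.5) fractions with a chi-squared contingency p.
#' Comparisons involving a category with fewer than 2 sites are skipped
#' (NA row, \code{skipped = TRUE}).
#'
#' @param siteTable a \code{SiteTable} with ELs.
#' @param cutoff clustered/individual threshold passed to
#'   \code{categorizeSites}.
#' @param heavyEl heavy-editing threshold (0.5).
#' @return data.frame, one row per comparison.
#' @export
compareElByCategory <- function(siteTable, cutoff = 100L, heavyEl = 0.5) {
  st <- sites(siteTable)
  cats <- categorizeSites(st, cutoff = cutoff)
  st <- merge(st, cats, by = c("transcript", "pos"))
  st <- st[!is.na(st$el), , drop = FALSE]
  els <- split(st$el, st$category)
  cmp <- list(c("DC", "individual"), c("DC", "clustered"),
              c("clustered", "individual"))
  rows <- lapply(cmp, function(pr) {
    a <- els[[pr[1L]]]; b <- els[[pr[2L]]]
    if (is.null(a) || is.null(b) || length(a) < 2L || length(b) < 2L)
      return(data.frame(groupA = pr[1L], groupB = pr[2L], nA = length(a),
                        nB = length(b), fold = NA_real_, pMWU = NA_real_,
                        heavyA = NA_real_, heavyB = NA_real_,
                        heavyFold = NA_real_, pChisq = NA_real_,
                        skipped = TRUE))
    hA <- sum(a > heavyEl); hB <- sum(b > heavyEl)
    tab <- matrix(c(hA, length(a) - hA, hB, length(b) - hB), nrow = 2L)
    pChi <- if (all(tab >= 0) && sum(tab) > 0)
      suppressWarnings(chisq.test(tab)$p.value) else NA_real_
    data.frame(
      groupA = pr[1L], groupB = pr[2L], nA = length(a), nB = length(b),
      fold = mean(a) / mean(b),
      pMWU = suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value),
      heavyA = hA / length(a), heavyB = hB / length(b),
      heavyFold = (hA / length(a)) / (hB / length(b)),
      pChisq = pChi, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighbor editing probability q(E) versus its null q0(E)
#'
#' Scanning downstream from every edited site, each adenine at distance d
#' with no edited adenine in between contributes a trial at S* = d; the
#' first edited adenine contributes the success and stops the scan.
#' q(E)[d] is the edited fraction at distance d; q0(E) is the same
#' quantity pooled over randomized control site sets. Each distance is
#' tested by a chi-squared contingency test, Bonferroni-corrected over the
#' distance bins; the significant window is the largest prefix of
#' consecutive significant distances.
#'
#' @param siteTable real sites.
#' @param transcripts a \code{TranscriptSet}.
#' @param controls list of control site data.frames.
#' @param maxSstar largest distance scanned.
#' @param alpha family-wise level (0.01 in the standard analysis).
#' @return list: \code{table} (d, q, q0, counts, p, significant) and
#'   \code{window} (largest significant prefix; 0 when none).
#' @export
neighborEditingProbability <- function(siteTable, transcripts, controls,
                                       maxSstar = 50L, alpha = 0.01) {
  st <- if (is(siteTable, "SiteTable")) sites(siteTable) else siteTable
  tally <- function(s) {
    succ <- integer(maxSstar); fail <- integer(maxSstar)
    for (tx in unique(s$transcript)) {
      chars <- .seqChars(transcripts, tx)
      isA <- chars == "A"
      len <- length(chars)
      edited <- logical(len)
      edited[s$pos[s$transcript == tx] + 1L] <- TRUE
      for (p in s$pos[s$transcript == tx]) {
        dmax <- min(maxSstar, len - 1L - p)
        if (dmax < 1L) next
        for (d in seq_len(dmax)) {
          q <- p + d + 1L
          if (!isA[q]) next
          if (edited[q]) { succ[d] <- succ[d] + 1L; break }
          fail[d] <- fail[d] + 1L
        }
      }
    }
    list(succ = succ, fail = fail)
  }
  real <- tally(st)
  ctrl <- list(succ = integer(maxSstar), fail = integer(maxSstar))
  for (cc in controls) {
    t0 <- tally(cc)
    ctrl$succ <- ctrl$succ + t0$succ
    ctrl$fail <- ctrl$fail + t0$fail
  }
  m <- maxSstar
  p <- vapply(seq_len(maxSstar), function(d) {
    tab <- matrix(c(real$succ[d], real$fail[d],
                    ctrl$succ[d], ctrl$fail[d]), nrow = 2L, byrow = TRUE)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
      return(NA_real_)
    suppressWarnings(chisq.test(tab)$p.value)
  }, 0)
  sig <- !is.na(p) & p < alpha / m
  window <- if (!sig[1L]) 0L else max(which(cumsum(!sig) == 0L))
  list(table = data.frame(
         d = seq_len(maxSstar),
         q = real$succ / pmax(1L, real$succ + real$fail),
         q0 = ctrl$succ / pmax(1L, ctrl$succ + ctrl$fail),
         realEdited = real$succ, realUnedited = real$fail,
         controlEdited = ctrl$succ, controlUnedited = ctrl$fail,
         p = p, significant = sig),
       window = window)
}

#' Compare real and control S distributions (long-range clustering)
#'
#' Two-sample Kolmogorov-Smirnov test of the all-pairs distance
#' distributions, plus the sorted-quantile curve (real vs pooled-control
#' S values at matched quantiles). The divergence range is estimated in
#' the density domain: real per-bin counts are compared against the
#' min-max envelope of the control replicates, and the range is the
#' upper edge of the maximal contiguous prefix of bins whose real count
#' exceeds the envelope (0 when the first bin does not). Only the
#' short-range excess counts as cluster signal; the thin compensating
#' deficit at long range (site totals are preserved) does not.
#'
#' @param realS integer vector of real S values.
#' @param controlS list of control S vectors (one per replicate), or a
#'   single vector.
#' @param nQuantiles resolution of the sorted-quantile curve.
#' @param binWidth histogram bin width (nt) for the divergence range.
#' @return list: \code{ks} (htest), \code{curve} (data.frame quantile,
#'   control, real), \code{bins} (per-bin counts with envelope),
#'   \code{divergenceS}.
#' @export
compareSDistributions <- function(realS, controlS, nQuantiles = 200L,
                                  binWidth = 25L) {
  if (!is.list(controlS)) controlS <- list(controlS)
  pooled <- unlist(controlS)
  ks <- suppressWarnings(ks.test(realS, pooled))
  qs <- (seq_len(nQuantiles) - 0.5) / nQuantiles
  realQ <- as.numeric(quantile(realS, qs, type = 1L))
  ctrlQ <- as.numeric(quantile(pooled, qs, type = 1L))
  brks <- seq(0, max(realS, pooled) + binWidth, by = binWidth)
  cnt <- function(v) tabulate(findInterval(v, brks, left.open = TRUE),
                              nbins = length(brks) - 1L)
  realC <- cnt(realS)
  envC <- vapply(controlS, cnt, realC)
  envC <- matrix(envC, nrow = length(realC))
  lo <- apply(envC, 1L, min); hi <- apply(envC, 1L, max)
  outside <- realC > hi
  prefix <- if (outside[1L]) max(which(cumsum(!outside) == 0L)) else 0L
  divergenceS <- if (prefix > 0L) brks[prefix + 1L] else 0
  list(ks = ks,
       curve = data.frame(quantile = qs, control = ctrlQ, real = realQ),
       bins = data.frame(lower = head(brks, -1L), upper = brks[-1L],
                         real = realC, lo = lo, hi = hi,
                         outside = outside),
       divergenceS = divergenceS)
}
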