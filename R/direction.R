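# Directionality of editing within dense clusters and globally:
# EL asymmetry of paired (EE) sites, recoding asymmetry, structural
# control matching, base-pairing comparisons, and read-level inference of
# the temporal order of editing events.

#' Paired (EE) dense dinucleotide sites
#'
#' All dinucleotide pairs where both adenines are edited (S = 1).
#'
#' @param siteTable a \code{SiteTable}.
#' @return data.frame: transcript, up, down, elUp, elDown, frameUp,
#'   recodingUp, recodingDown.
#' @export
densePairs <- function(siteTable) {
  st <- sites(siteTable)
  out <- list()
  for (tx in unique(st$transcript)) {
    sub <- st[st$transcript == tx, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    hit <- which(diff(sub$pos) == 1L)
    if (!length(hit)) next
    out[[tx]] <- data.frame(
      transcript = tx, up = sub$pos[hit], down = sub$pos[hit + 1L],
      elUp = sub$el[hit], elDown = sub$el[hit + 1L],
      frameUp = sub$frame_offset[hit],
      recodingUp = sub$recoding[hit], recodingDown = sub$recoding[hit + 1L],
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript = character(), up = integer(), down = integer(),
               elUp = numeric(), elDown = numeric(), frameUp = integer(),
               recodingUp = character(), recodingDown = character())
  rownames(df) <- NULL
  df
}

#' EL asymmetry of paired editing sites
#'
#' Distribution of EL(downstream) - EL(upstream) over EE pairs, Wilcoxon
#' signed-rank test, and the per-frame breakdown (by the upstream site's
#' codon offset).
#'
#' @param eePairs output of \code{densePairs} (rows with defined ELs).
#' @return list: diffs, meanDiff, p (NA with < 2 pairs), perFrame.
#' @export
aaElDifference <- function(eePairs) {
  ee <- eePairs[!is.na(eePairs$elUp) & !is.na(eePairs$elDown), ,
                drop = FALSE]
  d <- ee$elDown - ee$elUp
  p <- if (length(d) >= 2L)
    suppressWarnings(wilcox.test(ee$elDown, ee$elUp, paired = TRUE,
                                 exact = FALSE)$p.value) else NA_real_
  perFrame <- if (nrow(ee)) {
    agg <- aggregate(d, list(frame = ee$frameUp), function(v)
      c(n = length(v), mean = mean(v)))
    data.frame(frame = agg$frame, n = agg$x[, "n"], mean = agg$x[, "mean"])
  } else data.frame()
  list(diffs = d, meanDiff = if (length(d)) mean(d) else NA_real_,
       p = p, perFrame = perFrame)
}

# positional recoding propensities of AA dinucleotides (background)
.aaBackgroundRecoding <- function(transcripts, siteTable, maxPerTx = Inf) {
  st <- sites(siteTable)
  up <- 0L; upRec <- 0L; dn <- 0L; dnRec <- 0L
  for (tx in names(sequencesOf(transcripts))) {
    chars <- .seqChars(transcripts, tx)
    aa <- which(chars[-length(chars)] == "A" &
                chars[-1L] == "A") - 1L      # 0-based upstream positions
    edited <- st$pos[st$transcript == tx]
    aa <- aa[!(aa %in% edited) & !((aa + 1L) %in% edited)]
    if (length(aa) > maxPerTx) aa <- aa[seq_len(maxPerTx)]
    if (!length(aa)) next
    ru <- .recodingVector(transcripts, tx, aa)$recoding
    rd <- .recodingVector(transcripts, tx, aa + 1L)$recoding
    ok <- ru != "noncoding" & rd != "noncoding"
    up <- up + sum(ok); dn <- dn + sum(ok)
    upRec <- upRec + sum(ok & ru == "nonsynonymous")
    dnRec <- dnRec + sum(ok & rd == "nonsynonymous")
  }
  c(pUp = if (up) upRec / up else NA_real_,
    pDown = if (dn) dnRec / dn else NA_real_)
}

#' Recoding asymmetry of EE pairs, background-normalized
#'
#' Among coding EE pairs where exactly one position is recoding, tests
#' whether the recoding one is the downstream site more often than
#' expected from the positional recoding propensities of non-edited AA
#' dinucleotides: null p0 = pd(1-pu) / (pd(1-pu) + pu(1-pd)), binomial
#' test.
#'
#' @param eePairs output of \code{densePairs}.
#' @param transcripts a \code{TranscriptSet}.
#' @param siteTable the full \code{SiteTable} (to exclude edited AA pairs
#'   from the background).
#' @return list: k (downstream-recoding discordant pairs), n, p0,
#'   p (binomial), background; p is NA when no coding discordant pair
#'   exists (test skipped).
#' @export
recodingAsymmetry <- function(eePairs, transcripts, siteTable) {
  ee <- eePairs[eePairs$recodingUp %in% c("synonymous", "nonsynonymous") &
                eePairs$recodingDown %in% c("synonymous", "nonsynonymous"), ,
                drop = FALSE]
  discordant <- ee[xor(ee$recodingUp == "nonsynonymous",
                       ee$recodingDown == "nonsynonymous"), , drop = FALSE]
  n <- nrow(discordant)
  k <- sum(discordant$recodingDown == "nonsynonymous")
  bg <- .aaBackgroundRecoding(transcripts, siteTable)
  p0 <- if (!anyNA(bg)) {
    bg[["pDown"]] * (1 - bg[["pUp"]]) /
      (bg[["pDown"]] * (1 - bg[["pUp"]]) + bg[["pUp"]] * (1 - bg[["pDown"]]))
  } else 0.5
  p <- if (n > 0L) binom.test(k, n, p = p0)$p.value else NA_real_
  list(k = k, n = n, p0 = p0, p = p, background = bg)
}

#' Match AA / AE / EA control dinucleotides to each EE pair
#'
#' For every EE pair, the nearest dinucleotide of each control class
#' within a +-window around the EE upstream position: AA (neither
#' edited), AE (downstream edited only), EA (upstream edited only). In
#' strict mode an EE pair is retained only when all three classes are
#' found.
#'
#' @param eePairs output of \code{densePairs}.
#' @param siteTable the full \code{SiteTable}.
#' @param transcripts a \code{TranscriptSet}.
#' @param window half-width of the search window (nt; 20 in the standard
#'   analysis).
#' @param strict require all three control classes.
#' @return data.frame, one row per retained EE pair, with \code{aaUp},
#'   \code{aeUp}, \code{eaUp} upstream positions of the matched controls
#'   (NA when missing in non-strict mode).
#' @export
matchStructuralControls <- function(eePairs, siteTable, transcripts,
                                    window = 20L, strict = TRUE) {
  st <- sites(siteTable)
  rows <- list()
  for (tx in unique(eePairs$transcript)) {
    chars <- .seqChars(transcripts, tx)
    edited <- st$pos[st$transcript == tx]
    aaUpAll <- which(chars[-length(chars)] == "A" & chars[-1L] == "A") - 1L
    ee <- eePairs[eePairs$transcript == tx, , drop = FALSE]
    for (r in seq_len(nrow(ee))) {
      u <- ee$up[r]
      cand <- aaUpAll[abs(aaUpAll - u) <= window & aaUpAll != u]
      if (!length(cand)) { if (!strict) rows[[length(rows) + 1L]] <-
        cbind(ee[r, ], aaUp = NA, aeUp = NA, eaUp = NA); next }
      upEd <- cand %in% edited
      dnEd <- (cand + 1L) %in% edited
      pick <- function(mask) {
        h <- cand[mask]
        if (!length(h)) NA_integer_ else h[which.min(abs(h - u))]
      }
      aa <- pick(!upEd & !dnEd)
      ae <- pick(!upEd & dnEd)
      ea <- pick(upEd & !dnEd)
      if (strict && (is.na(aa) || is.na(ae) || is.na(ea))) next
      rows[[length(rows) + 1L]] <-
        cbind(ee[r, , drop = FALSE], aaUp = aa, aeUp = ae, eaUp = ea)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    cbind(eePairs[0, , drop = FALSE], aaUp = integer(), aeUp = integer(),
          eaUp = integer())
  rownames(df) <- NULL
  df
}

#' Base-pairing comparisons between EE sites and their control trios
#'
#' Paired Wilcoxon tests between the EE pair and each control class, for
#' the up- and downstream position separately, plus the up-vs-down
#' comparison within EE; Bonferroni over the performed comparisons.
#' Negative \code{direction} means the EE position is the less paired
#' one.
#'
#' @param trios output of \code{matchStructuralControls} (strict mode).
#' @param profiles a \code{PairingProfile}.
#' @return data.frame: comparison, n, direction (sign of the median
#'   difference EE - control), p, significant.
#' @export
compareBppPositions <- function(trios, profiles) {
  pp <- pairingProb(profiles)
  val <- function(txs, pos) {
    vapply(seq_along(txs), function(k) {
      v <- pp[[txs[k]]]
      if (is.null(v) || is.na(pos[k])) NA_real_ else v[pos[k] + 1L]
    }, 0)
  }
  eeU <- val(trios$transcript, trios$up)
  eeD <- val(trios$transcript, trios$down)
  sets <- list(
    EEup_vs_EEdown = cbind(eeU, eeD),
    EEup_vs_AAup = cbind(eeU, val(trios$transcript, trios$aaUp)),
    EEdown_vs_AAdown = cbind(eeD, val(trios$transcript, trios$aaUp + 1L)),
    EEup_vs_AEup = cbind(eeU, val(trios$transcript, trios$aeUp)),
    EEdown_vs_AEdown = cbind(eeD, val(trios$transcript, trios$aeUp + 1L)),
    EEup_vs_EAup = cbind(eeU, val(trios$transcript, trios$eaUp)),
    EEdown_vs_EAdown = cbind(eeD, val(trios$transcript, trios$eaUp + 1L)))
  m <- length(sets)
  rows <- lapply(names(sets), function(nm) {
    xy <- sets[[nm]]
    ok <- stats::complete.cases(xy)
    x <- xy[ok, 1L]; y <- xy[ok, 2L]
    if (length(x) < 2L)
      return(data.frame(comparison = nm, n = length(x),
                        direction = NA_real_, p = NA_real_,
                        significant = NA))
    p <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                      exact = FALSE)$p.value)
    data.frame(comparison = nm, n = length(x),
               direction = sign(median(x - y)), p = p,
               significant = !is.na(p) && p < 0.05 / m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer the temporal order of editing from read intermediate states
#'
#' For an ordered pair (up, down), over co-covering reads in which
#' exactly one of the two sites is edited,
#' d = (n[A_up I_down] - n[I_up A_down]) / (n[A_up I_down] + n[I_up A_down]);
#' d > 0 means the downstream site tends to be edited first. Pairs with
#' no single-edited read are excluded. The aggregate one-sample Wilcoxon
#' versus 0 is reported separately for S = 1 and S > 1.
#'
#' @param reads a \code{ReadMatrix}.
#' @param siteTable a \code{SiteTable}.
#' @param maxS largest pair distance (bounded by the read length).
#' @param minPairReads minimum informative reads per pair.
#' @return list: \code{pairs} (per-pair d with tallies), \code{S1} and
#'   \code{SgT1}, each with n, median d, Wilcoxon p.
#' @export
inferEditingOrder <- function(reads, siteTable, maxS = 100L,
                              minPairReads = 10L) {
  st <- sites(siteTable)
  prs <- .sitePairs(st, maxS)
  rows <- list()
  for (k in seq_len(nrow(prs))) {
    pc <- countPairStates(reads, prs$transcript[k], prs$i[k], prs$j[k],
                          minPairReads = minPairReads)
    if (!pc@informative) next
    nAI <- pc@nAI; nIA <- pc@nIA
    if (nAI + nIA == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript = prs$transcript[k], up = prs$i[k], down = prs$j[k],
      S = prs$S[k], nAI = nAI, nIA = nIA,
      d = (nAI - nIA) / (nAI + nIA), stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(), up = integer(), down = integer(),
               S = integer(), nAI = integer(), nIA = integer(),
               d = numeric())
  rownames(pairs) <- NULL
  summarize <- function(d) {
    if (length(d) < 2L)
      return(list(n = length(d),
                  median = if (length(d)) median(d) else NA_real_,
                  p = NA_real_))
    list(n = length(d), median = median(d),
         p = suppressWarnings(wilcox.test(d, mu = 0,
                                          exact = FALSE)$p.value))
  }
  list(pairs = pairs,
       S1 = summarize(pairs$d[pairs$S == 1L]),
       SgT1 = summarize(pairs$d[pairs$S > 1L]))
}
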