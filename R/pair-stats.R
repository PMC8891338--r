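# Read-level pairwise editing statistics: the correlation r (phi
# coefficient of the 2x2 co-occurrence table), the cooperativity ratio
# r' = f_II / (f_i^I f_j^I), and distance-resolved profiles.

#' Tally joint editing states for a site pair
#'
#' Counts reads covering both positions with informative A/I calls at
#' both; any read carrying a non-A/G call at either position is excluded
#' (the statistics are defined over A and I only).
#'
#' @param reads a \code{ReadMatrix}.
#' @param transcript transcript id.
#' @param i,j 0-based site positions, \code{i < j}.
#' @param minPairReads pairs with fewer informative reads are flagged
#'   uninformative (default 10).
#' @return a \code{PairCounts}.
#' @export
countPairStates <- function(reads, transcript, i, j, minPairReads = 10L) {
  stopifnot(i < j)
  cl <- readCalls(reads)
  cl <- cl[cl$transcript == transcript & (cl$pos == i | cl$pos == j), ,
           drop = FALSE]
  ci <- cl[cl$pos == i, c("read_id", "state")]
  cj <- cl[cl$pos == j, c("read_id", "state")]
  m <- merge(ci, cj, by = "read_id", suffixes = c("_i", "_j"))
  m <- m[m$state_i %in% c("A", "I") & m$state_j %in% c("A", "I"), ,
         drop = FALSE]
  n <- c(nAA = sum(m$state_i == "A" & m$state_j == "A"),
         nAI = sum(m$state_i == "A" & m$state_j == "I"),
         nIA = sum(m$state_i == "I" & m$state_j == "A"),
         nII = sum(m$state_i == "I" & m$state_j == "I"))
  new("PairCounts", transcript = as.character(transcript),
      i = as.integer(i), j = as.integer(j), S = as.integer(j - i),
      nAA = as.integer(n[1]), nAI = as.integer(n[2]),
      nIA = as.integer(n[3]), nII = as.integer(n[4]),
      informative = sum(n) >= minPairReads)
}

# internal: PairCounts from four tallies (used by tests and enumeration)
.pairCountsFromTallies <- function(nAA, nAI, nIA, nII, i = 0L, j = 1L,
                                   transcript = "tx",
                                   minPairReads = 1L) {
  new("PairCounts", transcript = transcript, i = as.integer(i),
      j = as.integer(j), S = as.integer(j - i), nAA = as.integer(nAA),
      nAI = as.integer(nAI), nIA = as.integer(nIA), nII = as.integer(nII),
      informative = (nAA + nAI + nIA + nII) >= minPairReads)
}

#' Co-editing correlation r (phi coefficient)
#'
#' r = (f_AA f_II - f_AI f_IA) / sqrt(f_i^A f_i^I f_j^A f_j^I), the
#' Pearson correlation of the two binary per-read editing-state vectors.
#' Undefined (NA) when any marginal frequency is zero.
#'
#' @param c a \code{PairCounts}.
#' @return numeric in [-1, 1], or NA.
#' @export
editingCorrelation <- function(c) {
  f <- pairFrequencies(c)
  if (anyNA(f)) return(NA_real_)
  fiA <- f["fAA"] + f["fAI"]; fiI <- f["fIA"] + f["fII"]
  fjA <- f["fAA"] + f["fIA"]; fjI <- f["fAI"] + f["fII"]
  den <- fiA * fiI * fjA * fjI
  if (den == 0) return(NA_real_)
  unname((f["fAA"] * f["fII"] - f["fAI"] * f["fIA"]) / sqrt(den))
}

#' Cooperativity ratio r'
#'
#' r' = f_II / (f_i^I f_j^I): the observed co-editing frequency over its
#' expectation under independence; 1 under independence, 0 under mutual
#' exclusion. Undefined (NA) when either site is never edited among the
#' tallied reads.
#'
#' @param c a \code{PairCounts}.
#' @return non-negative numeric, or NA.
#' @export
cooperativityRatio <- function(c) {
  f <- pairFrequencies(c)
  if (anyNA(f)) return(NA_real_)
  fiI <- f["fIA"] + f["fII"]; fjI <- f["fAI"] + f["fII"]
  if (fiI == 0 || fjI == 0) return(NA_real_)
  unname(f["fII"] / (fiI * fjI))
}

# all same-transcript site pairs within maxS, as a data.frame
.sitePairs <- function(sitesDf, maxS) {
  out <- list()
  for (tx in unique(sitesDf$transcript)) {
    p <- sort(sitesDf$pos[sitesDf$transcript == tx])
    if (length(p) < 2L) next
    prs <- list()
    for (a in seq_len(length(p) - 1L)) {
      b <- which(p > p[a] & p <= p[a] + maxS)
      if (length(b))
        prs[[a]] <- data.frame(transcript = tx, i = p[a], j = p[b])
    }
    if (length(prs)) out[[tx]] <- do.call(rbind, prs)
  }
  if (!length(out))
    return(data.frame(transcript = character(), i = integer(),
                      j = integer(), S = integer()))
  df <- do.call(rbind, out)
  df$S <- df$j - df$i
  rownames(df) <- NULL
  df
}

#' Per-pair r / r' table and per-distance summary of read-level correlation
#'
#' Computes \code{PairCounts} for every same-transcript site pair with
#' S <= maxS (both sites passing the EL filter), the correlation r and
#' cooperativity r' per informative pair, and a per-S distribution summary
#' (n, mean, quartiles, normal-approximation 95\% CI of the mean).
#'
#' @param reads a \code{ReadMatrix}.
#' @param siteTable a \code{SiteTable}.
#' @param maxS largest distance considered (should not exceed the read
#'   length; larger S has no co-covering reads).
#' @param elMin EL filter applied to both sites of a pair (0, 0.05, 0.10
#'   in the standard analyses).
#' @param minPairReads minimum informative reads per pair.
#' @return list: \code{pairs} (per-pair table with tallies, r, r'),
#'   \code{summary} (per-S data.frame).
#' @export
correlationProfileByDistance <- function(reads, siteTable, maxS = 100L,
                                         elMin = 0, minPairReads = 10L) {
  st <- sites(siteTable)
  st <- st[!is.na(st$el) & st$el >= elMin, , drop = FALSE]
  prs <- .sitePairs(st, maxS)
  if (nrow(prs) == 0L)
    return(list(pairs = prs, summary = data.frame()))
  res <- vector("list", nrow(prs))
  for (k in seq_len(nrow(prs))) {
    pc <- countPairStates(reads, prs$transcript[k], prs$i[k], prs$j[k],
                          minPairReads = minPairReads)
    n <- pairTallies(pc)
    res[[k]] <- data.frame(
      transcript = prs$transcript[k], i = prs$i[k], j = prs$j[k],
      S = prs$S[k], nAA = n[1], nAI = n[2], nIA = n[3], nII = n[4],
      total = sum(n), informative = pc@informative,
      r = if (pc@informative) editingCorrelation(pc) else NA_real_,
      rprime = if (pc@informative) cooperativityRatio(pc) else NA_real_,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, res)
  rownames(pairs) <- NULL
  ok <- pairs$informative & !is.na(pairs$r)
  summ <- do.call(rbind, lapply(split(pairs$r[ok], pairs$S[ok]), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75))
    se <- if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
    data.frame(n = length(v), mean = mean(v), q25 = q[1], median = q[2],
               q75 = q[3], ciLo = mean(v) - 1.96 * se,
               ciHi = mean(v) + 1.96 * se)
  }))
  if (!is.null(summ)) {
    summ$S <- as.integer(rownames(summ))
    summ <- summ[order(summ$S), c("S", "n", "mean", "q25", "median",
                                  "q75", "ciLo", "ciHi")]
    rownames(summ) <- NULL
  } else summ <- data.frame()
  list(pairs = pairs, summary = summ)
}

#' Correlation of editing levels across site pairs, by distance
#'
#' For each distance S in \code{sGrid}, Pearson correlation of the EL pairs
#' over all same-transcript site pairs at exactly that distance, with
#' Bonferroni-corrected confidence intervals (Fisher-z interval at the
#' adjusted quantile) and the p-value of the t statistic
#' r sqrt((n-2)/(1-r^2)).
#'
#' @param siteTable a \code{SiteTable} with ELs.
#' @param sGrid integer distances to evaluate.
#' @param alpha family-wise level; the Bonferroni family is
#'   \code{length(sGrid)}.
#' @return data.frame: S, n, r, ciLo, ciHi, p, significant.
#' @export
elCorrelationByDistance <- function(siteTable, sGrid = 1:100,
                                    alpha = 0.05) {
  st <- sites(siteTable)
  st <- st[!is.na(st$el), , drop = FALSE]
  prs <- .sitePairs(st, max(sGrid))
  key <- paste(st$transcript, st$pos)
  elOf <- setNames(st$el, key)
  m <- length(sGrid)
  rows <- lapply(sGrid, function(S) {
    sub <- prs[prs$S == S, , drop = FALSE]
    n <- nrow(sub)
    if (n < 4L)
      return(data.frame(S = S, n = n, r = NA_real_, ciLo = NA_real_,
                        ciHi = NA_real_, p = NA_real_, significant = NA))
    x <- elOf[paste(sub$transcript, sub$i)]
    y <- elOf[paste(sub$transcript, sub$j)]
    r <- suppressWarnings(cor(x, y))
    if (is.na(r) || abs(r) >= 1) r <- ifelse(is.na(r), NA_real_, sign(r) * 0.999999)
    z <- atanh(r); zc <- qnorm(1 - alpha / (2 * m))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    data.frame(S = S, n = n, r = r,
               ciLo = tanh(z - zc / sqrt(n - 3)),
               ciHi = tanh(z + zc / sqrt(n - 3)),
               p = p, significant = p < alpha / m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group contiguous distance ranges with indistinguishable correlations
#'
#' Greedy left-to-right grouping: a new group starts when the next range's
#' correlation array differs from the pooled current group by a
#' Mann-Whitney test at the Bonferroni-corrected level.
#'
#' @param rArrays named list of numeric vectors (r values), ordered by S
#'   range.
#' @param alpha family-wise level; the family size is the number of
#'   adjacent comparisons.
#' @return integer vector of group labels, one per input array.
#' @export
groupDistanceRanges <- function(rArrays, alpha = 0.05) {
  K <- length(rArrays)
  if (K == 0L) return(integer())
  labels <- integer(K); labels[1L] <- 1L
  if (K == 1L) return(labels)
  m <- K - 1L
  cur <- rArrays[[1L]]
  g <- 1L
  for (k in 2L:K) {
    p <- suppressWarnings(
      wilcox.test(cur, rArrays[[k]], exact = FALSE)$p.value)
    if (!is.na(p) && p < alpha / m) {
      g <- g + 1L
      cur <- rArrays[[k]]
    } else {
      cur <- c(cur, rArrays[[k]])
    }
    labels[k] <- g
  }
  labels
}
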