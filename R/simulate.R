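# Synthetic-data generator: transcripts, three-scale clustered editing
# sites, correlated/directional reads, and pairing-probability profiles
# with known ground truth.
#
# Site placement is a nested Neyman-Scott process: Poisson long-range
# parents (rate lambdaL per kb) spawn medium clusters spread with sd
# sigmaL; each medium cluster is a chain of sites whose inter-site gaps
# are uniform on {1..interactionRadius} nt (snapped to adenines); each
# placed site may seed a geometric run of consecutive edited adenines
# (dense clusters). Read-level co-editing follows a Gaussian copula over
# the within-cluster site chain, thresholded at each site's EL.

#' Build a validated simulation configuration
#'
#' All randomness in the generator flows from \code{seed}; the same
#' configuration reproduces its output exactly.
#'
#' @param seed mandatory integer seed.
#' @param nTranscripts number of transcripts.
#' @param lengthMean,lengthSd lognormal transcript-length model (mean in nt,
#'   sdlog); lengths are clamped to \code{minLength}.
#' @param minLength shortest transcript allowed.
#' @param baseFreq named A/C/G/T composition (adenine-rich by default, as in
#'   coleoid coding sequence).
#' @param lambdaL long-range parent rate per kb; 0 places medium-cluster
#'   centers uniformly at \code{mediumRatePerKb} instead (the null layout).
#' @param sigmaL spread (nt, sd) of medium clusters around a parent.
#' @param clustersPerParent mean medium clusters per parent (min 1).
#' @param mediumRatePerKb rate of uniform medium-cluster centers when
#'   \code{lambdaL == 0}.
#' @param offspringMean mean sites per medium cluster (min 1).
#' @param interactionRadius maximum chain gap between neighboring sites in
#'   a medium cluster (nt); this is the generator's editing-interaction
#'   window.
#' @param pDense probability of extending a site into the next consecutive
#'   adenine (geometric dense-run extension).
#' @param elShape1,elShape2 Beta parameters of the per-site editing level.
#' @param elFixed when non-NULL, every site gets this EL instead.
#' @param dcElShift additive EL shift applied to sites in dense runs.
#' @param rTarget target phi coefficient between chain-adjacent sites at
#'   S = 1 (calibrated mode) or the latent correlation itself (latent mode).
#' @param decayScale exponential decay scale (nt) of the pairwise target
#'   with distance: target(S) = rTarget * exp(-(S-1)/decayScale).
#' @param couplingMode \code{"calibrated"} inverts the copula so the
#'   realized phi matches the target regardless of ELs; \code{"latent"}
#'   fixes the latent correlation, so realized phi is attenuated for
#'   extreme ELs (high-EL pairs correlate more strongly).
#' @param delta downstream-first bias: in reads where exactly one site of a
#'   biased pair is edited, the edited one is the downstream site with
#'   probability 0.5 + delta.
#' @param readLength,meanDepth read simulation parameters.
#' @param noiseBand background pairing-probability band (lo, hi).
#' @param bumpWidth nominal above-band width (nt) of the structure bump
#'   centered at each site.
#' @param bumpHeight bump height above the band midpoint.
#' @param dipDepth pairing-probability dip at the site position itself.
#' @param minCoverage minimum informative reads for EL in the observed
#'   site table.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed,
                      nTranscripts = 40L, lengthMean = 2000, lengthSd = 0.25,
                      minLength = 300L,
                      baseFreq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                      lambdaL = 0.8, sigmaL = 150, clustersPerParent = 2,
                      mediumRatePerKb = 1.5, offspringMean = 4,
                      interactionRadius = 18L, pDense = 0.15,
                      elShape1 = 0.8, elShape2 = 5, elFixed = NULL,
                      dcElShift = 0,
                      rTarget = 0.4, decayScale = 30,
                      couplingMode = c("calibrated", "latent"),
                      delta = 0,
                      readLength = 100L, meanDepth = 50,
                      noiseBand = c(0.25, 0.35), bumpWidth = 36,
                      bumpHeight = 0.2, dipDepth = 0.25,
                      minCoverage = 10L) {
  if (missing(seed)) stop("seed is mandatory")
  couplingMode <- match.arg(couplingMode)
  if (delta < 0 || delta > 0.5) stop("delta must lie in [0, 0.5]")
  .stopifnotProb(c(pDense, baseFreq, noiseBand), "probabilities")
  if (abs(sum(baseFreq) - 1) > 1e-6) stop("baseFreq must sum to 1")
  if (bumpWidth <= 0) stop("bumpWidth must be positive")
  if (noiseBand[2] <= noiseBand[1]) stop("noiseBand must be (lo, hi)")
  if (delta < 0 || delta > 0.5) stop("delta must lie in [0, 0.5]")
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a full synthetic dataset with ground truth
#'
#' @param config a \code{SimConfig}.
#' @return list with elements \code{transcripts} (\code{TranscriptSet} with
#'   full-length CDS), \code{siteTable} (observed coverage/G-counts from the
#'   simulated reads), \code{reads} (\code{ReadMatrix}), \code{profiles}
#'   (\code{PairingProfile}) and \code{truth} (site placement table with
#'   cluster memberships and true ELs, the biased pair table, and the
#'   config).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  transcripts <- .simulateTranscripts(config)
  truthSites <- simulateSites(transcripts, config)
  reads <- simulateReads(transcripts, truthSites, config)
  profiles <- simulateStructureProfiles(transcripts, truthSites$sites,
                                        config)
  observed <- sitePileup(reads, transcripts = transcripts,
                         minCoverage = config$minCoverage)
  list(transcripts = transcripts, siteTable = observed, reads = reads,
       profiles = profiles,
       truth = c(truthSites, list(config = config)))
}

.simulateTranscripts <- function(config) {
  lens <- pmax(config$minLength,
               round(stats::rlnorm(config$nTranscripts,
                                   log(config$lengthMean), config$lengthSd)))
  seqs <- vapply(lens, function(n)
    paste(sample(names(config$baseFreq), n, replace = TRUE,
                 prob = config$baseFreq), collapse = ""), "")
  names(seqs) <- sprintf("tx%03d", seq_along(seqs))
  cds <- lapply(lens, function(n)
    matrix(c(0L, (n %/% 3L) * 3L), ncol = 2L,
           dimnames = list(NULL, c("start", "end"))))
  names(cds) <- names(seqs)
  TranscriptSet(seqs, cds = cds)
}

#' Place editing sites by the three-scale cluster process
#'
#' @param transcripts a \code{TranscriptSet}.
#' @param config a \code{SimConfig}.
#' @return list: \code{sites} — data.frame(transcript, pos, el, parent,
#'   medium, dense) where \code{dense} flags sites added by dense-run
#'   extension; \code{pairs} — the disjoint consecutive within-cluster site
#'   pairs that carry the directional bias (transcript, up, down).
#' @export
simulateSites <- function(transcripts, config) {
  R <- config$interactionRadius
  allSites <- list(); allPairs <- list()
  mediumId <- 0L
  for (tx in names(sequencesOf(transcripts))) {
    len <- length(sequencesOf(transcripts)[[tx]])
    aPos <- .adeninePositions(transcripts, tx)
    if (!length(aPos)) next
    # medium-cluster centers
    centers <- numeric(); parents <- integer()
    if (config$lambdaL > 0) {
      nPar <- rpois(1L, config$lambdaL * len / 1000)
      if (nPar > 0L) for (p in seq_len(nPar)) {
        nMed <- 1L + rpois(1L, max(0, config$clustersPerParent - 1))
        centers <- c(centers, runif(1L, 0, len) +
                       rnorm(nMed, 0, config$sigmaL))
        parents <- c(parents, rep(p, nMed))
      }
    } else {
      nMed <- rpois(1L, config$mediumRatePerKb * len / 1000)
      centers <- runif(nMed, 0, len)
      parents <- seq_len(nMed)   # each its own parent
    }
    keep <- centers >= 0 & centers < len
    centers <- centers[keep]; parents <- parents[keep]
    txPos <- integer(); txMed <- integer(); txPar <- integer()
    txDense <- logical()
    for (ci in seq_along(centers)) {
      mediumId <- mediumId + 1L
      m <- 1L + rpois(1L, max(0, config$offspringMean - 1))
      # chain with gaps uniform on {1..R}, snapped to the next adenine
      idx <- findInterval(centers[ci], aPos + 0.5) + 1L
      if (idx > length(aPos)) next
      cur <- aPos[idx]
      chain <- cur
      while (length(chain) < m) {
        target <- cur + sample.int(R, 1L)
        pool <- aPos[aPos > cur]
        if (!length(pool)) break
        nxt <- pool[which.min(abs(pool - target))]
        if (nxt - cur > 2L * R) break   # adenine desert: stop the chain
        chain <- c(chain, nxt)
        cur <- nxt
      }
      newMask <- !(chain %in% txPos)
      chain <- chain[newMask]
      txPos <- c(txPos, chain)
      txMed <- c(txMed, rep(mediumId, length(chain)))
      txPar <- c(txPar, rep(parents[ci], length(chain)))
      txDense <- c(txDense, rep(FALSE, length(chain)))
      # directional-bias pairs: greedy disjoint consecutive chain pairs
      if (length(chain) >= 2L) {
        ups <- chain[seq(1L, length(chain) - 1L, by = 2L)]
        downs <- chain[seq(2L, length(chain), by = 2L)]
        allPairs[[length(allPairs) + 1L]] <-
          data.frame(transcript = tx, up = ups, down = downs)
      }
      # dense-run extension (geometric)
      aSet <- c(rep(FALSE, len)); aSet[aPos + 1L] <- TRUE
      for (s in chain) {
        cur2 <- s
        while (runif(1L) < config$pDense && cur2 + 1L < len &&
               aSet[cur2 + 2L] && !((cur2 + 1L) %in% txPos)) {
          cur2 <- cur2 + 1L
          txPos <- c(txPos, cur2)
          txMed <- c(txMed, mediumId)
          txPar <- c(txPar, parents[ci])
          txDense <- c(txDense, TRUE)
        }
      }
    }
    if (!length(txPos)) next
    o <- order(txPos)
    allSites[[tx]] <- data.frame(
      transcript = tx, pos = txPos[o], parent = txPar[o],
      medium = txMed[o], dense = txDense[o], stringsAsFactors = FALSE)
  }
  sitesDf <- if (length(allSites)) do.call(rbind, allSites) else
    data.frame(transcript = character(), pos = integer(),
               parent = integer(), medium = integer(), dense = logical())
  rownames(sitesDf) <- NULL
  n <- nrow(sitesDf)
  sitesDf$el <- if (!is.null(config$elFixed)) rep(config$elFixed, n) else
    rbeta(n, config$elShape1, config$elShape2)
  sitesDf$el <- pmin(pmax(sitesDf$el, 0.005), 0.995)
  if (config$dcElShift != 0 && n > 0L) {
    inRun <- .inDenseRun(sitesDf)
    sitesDf$el[inRun] <- pmin(sitesDf$el[inRun] + config$dcElShift, 0.95)
  }
  pairsDf <- if (length(allPairs)) do.call(rbind, allPairs) else
    data.frame(transcript = character(), up = integer(), down = integer())
  rownames(pairsDf) <- NULL
  list(sites = sitesDf, pairs = pairsDf)
}

# sites that belong to a run of >= 2 consecutive edited positions
.inDenseRun <- function(sitesDf) {
  out <- logical(nrow(sitesDf))
  for (tx in unique(sitesDf$transcript)) {
    rows <- which(sitesDf$transcript == tx)
    p <- sitesDf$pos[rows]
    adj <- (p + 1L) %in% p | (p - 1L) %in% p
    out[rows] <- adj
  }
  out
}

#' Simulate reads with copula-correlated, optionally directional editing
#'
#' Per read, latent Gaussian states follow a Markov chain along the
#' transcript's sites (step correlation from the calibrated copula within
#' a medium cluster, zero across clusters) and are thresholded at each
#' site's EL. When \code{delta > 0}, the orientation of single-edited
#' reads at the biased pairs is redrawn so the downstream site carries the
#' edit with probability 0.5 + delta.
#'
#' @param transcripts a \code{TranscriptSet}.
#' @param truthSites the list returned by \code{simulateSites}.
#' @param config a \code{SimConfig}.
#' @return a \code{ReadMatrix}.
#' @export
simulateReads <- function(transcripts, truthSites, config) {
  sitesDf <- truthSites$sites; pairsDf <- truthSites$pairs
  calib <- .makeLatentCache()
  readsL <- list(); callsL <- list()
  for (tx in names(sequencesOf(transcripts))) {
    len <- length(sequencesOf(transcripts)[[tx]])
    rl <- min(config$readLength, len)
    nReads <- max(1L, round(config$meanDepth * len / rl))
    starts <- if (len == rl) rep(0L, nReads) else
      sample.int(len - rl + 1L, nReads, replace = TRUE) - 1L
    ends <- starts + rl
    ids <- sprintf("%s_r%05d", tx, seq_len(nReads))
    readsL[[tx]] <- data.frame(read_id = ids, transcript = tx,
                               start = starts, end = ends,
                               stringsAsFactors = FALSE)
    sd0 <- sitesDf[sitesDf$transcript == tx, , drop = FALSE]
    if (nrow(sd0) == 0L) next
    nS <- nrow(sd0)
    thr <- qnorm(sd0$el)
    x <- matrix(rnorm(nReads * nS), nReads, nS)
    if (nS > 1L) for (k in 2L:nS) {
      if (sd0$medium[k] != sd0$medium[k - 1L]) next
      d <- sd0$pos[k] - sd0$pos[k - 1L]
      tgt <- config$rTarget * exp(-(d - 1) / config$decayScale)
      rho <- if (config$couplingMode == "latent") min(tgt, 0.999) else
        calib(tgt, sd0$el[k - 1L], sd0$el[k])
      x[, k] <- rho * x[, k - 1L] + sqrt(1 - rho^2) * x[, k]
    }
    edited <- sweep(x, 2L, thr, `<`)
    if (config$delta > 0) {
      pd <- pairsDf[pairsDf$transcript == tx, , drop = FALSE]
      for (q in seq_len(nrow(pd))) {
        a <- match(pd$up[q], sd0$pos); b <- match(pd$down[q], sd0$pos)
        sel <- which(edited[, a] != edited[, b])
        if (!length(sel)) next
        downEd <- runif(length(sel)) < 0.5 + config$delta
        edited[sel, b] <- downEd
        edited[sel, a] <- !downEd
      }
    }
    for (k in seq_len(nS)) {
      p <- sd0$pos[k]
      cov <- which(starts <= p & ends > p)
      if (!length(cov)) next
      callsL[[paste(tx, k)]] <- data.frame(
        read_id = ids[cov], transcript = tx, pos = p,
        state = ifelse(edited[cov, k], "I", "A"),
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, readsL)
  calls <- if (length(callsL)) do.call(rbind, callsL) else
    data.frame(read_id = character(), transcript = character(),
               pos = integer(), state = character())
  rownames(reads) <- rownames(calls) <- NULL
  ReadMatrix(reads, calls)
}

#' Simulate pairing-probability profiles around editing sites
#'
#' Background values are iid uniform inside the noise band; a Gaussian
#' bump is added at every site, scaled so the nominal width of the
#' above-band region equals \code{bumpWidth}; the site position itself is
#' depressed by \code{dipDepth} (edited adenines sit in loops/bulges).
#'
#' @param transcripts a \code{TranscriptSet}.
#' @param sitesDf the truth site data.frame (or \code{sites()} of a
#'   \code{SiteTable}).
#' @param config a \code{SimConfig}.
#' @return a \code{PairingProfile}.
#' @export
simulateStructureProfiles <- function(transcripts, sitesDf, config) {
  band <- config$noiseBand
  halfBand <- (band[2] - band[1]) / 2
  h <- config$bumpHeight
  sdv <- if (h > halfBand * 1.0001)
    config$bumpWidth / (2 * sqrt(2 * log(h / halfBand))) else
    config$bumpWidth / 4
  reach <- ceiling(3 * sdv)
  pairing <- list()
  for (tx in names(sequencesOf(transcripts))) {
    len <- length(sequencesOf(transcripts)[[tx]])
    v <- runif(len, band[1], band[2])
    p <- sitesDf$pos[sitesDf$transcript == tx]
    for (s in p) {
      lo <- max(0L, s - reach); hi <- min(len - 1L, s + reach)
      o <- lo:hi
      v[o + 1L] <- v[o + 1L] + h * exp(-((o - s)^2) / (2 * sdv^2))
    }
    if (length(p)) v[p + 1L] <- v[p + 1L] - config$dipDepth
    pairing[[tx]] <- pmin(pmax(v, 0), 0.99)
  }
  PairingProfile(pairing)
}
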