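mkSiteDf <- function(pos, tx = "tx1")
  data.frame(transcript = tx, pos = as.integer(pos))

test_that("dense clusters are maximal runs of consecutive edited adenines", {
  dc <- findDenseClusters(mkSiteDf(c(10, 11, 12, 50)))
  expect_equal(nrow(dc), 1L)
  expect_equal(dc$start, 10L); expect_equal(dc$end, 12L)
  expect_equal(dc$size, 3L)
  expect_equal(nrow(findDenseClusters(mkSiteDf(c(7, 9)))), 0L)
  # random toys against the brute-force scan
  set.seed(17)
  for (rep in 1:20) {
    pos <- sort(sample(0:60, 20))
    got <- findDenseClusters(mkSiteDf(pos))
    want <- denseOracle(pos)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      w <- do.call(rbind, want)
      expect_equal(got$start, unname(w[, "start"]))
      expect_equal(got$size, unname(w[, "size"]))
    }
  }
})

test_that("S and S* distance tables match hand enumeration and brute force", {
  cs <- computeDistances(mkSiteDf(c(5, 6, 20)))
  expect_equal(sort(sDistances(cs)$S), c(1L, 14L, 15L))
  expect_equal(sort(sStarDistances(cs)$S), c(1L, 14L))
  expect_equal(nrow(sDistances(computeDistances(mkSiteDf(42)))), 0L)
  set.seed(23)
  for (rep in 1:15) {
    pos <- sort(sample(0:2000, sample(5:50, 1)))
    maxS <- sample(c(100, 500, 2000), 1)
    cs <- computeDistances(mkSiteDf(pos), maxS = maxS)
    want <- distanceOracle(pos, maxS)
    expect_equal(sort(sDistances(cs)$S), want$S)
    expect_equal(sort(sStarDistances(cs)$S), want$Sstar)
  }
})

test_that("site categories partition the site set", {
  pos <- c(0, 1, 2, 50, 120, 400, 401, 700)
  cats <- categorizeSites(mkSiteDf(pos))
  expect_setequal(cats$pos, pos)
  expect_equal(nrow(cats), length(pos))
  expect_equal(unname(cats$category[match(c(0, 1, 2), cats$pos)]),
               rep("DC", 3))
  expect_equal(cats$category[cats$pos == 50], "clustered")
  expect_equal(cats$category[cats$pos == 120], "clustered")  # 70 nt from 50
  expect_equal(cats$category[cats$pos == 700], "individual")
  expect_equal(unname(cats$category[match(c(400, 401), cats$pos)]),
               rep("DC", 2))
})

test_that("randomized controls preserve per-transcript counts and context", {
  cfg <- simConfig(seed = 41, nTranscripts = 10, lengthMean = 1500,
                   lengthSd = 0, offspringMean = 3)
  sim <- simulateDataset(cfg)
  st <- sim$truth$sites
  for (mode in c("uniform_adenine", "trinucleotide")) {
    ctrl <- randomizeSites(sim$transcripts, st, mode = mode, nReps = 5,
                           seed = 99)
    for (cc in ctrl) {
      expect_equal(table(cc$transcript), table(st$transcript))
      # every control position is an adenine
      for (tx in unique(cc$transcript)) {
        aPos <- editClust:::.adeninePositions(sim$transcripts, tx)
        expect_true(all(cc$pos[cc$transcript == tx] %in% aPos))
        expect_false(anyDuplicated(cc$pos[cc$transcript == tx]) > 0)
      }
    }
  }
  # trinucleotide mode reproduces the real flanking-context histogram
  ctx <- function(s) {
    unlist(lapply(unique(s$transcript), function(tx) {
      chars <- strsplit(as.character(
        sequencesOf(sim$transcripts)[[tx]]), "")[[1]]
      p <- s$pos[s$transcript == tx]
      paste0(ifelse(p >= 1, chars[p], "N"),
             ifelse(p + 2 <= length(chars), chars[p + 2], "N"))
    }))
  }
  ctrl <- randomizeSites(sim$transcripts, st, mode = "trinucleotide",
                         nReps = 1, seed = 7)[[1]]
  realH <- table(factor(ctx(st)))
  ctrlH <- table(factor(ctx(ctrl), levels = names(realH)))
  expect_gt(suppressWarnings(
    chisq.test(rbind(realH, ctrlH))$p.value), 0.01)
})

test_that("a transcript whose adenines are all edited forces a permutation", {
  ts <- TranscriptSet(c(tx1 = "ACAGACATTA"))
  aPos <- editClust:::.adeninePositions(ts, "tx1")
  st <- mkSiteDf(aPos)
  for (mode in c("uniform_adenine", "trinucleotide")) {
    ctrl <- randomizeSites(ts, st, mode = mode, nReps = 3, seed = 1)
    for (cc in ctrl) expect_setequal(cc$pos, aPos)
  }
})

test_that("DC overrepresentation flags the enriched generator and not nulls", {
  cfgNull <- simConfig(seed = 5, nTranscripts = 15, lengthMean = 1500,
                       lengthSd = 0, lambdaL = 0, mediumRatePerKb = 1.5,
                       offspringMean = 1, pDense = 0, meanDepth = 1)
  simN <- simulateDataset(cfgNull)
  ctrlN <- randomizeSites(simN$transcripts, simN$truth$sites,
                          mode = "uniform_adenine", nReps = 49, seed = 2)
  dcN <- dcOverrepresentation(simN$truth$sites, ctrlN)
  expect_gt(dcN$empiricalP[dcN$size == "total"], 0.05)

  cfgE <- simConfig(seed = 6, nTranscripts = 15, lengthMean = 1500,
                    lengthSd = 0, lambdaL = 0, mediumRatePerKb = 1.5,
                    offspringMean = 2, pDense = 0.3, meanDepth = 1)
  simE <- simulateDataset(cfgE)
  ctrlE <- randomizeSites(simE$transcripts, simE$truth$sites,
                          mode = "uniform_adenine", nReps = 99, seed = 2)
  dcE <- dcOverrepresentation(simE$truth$sites, ctrlE)
  expect_lt(dcE$empiricalP[dcE$size == "total"], 0.011)
  expect_gt(dcE$real[dcE$size == "2"],
            dcE$controlMean[dcE$size == "2"])

  # no DCs in input -> zero real counts
  dc0 <- dcOverrepresentation(mkSiteDf(c(10, 20, 30)), ctrlN[1:3])
  expect_true(all(dc0$real[dc0$size != "total"] == 0L))
})

test_that("EL comparisons recover a DC-specific editing boost", {
  cfg <- simConfig(seed = 8, nTranscripts = 50, lengthMean = 2000,
                   lengthSd = 0, lambdaL = 0.5, offspringMean = 3,
                   pDense = 0.35, dcElShift = 0.25, meanDepth = 150,
                   elShape1 = 2, elShape2 = 8)
  sim <- simulateDataset(cfg)
  cmp <- compareElByCategory(sim$siteTable)
  row <- cmp[cmp$groupA == "DC" & cmp$groupB == "individual", ]
  if (!row$skipped) {
    expect_gt(row$fold, 1)
    if (row$nB >= 30) expect_lt(row$pMWU, 0.01)
  }
  rowC <- cmp[cmp$groupA == "DC" & cmp$groupB == "clustered", ]
  expect_false(rowC$skipped)
  expect_gt(rowC$fold, 1)
  expect_lt(rowC$pMWU, 1e-3)
  # a category with < 2 sites is skipped with a flag
  few <- SiteTable(data.frame(transcript = "t", pos = c(0L, 1L),
                              coverage = 10L, g_count = 5L))
  cmpFew <- compareElByCategory(few)
  expect_true(all(cmpFew$skipped))
})

test_that("isolated sites show no neighbor-editing signal at small S*", {
  len <- 5000L
  pos <- seq(100L, 4800L, by = 300L)
  ts <- TranscriptSet(setNames(
    list(seqWithA(len, sort(unique(c(pos, seq(3L, len - 3L, by = 7L)))))),
    "tx1"))
  st <- mkSiteDf(pos)
  ctrl <- randomizeSites(ts, st, mode = "uniform_adenine", nReps = 20,
                         seed = 3)
  q <- neighborEditingProbability(st, ts, ctrl, maxSstar = 30)
  expect_equal(q$window, 0L)
  expect_true(all(q$table$realEdited[1:30] == 0L))
})

test_that("identical S distributions give KS D = 0 and a diagonal curve", {
  s <- sample(1:500, 400, replace = TRUE)
  out <- compareSDistributions(s, list(s, s))
  expect_equal(unname(out$ks$statistic), 0)
  expect_equal(out$curve$real, out$curve$control)
  expect_equal(out$divergenceS, 0)
  # clustered sites diverge from uniform controls at short range only
  cfg <- simConfig(seed = 12, nTranscripts = 25, lengthMean = 3000,
                   lengthSd = 0, lambdaL = 0.6, sigmaL = 150,
                   clustersPerParent = 2, offspringMean = 4,
                   meanDepth = 1)
  sim <- simulateDataset(cfg)
  st <- sim$truth$sites
  ctrl <- randomizeSites(sim$transcripts, st, mode = "uniform_adenine",
                         nReps = 20, seed = 4)
  realS <- sDistances(computeDistances(st, maxS = 1500))$S
  ctrlS <- lapply(ctrl, function(cc)
    sDistances(computeDistances(cc, maxS = 1500))$S)
  out2 <- compareSDistributions(realS, ctrlS)
  expect_lt(out2$ks$p.value, 1e-6)
  expect_lt(out2$divergenceS, 2 * 150 + 100)
  expect_gt(out2$divergenceS, 0)
})
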