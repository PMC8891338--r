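test_that("recoding classification agrees with codon translation", {
  ts <- toyTranscripts(c(t1 = "AAAACAACA"))   # codons AAA ACA ACA
  expect_equal(recodingFlag(ts, "t1", 0L), "nonsynonymous")  # AAA->GAA K>E
  expect_equal(recodingFlag(ts, "t1", 5L), "synonymous")     # ACA->ACG T=T
  ts2 <- TranscriptSet(c(t2 = "AAACCC"),
                       cds = list(t2 = cbind(start = 0L, end = 3L)))
  expect_equal(recodingFlag(ts2, "t2", 3L), "noncoding")
  expect_error(recodingFlag(ts, "t1", 1L), NA)  # pos 1 is A (AAA codon)

  # oracle: every NNA/NAN/ANN codon, checked against Biostrings translate
  bases <- c("A", "C", "G", "T")
  for (p in 0:2) for (b1 in bases) for (b2 in bases) {
    codon <- c(b1, b2, "X")
    codon <- append(codon[-3], "A", after = p)[1:3]
    if (codon[p + 1] != "A") next
    seqc <- paste(codon, collapse = "")
    tsO <- TranscriptSet(setNames(list(seqc), "o"),
                         cds = list(o = cbind(0L, 3L)))
    edited <- codon; edited[p + 1] <- "G"
    aaRef <- as.character(Biostrings::translate(
      Biostrings::DNAString(seqc), no.init.codon = TRUE))
    aaAlt <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(edited, collapse = "")),
      no.init.codon = TRUE))
    want <- if (aaRef == aaAlt) "synonymous" else "nonsynonymous"
    expect_equal(recodingFlag(tsO, "o", p), want, label = seqc)
  }
})

test_that("EE pair extraction and EL asymmetry summarize dense pairs", {
  ts <- toyTranscripts(c(t1 = paste0("AA", strrep("C", 6), "AAT")))
  st <- SiteTable(data.frame(transcript = "t1", pos = c(0L, 1L, 8L, 9L),
                             coverage = 100L,
                             g_count = c(20L, 30L, 10L, 50L)),
                  transcripts = ts)
  ee <- densePairs(st)
  expect_equal(nrow(ee), 2L)
  expect_equal(ee$up, c(0L, 8L))
  asym <- aaElDifference(ee)
  expect_equal(asym$diffs, c(0.1, 0.4))
  expect_equal(asym$meanDiff, 0.25)
  # frame stratification sums to the unstratified count
  expect_equal(sum(asym$perFrame$n), length(asym$diffs))
  # single pair: difference reported, test skipped
  one <- aaElDifference(ee[1, ])
  expect_equal(one$diffs, 0.1)
  expect_true(is.na(one$p))
})

test_that("order score follows the intermediate-state arithmetic", {
  states <- rbind(
    matrix(rep(c("A", "I"), 8), ncol = 2, byrow = TRUE),
    matrix(rep(c("I", "A"), 2), ncol = 2, byrow = TRUE),
    matrix(rep(c("I", "I"), 3), ncol = 2, byrow = TRUE))
  rm <- readsFromStates(states, c(4L, 5L))
  ts <- TranscriptSet(c(tx = seqWithA(20, c(4L, 5L))))
  st <- sitePileup(rm, transcripts = ts, minCoverage = 1L)
  ord <- inferEditingOrder(rm, st, minPairReads = 5L)
  expect_equal(ord$pairs$d, 0.6)
  # antisymmetry: swapping the two columns flips the sign
  rmSw <- readsFromStates(states[, 2:1], c(4L, 5L))
  ordSw <- inferEditingOrder(rmSw, sitePileup(rmSw, minCoverage = 1L),
                             minPairReads = 5L)
  expect_equal(ordSw$pairs$d, -0.6)
  # no single-edited reads -> pair excluded
  statesII <- matrix(rep(c("I", "I"), 10), ncol = 2, byrow = TRUE)
  rmII <- readsFromStates(statesII, c(4L, 5L))
  ordII <- inferEditingOrder(rmII, sitePileup(rmII, minCoverage = 1L),
                             minPairReads = 5L)
  expect_equal(nrow(ordII$pairs), 0L)
})

test_that("the strict downstream-first limit yields d = 1 at every pair", {
  cfg <- simConfig(seed = 71, nTranscripts = 10, lengthMean = 800,
                   lengthSd = 0, lambdaL = 0, mediumRatePerKb = 2.5,
                   offspringMean = 2, interactionRadius = 8, pDense = 0,
                   elFixed = 0.3, rTarget = 0.2, delta = 0.5,
                   meanDepth = 60)
  sim <- simulateDataset(cfg)
  ord <- inferEditingOrder(sim$reads, sim$siteTable, maxS = 20,
                           minPairReads = 10L)
  biased <- merge(ord$pairs, sim$truth$pairs,
                  by.x = c("transcript", "up", "down"),
                  by.y = c("transcript", "up", "down"))
  expect_gt(nrow(biased), 5)
  expect_true(all(biased$d == 1))
})

test_that("structural control matching is strict and hand-checkable", {
  # layout: EE at 30/31; AA at 20/21; AE at 40/41; EA at 10/11
  len <- 60L
  chars <- rep("C", len)
  for (p in c(10, 11, 20, 21, 30, 31, 40, 41)) chars[p + 1] <- "A"
  ts <- TranscriptSet(c(tx = paste(chars, collapse = "")))
  edited <- c(10L, 30L, 31L, 41L)
  st <- SiteTable(data.frame(transcript = "tx", pos = edited,
                             coverage = 50L, g_count = 10L),
                  transcripts = ts)
  ee <- densePairs(st)
  expect_equal(ee$up, 30L)
  trio <- matchStructuralControls(ee, st, ts, window = 20, strict = TRUE)
  expect_equal(nrow(trio), 1L)
  expect_equal(trio$aaUp, 20L)
  expect_equal(trio$aeUp, 40L)
  expect_equal(trio$eaUp, 10L)
  # shrink the window so the EA control at distance 20 falls outside
  trioNarrow <- matchStructuralControls(ee, st, ts, window = 15,
                                        strict = TRUE)
  expect_equal(nrow(trioNarrow), 0L)
  trioAny <- matchStructuralControls(ee, st, ts, window = 15,
                                     strict = FALSE)
  expect_equal(nrow(trioAny), 1L)
  expect_true(is.na(trioAny$eaUp))
})

test_that("base-pairing comparisons detect a deeper downstream dip", {
  set.seed(81)
  nEE <- 120L
  blocks <- 100L
  len <- nEE * blocks
  chars <- rep("C", len)
  upPos <- (seq_len(nEE) - 1L) * blocks + 40L
  for (u in upPos) for (q in c(u, u + 1, u + 10, u + 11, u - 10, u - 9,
                               u + 16, u + 17))
    chars[q + 1] <- "A"
  ts <- TranscriptSet(c(tx = paste(chars, collapse = "")))
  edited <- c(upPos, upPos + 1L,           # EE
              upPos + 11L,                 # AE (down edited)
              upPos - 10L)                 # EA (up edited)
  st <- SiteTable(data.frame(transcript = "tx", pos = sort(edited),
                             coverage = 50L, g_count = 15L),
                  transcripts = ts)
  v <- runif(len, 0.4, 0.6)
  v[upPos + 1L] <- v[upPos + 1L] - 0.15        # EE up dip
  v[upPos + 2L] <- v[upPos + 2L] - 0.30        # EE down deeper dip
  prof <- PairingProfile(list(tx = v))
  ee <- densePairs(st)
  ee <- ee[ee$up %in% upPos, ]
  trios <- matchStructuralControls(ee, st, ts, window = 20)
  expect_gt(nrow(trios), 50)
  bpp <- compareBppPositions(trios, prof)
  row <- bpp[bpp$comparison == "EEup_vs_EEdown", ]
  expect_equal(row$direction, 1)   # down is less paired than up
  expect_lt(row$p, 0.01)
  rowAA <- bpp[bpp$comparison == "EEdown_vs_AAdown", ]
  expect_equal(rowAA$direction, -1)
  expect_lt(rowAA$p, 0.01)
  # identical flat profiles: nothing significant
  prof0 <- PairingProfile(list(tx = rep(0.5, len)))
  bpp0 <- compareBppPositions(trios, prof0)
  expect_false(any(bpp0$significant, na.rm = TRUE))
})

test_that("recoding asymmetry uses the AA background expectation", {
  # all-AAA transcript: every position is recoding or synonymous the same
  # way by frame; with a symmetric layout there is no signal
  ts <- toyTranscripts(c(t1 = strrep("AAA", 60)))
  pos <- c(30L, 31L, 60L, 61L, 90L, 91L, 120L, 121L)
  st <- SiteTable(data.frame(transcript = "t1", pos = pos,
                             coverage = 50L, g_count = 20L),
                  transcripts = ts)
  ee <- densePairs(st)
  out <- recodingAsymmetry(ee, ts, st)
  expect_true(out$p0 > 0 && out$p0 < 1)
  if (out$n > 0) expect_gt(out$p, 0.05)
  # no coding EE pairs -> test skipped
  tsNc <- TranscriptSet(c(t1 = "AACCAACC"))
  stNc <- SiteTable(data.frame(transcript = "t1", pos = c(0L, 1L),
                               coverage = 10L, g_count = 5L),
                    transcripts = tsNc)
  outNc <- recodingAsymmetry(densePairs(stNc), tsNc, stNc)
  expect_true(is.na(outNc$p))
})
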