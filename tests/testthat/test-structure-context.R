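flatProfile <- function(ts, value = 0.3)
  PairingProfile(lapply(as.list(as.character(sequencesOf(ts))),
                        function(s) rep(value, nchar(s))))

test_that("profile averaging handles flat input and transcript ends", {
  ts <- TranscriptSet(c(tx1 = seqWithA(400, c(5L, 200L))))
  st <- toySites(ts, c(5L, 200L), el = 0.3)
  prof <- flatProfile(ts, 0.3)
  avg <- averageProfileAroundSites(prof, st, halfwidth = 50)
  expect_true(all(abs(avg$mean - 0.3) < 1e-12))
  # the site at 5 contributes nothing below offset -5
  expect_equal(avg$n[avg$offset == -40], 1L)
  expect_equal(avg$n[avg$offset == 0], 2L)
})

test_that("noise band and peak width are recovered from generated profiles", {
  cfg <- simConfig(seed = 61, nTranscripts = 50, lengthMean = 2000,
                   lengthSd = 0, lambdaL = 0, mediumRatePerKb = 0.5,
                   offspringMean = 1, pDense = 0, meanDepth = 1,
                   noiseBand = c(0.25, 0.35), bumpWidth = 36,
                   bumpHeight = 0.2, dipDepth = 0.25)
  sim <- simulateDataset(cfg)
  st <- sim$truth$sites
  band <- estimateNoiseBand(sim$profiles, st, minDist = 200)
  expect_lt(abs(band[1] - 0.2525), 0.02)   # 2.5% quantile of U(0.25,0.35)
  expect_lt(abs(band[2] - 0.3475), 0.02)
  avg <- averageProfileAroundSites(sim$profiles, st, halfwidth = 100)
  width <- estimatePeakWidth(avg, band)
  expect_gte(width, 32); expect_lte(width, 45)
  # flat profiles -> no peak
  tsF <- TranscriptSet(c(tx1 = seqWithA(600, c(300L))))
  stF <- toySites(tsF, 300L)
  profF <- flatProfile(tsF)
  avgF <- averageProfileAroundSites(profF, stF, halfwidth = 60)
  expect_equal(estimatePeakWidth(avgF, c(0.25, 0.35)), 0L)
  # no signal when the bump is absent
  cfg0 <- simConfig(seed = 62, nTranscripts = 10, lengthMean = 1000,
                    lengthSd = 0, meanDepth = 1, bumpHeight = 0,
                    dipDepth = 0)
  sim0 <- simulateDataset(cfg0)
  avg0 <- averageProfileAroundSites(sim0$profiles, sim0$truth$sites, 100)
  band0 <- estimateNoiseBand(sim0$profiles, sim0$truth$sites, 200)
  expect_lte(estimatePeakWidth(avg0, band0), 4L)
  # eligible-nucleotide error
  tsTiny <- TranscriptSet(c(t = seqWithA(50, 25L)))
  expect_error(estimateNoiseBand(flatProfile(tsTiny),
                                 toySites(tsTiny, 25L), minDist = 200),
               "minDist")
})

test_that("peak width is monotone in the generator bump width", {
  widths <- c(20, 36, 60, 100)
  est <- vapply(seq_along(widths), function(k) {
    reps <- vapply(1:5, function(r) {
      cfg <- simConfig(seed = 100 * k + r, nTranscripts = 40,
                       lengthMean = 1500, lengthSd = 0, lambdaL = 0,
                       mediumRatePerKb = 0.5, offspringMean = 1,
                       pDense = 0, meanDepth = 1, bumpWidth = widths[k])
      sim <- simulateDataset(cfg)
      st <- sim$truth$sites
      band <- estimateNoiseBand(sim$profiles, st, minDist = 200)
      estimatePeakWidth(averageProfileAroundSites(sim$profiles, st, 150),
                        band)
    }, 0L)
    mean(reps)
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("A-C mismatch enrichment matches the exact-test oracle", {
  # build one transcript: site/control A pairs in 20-nt blocks, explicit
  # partner map; sites: 10 across C, 2 other; controls: 1 across C, 8 other
  nBlock <- 12L
  len <- nBlock * 20L + 40L
  chars <- rep("T", len)
  sitePos <- integer(nBlock); ctlPos <- integer(nBlock)
  partner <- rep(NA_integer_, len)
  acSite <- c(rep(TRUE, 10), rep(FALSE, 2))
  # 1 control across C, 8 across G, 3 unpaired (counted as "other")
  acCtl <- c(TRUE, rep(FALSE, 8), rep(NA, 3))
  for (b in seq_len(nBlock)) {
    s <- (b - 1L) * 20L; ctl <- s + 2L; ps <- s + 10L; pc <- s + 12L
    chars[s + 1L] <- "A"; chars[ctl + 1L] <- "A"
    sitePos[b] <- s; ctlPos[b] <- ctl
    chars[ps + 1L] <- if (acSite[b]) "C" else "G"
    partner[s + 1L] <- ps
    if (!is.na(acCtl[b])) {
      chars[pc + 1L] <- if (acCtl[b]) "C" else "G"
      partner[ctl + 1L] <- pc
    }
  }
  ts <- TranscriptSet(c(tx1 = paste(chars, collapse = "")))
  st <- toySites(ts, sitePos)
  prof <- PairingProfile(list(tx1 = rep(0.5, len)),
                         partner = list(tx1 = partner))
  out <- acMismatchEnrichment(prof, st, ts)
  expect_equal(unname(out$table["site", ]), c(10, 2))
  expect_equal(unname(out$table["control", ]), c(1, 11))
  expect_equal(out$oddsRatio, (10 * 11) / (2 * 1))
  expect_equal(out$p, fisherOracle(10, 2, 1, 11), tolerance = 1e-8)
  # equal rows -> OR 1; zero margin -> Haldane-corrected OR, exact p kept
  tabEq <- matrix(c(5, 5, 5, 5), 2, byrow = TRUE)
  expect_equal(fisher.test(tabEq)$p.value, 1)
})

test_that("sites are less paired than their nearest-control adenines when
           the generator dips them", {
  cfg <- simConfig(seed = 63, nTranscripts = 20, lengthMean = 1200,
                   lengthSd = 0, meanDepth = 1, dipDepth = 0.3)
  sim <- simulateDataset(cfg)
  st <- SiteTable(transform(sim$truth$sites, coverage = 100L,
                            g_count = round(100 * el)),
                  transcripts = sim$transcripts)
  out <- siteVsNearestControl(st, sim$profiles, sim$transcripts)
  expect_lt(out$p, 0.01)
  expect_lt(median(out$pairs$sitePairing - out$pairs$controlPairing), 0)
  # without a dip the differences are centered
  cfg0 <- simConfig(seed = 64, nTranscripts = 20, lengthMean = 1200,
                    lengthSd = 0, meanDepth = 1, dipDepth = 0,
                    bumpHeight = 0)
  sim0 <- simulateDataset(cfg0)
  st0 <- SiteTable(transform(sim0$truth$sites, coverage = 100L,
                             g_count = round(100 * el)),
                   transcripts = sim0$transcripts)
  out0 <- siteVsNearestControl(st0, sim0$profiles, sim0$transcripts)
  expect_lt(abs(median(out0$pairs$sitePairing -
                       out0$pairs$controlPairing)), 0.02)
})

test_that("pair structure classification follows the partner map", {
  # hairpin: stem 20..34 pairs with 66..52; sites at 15 and 72 sit on
  # opposite arms, brought within a few nt by the stem
  len <- 100L
  chars <- rep("T", len); chars[c(16L, 73L)] <- "A"
  ts <- TranscriptSet(c(tx1 = paste(chars, collapse = "")))
  v <- rep(0.3, len); ptn <- rep(NA_integer_, len)
  stem5 <- 20:34; stem3 <- 66:52
  v[stem5 + 1L] <- 0.9; v[stem3 + 1L] <- 0.9
  ptn[stem5 + 1L] <- stem3; ptn[stem3 + 1L] <- stem5
  prof <- PairingProfile(list(tx1 = v), partner = list(tx1 = ptn))
  band <- c(0.25, 0.35)
  expect_equal(classifyPairStructure(prof, "tx1", 15L, 72L, band),
               "close_due_to_structure")
  # flat profile between distant sites
  prof0 <- PairingProfile(list(tx1 = rep(0.3, len)),
                          partner = list(tx1 = rep(NA_integer_, len)))
  expect_equal(classifyPairStructure(prof0, "tx1", 15L, 72L, band),
               "distant_unstructured")
  # a local hairpin strictly between the sites, too far from both
  ptn2 <- rep(NA_integer_, len); v2 <- rep(0.3, len)
  s5 <- 28:34; s3 <- 48:42
  v2[s5 + 1L] <- 0.9; v2[s3 + 1L] <- 0.9
  ptn2[s5 + 1L] <- s3; ptn2[s3 + 1L] <- s5
  prof2 <- PairingProfile(list(tx1 = v2), partner = list(tx1 = ptn2))
  lab <- classifyPairStructure(prof2, "tx1", 10L, 80L, band,
                               spatialCutoff = 10L)
  expect_equal(lab, "intermediate")
})

test_that("cooperativity by structure flags only coupled bins", {
  set.seed(31)
  mk <- function(n, S, rp, label)
    data.frame(S = S, rprime = rp, label = label)
  df <- rbind(
    mk(, S = sample(4:16, 200, TRUE), rp = rlnorm(200, log(2), 0.3),
       label = "close_due_to_structure"),
    mk(, S = sample(4:16, 200, TRUE), rp = rlnorm(200, 0, 0.3),
       label = "distant_unstructured"),
    mk(, S = sample(150:250, 200, TRUE), rp = rlnorm(200, 0, 0.3),
       label = "close_due_to_structure"),
    mk(, S = sample(150:250, 200, TRUE), rp = rlnorm(200, 0, 0.3),
       label = "distant_unstructured"))
  out <- cooperativityByStructure(df)
  hit <- out[out$bin %in% c("4-8", "8-16"), ]
  expect_true(all(hit$significant[!hit$skipped]))
  far <- out[out$bin == "128-256", ]
  expect_false(any(far$significant[!far$skipped]))
  expect_true(all(out$skipped[out$nStruct < 2]))
})

test_that("the naive pairing scorer separates structure from shuffle noise", {
  expect_error(naivePairingScore("ACGT", window = 60), "window")
  polyA <- strrep("A", 80)
  zA <- naivePairingScore(polyA, window = 40, positions = 40L)
  expect_equal(zA$z, 0)
  # perfect 20-nt inverted repeat with a 5-nt loop
  left <- "ACGUACGGUCACGUACGGUC"
  left <- chartr("U", "T", left)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(left)))
  hp <- paste0(strrep("A", 10), left, "AAAAA", rc, strrep("A", 10))
  z <- naivePairingScore(hp, window = nchar(hp),
                         positions = nchar(hp) %/% 2, nShuffle = 15,
                         seed = 4)
  expect_gte(z$score, 20)
  expect_gt(z$z, 2)
  # determinism given the seed
  z2 <- naivePairingScore(hp, window = nchar(hp),
                          positions = nchar(hp) %/% 2, nShuffle = 15,
                          seed = 4)
  expect_identical(z, z2)
})

test_that("single-exon annotation reproduces full-transcript structure
           analysis exactly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seq1 <- seqWithA(300, c(50L, 150L))
  writeLines(c(">tx1", seq1), f)
  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript\tstart\tend\ttype",
               "tx1\t0\t300\tcds", "tx1\t0\t300\texon"), ann)
  ts <- readTranscripts(f, annotation = ann)
  expect_equal(unname(exonsOf(ts)$tx1[, "end"] -
                      exonsOf(ts)$tx1[, "start"]), 300L)
  st <- toySites(ts, c(50L, 150L))
  prof <- flatProfile(ts)
  avgFull <- averageProfileAroundSites(prof, st, halfwidth = 40)
  # exon == transcript, so restricting to the exon changes nothing
  expect_equal(avgFull$mean, rep(0.3, 81))
})
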