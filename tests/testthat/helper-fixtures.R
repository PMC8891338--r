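# Shared toy builders and independent oracles. Everything is constructed
# in code; no fixture files.

# A ReadMatrix in which every read covers the whole transcript and calls
# the given states at the given site positions.
# states: character matrix, rows = reads, cols = positions ("A"/"I"/"other")
readsFromStates <- function(states, positions, transcript = "tx",
                            txLength = max(positions) + 10L) {
  nR <- nrow(states)
  ids <- sprintf("r%03d", seq_len(nR))
  reads <- data.frame(read_id = ids, transcript = transcript,
                      start = 0L, end = txLength)
  calls <- data.frame(
    read_id = rep(ids, times = length(positions)),
    transcript = transcript,
    pos = rep(positions, each = nR),
    state = as.vector(states))
  ReadMatrix(reads, calls)
}

# expand tallies (nAA, nAI, nIA, nII) into per-read binary state vectors
expandTallies <- function(n) {
  xi <- c(rep(0, n[1] + n[2]), rep(1, n[3] + n[4]))
  xj <- c(rep(0, n[1]), rep(1, n[2]), rep(0, n[3]), rep(1, n[4]))
  cbind(i = xi, j = xj)
}

# oracle: phi coefficient as Pearson correlation of the binary vectors
phiOracle <- function(n) {
  v <- expandTallies(n)
  suppressWarnings(cor(v[, 1], v[, 2]))
}

# oracle: two-sided Fisher exact p by direct hypergeometric enumeration
fisherOracle <- function(nAA, nAI, nIA, nII) {
  r1 <- nAA + nAI; r2 <- nIA + nII; c1 <- nAA + nIA
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  pObs <- dhyper(nAA, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# oracle: all-pairs and nearest-neighbor distances by double loop
distanceOracle <- function(pos, maxS = Inf) {
  pos <- sort(pos)
  S <- integer(); Sstar <- integer()
  n <- length(pos)
  if (n >= 2L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    d <- pos[b] - pos[a]
    if (d <= maxS) S <- c(S, d)
    if (b == a + 1L) Sstar <- c(Sstar, d)
  }
  list(S = sort(S), Sstar = sort(Sstar))
}

# oracle: dense clusters by O(n^2) scan
denseOracle <- function(pos) {
  pos <- sort(pos)
  runs <- list()
  k <- 1L
  while (k <= length(pos)) {
    e <- k
    while (e < length(pos) && pos[e + 1L] == pos[e] + 1L) e <- e + 1L
    if (e > k) runs[[length(runs) + 1L]] <-
      c(start = pos[k], end = pos[e], size = e - k + 1L)
    k <- e + 1L
  }
  runs
}

# a tiny deterministic TranscriptSet with a full-length CDS
toyTranscripts <- function(seqs) {
  cds <- lapply(seqs, function(s)
    cbind(start = 0L, end = (nchar(s) %/% 3L) * 3L))
  TranscriptSet(seqs, cds = cds)
}

# SiteTable straight from positions (no read data)
toySites <- function(transcripts, positions, el = 0.5,
                     transcript = NULL) {
  if (is.null(transcript))
    transcript <- names(sequencesOf(transcripts))[1L]
  n <- length(positions)
  SiteTable(data.frame(transcript = transcript, pos = positions,
                       coverage = 100L, g_count = round(100 * rep(el, n)),
                       el = rep(el, n)),
            transcripts = transcripts)
}

# build a transcript string with "A" at chosen 0-based positions and a
# non-A filler elsewhere
seqWithA <- function(len, aPositions, filler = "C") {
  x <- rep(filler, len)
  x[aPositions + 1L] <- "A"
  paste(x, collapse = "")
}
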