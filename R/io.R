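# External-format ingestion and TSV serialization of the internal data model.
# Coordinates are 0-based half-open throughout; transcripts are sense strand.

#' Read transcripts from FASTA with optional CDS/exon annotation
#'
#' Sequences are uppercased and U is mapped to T. Annotation is accepted
#' either as GFF3 (feature types \code{CDS} and \code{exon}, seqid =
#' transcript id, 1-based closed coordinates) or as a simple TSV with
#' columns \code{transcript}, \code{start}, \code{end} and optionally
#' \code{type} (\code{cds}/\code{exon}), already 0-based half-open.
#'
#' @param fasta path to a FASTA file of transcript sequences.
#' @param annotation optional path to a GFF3 (\code{.gff}/\code{.gff3}) or
#'   TSV annotation file.
#' @return a \code{TranscriptSet}.
#' @export
readTranscripts <- function(fasta, annotation = NULL) {
  raw <- Biostrings::readBStringSet(fasta)
  if (length(raw) == 0L) stop("empty FASTA: ", fasta)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- chartr("Uu", "Tt", as.character(raw))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  names(seqs) <- ids
  cds <- list(); exons <- list()
  if (!is.null(annotation)) {
    ann <- .readAnnotation(annotation)
    cds <- ann$cds; exons <- ann$exons
  }
  TranscriptSet(seqs, cds = cds, exons = exons)
}

.readAnnotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path)
    df <- data.frame(transcript = as.character(GenomicRanges::seqnames(g)),
                     start = GenomicRanges::start(g) - 1L,
                     end = GenomicRanges::end(g),
                     type = tolower(as.character(g$type)))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (is.null(df$type)) df$type <- "cds"
    df$type <- tolower(df$type)
  }
  split2 <- function(d) {
    if (nrow(d) == 0L) return(list())
    lapply(split(d[, c("start", "end")], d$transcript), .asIntervalMatrix)
  }
  list(cds = split2(df[df$type == "cds", , drop = FALSE]),
       exons = split2(df[df$type == "exon", , drop = FALSE]))
}

#' Read / write an editing-site table
#'
#' TSV columns: \code{transcript}, \code{pos} (0-based adenine position),
#' \code{coverage}, \code{g_count}. EL and CDS annotation are recomputed on
#' read when \code{transcripts} is given; the round trip through
#' \code{writeSiteTable} is lossless.
#'
#' @param path TSV path.
#' @param transcripts optional \code{TranscriptSet} for reference-base
#'   checking and frame/recoding annotation.
#' @return \code{readSiteTable}: a \code{SiteTable}.
#' @export
readSiteTable <- function(path, transcripts = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  SiteTable(df, transcripts = transcripts)
}

#' @rdname readSiteTable
#' @param x the \code{SiteTable} to write.
#' @export
writeSiteTable <- function(x, path) {
  write.table(sites(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-read A/I calls
#'
#' Internal TSV: \code{read_id}, \code{transcript}, \code{start}, \code{end}
#' (0-based half-open), \code{calls} as a semicolon-joined list of
#' \code{pos:state} tokens (\code{.} when the read overlaps no site).
#'
#' @param path TSV path.
#' @return \code{readReadCalls}: a \code{ReadMatrix}.
#' @export
readReadCalls <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(read_id = "character"))
  reads <- df[, c("read_id", "transcript", "start", "end")]
  keep <- df$calls != "." & !is.na(df$calls)
  if (any(keep)) {
    toks <- strsplit(df$calls[keep], ";", fixed = TRUE)
    nTok <- lengths(toks)
    flat <- unlist(toks)
    ps <- strsplit(flat, ":", fixed = TRUE)
    calls <- data.frame(
      read_id = rep(df$read_id[keep], nTok),
      transcript = rep(df$transcript[keep], nTok),
      pos = as.integer(vapply(ps, `[`, "", 1L)),
      state = vapply(ps, `[`, "", 2L),
      stringsAsFactors = FALSE)
  } else {
    calls <- data.frame(read_id = character(), transcript = character(),
                        pos = integer(), state = character())
  }
  ReadMatrix(reads, calls)
}

#' @rdname readReadCalls
#' @param x the \code{ReadMatrix} to write.
#' @export
writeReadCalls <- function(x, path) {
  reads <- readIntervals(x); calls <- readCalls(x)
  tok <- if (nrow(calls)) {
    sp <- split(paste0(calls$pos, ":", calls$state), calls$read_id)
    vapply(sp, paste, "", collapse = ";")
  } else character()
  reads$calls <- ifelse(reads$read_id %in% names(tok),
                        tok[reads$read_id], ".")
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest mapped reads (SAM against transcript coordinates)
#'
#' Accepts only records whose CIGAR is a single match run (\code{<n>M});
#' others are skipped and counted in the \code{"skipped"} attribute of the
#' result, since site calls under clipping/indels would need realignment.
#' At each editing-site position covered by a read, the called state is
#' \code{A}, \code{I} (sequenced G at the A reference) or \code{other}.
#'
#' @param path SAM file (with \code{@SQ} headers) mapped to transcripts.
#' @param transcripts a \code{TranscriptSet}; alignments to unknown
#'   transcripts are an error.
#' @param siteTable a \code{SiteTable}; calls are recorded at its positions.
#' @return a \code{ReadMatrix}.
#' @export
readAlignmentsSam <- function(path, transcripts, siteTable) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq"))
  a <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !is.na(a$pos)
  simple <- mapped & grepl("^[0-9]+M$", a$cigar)
  skipped <- sum(mapped & !simple)
  idx <- which(simple)
  txIds <- as.character(a$rname[idx])
  unknown <- setdiff(unique(txIds), names(sequencesOf(transcripts)))
  if (length(unknown)) stop("alignment to unknown transcript: ", unknown[1L])
  starts <- a$pos[idx] - 1L
  seqsC <- as.character(a$seq[idx])
  ends <- starts + nchar(seqsC)
  lens <- setNames(Biostrings::width(sequencesOf(transcripts)),
                   names(sequencesOf(transcripts)))[txIds]
  if (any(ends > lens)) stop("alignment extends outside transcript sequence")
  reads <- data.frame(read_id = as.character(a$qname[idx]),
                      transcript = txIds, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  st <- sites(siteTable)
  callRows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    sp <- st$pos[st$transcript == txIds[k]]
    cov <- sp[sp >= starts[k] & sp < ends[k]]
    if (!length(cov)) next
    base <- substring(seqsC[k], cov - starts[k] + 1L, cov - starts[k] + 1L)
    callRows[[k]] <- data.frame(
      read_id = reads$read_id[k], transcript = txIds[k], pos = cov,
      state = ifelse(base == "A", "A", ifelse(base == "G", "I", "other")),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, callRows[!vapply(callRows, is.null, TRUE)])
  if (is.null(calls))
    calls <- data.frame(read_id = character(), transcript = character(),
                        pos = integer(), state = character())
  out <- ReadMatrix(reads, calls)
  attr(out, "skipped") <- skipped
  out
}

#' Pileup of site-level coverage and G-counts from a ReadMatrix
#'
#' Coverage counts reads with an informative A/I call at the position
#' (non-A/G calls are treated as missing, consistent with the correlation
#' statistics being defined over A and I only).
#'
#' @param reads a \code{ReadMatrix}.
#' @param transcripts a \code{TranscriptSet} (for annotation).
#' @param minCoverage sites with fewer informative reads get \code{el = NA}.
#' @return a \code{SiteTable} over all positions present in the calls.
#' @export
sitePileup <- function(reads, transcripts = NULL, minCoverage = 10L) {
  cl <- readCalls(reads)
  cl <- cl[cl$state %in% c("A", "I"), , drop = FALSE]
  if (nrow(cl) == 0L)
    return(SiteTable(data.frame(transcript = character(), pos = integer(),
                                coverage = integer(), g_count = integer())))
  key <- paste(cl$transcript, cl$pos)
  cov <- tapply(rep(1L, nrow(cl)), key, sum)
  gc <- tapply(cl$state == "I", key, sum)
  parts <- strsplit(names(cov), " ", fixed = TRUE)
  df <- data.frame(transcript = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   coverage = as.integer(cov), g_count = as.integer(gc),
                   stringsAsFactors = FALSE)
  df$el <- ifelse(df$coverage >= minCoverage,
                  df$g_count / df$coverage, NA_real_)
  SiteTable(df, transcripts = transcripts)
}

#' Read / write RNAplfold-style per-nucleotide pairing tables
#'
#' Parses \code{_lunp}-style output: comment lines starting with \code{#},
#' then one row per position (1-based) with the probability in the second
#' column. Dialect \code{unpaired_prob} converts to pairing probability
#' = 1 - unpaired; \code{basepair_prob} takes values as given. Missing
#' values (\code{NA}) are kept as missing; a profile with no usable value
#' is flagged with attribute \code{unusable}.
#'
#' @param paths named character vector of per-transcript table paths
#'   (names = transcript ids).
#' @param dialect \code{"unpaired_prob"} or \code{"basepair_prob"}.
#' @param transcripts optional \code{TranscriptSet}; lengths are checked.
#' @return a \code{PairingProfile}.
#' @export
readPairingOutput <- function(paths, dialect = c("unpaired_prob",
                                                 "basepair_prob"),
                              transcripts = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named by transcript id")
  pairing <- list()
  for (tx in names(paths)) {
    ln <- readLines(paths[[tx]])
    ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
    m <- read.table(text = ln, header = FALSE)
    v <- rep(NA_real_, max(m[[1L]]))
    v[m[[1L]]] <- suppressWarnings(as.numeric(m[[2L]]))
    if (!is.null(transcripts)) {
      len <- length(sequencesOf(transcripts)[[tx]])
      if (is.null(len)) stop("unknown transcript: ", tx)
      if (length(v) != len)
        stop(sprintf("profile length %d != transcript length %d for '%s'",
                     length(v), len, tx))
    }
    if (dialect == "unpaired_prob") v <- 1 - v
    if (all(is.na(v))) attr(v, "unusable") <- TRUE
    pairing[[tx]] <- v
  }
  PairingProfile(pairing)
}

#' @rdname readPairingOutput
#' @param x a \code{PairingProfile} to write (one file per transcript).
#' @param dir output directory; files are named \code{<transcript>_lunp.tsv}.
#' @export
writePairingOutput <- function(x, dir,
                               dialect = c("unpaired_prob",
                                           "basepair_prob")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (tx in names(pairingProb(x))) {
    v <- pairingProb(x)[[tx]]
    if (dialect == "unpaired_prob") v <- 1 - v
    path <- file.path(dir, paste0(tx, "_lunp.tsv"))
    writeLines(c("#unpaired probabilities",
                 paste(seq_along(v), sprintf("%.10g", v))), path)
    paths[tx] <- path
  }
  invisible(paths)
}
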