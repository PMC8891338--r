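# End-to-end orchestration: run the simulation (or load inputs), execute
# the analysis stages in dependency order, and write TSV tables, a JSON
# summary and a plain-text log into a run directory.

#' Write a simulated dataset in the external formats the package reads
#'
#' FASTA + CDS TSV, site TSV, read-call TSV, RNAplfold-style profile
#' tables, and truth_*.tsv tables.
#'
#' @param sim output of \code{simulateDataset}.
#' @param dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "transcripts.fasta"),
             cds = file.path(dir, "cds.tsv"),
             sites = file.path(dir, "sites.tsv"),
             reads = file.path(dir, "read_calls.tsv"),
             truthSites = file.path(dir, "truth_sites.tsv"),
             truthPairs = file.path(dir, "truth_pairs.tsv"))
  Biostrings::writeXStringSet(sequencesOf(sim$transcripts), paths["fasta"])
  cdsRows <- do.call(rbind, lapply(names(cdsOf(sim$transcripts)), function(tx) {
    m <- cdsOf(sim$transcripts)[[tx]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(transcript = tx, start = m[, 1L], end = m[, 2L],
               type = "cds")
  }))
  write.table(cdsRows, paths["cds"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSiteTable(sim$siteTable, paths["sites"])
  writeReadCalls(sim$reads, paths["reads"])
  prof <- writePairingOutput(sim$profiles, file.path(dir, "profiles"))
  write.table(sim$truth$sites, paths["truthSites"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$pairs, paths["truthPairs"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(paths, prof))
}

#' Run the full analysis pipeline
#'
#' Stages: \code{simulate} (or load the configured inputs), then
#' \code{pairstats}, \code{diversity}, \code{clusters}, \code{structure},
#' \code{direction}. Every threshold, seed and stage outcome is echoed to
#' \code{run.log}; per-stage TSVs and a JSON summary with every statistic
#' (test, n, p, correction family) land in \code{outDir}. Stages whose
#' inputs are missing are skipped with a logged reason.
#'
#' @param config a named list (or YAML path) with elements \code{seed},
#'   \code{outDir}, optional \code{simulate} (arguments to
#'   \code{simConfig}; seed defaults to the run seed), optional
#'   \code{input} (paths: fasta, cds, sites, reads, profiles dir),
#'   optional \code{stages} (character subset), and optional thresholds:
#'   \code{minCoverage}, \code{minPairReads}, \code{elFilters},
#'   \code{categoryCutoff}, \code{noiseDist}, \code{controlWindow},
#'   \code{maxS}, \code{nReps}, \code{alpha}.
#' @return invisibly, the summary list (also written as summary.json).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  outDir <- config$outDir %||% "editclust_run"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    logLines <<- c(logLines, msg)
  }
  thr <- list(minCoverage = config$minCoverage %||% 10L,
              minPairReads = config$minPairReads %||% 10L,
              elFilters = config$elFilters %||% c(0, 0.05, 0.10),
              categoryCutoff = config$categoryCutoff %||% 100L,
              noiseDist = config$noiseDist %||% 200L,
              controlWindow = config$controlWindow %||% 20L,
              maxS = config$maxS %||% 1000L,
              nReps = config$nReps %||% 100L,
              alpha = config$alpha %||% 0.05)
  stages <- config$stages %||% c("pairstats", "diversity", "clusters",
                                 "structure", "direction")
  say("seed=%d stages=%s", config$seed, paste(stages, collapse = ","))
  for (nm in names(thr))
    say("threshold %s = %s", nm, paste(thr[[nm]], collapse = ","))
  summary <- list(seed = config$seed, thresholds = thr)
  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- simArgs$seed %||% config$seed
    sim <- simulateDataset(do.call(simConfig, simArgs))
    writeDataset(sim, file.path(outDir, "dataset"))
    transcripts <- sim$transcripts; siteTable <- sim$siteTable
    reads <- sim$reads; profiles <- sim$profiles
    say("simulated %d transcripts, %d sites, %d reads",
        length(sequencesOf(transcripts)), nrow(sites(siteTable)),
        nrow(readIntervals(reads)))
  } else if (!is.null(config$input)) {
    inp <- config$input
    transcripts <- readTranscripts(inp$fasta, annotation = inp$cds)
    siteTable <- readSiteTable(inp$sites, transcripts = transcripts)
    reads <- if (!is.null(inp$reads)) readReadCalls(inp$reads) else NULL
    profiles <- if (!is.null(inp$profiles)) {
      fs <- list.files(inp$profiles, full.names = TRUE)
      names(fs) <- sub("_lunp\\.tsv$", "", basename(fs))
      readPairingOutput(fs, transcripts = transcripts)
    } else NULL
    say("loaded inputs from configured paths")
  } else stop("config needs either a simulate block or input paths")
  ## ---- stages ----
  runStage <- function(name, need, fn) {
    if (!name %in% stages) return(invisible(NULL))
    ok <- tryCatch({
      res <- fn()
      summary[[name]] <<- res
      say("stage %s: ok", name)
      TRUE
    }, error = function(e) {
      say("stage %s: skipped (%s)", name, conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  tsv <- function(df, name) {
    write.table(df, file.path(outDir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  runStage("pairstats", "reads", function() {
    out <- lapply(thr$elFilters, function(em)
      correlationProfileByDistance(reads, siteTable,
                                   maxS = min(thr$maxS, 100L),
                                   elMin = em,
                                   minPairReads = thr$minPairReads))
    names(out) <- paste0("el", thr$elFilters)
    tsv(out[[1L]]$pairs, "pairstats_pairs")
    for (nm in names(out)) tsv(out[[nm]]$summary,
                               paste0("pairstats_summary_", nm))
    elc <- elCorrelationByDistance(siteTable, sGrid = 1:50,
                                   alpha = thr$alpha)
    tsv(elc, "pairstats_el_correlation")
    list(rByS = lapply(out, `[[`, "summary"), elCorrelation = elc)
  })
  runStage("diversity", "reads", function() {
    dT <- netEditingVariance(siteTable, reads, mode = "transcriptome",
                             alpha = thr$alpha,
                             minPairReads = thr$minPairReads)
    dP <- netEditingVariance(siteTable, reads, mode = "proteome",
                             alpha = thr$alpha,
                             minPairReads = thr$minPairReads)
    tsv(data.frame(mode = c("transcriptome", "proteome"),
                   netVariance = c(dT$netVariance, dP$netVariance),
                   covarianceFraction = c(dT$covarianceFraction,
                                          dP$covarianceFraction),
                   equivalentPolymorphisms =
                     equivalentPolymorphisms(c(dT$netVariance,
                                               dP$netVariance))),
        "diversity")
    list(transcriptome = dT[c("netVariance", "covarianceFraction")],
         proteome = dP[c("netVariance", "covarianceFraction")])
  })
  runStage("clusters", character(), function() {
    ctrl <- randomizeSites(transcripts, siteTable,
                           mode = "trinucleotide", nReps = thr$nReps,
                           seed = config$seed + 1L)
    dc <- dcOverrepresentation(sites(siteTable), ctrl)
    tsv(dc, "clusters_dc_overrepresentation")
    el <- compareElByCategory(siteTable, cutoff = thr$categoryCutoff)
    tsv(el, "clusters_el_by_category")
    cs <- computeDistances(siteTable, maxS = thr$maxS)
    tsv(sDistances(cs), "clusters_S")
    tsv(sStarDistances(cs), "clusters_Sstar")
    q <- neighborEditingProbability(siteTable, transcripts, ctrl,
                                    alpha = 0.01)
    tsv(q$table, "clusters_neighbor_probability")
    ctrlS <- lapply(ctrl, function(s)
      computeDistances(s, maxS = thr$maxS))
    ksOut <- compareSDistributions(
      sDistances(cs)$S, lapply(ctrlS, function(x) sDistances(x)$S))
    tsv(ksOut$curve, "clusters_S_quantile_curve")
    list(dc = dc, elByCategory = el, window = q$window,
         ks = list(D = unname(ksOut$ks$statistic),
                   p = ksOut$ks$p.value,
                   divergenceS = ksOut$divergenceS))
  })
  runStage("structure", "profiles", function() {
    if (is.null(profiles)) stop("no pairing profiles available")
    avg <- averageProfileAroundSites(profiles, siteTable, halfwidth = 100L)
    band <- estimateNoiseBand(profiles, siteTable,
                              minDist = thr$noiseDist)
    width <- estimatePeakWidth(avg, band)
    tsv(avg, "structure_average_profile")
    svc <- siteVsNearestControl(siteTable, profiles, transcripts)
    tsv(svc$pairs, "structure_site_vs_control")
    list(band = band, peakWidth = width, siteVsControlP = svc$p)
  })
  runStage("direction", "reads", function() {
    ee <- densePairs(siteTable)
    asym <- aaElDifference(ee)
    rec <- recodingAsymmetry(ee, transcripts, siteTable)
    ord <- inferEditingOrder(reads, siteTable,
                             maxS = min(thr$maxS, 100L),
                             minPairReads = thr$minPairReads)
    tsv(ord$pairs, "direction_order_scores")
    out <- list(nEE = nrow(ee), elAsymmetry = asym[c("meanDiff", "p")],
                recoding = rec[c("k", "n", "p0", "p")],
                order = list(S1 = ord$S1, SgT1 = ord$SgT1))
    if (!is.null(profiles)) {
      trios <- matchStructuralControls(ee, siteTable, transcripts,
                                       window = thr$controlWindow)
      if (nrow(trios) >= 2L) {
        bpp <- compareBppPositions(trios, profiles)
        tsv(bpp, "direction_bpp_comparisons")
        out$bpp <- bpp
      }
    }
    out
  })
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  writeLines(logLines, logFile)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
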