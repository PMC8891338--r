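# Editing-driven variance decomposition of transcriptome / proteome
# diversity: per-site variance f^A f^I, gated per-pair covariance
# f_AA f_II - f_AI f_IA, their sum under the variance-of-sum convention,
# and the population-genetic equivalents.

#' Variance generated by a single editing site
#'
#' v = f^A f^I, the Bernoulli variance of the site's editing state.
#'
#' @param fA,fI adenine / inosine state frequencies, summing to 1.
#' @return numeric in [0, 0.25].
#' @export
siteVariance <- function(fA, fI) {
  if (any(abs(fA + fI - 1) > 1e-9)) stop("fA + fI must equal 1")
  fA * fI
}

#' Gated covariance of an editing-site pair
#'
#' c = f_AA f_II - f_AI f_IA, retained only when the pair's 2x2 tally
#' table rejects independence by Fisher's exact test at the supplied
#' (already corrected) level; otherwise set to zero. Uninformative pairs
#' are zero by definition.
#'
#' @param c a \code{PairCounts}.
#' @param alpha the per-pair significance gate (pass the Bonferroni-
#'   corrected level, e.g. 0.05 / n_pairs).
#' @return the covariance, or 0 when gated out.
#' @export
pairCovarianceGated <- function(c, alpha = 0.05) {
  n <- pairTallies(c)
  tot <- sum(n)
  if (tot == 0L || !c@informative) return(0)
  p <- fisher.test(matrix(as.integer(n), nrow = 2L, byrow = TRUE))$p.value
  if (p > alpha) return(0)
  f <- n / tot
  unname(f["nAA"] * f["nII"] - f["nAI"] * f["nIA"])
}

#' Net variance generated by editing, with covariance fraction
#'
#' net = sum_i v_i + 2 sum_(i<j) c_ij over the retained (gated)
#' covariances; pairs are restricted to within-read-length distances, the
#' only ones with measurable covariance. Proteome mode restricts sites and
#' pairs to recoding (nonsynonymous) sites.
#'
#' @param siteTable a \code{SiteTable} with ELs (used for v_i = EL(1-EL)).
#' @param reads a \code{ReadMatrix} for the pairwise tallies.
#' @param mode \code{"transcriptome"} or \code{"proteome"}.
#' @param maxS maximum pair distance (default 100, a typical read length).
#' @param alpha family-wise level of the covariance gate; the Bonferroni
#'   family is the number of tested pairs. \code{gate = "none"} disables
#'   gating (every covariance retained), used for exact brute-force
#'   cross-checks.
#' @param gate \code{"fisher"} or \code{"none"}.
#' @param minPairReads minimum informative reads per pair.
#' @return list of class \code{DiversityComponents}: per-site variances,
#'   per-pair covariances, \code{netVariance}, \code{covarianceFraction},
#'   \code{mode}, and counts of gated / retained pairs.
#' @export
netEditingVariance <- function(siteTable, reads, mode = c("transcriptome",
                                                          "proteome"),
                               maxS = 100L, alpha = 0.05,
                               gate = c("fisher", "none"),
                               minPairReads = 10L) {
  mode <- match.arg(mode); gate <- match.arg(gate)
  st <- sites(siteTable)
  st <- st[!is.na(st$el), , drop = FALSE]
  if (mode == "proteome")
    st <- st[!is.na(st$recoding) & st$recoding == "nonsynonymous", ,
             drop = FALSE]
  v <- if (nrow(st)) siteVariance(1 - st$el, st$el) else numeric()
  prs <- .sitePairs(st, maxS)
  nPairs <- nrow(prs)
  covs <- numeric(nPairs)
  retained <- logical(nPairs)
  if (nPairs > 0L) {
    alphaPair <- if (gate == "fisher") alpha / nPairs else Inf
    for (k in seq_len(nPairs)) {
      pc <- countPairStates(reads, prs$transcript[k], prs$i[k], prs$j[k],
                            minPairReads = minPairReads)
      if (gate == "none") {
        f <- pairFrequencies(pc)
        covs[k] <- if (anyNA(f)) 0 else
          unname(f["fAA"] * f["fII"] - f["fAI"] * f["fIA"])
        retained[k] <- sum(pairTallies(pc)) > 0L
      } else {
        covs[k] <- pairCovarianceGated(pc, alpha = alphaPair)
        retained[k] <- covs[k] != 0
      }
    }
  }
  net <- sum(v) + 2 * sum(covs)
  out <- list(siteVariances = v, pairCovariances = covs, pairs = prs,
              netVariance = net,
              covarianceFraction = if (net > 0) 2 * sum(covs) / net
                                   else NA_real_,
              mode = mode, nPairs = nPairs, nRetained = sum(retained))
  class(out) <- "DiversityComponents"
  out
}

#' @export
print.DiversityComponents <- function(x, ...) {
  cat(sprintf(
    "DiversityComponents (%s): %d sites, net variance %.4g, %.1f%% from covariance (%d/%d pairs retained)\n",
    x$mode, length(x$siteVariances), x$netVariance,
    100 * x$covarianceFraction, x$nRetained, x$nPairs))
  invisible(x)
}

#' Equivalent number of biallelic polymorphisms
#'
#' The number of additive two-allele diploid loci at allele frequency 0.5
#' without dominance whose genotypic variance matches the supplied net
#' editing variance. One such locus (genotype values 0, 1/2, 1 under
#' Hardy-Weinberg) contributes 2pq a^2 = 0.125.
#'
#' @param vTotal net variance.
#' @return integer count.
#' @export
equivalentPolymorphisms <- function(vTotal) {
  if (any(vTotal < 0)) stop("variance must be non-negative")
  as.integer(round(vTotal / 0.125))
}

#' Decimal exponent of the number of transcriptome editing states
#'
#' n independently editable genes yield 2^n transcriptome states; this
#' returns floor(n log10 2), the exponent of the decimal magnitude.
#'
#' @param nEditedGenes number of edited genes.
#' @return integer exponent.
#' @export
transcriptomeStatesExponent <- function(nEditedGenes) {
  if (any(nEditedGenes < 0)) stop("gene count must be non-negative")
  as.integer(floor(nEditedGenes * log10(2)))
}
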