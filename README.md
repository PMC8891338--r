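# editClust

Statistical machinery for characterizing adenosine-to-inosine (A-to-I)
mRNA editing sites along transcripts, aimed at transcriptomes where
editing is pervasive enough — as in coleoid cephalopods — for *pairs* of
editing sites to carry signal: read-level co-editing, cluster structure at
three scales, the contribution of editing to transcriptome/proteome
diversity, and the 3′-to-5′ directionality of editing.

It is written for computational biologists who have (a) transcript
sequences, (b) an editing-site table with per-site coverage and G-counts,
(c) reads mapped to transcript coordinates, and optionally (d)
RNAplfold-style pairing-probability profiles — or nobody's data at all:
the package ships a fully seeded synthetic-data generator that emulates
clustered, correlated, directional editing with known ground truth, and
every analysis is validated against it.

## The statistics at the core

For an ordered pair of editing sites (i, j) at distance S = j − i, with
joint read-state frequencies f<sup>AA</sup>, f<sup>AI</sup>,
f<sup>IA</sup>, f<sup>II</sup> and marginals f<sup>A</sup>, f<sup>I</sup>:

* co-editing correlation (phi coefficient)
  r(E_i, E_j) = (f<sup>AA</sup>f<sup>II</sup> − f<sup>AI</sup>f<sup>IA</sup>) /
  √(f_i<sup>A</sup> f_i<sup>I</sup> f_j<sup>A</sup> f_j<sup>I</sup>)
* cooperativity ratio r′ = f<sup>II</sup> / (f_i<sup>I</sup> f_j<sup>I</sup>)
* editing level EL = g_count / coverage
* per-site variance v_i = f_i<sup>A</sup> f_i<sup>I</sup> and gated pair
  covariance c_ij = f<sup>AA</sup>f<sup>II</sup> − f<sup>AI</sup>f<sup>IA</sup>,
  combined as net variance Σv + 2Σc with the covariance fraction 2Σc/net
* order score d = (n[A_up I_down] − n[I_up A_down]) /
  (n[A_up I_down] + n[I_up A_down]) over single-edited reads
  (d > 0 ⇒ downstream edited first)

Around these: dense-cluster detection (maximal runs of consecutive edited
adenines) with context-preserving randomized controls, S/S* distance
tables, the neighbor-editing-probability window q(E) vs q0(E),
Kolmogorov–Smirnov comparison of real and control S distributions,
base-pairing profiles around sites (noise band, peak width, A–C mismatch
enrichment, site-vs-control comparisons), structural pair classification,
and EE/AE/EA/AA dinucleotide analyses of directionality. See the methods
vignette (`vignettes/editing-clusters.Rmd`) for the full model and the
design decisions.

## Worked example

```r
library(editClust)

cfg <- simConfig(seed = 7, nTranscripts = 20, lengthMean = 1500, lengthSd = 0,
                 lambdaL = 0, mediumRatePerKb = 2.5, offspringMean = 2,
                 interactionRadius = 10, pDense = 0.25, elFixed = 0.25,
                 delta = 0.15, meanDepth = 60)
sim <- simulateDataset(cfg)
sim$siteTable
#> SiteTable: 171 sites on 19 transcripts; median EL 0.250

## read-level co-editing falls off with distance
prof <- correlationProfileByDistance(sim$reads, sim$siteTable,
                                     maxS = 50, elMin = 0.05)
head(prof$summary[, c("S", "n", "mean", "median")], 3)
#>   S  n      mean    median
#> 1 1 17 0.3583861 0.3317432
#> 2 2 10 0.3001325 0.2962770
#> 3 3 14 0.2816213 0.2910003

## editing-driven variance decomposition
div <- netEditingVariance(sim$siteTable, sim$reads)
div
#> DiversityComponents (transcriptome): 163 sites, net variance 32.42,
#> 7.5% from covariance (10/229 pairs retained)
equivalentPolymorphisms(div$netVariance)
#> [1] 259

## dense clusters vs context-preserving randomized adenines
ctrl <- randomizeSites(sim$transcripts, sim$siteTable,
                       mode = "trinucleotide", nReps = 50, seed = 8)
dc <- dcOverrepresentation(sites(sim$siteTable), ctrl)
dc[dc$size %in% c("2", "total"), ]
#>    size real controlMean controlSd empiricalP
#> 1     2   11        0.84 0.7917947 0.01960784
#> 8 total   31        1.68 1.5835893 0.01960784

## editing order from read intermediate states
ord <- inferEditingOrder(sim$reads, sim$siteTable, maxS = 50)
ord$SgT1
#> n = 172 pairs, median d = 0.116, Wilcoxon p = 3.9e-05
```

The generator placed site pairs with a downstream-first bias
(delta = 0.15) and geometric dense-run extensions (pDense = 0.25); the
pipeline recovers all three signatures: correlation decaying from
r ≈ 0.36 at S = 1, dense clusters far above the randomized controls
(31 DC sites vs 1.7 ± 1.6 expected, empirical p = 0.02 at 50 replicates),
and a positive read-level order score.

`runPipeline(config)` (or `Rscript inst/scripts/edclust.R --config
run.yaml`) orchestrates all stages end to end, writing per-stage TSVs,
a JSON summary and a run log.

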