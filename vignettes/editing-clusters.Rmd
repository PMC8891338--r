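---
title: "Cluster structure, co-editing and directionality of A-to-I mRNA editing sites"
author: "editClust"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Cluster structure, co-editing and directionality of A-to-I editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editClust)
```

# The problem

Adenosine-to-inosine (A-to-I) editing substitutes A with I in mRNA; inosine
is read as guanosine by sequencers and ribosomes, so edited positions appear
as A-to-G mismatches in RNA-seq reads. In soft-bodied cephalopods
(octopus, squid, cuttlefish) editing is massive — up to 1% of transcript
adenines — which makes read-level statistics of *pairs* of editing sites
informative: one can ask whether two sites tend to be edited on the same
molecule, at what distances such coupling operates, and in which order the
edits occur. `editClust` implements this statistical machinery end to end
and ships a seeded synthetic-data generator so that every stage can be
validated against known ground truth without any external download.

# The statistics

**Editing level (EL).** For a site with `coverage` informative reads of
which `g_count` carry G, EL = g_count/coverage. Non-A/G calls at a site are
treated as missing, because every pairwise statistic below is defined over
the A and I states only.

**Read-level co-editing correlation r.** For an ordered site pair (i, j) on
one transcript, reads covering both positions are tallied into a 2x2 table
of joint states. With `f_AA, f_AI, f_IA, f_II` the joint frequencies and
`f^A, f^I` the marginals,

    r(E_i, E_j) = (f_AA f_II - f_AI f_IA) / sqrt(f_i^A f_i^I f_j^A f_j^I)

which is exactly the phi coefficient — the Pearson correlation of the two
binary per-read state vectors. The test suite asserts this equivalence on
every enumerable table of up to 12 reads. r is undefined (and the pair is
excluded, with a logged count) when any marginal is zero.

**Cooperativity ratio r'.** `r' = f_II / (f_i^I f_j^I)` compares the
observed co-editing frequency with its expectation under independence:
1 means independent, >1 cooperative, 0 mutually exclusive.

**Distances S and S*.** S is the nucleotide distance between any two
edited adenines on one transcript regardless of intervening sites; S* is
restricted to nearest neighbors (no edited adenine in between). Dense
clusters (DCs) are maximal runs of consecutive edited adenines (S = 1
chains); sites are categorized as DC, clustered (nearest edited neighbor
< 100 nt) or individual.

**Null models.** Controls are drawn per transcript by sampling the real
number of sites from the transcript's adenines, either uniformly or
stratified by the (-1, +1) flanking context of the real sites (16 strata;
the site base is always A). Per-transcript counts are preserved exactly in
every replicate, which the tests assert. Strata with too few eligible
adenines fall back to uniform sampling, with the event counted.

**Medium-range window.** Scanning downstream of each site, every adenine
at distance d before the first edited one is a trial and the first edited
adenine a success; q(E)[d] is the success fraction and q0(E)[d] the same
quantity on randomized controls. Each distance is tested with a
chi-squared contingency test at the 0.01 level, Bonferroni-corrected over
the scanned distances, and the reported window is the largest significant
prefix — the scale at which editing at one site directly raises the
editing probability of its neighbors.

**Long-range comparison.** The real and control S distributions are
compared with the two-sample Kolmogorov–Smirnov test, and a sorted-quantile
curve (real vs control order statistics) is drawn. The divergence range is
estimated in the density domain: per-bin real counts are compared against
the min–max envelope of the control replicates and the range is the upper
edge of the maximal contiguous prefix of bins whose real count exceeds the
envelope. Only the short-range *excess* counts as cluster signal: because
per-transcript site totals are preserved, the excess is compensated by a
thin deficit spread over the whole long-range tail, which a two-sided rule
would misread as divergence far beyond the cluster scale.

**Diversity decomposition.** Each site contributes variance
`v_i = f_i^A f_i^I`; each pair contributes covariance
`c_ij = f_AA f_II - f_AI f_IA`, retained only when the pair's table
rejects independence by Fisher's exact test at a Bonferroni-corrected
level (the gate is configurable, including `gate = "none"` for exact
brute-force cross-checks). The net variance is `sum v_i + 2 sum c_ij`
(the standard variance-of-a-sum convention; pairs enter once and are
doubled), and the covariance fraction is `2 sum c / net`. Proteome mode
restricts sites and pairs to recoding (nonsynonymous) sites, counting
each site once. Two population-genetic equivalents are provided: the
number of additive biallelic loci at p = 0.5 matching a given variance
(per-locus variance 2pq a^2 = 0.125 for genotype values 0, 1/2, 1), and
the decimal exponent `floor(n log10 2)` of the 2^n editable-gene state
count.

**Directionality.** For paired edited adenines (EE dinucleotides) the
package reports the EL difference downstream minus upstream (Wilcoxon
signed-rank, stratified by the upstream codon offset), the
background-normalized recoding asymmetry, structural comparisons against
matched AA/AE/EA control dinucleotides within a ±20 nt window (strict
mode requires all three classes; an any-available mode is provided), and
the read-level order score

    d = (n[A_up I_down] - n[I_up A_down]) / (n[A_up I_down] + n[I_up A_down])

over reads with exactly one of the pair edited; d > 0 means the
downstream site tends to be edited first. d is antisymmetric under
orientation swap, and the aggregate one-sample Wilcoxon against 0 is
reported separately for S = 1 and S > 1. The recoding-asymmetry null
uses the positional recoding propensities (pu, pd) of non-edited AA
dinucleotides: among EE pairs where exactly one position is recoding,
the probability that it is the downstream one is tested against
`p0 = pd(1-pu) / (pd(1-pu) + pu(1-pd))` with a binomial test. This is
the most direct reading of "accounting for the background"; a stratified
permutation alternative would condition on more context but needs far
more data.

# The synthetic-data generator

The generator (`simConfig()`, `simulateDataset()`) defines the study
conditions under which the pipeline is validated. All of its randomness
flows from a single mandatory seed; the same configuration reproduces its
output exactly.

**Site placement** is a nested Neyman–Scott process, the minimal
generative model with the three observed scales:

* long-range parents: Poisson with rate `lambdaL` per kb; each spawns
  `clustersPerParent` (Poisson, min 1) medium-cluster centers spread
  N(0, `sigmaL`), default 150 nt, so long-range structure lives at the
  ~2 sigma ≈ 300 nt scale;
* medium clusters: chains of `offspringMean` sites whose successive gaps
  are uniform on {1..`interactionRadius`} nt (default 18), snapped to the
  nearest adenine — the interaction window is therefore a direct generator
  parameter and the neighbor-probability analysis should recover it;
* dense runs: each placed site extends into the next consecutive adenine
  with probability `pDense`, geometrically.

Setting `lambdaL = 0` removes the long-range layer and places
medium-cluster centers uniformly at `mediumRatePerKb`; with
`offspringMean = 1` and `pDense = 0` this is the null layout whose S
distribution is indistinguishable from the randomized controls (a literal
zero parent rate would place no sites at all, so this reading keeps the
null configuration usable).

**Read simulation** draws, per read, a latent Gaussian Markov chain along
the transcript's sites: the step correlation between chain-adjacent sites
at gap d targets a phi of `rTarget * exp(-(d-1)/decayScale)` and is zero
across cluster boundaries. In the default calibrated mode, the latent step
correlation is obtained by inverting the Gaussian copula: the bivariate
orthant probability is computed by one-dimensional quadrature of
`dnorm(x) * pnorm((b - rho x)/sqrt(1-rho^2))` and the inversion solved
with `uniroot`, memoized on a rounded (target, EL, EL) grid (0.005
resolution, far below read-sampling noise). The latent correlation is
capped at 0.999 when the target phi is unattainable for the pair's
marginals — for very unequal ELs the maximum achievable phi is well below
1, which is why the correlation-recovery condition uses homogeneous ELs
(`elFixed = 0.3`); with Beta-distributed ELs the average realized phi is
necessarily attenuated. Latent states are thresholded at `qnorm(EL)`, so
marginal ELs are exact by construction. The alternative `latent` coupling
mode fixes the latent correlation instead, so realized phi is higher for
balanced (higher-EL) pairs — used to emulate EL-dependent coupling.

**Directional bias.** With `delta > 0`, for each of a set of disjoint
consecutive within-cluster site pairs (greedy 1–2, 3–4, ... pairing of
each chain; disjointness keeps a read's states consistent when pairs
share no site), every read with exactly one of the pair edited has its
orientation redrawn: the edited site is the downstream one with
probability 0.5 + delta. This simultaneously produces the positive order
score and the downstream EL excess, as both follow from the same
intermediate-state asymmetry.

**Structure profiles.** Background pairing probabilities are iid uniform
in `noiseBand` (default 0.25–0.35). Each site adds a Gaussian bump of
height `bumpHeight` whose sd is chosen as
`bumpWidth / (2 sqrt(2 log(bumpHeight/halfBand)))`, so the nominal
above-band width of the bump equals `bumpWidth`; the site position itself
is depressed by `dipDepth` (edited adenines sit in loops/bulges flanked by
helices).

**What the generator does not emulate.** Sequencing errors at non-site
positions, splicing and intronic structure, quality scores, indels,
inosine-specific base-pairing energetics, and any mechanistic coupling
between editing and structure — co-editing is generated phenomenologically
through the copula, not through refolding. Passing recovery tests
therefore shows that the estimators measure what they claim on data with
the assumed correlation structure, not that real transcriptomes follow
that structure.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| minCoverage | 10 | reads | EL defined only at this coverage |
| minPairReads | 10 | reads | pair informative only at this tally |
| EL filters | 0 / 0.05 / 0.10 | — | pair-level EL threshold (both sites) |
| category cutoff | 100 | nt | clustered vs individual |
| interactionRadius | 18 | nt | generator chain gap / expected q(E) window |
| noise distance | 200 | nt | background band for profiles |
| control window | 20 | nt | EE control-trio search half-width |
| maxS | 1000 | nt | cap on the all-pairs S table |
| alpha | 0.05 (0.01 for q(E)) | — | per-analysis family-wise level |

Multiple-testing families are always per analysis (one figure-equivalent),
never global across a run: the S-bin family for EL correlations, the
scanned-distance family for q(E), the occupied-bin family for the
structure-stratified cooperativity, the seven comparisons of the
base-pairing matrix.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere; transcripts are
  sense-strand.
* SAM ingestion accepts only single-run `nM` CIGARs (clipping or indels
  over a site would need realignment); skipped records are counted.
* The EL filter applies to both members of a pair.
* Fisher gating of covariances uses alpha/n_pairs; "stringent" is
  deliberately conservative and the gate is configurable.
* The peak-width estimator bridges the central dip (up to 5 nt) when both
  flanks are above the band, since the biological peak contains the dip;
  a no-bridge mode exists.
* Odds ratios use the Haldane 0.5 correction only when a margin is zero;
  the exact p is unaffected.
* "Close due to structure" requires an above-band run of >= 5 nt with a
  consistent (stepwise ±1) partner mapping between the sites that brings
  them within 20 nt along the structure; both knobs are configurable, as
  the underlying definition is not fully recoverable from published
  descriptions.
* The editing-order estimator is the minimal read-intermediate-state
  score; it chains only pairwise evidence and does not reconstruct
  multi-site paths per read beyond pairs at S = 1 and S > 1.
* The pipeline exposes one pooled dataset per run; per-sample ELs are not
  distinguished downstream.
* A desk-scale structural scorer (`naivePairingScore`: Nussinov pair
  counting, minimum loop 3, GU allowed, Z-scores against
  Altschul–Erickson dinucleotide shuffles) is provided for inputs without
  thermodynamic-folding output; it is a screening tool, not a
  replacement for plfold-style probabilities.

# Validation problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to give stable statistics while keeping a full run in the order of
a minute: correlation recovery uses 16 transcripts x 500 nt at depth
10^4 (phi standard error ~0.01 per pair); the window and enrichment
analyses use 20–40 transcripts x 2 kb with 40–199 control replicates; the
directionality power condition uses ~500 biased pairs at depth 50; null
calibration uses 100 seeded replicates of small null generators. These
are the package's validation conditions; all of them are plain
configuration and scale up directly.

# Known limitations

Exact inversion of the copula is per adjacent pair; correlations between
non-adjacent sites decay as products of step correlations, so only the
adjacent-pair phi is calibrated exactly. The divergence-range estimate
depends on the control envelope (min–max across replicates) and therefore
on the number of replicates. The recoding-asymmetry background assumes AA
dinucleotides far from editing sites are representative of the pre-editing
state of EE pairs. Exon-aware analysis is supported through interval
annotation, but no splicing is simulated, so exon-restricted runs are only
validated on single-exon data. The aggregate order-score test treats pairs
as independent; pairs sharing a site are pseudo-replicates, and with
strongly heterogeneous ELs the relative-difference form of d makes the
aggregate wander more than the Wilcoxon null assumes — its null
calibration is therefore verified under homogeneous ELs, and on real data
the S = 1 and S > 1 scopes should be read as effect estimates with the
p-value as a guide rather than an exact size guarantee.
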