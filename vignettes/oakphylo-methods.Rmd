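---
title: "Models and methods behind oakphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oakphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oakphylo` packages the complete analysis chain used in microsatellite
phylogeography of Andean montane trees — marker quality control, diversity
statistics, hierarchical structure and phylogeographic permutation tests,
spatially aware ancestry estimation, coalescent-based demographic inference,
and landscape-connectivity analysis — together with a synthetic-data module
so that every stage can be exercised and verified offline.  This vignette
explains the models, the tunable parameters, the numerical choices, and what
the test suite does and does not establish.

## Data model

Genotype tables hold one row per individual and `ploidy` allele-size columns
per locus.  Nuclear microsatellites (nSSR) are diploid; chloroplast
microsatellites (cpSSR) are haploid, maternally inherited and fully linked,
so the unit of cpSSR analysis is the multilocus haplotype.  A missing allele
copy is the reserved negative sentinel `-9`; every statistic skips missing
copies and renormalises its denominators.  Individuals with more missing
loci than a threshold (default 1) are dropped by `filter_missing()`,
mirroring common practice for multiplexed fragment data.

Inter-haplotype distance is Manhattan distance in motif units — the number
of single-repeat mutation steps separating two haplotypes under the
stepwise mutation model (SMM).  For mononucleotide cpSSR motifs this equals
the base-pair difference.  This one metric feeds the ordered diversity *v*,
the NST test and the haplotype network, which keeps those analyses mutually
consistent.

A haplotype is called *unique* when it occurs in exactly one sampling
location, regardless of count.

## Diversity statistics

For one location with allele (or haplotype) counts `n_i`, total `n`:

* `h = n/(n-1) (1 - sum p_i^2)` — unbiased gene diversity, unordered.
* `v = n/(n-1) sum_{i != j} p_i p_j D_ij` — nonstandardized ordered
  diversity; with a 0/1 distance matrix `v` reduces to `h` exactly, a
  degeneracy the tests assert.
* `AR(g) = sum_i [1 - C(n - n_i, g)/C(n, g)]` — rarefied richness, the
  hypergeometric expectation of distinct alleles among `g` copies.  The
  default `g` is the smallest complete per-location gene-copy count; the
  source literature rarely states this choice, so it is exposed as a
  parameter.
* `uHe = 2n/(2n-1) (1 - sum p_i^2)` and `Ho` (fraction of heterozygous
  genotypes) for diploid data; `Ae = 1/sum p_i^2`.

Means across locations are unweighted with `SE = sd/sqrt(n_locations)`.
Private alleles are counted at both the location and the region level.

All four estimator families are verified against brute-force enumeration
(direct averaging over all pairs of gene copies; all subsamples for
rarefaction) on every allele-count vector with `n <= 8`.

## Marker quality control

Permutation p-values use the add-one rule `p = (1 + #{perm >= obs}) /
(1 + n_perm)`, so no test ever reports exactly zero.  The Hardy–Weinberg
test statistic is the heterozygote deficit `uHe - Ho` with gene copies
shuffled among individuals within a location; the linkage test uses the
log-likelihood-ratio G statistic on the two-locus genotype table with one
locus permuted.  No multiple-testing correction is applied by default (a
Bonferroni column is available), matching how such scans are usually
reported.

Null alleles are estimated by an EM algorithm in which a latent null allele
segregates under Hardy–Weinberg proportions: observed homozygotes for
allele *i* are a mixture of true `i/i` genotypes and `i/null`
heterozygotes, and (optionally) fully blank genotypes are `null/null`.
Convergence is declared when the largest frequency change drops below
`1e-8` (cap 10,000 iterations).

FST is the Weir–Cockerham ratio-of-sums estimator over loci and alleles.
The ENA-style correction re-estimates visible allele frequencies per locus
and location with the EM, excludes the null allele, renormalises, and
computes theta from the corrected frequencies with heterozygosity at its
Hardy–Weinberg expectation.  Confidence intervals bootstrap loci
(percentile, 95%).  As simulated null-allele frequency goes to zero the two
routes converge, which the tests check.

## AMOVA and phylogeographic tests

AMOVA decomposes sums of squared inter-unit distances hierarchically
(among regions, among locations within regions, within locations).  Units
are gene copies per locus for diploid data (components summed across loci)
and multilocus haplotypes for cpSSR.  Squared distances are 0/1 allele
identity under the infinite-allele model (IAM) and squared size differences
in motif units under the SMM.  Negative variance components are retained —
not truncated — and flagged; percentages are computed on the raw
components, which matches the convention of the standard AMOVA software.  Permutation nulls: individuals among
locations (Phi_ST), individuals among locations within regions (Phi_SC),
whole locations among regions (Phi_CT).  The implementation computes sums
of squares from group aggregation identities; the test oracle recomputes a
12-copy toy directly from the N x N squared-distance matrix definition and
requires agreement to 1e-10.

NST and GST follow the ordered/unordered diversity construction: `vS` is
the unweighted mean within-location *v*; `vT` is *v* on unweighted mean
haplotype frequencies with the total-sample factor `N/(N-1)`; the statistic
is `(vT - vS)/vT`.  GST is defined as NST with the 0/1 matrix, which makes
the degeneracy identity exact by construction.  pNST permutes haplotype
identities in the distance matrix; a significant excess of NST over pNST
means related haplotypes co-occur — phylogeographic structure.  RST is
Phi_ST from the SMM AMOVA; its null permutes the assignment of observed
sizes to allelic states within each locus (pRST), and pRST approximates
FST.  Both tests are invariant to uniform scaling of the distance matrix.

The haplotype network is Kruskal's algorithm with ties retained: within a
weight class, every edge joining components that were distinct when the
class opened is kept, so all equally parsimonious connections survive;
edges a strict minimum spanning tree would drop are flagged.  The edge set
always contains an MST and its optimal weight, which the tests verify
against an independent MST routine.

## Spatially regularized ancestry

The encoded genotype matrix `X` (entries 0, 1/2, 1 per allele column; rows
sum to 1 within each locus block; missing loci masked) is factorized as
`Q G` with `Q` rows on the probability simplex and `G` in [0, 1],
minimising

```
|| M o (X - Q G) ||^2 + lambda * tr(Q' L Q)
```

where `L` is the *normalized* graph Laplacian of the heat-kernel similarity
`W_ij = exp(-(d_ij / sigma)^2)`, `d_ij` great-circle distance and `sigma`
the mean pairwise distance.  Two numerical choices matter:

* **Normalized Laplacian.**  With the raw Laplacian the penalty grows like
  `n^2` against a data term of order `n * p`; at `lambda = 1` it
  overwhelms the likelihood and erases genuine structure.  The normalized
  form keeps the penalty `O(n)`, making `lambda = 1` a mild default.  Both
  `sigma` and `lambda` are exposed.
* **Optimization.**  Block projected-gradient descent with conservative
  Lipschitz step sizes; the objective is asserted nonincreasing at every
  sweep, and `Q` starts from k-means on the zero-filled encoding (random
  fallback), which empirically lands in the basin of the population
  structure and cuts fitting time roughly eight-fold.

Cross-validation (`select_k`) masks 5% of observed entries per replicate
and scores RMSE between `Q G` and the held-out truth.  "Lowest error
before the curve plateaus" is operationalized as: the smallest K whose
median error is within one standard error of the global minimum median.

A note on statistical power: with 10 microsatellite loci at FST 0.15 the
*optimum* of the least-squares objective has mean max-ancestry around
0.78 — the blending is information-limited, not a solver failure.  The
recovery tests therefore simulate 50 loci, where the optimum is sharp;
conclusions about the solver transfer, conclusions about 10-locus datasets
do not.

## Coalescent simulator and ABC

The simulator is a single-population Kingman coalescent with
piecewise-constant effective size: `k` lineages coalesce at rate
`k(k-1)/(4N)` per generation, so a pair has expected TMRCA `2N` and, with
`theta = 4 N mu`, equilibrium heterozygosity `1 - 1/sqrt(1 + 2 theta)`
(Ohta–Kimura) — the simulator's primary oracle, checked to within 0.03 at
`theta = 4` over 2,000 loci.  Mutations are strict single-step: the count
on a branch is Poisson(`mu * length`) and the net displacement is sampled
as `2 * Binomial(m, 1/2) - m`, which is exactly equivalent to simulating
individual steps and is what makes 100,000-row reference tables affordable.
Chloroplast loci share one genealogy (`linked = TRUE`); nuclear loci draw
independent genealogies.  The ancestral allele size is fixed at 100 motif
units; all summary statistics are translation invariant.

Three demographic scenarios are compared on the pooled nuclear sample:
(1) constant size; (2) expansion, implemented as a single stepwise size
change (the standard discretisation of a progressive expansion — an
exponential ramp is deliberately not the default); (3) bottleneck followed
by expansion, with the bottleneck size constrained below both the current
and ancestral sizes.  Default priors are deliberately broad surrogates: Ne log-uniform on
[1e2, 1e6], event times uniform on [10, 10000] generations, per-locus
mutation rate log-uniform on [1e-4, 1e-3].  A generation time of 100 years
converts times to years.

Summary statistics are the mean and variance across loci of allele count,
unbiased expected heterozygosity, allele-size variance (denominator `n`)
and Garza–Williamson `M = A/(range + 1)`.  Distances are Euclidean on
MAD-standardized statistics.  Scenario choice reports both the direct
rejection estimate (scenario frequencies among the `n_closest_direct`
nearest rows; default 500, mirroring DIYABC's count at its 3-million-row
scale) and an Epanechnikov-weighted multinomial logistic regression over
the closest `tolerance` fraction (default 1%), evaluated at the observed
point; optional bootstrap over retained rows gives CIs.  At desk scale the
direct estimate is sensitive to the retained *fraction*: 500 of 100k is a
30-fold looser neighborhood than 500 of 3M, and the acceptance test keeps
the fraction comparable (30 of 100k) rather than the count.

Parameter estimation is Beaumont local-linear regression adjustment with
Epanechnikov weights, performed on log-transformed parameters (all are
positive and heavy-tailed; raw-scale adjustment measurably undercovers)
and back-transformed for reporting.  `tolerance >= 1` disables
conditioning entirely and returns the prior sample — the no-data limit.
Calibration is verified by pseudo-observed coverage: 90% credible
intervals for the bottleneck time cover the truth for 0.85–0.95 of 50
pods drawn from the prior.

Not every "x100 bottleneck" is detectable, and the recovery test's pod is
chosen to be one that is: if the bottleneck is long relative to `2 N_bot`
every lineage coalesces inside it and the data are mathematically
indistinguishable from the expansion scenario; if it is much shorter, from
the constant scenario.  The test pod (Ne 50000 -> 500 -> 50000, events at
300 and 1000 generations, locus rates from the informative upper half of
the mutation prior) has intensity ~0.7, where deep lineages survive and
the Garza-M/heterozygosity signature exists.

Scenario-confidence error rates (posterior error over the closest rows;
type I and type II for a focal scenario over prior-drawn pods) re-run
scenario choice with each pod's row excluded from the reference.  The
logistic variant refits per pod and is opt-in; at full field scale
(1,000 pods against 3 million rows) this is a batch job, and the tests
exercise the machinery on controlled toys where the answers are knowable:
fully separable scenarios give zero error, identical scenarios give type I
near 2/3.

## Landscape connectivity

Rasters are plain matrices with ESRI ASCII grid I/O (row 1 = north).  The
processing chain per period: rescale a 0–1 suitability model around a
logistic threshold (`v < thr -> 100 v / thr`, else 100); compute the
topographic ruggedness index `TRI = sqrt(sum over 8 neighbours
(z_c - z_n)^2)` (available neighbours at edges; nodata excluded); classify
TRI into 10 Fisher–Jenks natural breaks mapped linearly to suitability
100, 90, ..., 10 (the flattest class is best — the mapping is a documented
surrogate, as is the equal-weight arithmetic mean that combines the two
layers, since the upstream tooling leaves both unstated); threshold the
combined habitat at 50 on the 0–100 scale (habitat tools state the per-pixel
threshold of 0.5 on the 0–1 scale); extract 8-connected patches;
build the least-cost graph (move cost = mean of the two cells'
resistances x cell size, x sqrt(2) diagonally, resistance = 101 - habitat
so costs stay positive); and compute the equivalent connectivity area

```
ECA = sqrt( sum_i sum_j a_i a_j p*_ij ),   p*_ij = exp(-alpha d*_ij)
```

with `alpha = -ln(p_ref)/d_ref` (defaults: dispersal probability 0.5 at
the cost equivalent of 1 km at minimum resistance) and `d*` the shortest
path through the patch graph — the max-product convention; a
`direct_only` flag gives the single-edge variant.  Least-cost distances
use one Dijkstra per patch from a zero-cost virtual source on a directed
graph, so routes cannot teleport through another patch's virtual node;
distances above the cost threshold (default 100,000) count as
unreachable.  ECA always lies between `sqrt(sum a_i^2)` and `sum a_i`,
never decreases when links are added or shortened, and the Dijkstra core
is checked against exhaustive path enumeration on small grids.

Fisher–Jenks is exact dynamic programming on up to `max_values = 4000`
points; larger inputs are reduced by a deterministic quantile subsample, a
standard cartographic compromise.

## Synthetic data: what it does and does not emulate

`simulate_dataset()` reproduces the *statistical design* of a northern-Andes
oak study system: 22 sampling locations of 5–13 individuals along three linear
cordilleras, 10 diploid nSSR and 9 linked haploid cpSSR loci, a
bottleneck-then-expansion history, and a target among-deme FST (default
0.07, the nuclear estimate) implemented by Balding–Nichols Dirichlet draws
around a coalescent ancestral pool — fast, and adequate for estimator
recovery tests; it is not a spatially explicit migration model, so it does
not emulate isolation-by-distance gradients, clinal cpSSR sorting, null
alleles or genotyping dropout.  `simulate_landscape()` produces a ridge
DEM and logistic elevation-band suitability whose width grows per period,
so habitat area and ECA increase monotonically — the qualitative
glacial-to-present trend — without pretending to be Andean topography.
A green test therefore establishes that the estimators and the pipeline
are correct on data satisfying their assumptions, not that any particular
field dataset's values are reproduced; real-data replication requires the
archived genotypes, an external download.

## Known limitations

* Rejection-based direct scenario probabilities are scale-sensitive; at
  desk scale prefer the logistic estimate (the two agree for reference tables in the
  millions of rows).
* The INEST-style joint Bayesian model of inbreeding and null alleles is
  replaced by EM null-allele estimates plus Weir–Cockerham FIS, so a
  jointly-estimated inbreeding coefficient is not reported.
* The haplotype network retains ties but does not infer unobserved median
  haplotypes (no median-joining search).
* GeoTIFF input is out of scope; rasters travel as ESRI ASCII grids.
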