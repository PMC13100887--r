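---
title: "Models and methods in hedgescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hedgescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgescape)
```

`hedgescape` asks a single scientific question in several statistical
forms: does the structure of an urban landscape — buildings, roads,
railways, rivers, greenspace — explain how genetically differentiated the
animals living in it are, better than plain geographic distance does? This
vignette documents the models behind each stage, the parameters that
matter, and the design decisions taken where the methodological literature
leaves a choice open.

## The genotype substrate and the filter chain

All genetic statistics operate on a `GenotypeMatrix`: individuals × biallelic
SNPs coded 0/1/2 (alternate-allele count) with `NA` for missing calls.
Reduced-representation SNP data (here, SNPs from the flanks of
ultraconserved elements) arrive as VCF with per-genotype depths and site
annotations, and are curated by `applyFilterChain()` in a fixed order:

1. genotype calls with depth < 5 are **masked** (set missing), the site kept;
2. sites with QUAL < 20 removed;
3. sites with mean depth across individuals < 10 removed;
4. sites with mapping quality < 30 removed;
5. sites with minor allele count < 3 removed — computed on the *masked*
   matrix, so depth-masked calls count as missing;
6. sites genotyped in < 95% of individuals removed;
7. non-biallelic sites removed;
8. one SNP per UCE locus retained, to avoid tightly linked markers.

Two levels are deliberate: depth failures are a property of a single call
(masking), while the other rules judge the site. The per-step survivor
report makes the chain auditable, and refiltering its own output changes
nothing (idempotence — a property the tests check). Missingness thresholds
are strict inequalities: an individual at exactly 20% missing data is
retained, one above it removed. The SNP-per-locus tie-break (highest call
rate, then lowest position) is a convention of this package; published
pipelines rarely state theirs.

Sample curation mirrors field reality: carcass collections cluster where
people find animals. `groupByLocation()` groups samples into candidate
populations by single-linkage clustering at 1 km (a chain of ≤ 1 km steps
joins a group — about a nightly movement range), and
`subsetOversampledSite()` thins an over-collected site to its most recent
samples while greedily excluding first-degree relatives (QG relatedness ≥
0.35 by default; the threshold is a configuration knob because any cutoff
on a continuous estimator is a judgement call).

## Population-genetic statistics

*Standardised heterozygosity.* Per individual, the heterozygous fraction of
its non-missing sites divided by the sample mean fraction, so `mean(Hs) = 1`
by construction; values below 1 flag relatively inbred or drift-affected
individuals.

*Ho, He, Fis.* He uses the unbiased small-sample correction
`2p(1−p)·2n/(2n−1)`; Fis = 1 − Ho/He. The correction matters at the n = 3–8
population sizes typical of opportunistic urban sampling.

*Rarefied allelic richness.* Sample-size bias is removed by rarefying to a
common number of **genes** (2 per diploid): the expected allele count in a
hypergeometric draw of g genes, `Ar = Σ_a [1 − C(N−N_a, g)/C(N, g)]`,
averaged over loci. "Rarefied to n = 3 individuals" therefore means g = 6
genes — the unit is stated explicitly because the two conventions are often
conflated.

*Weir–Cockerham θ.* The 1984 variance-component estimator (components a, b,
c per locus; ratio of sums over loci), which is unbiased under unequal
sample sizes — essential here. Confidence intervals are a seeded percentile
bootstrap over loci (1000 resamples by default); the resampling unit is the
locus because loci, not individuals, are exchangeable under the model.

*Queller–Goodnight relatedness.* Computed per pair with reference allele
frequencies from the sample **excluding the focal pair**, reciprocal
estimates averaged. The estimator is unbiased but noisy and its reference
frequencies matter: with few individuals it is negatively biased (the
package's pedigree tests use ≥ 30 founders for this reason). It is invariant
to locus order and to swapping which allele is called reference.

*Evanno ΔK.* Post-processing only: given replicate log-likelihoods from an
external Bayesian clustering program, ΔK(K) = |L(K+1) − 2L(K) + L(K−1)| /
sd(L(K) replicates), undefined at the boundary K values and wherever the
replicate sd is zero. The MCMC itself is out of scope.

*Moran's I.* Global and local, with row-standardised weights from k-nearest
neighbours (default k = 8) or a distance band; the scheme is configurable
because the choice is not standardised in the literature. Expectation
−1/(n−1), normal-approximation variance. The ±1 checkerboard under rook
weights gives I = −1 exactly (each row-standardised neighbour average is the
negative of the focal value), a closed form the tests pin down. Residual
Moran's I accompanies the Hs ~ urban-proportion regression because spatially
clustered sampling (one heavily monitored park, say) otherwise masquerades
as an urbanisation effect.

## Landscape: mosaics, hypotheses, resistance

Landcover arrives as per-class binary masks on a shared projected grid
(cells square, metres). `mosaicWithPrecedence()` assigns each cell the
highest-precedence covering class — buildings over gardens over lawns —
because urban features nest (a pond inside a park). Linear features
(roads, railways, waterways) are dilated by at least one cell
(`bufferLinearClass()`, chessboard metric) before mosaicking so
rasterisation cannot break them.

A `ResistanceHypothesis` maps classes to per-cell movement costs ≥ 1, with
an absolute-barrier set. Packaged hypotheses:

- `EMP` — empirical per-class resistances for urban hedgehogs derived from
  radiotracking literature (gardens/parks/cemeteries/allotments 1, amenity 6,
  lawns 5, small streets 8, impervious 13, paths 14, unclassified 15,
  large streets/highways/railways/linear water/wetland/woodland/farmland
  100, buildings and waterbodies barriers);
- `NULL` — isolation by distance: every traversable class has resistance 1.
  Buildings and waterbodies remain barriers under every hypothesis,
  including `NULL`; the distance-only model is "uniform cost over habitat",
  not "walk through walls". (Published treatments vary here; this package
  fixes the convention and states it.)
- single-landcover contrasts (`RAILCOR`, `FARMBAR`, …) set a focal class
  group to 1 or 100 and everything else to the opposite value — blunt by
  design, for asking whether one feature acts as corridor or barrier.

Barriers are non-traversable cells removed from the movement graph, not a
large finite cost; a `barrierResistance` option substitutes a finite value
for sensitivity checks.

## Connectivity: least-cost paths and random walks

`buildTransitionGraph()` converts a surface to a graph: one node per
traversable cell, edges between 8-neighbours (4 by option) with conductance
`((1/r_i + 1/r_j)/2)/d`, d the centre distance (so a uniform surface of
resistance r yields least-cost distance r × path length). Least-cost
distances are Dijkstra shortest paths with step cost 1/conductance; on an
open uniform grid they exceed straight-line distance by at most the octile
factor ≈ 1.083, which the tests bound.

Commute distance — the expected round-trip steps of the random walk —
comes from circuit theory: `C_ij = 2 · S · R_eff(i,j)` with S the total
edge conductance and effective resistance obtained from sparse solves
against a grounded graph Laplacian (one solve per source point; a dense
pseudoinverse oracle checks the implementation on every small graph).
Random walks require a connected graph, so a small conductance ε (default
1e-4) is added between every pair of adjacent traversable cells before
commute and passage computations only — never for least-cost paths, which
are well-defined on disconnected graphs (infinite distance, flagged). The
repair is applied to conductances, not to the resistance raster: it is a
graph-side regularisation and leaves least-cost structure untouched.
ε repair cannot reconnect habitat separated by true barriers;
`pruneIsolatedHabitat()` drops barrier-ringed pockets (keeping the largest
8-connected habitat component) for analyses that need a connected graph.

Passage maps inject a unit current per origin–destination pair and
aggregate, per cell, half the sum of absolute net edge flows from the
harmonic potential: 1 for every interior cell of a forced corridor, 0.5 per
branch for two equal alternatives, invariant to rescaling all conductances.
Net (not gross) flow is used because corridor mapping asks where movement
*must* pass, not how much local back-and-forth occurs; a gross-flow variant
would differ only by local diffusion noise.

Points snap to the nearest traversable cell centre within 3 cell widths by
default; a sample on a building footprint (GPS error, 1 km grid-reference
centroids) snaps to adjacent habitat, while a genuinely misplaced point
errors by name.

## MLPE model selection

Pairwise tables (one row per unordered pair) relate genetic distance —
Euclidean distance on genotype codes over shared loci, rescaled by
√(L/L_shared) so differently-missing pairs are comparable — to log
resistance distance (natural log; resistance distances are
positive-skewed), optionally with an untransformed Euclidean-distance
covariate to absorb plain isolation by distance.

Pairwise distances are not independent: two pairs sharing an individual are
correlated. The MLPE model handles this with one random effect per
individual, entering every pair it belongs to:

y_ab = Xβ + u_a + u_b + ε_ab,  u ~ N(0, τ²),  ε ~ N(0, σ²),

giving correlation ρ = τ²/(2τ² + σ²) ∈ [0, 0.5) between pairs sharing one
individual. The likelihood is profiled over λ = τ²/σ² (β and σ² have
closed-form generalised-least-squares/ML solutions given λ) and λ is
optimised numerically on the log scale, with the λ = 0 boundary checked
explicitly — at which point the model collapses *exactly* to ordinary least
squares, an identity the tests verify to 1e-6. Full maximum likelihood (not
REML) is used throughout because the compared models differ in their fixed
effects, and information criteria require it. The parameter count is
k = (fixed effects) + 2 variances; n is the number of pairs; AICc = AIC +
2k(k+1)/(n−k−1); R² is the squared correlation of fixed-effect predictions
with the response (a definition that must be stated, since "R²" is
ambiguous for mixed models). Pairs with infinite least-cost distance are
dropped from *all* models of a comparison so every fit shares one response.
Ties on AICc are broken by lower BIC — documented, arbitrary, and rare.

## The synthetic generators: what they emulate and what they do not

Every generator is a pure function of (parameters, seed); same seed, same
bytes.

*Island model* (`simulateIslandGenotypes`). Balding–Nichols: ancestral
frequencies Uniform(0.1, 0.9); population frequencies Beta with mean p and
variance F·p(1−p); genotypes Binomial(2, p_pop). The expected
Weir–Cockerham θ equals F, which makes it the calibration truth for the
Fst machinery (recovered within ±0.02 at 8 demes × 20 individuals × 2000
loci).

*Spatial model* (`simulateIbrGenotypes`). A logit-normal spatial process
rather than a coalescent simulation: per locus, site-level deviations on
the logit-frequency scale drawn from a zero-mean Gaussian with covariance
σ²·exp(−d_ij/φ) in commute distance on a truth surface, back-transformed
and clipped to [0.01, 0.99] (monomorphic loci are retained — filtering is
downstream's job). This is cheap, exact, and sufficient for what it must
support: distinguishing distance-driven from resistance-driven
differentiation. It does not emulate linkage, drift dynamics, range
expansion or temporal change, so passing tests say nothing about those.

*Pedigrees* (`simulatePedigreeGenotypes`). Founders Binomial(2, p);
offspring get one allele per parent by fair Mendelian transmission; clones
copy exactly. Expected QG relatedness is 1 (clones), 0.5 (parent–offspring
and full sibs), 0.25 (half sibs), 0 (founders) — the validation targets for
the relatedness code.

*VCF degradation* (`degradeToVcfRecords`). Adds Poisson per-genotype depths,
Gaussian site qualities and mapping qualities, and random missingness, with
per-site overrides so any single filter rule can be forced to fire. It
produces valid VCF via standard VCF tooling; it does not simulate reads.

### Chosen defaults, and why

The reference study conditions are ~70 individuals in 4–8 spatial clusters,
~1400 SNPs, ~5% missing calls, Fst targets 0.05–0.25 — desk-scale versions
of a realistic urban SNP dataset. Where a value had to be fixed by design:

- **Study landscape for selection experiments**
  (`ibrStudyLandscapeSpec()`): garden and woodland patches with building
  and impervious patches plus street/railway strips, 24 × 24 cells at 5 m.
  Woodland is the load-bearing choice: it is traversable under every
  hypothesis but expensive under the empirical one, so the candidate
  surfaces genuinely differ. On a gardens-and-buildings-only landscape the
  empirical and distance-only surfaces nearly coincide (buildings are
  barriers in both) and no method could — or should — tell them apart.
- **σ² = 1** on the logit scale: differentiation of roughly the magnitude
  of the island model's mid-range targets.
- **φ = 0.5 × median pairwise site commute distance**: the covariance
  decays appreciably across the sampled extent, neither flat (no signal)
  nor collapsed (independent sites).
- **5 clusters × 4 individuals** for the 20-individual experiments: enough
  between-cluster contrasts for the pairwise regression to have leverage.
- Simulation sizes throughout (2000-locus calibrations, 1000-locus
  pedigrees, 50-replicate operating characteristics) are chosen so the full
  validation suite runs in minutes on a laptop while keeping Monte Carlo
  error well inside the asserted tolerances.

## Numerical notes and degenerate inputs

- Frequencies are clipped to [0.01, 0.99] after back-transform; rarefaction
  uses `lchoose` to avoid overflow; Laplacian solves use sparse Cholesky
  factorisations; the commute ground node is arbitrary (the effective
  resistance is grounding-invariant).
- Constant responses, constant predictors, empty populations, individuals
  with no non-missing sites, pairs with no shared loci, points on barriers
  and disconnected graphs all raise explicit errors or flagged NAs — never
  silent NaN propagation.
- θ is undefined (flagged) when all variance components are zero; ΔK is
  undefined at boundary K and zero replicate sd; AICc is undefined when
  n ≤ k + 1.

## Known limitations

- The spatial genotype model is not a coalescent: no linkage, no ancestry,
  no temporal dynamics over multi-year sampling windows.
- Movement is isotropic and static: no traffic volumes, no behavioural
  avoidance, no seasonal change in resistance.
- Resistance values themselves are taken as given (literature-derived or
  hypothesis-driven); the package deliberately does not optimise per-class
  resistances against the genetic data.
- Analyses assume one shared projected CRS in metres; there is no
  reprojection, and no vector-GIS preprocessing of source geodata.
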