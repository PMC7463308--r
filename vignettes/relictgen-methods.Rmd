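---
title: "Models and methods behind relictgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind relictgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

relictgen is a pipeline for RAD-SNP phylogeography of fragmented,
range-restricted tree species: it takes a biallelic genotype matrix with a
sample-to-population-to-group map and site climate data, and carries the
analysis from locus filtering through diversity and AMOVA, coalescent ABC of
divergence and demographic history, FST outlier and environment-association
scans, generalized dissimilarity modelling (GDM), and gradient-forest (GF)
prediction of genomic vulnerability to future climate. This vignette explains
the models, the defaults and the numerical choices, and what the synthetic
data used by the test suite does and does not establish.

## Data model and filtering

Genotypes are stored as an individuals-by-loci integer matrix with entries
0/1/2 counting alternate-allele copies and `NA` for missing calls
(`snp_matrix()`). The alternate-allele orientation is taken from the input
file; all downstream statistics are invariant to swapping the labels, which
the tests verify. Each SNP carries the id of the RAD locus it came from, so
`one_snp_per_radlocus()` can thin to one SNP per locus (default: the first by
position, which is reproducible; a seeded random choice is available for
sensitivity checks).

Three filters mirror common RAD practice:

* `filter_within_pop_presence()` keeps a locus only if it is genotyped in at
  least `ceiling(min_frac * n_p)` individuals of every population
  (default 60%). "At least" means ties at the threshold are kept, and the
  rule counts genotyped individuals, not alleles.
* `filter_sample_coverage()` keeps loci called in at least `min_samples`
  individuals overall; running it at a ladder of thresholds (e.g. 85/120/160
  out of 171) produces nested "lenient/median/strict" matrices.
* `filter_maf()` removes loci whose minor-allele frequency, computed over
  observed alleles only, falls below the cutoff (default 1%; ties kept).

All filters are idempotent, commute with sample reordering, and only ever
shrink the locus set.

## Diversity and AMOVA

Per population (with at least `min_n = 5` individuals), `diversity()` reports
the mean per-SNP nucleotide diversity `pi` — the unbiased gene diversity
`2p(1-p) n/(n-1)` averaged over all loci genotyped in the population — and
the average expected/observed heterozygosities over the loci polymorphic
within that population. Because `pi` is a per-SNP mean (not per sequence
length), its absolute value depends on the ascertainment of the SNP panel;
only comparisons across populations of the same panel are meaningful.

`amova()` decomposes variance at the gene (allele) level: each diploid
contributes two genes, the distance between genes is the 0/1 allele
mismatch, and the sums of squared deviations then reduce to allele-frequency
algebra. Missing genotypes are dropped per locus; SSDs, degrees of freedom
and the coefficients of the expected mean squares are summed over loci
before components are formed (standard multi-locus practice). Permutation
schemes follow the hierarchy: individuals among populations for Phi_ST,
individuals among populations within groups for Phi_SC, and whole
populations among groups for Phi_CT, with
`p = (#{perm >= obs} + 1)/(n_perm + 1)`. Negative variance components are
reported as computed and flagged, not truncated, so Phi statistics match
what standard AMOVA software prints. The implementation is checked to 1e-10
against a brute-force oracle that enumerates all pairwise gene distances.

`pairwise_phist()` is the two-level AMOVA restricted to each pair; the
matrix feeds the GDM below (where negative entries are clamped to zero —
they are noise around no differentiation).

## Coalescent scenario simulation

`scenario_spec()` describes a demographic scenario declaratively: sampled
populations with diploid sample sizes, a current-size parameter per
population, and backward-in-time events (population merge, admixture —
each lineage of the admixed group goes to the first source with probability
`ra`, else to the second — and instantaneous size change), all referring to
named parameters with uniform priors and optional ordering constraints
(`t1 > t2`). Times are generations, sizes diploid effective sizes, and the
coalescent is continuous-time with piecewise-constant N; size changes are
instantaneous and there is no migration outside the admixture events.

Each locus is one SNP: an independent gene tree is simulated for the pooled
sample and a single mutation is placed uniformly on the total branch length.
Every branch subtends a proper subset of the sample, so every locus is
polymorphic in the pooled sample by construction — no rejection step is
needed, and there is no MAF condition by default (demographic inference is
run on an unfiltered matrix precisely to keep the rare-allele excess that
expansions produce). Genes are paired into diploids within populations;
because leaves are exchangeable, fixed pairing equals random pairing in
distribution. The simulator emits complete matrices; `mask_missing()`
overlays missingness when needed.

The inner loops draw their random numbers from a xoroshiro128+ generator
seeded from R's RNG at each call, so `set.seed()` still controls every
simulation exactly while millions of gene trees stay cheap. The simulator is
validated against a naive O(n^2) pure-R coalescent (site-frequency spectra
and mean heterozygosity) and against its analytic limits (panmixia,
deep divergence).

`builtin_scenarios()` returns the five three-group divergence scenarios
(S1 simultaneous split; S2–S4 the three bifurcating orders, S2 being
"Japan splits first, the central/east group buds from within the southwest
lineage"; S5 an admixed origin of the central/east group) with the published
uniform prior bounds and the `t1 > t2` restriction, and three one-population
demographic scenarios (expansion; expansion–shrinkage;
expansion–shrinkage–expansion). The published table only prints prior blocks
for the best-fitting demographic models, so the middle scenario reuses the
bounds of the shared parameters from the richer block; all bounds are plain
data and editable. The admixture proportion gets a Uniform(0.001, 0.999)
prior to avoid the degenerate endpoints. On a merge the target population
keeps its own size until a later resize event — so in S2 the
southwest+central/east ancestor lives at the southwest size between the two
split times, which encodes "budding from within" that lineage.

## Approximate Bayesian computation

`summarize_snps()` computes a fixed-order registry of summaries per group
structure: per group the proportion of monomorphic loci and the mean and
variance of unbiased gene diversity; per group pair the multi-locus Hudson
FST (ratio of averages), Nei's standard distance and the proportion of loci
monomorphic in the pooled pair. The registry is recorded in every reference
table so the statistic list is always explicit; a three-group admixture-type
statistic was considered and left out of the default registry — the
cross-validation rates below are achieved without it, and a fixed registry
keeps observed and simulated paths trivially identical.

`model_posterior()` retains the `tolerance` fraction of reference rows
nearest the observed vector (Euclidean distance on SD-standardized
summaries) and either reports scenario frequencies (rejection), fits a
weighted multinomial logistic regression on the retained rows
(Epanechnikov weights; the default), or a single-hidden-layer neural
network. Probabilities are renormalized to sum to one and Bayes factors are
their ratios. `cv_model_selection()` classifies reference rows with
themselves held out; at study scale (five scenarios, 1,050 simulations per
scenario, 1,383 loci, tolerance 0.05) the mean correct-identification rate
is well above the published cross-validation range's lower end, and that
computation is what `scripts/acceptance.R` reruns end to end.

`estimate_params()` implements rejection and local-linear regression
adjustment: parameters are logit-mapped to their prior support, regressed on
the standardized summaries over the retained rows with Epanechnikov
weights, adjusted to the observation (fitted value at the observation plus
residuals), back-transformed and summarized by weighted equal-tailed 2.5/50/
97.5% quantiles — so estimates always respect the prior bounds, and
credible intervals are equal-tailed, not HPD. A singular regression falls
back to rejection with a warning. `cv_estimation()` reports
`mean((est - true)^2)/var(true)` so uninformative summaries score ~1.
`model_check_pca()` projects observed and posterior-predictive summaries
onto the first two components of the prior-predictive cloud and flags
whether the observation sits inside the axis-aligned 1–99% quantile box.
Divergence times convert to years via `generations_to_years()` (default 10
years per generation).

Problem sizes in the tests were chosen to make each check sharp at desk
scale: scenario-choice cross-validation runs the full five-scenario design
at 1,050 simulations per scenario; parameter-recovery coverage uses an
8,000-row single-scenario table with 200 retained rows and 100
pseudo-observed datasets.

## FST outlier scans

`bayescan_scan()` implements the Bayesian FST decomposition: allele counts
per locus and population follow a beta-binomial likelihood in which
`FST_ij = plogis(alpha_i + beta_j)`; the population frequencies are
integrated out analytically, which shortens the chain the sampler needs. A
reversible-jump move (prior-as-proposal) toggles each locus effect against
a point mass at zero with prior odds 10 for neutrality; included effects
have a N(0, 1) prior, population effects N(-1, 1.8), ancestral frequencies
Uniform(0, 1) updated on the logit scale. Pilot runs adapt the proposal
scales toward acceptance rates in [0.25, 0.45], and a warning is raised if
any end outside [0.1, 0.6]. Loci are ranked by posterior inclusion
probability; the q-value at rank k is the running mean of (1 - probability)
over the top k, and a locus is flagged when q < 0.001 with positive mean
alpha (diversifying selection; negative alpha is reported but not
interpreted). Chain-length defaults follow common practice for the method
(20 pilots of 5,000, 50,000 burn-in, 5,000 samples thinned by 20); the test
suite uses shorter pilot-adapted chains and correspondingly relaxed power
thresholds, as the flags at the strict q on short chains are conservative.

`fdist_scan()` builds the island-model null: the global FST is estimated
with the multi-locus pi-based Hudson estimator (one minus the ratio of mean
within-population to mean between-population diversity), migration is tuned
by the finite-island relation `FST = 1/(1 + 4 N m D/(D-1))` with each
sampled population occupying one deme among `100 * n_pops`, and neutral SNP
loci are simulated under the structured coalescent with migration. The
pi-based estimator is used for tuning because it is unbiased for the
pairwise-coalescence-time FST, which makes the simulated null hit the target
exactly; the per-locus scan statistic is the variance-components FST ratio,
applied identically to observed and simulated loci. Observed loci get
upper-tail p-values within heterozygosity bins (equal-count bins on the
null, pooled with neighbours until at least `min_bin` null points — the
pooling floor of 5,000 keeps the attainable p-value small enough for the
Benjamini–Hochberg step at FDR 0.01 to have power); monomorphic loci are
excluded. `intersect_outliers()` takes the intersection of the two scans'
flags, the conservative criterion used for downstream association.

## Environment association and GDM

`mlr_adaptive_scan()` regresses population allele frequencies of candidate
loci on all climate predictors jointly (ordinary least squares; frequencies
used raw) and flags a locus "adaptive" when adjusted R^2 exceeds 0.5 and at
least one coefficient t-test has p < 0.05. No multiple-testing correction is
applied across loci by default — the rule is per locus, matching how such
scans are usually reported — but a `p.adjust` method can be switched on.
Geographic distance is deliberately not among the regressors; it enters the
GDM instead.

`fit_gdm()` models pairwise dissimilarities as `1 - exp(-eta)` with `eta`
the non-negative sum of I-spline differences: order-2 I-splines (cumulative
degree-2 B-splines via `splines::splineDesign`) with knots at the minimum,
median and maximum of each gradient, so every basis function runs
monotonically from 0 to 1 over the observed range. Climate predictors enter
as `|I(x_i) - I(x_j)|`; geographic distance enters as a spline of the
pairwise great-circle (haversine) distance in km. Fitting minimizes squared
error on the `-log(1 - d)` link scale under non-negativity constraints
(Lawson–Hanson NNLS), and deviance explained is `100 (1 - RSS/RSS_null)` on
that scale; the response (pairwise Phi_ST) is clamped into [0, 1). A
predictor's importance is the maximum height of its fitted spline, which
equals the sum of its coefficients exactly. The published I-spline displays
rescale maxima to a fixed range for plotting; that is presentation only and
not part of the model here.

`backward_eliminate()` refits with one predictor's site values permuted to
build a null of model deviance (`p = (#{null >= obs} + 1)/(n_perm + 1)`,
100 permutations by default), drops the least-important non-significant
predictor, and repeats until every retained predictor is significant;
whole-model significance permutes all predictors jointly. With all-noise
predictors the expected per-variable false-retention rate is the test level,
so the final model is empty in roughly `(1 - alpha)^k` of runs — about 80%
with three or four noise predictors at alpha 0.05, which is what the
acceptance check asserts.

## Gradient forest and genomic vulnerability

`fit_gf()` fits one regression forest per locus (population allele
frequency on the predictors) with tree depth limited to
`floor(log2(0.368 n)/2)` (floor 1; the 0.368 constant, approximately 1/e, is
used as published). Each split's decrease in sum of squares is recorded at
its split value; per locus the improvements are rescaled to sum to the
locus's out-of-bag R^2 (negatives truncated to zero, so poorly modelled
loci contribute nothing), pooled across loci per predictor, standardized by
the data density over a 101-point grid, rescaled to preserve the total, and
accumulated into the non-decreasing turnover curve F_p. The total rise of
F_p is the predictor's overall importance by construction. randomForest
does not expose per-split improvements, so they are recomputed by passing
the training data down each tree's split structure. Predictors correlated
above 0.5 are grouped; `gf_permutation_importance()` permutes such groups
jointly so collinear variables do not launder importance through each other.

`transform_climate()` maps any climate grid (or site table) through the
turnover curves into genomic-composition space, clamping and flagging cells
outside the training gradient; `genomic_vulnerability()` is the per-cell
Euclidean distance between the compositions of two epochs with identical
geometry — zero iff the compositions agree, symmetric under epoch swap, and
monotone in the size of a single-variable perturbation. Rasters are plain
ESRI ASCII grids (`read_ascii_grid()`/`write_ascii_grid()`), a deliberately
simple text container; vulnerability should be interpreted only within the
species range, so mask the grid accordingly.

## The synthetic study generator

`make_study()` builds a complete study-shaped dataset with known truth:
35 populations in three regional groups (10 + 14 on one landmass, 11 on the
other; 45/75/51 diploids, 171 individuals, 2–6 per population), neutral loci
from the coalescent under the configured divergence scenario (default: the
"Japan splits first, central/east buds from southwest" scenario at the
published posterior medians), adaptive loci as logistic allele-frequency
clines `plogis(a + b z)` in the z-scored site value of a target climate
variable (default slope 5 across the gradient, cycling over the four
temperature variables), 5% missingness, and spatially autocorrelated
climate fields (latitudinal trend plus Gaussian-smoothed noise with
variable-specific means and spreads in conventional units) with a uniformly
shifted "future" copy. The default matrix is 8,733 neutral + 49 adaptive
loci, mirroring the scan-matrix shape; everything derives from one master
seed and regenerates byte-identically.

Two deliberate simplifications matter for interpretation. Adaptive loci are
generated independently of the coalescent, so they carry no linked neutral
structure and no drift covariance with the genome-wide background —
power estimates for the association scans on these fixtures are therefore
optimistic relative to real data, where population structure confounds
climate. And missingness is uniform rather than coverage-driven, so filter
behavior on pathological dropout patterns is exercised only by the
hand-built fixtures in the unit tests. Passing tests establish correctness
of the machinery and calibration under the stated models, not robustness to
everything real RAD data can do.

## Pipeline

`run_pipeline()` executes the enabled stages — synth, filter, stats, abc,
outliers, adaptive, gdm, gf, vulnerability — off one nested configuration
(R list, YAML or JSON), writes each stage's tables under the run directory,
and records a manifest with the config hash, per-stage derived seeds,
wall-clock seconds and MD5 checksums of every output, so deterministic
stages can be verified to reproduce. Stages never modify an earlier stage's
files; a failing stage aborts with its partial outputs preserved. A thin
command-line wrapper (`inst/scripts/relictgen`) exposes `run` and `synth`
for shell use.
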