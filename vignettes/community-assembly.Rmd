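---
title: "Trait variance ratios, null models and the decomposition of community-weighted means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait variance ratios, null models and the decomposition of community-weighted means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitassembly)
```

This vignette is the package's own account of its methods: the statistical
model behind each stage, the parameters that matter and their defaults, the
null models and their calibration, what the synthetic-data generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## The scientific setting

Leaf mass per area (LMA, g·m⁻²) summarises the leaf economics spectrum:
dry, cold or nutrient-poor environments favour robust, long-lived,
high-LMA leaves; productive environments favour cheap, fast, low-LMA
leaves. Along a strong environmental gradient — an Andean elevation
transect, a forest–savanna mosaic — community-level LMA can change for two
distinct reasons: the species present change (*turnover*), or the same
species change their leaves (*intraspecific variation*). Comparing the
magnitudes of intra- and interspecific variance, against explicit null
models, lets one ask whether communities are assembled by *internal*
filters (interactions among coexisting individuals, e.g. competition and
niche packing, which compress within-population variation) or *external*
filters (abiotic constraints that compress whole-community variation
relative to the regional pool).

The data layout the package expects mirrors a standard trait campaign:
plots with a basal-area census, dominant species sampled per plot to a
coverage target, a few trees per species, a few leaves per tree, lamina
and petiole measured separately, sun and shade branches kept apart.

## From leaves to trait values

Whole-leaf LMA is `(lamina dry mass + petiole dry mass) / (lamina fresh
area + petiole fresh area)`; the rachis of compound leaves is treated with
the petiole. Two field artifacts are handled explicitly:

* **Zero petiole masses.** Petioles below the balance's precision are
  recorded as 0 g. They are reconstructed as `petiole_fresh / R_plot`,
  where `R_plot` is the plot-level ratio of summed petiole fresh mass to
  summed petiole dry mass over leaves with both measurements. Two choices
  were open here. First, the ratio of sums is used rather than the mean of
  per-leaf ratios, because single tiny dry masses make per-leaf ratios
  explode; the ratio of sums is the weighted, robust version. Second, the
  direction of the correction (divide fresh mass by the fresh:dry ratio)
  is fixed by dimensional analysis — it is the only direction that yields
  a dry mass — and is isolated in `correct_petiole_mass()` so an alternate
  convention could be swapped in without touching anything else.
* **Single aberrant leaves.** A tree whose leaf-LMA sample variance
  exceeds 2000 g²·m⁻⁴ (the default `threshold`) almost always contains one
  mis-measured leaf. The rule is intentionally algorithmic: remove the
  single leaf whose removal minimises the remaining variance, never more
  than one per tree; trees still above threshold afterwards are flagged
  but kept. This makes the stated intent ("single leaves removed as
  outliers") deterministic and testable. Ties in the variance reduction
  are broken by leaf order (first minimiser wins).

Aggregation always goes leaf → tree → population (species × plot) → plot
using means of the level below, never pooled leaves, so unbalanced leaf or
tree counts cannot bias higher levels; this matters, and a test asserts
that pooled-leaf and tree-based plot means disagree on unbalanced designs.
Sun and shade layers never mix at any level. Descriptive statistics (CWM,
plot means) stay on the raw g·m⁻² scale; all variance decompositions use
the natural log of LMA to avoid mean–variance scaling. Natural rather than
base-10 log is a convention choice only — every statistic computed from
log values is a ratio or proportion and is invariant to the base.

## Community-weighted means

For plot *k*, `CWM_k = Σ_i μ_i f_i / Σ_i f_i`, with `μ_i` the species mean
of tree-level LMA and `f_i` the species' share of total plot basal area.
Because only dominants are sampled, `Σ f_i` (the *coverage*, reported
alongside) differs between plots; dividing by it removes that sampling
bias and makes the CWM invariant to uniform rescaling of abundances. The
community-weighted variance uses the same normalised weights. Regressions
of CWM on the gradient are ordinary least squares — measurement-error and
mixed-model extensions are deliberately out of scope — with an optional
named-plot exclusion set that is echoed in the output.

## T-statistics and their null models

With *i* = individual (tree), *p* = population (species × plot), *c* =
community (plot) and *r* = region (all plots of a transect), and σ²~AB~
the variance of *A* within *B*:

* `T_IP.IC = σ²_IP / σ²_IC` — internal filtering on individuals. Computed
  as the within-population sum of squares over the total within-community
  sum of squares: with a common denominator the (n−1)'s cancel, the ratio
  is bounded in [0, 1], and it equals 1 minus the between-population SS
  fraction of a one-way ANOVA (an oracle test asserts agreement to
  10⁻¹²).
* `T_IC.IR = σ²_IC / σ²_IR` — external filtering on individuals; the
  ratio of community to regional variance with (n−1) denominators.
* `T_PC.PR = σ²_PC / σ²_PR` — the same at the level of population means,
  i.e. ignoring intraspecific variation.

Each statistic is compared to a permutation null that randomises exactly
the structure it measures: for `T_IP.IC`, individual values are shuffled
among individuals *within* each community (population structure destroyed,
community pool preserved); for `T_IC.IR`, each community is rebuilt by
drawing its n~c~ individuals without replacement from the regional pool;
for `T_PC.PR`, population means are shuffled across all populations in the
region, preserving each community's population count. The scheme layer is
a single function (`null_distribution()`) so alternate schemes can be
added without touching the statistics. Because observed and null values
use the *identical* estimator, the standardized effect size
`SES = (obs − mean(null)) / sd(null)` is invariant to the estimator
convention (SS fraction vs variance ratio).

Significance is judged per community against the α/2 and 1−α/2 quantiles
of the SES-transformed null (α = 0.05 by default); per-community nulls are
used for all three statistics, matching the per-plot confidence boxes in
the reported figures. Transect-level inference compares the mean of
per-plot SES values against the null distribution of that mean (each
permutation's SES averaged over plots). Ties and duplicated trait values
permute as ordinary values — no jitter. The default is 999 permutations;
all permutation streams derive from one master seed (statistic *i* uses
`seed·10 + i`, and the pipeline offsets layers by 100), so a run is
reproducible end to end from a single integer.

Degenerate communities are reported, not fatal: a community whose
individuals are all identical has no defined `T_IP.IC` (error, since the
data cannot support the analysis), but a community with a single sampled
population simply gets `NA` for `T_PC.PR` (with a warning) and is dropped
from the transect aggregate — real sparse plots do this.

## Nested variance components

The hierarchy plot / family / genus / species / tree (residual = leaf) is
fitted as an intercept-only nested random-effects model on log-LMA by
REML, via `nlme::lme` with the variance-component extraction of
`ape::varcomp`; the optimizer runs with a 10⁻⁸ convergence tolerance and
a 500-iteration ceiling. A "country" level would sit above "plot" for
multi-transect data; single-transect runs drop it. Taxonomic labels must
be consistently nested (a genus under two families is an error listing the
offenders), whereas plot and tree labels are nested by interaction, so
re-use across parents is fine. Negative component estimates are truncated
at zero before proportions are formed. `moments_oracle()` provides the
closed-form expected-mean-squares solution for perfectly balanced designs;
on balanced data REML and the moments estimator coincide (to 10⁻⁶ in the
tests) whenever the estimates are interior, which is what makes it a
genuinely independent check.

## Decomposing CWM variance

Across plots, the variance of the CWM computed with plot-specific species
means (`ss_specific`) splits into the variance of the CWM computed with
region-wide fixed species means and the same weights (`ss_fixed`, the
*turnover* part), the variance of the per-plot difference (`ss_intra`, the
*intraspecific* part), and a covariance remainder defined as
`cov = ss_specific − ss_fixed − ss_intra`, so the identity holds to
machine precision on every input — this is asserted, not assumed. The
covariance is reported signed; a negative value means species turnover
and intraspecific shifts oppose each other. This decomposition operates on
the raw CWM scale (it decomposes the quantity of interest itself), while
the nested components above use the log scale; the two scales are never
mixed within one statistic.

## Beta diversity

Sørensen dissimilarity is incidence-based, `(b + c) / (2a + b + c)`, with
presence defined as positive census basal area; abundance-based variants
are out of scope. The Mantel test correlates lower triangles and permutes
rows/columns of the second matrix jointly; the p-value is one-sided for
positive association, `p = (1 + #{r_perm ≥ r_obs}) / (nperm + 1)`, with
999 permutations by default (neither the permutation count nor sidedness
is forced by convention elsewhere, so both are documented defaults here).

## The synthetic-community generator

The generator is first-class, tested code: it is the package's instrument
for validating every downstream stage against known truth. The trait model
is Gaussian on the natural-log scale:

* Species *s* has a niche optimum `opt_s` drawn uniformly along the
  gradient (padded at each end by the niche width, capped at half the
  gradient span so broad niches cannot extrapolate trait optima far
  off-gradient) and a trait mean
  `μ_s = grand mean + β_env · opt_s + N(0, σ²_species)`.
* Plot *k* at gradient position `env_k` admits species with basal-area
  weight `∝ exp(−(env_k − opt_s)² / 2w²) · Lognormal(0, shape)`; species
  with relative weight above 10⁻⁶ are "present" in the census. Sampling
  emulates the field protocol: dominants in decreasing basal-area order
  until 80% coverage, then 3–5 trees per species and 3–5 leaves per tree
  and layer.
* The population mean shrinks toward the plot's trait optimum by the
  external-filter multiplier:
  `θ_k + γ_ext(μ_s − θ_k) + site effect + N(0, (σ_pop γ_int)²)`; tree
  values add `N(0, (σ_tree γ_int)²)`, leaves add `N(0, σ²_leaf)`.
  `γ_ext = 1` and `γ_int = 1` mean no filtering; smaller values compress
  exactly the variance components the corresponding T-statistic measures.
  The multiplier-on-σ form for internal filtering and the
  shrinkage-toward-optimum form for external filtering are the simplest
  mechanisms that target σ²~IP~ and σ²~IC~ respectively; simulated effect
  sizes are calibration knobs for the method, not estimates of any field
  system.
* A per-plot site intercept `N(0, σ²_site)` shifts all individuals in a
  plot, giving the nested decomposition a recoverable site component.
* Each leaf's log value is exponentiated to an LMA and split into lamina
  and petiole masses and areas with fixed geometry (petiole = 5% of fresh
  area and 8% of dry mass, fresh:dry petiole ratio 3.0, lamina area
  lognormal around 50 cm²). The geometry is arbitrary but recorded in the
  ground truth, which is what makes the petiole correction exactly
  testable.

Default parameters describe a plausible tropical elevation transect: 10
plots from 200 to 3500 m, a 60-species pool, niche width 400 m (strong
turnover, mean pairwise Sørensen ≈ 0.25–0.6 depending on seed), grand
mean log(120) g·m⁻², σ_site = 0.10, σ_species = 0.35, σ_pop = 0.15,
σ_tree = 0.12, σ_leaf = 0.10 (so intraspecific variation is a minority
but non-trivial share, in line with published LMA partitions),
β_env = 3·10⁻⁴ log units per m (LMA roughly doubles bottom to top),
lognormal abundance shape 1, coverage target 0.80, and a shade-layer
offset of −0.25 log units (shade leaves ≈ 22% lighter per area). All
randomness flows from one seed; a fixed configuration is bit-reproducible.

What the generator does *not* emulate: spatial structure within plots,
temporal dynamics, phylogenetic signal in trait values (genus/family
labels are nested but carry no extra variance by default), folded-leaf
scan artifacts, herbivory damage, or non-Gaussian trait tails. Passing
tests on synthetic data therefore demonstrate correctness of the
*statistical machinery* under the stated model, not robustness to every
feature of field data.

## Validation design and problem sizes

The test suite validates each stage against an independent route:

* `T_IP.IC` against a brute-force one-way ANOVA decomposition on 40
  random communities of ≤ 20 individuals (agreement < 10⁻¹²).
* REML components against the expected-mean-squares closed form on
  balanced two- and three-level designs (10 × 10 and 5 × 4 × 6; relative
  tolerance 10⁻⁶), and recovery of the generator's configured σ's from a
  12-plot, 15-species, 4 × 4 balanced scenario.
* Null-model calibration on 200 replicate datasets of a *neutral*
  scenario — all trait structure at the individual level, so individuals
  are exchangeable within communities and across the region — with 199
  permutations: per-plot rejection at α = 0.05 must stay within the 99%
  binomial band around 0.05 for all three statistics (observed ≈
  0.048–0.059 over 1200 plot-tests).
* Filter recovery: `γ_int = 0.3` must yield significantly negative
  SES(`T_IP.IC`) in ≥ 90% of 100 replicate plots, `γ_ext = 0.3`
  significantly negative SES(`T_IC.IR`) in ≥ 80% (observed ≈ 100% and
  ≈ 90%).
* Mantel p-values approximately uniform under independence (200
  replicates of 8 × 8 exchangeable random matrices, 99 permutations,
  Kolmogorov–Smirnov check), and the Sørensen/Mantel/decomposition
  fixtures computed by hand.
* The qualitative contrast that motivates the whole pipeline: a
  high-turnover gradient (niche width 400 m) puts > 60% of CWM variance
  into the turnover component, while a *no-turnover* scenario — shared
  pool (`niche_width = 10⁶`), uniform abundances (`abundance_shape = 0`)
  and full sampling (`basal_area_target = 1`), so every plot holds the
  same species at the same weights — puts essentially all of it into the
  intraspecific component. Defining "no turnover" required all three
  settings: with skewed abundances redrawn per plot, the churn of which
  dominants are sampled is itself a form of turnover and shows up as
  such.

These sizes keep the complete suite around a minute on one core while
leaving each check statistically meaningful.

## Known limitations

* T-statistics are not independent of each other (they share variance
  components), and they diagnose internal vs external *pattern*, not
  mechanism; interpretation needs the environmental context.
* The `T_IC.IR` null resamples individuals ignoring their species
  clustering, so under strong turnover the observed value sits below the
  null even without plot-level environmental filtering — on gradients
  this statistic partly reflects turnover itself. The calibration
  scenario is correspondingly structure-free; on structured data the SES
  should be read comparatively across plots.
* Single-population communities carry no information for `T_PC.PR` and
  are reported as `NA`.
* REML confidence intervals, fixed-effect covariates, abundance-weighted
  T-statistics, multi-trait extensions and the turnover/nestedness
  partition of beta diversity are out of scope.
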