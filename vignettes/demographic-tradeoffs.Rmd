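---
title: "Estimating demographic trade-off axes from forest census data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating demographic trade-off axes from forest census data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demaxes)
```

## The problem

Tree species in diverse forests differ enormously in how fast they grow, how
long they survive, and how successfully they recruit from seed. Much of this
variation is structured by a small number of life-history axes: a
growth–survival trade-off (the fast–slow continuum separating fast-growing,
short-lived pioneers from slow, persistent species) and a
stature–recruitment, or ontogenetic, trade-off (species performing well as
seedlings versus species whose performance peaks in the larger size
classes). `demaxes` estimates species-level demographic rates from repeated
census data spanning the whole ontogeny — seedling plots, seed traps and
mapped stems — and extracts and tests these axes.

The pipeline has four stages:

1. **Canopy layering.** Every stem ≥ 1 cm dbh is assigned to the overstory
   or understory by a perfect-plasticity crown-packing rule, per census.
2. **Rate estimation.** Hierarchical Bayesian models give species-level
   mean growth and annual survival in four size classes (seedlings < 20 cm,
   seedlings 20–50 cm, understory and overstory trees), plus
   seed-to-seedling transition rates from seed-trap and recruit counts.
3. **Trade-off extraction.** The species × 9 rate matrix is normalized,
   missing cells are imputed by a regularized iterative PCA, and the
   principal components are tested by eigenvalue permutations and labeled
   by the sign structure of their significant loadings.
4. **Post-hoc analyses.** Trait vector fits, Procrustes comparison of
   ordinations, an inverse-richness-weighted global PCA, and 10%/90%
   life-history hulls.

A synthetic community generator with two planted latent axes provides ground
truth; every stage of the pipeline is validated by recovering what was
planted.

## Canopy layers

Crown area is a power law of diameter, `a · dbh^b` (dbh in mm, area in m²),
with species coefficients and a site-level default. The plot is divided into
31.5 m × 31.5 m subplots (trailing partial tiles keep their true area, so
the packing threshold always refers to actual ground area). Within each
subplot stems are ranked by dbh, largest first, and assigned to the
overstory until their cumulative crown area exceeds twice the subplot area;
the rest are understory. Two details of the verbal rule needed fixing:

* the stem whose crown first pushes the sum over the threshold is itself
  kept in the overstory (`include_crossing = TRUE`; the stricter reading is
  available as a switch), and
* dbh ties break by tree identifier, so assignments are reproducible.

Palms, hemi-epiphytes and unidentified species can be listed in
`exclude_species`: they take part in the packing (their crowns shade
others) but carry no rate estimates.

## Rate models

Growth observations are annual increments `(size2 − size1)/t` for
individuals that survived an interval, classed by their state at the
*first* census of the interval. Increments are brought to an approximately
normal scale by the modulus transform `sign(g)·|g|^0.4`, which is odd and
strictly increasing, so negative increments (shrinkage, breakage) need no
special treatment. Per species and class, at most 200 growth and 1000
survival observations are used (seeded subsampling without replacement),
and a species needs at least 10 observations in a class for that rate to be
estimated.

The growth model pools species within one size class:

$$y_{ij} \sim \mathrm{Normal}(g_j, \sigma_j),\quad
  g_j \sim \mathrm{Normal}(g_k, 1),\quad
  \sigma_j \sim \mathrm{Lognormal}(\sigma_k, 1),$$

with effectively flat (wide proper uniform) priors on the class-level
locations `g_k ∈ [−100, 100]` and `σ_k ∈ [−20, 20]` (log scale) so that all
posteriors are proper. The survival model is interval-censored: an
individual alive at the start of a `t`-year interval survives it with
probability `s_j^t`, and the annual probabilities are pooled through a
class-level Beta(α, β) whose parameters are estimated jointly (uniform
priors on (0, 1000]).

Both posteriors are small — two scalars per species plus two
hyperparameters — so the package uses purpose-built vectorized samplers:
conjugate Gibbs updates for the species means, adaptive random-walk
Metropolis for the species SDs and survival rates (on log and logit
scales), and, for (α, β), a random walk on (logit mean, log concentration),
which mixes far better than naive per-parameter moves. Sufficient
statistics (per-species counts, means, sums of squares; survived years and
death counts per distinct interval length) make the cost per sweep
independent of the number of raw observations. Point estimates are
posterior means; the species growth means are Rao-Blackwellized (the
posterior mean of the conditional mean), which removes Monte-Carlo jitter
and guarantees the hierarchical pooling direction — every species estimate
lies between its raw mean and the class mean — exactly rather than just in
expectation. Convergence requires split-R̂ < 1.01 and a total effective
sample size > 400 for every reported quantity (3 chains × 1500 post-burn-in
draws by default); fits failing the contract are flagged, not silently
accepted.

Survival enters the rate matrix as log expected lifespan,
`log(1/(1−s))`, a strictly monotone map that linearizes the severe
compression of survival probabilities near one.

Seed-to-seedling transition rates divide newly emerging seedlings per
hectare per year (scaled from the summed seedling-plot area) by seeds
captured per hectare per year (scaled from the summed trap area), per
census interval; per-interval ratios are averaged over intervals with at
least one trapped seed, means above one are capped at one, and the result
is log-transformed. A recruit is a seedling first tagged after the initial
census with first height below 500 mm (configurable; census protocols do
not pin down "newly emerging" exactly). Species never caught in the traps
get a missing — not infinite — transition rate.

## Trade-off extraction

Each rate column is z-scored over its observed cells. Species with growth
and survival estimates in fewer than two of the eight class cells are
dropped (the transition column does not count towards retention, but does
participate in the PCA). Missing cells are then imputed by regularized
iterative PCA: initialize at column means, alternate a rank-4 SVD
reconstruction with replacement of the missing cells, and stop when the
largest change in an imputed cell falls below `1e-6`. The retained singular
values are shrunk by the estimated noise variance (the mean trailing
eigenvalue); on noiseless low-rank matrices the shrinkage vanishes and
deleted cells are recovered essentially exactly, while on noisy matrices it
suppresses the limit cycles the unregularized alternation falls into when
eigenvalues near the rank cutoff cross. Because convergence is linear with
a possibly small eigengap, the pipeline calls the imputer with a generous
sweep cap (20 000) rather than erroring early; observed cells are never
altered.

Principal components come from the correlation structure of the completed
matrix, with each component oriented so its largest-magnitude loading is
positive (PCA signs are otherwise arbitrary, and labels and cross-site
comparisons need a fixed orientation). Significance is assessed by
permuting every column independently across species 1000 times — destroying
all correlation while preserving the margins — and comparing each observed
eigenvalue with its permuted distribution; permutations act on the
completed matrix (re-imputing inside every permutation is available but off
by default, on cost grounds). Rates with |loading| ≥ 0.3 on a significant
component are flagged.

Components are then labeled from the flags. A growth–survival axis opposes
the two rate types; a stature–recruitment axis opposes the two life stages.
With a hard 0.3 flag threshold the flagged subset is often a 2 × 2 "cross"
(say, tree growth positive and seedling survival negative) that is
simultaneously type-opposed and stage-opposed, so the flags alone cannot
decide. The package resolves such components by the dominant contrast of
the full loading vector: the absolute projection onto the type contrast
(growth vs survival) against the absolute projection onto the stage
contrast (seedling vs tree classes). Unambiguous components are labeled
directly from their flags. On synthetic communities with both axes planted
this operationalization recovers the planted labels in essentially all
replicates; with the literal "any opposed pair, growth–survival first"
reading, the stature axis would almost always be mislabeled, because a
stage-opposed component always contains some cross-stage growth-vs-survival
pair.

## Post-hoc analyses

Trait–axis relations are two-dimensional linear trend-surface fits
(`vegan::envfit`): the arrow is the direction of steepest increase of the
trait in the (PC1, PC2) plane, r² its explained variation, and significance
comes from permuting trait values (Bonferroni threshold p < 0.0125 for four
traits). Strictly positive traits with sample skewness above one are
log-transformed first.

Site ordinations are compared by symmetric Procrustes superposition of the
loadings of the first two components (species scores by flag), restricted
to shared rate columns; similarity is `r = √(1 − m²)` with permutation
significance via `vegan::protest`.

The global analysis pools per-site normalized matrices and weights every
species by the inverse of its site's species count, so each site
contributes equally; the weighted correlation structure is decomposed
directly, and the same imputation and permutation machinery applies. With
equal site richness the analysis reduces exactly to the pooled unweighted
PCA. Life-history hulls peel the convex hull — repeatedly removing the hull
vertex farthest from the centroid of the remaining points — until 10% (the
core) or 90% (the extent) of species remain, and report the polygon and its
area; no standard algorithm is prescribed for "a polygon covering X% of
species", and centroid-distance peeling is simple, deterministic and
monotone in the fraction.

## The synthetic community

`simulation_design()` describes a single densely censused forest emulating
the scale of one large plot subsample: 150 species, three censuses five
years apart, ~10 500 mapped stems on 1 ha, 400 seedling plots of 1 m², 150
seed traps of 0.5 m², and a median seed rain of 2000 seeds ha⁻¹ yr⁻¹.
Species positions on the two latent axes are i.i.d. standard normal; the
nine rates are `loading · axes + noise` on link scales (log for growth
means, logit for survival and transition), with axis 1 opposing growth
(+) and survival (−) in every class and axis 2 opposing seedling
(+) and tree (−) classes, transition aligned with survival on axis 1 and
with the seedling stage on axis 2. Link-scale noise is 0.2; traits are
generated analogously on the log scale (stature loading against the
seedling end of axis 2, wood density with the survival end of axis 1, seed
mass with recruitment, SLA with fast seedling growth).

The simulator then runs the community forward: stems survive an interval
with `s_k^t` (class k assigned by the same packing rule as the analysis)
and survivors add increments from `Normal(g_k·t, sd·√t)` truncated below at
0.1 mm — the √t scaling is the Brownian-increment convention, chosen
because nothing in census data identifies within-interval variance — while
recruits enter the seedling plots as Poisson thinning of the seed rain with
the species' transition probability, at heights uniform in (10, 200) mm so
they start in the smallest class. Seed rain is spatially uniform: no
dispersal kernels, no masting, no clumping.

What the generator deliberately does **not** emulate: measurement error in
dbh and height, multi-stem individuals, spatially autocorrelated mortality
(cyclones, pest outbreaks), density dependence, and temporally varying
rates. Passing the recovery tests therefore shows the estimators are
correct under the stated model, not that real censuses satisfy that model.

## Numerical choices and limitations

* All randomness flows from one seed (`rng_seed`); stage seeds are derived
  deterministically, so changing, say, the permutation count never perturbs
  the simulated community. Identical seeds give byte-identical outputs
  (manifests carry no timestamps).
* Problem sizes in the validation suite are chosen to exercise the stated
  study conditions at desk scale: 100-species recovery designs with
  200–1000 observations per species, 60 × 6 null matrices with 200
  replicates for the permutation-test size, 20 end-to-end replicates of the
  150-species default community at reduced draw counts (2 chains × 1200
  draws), which leaves posterior means essentially unchanged.
* Empirical claims about the pipeline's behaviour are exactly those the
  test suite and `scripts/acceptance.R` compute; nothing beyond them is
  asserted here.
* Known limitations: the survival sampler assumes intervals are exact (no
  staggered census dates within an interval beyond their recorded values);
  the transition rate ignores seed and seedling spatial covariance (traps
  and plots are treated as unbiased samplers of the same rain); and the
  labeling rule, like any hard-threshold rule, can leave genuinely mixed
  components `"unlabeled"`.
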