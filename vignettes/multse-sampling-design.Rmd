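---
title: "Optimising coral survey designs with the multivariate pseudo standard error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimising coral survey designs with the multivariate pseudo standard error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralmse)
```

## The problem

Benthic monitoring programs estimate the structure of a coral assemblage
from a nested design: line transects along the reef, photo-quadrats
along each transect, and classified points within each quadrat. Most
power analyses for such surveys are univariate (total coral cover), but
monitoring questions are increasingly multivariate — which species make
up the assemblage and how that composition shifts. `coralmse`
quantifies how precisely a given design estimates the multivariate
community structure, and searches the design space for the allocation
of transects, quadrats and points that improves that precision most.

## The statistic

For $n$ sampling units and a dissimilarity matrix $d_{ij}$, define

$$SS = \frac{1}{n}\sum_{i<j} d_{ij}^2, \qquad
  V = \frac{SS}{n-1}, \qquad
  \mathrm{MultSE} = \sqrt{V/n}.$$

$V$ is the multivariate pseudo-variance: $SS$ equals the sum of squared
distances of the units to their centroid in the full signed
principal-coordinate embedding of $d$ (this is the Gower-trace identity
that `pcoa()` verifies against `pseudo_variance()`), so $V$ generalises
the sample variance to any dissimilarity. With a Euclidean distance on
one variable, MultSE *is* the classical standard error of the mean —
`multse(dist(y))` equals `sd(y)/sqrt(n)` to machine precision — and
with Bray–Curtis it measures the precision of the community centroid in
the space community ecologists actually analyse.

Dissimilarities here are quantitative Bray–Curtis on untransformed
percent cover (a square-root option exists but is off by default).
Cover of a species in a unit is `100 * points labelled s / all points`,
substrate points included in the denominator: that is the
point-intercept definition, and renormalising to coral-only
compositions would distort Bray–Curtis between sparse and dense units.
Empty (all-substrate) units are retained; the Bray–Curtis convention
for them is explicit and configurable (`d = 0` between two empty units,
`d = 1` against a nonzero unit).

## Uncertainty and site ranking

`bootstrap_multse()` resamples each site's units with replacement,
recomputes MultSE per resample, recentres the bootstrap distribution on
the observed value (observed minus bootstrap mean — the first-order
bias correction) and reports percentiles of the recentred distribution,
by default 2.5% and 97.5%, plus the 5%–95% interquantile range.
`rank_groups_by_iqr()` picks the sites with the widest IQR — the sites
whose precision is least well determined and which repay densification
(re-annotation at higher point density) before design simulation.

Degenerate resamples that collapse onto few distinct units are kept:
their MultSE is computable (possibly 0), rejection would bias the
distribution, and the recentring compensates the mean shift.

A known limitation, verified by simulation during development: for
strongly dominance-structured assemblages (one or two species carrying
most of the cover) the squared-dissimilarity distribution is heavy
tailed, and with ~20 units the plug-in bootstrap underestimates the
sampling spread of MultSE by roughly 15–20%, so nominal 95% intervals
cover the large-sample value in only ~85–90% of replicates. The
alternative interval constructions (basic/reverse percentile, BCa) do
not repair this — the deficit is in the bootstrap width itself, not the
correction — while for more even assemblages coverage is close to
nominal. Interval widths for low-diversity, high-dominance sites should
be read as slightly optimistic.

## Simulating alternative designs

`simulate_site()` implements the resampling algorithm that turns a
densely annotated site (100 points per quadrat) into a simulated survey
with `nbT` transects, `nbQ` quadrats per transect and `nbP` points per
quadrat:

1. simulated transects map onto the real ones by cyclic recycling of
   the stored transect order (4 real transects and `nbT = 10` give
   T1–T4, T1–T4, T1, T2); the order is preserved, not shuffled — a
   convention we fix for reproducibility since either choice yields the
   same marginal distribution;
2. each simulated transect draws `nbQ` quadrats from its real
   transect's `NQ` — a uniform random subset without replacement when
   `nbQ <= NQ`, uniform with replacement when `nbQ > NQ`;
3. each drawn quadrat contributes `nbP` of its observed points by
   simple random sampling without replacement, so `nbP` can never
   exceed the observed point count (attempting it is an error, not a
   silent cap).

Provenance columns (`source_transect`, `source_quadrat`,
`source_point`) keep the pseudo-replication auditable. Note what
recycling means: transect-level variance beyond the real transects is
*not* invented, so designs with `nbT` far above the observed transect
count mix duplicated sources whose dissimilarity reflects only
quadrat- and point-level noise. This is faithful to the resampling
design being emulated, and it is why simulated precision gains from
very large `nbT` should be read as optimistic.

`evaluate_grid()` runs the pipeline simulate → aggregate (transect
level) → Bray–Curtis → MultSE over a factorial grid, by default
`nbT` 2–20 × `nbQ` 5–25 × `nbP` {25, 50, 75} (1197 designs; the floor
`nbT = 2` exists because MultSE is undefined for one unit). One MultSE
is computed per simulated dataset; the spread over replicates (default
10 per cell) measures Monte-Carlo uncertainty, so no bootstrap runs
inside cells. Internally the grid path tabulates label counts directly
instead of materialising annotation tables; a unit test asserts the
two paths consume the random stream identically, draw for draw. Every
cell's child seed derives from (root seed, site, design, replicate),
making any cell reproducible in isolation and the whole grid
bit-identical under re-execution.

The sampling unit throughout is the transect-level cover vector within
a site. The quadrat level is available (`aggregate_cover(level =
"quadrat")`, `--unit-level` in the pipeline config) for surveys where
the quadrat is the replicate.

## Finding the best design

`fit_design_model()` regresses Box–Cox-transformed MultSE on the
numeric design counts (main effects only, sites and replicates pooled).
The power parameter is profiled once on the pooled response over a
grid of λ from −2 to 2 in steps of 0.01 with one quadratic refinement —
profiling per site would let λ absorb between-site scale differences
that the regression should see. A fixed λ can be supplied instead
(λ = 1 reduces to ordinary least squares on `y − 1`, which the tests
exploit for exact recovery checks). Site fixed effects are available
behind `by_site = TRUE` but off by default, since the pooled model is
the simpler, more conservative reading of a design question that is
common to all sites. Zero MultSE rows (degenerate simulated datasets)
are a hard error unless the caller explicitly drops or offsets them;
silently log-transforming zeros away would hide a data problem.

A negative transect coefficient with the dominant |t| is the expected
signature: under independent and identically distributed units, MultSE
scales as $1/\sqrt{nbT}$, while adding quadrats or points only shrinks
the within-transect component. The test suite checks this direction on
a full synthetic grid, and `compare_schemes()` quantifies the paired
improvement of one scheme over another (for example a 10 × 10 × 25
scheme against a 4 × 15 × 25 field protocol).

## The synthetic generator

Because raw survey data are not shipped, `generate()` produces
point-annotation datasets with the hierarchical structure the analysis
assumes: a Dirichlet-multinomial cascade in which each site draws a
composition from `Dirichlet(alpha_site * uniform)`, each transect
perturbs it by `Dirichlet(alpha_T * site)`, each quadrat by
`Dirichlet(alpha_Q * transect)`, and each point lands on substrate with
probability `1 - coral_fraction` or on a species drawn from the quadrat
vector. The hierarchy was chosen because the analysis only assumes
exchangeable units with controllable compositional variance per level,
and the Dirichlet-multinomial has closed-form expectations, which the
recovery tests use. All latent vectors are returned in a truth record.

Defaults emulate a Caribbean survey: 12 sites × 4 transects ×
15 quadrats × 100 points over 43 species. `coral_fraction = 0.35`
(moderate Caribbean coral cover), `site_concentration = 1.5` (sites are
strongly differentiated with a few dominant species each — total
concentration of the site-level Dirichlet is 1.5 spread over 43
species), `transect_concentration = 100` and `quadrat_concentration =
100` (precision ~100 at the within-site levels, i.e. per-species
standard deviations of a few percentage points, matching the moderate
patchiness of reef transects). These are fixed modelling choices, not
fitted quantities.

What the generator does *not* emulate: spatial autocorrelation along
transects, species co-occurrence structure, and observer
misclassification. Tests passing on generated data therefore establish
the pipeline's statistical mechanics (scaling laws, coverage,
recovery), not robustness to those field realities.

`reference_multse()` supplies the generator's large-sample
pseudo-variance (default 5000 fresh transects per site) as the "true"
value for coverage and recovery tests, and `sample_transect_cover()`
exposes the unit sampler directly.

## Numerical conventions

- Child seeds are derived by hashing the root seed with the stream's
  identity (site, design, replicate, …) into 31-bit integers, so
  results do not depend on iteration order and any sub-computation can
  be replayed alone.
- Ties in site ranking break lexicographically by site id.
- PCoA keeps negative eigenvalues as signed axes (no Lingoes/Cailliez
  correction by default), which is what makes the trace identity with
  `pseudo_variance()` exact for non-Euclidean Bray–Curtis input; axis
  signs are fixed by making the largest-magnitude loading positive.
- Species columns of cover matrices are the schema species observed in
  the data, in lexicographic order, so matrices are reproducible across
  runs.
- Dirichlet draws with extremely small shape parameters can underflow
  to an all-zero gamma vector; the sampler then falls back to the
  distribution's mean rather than dividing by zero.

## Problem sizes used in checks

The shipped checks run at deliberately modest scale: most module tests
use 2-site surveys of 4 × 5 × 25 points with ~10 species; the
direction-of-effect check runs the full 1197-cell grid over 3 sites at
5 replicates per cell; the coverage simulation uses 500 groups of 20
units at 1000 bootstrap resamples; `scripts/acceptance.R` analyses a
12-site survey at the default geometry with a reduced factorial grid
(`nbT` 2–20 step 2, `nbQ` 5–25 step 5, `nbP` {25, 50, 75}, 5 replicates
per cell on the 3 highest-IQR sites). These sizes were chosen to keep
the full analysis comfortably reproducible on a laptop while leaving
the Monte-Carlo error well below the effects being demonstrated.

## Worked example

```{r example, eval = FALSE}
library(coralmse)

cfg <- synthetic_config(n_sites = 4, seed = 7)
ds <- generate(cfg)

cover <- aggregate_cover(ds$annotations, "transect", ds$schema)
est <- bootstrap_multse(cover, cover_units(cover)$site,
                        n_boot = 10000, seed = 7)
est
top <- rank_groups_by_iqr(est, 2)

raws <- lapply(top, function(s) site_raw_data(ds$annotations, s))
gr <- evaluate_grid(raws, ds$schema, replicates = 5, seed = 7)
plot(gr)
fit_design_model(gr, drop_zero = TRUE)
```

## Limitations

- Recycled transects understate between-transect variance for `nbT`
  much larger than the observed transect count (see above); treat the
  far right of the grid as a lower bound on achievable error.
- Bootstrap intervals are mildly anticonservative for high-dominance
  assemblages at small unit counts (see the uncertainty section).
- The regression is a descriptive main-effects summary of the grid, not
  a causal or mixed-effects model; replicates of the same site are
  treated as exchangeable observations.
- MultSE depends on the chosen dissimilarity; conclusions here are
  specific to quantitative Bray–Curtis on percent cover.
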