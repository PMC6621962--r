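---
title: "Movement states, multi-scale step selection and predictive surfaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement states, multi-scale step selection and predictive surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bearmove` implements a complete analysis chain for GPS collar data from
black bears living in landscapes with a gradient of human development:
quality filtering and den delineation, step construction, behavioral-state
segmentation, ecological season identification, diel selection ratios,
multi-scale step selection functions (SSFs), a development-acclimation
model, and spatially weighted predictive movement surfaces. Because real
collar data of this kind are rarely shareable, the package carries a
first-class synthetic-data module that generates landscapes and tracks with
known ground truth; every stage is tested against that truth.

This vignette explains each model, its assumptions, the tunable parameters
that matter, and the design choices made where the methodology left the
design open.

## The synthetic study

`make_landscape()` builds a co-registered 30 m raster stack: mutually
exclusive cover classes (deciduous, coniferous and mixed forest, forested
wetland, agriculture, low-density residential) carved from thresholded
smoothed Gaussian noise so patches are contiguous, plus curvilinear roads,
percent impervious surface (elevated in and around residential cells) and
slope. Class proportions are realized almost exactly by construction
(quantile thresholding), so tests can assert them tightly. The
autocorrelation range (default 300 m) controls patch size.

`simulate_tracks()` produces a state-switching biased correlated random
walk per bear. At each fix interval a behavioral state is drawn from the
transition matrix; a step length comes from that state's gamma
distribution, a turning angle from its von Mises distribution; the heading
is pulled toward the home center with a bias that grows with displacement
(keeping each bear in a stable home range); and the candidate endpoint is
accepted with probability proportional to `exp(sum(beta * x))`, with
covariates read at the endpoint and coefficients switched by season and by
a fixed day/night schedule. Denning is simulated as 5 m Gaussian jitter
around the den site, which makes den detection a testable recovery
problem.

The three-state emission defaults (`hmm_par()`) are not reported by any
field study we mirror, so they are free parameters of the generator. They
were fixed once at values plausible for bears on a 45-minute schedule and
separable enough that state decoding is informative: encamped
gamma(mean 20 m, sd 15) with diffuse reversing turns (kappa 0.3, mean pi),
foraging gamma(120, 80) with weak directionality (kappa 0.7), movement
gamma(450, 200) with strongly directed turns (kappa 4), and a sticky
transition matrix (diagonal 0.85/0.80/0.85). Decoding the simulated states
with the *true* parameters succeeds about 95% of the time; that is the
ceiling any estimator can reach under these emissions, and the recovery
tests sit safely under it.

The development-acclimation ground truth is a four-parameter logistic:
each bear's percent-impervious selection coefficient equals
`L0 + (L1 - L0) / (1 + exp(-s (HRHD - x0)))` evaluated at the housing
density around its home center, plus Gaussian noise (default SD 0.05).
Defaults put the inflection at 75 houses/km^2 — the rural-to-acclimated
transition zone — with a strongly avoiding rural asymptote (-3) and a
near-neutral developed asymptote (-0.2).

What the generator does *not* emulate: positional (coordinate) error, male
bears, inter-annual food variation, or realistic geography. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every artifact of field data.

## Preprocessing

Fix filtering removes unresolved fixes, fixes with PDOP > 5 in the weaker
classes (uncertain quick-fix, 2D) and fixes with PDOP > 20 in the stronger
classes (certain quick-fix, 3D). The rules are strict inequalities and
idempotent. Removal fractions are reported per bear and pooled, since a
"mean loss" can be read either way.

Den delineation is automated: a day is *stationary* when the bounding-box
diagonal of its fixes is under 100 m, and the longest run of at least 30
consecutive stationary days within October-May is the den period. The
traditional approach is visual inspection of the fix map; a displacement
rule is the reproducible equivalent, and on synthetic tracks (5 m den
jitter) it recovers den entry and emergence to within about two days.

Steps join only fixes spaced one nominal interval apart (+-2 minutes by
default — collars jitter slightly, and nothing in a step's interpretation
survives interpolation across gaps). Turning angles are heading changes
between consecutive steps and exist only when the previous step shares a
fix. Diel labels use the step's *start* time against sunrise/sunset from
the standard solar-geometry equations for the study site, with day defined
on the half-open interval `[sunrise, sunset)` so each step gets exactly
one label. Season labels default to the three-season calendar (spring =
den emergence to June 14, summer = June 15 to August 9, fall = August 10
to den entry) and can be replaced by a clustered calendar (below).

## Behavioral states

`fit_hmm()` fits a three-state hidden Markov model: gamma step lengths and
von Mises turning angles per state, a full 3x3 transition matrix, and the
initial distribution tied to the stationary distribution of the transition
matrix (one fewer free block; with thousands of steps the initial
distribution is not estimable anyway). The likelihood is the scaled
forward recursion, implemented in C++ for speed; estimation is BFGS on an
unconstrained working parameterization (log means/SDs/concentrations,
multinomial-logit rows) with ten perturbed quantile-based restarts by
default, because the likelihood is multimodal. Zero step lengths (where
the gamma density is undefined) are replaced by half the smallest positive
length. The angular term is simply omitted for steps without a defined
turning angle. States are relabeled in increasing order of mean step
length so that state 3 is always the long-step directed *movement* state;
only movement steps feed the selection analyses. Models are fitted per
bear, since every downstream analysis is individual-based.

Correctness anchors: the forward value is checked against brute-force
enumeration over all `3^n` state paths for short sequences, and decoded
paths are checked to dominate random paths in joint likelihood.

## Seasons from movement and habitat

Daily per-bear series (speed, absolute turning angle, forest/wetland/
agriculture occupancy, impervious value at fixes) are smoothed with a
5-day centered window and range-standardized to [0, 1] within bear-year;
zero-range features are flagged and set to zero rather than producing
NaNs. K-means (multiple restarts) with the gap statistic — uniform
reference over each feature's range, first-SE-rule choice of k — selects
the number of behavioral regimes; daily aggregation (rather than per-fix
clustering) gives every day equal weight. Cluster labels are pooled across
bear-years by modal label per calendar day, smoothed with a 7-day majority
filter, and returned as one date calendar; the modal-label pooling is our
construction, chosen because a single statewide calendar is the output the
rest of the pipeline consumes. A bypass flag returns the default calendar
verbatim.

## Diel selection ratios

Availability is the bear's seasonal 95% kernel density home range:
bivariate Gaussian KDE on the landscape grid (normal-reference bandwidth
per axis — the common default where no study-specific bandwidth is
published), with the isopleth taken as the smallest level set holding at
least 95% of mass. Use is the fraction of each step's path in a category,
computed by sampling the segment every 10 m — resolution-independent, and
configurable if a buffered-path variant is wanted. The third-order
selection ratio for a bear, bin and category is mean path fraction divided
by home-range availability; forest, wetland and residential variants are
unioned before the ratio is computed. The bootstrap resamples *bears* (the
across-bear mean is the estimand), with percentile 95% intervals per
45-minute bin; bins with fewer than two bears are flagged instead of
getting a meaningless interval.

## Multi-scale step selection functions

The used summary of a step is the mean (continuous) or proportion
(categorical) of each layer within a 30 m uniform buffer around the
segment. Availability is a Gaussian kernel placed over the step at each
candidate scale; the kernel is centered on the cell containing the step
midpoint (configurable to the start point), truncated at 3 SDs per axis
and renormalized over in-raster cells. Centering on the grid makes
per-step extraction *identical* to sampling the Gaussian-smoothed raster
at the step, which is both a large speedup (smooth once per layer-scale)
and the exact consistency needed at prediction time; the equality is
asserted to 1e-10 in the tests. Candidate scales default to the mean
distance moved over 45 min to 6 h, recomputed from the data
(`compute_scales()`), or can be supplied directly.

Used and available values are z-scored per covariate over the pooled
used+available rows of the bear's dataset, and the pairing is fitted by
the 1:1 matched conditional likelihood — logistic regression without
intercept on within-stratum differences — by Newton's method with a
damped step. Complete separation is detected (diverging coefficients or a
perfect fit with likelihood at its supremum) and the variable flagged
rather than reported with a meaningless estimate. The implementation is
checked against both a brute-force likelihood search and the exact
partial-likelihood fit in the survival package.

Scale selection runs univariate fits per (variable, scale) and takes the
lowest AICc (`-2 logL + 2k + 2k(k+1)/(n-k-1)`), ties to the smaller
scale. Variables correlated above |r| = 0.7 (strict) at their
characteristic scales are pruned greedily, dropping the higher-AICc member
of the worst pair. Model search is greedy bidirectional stepwise from the
null model, taking the single add/drop that most reduces AICc until no
move helps. Strata with any missing covariate are dropped listwise. The
same machinery runs pooled (all seasons and diel periods) or per
season/diel subset.

## Development acclimation (HRHD)

For bears whose final model retains percent impervious surface, the
standardized coefficient is modeled against home-range housing density
(houses within the 95% isopleth divided by isopleth area). Three forms
compete by AICc under Gaussian error, each charged one parameter for the
error variance: intercept-only, linear, and a four-parameter logistic
`L0 + (L1 - L0)/(1 + exp(-s(x - x0)))`. The four-parameter form is chosen
because "weaker avoidance with development" is a shift between two
negative plateaus — a three-parameter logistic through zero could not
express it. The logistic is fitted by Levenberg-Marquardt with
quantile-based multi-starts. Fits require at least eight bears (the limit
is configurable); with fewer the seasonal fits are skipped, mirroring the
data-thinness that motivates the rule.

## Predictive surfaces

A bear's surface is `exp(b1 x1 + ... + bp xp)` with each covariate raster
smoothed at the variable's characteristic scale and standardized with the
stored fit-time constants. Smoothing at the characteristic scale is an
assumption — the alternative is projecting raw rasters — and we flag it
prominently: it is the choice consistent with how availability entered the
fit. Per-bear surfaces are combined by inverse distance from each bear's
home-range centroid, floored at half a pixel (the weight is singular at
the centroid), normalized per pixel to sum to one; the combined surface is
therefore a per-pixel convex combination, bounded by the per-bear
extremes. Surfaces are kept on the relative exponential scale.

The Boyce index partitions the surface's value range into equal-width
classes (default 10, configurable) and computes the Spearman rank
correlation between class rank and the predicted-to-expected ratio of
hold-out points. Note the Spearman form ranges -1..1 even though the index
is often described on 0..1; we report the Spearman value. Two numerical
cautions discovered in testing and reflected in the test harness: with
few classes the null distribution of the index is wide (|rho| > 0.5 is
common with 10 classes), and strongly skewed exponential surfaces leave
the top classes nearly empty, destabilizing both tails. The calibration
tests therefore use a rank-balanced surface and 20 classes; applications
should prefer enough classes that each holds pixels.

Surface comparison reports pixelwise Pearson correlation, the difference
raster, and masks of the top 20% of positive and top 20% of negative
differences, each quantile computed within its own sign class.

## The demonstration pipeline

`run_pipeline()` chains all stages on a packaged five-bear, 60-day,
45-minute synthetic study on a 200 x 200-cell (6 km) landscape, writing
every intermediate as CSV or ASCII grid with an MD5 manifest; a rerun with
the same configuration is bit-identical. Problem sizes are deliberately
compact: the scale ladder is capped at the 3-hour horizon because on a
6 km landscape longer horizons imply availability kernels wider than a
third of the study area, dominated by edge renormalization. The housing-
density acclimation stage is skipped (with a note in the manifest) when
fewer than eight bears retain the impervious coefficient — with five bears
that is the norm, exactly as small field datasets behave.

Hold-out validation at this scale deserves honesty: twelve fresh
wide-roaming bears are simulated from the same population schedule and
their steps scored against the combined surface. Because a bear's use is
dominated by where its home range happens to fall, and the demo landscape
offers only a handful of independent home ranges, the resulting Boyce
value is highly variable across hold-out cohorts (we observed roughly
-0.2 to +0.95 across seeds); the per-bear in-sample calibration checks in
the test suite are the sharper instrument at this problem size. A
statewide study with dozens of hold-out animals does not have this
problem, which is why the index is useful there.

## Numerical choices and degenerate inputs, in one place

* Gamma density at zero step length: replace zeros by half the minimum
  positive length.
* Reducible transition matrices (e.g. the identity): stationary
  distribution falls back to uniform.
* Zero-range season features: set to 0 and flagged.
* Zero-SD covariates: dropped from the SSF design, logged.
* Separation in the conditional logit: flagged, variable excluded from
  stepwise.
* KDE with identical fixes: error (bandwidth undefined).
* Availability of zero for a category: that bear is excluded from the
  ratio with a warning.
* Inverse-distance weight at the centroid pixel: floored at half a pixel
  width.
* Empty Boyce classes: omitted from the rank correlation.
* AICc with `n - k - 1 <= 0`: error, never silently NA.

## Known limitations

Per-step rejection sampling in the generator produces weaker
landscape-scale redistribution than its per-step coefficients suggest, so
utilization-level summaries (home-range composition, global Boyce) are
muted relative to step-level truth. The HMM treats each bear's step series
as a single chain across schedule gaps, a standard simplification. Season
clustering assumes one calendar across bears. None of the spatial layers
move within a year.
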