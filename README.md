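# bearmove

Tools for analyzing how black bears move through human-dominated
landscapes, built for movement ecologists working with GPS collar data at
15- or 45-minute fix schedules. The package covers the full chain from raw
fixes to predictive maps:

1. **Preprocessing** — fix-quality filtering (PDOP/fix-class rules), automated
   den delineation, step construction from schedule-consecutive fixes, and
   diel (sunrise/sunset) and seasonal labeling.
2. **Behavioral states** — a three-state hidden Markov model with gamma step
   lengths and von Mises turning angles; only long, directed *movement*
   steps feed the selection analyses.
3. **Seasons** — k-means clustering of smoothed movement/habitat series with
   the gap statistic, pooled into one date calendar.
4. **Diel selection** — bootstrapped mean step lengths and third-order
   selection ratios per 45-minute period, with availability from 95%
   kernel density home ranges.
5. **Multi-scale SSFs** — used habitat in a 30 m buffer around each step
   contrasted against Gaussian-kernel availability at a ladder of scales,
   fitted per bear by 1:1 matched conditional logistic regression, with
   AICc characteristic-scale selection, |r| > 0.7 pruning and
   bidirectional stepwise AICc search.
6. **Development acclimation** — the standardized impervious-surface
   coefficient modeled against home-range housing density (HRHD) by
   competing intercept/linear/logistic forms under AICc.
7. **Predictive surfaces** — per-bear projections
   `w(x) = exp(beta_1 x_1 + ... + beta_p x_p)`, combined across bears by
   per-pixel-normalized inverse distance from home-range centroids,
   validated with the Boyce index and compared pixel by pixel.

A first-class synthetic-data module (`make_landscape()`,
`synthetic_study()`, `simulate_tracks()`, `inject_fix_errors()`) generates
landscapes, bear populations and quality-annotated tracks with known
ground truth — state sequences, selection coefficients, den dates, and a
logistic acclimation curve — so every stage is testable without field
data.

## The core models

The movement HMM emits, in state *i*, step lengths
`L ~ Gamma(mean mu_i, sd sigma_i)` and turning angles
`theta ~ vonMises(nu_i, kappa_i)`, with latent states following a 3x3
transition matrix; the likelihood is computed by the scaled forward
recursion and maximized with multiple restarts.

The SSF contrasts each used step against its availability kernel through
the paired conditional likelihood

```
L(beta) = prod_s exp(beta' x_used,s) / (exp(beta' x_used,s) + exp(beta' x_avail,s))
```

equivalently logistic regression without intercept on within-stratum
differences. Characteristic scales minimize
`AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)` among univariate fits.

The acclimation model fits
`beta_imp = L0 + (L1 - L0) / (1 + exp(-s (HRHD - x0)))` against linear and
intercept-only alternatives.

## Worked example

Simulate a three-state step series, fit the HMM, and keep movement steps:

```r
library(bearmove)
set.seed(7)
sim <- r_hmm_steps(hmm_par(), 3000)          # ground-truth generator
fit <- fit_hmm(sim, n_restarts = 5, seed = 1)
print(fit)
#> 3-state movement HMM  (logLik -21704.95  n = 3000 )
#>          step mean (m) step sd angle mean kappa
#> encamped        19.636  14.450      3.075 0.369
#> foraging       120.344  83.791      0.064 0.660
#> movement       448.266 195.032      0.002 3.819
#> transition matrix:
#>       [,1]  [,2]  [,3]
#> [1,] 0.859 0.095 0.046
#> [2,] 0.122 0.779 0.099
#> [3,] 0.043 0.091 0.866

dec <- decode_states(fit, sim)
mean(as.integer(dec$behavior_state) == sim$state)
#> [1] 0.952
nrow(extract_movement_steps(dec))
#> [1] 1037
```

The generating truth was step means 20/120/450 m with a sticky transition
matrix (diagonal 0.85/0.80/0.85): the fit recovers the emission means
within a few percent, and Viterbi decoding labels 95% of steps correctly.
The 1037 movement-state steps are what the selection analyses would use.

The full pipeline — synthetic study in, surfaces out — is one call:

```r
manifest <- run_pipeline(pipeline_config(), "out/")
```

which writes tracks, the removal report, decoded steps, the season
calendar, diel selection ratios, per-bear SSF model tables, and the
combined movement surface under `out/`, with an MD5 manifest; rerunning
with the same configuration reproduces every file bit for bit.

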