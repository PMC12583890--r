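---
title: "Modeling VAS speech categorization: the psychometric model, its indices, and the growth-curve analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling VAS speech categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In a visual analogue scale (VAS) speech categorization task a listener hears
a token from a 7-step acoustic continuum between two minimal-pair words
(e.g. *beach*–*peach*) and taps a continuous 0–100 line anchored by the two
endpoint pictures. Unlike forced-choice identification, the continuous
response separates two properties of a listener's category structure that a
binary response conflates:

* **Slope (gradiency)** — how steeply the average rating changes across the
  continuum at the category boundary. A shallow slope means the listener's
  ratings track fine-grained acoustic differences (gradient categories);
  a steep slope means near-discrete categories.
* **Response Variability (consistency)** — how much single-trial ratings
  scatter around the listener's own average function. A categorical-but-noisy
  listener and a genuinely gradient listener can produce the same *average*
  function; only the trial-level variance tells them apart.

`vascat` implements a complete, testable analysis of how these two indices
develop in school-aged children followed in an accelerated longitudinal
design: three cohorts enter the study in grades 1–3 and are each tested in
four consecutive years, so overlapping grades separate within-child change
from cohort differences.

## The hierarchical psychometric model

For trial $n$ of subject $j$ on continuum (item) $k$ at step $x \in 1..7$:

$$y_n \sim \mathcal{N}\big(\mu_{jk}(x_n),\ \sigma^2_j(x_n)\big)$$

$$\mu_{jk}(x) = L_{jk} + \frac{U_{jk}-L_{jk}}{1+\exp\{-\tfrac{4 s_{jk}}{U_{jk}-L_{jk}}(x - c_{jk})\}}$$

with each curve parameter decomposed as population value + subject random
intercept + item random intercept, e.g.
$s_{jk} = s_0 + u^{(s)}_j + v^{(s)}_k$. The function is parameterized
directly by its derivative at the crossover, so "slope" is a native model
parameter: $\mu'(c) = s$ exactly.

Trial-level variance is log-quadratic in step, centered at the middle of the
continuum (step 4), with a subject-specific intercept:

$$\log \sigma^2_j(x) = w_0 + \theta_j + w_1 (x - 4) + w_2 (x - 4)^2 .$$

A negative $w_2$ captures the necessary fact that ratings near the boundary
are more variable than ratings of clear endpoint tokens. The quadratic is
centered at the fixed mid-step rather than at each subject's crossover; a
fixed center keeps the generator and the model aligned and the profile
identifiable, at the cost of slightly misplacing the variance peak for
subjects whose boundary is far from the middle.

**Priors** are weakly informative on the known measurement scale: asymptotes
$\mathcal{N}(0, 20)$ and $\mathcal{N}(100, 20)$, crossover
$\mathcal{N}(\text{mid}, 2)$ steps, slope $\mathcal{N}(15, 15)$ VAS/step
(soft positivity through prior mass, not a hard bound — screened data always
carry rising profiles, and hard constraints distort boundary cases),
$w_0 \sim \mathcal{N}(5, 3)$, $w_1, w_2 \sim \mathcal{N}(0,1)$, and
half-normal priors on all random-intercept SDs (subject:
15, 15, 1.5, 10, 1.5 for $L, U, c, s, \theta$; item: 10, 10, 1, 5).

**Observation family.** The likelihood is plain Gaussian, not truncated at
the physical 0–100 bounds. The free asymptotes absorb most edge effects, but
for very noisy responders the clipping of real (and simulated) ratings at the
scale ends compresses the observed variance relative to the model's variance.
The practical consequence, quantified in the test suite, is a conservative
(attenuating) bias on Response Variability *differences*: RV levels and all
developmental trends keep their signs but shrink toward zero by roughly a
factor of two at the default noise levels. Tests and acceptance checks were
sized with this attenuation in mind.

**Per-year fitting.** The model is fit to each testing year separately — the
crossed nonlinear random-effects structure makes a single longitudinal fit
impractical — and the longitudinal analysis happens downstream on the
extracted indices.

## Sampling

The posterior is sampled by a purpose-built adaptive Metropolis-within-Gibbs
algorithm (C++ via Rcpp) with all random intercepts in non-centered form:

* single-site Gaussian random walks on every scalar (scales adapted toward a
  0.44 acceptance rate during warmup only, frozen afterwards);
* a joint adaptive-covariance (Haario-style) block proposal on the seven
  population parameters, which handles their strong cross-correlations;
* exact Gibbs draws along the likelihood-invariant translation ridges
  $(\text{pop}, z) \to (\text{pop} + \delta, z - \delta/\text{sd})$ — the
  conditional of $\delta$ is Gaussian, so the population-mean/random-effect
  trade-off mixes in one step;
* Metropolis scale moves $(\log \text{sd}, z) \to (\log \text{sd} + t,
  z e^{-t})$ that traverse the funnel between each intercept scale and its
  standardized effects.

Defaults are 4 chains of 1500 warmup + 1500 kept iterations, which on the
package's reference fixture (30 subjects, 2 continua, 1680 trials) gives
split-chain potential scale reduction below 1.01 and effective sample sizes
in the hundreds-to-thousands for all population parameters, in roughly ten
seconds. Convergence diagnostics (split-$\widehat{R}$, ESS via `coda`) are
computed for every population and scale parameter and any value above the
warning threshold raises an R warning that the pipeline records — never a
silent pass. The log-variance linear predictor is clamped to $[-30, 30]$ so
near-noiseless data cannot overflow `exp()`.

## The subject indices

* `slope_hat` — posterior mean of $s_0 + u^{(s)}_j + \overline{v^{(s)}}$,
  the subject's slope averaged over the tested continua. The item average is
  included deliberately: the *split* between the population slope and the
  item mean is informed only by the prior, so it can drift between
  independently fitted years, while their sum is pinned by the data. Leaving
  it out makes year-to-year comparisons noisier for no benefit.
* `rv_hat` — posterior mean of the subject's trial variance averaged over
  the 7 steps, $\tfrac{1}{7}\sum_x \exp(w_0 + \theta_j + w_1(x-4) +
  w_2(x-4)^2)$. On this squared-VAS scale 0 is perfect consistency and a
  trial SD of ~23 points corresponds to RV ≈ 530, so values of 500–600 are
  possible for noisy responders. Step-averaged variance (rather than
  mid-step variance or an SD scale) is a documented convention choice; it
  reproduces the published scale and weighs the whole continuum.

## Preprocessing

Raw ratings are orientation-normalized (`100 - rating` on blocks where the
endpoint pictures were swapped, an involution), then each participant-year is
screened: pooling all continua, the mean rating per step must reach down to
25 and up to 75 (inclusive). Below that one cannot distinguish poor endpoint
perception from task misunderstanding. Screening is year-specific — a child
excluded in year 2 keeps years 1, 3 and 4. Pooling over continua (rather
than screening per continuum) matches the year-level granularity of the
exclusions; a per-continuum switch is available. The screen uses empirical
step means, not fitted asymptotes: it must run before any model is fit, and
the inclusive reading of the criteria is the permissive one.

Screening has a scientific side effect worth knowing: because shallow-slope
datasets fail the screen more often, and slopes get shallower with age under
the default trends, the screened sample's year trend is attenuated relative
to the generator truth. That selection effect is inherent to the screened
design, not an estimator defect; simulation sizes in the test suite account
for it.

## The synthetic-study generator

The generator is first-class, tested code: it emulates the full study design
(3 cohorts × 4 years × 5 continua × 7 steps × 2 days × 2 repetitions = 140
trials per participant-year), draws per-subject curve parameters from normal
populations, applies developmental trends, simulates heteroscedastic
Gaussian trial noise clipped to the physical scale, and stores flipped
blocks un-normalized so preprocessing has real work to do. Missing
participant-years are completely at random (default 1.5%, the scale of the
real study's year-specific exclusions).

Default ground truth (all configurable in `vas_truth()`):

* 4PL populations: $L$ 8 (SD 5), $U$ 92 (SD 5), $c$ 4 (SD 0.5), $s$ 20
  (SD 6) — asymptotes near but not at the scale edges and mid-continuum
  boundaries, as school-age children produce;
* item SDs 3, 3, 0.3, 2 — continua differ modestly;
* variance profile $w_2 = -0.155$ ($w_1 = 0$), median RV 320
  (mid-continuum trial SD ≈ 20 VAS points), between-subject RV spread 0.4 on
  the log scale;
* developmental trends set to the headline longitudinal estimates the
  package is designed to recover: slope −1.39/year, +2.42/grade,
  −0.81 interaction; RV −26.08/year, −36.78/grade, +26.52 interaction
  (RV trends linear on the variance scale, floored at 20);
* per-subject heterogeneity in the year trends: SD 1.5 VAS/step/year for
  slope, 0.03/year (log scale) for RV.

What the generator does **not** emulate: response piling exactly at 0/100
beyond what Gaussian clipping produces (no censored-response option yet),
lapses/attention failures, session order or fatigue effects, talker or
stimulus acoustics, and non-normal subject populations. Passing tests
therefore show that the estimators recover truth under the stated data model,
not that the model is correct for any particular real dataset.

## Growth-curve stage

The per-subject-year indices enter a linear mixed model with fixed effects
centered testing year, centered start grade and their interaction, and a
by-subject random intercept and random year slope with correlation (REML).
A fallback ladder (drop the correlation, then the random slope, then — for
degenerate zero-variance data — plain least squares) is tried only when a
rung fails to converge or yields an unusable fit, and the simplification is
always flagged in the result's metadata.

Degrees of freedom default to the residual convention
$\mathrm{df} = N - (\text{fixed effects}) - (\text{variance-covariance
parameters})$; Satterthwaite approximation (via `lmerTest`) is available as
an option. Two-sided p-values and Wald t intervals follow that df.
Standardized betas come from refitting the identical model on the z-scored
outcome and predictor columns (each column scaled separately, including the
interaction column), which on any dataset reproduces
$\beta = B \cdot \mathrm{SD}(x)/\mathrm{SD}(y)$.

Marginal predictions over the year × grade grid are fixed-effect linear
combinations with delta-method intervals from the fixed-effect covariance
matrix — enough to draw the cohort trajectory plot in which a positive
interaction on a negative year effect flattens the oldest cohort's decline.

The practice-effect contrast asks whether improvement is a one-time
task-learning jump: for each subject observed in years 1, 2 and at least one
later consecutive pair, it computes (year-1→2 change) minus the subject's
mean later year-to-year change, and t-tests the mean across subjects. Steady
linear development gives exactly zero; a one-time jump after the first year
appears at full size. The injected-jump magnitude used in the power check is
2.78 VAS/step — two years' worth of typical change.

## Numerical and design choices

* Noise is Gaussian on the VAS scale, clipped to [0, 100]; clipping is part
  of the generator (physical scale), not the likelihood (see above).
* The simulated study writes ratings at 17 significant digits so a written
  study round-trips through text exactly and ingest mode reproduces
  simulate mode bit-for-bit.
* Seeds: every stochastic stage takes an explicit seed; the pipeline derives
  per-year fit seeds as `seed + 101 * year`.
* The per-subject NLS check (`oracle_subject_fit`) uses Levenberg–Marquardt
  with three crossover starting points and physical parameter bounds,
  keeping the lowest-SSE solution; it shares no code with the sampler. The
  two routes are compared in a regime chosen by design: 40 subjects with 112
  trials each and a slope spread (SD 8) large relative to either route's
  estimation noise (trial SDs ~11 VAS points), where the expected
  cross-route correlation, `cor(route1, truth) * cor(route2, truth)`,
  exceeds 0.9. With noisier trials or a tighter population the comparison
  would bound the correlation below 0.9 regardless of implementation
  quality.
* Simulation sizes in the test-suite: single-year recovery uses 20 studies
  of 30 subjects × 2 continua with a reduced sampler (2 × 700 + 700); the
  end-to-end sign check uses 20 studies of 3 cohorts × 40 subjects ×
  3 continua with 2 × 350 + 350 sampling — sized by a pre-run power
  calculation so each recovered effect has expected |t| ≥ 7 under the
  default trends; growth-model calibration uses 500 null and 2 × 200
  coverage replicates at 200 subjects.

## Known limitations

* The Gaussian (non-censored) likelihood attenuates RV contrasts for very
  noisy responders; a censored-response option is the natural next step.
* Item random intercepts do not enter the variance profile; continua are
  assumed equally noisy after the mean structure is accounted for.
* The exact df bookkeeping of published mixed-model tables cannot be
  reproduced in general; the residual convention here is documented and
  configurable, and inference is insensitive to it at these sample sizes.
* Per-year fitting ignores the longitudinal correlation of subject effects;
  this follows the published procedure and keeps each year's fit tractable,
  but slightly under-uses information relative to a joint model.
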