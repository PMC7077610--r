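---
title: "Affect variability and discontinuous growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affect variability and discontinuous growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinpulse)
library(dplyr)
```

## The scientific problem

When people repeatedly report how they feel while learning a demanding
task, the reports can be placed in the affect circumplex: a plane whose
axes are valence (pleasant--unpleasant) and activation
(aroused--deactivated). Two people with the same *average* affect can
differ enormously in how much they *move around* that plane. Two
between-person traits summarize that movement:

* **Affect spin** — the circular standard deviation of the angular
  positions of the repeated reports. High spin means the person swings
  between qualitatively different emotional states.
* **Affect pulse** — the within-person standard deviation of the
  extremity (vector length) of the reports, irrespective of direction.
  High pulse means the *intensity* of emotion fluctuates.

`spinpulse` implements the full analysis pipeline for studying how spin
and pulse relate to skill acquisition and adaptation in a
repeated-measures design with an abrupt, unannounced task change:
scoring circumplex reports, computing the variability metrics, building
discontinuous growth-model time codes, fitting the stepwise ladder of
random-intercept mixed models, and generating synthetic studies with
known ground truth so that every stage is testable by parameter
recovery.

## Scoring affect reports

Sixteen adjectives rated 1–9 after each session are averaged into four
subscales: positive-activating (`pa`), positive-deactivating (`pd`),
negative-activating (`na`), negative-deactivating (`nd`). We use item
*means* rather than sums so that every subscale stays on the 1–9
response metric and the composites lie in $[-16, 16]$; `aggregate =
"sum"` is available, and the choice affects scale but not correlations.
The composites are

$$\mathrm{valence}_t = (PA_t + PD_t) - (NA_t + ND_t), \qquad
  \mathrm{activation}_t = (PA_t + NA_t) - (PD_t + ND_t).$$

## Spin, pulse, and their conventions

Each session's report $(v_t, a_t)$ is normalized to a unit vector; the
mean resultant length ratio is

$$\frac{\lVert R \rVert}{n} =
  \frac{1}{n}\Big\lVert \sum_t \big(v_t, a_t\big)/d_t \Big\rVert,
  \qquad d_t = \sqrt{v_t^2 + a_t^2},$$

which is 1 when every report shares a direction and approaches 0 when
directions cancel. Spin is the circular standard deviation

$$\mathrm{spin} = \sqrt{-2 \ln (\lVert R \rVert / n)},$$

which is 0 at the ratio's upper bound and unbounded as the ratio
approaches 0 (the package returns `Inf` there, and the model-fitting
layer *refuses* non-finite spin rather than silently imputing). The
expression without the radical is occasionally seen in print; it is
exposed as `variant = "neg2log"`, but the radical form is the standard
circular SD and the default. Pulse is the standard deviation of the
distances $d_t$ measured from the neutral origin, as the distance
formula reads — not from the person's mean affect point; the origin
convention is a documented choice, and the package implements it as
printed.

Three further conventions matter and are all configurable:

* **Sample SD** ($n-1$ denominator) for pulse and the uni-dimensional
  valence/activation variabilities, matching common psychometric
  practice.
* **Degenerate sessions** with $v_t = a_t = 0$ have no direction: they
  are excluded from the spin sum (with a logged count,
  `n_degenerate_dropped`) but contribute distance 0 to pulse.
* **Missing sessions** are simply omitted; the number used is recorded;
  nothing is imputed.

Numerically, unit-vector normalization leaves $O(10^{-16})$ noise in
the ratio. Because the circular SD has a square-root singularity at the
boundary, that noise would surface as spurious spin of order $10^{-8}$
for a perfectly constant series, so ratios within $10^{-12}$ of 1 are
snapped to exactly 1. Angular dispersion below that level is not
distinguishable from zero in double precision.

## Performance scoring and screens

Per-trial game performance is
$100 \times \big(k/(k+d) + r\big)$ for $k$ kills, $d$ deaths and a rank
term $r \in [0,1]$. The published rank operationalization is not given
numerically, so the package uses the normalized standing
$r = (n_c - \mathrm{place})/(n_c - 1)$ (1 = first among $n_c$ players),
which keeps both addends on comparable scales and the score within
$[0, 200]$; the definition is a documented stand-in and configurable
via a precomputed `rank_term` column. Trials with $k + d = 0$ are
*flatlines*: they get a flag rather than a `NaN`, and the
participant-level screen drops anyone with 2 or more flatlined sessions
("repeated" flatlining; threshold configurable) or any missing session.
Consecutive trial pairs are averaged into session scores (28 trials
$\to$ 14 sessions). Session effort is the mean of six 0–10 items, and
video-game experience is a within-cohort standardized composite of two
frequency and two hours items.

## The discontinuous growth design

For $S$ sessions with a task change after session $c$ (study design:
$S = 14$, $c = 7$), session $s$ receives five codes: `SA` $= s-1$
(linear acquisition), `TA` $= \mathbf{1}[s > c]$ (post-change level
shift), `RA` $= \max(0, s - c - 1)$ (post-change slope change), `SA2`
$= \min(s-1, c-1)^2$ (quadratic acquisition, capped at its pre-change
maximum), and `RA2` $=$ `RA`$^2$. The cap generalizes the published
14/7 table, whose quadratic column freezes at $36 = 6^2$ after the
change; interfaces are 1-based in `session_index` while `SA` starts at
0 — stated explicitly to avoid off-by-one drift.

```{r design}
growth_design(14, 7)
```

## The model ladder

The core model is a two-level linear mixed model with a participant
random intercept, fitted by **maximum likelihood** (not REML) so that
log-likelihoods are comparable as fixed effects are added:

$$Y_{ij} = \gamma_{00} + \gamma_{10}\,SA_{ij} + \gamma_{20}\,TA_{ij}
 + \gamma_{30}\,RA_{ij} + \gamma_{40}\,SA^2_{ij} + \gamma_{50}\,RA^2_{ij}
 + u_i + \varepsilon_{ij},$$

with $u_i \sim N(0, \tau^2)$ and
$\varepsilon_{ij} \sim N(0, \sigma^2)$. The random structure is the
intercept only — no random slopes — which is what the printed
degrees of freedom imply at the study's dimensions
($2996 - 214 - 5 = 2777$). The effort ladder adds, stepwise: ten
person covariates; spin and pulse main effects; their `SA`
interactions; their `TA`/`RA` interactions. The performance ladder
additionally inserts the effort main effect and ends with the
spin/pulse × effort × {`SA`, `TA`, `RA`} three-way products. A
quadratic code that is non-significant in step 1 is dropped from all
later steps (in practice this removes `RA2` from the performance
ladder). The estimation engine is `nlme::lme` with a convergence
tolerance of `1e-8` and up to 500 iterations; starts are deterministic,
so refits are reproducible to `1e-8` under row permutation.

**Degrees of freedom.** Each fixed term is classified by a single rule:
it is a level-1 term iff it involves a time code (alone or in a
product); everything else — person covariates, traits, effort, and the
trait × effort products — is between-person. Level-1 terms get
$N - n - p_1$ df and between terms $n - p_b - 1$, where $p_1$ and $p_b$
count terms of each class in the model. This reproduces the original
software's term-level bookkeeping across both ladders and the ancillary
refits. Classifying effort (a session-level measure) as between-person
looks surprising, but it is what the published df trail implies; the
package reproduces the convention rather than rationalizing it. t
statistics are $B/SE$ against a t distribution with these df; all
displayed p-values are two-tailed, with directional (one-tailed)
p-values alongside in the hypothesis report since every substantive
hypothesis predicts a harmful (negative) effect.

Covariates are *not* centered by default (an explicit
`center_covariates` flag z-scores person-level mains and records the
fact in the fit object).

The six hypothesis families map onto ladder terms as: H1 spin/pulse
mains (effort, step 3); H2 their `SA` interactions (step 4); H3 their
effort interactions (performance, step 5); H4/H5 their `TA`/`RA`
interactions (effort, step 5); H6 the `TA`/`RA` three-ways with effort
(performance, step 6). The ancillary refits substitute emotional
stability for every spin/pulse term (`substitute_covariate()`), which
collapses each former pair of terms into one.

## The synthetic-study generator

`simulate_study()` produces a complete linked study: persons (with
covariates drawn from the cohort descriptive anchors), per-session
circumplex affect, trial-level game results, and effort/performance
outcomes following the discontinuous growth model. Its design choices:

* **Wrapped-normal angles.** Session angles are
  $\theta_t = \mu_\theta + N(0, \sigma_\theta)$. The circular SD of a
  wrapped normal equals $\sigma_\theta$ exactly, so spin recovery
  targets are analytic rather than themselves simulated (a von Mises
  alternative would make the mapping non-trivial for no benefit here).
* **Truncated-normal extremities.** $d_t \sim N(\mu_d, \sigma_d)$
  truncated at 0 keeps distances valid; the truncation bias on pulse is
  small at the default $\mu_d = 6$ and is tolerated inside the
  stochastic test tolerances.
* **Person parameters.** $\sigma_\theta$ and $\sigma_d$ are drawn from
  gamma distributions whose mean/SD equal the published cohort
  descriptives for spin (0.83 / 0.51) and pulse (2.49 / 0.94), so
  realized cohort metrics land near those anchors. Note that the
  sample circular SD at 14 sessions is mildly attenuated relative to
  the generating $\sigma_\theta$ — negligibly at moderate dispersion,
  more visibly in the distribution's right tail where the statistic
  saturates — so realized cohort mean spin sits slightly below the
  anchor, inside the stochastic test tolerances. $\mu_\theta \sim
  N(0.5, 0.6)$ radians (mildly pleasant mean direction) and $\mu_d \sim
  N(6, 1.5)$ truncated at 0 (mid-scale extremity) are the package's own
  choices where no value is reported.
* **Subscale back-fill.** Composites are inverted to subscales around
  the scale midpoint 5 via $pa = 5 + (v+a)/4$, $nd = 5 - (v+a)/4$,
  $pd = 5 + (v-a)/4$, $na = 5 - (v-a)/4$, clipped to $[1, 9]$ with
  clipped rows flagged, so round-trip tests can condition on clip-free
  rows.
* **Outcome coefficients.** Defaults are seeded from the published
  model estimates (time codes and covariates from the base models,
  trait and interaction terms from the final ladder steps), applied on
  the raw, uncentered scales exactly as a fitted model matrix would be.
  The random-intercept and residual SDs are not reported anywhere, so
  the package fixes plausible values once
  ($\tau = 1.6, \sigma = 1.3$ for effort; $\tau = 9, \sigma = 10$ for
  performance) consistent with the published between-person SDs of the
  session-averaged outcomes; they are generator conditions, not tuning
  knobs.
* **Effort enters performance.** Session effort is generated first and
  then feeds the performance predictor; the emitted `effort` column is
  the generated value, while the six 0–10 effort items are integer
  approximations around it for exercising the scoring stage.
* **Trial inversion.** Session performance targets are decomposed into
  place (coarse) plus kill ratio (fine) with integer rounding as the
  only error; targets outside $[0, 200]$ move to the nearest feasible
  value with a warning. Flatlining participants can be injected to
  exercise the exclusion screen.
* **Reproducibility.** One global seed expands into per-participant
  substreams, so any subset of participants re-simulates
  bit-identically.

What the generator deliberately does **not** model: within-person
affect autocorrelation (sessions are drawn independently — real
momentary affect is serially correlated), item-level measurement
models, and any skill dynamics beyond the growth-model functional form.
Passing recovery tests therefore show that the *pipeline* is correct
and well calibrated, not that the substantive findings would replicate
on new human data.

## What the test suite establishes, and at what sizes

The suite checks exact structural facts (the 14-session coding table
cell-for-cell; the df arithmetic implied by every printed t(df),
including the ancillary refits), analytic boundaries of spin, the
equivalence of the vector-formula spin with an angle-space oracle to
$10^{-10}$, rotation/scale invariances, log-likelihood monotonicity
along the nested ML ladders, and the OLS limit of the mixed model when
$\tau^2 = 0$. Simulation-based calibration runs at the study's scale:
basic growth coefficients recovered within $\pm 2$ SE in $\ge 93\%$ of
200 replicates of a 214 × 14 study; mean realized spin within 0.05 of
the generating $\sigma_\theta$ over 500 simulated persons; and null
spin/pulse effects rejected at the nominal 5% rate (within binomial
Monte-Carlo bounds) over 500 replicate fits. Module-level tests use
smaller cohorts (typically 20–60 participants) so the full suite runs
in a couple of minutes; the sizes are stated in the test files
themselves.

## Known limitations

* The rank term in the performance formula is a documented stand-in for
  an operationalization the source literature does not print.
* The between-person classification of effort in the performance
  ladder is a reproduced bookkeeping convention, not a modelling
  recommendation; with it, one isolated printed df (200 for the pulse
  main effect in the two-way performance model, where the accompanying
  printed estimate also disagrees with its own table) cannot be
  reconciled and is treated as a typo.
* Spin of a participant whose directions fully cancel is `Inf`;
  downstream fitting refuses such data by design, and the analyst must
  decide how to handle that participant.
* The generator's independence of sessions makes its affect series
  slightly *less* noisy than real momentary affect; stochastic test
  tolerances are set under that assumption.
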