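---
title: "Methods: from larval behavior and brain expression to cohort outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from larval behavior and brain expression to cohort outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killitox)
```

This vignette is the package's own account of its models: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and
where the design was genuinely open.

## The design

Two killifish populations — a reference site (SCO) and a PCB-tolerant,
historically contaminated site (NBH) — provide larvae in five treatment
groups: SCO control, SCO parental-MeHg, SCO PCB126-exposed, NBH control,
NBH PCB126-exposed. All statistics are organised around five *ordered*
treatment comparisons (`comparison_plan()`): the MeHg contrast, and the
four PCB/population contrasts. Trend signs always read second-minus-first.

## Movement model and its endpoints

Swimming is modelled as a hidden Markov chain over K = 3 latent states
(slow, medium, fast), observed each video frame (default `dt` = 1/30 s)
through a step length and a turning angle. Emissions are gamma (step, mm)
and von Mises (angle, rad), conditionally independent given the state —
the standard choice for discrete-time animal-movement HMMs; nothing in the
assays identifies a different family, and both are flexible enough to code
"slow and tortuous" versus "fast and directed" states. States are
canonically ordered by increasing mean step length, so "the medium-state
step length" or "the probability of staying in the fast state" are
well-defined endpoints across fits.

Fitting is Baum-Welch EM, pooled across larvae: one shared parameter set
per treatment group, larvae as independent chains. Group-level pooling is
the default because the comparisons of interest are group-level transition
endpoints; per-larva empirical transition frequencies (from Viterbi
decoding with the group fit, lightly smoothed) are provided when the trend
caller needs per-individual values. Numerical choices:

* forward/backward/Viterbi run in compiled code in log space with
  log-sum-exp; Viterbi ties break deterministically toward the lower
  (slower) state index;
* zero step lengths (outside gamma support) are floored at
  `step_floor = 1e-6` mm and counted in the fit object;
* turning angles are undefined for the first step of a series and after a
  zero-length displacement; those frames contribute only the step density;
* convergence: relative log-likelihood change below `tol = 1e-6` or 500
  iterations (non-convergence is flagged, best iterate returned);
* `n_restarts = 10` jittered moment-based initializations by default
  (quantile-split step lengths; multiplicative log-normal jitter, sd 0.3);
  the first restart is unjittered, which already sits close to the optimum
  for well-separated states.

The M-step uses weighted maximum likelihood: Newton iteration on the gamma
shape (Minka initialization), and the Best-Fisher approximation to invert
the mean-resultant-length function for the von Mises concentration
(capped at 1e4 — beyond that the angle distribution is numerically a point
mass).

## Behavior endpoints

Time is 0-based; periods and windows are half-open `[start, end)`. The
swimming catalogue per larva and per period: total distance, total time
swimming, bout count/frequency/mean duration, step-length mean and SD,
turning-angle circular mean and circular variance, startle magnitude.
Definitions that the assays leave open were fixed as:

* *step length* is the per-frame displacement (mm per `dt`); "variation"
  endpoints are standard deviations, except turning angles, which use the
  circular variance `1 - R` because angles wrap;
* *bouts* are maximal runs with speed at or above `speed_threshold`
  (default 5 mm/s, between the slow- and medium-state speeds of the
  default movement model), merging pauses shorter than `min_pause`
  (default 0.2 s, a few frames at 30 Hz);
* *startle* is the distance in the `window` (default 2 s) after a light
  transition minus the distance in the equal window before it; positive
  means a burst, negative a freeze. The two windows are closed on the
  shared transition point so their displacements partition the
  surrounding record;
* fewer than two positions in a window yields `NA`, never a silent 0.

The five feeding endpoints are counts and ratios of the event records:
capture attempts, capture probability (captures/attempts), capture attempt
ratio (attempts/encounters), mean reaction distance, mean handling time;
empty denominators give `NA`.

## Trend calling

*Behavior.* The main text of the underlying study specifies only that
treatment comparisons were tested "using Bayesian modeling"; the model here
is deliberately minimal: on a configurable transform (identity, log or
logit), each arm is normal with unknown mean and variance under Jeffreys
priors, so each arm mean has a scaled-t posterior; the treatment difference
is summarised by Monte Carlo (8000 draws per arm), and a comparison is
significant when the central 95% credible interval excludes zero. The
Pos/Neg direction comes from the back-transformed arm means. Arm draws are
keyed to (endpoint, sorted arm labels), which makes reversal of a
comparison *exactly* antisymmetric. A Welch t alternative
(`method = "welch"`) exists for large simulation loops. No multiplicity
correction is applied across behavior endpoints — mirroring the design's
per-test alpha of 0.05 and its explicit "expected by chance"
accounting (`expected_false_positives(0.05, 83)` = 4.15); this is a
deliberate, documented choice, not an oversight.

*Expression.* Per gene: negative binomial GLM with log link and log
library-size offset. The dispersion is estimated in two stages — ML
(`MASS::glm.nb`) for the mean structure, then df-corrected Pearson
residuals, with the model refit at the fixed dispersion — because plain ML
dispersions are biased low with a handful of samples per group and inflate
the Wald statistic; the Wald test is referred to a t distribution with the
residual df. Benjamini-Hochberg adjustment at FDR 0.05 gates the Pos/Neg
calls. Genes with mean count below 1 are excluded and reported. Exact
replication of any named DE package is a non-goal; edgeR appears in the
test suite only as an independent cross-check of the fold-changes.

*Gene sets* use the one-sided hypergeometric tail for Pos and Neg calls
separately, BH-adjusted across sets within a direction.

## Pattern concordance

Each endpoint or gene becomes a vector over the five comparisons with
entries in {+, -, 0}. Grouping is exact equality; matching genes to
behaviors requires equality on *all* positions including zeros (strict
mode, the default) because the patterns are contrasts of the full
treatment design; a relaxed significant-positions-only mode exists behind
a flag. All-zero vectors are ineligible — with nothing significant there
is nothing to match. Single-entry vectors are eligible. Negation is an
involution, and "opposite" matches are reported only when requested.

## The individual-based model

The IBM tracks 2500 larvae per replicate, 10 replicates per scenario, from
hatch (5 mm) to juvenile graduation (15 mm, a configurable stand-in for
"juvenile stage") or 100 days. The source lineage of the original model
defers its equations and constants to supplementary material that is not
part of this package's inputs, so the parameterization here is a concrete,
fully documented stand-in, with every constant exposed in `ibm_config()`
so an external parameter table can be dropped in verbatim:

* **Encounters**: search-volume model, mean = prey density x pi RD^2 x
  swim speed x foraging time; reactive distance and speed scale with body
  length (0.5 BL and 1.5 BL/s); realized counts are Poisson.
* **Consumption**: per-encounter Bernoulli capture (baseline probability
  0.17), capped by the handling budget (foraging time / 40 s per prey) and
  by an allometric, temperature-scaled maximum consumption; prey are
  0.0025 mg dry each. A per-individual lognormal quality scalar
  (CV 0.08) on the maximum consumption supplies individual growth
  heterogeneity.
* **Growth**: dW = 0.7 C - R, with R = 0.08 W^0.8 exp(0.06 (T - 20)) mg/d;
  length follows weight through W = 0.0035 L^3.2 and never decreases.
* **Mortality**: size-dependent predation mu(L) = 11.5 L^-2 per day, plus
  certain death below 60% of the allometric weight-at-length (starvation).
  The steep size exponent concentrates predation risk in the smallest
  larvae, which is what makes cohort survival sensitive to anything that
  prolongs the early, slow-growing phase while leaving survivor growth —
  largely ceiling-limited later in life — comparatively stable.
* **Scenarios**: spring and summer differ only through a sinusoidal daily
  temperature series (summer +4 C); prey density (130/L) is constant by
  default. A per-population foraging-activity scalar (NBH 0.93) encodes
  the tolerant population's lower baseline activity.
* **RNG**: one stream per replicate (base seed + replicate index), with
  vectorized draws across the cohort; results are bit-reproducible given
  the seed and independent of scenario order.
* Parameter uncertainty is deliberately excluded: replicates differ only
  through individual stochasticity, matching the design being emulated.

The constants above were calibrated once, jointly, to the study
conditions the stand-in is required to reproduce — control cohort survival
in the low single digits (1-2%) with survivor growth around 0.3 mm/d, and
the qualitative treatment orderings (PCB-exposed cohorts below their
controls in both populations, the reference-population PCB cohort worst,
tolerant-population PCB growth close to its control) — and are not tuned
beyond that. Treatment multiplier sets in `default_multipliers()` are
synthetic stand-ins encoding reported effect *directions* (handling time
up under PCB everywhere; MeHg improving feeding metrics slightly), since
the quantitative endpoint means behind the real multipliers are not
available as inputs; `derive_multipliers()` computes multiplier sets from
any endpoint-mean table.

## What the generators emulate — and what they do not

The synthetic trajectories have the exact statistical structure the HMM
assumes (true Markov switching, gamma/von Mises emissions), so parameter
recovery there validates the estimator, not the model's adequacy for real
video tracks; real larvae have autocorrelated speeds within states,
tracking noise, wall effects and missing frames, none of which are
simulated. Feeding events are independent Bernoulli/Poisson draws without
satiation or depletion. Counts are NB with a shared (optionally per-gene)
dispersion and planted symmetric fold-changes, without library-size
imbalance or batch structure. Passing tests therefore demonstrate
correctness of the implementations and calibration of the callers under
their assumed models — not robustness to real-data pathologies.

## Problem sizes

The test suite and acceptance script use: 20,000 frames for HMM
transition-probability recovery (50,000 x 20 seeds for the dwell-bias
property), 200 simulated datasets of 50 larvae per arm for the behavior
caller's type-I calibration, 2000 genes for the null expression
simulation and 700-1000 for planted-effect power and FDP, enumeration up
to 10-step chains (59,049 paths at K = 3) for Viterbi equivalence, and
full-scale cohort runs (2500 x 10 replicates x up to 100 days) for every
treatment scenario. These sizes make the whole suite run in a couple of
minutes while leaving the Monte Carlo error of each check well below its
decision threshold.

## Known limitations

* The behavior caller's model (normal on a transform, Jeffreys priors) is
  an interpretation of an under-specified "Bayesian modeling" step; other
  reasonable choices (hierarchical shrinkage across endpoints, explicit
  priors) would change borderline calls.
* The expression caller controls FDR under its NB assumptions; it makes no
  attempt at dispersion moderation across genes beyond the df correction,
  and weak effects at small n will be underpowered relative to moderated
  methods.
* The IBM is a calibrated stand-in: its absolute treatment numbers are
  products of the documented default parameterization and multiplier sets,
  and should be read as structural translations of behavior effects, not
  as re-estimates of any published figure. Spatial structure, prey
  depletion, density dependence and multi-season dynamics are out of
  scope.
* The endpoint catalogue covers the documented suite plus the feeding
  five; it does not attempt to reconstruct a full 83-endpoint battery
  whose exact definitions are not part of this package's inputs.
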