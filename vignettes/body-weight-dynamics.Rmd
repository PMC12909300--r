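---
title: "Modelling body-weight dynamics: states, homeostasis, survival, and genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling body-weight dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwdyn)
```

## Overview

`bwdyn` treats an animal's body-weight trajectory as a switching process:
stretches of weight gain, weight maintenance, and weight loss that
alternate throughout life in response to age, diet, and stressors. This
vignette describes the models and the design choices behind each stage,
what the synthetic-data generator does and does not emulate, and the
numerical conventions used throughout.

## Preprocessing

Raw weights arrive irregularly sampled (roughly every 7–10 days). Each
measurement age is rounded to the nearest multiple of 10 days, with the
half-way tie (e.g. day 15) rounded **up** — a deterministic convention;
collisions on a grid day are averaged. Gaps in the resulting grid are
filled by linear interpolation between the nearest occupied grid days and
flagged, so downstream stages can distinguish observed from imputed
points. The grid never extrapolates beyond the first and last observed
grid days. Animals with fewer than seven raw measurements are excluded:
so few points cannot support state inference. Ages are 0-based days,
intervals are closed-open `[start, stop)`, weights are grams, and the
dietary intervention defaults to day 180 (6 months at 30 days/month).

## The autoregressive hidden Markov model

The weight increment over each 10-day step is modelled conditional on a
latent state $s_t \in \{1,\dots,K\}$:

$$y_t = \phi_0^{s_t} + y_{t-1} + \epsilon_t^{s_t},\qquad
\phi_0^{s} \sim N(\eta_{0s},\, \sigma^2_{0s}),\quad
\epsilon_t^{s} \sim N(0,\, \sigma^2_s),$$

with the lag-1 autoregressive coefficient fixed at 1. This constraint is
what makes the states interpretable: the trajectory is a random walk
whose drift switches with the state, so the sign of $\eta_{0s}$ alone
separates growth, steady, and decline regimes. States follow a
first-order Markov chain.

**Two inference variants.** Where the state intercept's random draw
lives is a genuine modelling choice, so both natural readings are
implemented:

* `collapsed` — the intercept is redrawn at every step. Marginalising it
  gives an *exact* HMM on first differences with emission
  $N(\eta_{0s}, \sigma^2_{0s} + \sigma^2_s)$, fitted by exact EM with
  closed-form M-steps. The two variance components are not separately
  identifiable here, so the fit reports the pooled variance in
  $\sigma^2_s$ and zero in $\sigma^2_{0s}$. This variant doubles as the
  reference oracle: its forward–backward recursions are tested against
  exhaustive path enumeration.
* `random_intercept` (default) — one intercept per animal and state,
  drawn once per life. A structured mean-field variational EM keeps a
  Gaussian posterior $q(\phi_{0}^{m,s})$ per animal and state; the
  E-step alternates closed-form updates of $q(\phi)$ with
  forward–backward passes under expected emission densities, and the
  ELBO is monitored for monotonicity. In the $\sigma^2_{0s}\to 0$ limit
  the two variants agree, which the test suite checks.

**Numerical conventions.** Forward–backward uses scaled recursions
(stable for traces of 200+ points). Per-state noise variances are
floored at $10^{-6}\,\mathrm{g}^2$ to prevent collapse. Initialisation
is k-means on the pooled first differences for the intercept means and a
sticky (0.9 diagonal) transition matrix; restarts use seeds
`seed + 0, 1, ...` and the best restart by final objective wins.
Convergence is declared at a relative objective change below $10^{-8}$,
capped at 500 iterations. Decoding assigns each step the state with the
highest smoothing marginal (not Viterbi); exact ties take the lowest
state index. For $K = 3$, states are relabeled in decreasing intercept
order as growth/steady/decline; an exact intercept tie sends the state
with the smaller noise variance to the steady slot, since steady-state
dynamics are the quietest.

**Choosing K.** The cohort is split 70/30 by animal, stratified by diet.
For each K the model is fitted on the training set and scored on the
held-out set with a deviance information criterion,
$\mathrm{DIC} = 2\bar D - D(\bar\theta)$. The parameter posterior is
approximated from the fit's expected sufficient statistics: Dirichlet
over the initial distribution and each transition row (expected counts
plus a flat prior), Gaussian over the intercept means with asymptotic
variance $(\sigma^2_{0s}+\sigma^2_s)/N_s$; variances stay at their point
estimates, where the held-out deviance is locally flat and draws would
only add noise. The plug-in deviance $D(\bar\theta)$ is evaluated at the
*mean of that posterior* — in particular at the smoothed transition
matrix — not at the raw EM maximiser: an overfitted model's maximiser
contains near-zero transition entries whose log-probabilities explode on
held-out sequences, which would otherwise make the effective-parameter
term negative and reward overfitting. The model-order study in the test
suite uses 10 replicates of 40 traces × 60 grid points with
collapsed-consistent generating parameters ($\sigma^2_{0}=0$), so that
order selection is assessed under a correctly specified likelihood
rather than confounded with variance-component misspecification; sizes
were chosen as the smallest at which the four candidate orders separate
reliably.

## Derived traits

Traits that weigh posterior uncertainty (occupancy, transition
frequencies, binned homeostasis, stability) use the marginals
$\gamma$/$\xi$; traits defined by contiguous runs (longest bouts, their
onsets) and extreme increments (maximum rates) use the MAP path, since a
soft average of a maximum or a run length is not meaningful. Rates
convert 10-day increments to grams/week (×7/10); the normalised variant
divides by the body weight at the step's right endpoint — the weight at
the moment the maximum rate was recorded. Age bins are 6-month
(180-day) intervals from birth to 42 months; life-fraction bins split
`[0, death_day)` into ten deciles and are only defined for uncensored
animals. Missing bins stay missing — zero-filling would fabricate
homeostasis where nothing was observed. The full per-phase catalog has
20 scalar columns (3 occupancies, 9 transition frequencies, 3 bout
durations, 3 bout onsets, 2 maximum rates); a `drop` argument lets a
study work with any subset, e.g. a 19-trait catalog.

## Adaptation to stress

A recovery region opens where the steady-state posterior drops below
0.05 and follows the subsequent strictly increasing stretch, closing at
the first non-increase or on crossing 0.95. Any non-increase breaks the
run — no slack is applied, because the posterior is already a smoothed
quantity. Regions spanning at least 30 days with at least 3 points are
kept. The recovery rate is the $\lambda$ minimising the squared
deviation between the region's steady posterior and the exponential CDF
$1-e^{-\lambda x}$, with $x$ in days from the region's first point and
$\lambda$ bounded in $[10^{-6}, 10]$ per day. Because the CDF saturates,
the objective is flat over most of that interval; the fit therefore
brackets the minimum on an 80-point log-spaced grid before
golden-section refinement, which makes noiseless recovery exact to
optimizer tolerance for any $\lambda$ in the bracket. Regions are
attributed to the most recent phenotyping event within a 30-day
lookback (a plumbing default, configurable), and to age bins of 6–18 and
18–30 months.

## Survival association

Episodes are start-stop rows split at every grid measurement and every
age-bin boundary, with three covariate families: time-fixed diet and
cohort dummies (ad libitum as reference), bin-gated trait values (the
bin-j trait is live only while age lies in bin j, zero elsewhere), and
bin-gated current body weight with optional diet interactions. The
gating reading — weight active within its bin rather than cumulatively
summed — is the only one consistent with body weight acting as an
internal time-varying covariate; a within-episode cumulative sum would
grow without bound. Trait values are z-scored across animals within
each bin so effect sizes are comparable between bins; body weight is
centered at 30 g and scaled by 5 g (configurable). Fitting maximises
the ridge-penalised Cox partial likelihood with Efron ties via
`survival::coxph`; the baseline hazard is left unestimated. The penalty
is chosen by concordance on a held-out 20% of animals (split by animal,
never by episode; ties prefer the smaller penalty; a validation draw
with no events is redrawn with an incremented seed). Effect sizes
report as log proportional hazards; `hazard_interpretation()` converts
$\beta$ to $e^\beta$ and $100(e^\beta-1)$ percent risk change per
covariate unit.

## Genetics

The founder scan regresses a trait on the 8 founder-of-origin dosage
columns (one dropped; rows sum to 2) on top of the nuisance design, and
compares against the covariates-only null with a likelihood-ratio
statistic; $\mathrm{LOD} = \mathrm{LRT}/(2\ln 10)$. Random-effect
genotype-by-diet machinery is out of scope here; the scan is the
fixed-effect analogue. Significance comes from an adaptive sequential
permutation scheme permuting the trait vector: permutation stops at 10
exceedances or a cap of $10^4$, and reports
$p = (1+\#\mathrm{exceed})/(1+\#\mathrm{perm})$ — valid and
approximately uniform under the null while spending almost all
permutations on the promising markers.

The clustered FDR threshold handles correlated phenotypes: within each
phenotype cluster, a per-variant Benjamini–Hochberg pass across the
cluster's phenotypes marks significant associations; each variant then
contributes one sampled p-value (from the significant subset when any,
otherwise from all); BH across variants on the sampled vector yields the
cluster threshold (the largest sampled p passing), and the study
threshold is the minimum across clusters. With singleton clusters the
procedure reduces exactly to textbook BH, which the tests verify, and on
null matrices the fraction of variants below the study threshold stays
at or below the nominal level.

For fine-mapping, each biallelic variant's minor allele is the one
carried by the smaller founder set (a 4-vs-4 split resolves to the
lexicographically smaller set, logged); variants sharing the resulting
founder-allele pattern (FAP) form a group, and groups are ranked by
their best LOD. Patterns print in the conventional founder order (AJ,
B6, 129, NOD, NZO, CAST, PWK, WSB).

## The synthetic cohort generator

`simulate_cohort()` produces data with the structure every stage
assumes: 10-day grids from day 60 to at most day 1260, a shared
pre-intervention chain switching to diet-specific transition matrices at
day 180 (calorie-restricted groups hold steady state longer), initial
weights $N(20, 2^2)$ g, annual phenotyping events that force decline
bouts ending into steady state with a diet-specific per-step probability
$1-e^{-\lambda\cdot 10}$, piecewise-exponential death times whose
per-bin log hazard rises with decline occupancy (default 0.065 per
percentage point), administrative censoring at 1260 days, and
founder-dosage genotypes (two founder draws per animal per marker from a
Dirichlet-perturbed frequency) with an optional planted trait effect.
Events force the *latent chain* rather than editing weights post hoc, so
state-recovery tests are fair. Default intercepts (+0.5, 0, −0.8 g per
10-day step with noise SD 0.15 g) echo the scale of fitted growth /
steady / decline states; they are simulation defaults defining the test
conditions, not estimates from data. What the generator does **not**
emulate: estrous or seasonal periodicity, cage-level food competition,
litter structure, measurement outliers, and missing-visit patterns —
so green tests demonstrate correctness of the machinery under the
stated generative assumptions, not robustness to every artefact of real
colony data.

Simulation studies in the tests and acceptance script use deliberately
modest sizes (e.g. 200 traces × 120 points for parameter recovery, 40 ×
60 for order selection, 500 animals for the hazard recovery, 80-animal
replicates for interval coverage), chosen as the smallest designs whose
Monte-Carlo error is comfortably below the effects being verified.

## Known limitations

* Lag orders beyond 1 and free lag coefficients are intentionally out of
  scope; the φ₁ = 1 constraint is the point of the model.
* A single model is trained across diets; diet-specific transition
  matrices exist only in the generator, mirroring the study design.
* The collapsed likelihood cannot separate intercept from noise
  variance; use the random-intercept variant when that decomposition
  matters.
* The recovery-rate fit conditions on detected regions; rates for
  disruptions that never dip below the 0.05 threshold are undefined by
  construction.
* The founder scan assumes complete trait vectors after listwise
  deletion and fixed-effect covariates only.
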