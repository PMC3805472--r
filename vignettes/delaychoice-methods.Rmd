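---
title: "Modelling intertemporal choice between observed and simulated rewards"
author: "delaychoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intertemporal choice between observed and simulated rewards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaychoice)
```

## The problem

In everyday intertemporal conflicts the tempting option is in front of us
while the delayed alternative exists only as a mental simulation. The
tasks modelled here oppose a less pleasant immediate option to a more
pleasant delayed one (1 month, 1 year or 10 years away), while also
manipulating the presentation mode: *observed* (Obs) options are shown as
pictures, *simulated* (Sim) options as text that must be imagined. Trials
where the immediate option is observed and the delayed one simulated
(Obs/Sim) constitute the *ecological* condition; Obs/Obs and Sim/Sim
trials are *control* conditions that carry the same delay conflict
without a presentation-mode asymmetry. The package implements the full
analysis chain for such experiments — task design, choice modelling,
behavioral and intersubject statistics, and a mediation analysis linking
anatomy, activation and behavior — together with a synthetic-cohort
simulator that generates data with the relevant structure built in,
since no human data ship with the package.

## Task designs

An episodic session has 72 trials: 36 Obs/Sim, 18 Obs/Obs and 18
Sim/Sim, so Obs and Sim options are equally frequent in ecological and
control conditions. Domain (food, culture, sport), condition and delay
are fully crossed — arithmetic then forces 4 repetitions per
domain-by-delay cell in the ecological condition and 2 in each control
subtype. The monetary session keeps the subtype-by-delay crossing;
immediate payoffs are drawn without replacement from the 0.5, 1, ..., 36
euro grid (72 values, each used once) and the delayed payoff adds an
extra amount from the 1, 2, ..., 36 euro vector. That extras vector has
36 elements for 72 trials; it is drawn without replacement within each
half-session block of 36 trials and refilled once, so every extra occurs
exactly twice. Delays are converted to days as 1 day = 1, 1 month = 30,
1 year = 365, 5 years = 1825, 10 years = 3650.

The item catalog lists ten items per domain with ordinal price tiers
1–10. A session needs 48 item draws per domain, so drawing strictly
without replacement over a whole session is impossible with a ten-item
list; item pairs are therefore drawn without replacement from a shuffled
per-domain pool that is reshuffled and refilled whenever fewer than two
items remain — the same block-refill rule used for the monetary extras.
Within a trial the higher-tier item takes the delayed slot, which is
what makes the delayed option the more pleasant one. Presentation order
and the screen side of the immediate option are counterbalanced exactly
50/50 per session, with randomized assignment per seed.

Patient variants: `"expA"` keeps the full 72-trial factor structure
(choice screens only); `"expB"` restricts the design to food items with
delays 1 day / 1 month / 5 years, 36 trials per session (18 ecological,
9 + 9 control) — the proportions of the main design on the condition ×
delay crossing.

## The choice model

Option values live on the likeability-rating scale. Monetary amounts are
mapped onto it by the affine transform of the session's amount range
onto $[-10, 10]$ (minimum to $-10$, maximum to $+10$; an order-preserving
minimal choice — the mapped range can also be fixed to the theoretical
grid limits 0.5–72 euros). Values are discounted hyperbolically,

$$V = \frac{R}{1 + kD},$$

with $R$ the rating or transformed payoff, $D$ the delay in days and
$k$ the discount rate per day; immediate options have $D = 0$ and are
never discounted. Choice probabilities follow a softmax rule with
temperature $\beta$,

$$P_\text{imp} = \frac{e^{V_i/\beta}}{e^{V_i/\beta} + e^{V_d/\beta}}
             = \frac{1}{1 + e^{(V_d - V_i)/\beta}},$$

computed in the logistic form on log scale so the likelihood is finite
for any $\beta > 0$. The free parameters $(k, \beta)$ are fitted per
subject (or pooled over subjects for a common set) by maximising the
log-likelihood of the observed choices. The optimizer is deterministic:
a coarse grid over $\log_{10} k \in [-5, 0]$ and $\log \beta \in [-2, 3]$
(25 × 25 points), then Nelder–Mead refinement from the grid optimum,
with parameters in log space to enforce positivity. Fits whose optimum
sits within 0.25 log units of the search boundary, or whose data contain
only one choice type, carry a boundary flag. Tasks are fitted separately
by default because their value units differ; pooling is explicit.

Fit quality is summarised by the *prediction score*: the percentage of
trials on which the option with the strictly higher fitted value was
chosen, with exactly tied trials excluded from the denominator (the
"higher value" is undefined at a tie).

### Precision of the discount-rate estimate

The recovery precision of $\hat k$ is bounded by the information in the
design, not by the optimizer (which was checked against a dense
brute-force grid). With 720 trials, $\beta = 2$, integer values spanning
the rating scale and delays split equally across 30/365/3650 days, the
Cramér–Rao bound on the standard deviation of $\log_{10}\hat k$ is about
0.12 at $k = 0.001$–$0.01$ and 0.16 at $k = 0.1$ per day: even an
efficient unbiased estimator localises $\log_{10} k$ to $\pm 0.2$ in at
most roughly 79–91% of replicates, and the implemented MLE operates at
that bound (it is empirically unbiased with matching spread). Away from
the delay set's sensitive range, single-subject discount rates should
therefore be interpreted with order-of-magnitude caution.

## The synthetic cohort

Because the analyses need data with known ground truth, the simulator
generates agents whose internal valuations, ratings, richness reports,
choices and scalar neural measures follow one coherent generative story.
Per item, simulation richness is a truncated-normal draw on the 0–20
detail-count scale, rounded to an integer. The latent item value is

$$\text{latent} = \text{baseline} + b_\text{tier}(\text{tier} - \bar{\text{tier}})
  + b\,(r - \bar r) + \varepsilon,$$

and the reported rating is the latent value rounded and clipped to
$[-10, 10]$; Sim-presented ratings are further reduced by the agent's
Sim-valuation deficit $\delta_\text{sim}$ before clipping. Choices are
generated from the latent values: the delayed option is discounted
hyperbolically with the agent's true $k$, then $\delta_\text{sim}$ is
subtracted from the decision value of any Sim-presented option, and the
choice is a Bernoulli draw from the softmax with the agent's true
$\beta$. Applying the deficit *after* discounting is deliberate: in
Sim/Sim control trials it cancels exactly from the value difference, so
a Sim-specific valuation deficit produces ecological-specific
impulsivity and leaves control behavior intact — subtracting it from the
undiscounted rating would instead make strongly affected agents *less*
impulsive on Sim/Sim trials, because hyperbolic discounting shrinks
negative values toward zero. The richness term enters the latent value,
so richness and ratings are correlated across trials within every agent;
the direction (richness driving value) is a modelling choice the
behavioral data cannot adjudicate.

Default generative distributions (per-group means; all exposed in
`group_spec()` / `cohort_config()`):

| parameter | default | units / rationale |
|---|---|---|
| $k$ | lognormal(log 0.01, 0.9) | per day; median 0.01 with roughly half-a-decade spread in $\log_{10}k$, as in discounting cohorts |
| $\beta$ | lognormal(log 2, 0.3) | rating units; moderate choice stochasticity |
| baseline likeability | N(2, 1.5) between subjects, SD 2 across items | rating units; reward items are mildly pleasant on average |
| tier slope | 0.7 | rating units per price tier; spans ~6 units across the catalog |
| richness | mean N(10, 2) between subjects, SD 4 across items | detail counts on 0–20 |
| richness slope $b$ | N(0.4, 0.1) | rating units per detail |
| age | healthy 24, CTL 68, AD 72, bvFTD 67 | years |

Phenotypes: **CTL** (elderly control) has $\delta_\text{sim} = 0$ and
baseline $k$; **AD-like** adds $\delta_\text{sim} \sim N(6, 1)$ —
a Sim-specific valuation loss producing ecological-specific impulsivity;
**bvFTD-like** multiplies the median discount rate tenfold — a
condition-general impulsivity. **healthy** (young adults) carries a
small positive deficit, $\delta_\text{sim} \sim N(1.5, 0.5)$ reduced by
the neural coupling below and truncated at zero, creating the
intersubject variability in ecological impulsivity that the
intersubject analyses exploit.

Scalar neural measures are generated with explicit directionality:
grey-matter density $GM \sim N(0, 1)$; ecological activation
$BOLD_\text{eco} = \beta_1 GM + \varepsilon$; control activation is
noise; the reported contrast is their difference. The neural score
$\beta_0 GM + \beta_2 BOLD_\text{eco}$ feeds back into the agent's
$\delta_\text{sim}$ with a coupling of 4 rating units per score unit
(healthy experiments), so anatomy influences choice *only through*
activation when $\beta_0 = 0$ — the structure the mediation analysis is
meant to recover. All randomness flows from one master seed through
named substreams (`substream_seed()`), so any stage can be reproduced in
isolation.

What the simulator does *not* emulate: response times, fMRI time series,
session-order effects, satiation or learning, and the observed monetary
choice rates — under the printed affine transform every immediate option
maps to a negative value and every delayed option exceeds its immediate
counterpart, so a model-consistent agent chooses the immediate option
only through softmax noise (about 15–20% of monetary trials, against
roughly 46% in human cohorts). Passing tests therefore certify the
analysis chain and its calibration on model-consistent data, not the
behavioral realism of the monetary task under this value transform.

## Statistics

* **Robust regression** (`robust_fit()`): iteratively reweighted least
  squares with Tukey's bisquare weights, tuning constant 4.685, robust
  scale $\mathrm{MAD}/0.6745$, iterated until the maximum coefficient
  change falls below $10^{-8}$ or 50 iterations. Intersubject tests use
  the studentized slope ($t$ = coefficient/SE from the final weighted
  step). With small residuals all weights are 1 and the fit reduces to
  least squares.
* **Per-subject slope test**: robust slope within each subject, then a
  one-sample $t$ test across subjects; one-sided by default for
  directional couplings (e.g. richness–rating).
* **Binned summaries**: equal-count quantile bins computed within
  subject (ties broken by stable order), bin means averaged across
  subjects with intersubject SEMs — 8 bins for rating-by-richness,
  9 for choice-rate-by-value-difference displays.
* **Interaction GLM**: outcomes for both conditions stacked and
  regressed on behavior $X$, a condition dummy $Z$, their product and
  covariates of no interest; the condition-specific correlation test is
  the $t$ test on the $X{\times}Z$ coefficient.
* **Group × Condition**: split-plot ANOVA (`aov` with an
  `Error(subject)` stratum); interaction df $(g-1)(c-1)$, error df
  $(N-g)(c-1)$ — $F_{1,28}$ at 15 + 15 subjects and two conditions. The
  per-subject ecological-minus-control difference is also fed to an OLS
  GLM with group and age regressors to verify the group effect survives
  age adjustment. No multiplicity correction is applied across
  behavioral tests.
* **Mediation** (`mediate()`): OLS estimation of
  $BOLD = \beta_1 GM$ and $CHOICE = \beta_0 GM + \beta_2 BOLD$
  (intercepts always included), nonparametric case resampling of
  subjects (default 10,000 bootsamples), percentile CIs (BCa optional),
  two-sided p-values from doubled tail proportions. The OLS identity
  total $= \beta_0 + \beta_1\beta_2$ (with the total effect from the
  marginal regression $CHOICE \sim GM$) holds exactly on every sample
  and is recomputed as a self-check. "Full mediation" is flagged when
  the indirect CI excludes zero while the direct CI includes it.
  Variables can be standardized first (off by default). Degenerate
  bootstrap resamples with constant GM or BOLD are redrawn.

Type-I error of the slope test, the interaction GLM and the split-plot
interaction was verified by null simulation (1,000 replicates each,
rejection rates 0.045–0.053 at $\alpha = 0.05$); indirect-effect CI
coverage under a null $GM \to BOLD$ path is 0.956 over 500 replicates
(n = 200 subjects, 400 bootsamples per replicate — sizes chosen to keep
the default check affordable while leaving the binomial error below one
point).

## End-to-end runs

`run_healthy_experiment()` composes the healthy analyses (subject and
pooled fits, richness coupling, binned summaries, intersubject
consistency of choice rate and discount rate between tasks, the
interaction GLM on per-condition activation, mediation) and
`run_patient_experiment()` the patient ones (per-group rates by
condition, within- and between-group tests, the interaction ANOVA, the
age-adjusted GLM). Both are deterministic functions of config + master
seed; with an output directory they write CSV/JSON tables and a manifest
with MD5 checksums, and re-running reproduces every output byte for
byte. `scripts/acceptance.R` drives both runs (n = 20 healthy; 15 + 15
patients) plus a 100-replicate recovery study per true discount rate and
writes the headline numbers as JSON.

## Known limitations

* The monetary task is weakly informative about $k$ under the printed
  value transform (see above); intersubject discount-rate consistency
  between tasks is reliably detected at pooled-cohort sizes (n ≈ 34)
  but not in small samples.
* Discount-rate recovery at the edges of the delay set's sensitive
  range ($k \ge 0.1$/day with a 30-day shortest delay) is bounded below
  ±0.2 log-unit precision by the design's Fisher information.
* Group differences driven by a tenfold discount-rate shift are
  direction-stable but modest in rate units (the nonimpulsive rate has
  a floor where the immediate option's value is negative), so
  bvFTD-style comparisons at n = 15–20 per group have limited power;
  the AD-style ecological dissociation is large and detected
  essentially always.
* Mediation at n ≈ 20 subjects (the single-cohort scale) is
  underpowered for the indirect-path test; the package's coverage and
  recovery guarantees are stated at n = 200–1,000.
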