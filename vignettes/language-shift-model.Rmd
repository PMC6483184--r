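---
title: "Modelling contact-induced language change during language shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling contact-induced language change during language shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftsim)
```

## The model

shiftsim simulates how a novel variant of a single linguistic feature
spreads through a speech community undergoing language shift, i.e. a
community in which large numbers of second-language (L2) speakers are
joining the population of an expanding language.  The hypothesis embodied
in the model is that L2 speakers, and only L2 speakers, introduce the novel
variant — as a by-product of second-language acquisition — and that
ordinary conversational interaction then propagates it.

Each agent $i$ carries a usage distribution
$p_i = (p_{i1}, \dots, p_{in})$, $\sum_k p_{ik} = 1$: the probability of
producing variant $k$ of the feature in an interaction.  Variant 1 is the
conservative (pre-contact) variant; variant 2 is by default the designated
novel variant.  In each interaction round, agents are paired by a uniformly
random perfect matching; both members of a pair utter a variant drawn from
their own distribution and both then update toward the partner's utterance
$u_j$:

$$p_{ik}' = p_{ik} + (1 - p_{ik})\,l \quad\text{if } u_j = k, \qquad
  p_{ik}' = p_{ik} - p_{ik}\,l \quad\text{otherwise},$$

where $0 \le l \le 1$ is the learning weight.  The update conserves the
unit sum algebraically, and the round as a whole is *neutral*: the expected
change in the population mean usage $\bar p_k = \frac1N \sum_i p_{ik}$ is
zero for every variant.  `expected_round_change()` verifies this by exact
enumeration of all matchings and utterance outcomes for small $N$; the test
suite checks it to $10^{-12}$.  Change in mean usage therefore comes only
from demographic turnover, not from the interactions themselves — drift
plus directional innovation, with no selection on either variant.

A model year consists of $T$ interaction rounds (default 365) followed by
demographic change:

* **L1 births.**  A newborn averages the usage distributions of two
  distinct, randomly chosen parents (acquisition from a small set of native
  models) and enters as an L1 speaker.
* **L2 recruitment.**  A recruit averages the entire (pre-turnover)
  population — acquisition from many models — *except* that with
  probability $\mu$ it instead enters using the novel variant
  categorically ($p = 1$ on the novel variant).  This entry-time
  innovation is the engine of change.
* **Deaths** are uniform over agents.

Because innovation is unidirectional (nothing ever reintroduces the
conservative variant categorically), universal novel-variant use is the
only absorbing state when recruitment continues; the quantity of interest
is the *rate* at which mean novel usage rises.

Two innovation models are supported.  Under **model 1** the $\mu$-draw
happens only at the moment of entry.  Under **model 2**, second-language
acquisition is treated as a multi-year process: every L2 speaker still
inside an acquisition window of `sla_window_years` (default 7) years may
additionally adopt the novel variant with probability $\mu$ at the start of
each year.  Entry counts as the first opportunity, so a recruit gets
exactly seven opportunities in total; `sla_entry_counts = FALSE` switches
to the reading in which the seven annual passes come on top of the entry
draw.

## Demographic regimes

Three regimes drive turnover:

* **fixed** — $\mathrm{round}(dN)$ agents die each year and are replaced
  (L1 birth with probability $b/(b+r)$, else L2 recruit); $N$ is constant.
* **expanding** — deaths, births and recruitments are integer realizations
  of $dN$, $bN$, $rN$ via stochastic remainder rounding (floor plus a
  Bernoulli on the fractional part, which keeps small scaled counts
  unbiased); the expected growth rate is $g = b + r - d$.
* **census** — turnover follows a per-year schedule built from a census
  table of L1/L2 counts by `census_to_schedule()`.

The census regime is built around the Maputo, Mozambique data
(`maputo_census()`): Portuguese speakers by first/second language at 1975,
1980, 1997 and 2007.  Between anchors the class totals are interpolated
geometrically (constant yearly growth factors; linear interpolation is used
only where an endpoint is zero, where a geometric path is undefined).  Each
year, `round(mortality * N)` deaths are apportioned deterministically to
the two classes by composition, and the yearly L1 births and L2 recruits
are exactly the net changes needed to reach the next year's targets plus
replacement of that class's deaths.  Deaths are then sampled uniformly
*within* each class when the schedule is applied.  This construction makes
the schedule reproduce the census totals exactly at every census year at
`scale = 1` (a property the test suite asserts for the Maputo table), which
a fully class-blind death draw could not guarantee.  If a class shrinks
faster than mortality allows, implied negative births/recruits are clamped
to zero and compensated by extra deaths, with a warning.

Two reconstruction parameters are genuinely under-determined by the census
anchors and are therefore exposed as configuration:

* `mortality` (default 0.02/yr): a plausible crude death rate for the
  population and period; the qualitative behaviour of the comparison is not
  driven by it, but the late-period recruit flow (when the census L2 total
  is nearly flat) is proportional to it.
* the interpolation shape: geometric was chosen because population growth
  between censuses is multiplicative; other schedules consistent with the
  same anchors would redistribute the (very large) 1975–1980 recruitment
  wave within that phase.

`scale` divides all census counts for desk-scale runs (default 100, giving
a 1975 population of 201 agents growing to about 10,800 by 2007; interior
per-year targets are realized by stochastic remainder rounding, census
anchors deterministically).  Scaling up the population reduces drift but
leaves ensemble mean trajectories essentially unchanged.

Initial conditions follow the historical reading of the data: in 1975 every
agent — including the existing L2 stock — uses the conservative variant
categorically, and the initial L2 speakers are treated as established
(tenure equal to the acquisition window), so under model 2 they are not
retroactive innovators.  `initial_l2_tenure` overrides this.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `l` | 0.05 | learning weight per interaction; affects variance across runs far more than the mean trajectory.  0.05 is the conservative choice (small weight per encounter, tighter ensembles); sweep-style figures often use 0.1. |
| `mu` | 0 | innovation probability per opportunity; with recruitment rate $r$, the product $\mu r$ sets the rate of introduction and is the dominant control on the rate of spread. |
| `rounds_per_year` | 365 | one interaction per agent per day; interactions are neutral, so this mainly sets how fast individual distributions track the population mean. |
| `b`, `r`, `d` | 0.007, 0.063, — | per-capita yearly rates; expanding-regime default $d = b + r - 0.05$ (growth 0.05), fixed-regime default $d = b + r$. |
| `sla_window_years` | 7 | duration of the L2 acquisition window under model 2, an estimate of the length of second-language acquisition. |

## The model–data comparison

Corpus observations are speaker-level token counts: per speaker and
recording year, the number of tokens of the variable context and the
number using the novel variant.  The population mean usage is estimated by
a beta-binomial model — counts binomial given a speaker-specific rate, the
rate drawn from a Beta($\alpha$, $\beta$) across speakers — whose mean
$\alpha/(\alpha+\beta)$ is the quantity of interest.  `fit_betabinom()`
maximizes the likelihood by multi-start L-BFGS-B on (logit mean, log
concentration) coordinates.  Log-concentration is box-bounded at 15:
beyond $e^{15}$ the model is numerically indistinguishable from a plain
binomial while the log-beta differences lose all precision to
cancellation, which would otherwise let the optimizer wander to absurd
shape values.  Datasets with all-zero (or all-saturated) counts get an
explicit boundary fit rather than an error.  Uncertainty comes from a
nonparametric bootstrap over speakers (500 replicates, percentile
interval, refits warm-started from the full-data optimum); no closed-form
CI is attempted because speaker counts are few and unbalanced.

Simulated predictions are summarized per parameter setting by replicate
ensembles (default 10 runs).  The per-year "95% interval" is
$m_y \pm 1.96\, s_y$ where $m_y, s_y$ are the mean and standard deviation
of the run values — the spread of runs, not a standard error — i.e. where
a single realization of the process is expected to land.  A setting
*fits* the data only if this interval contains the data MLE in **every**
observation year (`overlap_fit_check()`).  Among candidate innovation
rates, `select_min_mse()` picks the setting minimizing the mean squared
distance between ensemble means and MLEs over observation years (ties to
the smaller $\mu$; arbitrary, including refined, grids are accepted).  For
the selected setting, `joint_tail_probability()` fits a normal per
observation year to a larger replicate set and multiplies the two-sided
tail masses $2\min(\Phi(z_y), 1-\Phi(z_y))$,
$z_y = (\mathrm{MLE}_y - m_y)/s_y$, treating years as independent
conditional on the model.  Two-sided tails are the default because the
direction of a misfit is not privileged; `sided = "one"` halves each
year's mass (an exactly central year then contributes 0.5, not 1).

## Synthetic data

`generate_speaker_counts()` inverts the inference model: speaker rates
from a Beta(mean $\times$ c, (1-mean) $\times$ c), counts binomial.  The
concentration parameterization (mean, $\alpha + \beta$) is used for
interpretability; the default concentration 10 represents moderate
speaker heterogeneity, and default token counts are drawn uniformly from
5–40 to mimic uneven interview yields.  The packaged corpus files under
`inst/extdata/` (`synthetic_verb_counts.csv`,
`synthetic_preposition_counts.csv`) are *synthetic stand-ins*, generated
by this machinery and then calibrated so that their pooled novel-token
proportions equal the published sample means for the two Maputo features
(verbs: 10.6% in 1993, 20% in 2007; prepositions: 16.9% and 25.7%).  They
reproduce those pooled proportions and the beta-binomial structure, not
the original speakers' individual counts, which are not redistributable
here.  Passing tests on these fixtures therefore demonstrate that the
pipeline recovers the published summary statistics from data of the
assumed form — not that the original corpora satisfy the beta-binomial
assumption.

`generate_census()` produces census tables with phase-wise geometric
growth for testing the schedule builder.

## Numerical and design choices

* **Pairing.**  Uniform random perfect matching per round, both partners
  utter and both update, one uniformly chosen agent idle at odd $N$.  Each
  agent has exactly one encounter per round; both utterances are sampled
  before either update, so there is no order-dependence within a pair.
* **Year-boundary ordering.**  Interactions, then the tenure increment,
  then the model-2 innovation pass, then demographic turnover.  Because
  interactions are neutral in expectation, recorded mean trajectories are
  insensitive (in expectation) to where the innovation pass sits relative
  to the rounds; the chosen order maps "at the start of a year" to
  immediately after the year boundary.
* **Batch turnover.**  All deaths, parent draws and recruit means within a
  year use the same pre-turnover snapshot, making the yearly step
  order-independent and vectorizable.
* **Determinism.**  All randomness flows through R's RNG (the compiled
  interaction kernel included), so any run, ensemble or table is
  bit-reproducible from its seed; ensembles derive per-run seeds from a
  master seed.
* **Tolerances.**  Usage rows are validated to sum to 1 within $10^{-12}$;
  the engine renormalizes (with a warning) only if floating drift exceeds
  $10^{-9}$, which the algebraically conserving update never approaches in
  practice.  The likelihood optimizer converges to ~$10^{-8}$ relative on
  the log-likelihood.
* **Speed.**  The interaction round is O(N) compiled code; a scale-100
  Maputo run (32 years, 365 rounds/year, up to ~10,800 agents) takes on
  the order of a second, so grid sweeps with replicate ensembles are
  desk-scale.

## Problem sizes used by the test suite

The packaged tests exercise the full pipeline at the study's scales:
sweep-style ensembles use 10 replicate runs of 100 years; the Maputo
comparisons use scale 100, the innovation grid $\mu = 0.01$–$0.1$ in steps
of 0.01 with 10 runs per setting, and 100 replicate runs at each selected
minimum-MSE setting; estimator calibration uses 100 synthetic corpora of
50 speakers x 20 tokens with 500-replicate bootstraps.  Exact properties
(neutrality, schedule/census agreement, pooled fixture proportions) are
asserted to $10^{-12}$ or exactly.

## Known limitations

* The learning weight is homogeneous: no speaker-class-dependent learning,
  interaction biases between classes, or network structure.  The model is
  strictly neutral — a variant favoured by production or learnability
  biases (a live hypothesis for morphological simplification) will depart
  from its predictions.
* The census-driven schedule is a reconstruction from four census anchors;
  within-phase timing of the (historically enormous) early recruitment
  wave, and the mortality rate, are modelling choices that shape how
  innovation opportunities are distributed over time — materially so for
  model 2, whose innovation flux follows the standing stock of recent
  recruits rather than the inflow itself.
* Demographic events are batched at year boundaries; there is no
  within-year turnover, age structure, or emigration.
* With two observation years per feature, the comparison machinery can
  rank settings and models but cannot validate the model class.
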