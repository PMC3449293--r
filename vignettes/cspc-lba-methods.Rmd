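---
title: "Modelling context-specific proportion congruent effects with the linear ballistic accumulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling context-specific proportion congruent effects with the linear ballistic accumulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspclba)
```

## The scientific question

In a flanker task, responses to a central target are slower and less
accurate when the surrounding distracters are associated with the opposite
response (incongruent trials). When stimuli appear in a *context* — here, a
side of fixation — where incongruent trials are frequent (75%), this
interference effect shrinks relative to a context where they are rare: the
context-specific proportion congruent (CSPC) effect. Two mechanistic
accounts compete. Under a *processing-selectivity* account, frequent-conflict
contexts prime a tighter attentional focus, changing the **rate** at which
sensory evidence for the correct response accumulates. Under a
*response-caution* account, contextually unexpected stimuli (e.g. a
congruent array on the mostly-incongruent side) trigger a prediction-error
signal that raises the **amount** of evidence required before responding.
Mean RTs cannot separate these; a process model of the full choice-RT
distribution can.

This package implements that comparison with the linear ballistic
accumulator (LBA) and provides everything needed to run it end to end on
delimited trial data or on synthetic cohorts with the same design.

## The LBA and its closed forms

Each response (left/right) has an independent accumulator that starts a
trial at a uniformly random evidence level in $[0, A]$, rises linearly at a
drift rate drawn once per trial from $\mathcal N(v, s^2)$, and triggers its
response on reaching threshold $b \ge A$. The observed RT is the winning
crossing time plus a non-decision time $t_0$ (encoding + motor). For one
accumulator the crossing-time distribution has the standard closed forms

$$F(t) = 1 + \tfrac{b-A-tv}{A}\Phi\!\big(\tfrac{b-A-tv}{ts}\big)
       - \tfrac{b-tv}{A}\Phi\!\big(\tfrac{b-tv}{ts}\big)
       + \tfrac{ts}{A}\phi\!\big(\tfrac{b-A-tv}{ts}\big)
       - \tfrac{ts}{A}\phi\!\big(\tfrac{b-tv}{ts}\big)$$

with the density $f(t)$ its derivative (`lba_cdf()`, `lba_pdf()`). The
probability of observing choice $c$ at time $t$ is the *defective* density
$f_c(t-t_0)\,[1 - F_{\bar c}(t-t_0)]$ (`lba_defective_density()`), which
integrates to the probability of that choice rather than to 1.

Numerical conventions, chosen once:

* **Degenerate start point.** For $A$ below $10^{-8}$ the closed forms
  divide by ~0; the crossing law then is $b/\text{drift}$, giving
  $F(t) = \Phi\!\big(\tfrac{v - b/t}{s}\big)$. The branch agrees with the
  general formula to well under $10^{-6}$ near the switch.
* **The $ts$ denominator** is floored at $10^{-10}$ so $t \to 0^+$ is
  well defined.
* **Density floor.** Log-likelihoods use $\ln \max(f, 10^{-10})$, keeping
  the optimization objective finite everywhere inside its box.
* **Error-accumulator drift.** The study's parameter tables report a single
  drift per condition; the mean drift of the losing accumulator is taken as
  $1 - v$. This sum-to-one convention makes the reported scale
  ($v \approx 0.6$–$0.8$, $s \approx 0.13$–$0.19$) identifiable and is the
  common choice for two-choice LBA fits.
* **No renormalization** of the (both-drifts-negative) defect: at the
  scales involved its probability is $<10^{-5}$. The simulator redraws such
  trials.
* **Units.** Seconds internally; RT columns in files are milliseconds and
  divided by 1000 at ingest.

## The model space

Four conditions (context high/low conflict × congruent/incongruent) and
six parameterizations (`build_condition_params()`), all sharing $s$, $A$
and — except the `T0` extension — a single $t_0$. Thresholds are
parameterized as distances $d = b - A$, which keeps $b \ge A$ under plain
box constraints; reported thresholds are $b = A + d$.

* **V1** (k = 8): one $d$; a free drift per condition.
* **V2** (k = 7): one $d$; drifts $v_{C\text-L}, v_{I\text-L}$ and a shift
  $\Delta v$, with $v_{I\text-H} = v_{I\text-L} + \Delta v$ and
  $v_{C\text-H} = v_{C\text-L} - \Delta v$.
* **B1** (k = 9): a free $d$ per condition; drifts vary with congruency
  only.
* **B2** (k = 8): $d_{C\text-L}, d_{I\text-L}$ and a shift $\Delta b$, with
  $d_{I\text-H} = d_{I\text-L} - \Delta b$ and
  $d_{C\text-H} = d_{C\text-L} + \Delta b$; congruency-only drifts.
* **VB** (k = 11) and **T0** (k = 8): extension models (both $d$ and $v$
  free, resp. a condition-varying $t_0$), kept for recovery completeness
  but outside the headline four-model comparison.

Positive $\Delta v$/$\Delta b$ produce the standard CSPC pattern; their
sign is unrestricted in fitting. Two genuinely open points were settled as
follows. First, the verbal description of B2 (equal-magnitude threshold
decrease for incongruent and increase for congruent stimuli in the
high-conflict context, anchored on each congruency's own low-conflict
cell) conflicts with a formula rendering that anchors both high-conflict
cells on the incongruent-low distance; only the verbal reading makes a
positive $\Delta b$ produce the standard CSPC effect, so it is the
default, with the literal reading available via
`b2_mapping = "literal"`. Second, whether the drift models estimated one
$b$ or one $d = b - A$ is not determinable from the reported averages; a
single $d$ is used, consistent with the distance parameterization of the
threshold models.

## Fitting

`fit_participant()` maximizes the summed log defective density over a
participant's omission-free trials (`prepare_fit_data()`; no RT-window
trimming is applied for fitting — the stricter descriptive trimming is a
separate accounting). The search is a particle swarm with standard
constriction-style settings — 40 particles, 500 iterations, inertia 0.72,
cognitive = social = 1.49, 3 restarts — plus two robustness measures that
matter more than raw budget:

* one particle per restart starts at a data-informed point ($t_0$ just
  below the fastest RT, $d$ sized from the median decision time, drifts at
  the scale typical of flanker fits);
* each restart's best particle is polished with bounded L-BFGS-B (the
  likelihood is smooth in the parameters), and the best polished optimum
  wins.

With the heuristic start and polish, a reduced budget (24 particles, 80
iterations, 2 restarts) reaches the same optima on session-sized data
(448 trials) in a few seconds per model; the simulation studies in the
tests and scripts use that budget, and fitted log-likelihoods are checked
against the generating parameters (they should rarely fall more than 1
log-unit below, and in practice exceed them). Box bounds are generous
brackets of the published scales — $s, A, d \in (0.001, 2]$,
$v \in [0, 2]$, $\Delta b, \Delta v \in [-1, 1]$ — except $t_0$, which must
stay below the participant's fastest RT or every density vanishes. All
randomness flows from the seed recorded in the returned object;
re-running a configuration reproduces the fit bit for bit.

## Model selection

`information_criteria()` computes $\mathrm{AIC} = 2k - 2\ln L$ and
$\mathrm{BIC} = k \ln N - 2\ln L$; their penalties cross at $\ln N = 2$,
so at $N \approx 445$ BIC is always the stricter criterion.
`ic_weights()` applies the usual transformation
$w_i = e^{-\Delta_i/2} / \sum_k e^{-\Delta_k/2}$, and `b_vs_v_ratio()`
forms the evidence ratio $(w_{B1}+w_{B2})/(w_{V1}+w_{V2})$ — how much more
likely a response-caution model is to be the true model than a
processing-selectivity model. Ties in best-model tallies are split equally
(order-independent); the mean cross-data-set ratio is the unweighted
arithmetic mean, which reproduces the published 1.87 (BIC) and ≈4 (AIC)
from the printed weights. Reconstruction of those printed tables is exact
up to the 3-decimal rounding of the published weights (about ±0.01 on the
ratios, ±0.1 percentage points on pooled percentages).

Fit quality is displayed through defective quantile summaries
(`quantile_summary()`, `predicted_quantiles()`): within-class 10/30/50/70/90%
RT quantiles with cumulative heights scaled by each class's response
proportion, and through quadrature-based predicted moments
(`predicted_moments()`).

## Conventional behavioral statistics

`trim_trials()` removes the first trial of each block (by its recorded
index, so trimming is idempotent), omissions, and RTs outside
150–2000 ms; post-error correct trials are flagged and excluded from RT
means only. `cspc_statistic()` is the interference difference
(incongruent − congruent), low- minus high-conflict context, in ms and
error percentage points; `label_transitions()` marks context repetitions
vs switches using the previous *retained* trial (the alternative —
pre-trim adjacency — is not recoverable from the published description,
and the difference only affects trials adjacent to a trimmed one).
Inferential ANOVAs are deliberately out of scope: with no raw data
deposited, the package exposes the cell means and contrasts those tests
were built on.

## The synthetic-data generator

`design_spec()`/`generate_design()` reproduce the study's design exactly:
448 trials (4 × 112 scanner blocks or 7 × 64 behavioral blocks), equal
trial counts per side, one side 75% incongruent and the other 75%
congruent, realized as exact per-block counts followed by a seeded shuffle
(the study says only "pseudorandomly", so exact counterbalancing is the
cleanest reproducible reading). `simulate_participants()` draws each
trial's choice and RT from the LBA race at a specified parameterization —
by default the published group-average values, the realistic operating
point — and injects omissions at 0.7%, matching the reported mean of ~445
valid trials of 448. A master seed spawns per-participant streams, so any
participant regenerates in isolation.

What the generator deliberately does **not** emulate: per-participant
parameter heterogeneity (the published averages carry no dispersion
information, so cohorts are homogeneous at the generating values — a
jitter knob would be a straightforward extension), sequential dependencies
beyond the design's context-transition structure (no post-conflict or
post-error adaptation), and the occasional very fast errors seen in real
data. Passing recovery tests therefore show that the pipeline is correct
and well calibrated for LBA-distributed data of this size, not that the
LBA is the true model of any particular data set.

## What recovery can and cannot show at the published scale

At the published B2 averages the context shift is small
($\Delta b = 0.01$, against threshold distances of 0.26–0.31). With 448
trials, drift rates recover to a median absolute error well under 0.05 and
the *sign* of $\Delta b$ recovers in roughly three quarters of simulated
sessions — informative but not certain, which is worth knowing when
interpreting per-participant shift estimates. Class recovery is similarly
asymmetric: data generated from V2 are confidently assigned to the drift
class, while for B2-generated data the extra threshold parameter buys only
a ~2 log-unit likelihood advantage over V2, which BIC's $\tfrac12\ln N$
per-parameter penalty can erase; AIC, with its smaller penalty, remains
better at crediting the threshold class. The published weights show the
same signature — BIC spreading mass onto V2 while AIC concentrates on the
threshold models — so this is a property of the inference problem at these
effect sizes, not an artifact of the optimizer.

## Problem sizes

The packaged tests and scripts keep simulation studies at sizes chosen to
make their statistical claims at reasonable cost: oracle comparisons use
$10^5$–$10^6$ draws; parameter recovery uses 20 session-sized replicates;
model recovery uses 10 simulated participants per generator with all four
models fitted at the reduced swarm budget; CSPC-direction checks use
25–50 replicates. The analysis scripts under `analysis/` run an 8-participant
demonstration cohort end to end.
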