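---
title: "Discordant pair analysis: model, assumptions, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discordant pair analysis: model, assumptions, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discordr)
```

## The estimation model

Two binary classifiers score the same n unlabeled samples: a baseline M0
with known operating characteristics (sensitivity SENS0, specificity
SPEC0, positive-outcome prevalence PREV) and an updated M1 whose
performance is to be estimated. Cross-tabulating the paired predictions
gives four cells: both-positive (C_PP), both-negative (C_NN), and the two
discordant cells D_NP (only M1 positive) and D_PN (only M0 positive).
Only the D = D_NP + D_PN discordant samples are adjudicated by experts.

The identification argument rests on one structural fact: within the
concordant set the two models made identical calls, so they share the same
true positives (TP_0C = TP_1C) and true negatives (TN_0C = TN_1C). Writing
P = n x PREV for the assumed positives, the baseline assumption
SENS0 = (TP_0C + TP_0D)/P can be solved for the unobservable TP_0C, and
substituting it into M1's sensitivity gives the closed form implemented in
`estimate_sensitivity()`:

SENS1 = (SENS0 x P − TP_0D + TP_1D) / P,

with the mirror-image `estimate_specificity()` on the negative side using
N = n − P, TN_0D = D_NP − TP_1D and TN_1D = D_PN − TP_0D. Everything the
data contribute enters through the two adjudicated counts; in fact both
estimators depend on the discordant labels only through the *net*
differences TP_1D − TP_0D and TN_1D − TN_0D.

The method's assumptions are therefore explicit inputs: SENS0, SPEC0 and
PREV must transport from the baseline's earlier validation to the current
evaluation population. Misspecifying them biases the estimates directly
(see the prevalence study below); the method offers no internal check of
these assumptions.

`af_example_records()` ships a deterministic reconstruction of the
evaluation this methodology was developed on — 4,302 ICM-detected atrial
fibrillation episodes scored by a high-sensitivity baseline detector and a
specificity-improving update (cells 2640/272/35/1355, D = 307). The
published tabulation identifies the discordant adjudications only up to
the net differences (+8 true positives, +245 true negatives in the updated
model's favour); the bundled split (33 of 35 in D_NP positive, 25 of 272 in
D_PN positive) is one representative, and every quantity the package
computes from the fixture depends only on the nets.

## Confidence intervals

`sample_sensitivity()` / `sample_specificity()` implement a multi-stage
Monte Carlo bootstrap that propagates the assumption uncertainty. For draw
k of K:

1. PREV_k ~ Beta(c, c/PREV − c) — a prevalence prior with mean exactly
   PREV and concentration c (`prev_concentration`, default 100, giving
   roughly ±4 percentage points of spread at PREV = 0.615);
2. P_k ~ Binomial(n, PREV_k), N_k = n − P_k — one shared class split per
   draw, used by both metric chains;
3. TP_0k ~ Binomial(P_k, SENS0) (and TN_0k ~ Binomial(N_k, SPEC0));
4. SENS_1k ~ Beta(a + 1, P_k − a + 1) with a = TP_0k − TP_0D + TP_1D, the
   discordant correction applied to the simulated baseline count (mirror
   for SPEC_1k).

`ci_from_samples()` returns empirical quantiles at (1 − level)/2 and
1 − (1 − level)/2 with linear interpolation between order statistics
(quantile type 7); the choice of quantile rule is a convention — at
K = 10,000 the interpolation scheme moves the bounds by well under the
Monte Carlo noise.

Numerical guards, all unreachable at realistic problem sizes but needed
for a total function:

- a (and its mirror b) is clamped into [0, P_k] so the Beta shapes stay
  positive even under extreme draws;
- draws with P_k = 0 or P_k = n are redrawn from stage 1, since both
  chains need a non-degenerate split;
- the point estimators clamp results into [0, 1] with a warning — possible
  only when the baseline assumptions are misspecified, and worth surfacing
  because it almost always means they are.

The concentration c is deliberately exposed: how much prevalence
uncertainty to admit is an application judgement, and tightening c toward
infinity recovers a fixed-prevalence analysis.

## The simulator

`simulate_trial()` generates paired predictions with known truth. True
labels are Bernoulli(prev); *conditional on the label*, the pair of model
predictions is drawn from a bivariate Gaussian copula
(`correlated_bernoulli_pair()`): latent (Z0, Z1) standard bivariate normal
with correlation rho, prediction_i = 1 iff Z_i <= qnorm(p_i), where the
marginal positive-call rates are the two sensitivities among true
positives and the false-positive rates 1 − spec among true negatives.

Two design choices deserve note:

- **Class-conditional correlation.** Conditioning on the truth is what
  lets the true sensitivities and specificities be exact marginal
  Bernoulli parameters, which the study design requires; the same latent
  rho is used in both classes. rho is the *latent* correlation, not the
  Pearson phi of the binary pair; `implied_phi()` reports the implied phi
  for any (p1, p2, rho) so sweep results can be read on either scale.
- **Degenerate margins short-circuit.** p = 0 or 1 and rho = ±1 skip the
  latent draw, making comonotone identical models (rho = 1, equal
  margins) produce exactly zero discordance rather than
  floating-point-occasionally-one.

What the simulator emulates is the *stochastic* structure of a paired
evaluation: exchangeable samples, label-conditional dependence between the
models, binomially realized class sizes. What it does not emulate — and
what passing simulation tests therefore cannot vouch for — includes
within-patient clustering of episodes (multiple episodes per monitor are
correlated in reality), data and adjudication drift between the baseline's
validation era and the new evaluation, and adjudicator labeling error.

## Simulation studies

`run_correlation_study()`, `run_samplesize_study()` and
`run_prevalence_study()` sweep one factor while holding the others at the
reference operating point (sensitivities 0.988/0.990, specificities
0.727/0.882, prevalence 0.615, n = 5000, rho = 0.90). Per sweep point they
aggregate, over independent trials: MSE of each estimate against a
comparator, mean bootstrap CI width, CI coverage of the comparator, and
mean percent adjudication reduction 100(1 − D/n).

**Comparator.** The default comparator is each trial's fully adjudicated
*observed* updated-model metric; `comparator = "true"` switches to the
generating parameter. The choice matters more than it may seem. Against
the observed metric, the specificity estimator's error reduces
algebraically to SPEC0 minus the baseline's *realized* specificity, so its
MSE has an irreducible floor SPEC0(1 − SPEC0)/N — about 1.03e-4 at
n = 5000 — regardless of implementation: the assumed baseline specificity
is a constant while every trial realizes a binomially noisy one. Against
the true parameter that term drops out and the MSE at the same design
point is ~8e-5. The package defaults to the observed comparator (it is the
operationally meaningful one: "what would full adjudication have said on
*this* dataset") and documents the floor rather than hiding it.

**Reproducibility.** Every trial runs on its own RNG substream derived
arithmetically from (study seed, sweep value, trial index), so per-point
results are independent of sweep order, any single trial can be re-run in
isolation, and a whole study is bit-reproducible from its seed.

**Flagged trials.** A trial that realizes zero positives or zero negatives
cannot be scored against an observed comparator; such trials are flagged,
excluded from aggregation, and counted in the output (`n_flagged`). At the
reference design points this never triggers; it exists for extreme
prevalence-by-small-n corners.

**Study defaults and desk-scale runs.** `n_trials` defaults to 10,000 —
the replication level appropriate for production characterization — with
bootstrap K = 2,000 inside studies (K = 10,000 is reserved for the
one-shot real-data analysis, where the extra precision is cheap). The
package's own test suite and the acceptance script run the sweeps at 500
trials per point, which resolves the qualitative behaviour (savings above
80–90%, conservative specificity coverage, the n = 5000 precision
benchmarks) at a few percent Monte Carlo error; coverage assertions allow
two binomial standard errors at that replication.

## What the sweeps show

The tests assert, and the acceptance script recomputes, the following
patterns at the reference operating point:

- **Correlation** drives the economics: percent adjudication reduction is
  above 80% at every rho and above 90% as rho approaches 1 (correlated
  models rarely disagree), while specificity CI coverage stays at or above
  nominal throughout — the prevalence prior makes the intervals
  conservative.
- **Sample size** drives precision: MSE and CI width shrink monotonically
  in n; near n = 5000 the sensitivity MSE is a few 1e-6, the specificity
  MSE sits at its ~1e-4 floor, and both CI widths are at or below 0.08.
- **Prevalence misspecification** is the method's soft spot, and it is
  asymmetric. The discordant corrections scale with the *realized* class
  sizes while the estimator divides by the *assumed* ones, so
  under-specifying the prevalence (true above assumed) collapses coverage
  sharply, and over-specifying it is safe only within about ten
  percentage points — beyond that the specificity correction overshoots
  (estimates clamp at 1) and its coverage collapses too. Sensitivity MSE
  grows once the true prevalence exceeds the assumed value. Practical
  guidance: err on the side of over-specifying PREV, but not by more than
  ~0.1.

## Known limitations

- Binary outcomes only; no multi-class or score-threshold support, and no
  PPV/NPV estimation (those would need different identification
  arguments).
- The baseline assumptions are taken on faith; the method cannot detect a
  stale SENS0/SPEC0, and the prevalence study shows what a stale PREV
  costs.
- Episodes are treated as independent; clustered data (many episodes per
  patient) would need wider intervals than the bootstrap produces.
- The bootstrap quantifies assumption uncertainty, not adjudicator error:
  discordant labels are treated as ground truth.
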