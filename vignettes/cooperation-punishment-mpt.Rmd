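---
title: "Measuring cooperation and costly punishment with a multinomial processing tree model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cooperation and costly punishment with a multinomial processing tree model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punishMPT)
```

## The measurement problem

In a one-shot simultaneous Prisoner's Dilemma with a costly punishment
option, the raw frequency of punishment conflates qualitatively different
motives. A participant who punishes a partner that cheated on their
cooperation (moral punishment) is doing something very different from one
who punishes a cooperating partner after cheating themselves (antisocial
punishment), or from one who simply tends to press the punish button no
matter what happened. A framing manipulation — morally loaded choice labels
("I cooperate"/"I cheat") versus neutral ones ("A"/"B") — may affect these
motives differently, so they must be separated before the conditions are
compared.

The multinomial processing tree (MPT) model implemented here does that
separation. Per framing condition it has five latent probabilities:

| parameter | meaning |
|---|---|
| `C` | cooperating in a round |
| `P_Moral` | punishing a partner whose defection met one's own cooperation |
| `P_Hypocritical` | punishing a defecting partner after defecting oneself |
| `P_Antisocial` | punishing a cooperating partner after defecting |
| `b` | outcome-independent punishment bias |

The participant's choice is made simultaneously with the partner's, so `C`
is shared across both trees (it cannot depend on what the partner will
do). Punishment after mutual cooperation has no plausible dedicated motive,
so the model attributes it entirely to the bias `b`; in the remaining
three outcomes a dedicated punishment parameter acts first and the bias
mops up afterwards, giving branch probabilities of the form
`P + (1 − P) b`. Each tree (partner cooperated / partner defected)
therefore predicts four cell probabilities that sum to one:

```{r}
category_probabilities(mpt_parameters(C = 0.4, P_Moral = 0.6,
                                      P_Hypocritical = 0.3,
                                      P_Antisocial = 0.2, b = 0.1))
```

Punishment is treated as binary (any investment above 0 cents); the model
makes no statement about the invested amount.

## Estimation

Trial-level data are pooled within condition into the eight-cell category
table (`aggregate_trials()`), the model's sufficient statistic. Pooling
across participants is the standard convention of aggregate-frequency MPT
fitting; per-participant heterogeneity is deliberately not modelled, which
is a recognised limitation of the approach rather than an oversight —
hierarchical MPT variants exist but are out of scope here.

`fit_mpt()` minimizes the likelihood-ratio statistic
`G² = 2 Σ n ln(n/e)` over the free parameters, which is equivalent to
maximizing the multinomial likelihood. Numerical choices:

* **Scale.** Optimization runs on the log-odds scale, so there are no box
  constraints for the optimizer to collide with; estimates are
  back-transformed. Estimates within `1e-6` of 0 or 1 are flagged as
  boundary solutions.
* **Starts.** The first start is a moment-based inversion of the observed
  cell proportions (the bias is read off the mutual-cooperation tree, then
  each punishment parameter is unfolded from its punish cell); the
  remaining starts (default 20 in total) are drawn uniformly on the
  log-odds scale from a fixed start seed, so fits are deterministic. Ties
  between optima are broken by the lower G², then by the lexicographically
  smallest parameter vector.
* **Tolerances.** BFGS with a relative convergence tolerance of `1e-12`
  on G² (configurable via `reltol`).
* **Degenerate cells.** Zero observed counts contribute `0 · ln 0 = 0`; a
  positive count in a cell the parameters make impossible yields `G² = +∞`
  with a warning rather than silent clamping.
* **Standard errors** come from the inverse observed information of the
  multinomial log-likelihood at the optimum (numerical Hessian). The
  reference analyses report standard errors without naming a method;
  observed information is the standard choice and is what the coverage
  simulations below validate. SEs are omitted with a warning at boundary
  solutions, where the quadratic approximation fails.

Equality constraints across conditions are implemented by parameter
sharing — one free value bound to several slots — not penalties, so the
nested-model difference `ΔG²` follows from simply refitting. With two
conditions the unconstrained model has 10 free parameters against
12 free cells (df = 2), and each constraint adds one df.
`check_identifiability()` confirms local identifiability numerically: the
Jacobian of the free cell probabilities has full rank 10 at generic
interior points, and degenerates in interpretable ways (with `C = 0` in a
condition, that condition's `P_Moral` is confounded because no trial mass
reaches the cooperate cells).

## Inference and power

Goodness of fit refers G² to the central χ² distribution with the model's
residual df. Framing effects are tested per parameter by
`ΔG² = G²(restricted) − G²(full)` against χ²(1); the package reports raw
p-values per parameter, mirroring the reference analyses, and applies no
multiplicity correction. The effect size is Cohen's
`w = √(ΔG²/N)` with `N` the total category-observation count
(participants × trials across both conditions — 1960 for the 98-participant
design; this convention reproduces all ten reference (ΔG², w) pairs at two
decimals, which is how it was pinned down). Power calculations use the
noncentral χ² distribution with `λ = N w²` (the G*Power convention for
χ²-family tests, confirmed by round-trip tests);
`sensitivity_w()` inverts the power function by bracketed root finding
(tolerance `1e-10`), giving the familiar minimal detectable `w ≈ 0.08`
for both reference designs at α = β = 0.05.

## What the simulator emulates

`simulate_experiment()` is the generative counterpart of the measurement
model, reproducing the reference designs: 98 (or 93) participants assigned
alternately to the two framing arms, 20 one-shot rounds each against
partners with an exactly balanced cooperate/defect schedule in uniformly
random order, a 400-cent endowment, the payoff matrix
(temptation 20 > reward 10 > mutual-defection 0 > sucker −10, in cents),
and punishment investments of 1–9 cents removing ten times that amount.
The second design adds partners who morally punish the participant's
unilateral defection at a uniformly random 1–9 cent cost. Choices are
Bernoulli in `C`; punishment is Bernoulli in the branch probability of the
realized outcome cell.

Choices the data do not dictate, made once:

* The punishment **amount**, which the model ignores, is drawn uniformly
  from 1–9 cents; the rule is pluggable (`agent_profile()`), because no
  empirical amount distribution is available.
* Partner identity is reduced to the trial index, and the display rule
  that a partner's balance starts within ±10 cents of the participant's is
  implemented as cosmetic jitter with no behavioral consequence.
* Randomness uses one root seed with per-participant child streams, so
  enlarging a simulated sample leaves earlier participants' data
  byte-identical.

The simulator emulates the *designs*, not everything about real
participants: agents are homogeneous within condition, memoryless across
rounds (truly one-shot), and exactly faithful to the tree. Passing
recovery and calibration tests therefore shows the estimator and tests are
correct and well-calibrated *under the model*; it cannot show that real
participants satisfy the model's assumptions (that is what the
goodness-of-fit test is for on real data), nor calibrate against
individual differences the aggregate model ignores.

## Calibration evidence and problem sizes

The test suite computes (sizes chosen to give stable Monte-Carlo checks at
interactive runtimes):

* **Parameter recovery**: 200 replications of the 98-participant design
  with interior true values; absolute bias of every free parameter below
  0.02 and ~95% coverage of `estimate ± 1.96 SE`, judged against the exact
  binomial 99% band.
* **Type-I error**: 500 null replications (equal parameters across arms);
  the `P_Moral` equality test's rejection rate at α = 0.05 must fall in
  the exact binomial 99% band around 0.05.
* **Oracle equivalence**: the fitted minimum beats every point of a
  0.05-step grid over the free parameters on a one-condition toy table,
  and the closed-form category probabilities match a million-trial
  simulation within 3 SE per cell.
* **Printed-value reproduction**: all ten reference (ΔG², w) pairs and
  both sensitivity analyses.

## Known limitations

* Aggregate (pooled) fitting assumes homogeneous participants within
  condition; real heterogeneity can bias parameter estimates and inflate
  G² — a hierarchical extension would be the remedy.
* Chi-square calibration of G² and ΔG² is asymptotic; with very small
  samples or boundary parameters the reference distribution degrades.
* Punishment magnitude carries information the binary model discards.
* The power machinery treats the ΔG² test as a generic χ²-family test via
  `λ = N w²`; this is the convention the reference sensitivity analyses
  used, not an exact small-sample computation.
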