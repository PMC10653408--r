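---
title: "Methods: the DR screening cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DR screening cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscreen)
```

## The decision problem

Diabetic retinopathy (DR) is a progressive microvascular complication of
diabetes and a leading cause of working-age blindness. In rural China,
DR prevalence among diabetics is high while ophthalmologists are scarce,
so the policy question is whether annual population screening — by an
ophthalmologist panel reading fundus photographs, or by an
artificial-intelligence grading system — is worth its cost to the health
system, compared with no screening at all.

`retscreen` answers this with a Markov cohort model: a closed cohort of
10,000 rural diabetic patients is propagated through seven health states
(no DR; mild, moderate and severe non-proliferative DR; proliferative DR;
blindness; death) over 50 annual cycles. Patients either keep their state
or progress one severity step per cycle; recovery is not allowed; death
is reachable from every state and absorbing. Costs and
quality-adjusted life years (QALYs) accrue per cycle, are discounted,
and the three strategies are compared by incremental cost-effectiveness
ratios (ICERs) against willingness-to-pay (WTP) thresholds of 1–3 times
per-capita GDP.

## States, transitions and mortality

The annual transition probabilities of the natural history are
progression rates between adjacent severity states (0.07, 0.19, 0.17,
0.29, 0.21 from no-DR onward). Mortality is composed per state from the
rural background annual death probability of 7.07 per mille and two
multipliers: 2.34 for diabetes and 1.9 for blindness.

Two composition choices deserve comment because the source material
leaves them open:

* **Order of events.** Death is resolved first each cycle, and
  progression applies to survivors: `P(progress) = (1 − d) · p`,
  `P(stay)` the remainder. Rows stay stochastic without renormalization,
  and the fraction of 5-cycle survivors still DR-free from an all-no-DR
  start is exactly `0.93^5 = 0.6957`, the value the study prints.
* **Multiplier wiring.** The default applies the diabetes multiplier to
  every alive non-blind state (`7.07‰ × 2.34`) and both multipliers to
  the blind state. Under this wiring the 50-cycle state distribution
  matches the published one (66.6% dead; 3.4% of survivors still
  DR-free), whereas the published 5-cycle death fraction (6.5%) would
  require the blindness multiplier on non-blind states instead — the two
  published figures are mutually inconsistent. Both wirings are
  available (`mortality_wiring` in `dr_parameters()`); the 50-cycle
  agreement decides the default.

## Reward accrual, discounting and the half-cycle correction

State membership is evaluated at the cycle nodes `t = 0 … n`. Node `t`
contributes `occupancy(t) · reward · (1 + r)^−t`; with the half-cycle
correction on (the default) the boundary nodes get weight ½ — the
trapezoid rule, equivalent to the classic "transitions happen mid-cycle
on average" correction of cohort software. With the correction off,
rewards accrue at end of cycle, so a single alive state with per-cycle
survival `s` yields the geometric sum `u · Σ s^t (1+r)^−t` exactly.
A 3% annual rate discounts both costs and QALYs; one-time treatment
costs are charged to new entrants of a treated state at their arrival
node.

Two base-case conventions were genuinely open and were fixed by
requiring the model to reproduce the published no-screening
effectiveness of 16.83 QALYs per patient:

* the cohort starts **all alive without DR** (the study states this as
  the cohort's initial stage; the observed stage-prevalence start
  remains available via `init = "prevalence"`), and
* rewards are discounted **at the node where they accrue** (the first
  half-cycle is undiscounted), rather than uniformly at end of interval.

With these, `dr_cea()` yields 16.8343 discounted QALYs for the
no-screening arm — the printed 16.83 — and sensible behaviour of every
toggle (turning the correction off, or starting from prevalent disease,
lowers QALYs). Note one side effect: under node accrual the half-cycle
correction is only exactly neutral on a constant-occupancy chain at a
zero discount rate, which is how the property is tested.

## Screening strategies and the treatment effect

Screened arms screen every alive state annually at 100% compliance.
Patients detected in a referable state (severe NPDR or PDR by default)
receive laser photocoagulation, which multiplies their progression
probability by a relative risk of 0.49. Progression out of a treated
state is therefore the mixture
`blended_progression(p, w, rr) = w·rr·p + (1 − w)·p`, where `w` is the
annual probability that a diseased patient is actually detected and
treated.

What should `w` be? The published per-patient test sensitivities are
90.79% (AI) and 96% (ophthalmologist). Keying treatment to them makes
ophthalmologist screening *more* effective than AI — the opposite of the
study's published ordering (AI 17.17 QALYs vs ophthalmologist 16.86),
of its dominance labelling and of its acceptability curves. The study,
however, lists the *observed positive detection rate* of each programme
(32.59% for AI, 16.54% for the ophthalmologist panel) among its model
parameters and sweeps it in sensitivity analysis. Keying annual
treatment uptake to the detection rate reproduces the published
structure exactly: ophthalmologist screening comes out less effective
than AI (16.8634 vs 16.8950 QALYs — the study prints 16.86) and
costlier, hence strictly dominated, while AI screening's ICER against no
screening (≈47,700 RMB/QALY) sits well below the 3×GDP threshold of
217,341 RMB/QALY. The package therefore defaults to
`uptake = "detection"` and retains `uptake = "sensitivity"` as an
option.

Referral costs follow the test operating characteristics rather than the
uptake rate: truly referable patients incur the diagnostic work-up
(610.2 RMB plus 17.80 RMB hospital transport) weighted by the published
sensitivity, and non-referable alive states incur a false-positive
work-up weighted by `1 − specificity` (toggleable). Laser treatment
(424.41 USD) is a one-time cost on entry into a treated state — an
episode, not an annuity — with a `per_cycle` option, and vitrectomy is
available as a PDR entry-cost option but disabled by default, since the
study's treatment assumption mentions laser only.

## Programme costing

The screening programme ledgers are itemized in RMB and reproduce the
published totals to the cent: annual direct costs of 176,420 RMB (AI:
camera amortized over 8 years, software over its 50-year copyright term,
screener fees) and 249,500 RMB (ophthalmologist arm), shared indirect
costs of 136,227.75 RMB, and per-capita screening costs of 25.01 and
30.86 RMB at 12,500 people screened per year.

Two source inconsistencies are resolved in the ledgers: the driver rate
is 200 RMB/day (the narrative's "20 RMB/day" contradicts its own
50,000 RMB total, which the tabulated USD figure confirms), and the
transport row is priced from the narrative quantities (29,346 km at
0.4224 RMB/km) because the tabulated unit×frequency pair is inconsistent
with its own total. Currency conversion defaults to **7.1895 RMB/USD**:
the tables caption 7.189, but every printed RMB/USD pair (camera,
indirect total, laser bounds) is consistent only at 7.1895.

## Economic evaluation

`ce_frontier()` sorts strategies by cost, removes strictly dominated
ones (no cheaper-and-at-least-as-effective competitor survives), then
iteratively removes extendedly dominated ones until the incremental
ICER sequence strictly increases. `optimal_at_wtp()` uses an inclusive
boundary (at an ICER exactly equal to the threshold the more effective
strategy is chosen) and cross-checks the frontier walk against the
net-monetary-benefit maximizer; the two must agree. Per-capita GDP
defaults to 72,447 RMB (one third of the study's 3× threshold of
217,341 RMB); the study elsewhere prints 71,828 RMB for 1×, which can
be supplied instead.

## Sensitivity analysis

One-way analysis re-runs the whole pipeline at each parameter's bounds
and reports the ICER of a comparator pair as a tornado. Probabilistic
analysis draws all parameters jointly: beta for probabilities, rates and
utilities, gamma for costs, lognormal for the relative risk and the
mortality multipliers, uniform for the discount rate (0–6%). Ranges are
±25% for prevalence, detection rates and transition probabilities, ±50%
for costs, and published 95% confidence intervals otherwise. Beta and
gamma are moment-matched from the base value as mean and
`(high − low)/3.92` as standard deviation; the lognormal takes the base
as median. Utilities whose published interval exceeds 1 are sampled on
the rescaled support and truncated to 1 (with a warning); sampled
prevalence vectors are renormalized to sum to one; costs are sampled at
the ledger-aggregate level.

Each parameter owns an RNG substream derived from the root seed by
hashing its name, so adding or removing a parameter never perturbs the
other parameters' draws and identical seeds reproduce output
bit-for-bit. A draw violating a model invariant (the blindness
multiplier's lognormal occasionally dips below 1) is rejected and
deterministically resampled, with the rejection count reported.

At 10,000 draws the acceptability curve at the 3×GDP threshold gives the
AI strategy by far the highest probability of being cost-effective, with
no screening retaining a minority share (driven mostly by utility draws
that invert the state ordering) — the same qualitative picture as the
published curves, and within ten percentage points of the published
(11.5%, 87.9%, 0.6%).

## The synthetic screening cohort

No patient-level data ship with the package. `simulate_screening_cohort()`
generates a stand-in for the field cohort: 3,102 patients whose true
grade is drawn from a prevalence vector (any-DR prevalence 16.54%,
split over grades in proportion to the study's graded-eye distribution),
and whose patient-level any-DR call per grader is drawn from the
grader's sensitivity/specificity. Eye-level grades are emitted only to
honour the worse-eye diagnosis rule; grade-level confusion, eye-level
correlation and image quality are *not* modelled — the binary referral
call is what the agreement statistics consume. Consequently, tests
passing on this cohort validate the agreement machinery (coincidence
rate, Cohen's kappa, detection rates) and its sampling behaviour, not
any claim about real grading data.

The published 2×2 screening counts are themselves internally
inconsistent (the disagreement cells implied by the margins exceed
`n − a − d`), so the published kappa of 0.780 cannot be recovered from
any consistent table; kappa is therefore validated against a
record-level brute-force oracle, while the detection and coincidence
rates are reproduced exactly from the counts that define them.

## Numerical choices and problem sizes

Row sums of transition matrices are checked to 1e-9 and cohort
conservation to 1e-6 relative. Path-enumeration oracle checks run on
chains of up to 4 active states and 6 cycles, where exhaustive
enumeration is exact and fast. Unit tests run the cohort model at
10–50 cycles and the PSA at 40–200 draws; the end-to-end acceptance
checks use the study scale (50 cycles, 10,000-patient cohort, 10,000
PSA draws), which completes in about a minute on one core. Ties in net
monetary benefit across strategies within a draw are split evenly — a
measure-zero event under continuous distributions, but the rule keeps
the acceptability curve deterministic.

## Known limitations

Rates are constant over the horizon (no age stratification), diabetic
macular edema is outside the model, compliance is 100% by assumption,
and the cohort is closed. The study's absolute per-capita cost totals
are not reproducible from its own cost tables by roughly an order of
magnitude; the package's costs are internally consistent with the
itemized ledgers, and comparisons against the published analysis are
therefore made on effectiveness, orderings, dominance structure and
thresholds rather than absolute cost levels.
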