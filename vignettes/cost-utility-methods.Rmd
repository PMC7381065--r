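---
title: "Methods: trial-based cost-utility analysis for telerehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis for telerehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telecua)
```

`telecua` implements the economic-evaluation pipeline of a two-arm
randomized trial comparing telerehabilitation-based against clinic-based
McKenzie therapy for chronic low back pain: design arithmetic, outcome
scoring and utility mapping, protocol costing, incremental analysis with a
bootstrap cost-effectiveness plane, and a synthetic cohort generator that
stands in for the (undeposited) patient-level data. This vignette explains
the model, the defaults, and the choices made where the design was open.

## Design arithmetic

The per-group sample size uses the classical two-proportion formula
$m = c\,[\pi_1(1-\pi_1) + \pi_2(1-\pi_2)]/(\pi_1-\pi_2)^2$, where $c$ is a
power constant ($c = 7.9$ for 80% power at a two-sided 5% level). With
$\pi_1 = 0.25$ and $\pi_2 = 0.65$ this gives 20.49, i.e. 21 per group and
42 in total. Equal proportions make the size undefined;
`sample_size_per_group()` raises an explicit error rather than returning
infinity.

`adjust_for_attrition()` multiplies the total by $1 +$ rate and rounds.
Rounding 46.2 to the *nearest* integer gives 46, which is the value the
design chain is expected to reproduce; a conservative analyst may prefer
`mode = "ceiling"` (47), so the mode is an argument with `"nearest"` as the
default.

Allocation uses random permuted blocks. For two arms and block size 4 there
are exactly $4!/(2!\,2!) = 6$ balanced orderings of $\{A,A,B,B\}$, and
`permuted_block_sequence()` draws each block uniformly from those 6. (A
count of 24 sometimes quoted in this context is $4!$, the number of
orderings of four *distinct* items, not the number of balanced blocks.)
Sealed-envelope mechanics and allocation concealment are out of scope: the
function returns the sequence itself, reproducibly for a fixed seed, and a
trailing partial block is truncated from a freshly drawn full block so the
final imbalance never exceeds half the block size.

## Outcomes: ODI, SF-6D, QALYs

The Oswestry Disability Index has 10 items scored 0 (best) to 5 (worst),
rescaled to 0–100 by `100 * sum(answered) / (5 * n_answered)`; unanswered
items rescale the denominator. Utilities come from the published linear
crosswalk

$$\text{SF-6D} = 0.78275 - 0.00518 \cdot \text{ODI},$$

which maps the admissible ODI range [0, 100] to (0.26475, 0.78275), a
strict subset of the death–full-health utility scale (0, 1). Because the
map cannot escape (0, 1) on valid input, utilities are never clamped;
out-of-range ODI is rejected instead, which surfaces data errors rather
than silently absorbing them. Re-estimating the crosswalk is a non-goal.

**QALY convention.** "Multiply utility by time and average weeks 4 and 8"
admits two readings. The default, `convention = "mean_utility"`, applies
the average of the two utilities to the whole 8-week horizon:
$\text{QALY} = \tfrac{u_4 + u_8}{2} \cdot \tfrac{8}{52}$. The alternative
(`"period_qaly"`) averages period-specific QALYs
$\tfrac{1}{2}(u_4 \cdot \tfrac{4}{52} + u_8 \cdot \tfrac{8}{52})$. Only the
first reproduces an arm-level QALY of ≈ 0.085 from utilities of ≈ 0.55
over 8 weeks (the second gives ≈ 0.063 at the same utility level), so it
is the default; both are selectable.

## Costing

Costs are the direct implementation costs of the two protocols, identical
for every participant within an arm: SMS messages and reminder calls
(50 naira, 3×/week, both arms), a compatible smartphone (20,000 naira,
one-off, telerehabilitation only), a pre-randomization consultation
(1,000 naira, one-off, both arms), clinic visits (1,000 naira, 3×/week) and
transport/refreshment (500 naira per visit) for the clinic arm. Over the
8-week horizon the defaults total 22,200 and 38,200 naira, an incremental
cost of exactly −16,000 naira for telerehabilitation. Medication and
indirect/personal costs are excluded; with an 8-week horizon there is no
discounting.

All accounting is done in naira (exact integer arithmetic with integer unit
costs). USD is display-only at a default 360 naira/USD — the rate
back-derived consistently from every published unit-cost pair (1,000 →
2.78; 500 → 1.39; 50 → 0.14; 20,000 → 55.56); it lives in the cost-model
configuration, never in the computation. `cost_breakdown()` additionally
reproduces the rounding chain used in the published cost table (unit naira
→ USD rounded to 2 decimals → × number of charges → rounded to 1 decimal →
summed), whose column totals (61.8 and 106.3) differ slightly from direct
conversion of the naira totals (61.67 and 106.11) — one reason to keep USD
out of the arithmetic. Cost models round-trip through YAML
(`read_cost_model()` / `write_cost_model()`), and the data model supports
participant-level cost variation even though the default protocol does not
produce any.

## Incremental analysis and the bootstrap

`icer()` classifies every sign pattern of (ΔCost, ΔEffect): *dominant*
(cheaper, more effective), *dominated* (dearer, less effective), numeric
ICER with a `tradeoff_NE` / `tradeoff_SW` label in the trade-off quadrants,
and *indeterminate* when ΔEffect = 0 (no division is attempted). Negative
ratios from the dominance quadrants are never reported as numbers: −16,000
naira divided by 0.001 QALY is arithmetically −16,000,000 but carries no
decision content, while "dominant" does.

`bootstrap_cea()` resamples participants with replacement within each arm
(arm sizes preserved), recomputes arm means and the incremental pair per
replicate, and reports percentile 95% intervals (BCa with jackknife
acceleration as an option — the percentile method is the default because no
method is canonical for this design), quadrant proportions, and the
replicate cloud itself. The default is B = 1000 replications, matching
standard practice for plane summaries; determinism under a fixed seed is a
contract, tested bit-for-bit. On the plane (`plot_ce_plane()`), ΔEffect is
horizontal and ΔCost vertical. Replicates falling exactly on an axis are
assigned to the clockwise-adjacent quadrant (positive cost axis → NE,
positive effect axis → SE, negative cost axis → SW, negative effect axis →
NW, origin → NE); with continuous data this has probability ~0 and is
documented for completeness. `ceac()` (acceptability curve over a
willingness-to-pay grid) is an extension beyond a point-estimate dominance
ruling and is flagged as such.

## Clinical-effectiveness comparisons

`mean_change_from_baseline()` reports baseline − follow-up (improvement
positive on the "higher is worse" ODI) with a t-based 95% interval.
Between-arm contrasts (`between_arm_difference()`) use the difference of
arm mean changes with a Welch interval. Published between-arm contrasts for
this trial (1.61 and 0.81 ODI points) do not equal the arithmetic
difference of the published arm mean changes (1.93 and 1.21) and their
construction is unexplained; the package reports the arithmetic difference
and does not attempt to reproduce those printed values. Two-sided 0.05 is
the significance convention. Rank-based comparisons delegate to base R:
`mann_whitney()` fronts `stats::wilcox.test` (exact for small tie-free
samples, tie-corrected normal approximation otherwise) and `friedman()`
fronts `stats::friedman.test`, with one addition — fully tied rows, where
the tie-corrected statistic is 0/0, return 0 by convention. The test suite
cross-checks both against independent oracles (exhaustive enumeration of
rank configurations; the raw rank formula).

## The synthetic cohort generator

`generate_cohort()` emulates the trial's data structure: 21
telerehabilitation and 26 clinic participants; age, weight, height and
pain duration from truncated normal distributions at the published arm
means/SDs (age restricted to the 20–65-year eligibility window); baseline
ODI truncated to [0, 100]; week-4 and week-8 ODI improvements from a
bivariate normal with correlation 0.7 (an assumption — follow-up change
scores in the same participants are strongly but not perfectly correlated;
configurable); follow-up ODI = baseline − change, clamped to [0, 100];
protocol cost attached by arm. Truncation of baseline quantities is by
rejection resampling, not clamping, to avoid point masses at the bounds.

Calibration inputs and their provenance:

* **Change-score means** are the published week-4/week-8 arm mean changes
  (10.43/15.71 telerehabilitation, 8.5/14.50 clinic, ODI points).
* **Change-score SDs** are back-derived from the published 95% CIs with
  `derive_sd_from_ci()` (halfwidth·√n / t₀.₉₇₅,ₙ₋₁): ≈ 4.17/6.28 and
  7.55/9.57 ODI points.
* **Baseline ODI is published nowhere**, so its defaults are back-solved:
  an arm QALY of 0.085 over 8 weeks implies a mean follow-up utility of
  0.5525, i.e. mean follow-up ODI ≈ 44.45; adding the arm's average
  improvement (≈ 13.1 points) gives a baseline mean of 57.52 for the
  telerehabilitation arm, and the same construction gives 57.20 for the
  clinic arm (QALY 0.084). The baseline SD of 10 ODI points is an assumed,
  realistic dispersion for a chronic low-back-pain cohort; neither it nor
  any baseline summary is printed in the source. With these defaults the
  clamping probability at either ODI bound is ~10⁻⁴, so calibration of the
  change scores is unaffected.

What the generator deliberately does **not** emulate: dropout and missing
data, adherence, item-level ODI responses (it draws total scores),
participant-level cost variation, baseline covariate imbalance effects, or
any correlation between demographics and outcomes. Passing tests therefore
show that the *pipeline arithmetic* is correct and calibrated to the
published summary statistics — not that the generator reproduces the real
trial's joint data distribution. In particular, the published incremental
QALY interval (0.001 to 0.002) cannot be reproduced from summary data: at
these arm sizes and an assumed baseline SD of 10, the sampling noise of
ΔEffect (SE ≈ 0.0026 QALY) is far wider than that interval, which could
only be this tight under strong within-participant cost–effect pairing
that patient-level data alone would reveal.

## Problem sizes and tolerances

Stochastic checks use sizes chosen to make Monte-Carlo error small relative
to the quantity checked: 500 simulated cohorts for generator calibration
(grand-mean SE ≈ 0.06 ODI points against a target of 15.71), B = 1000 for
bootstrap consistency (B = 5000 in the convergence property test), and
n = 500 per arm for parameter recovery, all under fixed seeds with 2–3
Monte-Carlo-SE acceptance bands. The full test suite runs in well under a
minute.

## Known limitations

* The economic evaluation is a payer-perspective, 8-week, trial-horizon
  analysis: no discounting, no extrapolation, no probabilistic sensitivity
  analysis over parameter distributions, and no Markov modelling.
* Utility derives from a single mapped instrument; the mapping's own
  estimation error is not propagated.
* Protocol-determined costs make ΔCost degenerate (zero-width bootstrap
  intervals); that is faithful to the costing design, but real resource-use
  data would add cost variance the defaults cannot show.
* The dominance ruling at trial scale rests on a ΔEffect whose sign is
  statistically fragile (see the worked example in the README); the plane
  and acceptability curve, not the label, are the honest summary.
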