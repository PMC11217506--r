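---
title: "Scoring preclinical tumor response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring preclinical tumor response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorresponse)
library(dplyr)
```

`tumorresponse` converts the raw measurements of a murine radiotherapy /
immunotherapy efficacy study — caliper tumor volumes, ex vivo lymph-node
bioluminescence, and gated flow-cytometry or cytokine summaries — into the
endpoints those studies report. This vignette explains each model and
procedure, the parameters that matter, and the design decisions taken where
conventions genuinely diverge.

## The measurement model

Tumor volumes come from two perpendicular caliper diameters via the
ellipsoid approximation \(V = L W^2 / 2\) (mm³). Days are integers relative
to the day of tumor irradiation (day 0); pre-treatment days are negative.
A growth curve is one mouse's time-ordered volume series for one tumor site
(primary or secondary), anchored at its day-0 volume \(V_{start}\).
Schedules are irregular in practice (every 2–4 days), so nothing below
assumes daily sampling.

Two data-hygiene rules are deliberate:

* **Duplicates are a hard error.** A repeated `(mouse, site, day)` row is
  an upstream fault; averaging it away would mask the problem.
* **The anchor falls back to \([-2, 0]\).** When no day-0 measurement
  exists, the nearest measurement at most two days earlier anchors the
  curve; with no anchor at all the curve is kept but flagged `excluded`,
  so cohort accounting never loses a mouse silently.

## mRECIST scoring

For each measured day \(d \ge 0\),

\[
\Delta V_d = 100\,\frac{V_d - V_{start}}{V_{start}}, \qquad
\bar{\Delta V}_d = \operatorname{mean}\{\Delta V_{d'} : d' \text{ measured},
0 \le d' \le d\}.
\]

Best response (BR) is the minimum of \(\Delta V_d\), and best average
response (BAR) the minimum of \(\bar{\Delta V}_d\), over measured days
\(d \ge 7\) (`min_day` is a parameter; the originating murine-RECIST
methodology used 10). The call applies strict thresholds in precedence
order:

| call | condition |
|------|-----------|
| mCR  | BR < −95 and BAR < −40 |
| mPR  | BR < −50 and BAR < −20 |
| mSD  | BR < 35 and BAR < 30 |
| mPD  | otherwise |

The threshold sets overlap, so evaluation order matters; the boundary pair
(−95, −40) fails mCR's strict inequalities and lands in mPR. A mouse with
no measurement on or after day `min_day` is `unevaluable` — a first-class
outcome, never dropped.

**Running-average denominator.** Written as a formula over daily sampling,
the running average is often printed as \(\sum_0^d \Delta V / d\), which is
undefined at \(d = 0\) and biased on sparse schedules. This package
defaults to the count-based mean over measured days (the convention above),
which reduces to the printed form exactly when sampling is daily; the
literal day-index denominator is available via `denominator = "day"` for
comparison.

Scoring is invariant to rescaling a curve's volumes — only relative change
enters — and monotone: lowering volumes pointwise can never worsen the
call. Both properties are enforced by randomized tests.

## Survival endpoints

`time_to_threshold()` records the first *measured* day at which the volume
reaches the threshold (500 or 1000 mm³ conventionally); no interpolation
is performed, so event times are always measured days. Mice that never
cross are censored at their last observed day; welfare or other early
exits are censorings, not events. For bilateral (abscopal) designs,
`cumulative_volume()` sums primary and secondary volumes on the union of
their measurement days, carrying a side's last value forward across
schedule mismatches and contributing 0 before a side's first measurement.

Kaplan–Meier estimation and the Mantel–Cox logrank test are delegated to
the `survival` package; the median reported is the smallest time at which
the survivor function is at or below 0.5, with the midpoint convention
when the curve sits exactly at 0.5 over an interval — this is how even,
fully observed groups produce half-day medians such as 36.5 days, without
any interpolation of volumes. The test suite cross-checks the logrank
statistic against a direct implementation of the Mantel–Cox formula and
the KM curve against a hand product-limit computation.

Two more growth endpoints:

* **AUC with carry-forward.** The trapezoidal integral of volume over
  \([0, \text{study end}]\). A mouse that exits early would otherwise be
  rewarded with a small AUC, so its curve is extended horizontally at the
  last measured value (Duan-style); the `extended` flag records when this
  happened. The AUC is not normalized by study length.
* **Nadir response.** A mouse is a local responder when its post-treatment
  volume nadir is at most 50% of the preceding maximum (inclusive
  boundary: "50% or more decrease"). \(V_{max}\) is taken over measured
  days up to and including the nadir day, since a decrease is only
  meaningful against a prior peak.

## Lymph-node metastasis calling

Ex vivo bioluminescence of the three tumor-draining lymph-node stations
(axillary, brachial, inguinal) and their contralateral counterparts is
background-corrected by subtracting an empty-well radiance; negative
differences clamp to 0 with a flag, since instruments can read below
background. The draining node with the highest corrected signal is divided
by the corrected signal of the *same-station* contralateral node
("corresponding" is read anatomically); a zero contralateral signal makes
the mouse unevaluable rather than infinitely positive. Positivity is a
strict fold change > 4, the cutoff equivalent to a 300% signal increase
over the non-draining node.

## Metric normalization

The normalization rules are small and exact: absolute counts from
"% of Total" × total cells; tumor counts per mg tissue; percent of the
control-group mean within each independent experiment (the control group
therefore averages to exactly 100%); isotype-control MFI subtraction
(negatives kept and flagged — clamping would bias group means upward);
migration index relative to basal serum-driven migration; and qPCR
target/reference-gene quantity ratios. Isotype subtraction precedes
control normalization when both apply.

## Normality-gated statistics

The dispatcher mirrors the field's standard workflow: optional Grubbs
outlier screening per group (single-pass, two-sided, at most one removal —
iterated removal inflates the false-exclusion rate); a Shapiro–Wilk gate
at \(\alpha = 0.05\) requiring *every* group to pass before the parametric
branch is taken (a group with \(n < 3\) forces the nonparametric branch);
then the two-sided unpaired *t* test or one-way ANOVA with Holm–Šídák
pairwise comparisons (pooled error variance) on the parametric branch, and
Mann–Whitney (exact for combined \(n \le 20\) without ties, otherwise the
tie-corrected normal approximation) or Kruskal–Wallis with Dunn's
multiple comparisons on the nonparametric branch. A second factor switches
to two-way ANOVA with Holm–Šídák comparisons. Categorical contingency
tables use the two-sided Fisher's exact test, checked in the suite against
exhaustive hypergeometric enumeration for all margins up to 30. A
1000-replicate null simulation keeps the parametric branch's measured
type-I error within \([0.03, 0.07]\).

## The cohort simulator

Real studies of this design deposit per-mouse data in supplementary files
rather than public accessions, so the package ships a generator that
reproduces the statistical structure the analysis assumes. Each mouse
draws one of three responder classes; the mean trajectory is exponential
growth \(V_0 e^{g t}\) for non-responders, regression at rate \(r\) for
`regrowth_delay_days` followed by regrowth for transient responders, and
regression to a 1 mm³ detection floor for durable responders.
Multiplicative log-normal noise (CV `noise_cv`) applies to each measured
volume, and measurements follow an alternating 3/2-day schedule.

Defaults and why:

* `v0_mm3 = 80` — the treatment-day volume typical of these models.
* `growth_rate = 0.18`/day — an untreated 80 mm³ tumor reaches the
  1000 mm³ endpoint in about 14 days, the observed behaviour of untreated
  B16F10 melanoma.
* `regression_rate = 0.25`/day with `regrowth_delay_days = 7` — chosen so
  the three classes map cleanly onto distinct mRECIST calls: a durable
  responder's nadir (≈ −99%) is mCR, a transient responder's (≈ −83%) is
  mPR, and a non-responder is mPD. This keeps class-mixture recovery tests
  interpretable.
* `noise_cv = 0.15` — a free choice in the range typical of caliper
  measurement repeatability; no published per-curve noise magnitude exists
  to calibrate against.
* Burden limits 1500 mm³ (single) / 2000 mm³ (bilateral cumulative) —
  standard welfare endpoints. Truncation drops the offending measurement:
  no emitted volume ever exceeds a limit, and the curve ends with
  `exit_reason = "welfare"` at the last compliant day.

What the simulator does **not** emulate: Gompertzian growth deceleration,
immune-mediated regression dynamics, correlated noise along a curve,
cage effects, or measurement-day jitter between mice. Passing tests on
simulated cohorts therefore demonstrate the correctness of the scoring
arithmetic and the stability of the pipeline, not the biological fidelity
of any particular rate parameter.

## Numerical and degenerate-input choices

* Detection floor 1 mm³ keeps log-scale arithmetic defined; calipers
  cannot report 0.
* Division-by-zero is never silent: zero contralateral signals, zero
  control means, zero reference quantities and zero baselines all raise
  or flag.
* Grubbs on constant or tiny samples is a warning no-op.
* Logrank with no events in either group warns and reports
  statistic 0, p = 1.
* All simulator randomness flows from a single integer seed with
  deterministic per-mouse substreams, so partial re-simulation and
  byte-identical pipeline reruns both hold.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data:
1000 random curves for the invariance properties, cohorts of 200 mice per
mixture for class recovery, 1000 null replicates for the type-I check, and
small hand-built curves for every worked example. These sizes give stable
results (binomial standard errors of a few percent) while keeping a full
run under a minute on one core.
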