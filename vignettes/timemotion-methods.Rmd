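---
title: "Models and conventions behind timemotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind timemotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timemotion)
```

This vignette documents the statistical model choices, numerical
conventions, and known limitations of the package, in the spirit of a
methods appendix. Nothing here states an empirical result that the test
suite does not itself recompute.

## The data model

A time-motion observation study produces, per observed clinician session, a
set of *task records*: half-open intervals `[start, end)` at one-second
resolution, each labelled on four dimensions — the task category (*what*,
nine fixed categories), the location (*where*, a site-specific controlled
vocabulary rather than an enum, because location lists do not transfer
between sites), the tool or channel (*how*) and the other person involved
(*who*). Three categories (gathering information, documentation,
professional communication) additionally carry a *drug-related /
non-drug-related* subcategory — drug-related meaning any conversation,
reading or writing involving the patient's drugs — and Social carries a
professional / non-professional split that reports collapse into one row.

Two modelling conventions matter downstream:

- **Half-open intervals on an integer second grid.** A task ending at
  second `t` and one starting at `t` do not overlap; durations are exact
  integers; and the one-second agreement windows tile the session without
  boundary ambiguity. All interval operations (union, intersection,
  sweep-line concurrency segmentation) are exact integer arithmetic, and
  the test suite checks them against a brute-force per-second array oracle
  rather than against tolerances.
- **Interruptions are task records.** An interruption (stopping the current
  task to respond to an external stimulus) is stored as a record with
  `is_interruption = TRUE`, linked to a record in the same session whose
  interval contains the interruption's start. Its time therefore counts
  toward its own task category in time budgets, and the category
  distribution of interrupters ("what was the most common reason for
  interruption?") is read directly off the linked records.

## Time proportions and denominators

The proportion of time on a slice is union-based within each session:
seconds covered by two simultaneous matching tasks count once. The default
denominator is the *scheduled* session time (including seconds with no
recorded task), because overall time budgets in this literature divide by
total observation time. Slice-conditional quantities (e.g. the share of
drug-related task time spent multitasking, or interruptions per hour of
drug-related time) instead use the slice's own union time as denominator.
Because every multitasked second counts once per slice it touches, slice
proportions sum to more than 100% exactly when multitasking occurs; each
individual slice proportion is always in [0, 1].

Unions are always taken *within* a session: two physicians observed at the
same wall-clock time contribute their seconds separately.

One convention is not fully determined by the field's usual descriptions:
whether an interruption "during drug-related task time" should qualify via
its own labels. We count an interruption toward a slice only if a record
*other than the interruption itself* matching the slice is ongoing at the
interruption's start second — otherwise a drug-related interrupter would
trivially qualify itself into the drug-related exposure even when it
interrupts unrelated work. The exposure denominator remains the slice's
union time.

## Resampling inference

Proportions of continuous, multitasked time have no convenient parametric
sampling model, so all uncertainty is resampling-based.

- **Cluster bootstrap.** The independence unit is the physician (several
  sessions by the same physician are clearly dependent), resampled with
  replacement to the original cluster count; the CI is the percentile
  interval. BCa and session-level resampling were considered; percentile +
  physician is the simplest defensible choice and the cluster is an
  argument. Every headline statistic is a *ratio of session-decomposable
  sums* (`Σ numerator seconds / Σ denominator seconds`), which the
  `ratio_stat` abstraction exploits: replicates are recomputed from
  per-cluster aggregates, and a unit test verifies the fast path equals
  resampling the full record tables. Replicates with a zero denominator are
  dropped and counted; more than 10% dropped is an error, because at that
  point the percentile interval no longer estimates what it claims.
- **Monte Carlo permutation test.** Two-group contrasts (medical vs
  surgical, experienced vs inexperienced) permute group labels over
  physicians, preserving observed group sizes (conditioning on the 3:1
  recruitment design), with the two-sided add-one p-value
  `(1 + #{|T*| ≥ |T|})/(1 + B)`, which is valid (never anti-conservative)
  at any `B`. The statistic is the difference in group proportions with
  group-specific denominators.

**Known limitation — few clusters.** The percentile bootstrap is justified
asymptotically in the number of clusters. In development-time simulations
with this package's generator, nominal 95% intervals covered ~0.96 of the
time with 100 single-session clusters, but only ~0.89 at a study-sized
roster of 31 physicians. The calibration test in the suite therefore runs
in the 100-cluster regime, where it checks the *implementation*; users
analysing data from ~30 clusters should expect some undercoverage — a
property of the percentile method at that size, not of this code.

## Inter-rater agreement

Paired-observer reliability is computed on aligned one-second windows. Each
window carries, per dimension, the *set* of labels of all tasks active
during any part of that window (set-valued under multitasking; an
`"(idle)"` sentinel fills uncovered windows, so agreement on idle time
counts as agreement). The multivariate iota score is

> ι = 1 − D_o / D_e,

where the per-window distance is the sum over dimensions of
`1 − |A∩B|/|A∪B|` (Jaccard; exactly a 0/1 mismatch for singleton labels),
`D_o` is its mean over the n aligned windows and `D_e` its mean over all n²
cross pairs of windows (per-observer marginals, i.e. Cohen-style rather
than Scott/Fleiss pooling). Two choices deserve justification:

- **Jaccard on label sets**: the historical definitions of multivariate
  chance-adjusted agreement assume one label per variable and do not say
  how to treat multitasked windows. Jaccard degrades continuously with
  partial overlap and collapses to the 0/1 mismatch for singletons, which
  preserves the binding identity below.
- **Cohen-style expectation**: with one dimension and singleton labels,
  `D_o = 1 − P_o` and `D_e = 1 − P_e`, so ι coincides *exactly* with
  Cohen's kappa. This reduction is tested as an identity on random
  sequences, and a worked 2×2 confusion matrix ([[20, 5], [10, 15]], κ =
  0.4) pins the arithmetic.

Sequences of unequal recorded extent are truncated to the common span with
a warning. Degenerate cases (both observers constant and identical, so
expected disagreement is zero) are signalled as errors rather than returning
a conventional value.

## The synthetic generator

The generator exists so that every estimator can be validated against known
truth; it emulates the *structure* of a two-hour-session observation study,
not any particular clinic's microdynamics.

- **Chained task sampling.** Tasks are drawn sequentially: the cell (a
  what/subcategory/where/how/who combination) is drawn with probability
  proportional to `budget / mean duration`, the duration is exponential
  (lognormal optional) with a per-category mean, and the next task starts
  at the current task's end — or, with the multitask probability `p`,
  uniformly *inside* the current task. This chain covers the session
  exactly once, so total raw task time is `1/(1 − p/2)` session-times.
  The default `p = 2(1 − 1/Σbudget)` therefore makes each cell's realized
  raw-time fraction equal its configured budget; when budgets sum below
  what the multitask level sustains, idle gaps with the right mean are
  inserted instead. Default category mean durations (tens of seconds for
  movement/hygiene, minutes for documentation) are fixed at values typical
  of emergency-department observation tables.
- **Interruptions** arrive as a homogeneous Poisson process (default 4 per
  hour) and become linked interruption records targeting the most recently
  started task active at their onset; their categories follow a
  configurable interrupter distribution dominated by professional
  communication. Because interruptions overlay extra task time, realized
  budgets carry a small (~0.1–0.2 percentage point) deviation from
  configured values; the parameter-recovery test uses tolerances
  pre-simulated from replicate runs of the exact test configuration, so
  this deviation is part of the tested contract rather than tuned away.
- **Patient counts** are Poisson per session (defaults 2.0 new, 0.7
  follow-up); **rosters** draw affiliation 3:1 medical:surgical and
  experience 1:1, with a configurable number of physicians observed for a
  second session (never more than two).
- **Paired observers** degrade a true log with rounded Gaussian boundary
  jitter, per-dimension label confusion (with the subcategory repaired to
  stay schema-legal), and missed tasks; interruption links that no longer
  resolve are cleared so the degraded log still validates.

What a green test on generated data does *not* establish: realism of task
durations (real task lengths are heavy-tailed and autocorrelated), clumped
interruption arrival, observer drift over a shift, or any patient-level
process beyond counts. The generator's role is parameter recovery and
calibration of the inference machinery, and the `study_preset()` budgets —
which mirror a published emergency-department time-distribution table — are
a demonstration, not a reproduction target for published CI bounds (the
underlying raw logs are not publicly deposited).

## Numerical and formatting conventions

- Report tables round percentages and minutes half-away-from-zero to one
  decimal and agreement scores to two decimals; all machine-readable output
  keeps full precision. (Note that a figure quoted at one decimal, such as
  "12.9%", converts to minutes as 7.74 ≈ 7.7, while the unrounded
  proportion behind it may print as 7.8 — conversions should be done on
  unrounded values.)
- Every resampling call takes an explicit integer seed; pipeline-level
  seeds are derived deterministically from the single config seed, and all
  randomized code paths restore the caller's RNG state. Two runs with the
  same inputs and seed produce byte-identical written reports.
- Degenerate inputs (zero denominators, empty slices, undefined agreement)
  raise errors naming the condition; validation of datasets, by contrast,
  is total and returns a violation report rather than raising.
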