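---
title: "Measuring procedural competency with the consistency statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring procedural competency with the consistency statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consistr)
library(dplyr)
```

## The measurement problem

Undergraduate clinical training often treats the *number* of procedures a
student has completed as a proxy for competence. For operative dentistry,
workplace-based assessment systems record far richer data: every direct
restoration a student places is observed by a supervising staff member, who
scores each criterion-referenced stage of the procedure on a six-point
ordinal **developmental indicator (DI)** scale of learner independence.
DI 5 means the stage was performed *independently at the required quality*;
DI 6 exceeds that quality; lower values indicate increasing amounts of help.

`consistr` implements an analysis pipeline for such observation-level
records. Its core quantity is **consistency**:

> binarize each restoration by its *weakest* stage — indicator 1 if the
> minimum stage DI is at or above the independence threshold (default 5),
> else 0 — and take, per student and per year of study, the mean of those
> indicators.

Requiring the *minimum* stage to clear the threshold encodes the clinical
logic that a restoration is only independently completed if every stage of
it was. For ten restorations with lowest stage DIs
4, 3, 5, 5, 6, 6, 4, 5, 4, 6 the indicators are 0, 0, 1, 1, 1, 1, 0, 1, 0, 1
and C = 6/10 = 0.6:

```{r worked-example}
example <- system.file("extdata", "final_year_example.csv",
                       package = "consistr")
restorations <- assemble_restorations(read_observations(example))
consistency_score(restorations, di_threshold = 5)
```

A note on the definition: stated loosely as a "sum of the lowest DI per
restoration at or above threshold", the formula could be misread as summing
the DI values themselves. The worked example above fixes the intended
reading — the numerator counts *indicators*, not DI values — and that is
what `consistency_score()` computes. Consistency is undefined on an empty
restoration set; the functions raise an error rather than silently scoring
zero, and a student with no restorations in a year simply has no summary row
for that year.

## The surrounding pipeline

The package covers the full analysis around the statistic:

* **Records** (`read_observations()`, `assemble_restorations()`): one CSV
  row per stage judgement, validated against the domain invariants (DI in
  1–6, FDI quadrant 1–4 and tooth position 1–8, five surface classes), then
  grouped into restoration-level records. Context fields must agree across
  the stages of one restoration; stage order (lexicographic `stage_id`, or
  an explicit `stage_index`) never affects results because only the minimum
  DI is used.
* **Difficulty** (`is_difficult()`, `difficulty_summary()`): a restoration
  is *relatively difficult* if it is approximal (either approximal surface
  class), on an upper posterior tooth (quadrant 1–2, positions 4–8, where
  indirect vision is likely), or staff-tagged difficult for another reason.
  A restoration satisfying several clauses counts once. Exposure is reported
  per student as a count and a percentage of all restorations placed.
* **Stratification** (`assign_group()`, `group_descriptives()`): students
  are binned by total restorations across all years and cohorts — 40–49,
  50–59, 60–69, 70+ — with totals below 40 excluded from group-level
  analysis. Descriptives are computed per student first (a student with no
  restorations of a surface counts 0), then summarised over students as
  median (min–max), with mean ± sample (n−1) SD for the difficulty cells;
  the usual convention for cohort descriptives.
* **Comparisons**: a two-sample Kolmogorov–Smirnov check of cohort
  equivalence (asymptotic p-value — cohort sizes near 70, and ordinal-derived
  values are tied, which rules out the exact computation anyway); a one-way
  ANOVA of per-student yearly consistency across years of study with
  Bonferroni-adjusted Welch pairwise contrasts; and the Pearson correlation
  of total restoration volume with final-year consistency, with the fitted
  least-squares line.

`run_pipeline()` chains the stages, logs counts at each one, and optionally
writes a deterministic report bundle (CSV tables plus `tests.json`).

### A known simplification

The ANOVA treats the years of study as independent groups even though the
same students contribute one value per year. This mirrors the classical
analysis this pipeline reproduces; a repeated-measures or growth-curve model
would use the longitudinal structure and is deliberately out of scope. The
Welch (unequal-variance) form is used for the pairwise contrasts because
per-year consistency variances genuinely differ (students place more
restorations in year 4, and consistency near the top of the scale compresses
variance); Bonferroni adjustment multiplies each raw p by the number of
pairwise comparisons, capped at 1.

## The synthetic cohort generator

No identifiable assessment records can ship with an analysis package, so
`simulate_cohorts()` generates observation datasets with the statistical
structure the analysis assumes, and every downstream stage is tested against
them. The generative model:

* Each student has a small persistent latent ability intercept, plus a
  per-student-year ability term, plus a fixed year-of-study increment.
* Each staff member has a hawk/dove severity offset subtracted from the
  latent level of restorations they observe; each student works with a
  clipped-normal-sized subset (mean 10, SD 3, minimum 1) of the staff pool.
* Each restoration draws a surface class, quadrant, tooth position, patient
  and a rare staff difficulty tag from the configured case mix; restorations
  satisfying the *same* difficulty rule the analysis applies incur a latent
  penalty, so difficulty-related behaviour is self-consistent end to end.
* Stage DI scores are emitted by a cumulative-link mechanism: latent level
  plus per-stage Gaussian noise, discretised through five fixed cut-points
  into DI 1–6. DI ≥ 5 corresponds to latent values above the fourth
  cut-point.

### Default calibration

The defaults are fixed study conditions, not tuning knobs. They describe two
cohorts of 70 students over clinical years 3–5 with Poisson restoration
volumes whose per-year medians fall near 16/24/16 (totals then span the
40–70+ stratification range, with a few students below 40, as in a realistic
cohort), three judged stages per restoration, and a case mix in which about
47% of restorations are approximal and the overall difficult fraction is
roughly 56–57%. The tooth-position distribution leans anterior so that the
marginal difficult fraction lands in that range given the surface and
quadrant mixes. The year increments (0.55, 0.72, 0.94 on the latent scale)
were calibrated once, by simulation, so that per-year mean student
consistency at threshold 5 comes out near 0.46/0.60/0.76 with SDs near
0.17/0.15/0.14 — the regime of published undergraduate cohorts — and then
frozen.

Latent heterogeneity is split between a persistent intercept (SD 0.05) and a
larger student-year component (SD 0.12). The year-specific part stands in
for patient-mix and scheduling luck, which plausibly dominates persistent
ability differences on this scale; it also keeps per-student consistencies
nearly independent across years, which is the regime in which the one-way
ANOVA above holds its nominal size. With a strongly persistent intercept the
ignored repeated-measures correlation would make that ANOVA conservative —
one more reason the independence simplification must be read with care on
real data.

What the generator does *not* emulate: case-mix correlation between surface
and tooth position (draws are independent), staff assignment that depends on
clinic rotation structure, within-year learning trajectories, or any
patient-level covariates beyond an opaque identifier. Tests passing on
synthetic cohorts therefore validate the *arithmetic and inferential
machinery*, not distributional claims about any real school's data.

### Determinism

All randomness flows from the single integer `seed` in the configuration
through one RNG stream with a fixed draw order, so an identical
configuration reproduces the dataset — and the whole report bundle —
byte for byte. Partial regeneration of individual students is not a
supported use case, which is why a single stream was preferred over
per-student sub-streams.

## Numerical and design choices

* **Thresholds and boundaries.** A restoration whose minimum stage DI
  *equals* the threshold is independent (`>=`, not `>`). Experience-group
  edges are closed on the left: totals of 40, 50, 60 and 70 fall in groups
  1–4 respectively; 39 is excluded.
* **Empty cells.** Group descriptives are only defined when at least one
  student reaches 40 restorations; `run_pipeline()` reports `NULL` for
  stages whose preconditions a dataset cannot meet (single cohort, single
  year, degenerate variance) instead of failing.
* **Pooling decision.** The K-S stage flags the cohorts as poolable when
  p > alpha (default 0.05). The pipeline runs the check on both per-student
  restoration totals and per-student pooled consistency.
* **Overall consistency.** Both variants are available: per-student yearly
  values (the default unit of analysis for the ANOVA) and pooled-over-years
  per-student values (used for the cohort-equivalence check and the volume
  correlation, which pairs each student's total restorations with their
  final-year consistency over all students with final-year data).
* **Problem sizes in the test suite.** Unit tests run on small constructed
  fixtures and 10–25-student cohorts; the calibration checks of the ANOVA
  stage use 200 replicates of the full 140-student default configuration for
  power and 500 replicates with zero year increments for size, which keeps
  the whole suite in the low single-digit minutes on one core.

## Limitations

The pipeline reproduces a classical descriptive-plus-ANOVA analysis,
including its simplifications: no mixed-effects or growth-curve modelling,
no modelling of rater effects at analysis time (hawk/dove offsets exist only
in the generator), binary difficulty rather than a graded scale, and
independence assumptions noted above. The consistency statistic itself is
sensitive to case mix and activity level — a student who places few, simple
restorations well can look highly consistent — so it should be read
alongside the difficulty and volume outputs the pipeline emits, never alone.
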