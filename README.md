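# consistr

Analytics for longitudinal workplace-based clinical assessment records.

In programmatic assessment of operative dentistry, every direct restoration
a student places is directly observed, and each criterion-referenced stage
of the procedure is scored on a six-point ordinal **developmental indicator
(DI)** scale of learner independence (DI 5 = performed independently at the
required quality; DI 6 exceeds it). A recurring question for progression
decisions is whether the *number* of procedures completed is a valid proxy
for competence. `consistr` implements the analysis toolkit for that
question, built around the **consistency** statistic:

```
ind(r) = 1  if min(stage DIs of restoration r) >= threshold   (default 5)
         0  otherwise

C(student, year) = (1 / n) * sum over the student's n restorations of ind(r)
```

A restoration counts as independently completed only if *every* stage was.
Around the statistic the package provides:

- **Records** — a validated per-stage CSV schema (FDI tooth notation,
  five surface classes), schema dialects, and assembly of stage
  observations into restoration-level records (`read_observations()`,
  `assemble_restorations()`).
- **Difficulty** — the binary case-difficulty rule (approximal surface, or
  upper posterior tooth: FDI quadrant 1–2 positions 4–8, or staff-tagged)
  and per-student exposure percentages (`is_difficult()`,
  `difficulty_summary()`).
- **Stratification** — experience groups by total restorations (40–49,
  50–59, 60–69, 70+; totals under 40 excluded) and median (min–max) /
  mean ± SD descriptive tables (`assign_group()`, `group_descriptives()`).
- **Comparisons** — Kolmogorov–Smirnov cohort-equivalence check, one-way
  ANOVA of consistency across years of study with Bonferroni-adjusted Welch
  pairwise contrasts, and the volume-vs-final-year-consistency Pearson
  correlation (`ks_cohort_check()`, `year_effect_anova()`,
  `volume_consistency_correlation()`).
- **Synthetic cohorts** — a seeded generator of multi-year observation
  datasets (latent ability growth, hawk/dove rater offsets, configurable
  case mix, cumulative-link ordinal DI emission) so the full pipeline is
  testable without identifiable student data (`simulation_config()`,
  `simulate_cohorts()`).
- **Pipeline** — `run_pipeline()` chains read/simulate → assemble →
  consistency → difficulty → stratification → comparisons and writes a
  deterministic report bundle.

## Worked example

A final-year student has placed ten restorations whose lowest per-stage DIs
are 4, 3, 5, 5, 6, 6, 4, 5, 4, 6. At threshold 5 the indicators are
0, 0, 1, 1, 1, 1, 0, 1, 0, 1, so C = 6/10 = 0.6 — the student completed 60%
of their restorations fully independently. The stage-level records for this
example ship with the package:

```r
library(consistr)
example <- system.file("extdata", "final_year_example.csv", package = "consistr")
rest <- assemble_restorations(read_observations(example))
summarize_student_years(rest)
#> # A tibble: 1 × 6
#>   student_id cohort_id year_of_study n_restorations n_independent consistency
#>   <chr>      <chr>             <int>          <int>         <int>       <dbl>
#> 1 S001       cohort1               5             10             6         0.6
```

End to end on a simulated two-cohort, 140-student dataset:

```r
report <- run_pipeline(config = simulation_config(seed = 1))
report$year_table
#> # A tibble: 3 × 5
#>   year_of_study n_students mean_consistency sd_consistency median_restorations
#>           <int>      <int>            <dbl>          <dbl>               <dbl>
#> 1             3        140            0.436          0.171                  17
#> 2             4        140            0.611          0.153                  24
#> 3             5        140            0.731          0.149                  16

report$tests$anova$pairwise[, c("comparison", "mean_diff_pct", "p_bonferroni")]
#> # A tibble: 3 × 3
#>   comparison       mean_diff_pct p_bonferroni
#>   <chr>                    <dbl>        <dbl>
#> 1 year 3 vs year 4          17.5     9.34e-17
#> 2 year 3 vs year 5          29.5     1.96e-38
#> 3 year 4 vs year 5          12.0     4.45e-10

report$tests$correlation[, c("r", "p_value", "n")]
#> # A tibble: 1 × 3
#>         r p_value     n
#>     <dbl>   <dbl> <int>
#> 1 -0.0717   0.400   140
```

Mean consistency rises steeply with year of study (about 17 and 12
percentage points across successive years here), while total restoration
volume shows no meaningful correlation with final-year consistency — the
pattern the pipeline is designed to expose and quantify. The
cohort-equivalence check (`report$tests$ks_consistency`) supports pooling
the two simulated cohorts (D = 0.11, p = 0.75).

See the vignette (`vignettes/consistency-analytics.Rmd`) for the model
behind the generator, the calibration of its defaults, and the design
decisions in the statistical stages.

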