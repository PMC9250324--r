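# swimstrat

Search-strategy classification for Morris water maze (MWM) swim
trajectories.

The MWM is the standard assay of rodent spatial learning: the animal must
locate a hidden escape platform in a circular pool using distal cues. The
classical measures — escape latency, path length, swim speed,
correct-quadrant time, platform-zone crossings — describe how fast an
animal escapes but not *how* it searched, and they are notoriously noisy
in aged cohorts whose physical abilities differ. `swimstrat` implements a
parameter-based search-strategy algorithm that classifies every trial into
one of ten ordinal categories from three parameters applied in sequence:

1. **Effectiveness** — did the path reach the platform zone (zone 0)?
   Ineffective trials are **J** (thigmotaxis, confined to the outer pool
   ring), **H** (localized, at most three contiguous octants), or **I**
   (nonlocalized).
2. **Initial directionality** — direct if the peripheral platform zone
   (zone 1) is entered before the first trajectory change, indirect
   otherwise.
3. **Precision** — the number of trajectory changes *n* before the first
   zone-0 entry: direct trials map `n = 0 → A`, `1–3 → B`, `4–6 → C`,
   `≥ 7 → D`; indirect trials map `1–3 → E`, `4–6 → F`, `≥ 7 → G`.

Trajectory changes are discrete "mistake" episodes detected from the
heading series and the zone/octant sequence: curved movements with more
than 90° of cumulative angulation, nonsense movements (zigzags, spirals),
and peripheral seeking (more than three distinct octants traversed in
zone 3, or more than one in zone 4).

The package also provides the traditional per-trial measures, a synthetic
trajectory generator with construction-defined ground truth (the test bed
for the classifier), and the statistical layer used for cohort comparison:
strategy pooling into direct/indirect/non-effective sets with chi-square
tests, Cohen's kappa inter-rater agreement (overall and per parameter),
Mann–Whitney U, Friedman with Bonferroni post hocs, and a
Kolmogorov–Smirnov normality screen.

## Worked example

Simulate one indirect trial with two deliberate course changes, classify
it, and compute the traditional measures:

```r
library(swimstrat)

cfg <- pool_config()   # 180 cm pool, 15 cm platform on the NE axis
gen <- generate_archetype(archetype_spec("E", n_curves = 2, noise_sd = 0,
                                         seed = 7), cfg)
lab <- ssa_classify(gen$track, cfg)
lab
#> <ssa_label> category E (effective, indirect), 2 trajectory change(s): 2 curve, 0 nonsense, 0 peripheral
#>   platform reached at 15.6 s

trial_metrics(gen$track, cfg)[, 6:11]
#> # A tibble: 1 × 6
#>   platform_latency platform_distance mean_speed quadrant_time_pct
#>              <dbl>             <dbl>      <dbl>             <dbl>
#> 1             15.6              312.       20.0              14.8
#>   platform_crossings found_platform
#>                <int> <lgl>
#> 1                  1 TRUE
```

The trial reached the platform (effective) 15.6 s after release, but its
first course change came before it ever entered the platform ring
(indirect), with two changes in total: category **E**. `tidy(lab)` returns
the event-level audit table and `plot_track(gen$track, cfg)` draws the
path over the pool zones.

Cohort-level comparison on simulated young and aged groups:

```r
young <- generate_cohort(cohort_spec("young", n_rats = 4, days = 6, seed = 1),
                         labels_only = TRUE)
aged  <- generate_cohort(cohort_spec("aged",  n_rats = 4, days = 6, seed = 2),
                         labels_only = TRUE)
chi_square_pooled(young[young$day == 6, ], aged[aged$day == 6, ])
#> Chi-square on pooled strategies: X2 = 15.84, df = 2, p = 0.0003641
#>        direct indirect non_effective
#> group1     13        3             0
#> group2      2       10             4
```

Real tracking exports are read with `read_track()` /
`read_tracks()` (delimited text, one trial per file, with a metadata
sidecar), and a thin command-line front end ships in `inst/cli/ssa.R`
(`simulate`, `classify`, `stats` subcommands).

See the vignette (`vignettes/search-strategy-classification.Rmd`) for the
full account of the decision tree, the event detectors and their tunable
thresholds, the synthetic test bed, and known limitations.

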