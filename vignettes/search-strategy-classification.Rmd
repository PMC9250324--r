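---
title: "Classifying Morris water maze search strategies from swim trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Morris water maze search strategies from swim trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 5)
```

```{r setup, message = FALSE}
library(swimstrat)
```

## The problem

The Morris water maze (MWM) is the standard assay of spatial learning in
rodents: the animal must find a hidden escape platform in a circular pool
using distal visual cues. The classical per-trial measures — escape
latency, path length, swim speed, correct-quadrant time, platform-zone
crossings — summarise *how quickly* an animal escapes, but say little
about *how* it searched. Two animals with the same latency may have used
entirely different strategies: a direct, cue-guided (allocentric) approach
versus an indirect, route-based (egocentric) sweep, or no spatial strategy
at all (wall-hugging thigmotaxis).

`swimstrat` implements a parameter-based search-strategy algorithm that
classifies each trial into one of ten ordinal categories, A–J, from three
parameters applied in sequence:

1. **Effectiveness.** Did the path ever reach the platform zone (zone 0)?
   Effective trials continue to step 2; ineffective trials are split into
   **J** (thigmotaxis: the search stayed in the outer pool ring, zone 4),
   **H** (localized: the occupied octants form at most three contiguous
   sectors), and **I** (nonlocalized: anything else).
2. **Initial directionality.** Effective trials are **direct** when the
   first entry into the peripheral platform zone (zone 1, or zone 0
   directly) precedes the first trajectory change, **indirect** otherwise.
3. **Precision.** The number of trajectory changes committed before the
   first zone-0 entry, banded: direct 0 = **A**, 1–3 = **B**, 4–6 = **C**,
   ≥ 7 = **D**; indirect 1–3 = **E**, 4–6 = **F**, ≥ 7 = **G**.

A *trajectory change* is a discrete "mistake" episode of one of three
kinds: a **curved movement** with more than 90° of cumulative angulation, a
**nonsense movement** (zigzag or spiral), or **peripheral seeking**
(traversing more than three distinct octants while staying in zone 3, or
more than one octant while in zone 4).

## Pool geometry

The pool model is a 180 cm circular tank with a 15 cm platform on the NE
axis, halfway between the wall and the centre. Eight imaginary axes divide
the pool into octants; five analysis zones carry the decision tree: zone 0
(the platform disc) and zone 1 (a 75 cm disc around the platform) are
platform-centred, while zone 2 (90 cm), zone 3 (150 cm), and zone 4 (the
full 180 cm) are concentric with the pool. Membership precedence
0 > 1 > 2 > 3 > 4 makes the zones a partition.

Two centring choices deserve comment, because pool descriptions in the
literature typically list zone diameters without centres. A 75 cm disc
concentric with the pool could not contain a platform whose annulus spans
37.5–52.5 cm of radius, so the "peripheral platform zone" is only coherent
as a platform-centred disc; zones 2–4 are the usual pool-concentric rings.
All boundaries are treated as closed, with the precedence rule resolving
overlaps deterministically — in particular, a path that ends exactly on
the platform edge counts as having reached it.

```{r geometry}
cfg <- pool_config()
cfg
platform_center(cfg)
zone_of(0, 0, cfg)      # pool centre lies in the central pool zone
```

## From raw track to heading series

Tracking exports are time-stamped positions at an arbitrary rate.
`read_track()` maps them into pool-centred centimetres (dropping non-finite
rows, rejecting corrupt files and occlusion gaps longer than 1 s), and the
preprocessing pipeline is:

* **resample** to a uniform 0.1 s grid (linear interpolation);
* **smooth** positions with a centred moving average (window 7 samples)
  for angle measurement only — zones and metrics use the unsmoothed
  resampled track, since smoothing shortens paths;
* **headings**: merge vertices closer than 1 cm (so sub-centimetre jitter
  cannot manufacture angles), then compute per-step compass bearings and
  signed turns in (−180°, 180°].

None of these constants is inherent to the strategy definitions — a human
rater watching video needs no sampling grid — so all are exposed in
`classifier_params()`. The defaults were calibrated on the package's own
synthetic trajectories: window 7 and the turn thresholds below recover the
constructed category in ≥ 95% of trials at a realistic 0.5 cm tracking
jitter while remaining exact on noise-free paths.

## Detecting trajectory changes

The substrate for curves, spirals, and zigzags is a segmentation of the
turn series into *same-direction runs*. A run opens at a significant turn
(|turn| > `turn_tol` = 10°, back-extended over the sub-threshold ramp that
smoothing spreads ahead of a sharp turn), accumulates signed turns, and
closes when either straight swimming persists for `straight_break` = 0.5 s
or the cumulative turn retreats more than `opp_tol` = 30° from its running
extreme. This *drawdown* rule ends the run at its extreme and hands the
retreating turns to the next run; it makes segmentation insensitive to how
resampling and smoothing spread a sharp corner across samples, which a
literal "maximal run of same-signed turns" is not.

Runs become events as follows:

* **curve**: |cumulative turn| strictly greater than 90°;
* **spiral** (nonsense): |cumulative turn| > 360°, subsuming the curve it
  would otherwise be;
* **zigzag** (nonsense): at least `zig_count` = 3 consecutive runs of
  alternating direction, each of magnitude ≥ `zig_angle` = 45°, with at
  most `zig_max_gap` = 1 s between swings.

Curves and spirals must additionally reach a peak turning rate of
`min_turn_rate` = 125°/s over their best 0.5 s window. This gate encodes
the observation that deliberate course changes are executed sharply,
whereas runs opened by a stray jitter spike and then fed by slow steering
drift accumulate their angle an order of magnitude more slowly; on
synthetic data the two populations are separated by a wide margin (peak
rates ≥ ~140°/s versus ≤ ~110°/s). Zigzag swings are exempt — their chain
structure is already a strong filter, and a legitimate 45–60° swing cannot
reach 125°/s by construction. The 90° threshold is strict, guarded by a
10⁻⁹ epsilon so a nominal 90.0° arc never registers through floating-point
accumulation.

Peripheral seeking is detected on the per-sample (zone, octant) sequence of
the unsmoothed track: an event is a maximal episode confined to zone 3
spanning more than three *distinct* octants, or confined to zone 4
spanning more than one. Distinct octants, not boundary crossings: jitter
bouncing across a single boundary is not a sweep along the wall.

Overlap between kinds is resolved in `merge_events()`: nonsense subsumes
curves (a spiral is the extreme of its own curve; a zigzag's sharp swings
are not additionally curves), while peripheral events live on a different
substrate and are kept.

```{r events}
gen <- generate_archetype(archetype_spec("F", n_curves = 4, n_zigzags = 1,
                                         noise_sd = 0, seed = 8), cfg)
lab <- ssa_classify(gen$track, cfg)
lab
tidy(lab)
```

```{r plot-track}
plot_track(gen$track, cfg)
```

## The synthetic test bed

No tracking data ship with the package, so validation rests on a
generator whose ground truth is defined by *construction*, never by
running the classifier. Trajectories are built with a turtle-style path
engine that keeps two regimes strictly apart:

* **navigation** — approaches, corrections, wandering — is steered with
  per-step turns capped at 70°/s, well below the significance threshold,
  so it cannot register as a trajectory change;
* **motifs** — 120° arcs at 200°/s, 450° spirals, four-swing ±90°
  zigzags, and servo-driven wall excursions crossing an octant boundary in
  zone 4 — are the deliberately inserted changes, isolated by straight
  buffers longer than `straight_break`.

Direct archetypes clip zone 1 on a fixed pass through the point of the
platform ring facing the pool centre before committing any change;
indirect archetypes place their first change before ever nearing the
platform ring. Ineffective archetypes use sub-threshold wandering (a
patrol loop confined to three contiguous octants for H, anchors spread
around the pool for I) or wall-following at a radius outside the reach of
zone 1 (J). Every construction is validated geometrically — inside the
pool, platform disc untouched before the scheduled final approach, no
unintended multi-octant outer-zone episodes — and retried with a rotated
anchor layout when a layout happens to violate its own invariants; a spec
whose construction cannot be realised is rejected as infeasible rather
than mislabelled. Change counts are constructible only for the effective
categories; for I and J the wandering/wall-hugging geometry produces
peripheral episodes as a by-product, so their ground-truth change count is
undefined by design.

Release points rotate among three pseudo-random octants per day in cohort
simulations, mirroring standard acquisition protocols (four 90 s trials
per day, eight rats per group). The default per-day category mixtures
emulate the qualitative learning progression reported for young versus
aged cohorts — young animals shifting to direct, increasingly precise
strategies by day 10, aged animals gaining effectiveness mainly through
indirect strategies — interpolated smoothly across days; the exact
frequencies are the package's own choice, since published values exist
only as bar charts.

What passing tests show — and what they do not: the generator emulates
strategy *archetypes* with idealised kinematics (constant speed, Gaussian
positional jitter). Real swims have variable speed, drift, and
idiosyncratic micro-movements; the noise-robustness figures below bound
the pipeline's sensitivity to jitter, not to every property of real
tracking data.

```{r cohort, fig.height = 4}
young <- generate_cohort(cohort_spec("young", n_rats = 4, days = 6, seed = 1),
                         labels_only = TRUE)
plot_strategy_frequencies(pool_strategies(young, group, day))
```

## Validation results computed by the test suite

* Noise-free exactness: over the exhaustive archetype grid (all ten
  categories crossed with every feasible change count 0–8) and hundreds of
  random change-kind compositions, the classifier reproduces the
  constructed category and change count without error.
* Boundary exactness: sweeping constructed effective-direct trials over
  0–10 changes yields A,B,B,B,C,C,C,D,D,D,D; the indirect sweep over 1–10
  yields E,E,E,F,F,F,G,G,G,G.
* Threshold strictness: single arcs of 80°, 90°, 91° register 0, 0, 1
  curve events; zone-3 dashes spanning 1–3 octants register nothing and 4
  octants register one event; zone-4 episodes need a second octant.
* Noise robustness: at 0.5 cm per-sample jitter, category recovery is
  ~95–97% over random archetypes (the test asserts a conservative ≥ 85%).
* Statistics: the pooled chi-square has type-I error within 0.05 ± 0.02
  over 1000 same-mixture simulations; rank tests agree with brute-force
  permutation oracles at n = 8 per group; kappa reproduces hand-computed
  tables and an independent implementation.

Problem sizes in the routine test run are scaled to keep the suite quick
(e.g. 40–60 random specs per property, 10⁵ points for the partition
check); the standalone validation runs behind the defaults used several
hundred specs per configuration.

## Statistical layer

For cohort comparisons, categories are pooled into direct (A–D), indirect
(E–G), and non-effective (H–J) sets and compared with Pearson's chi-square
(no continuity correction on the 2×3 table; classes with a zero margin are
dropped with a warning and the degrees of freedom adjusted — the package
treats the 2×k table's empty class as uninformative rather than
contributing a 0/0 cell). Observer reliability uses Cohen's kappa, both on
the full A–J labels and per classification parameter
(`agreement_by_parameter()`), mirroring how inter-rater agreement is
reported for this class of algorithm: perfect agreement on effectiveness
and directionality is the degenerate κ = 1 case, while precision bands
carry most of the disagreement. Traditional measures are compared with
two-sided Mann–Whitney U (midranks, normal approximation), Friedman tests
across days with Bonferroni-corrected pairwise signed-rank post hocs, and
a Lilliefors-corrected Kolmogorov–Smirnov normality screen. Two-sidedness
throughout is the package's choice; the Bonferroni family is all pairwise
day comparisons within a group.

```{r stats}
aged <- generate_cohort(cohort_spec("aged", n_rats = 4, days = 6, seed = 2),
                        labels_only = TRUE)
chi_square_pooled(young[young$day == 6, ], aged[aged$day == 6, ])
cohens_kappa(young$category, young$category)$kappa
```

## Known limitations

* Turns slower than `turn_tol` per step (~100°/s at the default grid) are
  treated as drift: a rat that commits a genuine course change very slowly
  will not register it. This is the price of jitter immunity and is
  tunable.
* The H/I distinction inherits octant instability near the pool centre: a
  search hovering at the centre has ill-defined octants. The synthetic
  patrol avoids the centre; for real data the thresholds may need lab
  calibration.
* A wall-hugging episode that also accumulates > 90° of heading change
  counts as both a peripheral and a curve event (different substrates);
  whether one episode should count once is genuinely ambiguous, and the
  package counts both.
* Sequence memory across trials and left/right asymmetries are out of
  scope for the classifier by design.
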