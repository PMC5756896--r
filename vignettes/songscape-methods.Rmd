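---
title: "songscape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{songscape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songscape)
```

songscape studies how neighboring territorial songbirds time their songs
relative to one another. The pipeline starts from what a multi-microphone-array
deployment actually produces — per-array direction-of-arrival (DOA) event
streams — and ends with statistical statements about overlap avoidance and
directional influence between identified individuals. This vignette explains
each model, its assumptions, the parameters that matter, and the design
choices made where the design was genuinely open.

## 1. Time and interval conventions

All times are seconds from session start, and all intervals are half-open
`[begin, end)`. Abutting songs therefore do not overlap and durations are
additive, which makes the vacant/overlapped/solo decomposition exact under
interval sweeps with no grid. A bird's own songs are merged at load time: an
individual cannot overlap itself, so overlapping or abutting intervals on one
timeline are a representation artifact, not a behavior.

Azimuths are stored internally as degrees counterclockwise from east (the
mathematical convention). Compass azimuths (clockwise from north) are accepted
at the file boundary and converted on load; the conversion `90 − a (mod 360)`
is its own inverse.

## 2. Spatial localization

Each array reports DOA events: an azimuth track sampled every `DT = 0.2` s
between a begin and an end time. A candidate sound source is a triple of
events, one from each of three arrays. Each event is collapsed to a single
bearing — the circular mean of its azimuth track — and each bearing defines a
half line from the array. The three pairwise half-line intersections of a
consistent triple nearly coincide; their centroid is the location estimate.

Candidates must pass three gates:

* **Spatial gate `R` (default 15 m):** the maximum pairwise distance among
  the three intersection points. Triples built from different sounds
  intersect incoherently and are rejected.
* **Begin gate `DB` (default 6 s):** all member begin times within `DB`.
  Generous, because these songs open with quiet introductory notes that
  different arrays miss by different amounts.
* **End gate `DE` (default 1 s):** all member end times within `DE`. Tight,
  because the loud terminal notes give every array a sharp, consistent end —
  the end is the discriminative signal.

An accepted source takes its begin and end from the member event of the array
nearest the centroid (the cleanest recording), then subtracts
`end_correction = 0.6` s: the upstream detector needs trailing silence to
close an event, so raw ends systematically overshoot. Gates are checked on
raw (uncorrected) times; the correction applies to the accepted duration
only.

Open design points and how they were resolved:

* **Per-event vs per-frame intersection.** Tracks could be intersected frame
  by frame and clustered afterwards. We intersect once per event using the
  track-mean bearing: it is deterministic, matches the one-location-per-sound
  output the analysis needs, and averaging ~15–40 frames of 2° noise cuts the
  effective bearing error well below half a degree. Per-frame mode would be a
  straightforward extension.
* **Competing candidates.** Nothing in the problem fixes how to resolve
  triples that share an event. We process candidates greedily in ascending
  spatial-gate statistic (tightest triple first; ties broken by earlier begin
  then lexicographic event ids), and each event joins at most one source.
  This makes output independent of input row order.
* **More than three arrays.** All 3-subsets of arrays are enumerated, still
  with exactly-three-event triples. This stays within the combinatorics the
  gating was designed for.
* **Parallel rays** are declared at 1e-9 rad — far below any noise scale that
  matters here — and intersections behind either origin are rejected (half
  lines, not lines).
* **Degenerate durations.** A candidate whose corrected end does not exceed
  its begin (possible only for sub-0.6 s clutter) is dropped.

The observed-vs-localized diagnostic walks each human-observed interval in
1 s ticks and measures the distance from the observed location to the nearest
concurrently active source; summary statistics restrict to distances < 30 m,
separating localizations of the observed bird's own song from sources at the
other bird's post ~50 m away.

## 3. Song posts and timelines

Territorial males sing repeatedly from habitual perches, so localized sources
within a radius of a known post are attributed to that individual. Radii are
per-individual (defaults 15 m and 10 m in the bundled demo) because birds
differ in how far they range: a bird that moves more needs the larger radius.
If two posts qualify, the nearer center wins. When two sources assigned to one
individual overlap in time, the earlier-beginning one is kept and the other is
dropped entirely — the later "source" is almost always a refracted duplicate
of the same song. Unassigned sources are reported, never silently discarded.

Timelines are scored against annotated ground truth by exact interval sweep:
TP/FP/TN/FN *durations* over the window, with
`accuracy = (TP+TN)/(TP+FP+TN+FN)`, `TPR = TP/(TP+FN)`,
`FPR = FP/(FP+TN)`.

Binarization for the information-theoretic analysis assigns each 0.5 s bin a
1 iff a song interval contains the bin midpoint. The midpoint rule is
unbiased for duty cycle (any-overlap binarization inflates it by up to one
bin per song); only complete bins are emitted.

## 4. Interaction statistics

**Null model.** Every test uses the gap shuffle: a surrogate timeline keeping
each song's duration and order while permuting the multiset of
nonsinging-interval durations, including the leading and trailing gaps (they
are nonsinging time within the window like any other). The surrogate
preserves duty cycle and bout structure and destroys only the relative timing
between the two birds — precisely the quantity under test. All p-values are
Monte-Carlo proportions with *strict* inequalities, so ties count against
significance (conservative).

**Solo test.** Observed statistic: solo duration (time exactly one of the
pair sings). Both timelines are shuffled independently per draw;
`p = P*(solo_null > solo_obs)`. Overlap avoidance inflates solo time, so
avoidance is flagged at p < .025 and active overlap at p > .975 (two-tailed).

**Asymmetric active-overlap test.** Directional: the target's active overlap
is the co-singing time during target songs that began while the reference was
singing. Only the target is shuffled; `p = P*(null < observed)`, so p < .025
means the target avoided starting during the reference's songs. Two
attributions of co-singing seconds are implemented:

* `union` (default): a later-starting song collects *all* its co-singing
  seconds, even against reference songs that begin after it. Simple and
  monotone, but the two directed durations can jointly exceed the pair's
  total overlap (a second can be claimed by both directions when each bird
  starts a song inside the other's).
* `onset_song`: counts co-singing only with the reference song containing the
  onset. Under this attribution the two directions partition the overlap they
  cover and never jointly exceed the total.

The default follows the simpler, monotone reading; the alternative is a flag
because the partition property is sometimes wanted.

**Transfer entropy.** For binarized series, the plug-in estimator of

$$TE_{Y \to X}(k, l) = \sum p(x_{t+1}, x_t^k, y_t^l)\,
\log_2 \frac{p(x_{t+1} \mid x_t^k, y_t^l)}{p(x_{t+1} \mid x_t^k)}$$

with empirical frequencies over all valid t. The log base is 2 (bits); base
affects scale only, and every comparison is against a randomized null on the
same scale. History defaults are `k = l = 1`: the shortest histories the
definition admits, with 0.5 s bins spanning the typical pause between notes.
The TE null shuffles the *source timeline at the interval level* and
re-binarizes — not a bit permutation — so the null preserves the source's
bout structure, and `p = P*(TE_null > TE_obs)` (one-tailed: a shuffled source
should not predict the sink better).

**Bootstrap.** Session-level effects (null-expected minus observed overlap;
TE minus null-mean TE; difference of observed/expected overlap ratios between
the two individuals) are resampled over sessions with replacement — sessions
are the only exchangeable units — with percentile 95% intervals and a
two-sided sign bootstrap p-value `p = min(1, 2·min(P*(stat ≤ 0),
P*(stat ≥ 0)))`. The ratio-difference effect needs both individuals' observed
and expected values per session, hence its four-column input layout.

## 5. The synthetic soundscape

The generator is the package's stated world: every downstream claim is tested
against it, so its assumptions matter.

* **Singing model.** Each bird alternates an exponential gap (mean
  `gap_mean`, default 5 s — onset hazard is constant while waiting) and a
  lognormal song (`meanlog = log 3`, `sdlog = 0.4`: median 3 s, right-skewed,
  typical of a loud territorial warbler). Defaults give a duty cycle near
  0.4, the regime in which overlap statistics are informative. Simulation
  runs on a 0.05 s grid, ten times finer than the analysis bin.
* **Interaction.** While any attended bird sings, a waiting bird's onset
  hazard is multiplied by `suppression`: 0 is a hard avoider, 1 independence,
  >1 an overlapper. Only onsets are modulated; ongoing songs are never
  truncated, so song-duration distributions are independent of the
  interaction — the observable is "began to sing while the other sang",
  and that is the only thing the mechanism touches. Birds are staggered by a
  deterministic sub-step phase so cross-bird onsets never coincide exactly;
  without this, a hard avoider could start at the same grid instant as the
  driver and half-open semantics would count it as an overlap onset.
* **Observation noise.** Per (song, array): a miss with probability
  `miss_prob`; otherwise a begin delayed by `U(0, begin_jitter_max)`
  (default 2 s — quiet introductory notes are detected late), an end jittered
  by `N(0, 0.3 s)` plus the fixed +0.6 s detector tail that localization
  later removes, and azimuth-track frames with i.i.d. `N(0, azimuth_sd)`
  noise (default 2°) around the true array-to-song bearing. Clutter arrives
  per array as a Poisson process (default 1/min) with uniform azimuths,
  independent across arrays, so clutter only triangulates by coincidence —
  which is the failure mode the gates are meant to catch.
* **What it does not emulate.** No waveforms, no frequency content, no
  amplitude-distance attenuation, no correlated misses (e.g. a bird turning
  away from all arrays at once), no moving-while-singing trajectories, and no
  acoustic interference between simultaneous singers. A green test therefore
  establishes algorithmic correctness under the stated noise model, not field
  performance; the field numbers (5–6 m mean localization error, accuracy
  0.83–0.95 for a stationary bird) require real recordings and the upstream
  DOA estimator, which are out of scope here.

## 6. A known red result: reverse transfer entropy at k = 1

On hard driver/avoider scenes the avoider's asymmetric overlap test and the
driver→avoider TE test both reject essentially always — the designed signal.
One acceptance expectation is deliberately left failing: the claim that the
*reverse* direction (avoider→driver) should reject at ≈ α. Measured over 100
replicates it rejects ~40% of the time at `k = l = 1`.

This is a real property of plug-in TE with short sink history, not an
implementation defect. The driver's next state depends on its own hidden
renewal state (how long it has been singing or silent), which a single 0.5 s
bin cannot encode. The hard-coupled avoider's state is an informative proxy
for that hidden state, so conditioning on it genuinely reduces uncertainty
about the driver's future — a non-causal statistical dependence the
source-shuffling null correctly detects as "information". The suite's
diagnostics confirm the mechanism: at `k = 3` the reverse direction falls
back inside the 99% calibration band, and on independent pairs (suppression
1) both tests are exactly calibrated. Practical reading: a significant TE in
*one* direction only is evidence of asymmetry; significant TE in both
directions at `k = 1` should prompt a sensitivity check over `k` before any
causal interpretation.

## 7. Numerical choices

* Interval sweeps are exact (boundary arithmetic), never gridded; test
  oracles use 1 ms grids, hence millisecond tolerances in tests only.
* Circular means use the angle of the mean unit vector; bearings straddling
  0°/360° average correctly, and results are reduced mod 360 (a value within
  1e-9° of 360 is the same bearing as 0).
* Monte-Carlo tests take an explicit `seed` and save/restore the global RNG
  state, so library calls never perturb a caller's random stream and every
  p-value is reproducible in isolation.
* The pipeline derives per-stage seeds by fixed offsets from the run seed;
  rerunning a config byte-reproduces every output table.
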