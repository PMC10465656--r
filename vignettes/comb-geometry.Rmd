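---
title: "Measuring stimulus-guided comb construction: models, metrics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stimulus-guided comb construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combmetrics)
```

## The measurement problem

Honeybee comb construction experiments offer wax tabs carrying artificial
stimuli to a colony and ask whether the cell walls built afterwards follow
the geometry each stimulus predicts. A shallow pit the size of a nascent
cell base predicts wall deposition along its rim; a pair of pits predicts
a shared wall on their *common tangent* (the line through the gap,
perpendicular to the centre–centre line); a V-shaped strip predicts a wall
on the internal *bisection* at its apex; a hybrid (V plus a deliberately
misaligned pit pair) pits the two predictions against each other. The
evidence is always a comparison of the real stimuli against randomized
virtual stimuli measured by the same procedure: the controls estimate how
well walls align with arbitrary geometry by chance.

This package turns that protocol into reproducible code: batch landmark
annotations replace interactive marking, a four-point homography replaces
the manual photo alignment, the four metrics are computed analytically,
and the control populations are generated from a seeded RNG.

## Coordinate and angle conventions

Coordinates follow the image convention: x rightward, y downward, origin
at the top-left tab corner; angles are measured clockwise from horizontal
(which, with y down, is simply `atan2(dy, dx)`). Wall orientations are
undirected and live in [0°, 180°); angular divergences are reduced to
[0°, 90°] under the 180° equivalence. All geometry is computed in
millimetres in the after-photograph frame: stimuli marked on the before
image are mapped forward through the estimated homography, then divided
by the pixels-per-mm calibration (9 px/mm by default, the scale of the
photographic rig the annotation format assumes).

Because exactly four alignment landmarks are used, the homography is the
exact solution of an 8×8 linear system, not a least-squares fit: it
interpolates its defining correspondences to machine precision, and a
condition-number warning (above 1e8) flags degenerate landmark layouts.
Collinear triples and duplicate landmarks are rejected outright.

## The four metrics and their numerical choices

**Rim overlap.** The original operator judged rim–wall coincidence by
eye. We formalize it: a point of the 4.0 mm gauge circle is *overlapped*
when it lies within `tol_mm` of a wall segment, with `tol_mm = 0.35` —
about half a natural wall thickness — as the default. The overlapped set
is a union of arcs computed analytically: for each wall, the circle's
crossings of the tolerance band's boundary (two offset lines and two
endpoint cap circles) partition the circle, and each run between
consecutive critical angles is classified by one exact point-to-segment
distance test at its midpoint. Arcs are merged across walls, so the total
can never exceed 360°. Tests check this computation against a dense
0.1°-sampling oracle.

**Tangent divergence.** The measured wall for a pit pair is the wall
nearest (segment distance) to the pair midpoint, mirroring how a marker
chooses "the wall found between the two pits". A record is excluded when
the *infinite line* through the marked wall does not cross the open
segment between the pit centres — the line rather than the finite
segment, because marked walls are routinely offset along their own axis.
Exclusions are flagged per record, never silently dropped.

**Bisection divergence and proximity.** The V bisector is the internal
angle bisector at the apex (the direction into the opening), reduced mod
180° for divergence. The proximity ratio is `P = d1/(d1 + d2)` where
`d1`, `d2` are apex distances to the *corners* — each wall's nearer
endpoint — of the two nearest distinct walls; ties are broken by
annotation order, deterministically. `P = 0.5` exactly when the two
corners are equidistant; a wall corner exactly at the apex yields `P = 0`
with a warning.

**Orientation ratio.** The paired built and predicted orientations are
compared by a through-origin least-squares slope. Orientations are 180°
periodic, so each built value is first unwrapped to the representative
(± 180°) closest to its predicted partner; without this, a (1°, 179°)
pair would register as a gross disagreement instead of a 2° miss.

## Control populations

Controls are matched one-to-one with real stimuli: a virtual pit uniform
in the 10.0 mm disc around each real pit (radial density ∝ r, the
uniform-in-disc law), a virtual pair with uniform midpoint and
orientation and separation uniform on [5.0, 6.0] mm, a virtual V with
uniform apex and direction and splay uniform on [90°, 152.2°]. Draws
falling outside the tab are rejected and redrawn; near the tab edge this
slightly biases virtual stimuli inward, which we accept as the analogue
of drawing controls on the photographed tab. Hybrid stimuli receive no
randomized control: their comparison is paired within the stimulus (the
same wall measured against both guides) and, across experiments, against
the pit-pair and V-form real populations. Whether virtual stimuli should
be constrained to regions with nearby comb is an open question of the
protocol; no such constraint is applied.

Randomness everywhere comes from R's global RNG; the pipeline drivers
take an optional `seed` applied locally (via `withr`), and record seeds
in output headers, so identical seeds reproduce identical populations.

## The synthetic comb generator

The generator emulates the *statistical structure the analysis assumes*,
not comb growth. Per tab (25 × 40 mm, the tab size of the protocol):

- stimuli are placed with every pairwise distance ≥ 10 mm and each
  nearest neighbour ≤ 15 mm, at the per-tab densities of the protocol
  (6 pits or pairs, 4 Vs or hybrids), 4 mm from the edges;
- each stimulus receives one *response wall* (4 mm long) whose
  orientation is the predicted orientation plus folded-normal noise
  ε ~ N(0, σ) folded to [−90°, 90°], with σ = 5° by default — the scale
  of divergence observed in real comb — and whose position is the
  predicted location plus Gaussian offset (sd 0.5 mm). For pits the
  predicted geometry is the rim tangent at a random contact point; for
  hybrids the wall follows the tangent with probability `tangent_mix`
  (default 2/3) and the bisection otherwise, with the two guides
  misaligned by 30°;
- distractor walls fill the tab as the edges of a jittered hexagonal
  lattice at 5.2 mm pitch (worker-cell scale; the protocol does not fix
  a cell pitch, so it is configurable). The field overhangs the tab edge
  by 3 mm so boundary stimuli see the same wall density as interior
  ones; without the overhang, controls near edges measure systematically
  less comb and the null calibration below would be invalid. In biased
  mode, distractors within 3 mm of pair midpoints and V apexes are
  removed so the response wall is the nearest — for pits no clearance is
  applied, since rim overlap is additive and real comb would surround a
  pit as well as touch its rim;
- a mild random projective warp (corner displacements ≤ 5 px, mirroring
  a fixed photographic jig) separates the before and after frames, so
  the alignment stage is always exercised; stimuli are stored in
  before-image pixels, walls in after-image pixels.

**Null mode** severs the stimulus–wall relationship completely: response
walls get uniform orientation *and* uniform position. Keeping the wall at
the predicted location while randomizing only its orientation would leave
the position-sensitive metrics (rim overlap, proximity) correlated with
the real stimuli, and the "null" would not be null; full randomization
makes real and control populations exchangeable for all four metrics,
which is what a type-I-error calibration requires.

What the generator does *not* emulate: curved or branching walls, wall
thickness variation, partially built comb, annotation (marking) error,
and any actual construction dynamics. Passing tests therefore show that
the pipeline measures what it claims and detects biases of the assumed
form at the stated sample sizes — not that real photographs are free of
marking artefacts.

## Calibration and recovery properties

The test suite verifies, at desk scale (single CPU, minutes):

- **Type-I calibration.** On null-mode comb, each experiment's rejection
  rate at α = 0.05 stays within the 99% binomial band over 500
  replicates (12 pits, 18 pairs, or 12 Vs per replicate — sizes chosen
  so the exact rank-sum test's discreteness does not make the test
  overly conservative after exclusions).
- **Effect recovery.** With σ = 5° at the study sample sizes (63 pairs,
  79 Vs), the real-versus-control rank-sum p is below 0.001 in ≥ 95% of
  replicates, and σ̂ = sqrt(mean(d²)) — exact for a half-normal angular
  error — lands in [3.5°, 6.5°] in ≥ 90%.
- **Uniform controls.** Control divergences, measured before the
  between-centres filter, average 45° (a uniform orientation against
  anything gives divergence uniform on [0°, 90°]). The filter itself
  *selects* control walls whose lines pass between the centres and pulls
  the retained control mean down toward ~37°; this is a property of the
  exclusion rule worth knowing when comparing control means across
  analyses.
- **Preference recovery.** With a 2/3 tangent mixture at n = 81
  hybrids, the recovered preference fraction matches the exact binomial
  interval of 2/3 (misclassification is negligible: with a 30°
  guide misalignment, a wall is attributed to the wrong guide only when
  |ε| > 15°, about 0.3% at σ = 5°).

A small end-to-end run:

```{r example}
set.seed(1)
study <- simulate_study(synth_tab_spec("v_form", sigma_deg = 5), 16)
exp3 <- run_experiment3(study$tabs, seed = 2)
tidy(exp3)
```

```{r plot, fig.width = 6, fig.height = 3}
autoplot(exp3)
```

## Known limitations and open choices

- The wall-marking convention (midline versus edge) is left to the
  annotator; the schema stores one segment per wall.
- Measurements are taken in the after frame; mapping walls backward
  instead would change nothing for the divergence metrics (homographies
  this mild are locally near-rigid) but is not offered.
- The unpaired t test defaults to the Welch variant, with the pooled
  Student variant a flag away; for rank-sum statistics we report the
  first-group Mann–Whitney U (W = 0 when every real value precedes every
  control value), which is R's convention — other software reports the
  complementary statistic, so compare conventions before comparing W
  values.
- Experiment 4's cross-experiment comparisons pair the hybrid tangent
  divergences with the pit-pair experiment's real population and the
  hybrid bisection divergences with the V-form experiment's; both are
  optional arguments, since they mix populations collected under
  different stimuli.
- Simulation sizes in the test suite (500 null replicates, 100 recovery
  replicates, 10 000 generator draws) were chosen as the smallest runs
  whose pass/fail bands are statistically meaningful at 99% confidence.
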