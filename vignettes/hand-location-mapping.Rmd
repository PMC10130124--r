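---
title: "Mapping hand location in the visual scene: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping hand location in the visual scene: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis model

`handscape` treats the head-mounted camera frame as a proxy for the
head-centred visual field. This carries two assumptions that the package
inherits rather than corrects: the camera is aligned so that the centre of
the frame approximates the centre of the visual scene, and no eye-in-head
correction is applied — gaze can wander from the head axis, which adds
variance to any scene-based map but does not bias it in a known direction.
Analyses are frame-marginal: each frame is an observation, and no temporal
structure (dwell times, transitions between zones) is modelled.

Each detected hand in a frame is summarised by the centre of its bounding
box. Only the centre is classified; a box may straddle a midline, and that
partial overlap is deliberately ignored because the centre is the detector's
best single estimate of hand position. Image coordinates (origin top-left,
y downward) are converted to Cartesian screen coordinates (`y = H − cy`)
before any classification, so "upper" always means upper visual scene.

The frame is partitioned by its real-valued midlines (`W/2`, `H/2`) into
vertical hemiscenes, horizontal hemiscenes, quadrants, and — relative to the
hand's own side — ipsilateral/contralateral zones. Bimanual frames are
expanded into one record per hand. This makes "frames containing the left
hand" and "frames containing the right hand" sum to the analysis total, and
it is the unit on which every occupancy table and statistic is built.

## Tunable parameters

- **Midline tie-break** (`tie`, default `"lower_left"`): a centre exactly on
  a midline goes to the lower/left zone. With real-valued centres, ties have
  essentially measure zero, so the choice is immaterial in practice; it is a
  parameter (the alternative is `"upper_right"`) precisely so that this
  insensitivity can be demonstrated rather than asserted.
- **Pooling** (`pooling`, default `"frames"`): pooled occupancy tables are
  frame-weighted across all in-scope records. The alternative
  (`"participants"`) averages participant percentages with equal weight.
  Frame-weighting is the default because the pooled tables describe the
  corpus of frames; the per-participant tables (always computed alongside)
  are the correct input for inference, where each participant counts once.
- **Significance levels** (`alpha = 0.05`, `family_size = 8`): the two
  zone-versus-zone comparisons (lower vs upper; ipsilateral vs
  contralateral, both hands pooled) form one family tested at `alpha`. The
  eight left-versus-right-hand comparisons (two hemiscene pairs and four
  quadrant contrasts) form a second family tested at `alpha/8 = 0.00625`.
  Keeping the families separate matches how the two sets of questions are
  asked: the first family is two planned headline contrasts, the second is
  a battery over zones.
- **Density grid** (`grid_nx = 24, grid_ny = 16`): the computational grid is
  rectangular with an exact conservation contract (bin counts sum to the
  number of points; marginals equal the 1D histograms). Hexagonal binning is
  purely a rendering choice in `plot_hand_density()`.

## Statistical procedure

For each comparison the per-participant percentages are paired and

\[ t = \frac{\bar d}{s_d/\sqrt{n}}, \quad df = n - 1, \quad
   d_z = \frac{|\bar d|}{s_d}, \]

with a two-sided p value and a 95% confidence interval
\(\bar d \pm t_{0.975, n-1}\, s_d/\sqrt{n}\). Cohen's dz is reported as a
magnitude; direction is carried by `t` and the interval, and
\(|t| = d_z\sqrt{n}\) holds exactly. Tests are two-sided throughout.

Degenerate inputs fail loudly rather than silently: fewer than two
participants or zero-variance differences raise errors in `paired_t()`, and
`comparison_battery()` skips (with a warning naming the participants) any
comparison in which some participant has no records for one member — the
paired design would otherwise drop participants invisibly. Handedness ties
("undetermined") are likewise excluded from handedness-stratified tables
with a warning, because defaulting a tied participant to either side would
bias stratified outputs.

## The synthetic generator

The generator exists so every pipeline stage runs and is testable without
external data, and so that parameter recovery can be asserted: a stream is
drawn from a known configuration and the pipeline must recover the
configured marginals within binomial sampling error
(`recovery_check()`).

Frames are i.i.d.: presence → bimanuality → side → per-side centre → box →
contact state. What this emulates is the *marginal* statistical structure a
frame-marginal analysis consumes; what it does not emulate is temporal
autocorrelation (real hands move smoothly), detector noise or confidence
filtering, per-video heterogeneity, and any relation between contact state
and location. Passing tests therefore validate the bookkeeping and the
statistics, not the realism of any one kitchen.

Defaults are the study-like conditions the package targets:

- 37 participants, 456 × 256 frames, a hand present in 78.51% of frames, a
  32:5 right:left handedness mix, and contact states distributed
  (portable, stationary, no-contact, self-contact) =
  (0.832, 0.029, 0.127, 0.012).
- Bimanuality and unimanual-side rates cannot be pinned down exactly from
  aggregate frame counts alone: under "at most one box per side", the
  published style of totals (frames, frames-with-hands, per-side totals)
  over-determines the rates and is not jointly satisfiable. The defaults
  `p_bimanual_given_present = 0.9` and `p_left_given_unimanual = 0.25` were
  chosen once as a realistic compromise: kitchen work is heavily bimanual,
  and the resulting left:right record ratio (≈ 0.95) reproduces the
  characteristic small right-hand excess.
- The default spatial model is, per side, a two-component truncated-Gaussian
  mixture: a dominant component low and ipsilateral (mean at 33% of frame
  width from the hand's own edge, 30% of frame height) plus a broader
  central component. This echoes the smooth, unimodal-per-hand,
  lower-ipsilateral density that hex maps of real egocentric streams show.
  A `quadrant_spatial_model()` (multinomial over quadrants, uniform within)
  is provided where exact generating occupancy is wanted, e.g. for recovery
  tests.
- Truncation to the frame uses rejection sampling, not clipping: clipping
  would pile mass onto the frame edges and distort quadrant proportions.
  Boxes are drawn around the centre and shrunk to keep the centre in frame;
  box size is analytically irrelevant to classification (only centres are
  classified) and exists so the interchange format is fully exercised.
- Per-participant sub-streams use seeds derived from the master seed, so
  enlarging the cohort never perturbs earlier participants, and generation
  is bit-identical for a fixed configuration.
- Optional between-participant heterogeneity (`participant_jitter`, a
  per-participant shift of mixture means) is off by default: none of the
  analyses require it, and a homogeneous null is the cleaner base case for
  calibration.

## Numerical choices

Coordinates stay real-valued end-to-end; nothing is rounded before
classification (integer truncation would bias midline decisions).
Percentages are carried at full precision and only formatted to one decimal
in printed tables. The JSON-lines writer emits doubles at 17 significant
digits so a write/read round trip is bit-exact. Duplicate detections for one
(participant, video, frame, side) are rejected, keeping the earlier record,
rather than merged — the upstream detector emits at most one box per side,
so a merge rule would be an invention.

## Test problem sizes

The shipped test-suite sizes were chosen to make sampling-theory tolerances
tight while keeping the suite quick: parameter recovery runs at 10^6
detections (3-standard-error bands of about ±0.1 percentage points), and the
type-I-error calibration of the hand-comparison family runs 1,000 replicate
null streams of 37 participants × 120 bimanual frames each, checking each
comparison's rejection rate against its 0.00625 threshold within Monte-Carlo
error.

## Known limitations

- Scene-based, not gaze-based: no eye-tracking correction is possible from
  bounding boxes alone.
- Frame-marginal statistics; autocorrelated frames make per-participant
  percentages slightly noisier than i.i.d. theory suggests, which the
  paired design absorbs but the generator does not emulate.
- The interchange format carries no detector confidence, so no confidence
  filtering is applied or representable.
- Mixed frame geometries are supported everywhere except density grids,
  which require a single geometry.
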