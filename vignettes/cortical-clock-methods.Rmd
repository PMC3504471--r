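---
title: "Methods: the cortical FA clock, cross-species translation, and neurite orientation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cortical FA clock, cross-species translation, and neurite orientation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexclock)
```

## The maturation clock

Cortical fractional anisotropy (FA) is modelled as a piecewise exponential
in postconceptional age: a plateau at `FA_max` while pyramidal neurons are
still being generated and migrating, then

$$\mathrm{FA}(t) = (\mathrm{FA_{max}}-\mathrm{FA_{min}})\,
e^{-(t-t_\mathrm{init})/\tau} + \mathrm{FA_{min}}, \qquad t \ge t_\mathrm{init},$$

continuous at the breakpoint. The two clock parameters have anatomical
readings: `t_init` (days post conception) marks the completion of
pyramidal-cell neurogenesis and migration to the cortical plate, and `τ`
(days) the rate at which the neuropil arborizes — dendritic and axonal
branching progressively restricts water diffusion in all directions and FA
falls. The assumption doing the real work downstream is that the
*normalized* decay

$$f(t) = e^{-(t-t_\mathrm{init})/\tau} \in (0, 1]$$

indexes the same neuropil-maturation stage in every species, so `f` is a
species-free developmental coordinate. `FA_max`/`FA_min` cancel out of `f`;
the shipped registry therefore carries nominal bounds (1, 0) for every
species, and absolute FA output is nominal unless real bounds are supplied.

All internal ages are days post conception, floating point; postnatal ages
exist only at the I/O boundary (`pn_to_pc()` / `pc_to_pn()`, postnatal day
P*n* = gestation + *n*). This avoids birth — which falls at very different
maturational stages across species — entering any computation.

### Registry values and units

| species | gestation (d) | `t_init` (dpc) | `τ` (d) |
|---------|--------------:|---------------:|--------:|
| rat     | 21.5          | 22             | 5       |
| ferret  | 41            | 49             | 10.7    |
| human   | 270           | 173            | 39.8    |
| cat     | 65            | —              | —       |

The cat has no published cortical FA trajectory; it participates only in
age-frame conversions. Human gestation is set to the conventional 270 days;
it affects only postnatal/gestational rendering, never the translation
itself.

## Window translation

`translate_window()` composes two exact maps: a source window
`[t_1, t_2]` becomes fraction bounds `(f(t_1), f(t_2))`, which the target
clock inverts as `t = t_init + τ·ln(1/f)`. Consequences that the tests
exercise as invariants: translation is the identity within a species,
transitive across species (fractions are species-free), order-preserving,
and maps window length to `τ_target · (ln f_start − ln f_end)`.

A window that starts before the source `t_init` is rejected rather than
silently clamped: on the plateau `f` saturates at 1 and the window has no
unique fractional representation. This matters in practice — the ferret
enucleation experiments begin at P7 (PC 48), one day before the ferret
`t_init` of 49.

Reported ages round to the nearest whole day, half away from zero, and
gestational weeks to one decimal, matching the precision conventions of the
source literature (the exact bounds are always retained in the report
objects). The translated rat critical period P4–P6 lands at human
gestational days 200.86–216.78 → 201–217, and ferret PC 56.49–60.77 →
PC56–PC61. For the ferret the source literature itself prints two variants
(PC56–PC61 in the text, PC56–PC60 in a figure caption); the package
follows the computed values with away-from-zero rounding, which reproduces
the text variant.

The published Translating Time windows (human 138–150 gestational days,
ferret PC 52–56.5, and the single cat events at gestational days 61.9 and
66.8) ship as immutable constants in `tt_references()` for comparison only;
the underlying regression over species and event scores is out of scope
here, and no attempt is made to re-derive it.

Neither `t_init` nor `τ` carries a published uncertainty, so predicted
windows are reported without confidence intervals.

## Fitting the clock

`fit_fa_params()` minimizes squared error. The breakpoint makes the model
non-smooth in `t_init`, so gradient descent on all four parameters is
unreliable near the kink; instead, when `t_init` is free it is profiled — a
1-day sweep over the observed age range, then a 0.1-day refinement around
the coarse optimum — with a Levenberg–Marquardt solve of the remaining
parameters at each candidate. Starting values are scale-free (max/min
observed FA, a third of the age span for `τ`), bounds keep the FA
parameters in [0, 1] and `τ` positive, and the convergence flag is taken
from the inner optimizer rather than assumed. Published trajectory fits
treat `t_init` as anatomically determined, so the analysis scripts fix it
where that reading is wanted; with noisy data and few plateau observations
the free breakpoint is only weakly identified (typically recovered within a
day or two, versus exactly for noiseless input).

## Axial orientation statistics

Neurite segments are undirected: θ and θ+180° are the same line. All
circular statistics therefore run on the doubled circle — fit von
Mises(2μ, κ) to 2θ and halve the mean direction. This is the standard
axial correction; for distributions concentrated well within a half-circle
it coincides with treating the angles as ordinary circular data.

κ is the maximum-likelihood concentration: the mean resultant length
$\bar R$ of the doubled angles solves $A_1(\kappa)=I_1(\kappa)/I_0(\kappa)
= \bar R$, inverted by Fisher's three-branch series approximation polished
with five Newton steps on exponentially scaled Bessel functions (agreement
with a bracketing root-finder is ~1e-8 across $\bar R$, tested). κ = 0 is
the uniform axial distribution; near-degenerate samples are capped at
κ = 500 and flagged rather than returned as overflow. The estimator floor
is 10 angles by default.

Confidence intervals are percentile bootstrap (default 1000 replicates,
seeded, vectorised); two regions are called distinct when their 95%
intervals are disjoint — deliberately the same conservative criterion the
histology literature uses for such comparisons. The method was left at
plain percentile rather than BCa because the κ statistic's bias at the
sample sizes in play (hundreds of segments) is small relative to its spread,
and coverage at κ = 2, n = 300 measures ~95% (tested to sit in 90–99%).

## The image pipeline

`analyze_orientation()` chains:

1. **Threshold** — global Otsu split, with a polarity flag for dark-on-light
   stains (inverting contrast and flipping the flag yields the identical
   mask, tested).
2. **Thinning** — Zhang–Suen iterative thinning to a one-pixel skeleton.
3. **Branch splitting** — skeleton pixels whose 8-neighbourhood ring holds
   three or more connected foreground runs are branch points and are
   removed. The run (crossing-number) criterion matters: plain neighbour
   counting misclassifies the staircase corners of thinned diagonal lines
   as branches and shreds them — orientations near ±30–60° from the axes
   vanish from the sample, badly distorting κ in either direction.
4. **Segment approximation** — each remaining arc is traced pixel by pixel
   and recursively subdivided at the point of maximum perpendicular
   deviation from its chord (Ramer–Douglas–Peucker) until every piece
   deviates ≤ 2 px; pieces shorter than 10 px are discarded. Both controls
   are exposed (`max_deviation_px`, `min_length_px`); the defaults bound
   curvature error at roughly a degree for typical segment lengths while
   keeping enough segments per field.
5. **Angles and fit** — chord angles are measured from the declared radial
   (pial-normal) axis, folded into [0, 180). The radial axis is per-image
   metadata, defaulting to image-vertical since apical dendrites are the
   dominant near-radial structures in the intended fields.

Segment-derived samples are fitted with **length-weighted** circular
moments: a straight stroke's evidence about the orientation field scales
with its stained length, and crossings chop strokes into pieces whose count
(but not total length) depends on the local crossing geometry. Weighting by
length makes the estimator approximately invariant to that fragmentation
and down-weights short junction debris, whose chord angles are noisy;
end-to-end recovery error on synthetic fields drops from ~15–25% to under
~10% with weighting. Plain angle vectors (no lengths) are fitted
unweighted, so the distributional estimator itself is unchanged.

## Synthetic generators

The generators exist to give the pipeline inputs with known ground truth:

- `gen_fa_observations()` — clock curve plus i.i.d. Gaussian noise (default
  sd 0.02 FA units, typical of the scatter in published cortical FA
  measurements), clipped to [0, 1].
- `gen_axial_angles()` — exact von Mises sampling on the doubled circle via
  the Best–Fisher wrapped-Cauchy rejection envelope, halved and folded.
- `gen_golgi_image()` — anti-aliased dark strokes (default 500 strokes of
  30–80 px, width 3 px, on a 768² canvas) on a light background with
  Gaussian intensity noise (sd 0.03). Strokes are rendered smooth and only
  binarized by the pipeline's own thresholding step, so that stage is
  exercised end to end. Stroke centres are inset so no stroke can fall
  entirely off-canvas. Output is bit-deterministic per (spec, seed).

What these emulate — and do not. The image generator produces straight,
uniform-width, uniform-contrast strokes: it captures the geometry that the
skeleton/segment/angle chain must get right (orientation mixtures,
crossings, anti-aliased edges, background noise) but not curved or
branching dendrites, somata, uneven staining, or focus gradients. Passing
recovery tests on these fields therefore validates the estimator chain, not
robustness to real histology; the published field concentrations
(κ = 2.08 enucleated-like versus 1.41 control-like) are used as *generating*
values for those tests, since the original micrographs are not available
and the upstream study's exact skeletonization parameters, estimator and CI
construction are unpublished.

Coronal and axial sections are treated as separate samples (separate fits
per plane), mirroring how paired comparisons are presented in the source
literature.

## Problem sizes and numerical choices

The default test and analysis runs use: n = 5000 angles for direct κ
recovery (10% tolerance), 500-stroke fields for end-to-end recovery (25%
tolerance, reflecting the extra extraction noise), 200 simulations ×
1000 bootstrap replicates for CI coverage at κ = 2, n = 300, and 200
replicates of 50-point noisy trajectory refits. These sizes put Monte-Carlo
error comfortably inside the stated tolerances while keeping a full run in
the low minutes on one core.

Degenerate inputs are handled explicitly: flat images threshold to empty
masks (empty skeleton, empty segment set, empty histogram — not errors);
all-equal angle samples hit the κ cap and are flagged; windows on the FA
plateau and fractions outside (0, 1] are rejected; fits with fewer points
than free parameters raise an insufficient-data error rather than returning
garbage.

## Known limitations

- Translation inherits the assumption that fractional FA decay indexes the
  same developmental stage across species; it cannot be validated from
  within the package.
- Regional FA structure is deliberately averaged away (single whole-cortex
  clock per species); the regional terms of the underlying trajectory
  model are out of scope.
- The area-reduction stage ships synthetic per-subject values (group means
  were published, individual areas were not); only the group-level
  arithmetic is meaningful.
- The κ recovery tolerances are calibrated on the synthetic image model;
  real Golgi material will add segmentation error the generator does not
  represent.
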