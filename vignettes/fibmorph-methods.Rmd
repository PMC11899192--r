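---
title: "Ring-model morphometry of the fibular cortex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-model morphometry of the fibular cortex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibmorph)
```

## The measurement problem

In an axial T2-weighted MR cross-section, a healthy fibular shaft appears as
a hypointense ring of cortical bone around hyperintense marrow, embedded in
intermediate-intensity muscle. Given a manually traced binary bone mask (and
optionally a marrow mask), `fibmorph` quantifies four complementary aspects
of bone loss:

* **BA** (bone area, mm²): foreground pixel count × pixel area.
* **BT** (wall thickness, mm): `BA / CL`, where **CL** is the physical
  length of the one-pixel-wide medial-axis loop through the cortical wall.
  Dividing area by centerline length is the ring model: for an annulus with
  outer diameter $D_{out}$ and inner diameter $D_{in}$,
  $BA = \pi (D_{out}^2 - D_{in}^2)/4$ and the mid-wall circumference is
  $CL = \pi (D_{out} + D_{in})/2$, so $BA/CL = (D_{out} - D_{in})/2$ exactly.
* **g-ratio**: $D_{in}/D_{out}$, by analogy with the axonal myelination
  g-ratio; a larger g means a thinner wall relative to the enclosed marrow.
* **MPI** (mean pixel intensity): average normalized intensity over the bone
  mask; resorbed bone admits water and lipid, raising the T2w signal, so an
  elevated MPI indexes mineral-density loss.

Subject-level values average the central seven slices of a nine-slice
stack; BT is the mean of per-slice `BA/CL` ratios, and g is computed per
slice and then averaged (the difference against computing g from
subject-mean CL and BT is second order; the per-slice form parallels the BT
average and is frozen by a regression test).

## The g-ratio conventions

The loop length CL and the ring diameters live on different scales:
`CL ≈ π ×` (centerline diameter). Applying the form `(CL − BT)/(CL + BT)`
directly to the *loop length* gives ≈ 0.8 for a typical fibula
(CL ≈ 26 mm, BT ≈ 2.7 mm), which is not a diameter ratio. Under the
circular-ring approximation the centerline diameter is `CL/π`, and

$$ g = \frac{CL/\pi - BT}{CL/\pi + BT} = \frac{D_{in}}{D_{out}} $$

reproduces the published cohort-scale geometry: a 10.9 mm outer diameter
with a 2.7 mm wall gives `g = 5.5/10.9 ≈ 0.50`, inside the reported
0.49 ± 0.14 population interval. The package therefore defaults to this
**diameter convention**; the literal loop-length form remains available via
`g_convention = "literal"` for comparison. When the wall is thicker than the
ring model admits (`D_in ≤ 0`), g is reported negative and flagged — never
clamped.

## Centerline extraction

The centerline is extracted in three stages:

1. **Skeletonization** (`skeletonize_mask()`). Components smaller than 5
   pixels are removed (stray pixels in manual masks; far below any plausible
   bone area at 0.7 mm). When the mask has ring topology, the package first
   forms the *equidistance band*: pixels whose chamfer distance to the
   interior hole equals their distance to the exterior background within one
   step. This band is the discrete mid-wall locus — the centerline between
   the outer and inner boundaries — and is then thinned to unit width with
   Guo–Hall two-subiteration thinning. The band construction matters when
   the lumen is small: plain homotopic thinning can only delete pixels whose
   neighborhood is already sparse, so erosion cannot proceed outward from a
   one-pixel hole and the skeleton would drift toward the lumen instead of
   the mid-wall. A mask with no hole (a filled ring, below-resolution lumen)
   falls back to plain thinning with a topology warning.
2. **Spur pruning** (`extract_centerline_loop()`). The skeleton's pixels form
   a graph with 8-neighbor edges (diagonal shortcuts across an edge-connected
   corner are dropped so a thin digital curve is a proper path graph).
   Degree-1 pixels are removed iteratively; deformed, triangular rings
   generate spurs that would otherwise inflate CL and bias BT low.
3. **Loop selection**. The longest remaining simple cycle is the centerline
   loop (junction chains are contracted and the small junction multigraph is
   searched exhaustively; ties break deterministically in scan order). If
   pruning consumes everything, the wall is open — concave, thinned regions
   can break the ring — and the longest simple path is returned flagged
   `is_closed = FALSE` rather than failing, because exactly these bones are
   the clinically interesting ones.

CL is the sum of pixel steps along the loop: 1 per edge step, $\sqrt2$ per
diagonal step, times the pixel spacing, including the closing step.

### Known bias of the chain-length estimator

The (1, √2) chain-length rule overestimates the length of smooth curves by
roughly 4–6% regardless of resolution (the classical digitization bias of
the Freeman estimator; its worst case, +8%, is a straight segment at 22.5°).
On an r = 16 px digital circle the package measures +5.2%. BT inherits a
mirrored relative bias of about −5% as pixel spacing shrinks; at the native
0.7 mm resolution this floor sits well inside the half-pixel (0.35 mm)
accuracy band and partially cancels against discretization effects, but it
means BT and g errors do *not* converge to zero as the grid is refined —
only BA does. We keep the uncorrected step rule because it is the
transparent, standard definition; corrected estimators (e.g.
Vossepoel–Smeulders weights) would trade this transparency for ~1% residual
bias and break the exact unit-square step identity.

## MPI normalization

Raw scanner intensities are arbitrary up to gain and offset, so each slice
is normalized by a robust min–max rule before averaging over the bone mask:
subtract the 0.5th percentile, divide by the (99.9th − 0.5th) percentile
range, clip to [0, 1]. This makes MPI invariant under any global affine
intensity rescaling, which is the property the cross-subject comparisons
need. The near-extreme 99.9th upper reference (rather than the 99th) keeps
the brightest tissue — marrow, which may occupy only ~1% of a cropped
slice — anchored at 1; with a 99th-percentile reference the anchor slides
into the marrow intensity distribution and MPI acquires a spurious gain
that depends on marrow area.

## The phantom generator

`make_annulus_phantom()` renders a deformed annulus with full analytic
ground truth:

* The outer contour radius is
  $R(\theta) = \tfrac{D_{out}}{2}\,(1 + \sum_k a_k \cos(k\theta + \phi_k))$
  with harmonic orders ≥ 2 and amplitudes < 0.3 (the ring must stay simple);
  an order-3 harmonic emulates the triangular periosteal outline of real
  fibulae. The inner contour follows at constant radial wall thickness.
* The geometry is rendered at `supersample_factor` (default 8) linear
  oversampling and block-averaged to the target spacing: at 0.7 mm the
  dominant error source is partial volume, which a purely binary rendering
  would hide.
* Truth masks use majority occupancy (≥ 50% of subsamples inside the
  region), mirroring a careful manual tracer's rounding.
* Ground truth (`true_BA`, `true_CL`, `true_BT`, `true_g`, `true_BMA`) comes
  from dense polygonal integration of the continuous contours (3600
  vertices), never from pixels. `true_BT` is defined as `true_BA/true_CL`
  (the ring-model estimand), which equals the radial wall thickness exactly
  for an undeformed annulus.

One practical note: when a phantom's lumen is of sub-pixel scale (e.g. a
1.0 mm lumen at 0.7 mm spacing), whether it survives rasterization depends
on where the ring center falls relative to the pixel grid. The package's
phantom-validation fixtures therefore render on odd-sized grids, which place
the center on a pixel center — the canonical phantom placement.

`make_phantom_stack()` replicates one geometry over nine slices with ≤ 2%
multiplicative jitter. This tests the averaging behavior of the pipeline
without pretending to model the true proximal-to-distal shape change
(real fibulae grow more triangular distally); anatomy is out of scope.

## The cohort simulator

`make_cohort()` draws subjects from four sex × age-group cells
(split at 50 years, lower group inclusive). The packaged defaults
(`inst/extdata/cohort_defaults.yaml`) emulate the group statistics of a
published 107-subject adult 7T fibular cohort — group sizes 17F/13M under
50 and 26F/51M over 50, over-50 wall thickness 2.9 ± 0.6 mm (M) vs
2.0 ± 0.5 mm (F), and so on. They describe the *conditions being
simulated*; they are not targets the measurement pipeline is asked to
reproduce. Values not available from that literature were fixed once as
realistic choices and are documented here:

* age–BT slope −0.02 mm/yr in women, 0 in men; age–MPI slopes +0.0012/yr
  (F) and +0.0004/yr (M), applied about the group age midpoint with the
  residual SD shrunk so the realized group SD matches the specification
  (floored at 20% of it);
* MFI class probabilities (normal/mild/moderate) 0.50/0.35/0.15 under 50
  and 0.25/0.45/0.30 over 50; subcutaneous fat thickness 6 ± 2.5 mm;
* rendering intensities bone = sampled MPI, marrow 1.0, muscle 0.55,
  background 0, pixel noise SD 0.02.

Sampled values are truncated by rejection to their physical ranges
(BT, BA, MPI > 0; 0 < g < 1; image mode additionally requires the realized
ring, $D_{out} = 2\,BT/(1-g)$, to fit the rendering grid with margin and the
lumen to span at least two pixels — constraints that essentially never bind
at the default group parameters). Table mode derives the marrow area from
the sampled geometry, $BMA = \pi D_{in}^2/4$, since the group tables do not
parameterize it separately. Generation is bit-reproducible for a fixed seed.

What the simulator does **not** emulate: real segmentation error (masks are
exact up to rasterization), anatomical muscle-compartment geometry, MR
physics (T2 weighting, coil profiles), and between-slice anatomy. Passing
recovery tests therefore demonstrate that the *measurement chain* is
accurate and that the *statistical battery* detects effects of the
simulated size at the simulated n — not that the pipeline is robust to
tracing styles or acquisition artifacts.

## The statistical battery

Faithful to the source analyses: pooled-variance Student t-tests (Welch
available via `welch = TRUE`), Pearson correlations with the two-sided
t-transform p-value on n − 2 df, α = 0.05, and **no multiple-testing
correction** by default — the analyses this package mirrors report raw
per-test p-values (a Holm option exists on the MFI contrasts for
sensitivity checks). Degenerate inputs error explicitly (constant
correlation input, zero-variance samples with unequal means) rather than
propagating NaN; two identical constant samples give p = 1 by convention.

The reproducibility statistic is the coefficient of variation sd/mean of
repeated segmentations. `noise_perturbation_analysis()` propagates that
measured CV into the cohort stage: each of 10 executions multiplies the
target variable by $(1+\varepsilon)$, $\varepsilon \sim N(0, f)$, and the
per-execution correlation p-values are compared with the noise-free
baseline. The noise budget defaults to the measured CVs (1.3% for BT, 1.5%
for BA) plus a 2% leeway applied as an additive increment to the CV — the
source wording ("a 1–3% leeway") leaves the exact application open, so the
package fixes the midpoint additively and exposes it as configuration.

## Numerical and edge-case choices

* Coordinates: row = y, column = x, pixel centers on the integer grid,
  0-based in reported pixel paths; all lengths in mm. One stated convention
  avoids the classic off-by-one-pixel area drift.
* Anisotropic in-plane spacing is accepted by I/O but rejected by
  morphometry with a clear error: the step-length rule assumes isotropy.
* Even-slice-count centering (e.g. 8 slices, 7 central) breaks the tie
  toward the proximal (lower-index) side; the nine-slice protocol never
  hits this case, so the choice is documented and unit-tested.
* Slices whose mask fails (empty, fragmented, degenerate centerline) are
  dropped with a warning; a subject errors out only when fewer than the
  required seven usable slices remain.
* Missing spacing metadata is an error, never a silent default.

## Problem sizes used by the validation suite

The packaged tests and the acceptance script validate on: a 3 × 3 grid of
undeformed annulus phantoms (outer diameter 8–14 mm, wall 1.5–3.5 mm) at
0.7/0.35/0.175 mm spacing; full-size image-mode cohorts of the over-50
groups (77 subjects × 9 slices) for end-to-end recovery; 100-seed
table-mode sweeps for power and 200-seed sweeps for null calibration; and
10⁵-draw permutation oracles for the statistical primitives on n ≤ 12
fixtures.

## Known limitations

* BT carries the ~−5% chain-length bias floor described above; comparisons
  *across* subjects measured at the same resolution are unaffected.
* The open-ring fallback reports a length over the longest simple path,
  which underestimates CL for a nearly closed ring; such slices are flagged
  and counted per subject.
* MPI is only meaningful relative to the within-slice intensity range; it
  is not an absolute density measure and is not comparable across protocols
  with different tissue contrast.
* The simulator's linear age effects and Gaussian group distributions are a
  deliberate simplification; they match the first two moments of the
  emulated cohort but not its tails.
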