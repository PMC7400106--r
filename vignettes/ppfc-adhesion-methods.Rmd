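---
title: "Models and methods behind ppfcAdhesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ppfcAdhesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppfcAdhesion)
```

This vignette explains the models implemented in the package, the choices
made where the underlying methodology leaves room, and what the synthetic
test bed does and does not establish about real microscopy data.

## The experimental setting

A parallel-plate flow cell (PPFC) is a rectangular duct — here 1.6 cm wide,
0.8 cm high and 25.42 cm long — mounted on a microscope. A bacterial
suspension flows through at a controlled rate while frames of the lower
surface are taken every 60 s for 30 min; counting adhered cells per frame
yields a surface density (cells/cm²) versus time. Across flow rates of
1–10 mL/s the CFD-derived wall shear rates of this channel span
7.5–100.8 s⁻¹, a range typical of biomedical flows. These operating points,
together with the fluid and cell constants of an *E. coli* suspension in
citrate buffer, are bundled as `flowCellPreset()`.

Two reported geometry values conflict: the channel cross-section is printed
as 0.8 × 1.6 cm while the transport section quotes a height of 0.08 m. We
treat the latter as a typo and use h₀ = 0.008 m throughout; with the
mid-channel observation position this reproduces the 80–170 cells/(cm²·s)
deposition range, whereas h₀ = 0.08 m does not. The axial observation
position *x* is not reported; we default to mid-channel,
*x* = 0.1271 m, and expose it in `ChannelGeometry`.

## Transport and force model

The Smoluchowski–Levich (SL) approximation solves the convective–diffusion
equation for a perfect sink — every cell reaching the wall adheres — giving
the deposition flux

SL = 0.538 (D∞ C_b / R_b) (Pe h₀ / x)^{1/3},

with the parallel-plate Péclet number Pe = 3 v_av R_b³ / (2 (h₀/2)² D∞).
Internally everything is SI; only the flux is reported in cells/(cm²·s),
the unit deposition work is quoted in. Because SL ∝ Pe^{1/3} ∝ Q^{1/3},
doubling the flow rate raises transport by only 26%.

An adhered cell experiences the wall drag D = 32 τ_w R_b², the leading-order
Stokes result for a sphere on a wall in a linear shear flow; the neglected
terms are O(Re_c) with Re_c = ρ γ R_b² / µ ≤ 3 × 10⁻⁵ across the bundled
conditions, so the truncation is safe. Gravity and hydrodynamic lift are
not modelled.

The equivalent rod radius R_b = (L/2)/(ln(L/b) − 0.11) is offered as
`microbialRadius()`, but the printed radius 4.5 × 10⁻⁷ m is not obviously
the output of that formula for plausible cell dimensions (the source prints
neither L nor b, and the formula's typography is ambiguous). We therefore
treat R_b as a direct configuration parameter defaulting to 4.5 × 10⁻⁷ m
and never invoke the formula implicitly.

Wall shear values in the preset are the CFD-derived ones; the analytic
wide-slot formula γ = 6Q/(w h₀²) (`analyticShearRate()`) is available as a
fallback but differs from CFD by roughly 20–30% at the low end and is never
silently substituted. When a shear rate is supplied without a stress the
Newtonian closure τ_w = µγ is applied and recorded via `shearSource`.

## The adhesion simulator

`simulateAdhesion()` is a random-sequential-adsorption process in
continuous time:

- **Arrivals** are homogeneous Poisson at rate (arrival rate × field area);
  the natural arrival rate is the SL flux of the condition being emulated
  (`scenarioFromTransport()`).
- **Hard-core exclusion**: a placement within 2 × `hardCoreRadius`
  (default 0.5 µm, about one cell diameter) of an adhered cell is rejected
  and lost — the convective sweep carries rejected cells away, so nothing
  is re-queued.
- **Shadowing** (optional): each adhered cell casts a rectangular blocked
  strip downstream (+x), default 14.14 × 0.9 µm. Colloid deposition studies
  report blocked areas of 8–675 particle cross-sections; the default is
  20 cross-sections of a 0.45 µm cell, the simplest shape with a
  controllable area (`shadowAreaMultiple()`).
- **Detachment** (optional) is memoryless at rate k_det. Real adhesion
  strengthens with residence time; a history-dependent rate is out of
  scope, and the exponential model is the simplest mechanism that
  reproduces a two-phase count curve. The drag coupling
  k_det = k₀ D/F_ref has no measured constants; k₀ = 1/600 s⁻¹ at the drag
  of the lowest flow rate is an arbitrary, documented default.

One root seed drives everything; `simulateFields()` derives per-field seeds
as seed + k − 1. Identical seeds give bit-identical event logs, which the
suite asserts.

`renderFrame()` draws each cell as a dark Gaussian blob (default
σ = 0.7 µm, roughly a 0.45 µm cell radius convolved with a ~0.25 µm
optical PSF) of amplitude 60 on a background of 200, adds seeded Gaussian
noise, and quantises to 8 bits at 0.61 µm/px — the scale at which 50 px
correspond to 30.5 µm.

What the generator does *not* emulate: cell shape and orientation, uneven
illumination, focus drift, cells rolling before arrest, and
residence-time-dependent adhesion strength. Tests passing on this bed
validate the algorithms (detection recall, estimator bias, calibration of
the permutation test) under known ground truth; they do not certify
performance on real brightfield frames, where detection parameters may
need retuning.

## Cell detection

Frames are inverted (cells are dark in brightfield), optionally smoothed,
and local maxima with topological prominence ≥ `noiseTolerance` are
reported — the persistence formulation of ImageJ's "find maxima with noise
tolerance". A union–find sweep over pixels in decreasing intensity order
merges components; a peak that merges into a higher one at level v has
prominence (peak − v). Constant plateaus report their centroid pixel.
Maxima closer than `minSeparation` (default 3 px ≈ two cell radii) are
suppressed keeping the brighter, ties resolving to the smaller row-major
index. Coordinates are 0-based, x = column, y = row, origin top-left.

Defaults: `noiseTolerance = 10` intensity units (parameter-light, matching
common ImageJ practice) and a Gaussian pre-smoothing of σ = 1.5 px. The
smoothing acts as a matched filter: raw 8-bit noise of sd ≈ 12 would
otherwise generate spurious maxima with prominence above 10, while
smoothing suppresses the noise floor by roughly five-fold at a modest cost
in peak height. The same smoothing precedes Otsu thresholding in
`areaFraction()`, since an Otsu split of a mostly-background noisy frame
otherwise bisects the noise rather than separating cells. All parameters
sit in `DetectionParams`.

Detection quality on the synthetic bed (asserted in the suite): on
100-cell fields rendered at signal-to-noise 5, recall within 2 px is
≥ 95% with ≤ 5 false positives, and the mean count error over 20 seeds is
below 3%.

## Two-phase kinetics

`fitTwoPhase()` fits two independent ordinary-least-squares lines with the
breakpoint chosen over the observation times inside a search window
(default 5–9 min, where flow-cell adhesion rates are typically seen to
drop) to minimise the total SSE. Segments are deliberately *not*
constrained to meet: practice fits two separate regressions, and the
percent reduction (1 − s₂/s₁) × 100 compares their slopes. Points with
t ≤ t_b form the first segment. SSE ties — exact for noiseless continuous
kinks, which fit perfectly from either side of the kink observation —
resolve to the latest candidate, so the kink observation belongs to the
first segment and a noiseless breakpoint is recovered exactly. Slopes are
reported in cells/(cm²·min); with all-equal densities both slopes are 0
and the reduction is undefined (an error, since s₁ = 0).

`compareRates()` implements the one-way ANOVA F statistic and Tukey HSD
pairwise comparisons from group means and the pooled within-group variance;
the studentized-range tail probability comes from R's `ptukey`, so no
quantile approximation is needed. The suite cross-checks both against
`aov()`/`TukeyHSD()` and verifies the nominal 5% type-I error over 10⁴
null replications.

## Pair-correlation blocking analysis

For every reference cell — those at least `borderMargin` (default R_max)
from each edge, so the disc of radius R_max = 50 px lies wholly inside the
field and no pairwise edge correction is needed — displacements to all
neighbours within (0, R_max] are accumulated on 1-px bins of a
(2R_max + 1)² grid; the self-pair is excluded, fields are pooled before
normalisation, and bins within the disc sum to 1. Bin membership is decided
at bin resolution (rounded displacement), which keeps bins outside the disc
exactly zero. The bin size is not prescribed by the methodology we follow;
1 px² matches the pixel-resolved workflow, and with this normalisation a
uniform pattern sits at 1/(π R_max²) = 1.27 × 10⁻⁴ per bin — the scale on
which the 4.0 × 10⁻⁴ non-blocking ceiling is stated. "Excluding the
central cell" is implemented as excluding the self-pair only.

In **unordered** mode a displacement is directionless: each
reference-to-neighbour displacement enters together with its mirror −d.
This makes the map exactly centro-symmetric by construction *and* keeps the
per-bin expectation flat on uniform fields. (Accumulating mirrors only for
neighbours outside the reference margin was tried and rejected: it
double-weights border-band pairs and tilts the radial profile by up to
~10%.) An unordered end-of-assay snapshot therefore cannot reveal a
one-sided shadow — mirror symmetry is structural. The **time-ordered** mode
accumulates only neighbours that attached after the reference and is the
sensitive test for downstream blocking; it requires attachment times,
which snapshots of real assays may not provide.

The flow-axis depletion index compares the pair mass in a cone of
half-angle θ (default 30°) and radius r_s about the flow axis (both cones
in unordered mode) with the rotationally-uniform expectation. The sharp
choice for r_s is the shadow length in pixels when a blocking model is
being tested; the default falls back to R_max. `anisotropyTest()` builds a
null by rotating every unique pair by an independent uniform angle
(mirrored duplicates rotate together, preserving the symmetric structure)
and reports p = (1 + #{null ≤ observed}) / (1 + n_perm); fewer than 50
supporting pairs flags a caveat. The suite verifies calibration (p > 0.05
in ≥ 90% of 20 no-shadow runs) and power (p < 0.01 on ten pooled fields
with the default shadow).

Ripley-K/L statistics and kernel-smoothed isotropic g(r) estimators are
deliberately out of scope; the histogram estimator plus the depletion test
is the analysis under study.

## Problem sizes and numerical conventions

- Non-blocking reference maps pool twelve 1000 × 1000 px hard-core fields
  at 10⁶ cells/cm² (3721 cells per field at 0.61 µm/px), giving over two
  million symmetrised pairs — enough that the sampling excursion of the
  maximum bin stays well below the 4.0 × 10⁻⁴ ceiling.
- Simulated kinetics runs use the 610 × 610 µm field, 30 min, 60 s frames;
  calibration and power checks use 10–20 seeded replicates.
- The brute-force O(n²) pair accumulator in the test helpers reproduces the
  grid-indexed C++ implementation bit-exactly on fields of up to 200
  points, in both modes.
- CSV output is fixed to 6 significant digits so reruns with equal seeds
  are byte-identical; all RNG flows from explicit seeds and the caller's
  RNG state is restored.
- Degenerate inputs error early and name the offending field or index
  (non-positive flow rates, unordered timestamps, windows without feasible
  breakpoints, maps without reference cells, zero mass at r ≤ r_s).

## Known limitations

- The simulator's arrivals are point events: near-wall Brownian dynamics of
  approaching cells is already summarised by the SL flux, so spatial
  correlations *between* arrivals (beyond exclusion and shadowing) are not
  produced.
- The detachment coupling constants k₀ and F_ref are order-of-magnitude
  placeholders; fitted detachment rates from real series should replace
  them when available.
- The SL approximation assumes a perfect sink; surfaces with an energy
  barrier deposit more slowly, so SL is an upper bound on transport-limited
  adhesion.
- Detection does not split touching cells beyond maxima separation and does
  not track identity across frames; counts, not trajectories, are the
  observable.
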