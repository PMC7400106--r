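# ppfcAdhesion

Analysis of the initial adhesion of bacteria to a surface observed in a
parallel-plate flow cell (PPFC). In a typical assay a cell suspension is
pumped through a rectangular channel mounted on a microscope, frames are
acquired every minute for 30 minutes, and the number of adhered cells per
unit area is followed over time. Two questions dominate the interpretation
of such experiments, and this package addresses both:

1. **Why do adhesion rates drop after a few minutes?** The count series
   typically shows an initial linear accumulation followed by a lower slope.
   The classical explanation is *hydrodynamic blocking* — the near-wall flow
   around an adhered cell screens a downstream "shadow" where further
   adhesion is prohibited. The alternative is shear-driven *detachment*.
2. **Is the observed rate consistent with transport?** The
   Smoluchowski–Levich (SL) approximation gives the perfect-sink deposition
   flux, and the wall drag force sets the load an adhered cell must
   withstand.

## What the package computes

**Transport and forces** (SI in, reporting units out), for a channel of
width *w*, height *h₀*, observation position *x*, cell radius
*R_b*, diffusivity *D∞*, bulk concentration *C_b*:

- SL deposition flux `SL = 0.538 (D∞ C_b / R_b) (Pe h₀ / x)^(1/3)`
  in cells/(cm²·s)
- Péclet number `Pe = 3 v_av R_b³ / (2 (h₀/2)² D∞)`
- wall drag on an adhered cell `D = 32 τ_w R_b²` (valid because the local
  Reynolds number `Re_c = ρ γ R_b² / µ` is ≪ 1)
- equivalent rod radius `R_b = (L/2)/(ln(L/b) − 0.11)`

**Synthetic experiments**: a seeded random-sequential-adsorption simulator —
Poisson arrivals at the SL flux, hard-core exclusion, optional rectangular
downstream shadow per adhered cell, optional first-order detachment — plus a
brightfield-like frame renderer with ground truth.

**Image analysis**: cell detection by image inversion and prominence-based
local-maxima finding (topological persistence, the ImageJ "noise tolerance"
idea), and Otsu-thresholded covered-area fractions.

**Kinetics**: two-phase linear regression with an SSE-minimising breakpoint
search over a 5–9 min window, percent rate reduction `(1 − s₂/s₁) × 100`,
and one-way ANOVA + Tukey HSD comparison of slopes across conditions.

**Blocking analysis**: a 2D pair-correlation probability-density map —
displacements from each reference cell to all neighbours within
*R_max* = 50 px, 1-px bins, bins summing to 1 over the disc — with a
flow-axis depletion index and a rotation permutation test. A downstream
shadow shows up as a depleted cone along the flow axis in time-ordered
maps; an index near 1 with p > 0.05 means no blocking signature.

## Worked example

```r
library(ppfcAdhesion)

preset <- flowCellPreset()   # six flow rates, E. coli / PDMS constants
tt <- transportTable(presetFlowConditions(preset), preset@fluid,
                     preset@cell, preset@geometry)
print(data.frame(lapply(tt, signif, 4)))
#>   Q_mL_per_s v_av_m_s shear_rate_per_s tau_w_Pa        Pe SL_cells_cm2_s
#> 1          1 0.007812              7.5 0.005205 0.0001669          79.59
#> 2          2 0.015620             15.0 0.010410 0.0003337         100.30
#> 3          4 0.031250             33.7 0.023390 0.0006674         126.30
#> 4          6 0.046880             51.6 0.035810 0.0010010         144.60
#> 5          8 0.062500             80.3 0.055730 0.0013350         159.20
#> 6         10 0.078120            100.8 0.069960 0.0016690         171.50
#>      drag_N      Re_c
#> 1 3.373e-14 2.174e-06
#> 2 6.746e-14 4.348e-06
#> 3 1.516e-13 9.768e-06
#> 4 2.321e-13 1.496e-05
#> 5 3.611e-13 2.328e-05
#> 6 4.533e-13 2.922e-05
```

The SL flux spans 80–170 cells/(cm²·s) from 1 to 10 mL/s and the drag force
3.4–45 × 10⁻¹⁴ N; transport and detachment load both grow with the flow
rate. Simulate the 1 mL/s condition with drag-coupled detachment, fit the
two-phase kinetics, and test ten pooled fields for a blocking signature:

```r
cfg <- scenarioFromTransport(tt[1, ], seed = 42)
field <- simulateAdhesion(cfg)
field
#> SimulatedField: 610 x 610 um, 30 frames, 482 attach events (2 rejected),
#>   156 adhered at end

fitTwoPhase(countSeries(field))
#> TwoPhaseFit: t_b = 9 min, s1 = 2840, s2 = 765.7 cells/(cm^2.min),
#>   reduction = 73.0%

flds <- simulateFields(cfg, 6)
pts <- do.call(rbind, lapply(seq_along(flds), function(k) {
    pos <- framePositions(flds[[k]], 30)
    data.frame(field = k, x_px = pos$x_um / 0.61, y_px = pos$y_um / 0.61,
               t = pos$attach_s)
}))
anisotropyTest(pts, 1000, 1000, rMax = 50, mode = "time_ordered", rS = 23,
               seed = 1)
#> AnisotropyResult: index = 1.111 (theta = 30 deg, r_s = 23 px, time_ordered mode)
#>   permutation p = 0.735 (199 permutations)
```

The detachment model reproduces the two-phase kinetics (73% rate reduction
here), while the pair pattern stays isotropic (index ≈ 1, p = 0.74): the
slope decrease arises without any hydrodynamic blocking, exactly the
distinction the analysis is designed to draw. `runPipeline()` chains the
same stages (simulate/detect → kinetics → blocking → transport) over a YAML
config and writes byte-stable CSV/JSON outputs.

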