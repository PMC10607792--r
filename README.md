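# lvflow

Image-based modelling of blood flow in the left ventricle (LV), in R.

Cine cardiac magnetic-resonance (cMR) images record how the heart wall
moves, but not how the blood inside moves. `lvflow` closes that gap for the
LV: it delineates the lumen–wall interface on cine image stacks, rebuilds a
moving lumen geometry from the traces, simulates the incompressible blood
flow that this imaged wall motion drives, and quantifies the flow's
energetics over the cardiac cycle. It is aimed at cardiovascular
biomechanics researchers who want a self-contained, scriptable pipeline
from DICOM stacks to hemodynamic time series, with verification phantoms
built in.

The pipeline:

1. **Segmentation** — anisotropic diffusion pre-filtering, fuzzy c-means
   intensity clustering (minimizing `J = Σᵢⱼ uᵢⱼᵐ ‖qᵢ − cⱼ‖²` with
   reciprocal-distance memberships, default `C = 10`, `m = 2`),
   lumen-region selection near a ventricle-centre hint, sub-pixel boundary
   tracing with circularity filtering, and active-contour (snake)
   refinement.
2. **Geometry** — DICOM-metadata mapping of traces into patient space,
   base-to-apex ring stacking, corresponding end-diastole/end-systole shell
   surfaces with identical connectivity, linear-in-time motion, and
   quad-dominant (2D) or structured tetrahedral (3D) lumen meshes.
3. **Flow** — incompressible Newtonian Navier–Stokes
   (`μ = 4 cP`, `ρ = 1060 kg/m³`) in an arbitrary Lagrangian–Eulerian
   formulation: imposed kinematic wall velocity, zero-traction inlet–outlet
   (IO) boundary at the truncated base, harmonic interior mesh motion,
   stabilized equal-order finite elements, implicit time stepping.
4. **Energetics** — kinetic-energy density `KE = ½ρ‖v‖²` and its spatial
   average, vorticity `Ω = ∇×v` with magnitude/signed averages, hemodynamic
   force `F = ∮ σ·n dS` (σ = −pI + μ(∇v + ∇vᵀ)) and its base–apex HDF
   component, IO flow rate `Q = ∮ v·n dA`, stroke volume `V_ED − V_ES`
   (cross-checked against `∫Q dt`), and IO kinetic-energy power
   `P = ∮ KE (v·n) dA`.

Because clinical images cannot ship with the package, a phantom module
generates every input with known ground truth: cine-like DICOM stacks of a
contracting, apex-tapered lumen at a chosen SNR (with per-frame truth
masks), and analytic moving-domain benchmarks (piston box, contracting
cylinder, half-ellipsoid LV) with closed-form volumes and flow rates.

## Worked example

Simulate one cycle of the half-ellipsoid LV phantom (semi-axis
`a: 80 → 64 mm`, `b = 25 mm`, 40% systole — analytic stroke volume
`(2/3)π(a_ED − a_ES)b² = 20.94 mL`) and summarize its hemodynamics:

```r
library(lvflow)

bench <- make_benchmark_case(phantom_spec("half_ellipsoid_lv"))
bench$motion$geom
#> <lv_motion3d> 16 rings x 48 points + apex; V_ED = 104.0 mL, V_ES = 83.2 mL

cyc <- solve_cycle(bench$motion, n_steps = 40, n_cycles = 1)
cyc
#> <lv_cycle> 1 cycle(s) x 40 steps, dt = 0.025 s
#>   peak |Q| = 5.158e-05 m^3/s, max mass-balance error = 4.81e-14 of peak

series <- hemo_series(cyc)
series
#> <lv_hemo_series> 41 samples; measure mL, Q mL/s
#>   SV = 20.63 (flux est. 20.63, discrepancy 0.00%)
#>   peak |Q| = 51.58 mL/s, peak KEavg = 0.5 J/m^3, peak |P| = 0.02756 mW
```

Reading the numbers: the simulated stroke volume (20.63 mL, from the mesh
volumes at ED and ES) recovers the analytic 20.94 mL to 1.5% — the deficit
is the inscribed-polygon volume of the coarse flow mesh — and agrees with
the systolic flux integral to machine precision; the IO flux balances the
volume rate to 5e-14 of the peak flow rate, because the discretization
conserves mass exactly. `plot(series)` draws the volume, flow-rate, KE,
vorticity, HDF and power panels over normalized cycle time with end systole
marked.

The full imaging path runs the same way from a config:

```r
res <- run_pipeline(pipeline_config(
  phantom = list(kind = "image_stack", seed = 1),
  output = list(dir = "lv_run")))
res$summary$mean_dice     # segmentation vs ground-truth masks
```

or from a shell via the thin CLI
(`Rscript inst/cli/lvflow.R run --config cfg.yaml`), with subcommands
`phantom | segment | reconstruct | simulate | energetics` that stop at the
corresponding stage and reuse cached results.

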