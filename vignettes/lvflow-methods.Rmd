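---
title: "Image-based left-ventricular flow modelling with lvflow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based left-ventricular flow modelling with lvflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lvflow` builds a moving geometric model of the left-ventricular (LV) lumen
from cine cardiac-MR images and simulates the blood flow that this imaged
wall motion drives, quantifying the flow's energetics over the cardiac
cycle. This vignette explains the models and algorithms, the parameters
that matter, the numerical choices, and what the synthetic phantoms do and
do not establish about real data.

## The modelling idea

Cine cMR provides the *kinematics* of the heart wall: typically 20 frames
per cardiac cycle for each short-axis and long-axis section. If the
lumen-wall interface is delineated in these images, its motion can be
imposed as a boundary condition on an incompressible-flow simulation of the
blood inside, turning anatomy + wall motion into velocity and pressure
fields without measuring flow directly. Quantities derived from those
fields — kinetic-energy (KE) density and its spatial average, vorticity
averages, hemodynamic force (HDF), IO flow rate, stroke volume, and the
kinetic-energy power through the open base — summarize how effectively the
ventricle transfers energy to the blood.

The domain is truncated below the valve plane: mitral and aortic orifices
are not modelled. A single flat inlet-outlet ("IO") boundary replaces them,
carrying a zero-traction (natural) condition so blood enters and leaves
freely as the lumen volume changes; pressures are therefore gauged to the
IO. In the model frame the IO plane is `y = 0` (2D) or `z = 0` (3D) with
the apex toward negative values; "vertical" (for the HDF) means the
base-apex axis, positive toward the base. The HDF is reported with the
traction-integral sign convention (`F = ∮ σ·n dS`, `n` outward from the
fluid); for a still fluid at pressure `p0` in an open-top box of IO width
`W` this gives `+p0·W` along `+y`.

Shared physiological defaults: heart rate 60 bpm, systole 40% of the
cycle, Newtonian blood with `mu = 4 cP` and `rho = 1060 kg/m^3`.

## Segmentation (short-axis views)

Per frame, the chain is:

1. **Perona-Malik anisotropic diffusion** (10 iterations, exponential
   conductance with `kappa` = 10% of the intensity range, step 0.2). The
   4-neighbour explicit update is a convex combination of neighbours, so
   extrema are never amplified; edges above `kappa` are preserved.
2. **Fuzzy c-means (FCM)** intensity clustering, minimizing
   `J = sum_ij u_ij^m |q_i - c_j|^2` with the reciprocal-distance
   membership update and weighted-centroid centre update. Defaults `C = 10`
   clusters and fuzzy exponent `m = 2` (the field-standard choice in the
   open interval `m > 1`). Centres are initialized at uniform intervals of
   the intensity range and kept sorted, so the fit is deterministic — there
   is no RNG anywhere in the segmentation path. The update is computed over
   the intensity histogram (distinct values weighted by counts), which is
   algebraically identical to the per-pixel update (tested to 1e-9) and much
   faster on quantized images. `J` is non-increasing at every iteration.
3. **Lumen-region selection.** With `C = 10` and realistic noise the lumen
   intensity mode spreads over several adjacent clusters. Cluster centres
   are therefore merged into modes wherever the gap between sorted centres
   is below 10% of the centre range; the mode owning the majority label in
   a small window around the user's ventricle-centre hint is taken as the
   lumen mode, its combined membership is thresholded at 0.5, and among the
   connected regions with hint-distance in the closest decile the largest
   region wins. Minimal morphological closing plus hole filling (the lumen
   is simply connected) cleans speckle. If no region lies within the search
   radius (default a quarter of the image size) a "lumen not found" error
   is raised — the analogue of the occasional manual-retrace fallback.
4. **Sub-pixel tracing** of the region boundary (marching-squares isoline
   at 0.5) with a light moving-average along the contour, oriented
   counter-clockwise. Traces with circularity `4*pi*A/P^2` below 0.5, or
   with centroids outside the central third of the image, are rejected with
   an explicit reason. (An "optimal cluster count" criterion —
   minimal inter-cluster distance with circular symmetry — is not uniquely
   specified anywhere we know of; `fcm_cluster_diagnostic()` reports the
   ingredients instead of silently optimizing `C`.)
5. **Snake refinement**: a Kass-style active contour (implicit Euler on
   tension `alpha = 0.1` and stiffness `beta = 0.1`, explicit image force
   from the gradient-magnitude-squared edge map of the diffused image,
   step `gamma = 1`). The point count adapts to the contour length
   (about 1.5 px spacing) so the internal-energy finite differences remain
   well scaled on small apical contours. If the contour collapses or
   self-intersects, the input trace is kept with a warning. The final
   lumen mask is the filled refined trace — the delineation itself, as in
   the imaging workflow. Whether the snake sees the diffused or the raw
   image is a genuinely open choice; the diffused image is the default
   because the phantom's noise floor otherwise dominates the edge map.
6. **Spatial smoothing** of corresponding trace points along the contour
   and across adjacent slices (`smooth_traces()`, and the equivalent pass
   inside `reconstruct_3d_contours()`), applied to in-plane coordinates
   only — slice positions are scanner metadata and are not smoothed.

Long-axis outlines, which the imaging workflow traces manually, enter as
plain CSV polylines (`read_traces_csv()`), not via a GUI.

## Geometry reconstruction

**DICOM geometry.** Pixel indices are 0-based `(row, col)` with row = image
Y; `pixel_to_patient()` applies the DICOM affine
(`ImagePositionPatient + col*spacing_col*row_dir + row*spacing_row*col_dir`)
and is exactly invertible on each plane. Frames are grouped into stacks by
orientation; slices are ordered along the stack normal; phases sort by
TriggerTime, falling back to InstanceNumber. A stack whose normal is more
than 45 degrees from the dominant (short-axis) stack's normal is classified
long-axis — the views must be distinguished somehow, and the normal angle
is the only robust metadata-level criterion.

**2D model.** The traced outlines of one long-axis plane at (typically) 8
keyframes are clipped to the half-plane below the IO line, resampled to a
common point count by arclength from the left IO endpoint, and interpolated
piecewise-linearly in time between keyframes (`build_motion_2d()`).

**3D model.** Short-axis traces at end diastole (ED) and end systole (ES)
are mapped to patient space, rotated into the model frame, ordered base to
apex (the base is the larger-area end; for untapered stacks the choice is
arbitrary and fixed deterministically), and resampled to a common angular
count with index 0 where each ring crosses the +x ray from its centroid —
a deterministic angular datum that makes ring nodes correspond across
slices and phases. ED and ES must share one patient-to-model frame: the
frame computed at ED is reused at ES. Corresponding shell surfaces are
built by an identical construction order at both phases (structured
ring-by-angle grid split into triangles; apex closed by a fan grouped into
four quadrant patches converging to the apex point), which guarantees equal
node/element counts with index-wise correspondence. The apex point is
placed half an inter-slice spacing below the apical ring centroid — the
images cannot constrain the apex cap more precisely than the slice spacing,
so this midpoint is the least-committal choice. Motion interpolates
linearly between ED and ES with the contraction weight `s(T)` (0 at ED, 1
at ES at `T = 0.4`, back to 0 at `T = 1`); the 2D model uses all its
keyframes, and both laws sit behind the same interface so denser temporal
sampling drops in unchanged.

**Volume meshes.** 2D: transfinite blending between the IO chord and the
wall polyline gives a quadrilateral-dominant mesh whose wall nodes coincide
with the trace points (the collapsed end columns become triangles). 3D: a
structured, axis-centred tetrahedral mesh is built directly from the rings
(radial layers per ring level, prisms between levels split consistently
into tetrahedra by the minimal-global-index rule, apex fan); conformity and
orientation are asserted in the tests. The surface geometry keeps its full
angular resolution while the flow mesh may subsample the angle (default
every 2nd point) — surface volume is cheap, flow dofs are not. Areas come
from the shoelace formula; volumes from signed tetrahedra / the divergence
theorem with the IO capped by its flat spanning fan.

## Flow solver

Incompressible Newtonian Navier-Stokes in ALE form: nodal values ride on
the moving mesh, convection uses `v - w` (`w` = mesh velocity), and the
interior mesh motion is the harmonic extension of the wall displacement
computed once per step on the end-diastolic reference mesh (IO nodes slide
in the IO plane). The wall carries the kinematic no-slip velocity from the
motion law — the imposed-displacement wall of the imaging workflow is
mathematically equivalent to this direct kinematic boundary condition for
prescribed motion. The IO boundary carries the classical "do-nothing"
natural condition `mu dv/dn - p n = 0`, which also sets the pressure gauge.

Discretization: equal-order continuous linear velocity/pressure (P1 on
triangles/tetrahedra, Q1 on quadrilaterals) with PSPG-type pressure
stabilization (`tau = 1/sqrt((2/dt)^2 + (2|a|/h)^2 + (12 nu/h^2)^2)`,
elementwise). The stabilization vanishes on constant test functions, so
global mass conservation is exact at the linear-solve tolerance — this is
why the flow rate matches the volume change to machine precision on the
phantoms. Velocity converges at second order in L2 (measured 1.98-1.99 on
Poiseuille flow), satisfying the >= 1.8 contract for this element family.

Time stepping is implicit first order (backward Euler), 200 steps/cycle by
default, with two schemes:

* **coupled** — Picard iteration on the convective velocity, one sparse LU
  per iteration; robust, used for steady solves and (by the "auto" default)
  for 2D runs, where systems are small and the collapsed corner cells carry
  large local CFL.
* **semi_implicit** — convection evaluated at the old time level; the
  velocity block becomes one SPD scalar operator shared by all components,
  solved by Cholesky, and the pressure comes from a preconditioned CG on
  the Schur complement (preconditioner `dt/rho * K_p + S`). This is an
  order-of-magnitude faster in 3D and is the "auto" default there; it
  requires convective CFL of order one, which the structured 3D phantom
  meshes satisfy.

Backflow through the zero-traction IO during filling can destabilize both
schemes — the contracting-cylinder phantom, whose whole flat IO face
carries uniform inflow, demonstrates it. A standard backflow-stabilization
term (`rho/2 (v·n)_- v` on the IO) is available behind
`solver_options(backflow = TRUE)` and is OFF by default to match the plain
zero-traction condition. The convective CFL is reported, not enforced.
Simulations start from rest at ED and run 2 cycles by default: the rest
start is artificial, its transient decays on the viscous time scale
(`rho L^2 / mu` ~ 100 s >> one beat), and in practice one washout cycle
brings consecutive-cycle KE peaks within a few percent (the cycle-end L2
periodicity diagnostic is reported with every run).

Units: geometry in mm, solver internals in SI; `hemo_series()` reports
mm^2 and mm^2/s in 2D, mL and mL/s in 3D, KE in J/m^3, vorticity in 1/s,
force in N (2D: N per metre depth), power in mW.

## Energetics

All operators act on the discrete fields with quadrature exact for the
interpolation: KE averages via the consistent mass matrix; vorticity from
the elementwise consistent gradient (exact for affine fields, hence the
rigid-rotation identity `Omega_z = 2 omega` holds to machine precision);
IO flux by exact edge/face integration; IO power with degree-3 rules for
the cubic integrand; the hemodynamic force as the wall traction integral
with the full stress `sigma = -p I + mu (grad v + grad v^T)`, cross-checked
against the reaction-residual route (the discrete momentum residual summed
over wall nodes) to 1% on the piston benchmark. The vorticity-magnitude
average integrates `|Omega_z|`: the magnitude bars are occasionally dropped
in print but the quantity is meaningless without them for symmetric flows,
whose signed average `Omega_bar` is identically zero. In 3D the pair is
reported per long-axis cut plane (`plane_vorticity_averages()`, mirroring
the 2D definition) alongside the volume-averaged vorticity magnitude; both
are labelled distinctly. The 2D flow rate is the IO line integral, with
`-dA/dt` exposed as a cross-check column, and the stroke volume returns
both `V_ED - V_ES` and the systolic flux integral `∫Q dt` (right-Riemann,
matching the implicit-Euler fluxes that represent step averages) with
their relative discrepancy.

## Phantoms: what they establish (and what they do not)

The generator (`phantom_spec()`, `make_image_stack()`,
`make_benchmark_case()`) provides every input the pipeline needs with known
ground truth:

* **image_stack** — short-axis cine DICOM files (0.7 mm pixels, 8 mm slice
  spacing, 20 phases, mirroring standard acquisitions) of a bright lumen
  disk (intensity 200) in a darker myocardial ring (80) on background (20),
  radius contracting 25% over systole and tapering toward the apex, with
  additive Gaussian noise at SNR = (lumen - myocardium)/sd, default 10.
  Noise is the only randomness; one private RNG stream per phantom, seeded
  from the spec, leaves the global RNG untouched, and identical spec + seed
  is bit-identical.
* **piston_box** — 2D box with the bottom wall rising at constant speed:
  `Q' = W s` exactly.
* **contracting_cylinder** — flat-capped cylinder with radial wall motion:
  `V = pi R(T)^2 L`.
* **half_ellipsoid_lv** — the closest analogue of an LV: semi-axes
  `(b, b, a(T))` with `a: 80 -> 64 mm`, `b = 25 mm`, giving
  `SV = (2/3) pi (a_ED - a_ES) b^2 ≈ 20.9 mL` (a linear ED/ES law by
  default; a sinusoidal volume course is available for smooth-motion
  tests).

Passing on these phantoms establishes the *mechanics*: metadata handling
against the real DICOM byte format, segmentation accuracy at a realistic
SNR, exact mass conservation, discretization convergence, and closed-form
recovery of volumes, flow rates and energetic identities. It does **not**
establish clinical fidelity: the phantoms have no papillary muscles, no
myocardial texture, no MR artifacts (wrap, bias fields), no trabeculation,
and their motion laws are the model's own interpolation laws, so
image-to-model motion errors of real hearts are not probed.

## Problem sizes and numerical defaults

The shipped verification runs use deliberately coarse but converged sizes:
the half-ellipsoid flow mesh at 24 angular points, 16 ring levels, 4 radial
layers (~7.7k tetrahedra) with 40 steps/cycle recovers the analytic stroke
volume and peak flow rate to 1.5% (the inscribed-polygon volume deficit
dominates); Poiseuille verification uses channel-height/10, /20 and /40
meshes; the segmentation benchmark is the full 6-slice x 20-phase SNR-10
stack (Dice 0.99 mean, 0.98 minimum). Degenerate inputs are handled
explicitly: all-equal intensities flag a degenerate FCM fit, max-membership
ties break to the lowest cluster index, empty masks and hint-less lumens
raise errors rather than guessing, snake collapse falls back to its input
trace, and inverted elements abort a step with a remesh/smaller-step hint.

## Known limitations

* Only the lumen-wall interface is segmented; myocardium and heart base are
  out of scope, and valve asymmetries are deliberately absent (single IO).
* The 3D motion uses only ED and ES; filling/ejection *rate* shapes inside
  each phase are linear by construction.
* First-order time stepping smooths sharp transients; energy-budget
  quantities are reported but no turbulence model is included (laminar,
  transitional at most, as appropriate at these Reynolds numbers).
* The DICOM reader supports uncompressed Explicit VR Little Endian only —
  enough for the phantom round trip and typical exports, not for compressed
  archives.
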