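---
title: "Structural mechanics of swiftlet nests: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural mechanics of swiftlet nests: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestmech)
```

# The problem

Edible-nest swiftlets (*Aerodramus fuciphagus*) build half-cup nests on
vertical walls entirely from threaded saliva, layer by layer. The resulting
structure is a single-material, graded shell: a thick, dense anchor pad glued
to the wall, walls of ~0.25 mm strands, and a thin free rim where the adult
birds stand. Between the strands sit closed pores, elongated along the
horizontal (right-left) deposition direction. `nestmech` implements the full
quantitative chain for asking whether such a structure is mechanically
over-designed for its natural loads: volumetric image segmentation, closed-pore
morphometrics, tensile data reduction, and a voxel finite-element (FE)
simulation of bird/egg loading judged against the material's tensile fracture
strength with a maximum-principal-stress criterion.

Because no scan data are distributed, the package ships a seeded synthetic
phantom that reproduces the documented architecture, with exact ground-truth
masks. Every downstream stage is exercised — and tested — against that ground
truth.

# Axis convention and units

One convention is fixed globally: array axis 1 is **U-D** (up-down; gravity
acts toward decreasing index), axis 2 is **B-F** (back-front; the anchor wall
is the low-index face), axis 3 is **R-L** (right-left). Voxel `(i, j, k)`
(1-based) has physical center `((i-0.5), (j-0.5), (k-0.5)) * spacing`. All
I/O converts spacing to mm on demand; mechanics run in the consistent
mm–N–MPa–tonne/mm³ system with `g = 9806.65 mm/s²`, so an elastic modulus in
MPa and forces in N combine without conversion factors.

# The synthetic phantom

`generate_phantom()` builds a grayscale volume plus ground-truth material and
closed-pore masks. Its defaults *are* the study conditions and are not meant
to be tuned:

* overall extents 77.5 mm (R-L) × 39.8 mm (U-D), the documented nest
  dimensions; nest mass 5.93 g, used later to calibrate FE densities;
* a half-cup shell: the region between two ellipsoids clipped at a horizontal
  rim plane and at the wall plane, plus a solid anchor pad (2 mm deep) against
  the wall. The back-front depth (35 mm) and the wall thicknesses (8 mm at the
  anchor grading linearly to 4 mm at the rim) are **assumptions** — the source
  measurements do not include them — chosen to give a plausible shallow
  half-cup with an apparent density near 0.3 g/cm³;
* a strand-void pattern: ellipsoidal voids elongated along R-L, carved on a
  jittered lattice whose acceptance probability ramps linearly from
  `porosity_anchor = 0.02` at the wall to `porosity_rim = 0.09` at the rim.
  Any void that connects to the exterior is filled back, so every ground-truth
  pore is closed *by construction*;
* grayscale means: background 5, material 70 at the rim grading to 90 at the
  denser anchor, plus additive Gaussian noise (sd 8), clipped to 0–255. The
  means are chosen so the published segmentation threshold of 40 sits near the
  background/material midpoint — mirroring the fact that a fixed threshold of
  40 evidently separated the real scans' histogram;
* full determinism: a given `PhantomParams` + seed yields a bit-identical
  bundle (the generator saves and restores the global RNG state).

**The caricature scale.** The real strand pitch (0.25 mm) is far below the
desk voxel size (0.4 mm), so the void lattice coarsens the pitch to the
nearest integer multiple of `fiber_pitch` close to `coarse_pitch` (2 mm by
default). Voids then span ~3 × 3 × 7.5 voxels and are resolvable by the
segmentation chain. The phantom therefore reproduces the *kind* of
architecture (graded cross-section, anchor-to-rim porosity ramp, R-L-aligned
closed pores) at a coarser scale, not the literal strand microstructure.
Passing recovery tests demonstrate that the pipeline recovers architecture of
this kind at this contrast and noise level; they say nothing about scanner
physics (beam hardening, rings) or sub-voxel strands, which are out of scope.

The achieved closed-pore fraction is lower than the nominal ramp because
closure filtering removes voids near surfaces — more aggressively where the
wall is thin (the rim). The ramp survives qualitatively: per-slice porosity
increases from anchor to rim under a linear fit across seeds.

# Segmentation

`segment_nest()` fixes and logs the stage order:
Gaussian smoothing (`sigma = 1` voxel) → optional linear downsampling →
inclusive grayscale thresholding (40–255) → retention of the largest
26-connected component → closed-pore extraction (6-connected background) with
the small-pore fill rule.

Numerical choices:

* The "recursive Gaussian" of the original workflow is implemented as the
  equivalent sampled discrete Gaussian, truncated at radius 4σ, normalized,
  with reflected boundaries; output is re-quantized to 8-bit by
  round-half-even. Equivalence to the recursive filter family holds to 8-bit
  precision.
* Threshold bounds are inclusive at both ends so the value 255 stays
  reachable.
* Connectivity: 26 for material, 6 for background/pores. Complementary
  connectivities avoid topological paradoxes; because the choice affects pore
  counts it is exposed in `segmentation_params()`.
* Downsampling (`resample_factor = 2`, e.g. 34.04 µm → 68.1 µm class spacing)
  samples the coarse voxel centers by trilinear interpolation; output shape is
  `ceiling(shape / factor)`. The resampling stage is configurable: before
  thresholding (default, matching the original workflow where the stack was
  resampled on import), after mask formation, or not at all.
* Ties between equal-sized components are broken toward the component whose
  first voxel comes earliest in raster order — deterministic across runs.
* The fill rule operates *after* closed-pore classification: border-connected
  cavities are never filled.

**The 125-voxel rule across resolutions.** "Closed pores with fewer than 125
voxels are added to the mask" is a count at a specific voxel size (68.1 µm).
At the desk resolutions that count corresponds to a vastly larger physical
volume, so the recovery harness and the desk FE branch carry the rule across
resolution as a physical volume via `min_pore_voxels_for()` (125 × 68.1 µm
voxels ≈ 0.0395 mm³), which floors to 1 voxel at 0.4–0.8 mm spacing. The
literal count remains the default in `segmentation_params()` for use at scan
resolution.

Recovery is judged at the generation resolution (no resampling): material
Dice and the closed-pore census against the phantom truth over seeds 1–5.
Note that pores a few voxels wide are *eroded* by the σ = 1 smoothing — most
of their interior rises above the threshold and only a core survives — so the
pore census is recovered (counts within 20%) while individual pore volumes
are biased low near the resolution limit. The same would happen to real
scans segmented at a marginal resolution; pore-volume fidelity requires
voxels several times smaller than the pores, as in the original 34 µm scans.

# Morphometrics

* Surface area is counted as exposed voxel faces × face area. This estimator
  is exactly testable (a 10 mm cube gives 600 mm²) and is used comparatively
  along axes; it overestimates smooth surfaces by a factor converging to 1.5
  for a sphere (asserted within 5% at radius 20 voxels). It substitutes for
  the unspecified proprietary per-slice "surface area" of the original
  toolchain.
* Slice profiles report material area, the surface-area contribution of each
  slice, and closed porosity as `100 × pore / (pore + material)` voxels — the
  exterior air never enters the denominator, so profiles do not depend on
  bounding-box padding.
* Pore orientation uses the second central moment tensor of voxel centers
  per label, with the per-voxel cube self-moment `spacing²/12` added on the
  diagonal so single voxels are well-defined. Principal axis lengths use the
  uniform-ellipsoid identity `L = 2√(5λ)`, which recovers analytic ellipsoids
  exactly in the continuum limit. Angles are folded to [0°, 90°] (axis, not
  vector, orientation). Single-voxel pores are flagged degenerate (elongation
  1, angles undefined); elongation < 1.1 is flagged near-isotropic.

# Tensile reduction

Engineering quantities throughout: `σ = F/A₀`, `ε = ΔL/L₀`, no smoothing. The
elastic modulus is the OLS slope over `ε ∈ [0.002, ε(0.5·σ_peak)]` — the toe
and the nonlinear branch are excluded; the window falls back to the first
half of the pre-peak range when it holds fewer than 5 samples, and the window
actually used is recorded. Failure: peak stress is the global maximum; strain
to fracture is the first post-peak sample below `0.1·σ_peak` (final strain,
flagged, if never reached); drop events are post-peak decreases exceeding
`5%·σ_peak` between consecutive samples. The 0.1 and 0.05 factors formalize a
qualitative description and are exposed as parameters. Aggregation reports
unweighted means and (n−1) SDs overall and per cut orientation (0°/45°/90°),
with a single specimen's SD reported as `NA`; both readings of "averaging the
horizontal specimens" (overall vs per-orientation) are therefore available.

The cohort generator (`simulate_tensile_cohort()`) draws peak stresses from
N(2.75, 0.79²) MPa, moduli log-normally around 155 MPa (5% scatter), and
builds each curve piecewise: quadratic seating toe, exact linear regime with
slope E, parabolic cap tangent at both ends with apex at the peak, then a
staircase of fiber-failure drops ending in failure at ε ≈ 0.125. The linear
regime is exactly linear, so the modulus fit is exact on noiseless records.

# The voxel FE solver

Each material voxel becomes an 8-node trilinear hexahedron (one shared node
lattice), 2×2×2 Gauss quadrature, isotropic Hooke's law with E = 155 MPa and
ν = 0.3 — material isotropy at the element level, structural anisotropy from
geometry only. This voxel meshing replaces the original tetrahedral
free-meshing stage; it is the one deliberate methodological substitution
(the standard micro-FE convention for CT-derived volumes), chosen for
deterministic, dependency-free meshing.

* **Density and gravity.** Per-element density is proportional to the voxel
  grayscale and rescaled so total mass equals the calibrated nest mass
  (5.93 g) to machine precision; gravity enters as the consistent body force
  (equal 1/8 nodal shares per element — exact for a constant body force with
  trilinear shape functions), directed along −U-D.
* **Constraints.** Wall-face nodes are fully pinned (zero displacement in all
  directions), matching the anchoring boundary condition.
* **Loads.** Each ROI's total force is spread as a uniform traction: every
  exposed voxel face fully inside the ROI carries an equal share, a quarter
  per corner node. This reproduces constant-stress patch states exactly
  (`σ = F/A` to 1e-8 on a uniaxial bar at any resolution); ROIs smaller than
  one face fall back to equal nodal shares.
* **Solver.** Jacobi-preconditioned conjugate gradients to a relative
  residual of 1e-8 (cap 50,000 iterations), fixed ordering, so results are
  run-to-run deterministic; failure to converge is an error, never a silent
  return. A sparse-Cholesky path (`method = "direct"`) gives the same answer
  within tolerance when many load cases share one geometry.
* **Recovery.** Stresses are evaluated once per element at the centroid
  (`σ = D B(0) u_e`) — the simplest consistent recovery; no Gauss-point
  extrapolation. The maximum principal stress is the largest eigenvalue of
  the centroid tensor (tension positive), computed by a vectorized
  trigonometric closed form and cross-checked against dense eigensolves.
* **Verification.** The suite pins down: exact bar stress and `FL/AE` end
  displacement; cantilever tip deflection within 10% of `PL³/3EI` at
  slenderness 12 with 4 elements through the thickness (measured ~4%);
  equilibrium of reactions against applied loads to 1e-6 relative; exact
  linearity and superposition; frame consistency under axis permutation.

# Loading scenarios

Loads: each bird 16 g → 0.1569 N, each egg 1.2 g → 0.0117 N (weights under
standard gravity, truncated — not rounded — to 4 decimals by the published
convention), all directed downward.

* **worst_case** — two bird cuboids on the rim plus two egg patches at the
  cup floor, gravity on.
* **eggs_only** — the egg patches alone.
* **damaged** — the worst case after carving a 2.5 mm spherical defect 4 mm
  below the first bird stand (free-floating fragments are dropped before
  meshing).

ROI sizes and placements are not documented for the original analysis, so the
defaults are declared conventions exposed in `scenario_config()`: 5 × 5 mm
bird footprints at ±45° from the front midline on the rim's outermost band
(a large moment arm about the wall fixation while staying on the free rim),
10 × 6 mm egg ellipses beside the cup-floor low point, found geometrically
from upward-exposed surface voxels. Region statistics use declared
conventions that do not affect the solve: rim band = top 10% of the material
U-D extent, anchor band = 10% of the B-F extent from the wall, egg region =
elements inside the egg ROIs dilated 1.5×. The fracture strength (2.75 MPa)
enters only the safety factor, never the solver. Gravity is always on in the
named scenarios; whether the original peak values included self-weight
separately is not recoverable, so self-weight is simply always included here.

# Problem sizes

The desk preset generates the phantom at 0.4 mm voxels (~104 × 90 × 198
grid), segments at that resolution for recovery studies, and resamples to
0.8 mm for the FE stage (~54k elements, ~200k dof; a worst-case solve takes
on the order of a minute). Full-resolution 34 µm generation is permitted by
the same code but gated behind a voxel budget, since that grid would hold
~2.7 billion voxels. These sizes are the package's chosen study conditions
for a desk-scale, fully reproducible analysis.

# Known limitations

* The phantom's strand pattern is a coarse-scale caricature (see above); its
  wall thicknesses and depth are assumptions.
* No CT physics: no beam hardening, rings, or anisotropic noise.
* Face-count surface areas carry a known digitization bias (documented 1.5×
  on smooth surfaces) and are meaningful comparatively, not absolutely.
* The FE model is small-strain linear elastic with isotropic material; no
  contact, fracture propagation, or geometric nonlinearity. Peak stresses on
  the 0.8 mm phantom mesh are smoother (lower) than values from a ~5M-element
  tetrahedral mesh of a real nest would be; conclusions are drawn from
  orderings and safety margins, not from matching a particular peak value.
* Engineering stress-strain is used throughout, as in the source workflow;
  at ~0.125 strain to fracture the true-stress correction would be material.
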