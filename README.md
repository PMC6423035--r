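# nestmech

Structural mechanics of edible-nest swiftlet nests from volumetric images.

Edible-nest swiftlets (*Aerodramus fuciphagus*) build half-cup nests on
vertical walls entirely from threaded saliva — a natural additive
manufacturing process. The nests are graded structures: a thick, dense anchor
pad on the wall, walls of fine strands enclosing closed pores elongated along
the horizontal deposition axis, and a thin free rim where the adult birds
stand. `nestmech` is an R package plus analysis workflow for asking, with
desk-scale reproducibility, whether such a structure is mechanically
over-designed for its natural loads.

The package covers the full quantitative chain:

* **Synthetic phantom** (`generate_phantom()`) — a seeded generator producing
  a grayscale nest volume (77.5 × 39.8 mm, mass 5.93 g) with exact
  ground-truth material and closed-pore masks: graded wall cross-section,
  anchor-to-rim porosity ramp, pores elongated along the right-left axis.
* **Volume I/O** (`read_stack()`, `write_volume()`, `export_mesh()`) — TIFF
  slice stacks and multipage TIFF, 8-bit BMP (read), MetaImage, legacy VTK
  and Abaqus `.inp` mesh export, with explicit voxel-spacing metadata.
* **Segmentation** (`segment_nest()`) — Gaussian smoothing (σ = 1), linear
  resampling (34.04 µm → 68.1 µm class), inclusive thresholding (40–255),
  largest-component retention, closed-pore extraction with the small-pore
  fill rule (pores < 125 voxels added to the material mask).
* **Morphometrics** (`summarize_nest()`, `slice_profile()`,
  `pore_orientation()`) — volume, exposed-face surface area, per-slice
  profiles along the U-D/B-F/R-L axes, inertia-tensor pore orientation.
* **Tensile reduction** (`to_stress_strain()`, `extract_modulus()`,
  `detect_failure()`, `aggregate_curves()`) — engineering stress–strain
  (σ = F/A₀, ε = ΔL/L₀), elastic modulus from the linear regime, peak
  (fracture) stress, strain to fracture, post-peak stress-drop events.
* **Voxel FE** (`build_model()`, `solve_fe()`) — one trilinear hexahedron per
  material voxel, isotropic Hooke's law (E = 155 MPa, ν = 0.3), per-element
  density calibrated to the nest mass, gravity body forces, pinned wall-face
  nodes, uniform-traction ROI loads, Jacobi-PCG solve, centroid stress
  recovery, maximum principal stress (the brittle-fracture criterion).
* **Scenarios** (`make_scenario()`, `run_scenario()`) — worst case
  (two 16 g birds → 0.1569 N each, on the rim + two 1.2 g eggs → 0.0117 N
  each, on the cup floor), eggs-only, and damaged-rim loading, with region
  statistics and the safety factor against the 2.75 MPa fracture strength.

## Worked example

```r
library(nestmech)

bundle <- generate_phantom(phantom_params(seed = 42))   # ~1 s, 0.4 mm voxels
fe     <- desk_fe_inputs(bundle)                        # segment + resample to 0.8 mm
model  <- make_scenario("worst_case", fe$mask, fe$gray)
report <- run_scenario(model)                           # PCG solve, ~1 min
print(report)
```

```
scenario 'worst_case': global max principal 0.01258 MPa at (39.6, 18.8, 71.6) mm; safety factor 219
      region n_elements     mean_mpa     max_mpa
    rim_band       5545 0.0014231498 0.012579864
  egg_region        863 0.0002876490 0.001206756
 anchor_band      14120 0.0003133267 0.006425883
      global      54067 0.0004438771 0.012579864
```

Reading this output: under the worst-case load (two birds on the rim, two
eggs in the cup, self-weight on), the peak tensile stress in the phantom —
0.013 MPa, located on the rim where a bird stands — is two orders of
magnitude below the material's 2.75 MPa fracture strength (safety factor
~219 on this smooth desk-scale mesh). The egg region carries about a fifth
of the rim band's mean stress, and the anchor band is similarly quiet: the
half-cup geometry and the graded cross-section route the load away from the
eggs and spread it into the wall anchoring.

The numbered drivers under `analysis/` run the whole study and write tables
to `results/`:

```sh
Rscript analysis/01_generate_phantom.R       # phantom + ground-truth census
Rscript analysis/02_segmentation_recovery.R  # Dice / pore-count recovery, seeds 1-5
Rscript analysis/03_morphometrics.R          # summaries, profiles, pore orientation
Rscript analysis/04_tensile.R                # synthetic cohort reduction
Rscript analysis/05_fe_scenarios.R           # worst-case / eggs-only / damaged FE
```

The methods vignette (`vignettes/nest-structural-mechanics.Rmd`) documents
the models, parameter choices, numerical conventions and limitations.

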