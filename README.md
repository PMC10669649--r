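# necrovol

Quantification of ablation zones in serial histological sections.

`necrovol` reconstructs and measures zones of tissue necrosis (for example
after chemical or thermal ablation of the cervix) from stacks of serial
cryosections stained with a viability stain such as NADH-diaphorase:
metabolically active tissue stains blue, necrotic tissue and polymer
deposits remain unstained white/gray. The package provides the complete
semi-automated workflow:

- **Segmentation** — background removal (near-white, low-saturation),
  calibrated hole filling and speck removal, then color-based separation of
  viable (blue-dominant, saturated) from necrotic (unstained) tissue, with
  replayable, auditable stand-ins for manual corrections.
- **Quantification** — per-slice necrotic/viable areas, the depth and
  volume endpoints (below), hemi-section ("top half") variants split at the
  tissue centroid, and unpaired two-tailed t-tests between treatment groups
  (raw values or published summary statistics).
- **Registration** — rigid (translation + rotation) alignment of serial
  sections that landed at arbitrary positions on the microscope slides,
  driven by tissue silhouettes.
- **3D reconstruction** — an anisotropic voxel grid whose voxel-sum volume
  reproduces the volume formula exactly, plus a watertight iso-surface mesh
  exported as PLY/STL/OBJ for standard mesh viewers.
- **Synthetic phantoms** — stained-section image stacks with known lesion
  geometry, staining noise, artifacts and per-slice rigid jitter, together
  with exact ground truth, so the entire pipeline is testable end to end
  without any histology data.

## The endpoints

Sections of thickness *t* (default 0.02 mm) are cut every *t + s* (spacing
*s*, default 0.5 mm). With *A<sub>i</sub>* the necrotic area (mm²) of the
*i*-th of *N* sections containing necrosis:

- **Volume** (µL = mm³):
  *V* = Σ<sub>i=1..N−1</sub> *A<sub>i</sub>* (t + s) + *A<sub>N</sub>* t
  — each section but the last represents a full thickness-plus-spacing
  slab; at the defaults, Σ *A<sub>i</sub>* × 0.52 + *A<sub>N</sub>* × 0.02.
- **Depth** (mm): *D* = *N* t + (*N* − 1) s, i.e. 0.52 *N* − 0.5 at the
  defaults.

## Worked example

```r
library(necrovol)

geom <- stack_geometry()         # 20 µm sections, 500 µm spacing
necrosis_depth(25, geom)         # 12.5  (mm, stack of 25 affected sections)
necrosis_volume(rep(10, 10), geom)  # 47  (µL, ten 10 mm² sections)

# headline comparison from published summary statistics (mean, SD, n)
compare_groups(list(mean = 626.2, sd = 122.8, n = 10),
               list(mean = 1292.9, sd = 242.3, n = 10))
#> group_comparison (pooled): 626.2 +/- 122.8 (n=10) vs 1292.9 +/- 242.3 (n=10)
#>   t = -7.7613, df = 18.00, two-tailed p = 3.76e-07

# a synthetic 12-section stack with known ground truth, run end to end
p   <- phantom_preset("well_posed", seed = 1, n_sections = 12)
ph  <- generate_phantom(p$config, p$geometry)
ph$ground_truth$summary
#> necrosis_summary: N = 9 sections, depth = 4.2 mm, volume = 51.9 uL

rep <- run_pipeline(run_config(phantom = p$config, geometry = p$geometry,
                               edits = ph$ground_truth$edits,
                               out_dir = tempfile("necrovol_demo_")))
rep
#> necrovol run report: 12 sections
#>   whole:    N = 9, depth = 4.2 mm, volume = 51.3 uL
#>   top half: N = 9, depth = 4.2 mm, volume = 51.3 uL
```

The pipeline recovered the number of affected sections (and hence the
depth) exactly and the necrotic volume within about 1% of ground truth,
despite staining noise, rendered artifacts and per-slice rigid jitter of up
to 15 px / 8°. The output directory contains the per-slice CSV, mask PNGs,
the transform log, a `report.json`, and a binary PLY mesh of the necrosis.

A thin command-line wrapper with `simulate` / `segment` / `align` /
`quantify` / `reconstruct` / `compare` / `run` subcommands is installed at
`system.file("cli", "necrovol", package = "necrovol")`.

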