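# liverseg

Automatic liver segmentation of volumetric MRI in R.

Building a patient-specific 3D model of the liver — the starting point of
treatment planning for liver interventions such as electroporation-based
therapies — requires segmenting the organ on every slice of an abdominal
MRI acquisition. `liverseg` implements the full chain as a tested library
plus a small CLI:

* **Import**: DICOM series discovery, slice sorting by `SliceLocation`,
  missing-slice detection (empty slices inserted, never interpolated).
* **Preprocessing**, stored in named layers: per-slice sigmoid VOI
  transform `out(x) = R / (1 + exp(-4 (x - WC) / WW))`, homomorphic
  bias-field correction, 3x3 average + Gaussian denoising, and a fixed-VOI
  redistribution (WC = 20000, WW = 100, R = 2^16) that places liver tissue
  in a predictable 16-bit band.
* **Three segmentation algorithms**, all starting on the *referential
  slice* `z_ref = round(0.65 z_max)`:
  * seeded **3D region growing** (26-connectivity, open acceptance band
    `(I(1-d), I(1+d))`, default deviation `d = 0.20`, automatic
    median-intensity seeding);
  * **adaptive thresholding** — per-slice threshold sweep maximizing
    normalized cross-correlation (NCC) to the neighboring already-segmented
    slice, propagated bidirectionally with a 0.70 similarity stop;
  * **active contours** (greedy snake) driven by Gradient Vector Flow
    (mu = 0.2, 1000 iterations), energy weights 1, 3, 9, 3 for elasticity,
    curvature, GVF magnitude and direction, decimation spacing 8, at most
    100 moves per slice.
* **Postprocessing**: 3x3 disk erosion, largest-segment rule on the
  referential slice, per-segment NCC filtering (> 0.65) against the
  finalized neighbor slice in both Z directions, then dilation — removing
  leakage into similar-intensity organs attached by thin bonds.
* **Validation & optimization**: slice-wise NCC reports (mean/median/std)
  and exhaustive grid search returning per-case (S_C) and global (S_G)
  optima.
* **Phantom generator**: deterministic MRI-like abdominal volumes with
  ground truth (liver with vessels/nodules, a decoy organ on a thin bond,
  bias field, noise, VOI metadata), so everything above can be benchmarked
  without patient data.

## Worked example

Generate a phantom, export it as a DICOM folder, run the full pipeline
with region growing, and validate against the phantom's ground truth:

```r
library(liverseg)

ph <- generate_phantom(phantom_spec(seed = 1))
folder <- file.path(tempdir(), "phantom_dicom")
export_dicom_like(ph$volume, folder)

discover_series(folder)
#> DICOM acquisition series:
#>   [1] SYNTHETIC PHANTOM              (40 files)

res <- run_pipeline(folder, series = 1, algo = "rg", reference = ph$truth)
res
#> PipelineResult (rg): 105988 voxels segmented, z_ref = 26
#> SimilarityReport over 40 slices: mean 0.971, median 0.973, std 0.023

dice(res$mask, ph$truth)
#> [1] 0.978
```

The report's per-slice NCC values aggregate to a mean of 0.971 and a
median of 0.973 against ground truth; the whole-volume Dice overlap is
0.978. The decoy organ, although reached by the region growth through its
2-pixel bond, is removed entirely by postprocessing.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/liverseg.R phantom --out phantom_dicom
Rscript inst/cli/liverseg.R run phantom_dicom --series 1 --algo rg \
    --ref phantom_dicom/truth_mask.tsv --out results/
```

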