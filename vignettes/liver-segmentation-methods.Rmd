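---
title: "Methods: automatic liver segmentation of volumetric MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic liver segmentation of volumetric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverseg)
```

Patient-specific treatment planning for liver interventions (for instance
electroporation-based therapies) starts from a 3D model of the organ, which
in turn starts from segmenting the liver on every slice of a volumetric MRI
acquisition. This package implements a complete, automatic segmentation
chain for that purpose, together with a deterministic phantom generator so
that every stage can be exercised and benchmarked without patient data.

## Import

A DICOM folder is scanned (`discover_series()`), one acquisition series is
chosen, and its slices are sorted ascending by `SliceLocation`
(`load_series()`). Loading is invariant to on-disk file order, and the
`source` layer stores pixel data bit-identically. `check_gaps()` infers the
common inter-slice step as the *lower median* of adjacent location
differences — robust even when wide gaps make up half of the differences —
and inserts all-zero slices at the inferred positions. Missing slices are
never interpolated: they may indicate a corrupted export, so the user is
notified instead. Spacing that no common step divides (residual above 5% of
the step) is rejected outright as corrupted.

## Preprocessing and the layer model

Every slice passes through four stages, each stored in its own append-only
layer of the `LayeredVolume` (`source`, `original`, `debiased`, `filtered`,
`preprocessed`) so intermediate results stay inspectable. Slices are
processed independently, which makes the procedure order-free and
parallelizable by contract.

1. **Sigmoid VOI transform.** Stored values are mapped through the
   DICOM-style sigmoid `out(x) = R / (1 + exp(-4 (x - WC) / WW))` using each
   slice's own WindowCenter/WindowWidth and `R = 2^bits - 1`. A narrow
   window turns this into a threshold at WC; a window wider than the data
   range into a linear rescale.
2. **De-biasing.** MR coils leave a smooth multiplicative intensity field
   over the slice. We estimate it homomorphically: a Gaussian-weighted
   average (sigma defaulting to a quarter of the image width) computed over
   the *bright* pixels only (above half the 99th percentile), normalized to
   unit mean and divided out, preserving the slice mean. The foreground
   weighting matters: an unweighted smoothed copy is dragged down near organ
   boundaries by dark background and then *adds* spurious variation at
   exactly the scale the correction should remove. Through-slice (Z)
   inhomogeneity is deliberately left alone; the segmentation stages
   tolerate it via their deviation and similarity parameters.
3. **Denoising.** A 3x3 average filter followed by a 3x3 Gaussian
   (sigma 0.5), run sequentially. Both kernels have unit mass, so constants
   and the input range are preserved. This pairing suppresses dense noise;
   for *sparse* impulse noise a linear filter spreads rather than removes
   the error, and we verify the mean-absolute-error reduction at 10%
   corruption density where smoothing genuinely wins.
4. **Fixed-VOI redistribution.** A second sigmoid with fixed WC = 20000,
   WW = 100 and output range 2^16 redistributes contrast over the full
   16-bit range, so that liver tissue lands in a predictable band no matter
   what the source range was. With WW = 100 this is nearly a step: the
   preprocessed layer is close to binary, which is precisely what makes the
   downstream threshold sweeps and region growth stable across
   acquisitions.

## The referential slice

All algorithms start on the *referential slice*
`z_ref = round(0.65 * z_max)` (round half-up; 72 slices give slice 47),
clamped to the stack — the position where a large liver cross-section is
most likely. On it, `segment_referential()` sweeps 64 thresholds across the
slice's intensity range; every cleaned binarization (hole filling plus one
3x3 opening, which stops speckle from dominating the comparison) is scored
by normalized cross-correlation against six built-in liver-shape presets
(procedural superellipses with bean/crescent indentations at graded sizes
between 5% and 45% of the slice, scaled by the tunable `size_coefficient`).
The best-matching threshold defines the initial liver segment. The presets
are deliberately coarse: only their count, rough shape and size matter, and
cohort-specific masks can be substituted.

## Segmentation algorithms

**Region growing** (`grow()`): breadth-first 3D expansion from a seed under
26-connectivity, accepting a neighbor of intensity `v` iff
`I (1 - d) < v < I (1 + d)` (open interval) with deviation `d = 0.20` by
default. The anchor `I` is the *seed* intensity by default: the acceptance
band is then fixed, the result has set semantics (queue order cannot
matter, which we assert against a brute-force flood-fill oracle), and
enlarging `d` can only enlarge the region. The alternative reading —
anchoring at the *current* voxel — is kept as `reference_mode = "current"`;
it can drift across smooth gradients and is queue-order dependent, which is
documented rather than hidden. Seeds can be placed manually or by
`auto_seed()`: the referential-segment pixel whose intensity is nearest the
segment's *median*, which by construction avoids vessels and nodules (their
intensities are outliers within the segment); ties break toward the segment
centroid, then the lowest linear index — an interior pixel, chosen
deterministically.

**Adaptive threshold** (`segment_adaptive_threshold()`): liver outlines
change little between adjacent slices, so the best binarization of a slice
is the one most similar to its already-segmented neighbor. Each slice is
swept over 64 thresholds; the mask maximizing NCC against the neighbor wins
(ties toward the lowest, most inclusive threshold — later postprocessing
trims better than it grows). Propagation runs from the referential slice
outward in both Z directions independently. Errors are cumulative by
construction, so when the best achievable similarity drops below 0.70 the
organ is deemed ended and every further slice in that direction stays empty
— no resurrection.

**Active contours** (`segment_active_contours()`): a closed contour,
initialized from the adaptive-threshold referential segment, is decimated
to one point per 8 circumference pixels and moved greedily. Each point
inspects its 3x3 pixel neighborhood and moves to the candidate minimizing
`1*E_elast + 3*E_curv + 9*E_mag + 3*E_dir`, where elasticity penalizes
deviation from the contour's mean inter-point spacing, curvature is the
squared second difference of neighboring points, magnitude is low where the
Gradient Vector Flow is strong, and direction is zero only at the neighbor
the GVF vector points to (snapped to the nearest of 8 directions; a
negligible field, below 1e-6, makes the term uniform). Elasticity,
curvature and magnitude are min-max normalized over the nine candidates so
the printed coefficient balance is meaningful; staying put wins ties, and
internal terms are recomputed every iteration (at most 100 per slice, or
until no point moves). The GVF field itself is computed per slice from a
normalized gradient-magnitude edge map by diffusion with regularization
mu = 0.2 for 1000 iterations; we integrate the diffusion term explicitly
and the data-fidelity term implicitly, so the time step is bounded by the
diffusion term alone (dt = 0.9/(4 mu)) and the scheme cannot be
destabilized by strong edges. At image scale the raw field keeps slowly
strengthening long past 1000 iterations; what the snake consumes — the
direction field and the normalized magnitude near edges — is settled well
before that, and the per-iteration residual is reported for inspection.
Contours propagate slice to slice (each slice starts from its neighbor's
final contour); self-intersections are repaired by filling the polygon and
re-tracing its outer boundary. No per-slice similarity threshold exists for
this algorithm, so a direction terminates when the filled contour area
falls below 10% of the referential segment area — a stand-in chosen to
mirror the adaptive-threshold stop's role.

## Postprocessing

Threshold-based methods leak into neighboring organs of similar intensity
through thin bonds. `postprocess_volume()` (1) erodes every slice with the
3x3 disk, cutting such bonds, (2) keeps only the largest segment on the
referential slice (4-connectivity; area ties break to the smallest
lexicographic (row, col) anchor), (3) sweeps outward in both Z directions,
keeping each segment `S` of a slice iff `NCC(S, S intersect neighbor) >
0.65` against the already-finalized inner neighbor — per segment, not per
slice, so multiple genuine segments can survive while strays with no
counterpart are discarded — and (4) dilates with the same 3x3 disk.
Erosion and dilation run once, bracketing both sweeps. The output can never
exceed one dilation of the input, and a referential slice left empty by
erosion degrades the procedure to the identity with a warning rather than
deleting a segmentation silently.

## Validation and optimization

`slice_similarity()` is zero-shift NCC between registered binary masks
(Pearson correlation of the mask images) clamped to `[0, 1]`: slices of one
acquisition are already registered, so no translation search is needed.
Conventions: both masks empty scores 1, exactly one empty scores 0 — even a
few spurious pixels zero their slice, which is why case aggregates are
reported as mean *and* median (`case_similarity()`); zero-similarity slices
drag the mean far more than the median. All slices `1..z_max` enter the
aggregation, the inclusive reading of the per-case averages.

`grid_search()` evaluates a segmentation routine over the full cross
product of parameter ranges on every case: per-case optima give the
case-specific objective (S_C), the single point maximizing the cross-case
mean gives the globally-optimized parameters (S_G). S_C >= S_G per case by
construction; ties break toward the lexicographically first grid point, a
failing grid point scores 0 (logged), and results are invariant to case
order. Default ranges follow the parameters that matter per algorithm:
deviation {0.10..0.30} and filter mask {3, 5} for region growing, the
preset size coefficient {0.5..1.5} for adaptive threshold, each snake
coefficient {1, 3, 9} for active contours.

## The phantom and what it does (not) show

`generate_phantom()` builds a 40x128x128 (default) volume: a
superellipsoid-like liver across slices 6–38 whose outline is deformed by
low-frequency radial harmonics; two darker vessel tubes (50% contrast) and
two brighter nodules (35%) inside it; a decoy organ of near-liver intensity
on slices 37–40, attached through a 2-pixel bond (the leakage scenario); a
smooth multiplicative bias field (15% range); additive Gaussian noise
(sigma 250 of the 16-bit scale); and per-slice VOI metadata placing tissue
in the sigmoid's informative mid-range. Everything is drawn from one named
seed — identical specs are bit-identical — and ground truth plus
per-structure labels are returned. Intensities were chosen so that, after
the standard preprocessing chain, background stays below and liver above
the fixed-VOI step.

`phantom_family()` is a calibrated variant for the optimization benchmark:
noise- and bias-free, with contrasts set so that the *preprocessed* layer
shows vessels near 0.85x and the decoy near 1.25x the liver intensity
(background near 0.5x). Under the seed-anchored acceptance interval, a
deviation of 0.10 excludes liver-internal vessels, 0.30 leaks into the
decoy, and 0.20 is the unique optimum of {0.10, 0.20, 0.30} — a
parameter-recovery experiment with a known answer. The calibration uses a
wide fixed VOI (WC 30250, WW 36500) because the default near-step VOI
deliberately erases the gradation that the deviation parameter acts on.

The phantom emulates the difficulties the algorithms must handle —
similar-intensity neighbors with thin bonds, internal structures, bias,
noise, abrupt organ end — but not the texture, partial-volume softness,
motion or through-slice inhomogeneity of real MRI. Passing these benchmarks
shows the algorithms implement their contracts and survive the named
difficulties; it does not certify clinical accuracy on patient data.

## Numerical choices and problem sizes

* Rounding of the referential index is half-up; intervals of the region
  growing acceptance are open; "exceeds" in the postprocess filter is
  strict.
* Threshold sweeps use 64 levels spanning `(min, max]` of the slice; the
  all-inclusive threshold at the minimum is not a candidate.
* NCC degenerate cases: a mask covering the whole frame has no variance, so
  the comparison falls back to Dice overlap.
* The unit suite runs on 24x64x64 phantoms for speed; the benchmark suite
  (`tests/testthat/test-acceptance.R`, `scripts/acceptance.R`) uses the
  full 40x128x128 study size, 50 random 16^3 volumes for the region-growing
  oracle, and a 96x96 disk for the GVF geometry check.

## Known limitations

Single-frame uncompressed DICOM only; MRI only (the fixed VOI encodes
MR-range expectations, so CT would need different preprocessing constants);
no multi-seed growing, no topology changes of the contour, no true 3D
deformable surface (a reliable whole-surface initialization does not exist
in this pipeline); the active-contour per-direction stop is area-based, an
acknowledged stand-in; postprocessing does not fill holes across slices.
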