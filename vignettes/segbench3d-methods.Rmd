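---
title: "segbench3d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{segbench3d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segbench3d)
```

## The problem

Quantitative microscopy of 3D stacks (confocal z-series of fluorescently
labelled nuclei, whole larval brains, and similar) depends on
segmentation, and automated segmentation must be *validated*. The
empirical-discrepancy approach compares a machine segmentation (MS)
against a reference ground truth (GT) built by an expert. segbench3d
implements both halves of that loop as a scriptable library:
semi-automated, threshold-based GT construction from calibrated grayscale
stacks, and quantitative benchmarking of any labelled MS stack against a
labelled GT stack.

Both GT and MS are *labelled stacks*: integer 3D arrays where 0 is
background and each positive value identifies one object. Intensity
stacks carry a voxel calibration (dx, dy, dz in micrometres), so object
voxel counts convert to volumes in µm³.

## Pixel-level benchmarking

With foreground defined as "label > 0", every voxel falls into one of
four confusion classes: true positive (foreground in both), false
positive (MS only), false negative (GT only), true negative (neither).
The three summary statistics are

- precision \(p = tp/(tp+fp)\),
- recall \(r = tp/(tp+fn)\),
- F-measure \(F = 2pr/(p+r)\), the harmonic mean of the two.

All three are computed for the whole stack and for every optical slice;
per-slice confusion counts sum exactly to the stack counts.

**Degenerate conventions** (inputs where the textbook formulas divide by
zero) are chosen for totality and continuity with the GT identity
\(p_{GT} = r_{GT} = F_{GT} = 1\):

- both stacks empty (`tp = fp = fn = 0`): perfect agreement, all three 1;
- `tp = 0` with a nonempty union: all three 0.

Two structural laws follow directly from set containment and are used as
acceptance checks. For masks produced by global thresholding of the same
smoothed stack, a lower MS threshold gives a superset of the GT mask, so
`fn = 0` and `r = 1` exactly; a higher MS threshold gives a subset, so
`fp = 0` and `p = 1` exactly (whenever the intersection is nonempty).

## Object-level benchmarking

Objects are connected components: 18- or 26-connected voxel bodies in 3D,
4- or 8-connected pixel regions in 2D (defaults 26 and 8, the permissive
variants). `object_correspondence()` builds the bipartite overlap graph
between GT and MS labels — an edge requires at least one shared
foreground voxel, optionally at least a given fraction of the GT object —
and classifies:

| situation | class |
|---|---|
| GT and MS object overlap, both degree 1 | one-to-one |
| GT object with ≥ 2 MS partners | split (one-to-many) |
| MS object with ≥ 2 GT partners | merged (many-to-one) |
| MS object with no partner | false-positive object |
| GT object with no partner | false-negative object |

Classification is exhaustive per label. In correspondence chains (a GT
object linked to an MS object that also covers a second GT object) a
label can legitimately appear both as a split member and inside a merged
group; one-to-one and FP/FN are exclusive of everything else.

**Per-slice semantics.** Slice reports classify the 2D *cross-sections of
the 3D labels*; slices are deliberately not re-labelled. This preserves
object identity, so the report can name which 3D objects merge on which
slice — the practical use case is pinpointing the exact optical section
where two nuclei fuse under a too-low threshold. A consequence worth
knowing: a single merged 3D MS object reports a merge on every slice
where two GT cross-sections coexist, not only where they touch.

## Ground-truth construction routes

Every route operates on the stack after slice-wise median smoothing
(`median_filter_2d()`, default radius 3, i.e. a 7×7 window — the square
window interpretation of a "3 pixel radius" filter). Borders are handled
by edge replication so no artificial dark rim perturbs thresholding near
the image edge. Median filters are not idempotent and the implementation
does not pretend otherwise; the tested guarantee is agreement with a
naive sliding-window oracle.

1. **Global window threshold** (`apply_global_threshold()`): foreground
   iff intensity ∈ [θmin, θmax], closed interval. θmax defaults to the
   bit-depth maximum (255 or 65535).
2. **Slice-based wand ROIs** (`wand_roi()`,
   `build_gt_from_roi_params()`): each ROI is specified by four stored
   parameters (StartX, StartY, θmin, θmax). The slice row is scanned
   rightward from the start point to the first in-range pixel (the start
   pixel itself counts); the ROI is the 8-connected in-range component
   containing the hit with its interior holes filled, matching
   contour-trace-and-fill semantics. ROIs sharing an objectId across
   slices form one 3D labelled object. Two objects claiming one voxel is
   an error by default (`"last-wins"` is available).
3. **Seeded 3D region growing** (`region_grow_3d()`): the maximal
   connected set containing the seed in which all intensities lie in
   [θmin, θmax]; connectivity configurable (6/18/26, default 26), result
   independent of traversal order. A seed whose own intensity is outside
   the window is rejected by name.
4. **Dual-threshold depth compensation** (`dual_threshold_segment()`):
   axial light attenuation dims deep objects, so seeds at or above the
   demarcation slice grow with θ_shallow and deeper seeds with θ_deep.
   Slice 1 is the shallowest section; "deeper" means a larger 1-based
   slice number. Colliding regions resolve first-seed-wins with a
   warning; an under-threshold seed is skipped and listed rather than
   failing the batch.

## Histogram auto-thresholding

Six classical global methods (`auto_threshold()`), all operating on the
pooled stack histogram and all using the strict foreground rule
"intensity > θ" of the common ImageJ implementations:

- **Otsu** — maximise between-class variance;
- **IsoData** — Ridler–Calvard fixed point: θ ← round of the midpoint of
  the two class means, started from the global mean, iterated until θ
  repeats;
- **Li** — minimum cross entropy. Implemented as an exhaustive scan of
  the cross-entropy criterion rather than Li's accelerated fixed-point
  iteration: on histograms of at most 65536 bins the scan costs nothing,
  is tie-break deterministic, and is exactly the criterion the iterative
  scheme approximates;
- **Huang** — minimise fuzziness: Shannon entropy of the fuzzy
  membership u = 1/(1 + |g − µ_class|/C) with C the occupied histogram
  range;
- **Yen** — maximise the entropic correlation criterion;
- **Rényi** — the three-order combination rule: thresholds at orders
  ρ→1, ρ=1/2 and ρ=2 merged by the published proximity-weighted formula.

Numerical conventions: candidate splits are "≤ t | > t"; empty-class
candidates are invalid; zero-count bins contribute nothing to entropy
sums; criterion plateaus (which arise whenever the histogram has an
empty gap between modes) are broken toward the smallest optimal θ. That
tie-break matters when reasoning about symmetry: on a gap histogram,
inverting intensities moves the reported θ to the other end of the same
plateau, so equalities of the form θ_inv = 255 − 1 − θ hold exactly only
for dense histograms, and the tests check criterion-value equality
instead. 16-bit histograms are supported at full depth (65536 bins) even
though the classical plugin implementations are 8-bit only; 8-bit
behaviour is unchanged by this extension.

## The phantom generator

Real stacks of the kind this toolkit targets are not shippable, so the
`synth` module generates calibrated phantoms whose ground truth is known
*by construction*:

- nuclei are ellipsoidal intensity plateaus with a cosine falloff rim
  (`edge` = falloff extent in normalised radius; `edge = 1` gives hard
  shells);
- truth label k is the voxel set where nucleus k's *noiseless,
  unattenuated* field reaches the iso level after quantisation — haze,
  droplets, attenuation and noise corrupt only the image, never the
  truth;
- confounders emulate the classic failure modes: a diffuse haze halo
  (free unincorporated label around chromatin), droplet blobs attached to
  or detached from nuclei (lipid droplets), exponential per-slice
  attenuation `exp(−α(z−1))`, and Gaussian read noise (Poisson
  optional — Gaussian is the default because the tests need controlled,
  not photorealistic, corruption);
- everything is reproducible from a single `rng_seed`, and generation
  restores the session RNG state.

Default parameter choices (8-bit depth, 0.25 × 0.25 × 1 µm calibration,
peaks ≈ 200, iso level ≈ 100, nuclei spanning ~8–16 slices) mirror
ordinary confocal practice: sub-micron lateral sampling with coarser
axial steps, and objects about half saturation with background well
below.

`standard_fixtures()` pins six named worlds (clean-nuclei,
attached-droplet, free-histone, low-contrast, deep-attenuated,
merge-bridge); the deep-attenuated fixture is constructed so the deep
nucleus's attenuated intensities (≈ 68–94) fall entirely below the
shallow threshold (120) but above the deep threshold (60), making dual
thresholding exactly right and a single global threshold provably
insufficient, and the merge-bridge fixture offsets its two nuclei axially
so their cross-sections coexist — and hence can merge — only on the
three bridge slices.

**What a green test does not establish.** Phantoms have piecewise-smooth
intensity profiles, no point-spread blur, no chromatin texture and no
spatially correlated noise. Passing the suite demonstrates that the
algorithms implement their definitions and that the analytic identities
hold; it does not certify segmentation accuracy on real microscopy data,
which is exactly why the benchmarking half of the package exists.

## Other numerical choices

- Label assignment order in connected-component labelling is the scan
  order of each component's first voxel (y fastest, then x, then z) —
  deterministic, so reports are reproducible.
- Labelled TIFF output picks 16-bit when the maximum label fits, else
  32-bit; read-back is bit-exact. Only uncompressed baseline TIFF is
  supported; compressed or exotic files are rejected with a format error
  rather than guessed at. Stacks with no calibration metadata default to
  1 µm isotropic with a warning (benchmarking is calibration-independent;
  volumetry is not, hence the warning rather than silence).
- CSV sidecars (seeds, ROI parameters, reports) use 1-based ImageJ-style
  coordinates and slice numbers. Benchmark CSVs put slices in columns
  (`slice1` … `sliceN`, then `stack`), with label groups encoded
  `owner=member;member` and groups joined by `|`.
- CLI exit statuses: 0 success, 1 data/validation error, 2 usage error;
  file outputs are written to a temporary name and renamed, so a crash
  never leaves a half-written artifact.

## Known limitations

- No ICS/LSM/OME input; convert to plain TIFF first.
- No boundary-distance metrics (Hausdorff, NSD) or Jaccard/Dice; the
  benchmark surface is precision/recall/F plus object correspondence.
- The wand traces 8-connected contours only (the ImageJ wand behaviour);
  4-connected tracing is not offered.
- Volumetry reports voxel count × voxel volume; no partial-volume or
  surface-area estimation.
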