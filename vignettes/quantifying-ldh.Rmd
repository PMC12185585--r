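---
title: "Quantifying lumbar disc herniation from axial keypoints and masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lumbar disc herniation from axial keypoints and masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldhquant)
```

## The measurement model and its assumptions

`ldhquant` turns two detector (or annotator) outputs — a binary disc mask
and nine anatomical keypoints — into a reproducible herniation grade and
region. The model is purely geometric:

1. Convert every coordinate to millimetres using the pixel spacing. Nothing
   downstream sees pixels, so anisotropic spacing and resampled images are
   handled uniformly. Intensities are never used by the geometry.
2. The straight chord through the two facet apices is the **inter-facet
   line**; the assumption is that the apices are reliably identifiable and
   that a straight chord (not the curved facet edge) is the clinically
   intended reference, as it is in the grading rule itself.
3. The signed distance of the posterior-most disc pixel center (the apex)
   from that line is the protrusion depth *D*; the spinous keypoint's
   perpendicular distance is the sagittal diameter *L*~sag~ of the
   posterior (ligamentum-flavum) zone; *I* = max(*D*, 0)/*L*~sag~.
4. The six boundary keypoints are projected perpendicularly onto the line
   and partition it into the seven Wiltse zones; the apex's along-line
   coordinate picks the region.

The grade thresholds (3 mm; index 0.3) encode the clinical rule: a disc
margin that stays more than 3 mm anterior of the line is normal (grade 0),
within 3 mm is grade 1, beyond the line is grade 2, and beyond with
*I* > 0.3 is grade 3.

Working per-slice is itself an assumption: each axial slice is quantified
independently, and multi-slice/3-D extent of a herniation is out of scope.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `near_mm` | mm | 3 | clinical near-line band of the grading rule |
| `index_cut` | — | 0.3 | grade-2/3 cut on the sagittal diameter index |
| canonical size | px | 512 | working frame all inputs are resampled to |
| crop margin | fraction/side | 0.1 | context kept around a stage-1 box |
| confidence threshold | — | 0.25 | minimum box score a locator must clear |
| orientation | — | radiological | image right = patient left; switchable |

All are surfaced through `ldh_config()` / `grading_thresholds()`; the CLI
takes a YAML file with CLI-flag precedence over file values over defaults.

## Conventions and numerical choices

- **Coordinates.** 0-based pixel indices, origin at the top-left pixel
  center, x = column (mediolateral), y = row, increasing posteriorly —
  the standard axial display with the spinous process at large y.
- **"Vertical intersection" of boundary points.** Boundary keypoints are
  moved to their *perpendicular foot* on the inter-facet line, not dropped
  along the image's vertical axis. Only the perpendicular reading is
  invariant under in-plane rotation of the patient, which is the stated
  purpose of the correction; the test suite checks rigid-motion invariance
  to 1e-6 mm.
- **Six boundary points, unbounded outer zones.** The zone edges between
  EFZ|FZ, FZ|SAZ and SAZ|CCZ on each side are annotated; the outer
  extraforaminal zones extend indefinitely. (Eight points including outer
  EFZ limits would also be defensible; six keeps every interval decision
  inside the annotated span.)
- **Apex at pixel centers.** *D* is a maximum over foreground pixel
  centers; sub-pixel contour interpolation is not attempted because the
  annotation itself is pixel-level. The recovery error is therefore bounded
  by half the pixel diagonal (0.354 mm at 0.5 mm/px).
- **Apex ties** break toward the most central apex (smallest |u|, then
  smallest u). The central canal is the most prevalent herniation site, so
  centrality is the least surprising deterministic choice.
- **Grade boundaries** are inclusive exactly as the rule reads: *D* = −3 mm
  and *D* = 0 are grade 1, *I* = 0.3 is grade 2. Grade is then monotone
  non-decreasing in *D* for fixed *L*~sag~.
- **Out-of-lattice pairs.** Geometry can produce e.g. (LFZ, grade 2) even
  though the category scheme says it cannot exist; the default policy
  clamps to grade 1, records `valid = FALSE` and warns, so the event is
  auditable. A `reject` policy raises instead.
- **Rasterization.** Polygons rasterize by an even-odd test at pixel
  centers with an *inclusive* boundary (a center exactly on an edge is
  foreground); an axis-aligned integer square (10,10)–(20,20) covers
  11 × 11 pixels. The tie rule is fixed and documented because downstream
  counts (IoU, apex search) depend on it.
- **Canonicalization.** Images are resampled to 512 × 512 (bilinear);
  points map by pure axis scaling and the spacing is rescaled by the
  inverse factors, so mm distances are preserved exactly (to float
  precision), not approximately. Intensity is min–max normalized to [0, 1];
  since no geometric quantity reads intensities, the simplest deterministic
  normalization wins.
- **Kappa.** Unweighted Cohen's κ (no linear/quadratic weighting, matching
  how the agreement scheme treats categories as nominal), asymptotic
  Fleiss–Cohen–Everitt SE with a symmetric 1.96·SE CI truncated to [−1, 1],
  and a null-variance z-test. A p-value below 0.01 is reported as "<0.01"
  in displays while the raw value is retained.
- **Precision/F1 averaging.** Support-weighted one-vs-rest averages over
  the classes present in the reference (macro available by flag). Weighted
  averaging keeps precision commensurate with accuracy on the heavily
  imbalanced category distributions typical of this task.

## The phantom generator

`phantom_spec()` / `make_phantom()` build an axial-slice stand-in: an
elliptical disc (default 55 × 15 mm semi-axes) whose posterior margin sits
6 mm anterior of the inter-facet line, facet apices 104 mm apart, a 20 mm
ligamentum-flavum diameter, and zone boundaries at ±12, ±24, ±40 mm — a
plausible adult lumbar geometry on a 512 px, 0.5 mm/px grid. A herniation
is added as a parabolic-cap posterior extension
`max(P_ell(u), D_target − (u − u_t)²/(2ρ))`: unlike a Gaussian bump added
to the ellipse profile, the cap's maximum is *exactly* `(u_t, D_target)`,
so the constructed truth is the analytic truth, not an approximation. The
whole construction is rotated/translated rigidly into the image, which
exercises the rotation invariance of the geometry on every phantom.

Keypoint jitter (Gaussian, in mm) models annotator/detector error; truth is
recorded pre-jitter. Cohort sampling draws categories from the shipped
reader-study distribution (`default_category_mix()`), apex depths uniformly
inside grade-consistent ranges that stay at least 1 mm away from every
grading boundary, and poses uniformly in ±15° / ±5 mm.

What the phantom does **not** emulate: MR texture, bias fields, partial
volume, osteophytes or sequestrated fragments, multi-level anatomy, or
correlated (structured) annotation error. Passing phantom tests therefore
demonstrates the correctness of the geometry, grading, bookkeeping and
evaluation arithmetic — not clinical detector performance, which requires
real annotated MRI.

## Problem sizes in the test and acceptance runs

The shipped checks use: a 90-phantom noise-free grid (all 18 categories ×
5 rigid poses, expecting 100% category round-trip), 100 random fixtures for
oracle equivalence of the apex search (96 × 96 grids, so the brute-force
double loop stays fast), and a 1000-phantom cohort at 0.5 mm keypoint
jitter for grade recovery (expecting ≥ 95% agreement away from decision
boundaries). These sizes give stable pass/fail behaviour at interactive
runtimes; nothing in the method depends on them.

## Known limitations

- Single-slice, single-disc: one disc per image (the most confident box
  wins); L1–S1 level naming and 3-D extent are out of scope.
- The DICOM reader is deliberately minimal (single-frame, explicit-VR
  little endian, uncompressed); series sorting and other transfer syntaxes
  are not supported — convert upstream if needed.
- No trained detectors ship with the package: the detector-stage contract,
  the oracle detectors and the file-replay detector exercise the pipeline;
  plugging in a learned model is the user's integration.
- The grade-0/grade-1 wording of the underlying clinical rule is
  ambiguous at the margin; the package fixes the reading in which grades
  are monotone in protrusion depth (see the grade table above) and keeps
  both thresholds configurable.
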