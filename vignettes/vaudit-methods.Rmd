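---
title: "Methods: film and array dosimetry audits with a global gamma index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: film and array dosimetry audits with a global gamma index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vaudit)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic test bed
does and does not demonstrate about real data.

## The audit problem

IMRT credentialing asks a narrow question: when an institution delivers its
own plan for a standardized C-shaped target to its own QA phantom, does the
measured dose distribution agree with the planned one within stated
criteria? The audit plan class prescribes 20 Gy in 10 fractions covering a
C-shaped target wrapped around a central avoidance structure, with a global
maximum below 110% of the fractional 2 Gy and the avoidance core below 60%.
A single fraction is delivered to the phantom; everything in this package
therefore works in absolute Gy per fraction. There is deliberately **no
normalisation step anywhere** — "no dataset scaling" is enforced
structurally, not by a flag.

## Dose-grid model and DICOM-RT

All dose distributions live on axis-aligned regular grids in the DICOM
patient coordinate system, millimetres, voxel-center convention
(`dose_grid_3d`, `dose_grid_2d`). Interpolation is bilinear/trilinear
everywhere; higher-order schemes were excluded on purpose so that linear
dose fields are reproduced exactly, which gives the test suite closed-form
oracles (`extract_plane` and `resample_plane` are exact on globally linear
fields to 1e-9 relative).

The DICOM layer is a minimal, audited subset of part-10 reading (explicit
and implicit VR little endian, nested sequences) sufficient for RT Dose
(dose-grid scaling, frame offsets, geometry) and RT Plan (isocenter,
fraction count, target prescription). Oblique orientations and non-uniform
frame offsets are *rejected*, not coerced: audit phantoms are scanned
axis-aligned, and a grid that is not is evidence of a mix-up upstream. The
synthesis side carries an independent writer, so reader round-trips are a
genuine cross-implementation check; one test additionally reads files
produced by a second, external DICOM implementation.

## Film pipeline

The measured film arrives as one composite scan: irradiated film plus at
least three calibration subfilms at nominal 0, 0.5 and 2 Gy, described by a
small layout file (rectangles in pixels, nominal doses). The steps, in
order:

1. **Red channel, verbatim.** 16 bits/channel RGB at nominally 150 dpi; the
   red channel is used with no smoothing or filtering (the tests assert
   bit-identity). The mm pitch comes from the file's resolution metadata,
   not an assumption; a mismatch against the expected 150 dpi is a warning,
   not an error.
2. **Optical density.** `OD = -log10(PV / 65535)` with pixel values clipped
   to ≥ 1. The white level as reference makes the unset-film subtraction
   absorb both the film-base density and the scanner response.
3. **Non-uniformity correction.** Scanner response is not uniform across
   the bed. If an unset (unexposed) film scan is supplied, its OD map —
   median-filtered 5×5, and only this correction map is ever filtered — is
   subtracted pixelwise, so any additive scanner field shared by the two
   scans cancels identically (tested to 1e-12). Without an unset scan, the
   scalar mean OD of the 0 Gy subfilm is the baseline; this cancels the
   mean response but not its spatial structure. Whether the original
   workflow used a map or a scalar is ambiguous in the source material;
   both are supported, the map is the default when available, and the
   choice is logged. Negative net ODs are sub-base noise: clipped to zero
   and counted, with an audit warning only when a sizable film region reads
   *systematically* (> 0.01 OD) below base.
4. **Calibration.** A third-degree polynomial maps net OD to dose. A cubic
   through three points is underdetermined, so the fit is constrained:
   `D(0) = 0` (anchored by the 0 Gy subfilm) and degree
   `min(3, n_points - 1)`. The canonical three-subfilm set yields a
   constrained quadratic; five or more points the full constrained cubic.
   This makes the fit deterministic and never underdetermined, degrading
   gracefully. The fitted curve must be strictly increasing over the fitted
   OD range — a non-monotone fit (e.g. doses decreasing with OD) is an
   error, not a warning. OD above the fitted range is evaluated by
   polynomial extrapolation; with noise, about half of the 2 Gy plateau
   pixels sit marginally above the top anchor, which is expected, so the
   audit only flags extrapolation *far* (> 0.02 OD) above the range.
5. **Registration.** Four fiducial marks, one near each film side, are
   found per side band by Otsu thresholding and connected-component
   labelling (EBImage); each mark is the intensity-weighted centroid of the
   strongest blob. A second candidate within 80% of the strongest mass is
   an error naming the side — an audit must fail loudly rather than guess.
   The isocenter is the intersection of the two lines joining opposite
   marks; the rotation is the mean angular deviation of those lines from
   the image axes, bounded at ±10° for sanity. The film dose is rotated
   back about the isocenter (bilinear) and re-centered so the isocenter is
   (0, 0); pixels leaving the film support become `NA` and are excluded
   downstream.
6. **Scoring.** The registered film is resampled to 1 mm (configurable) and
   scored as the reference against the planned plane extracted at the
   isocenter in the configured orientation (axial or coronal — declared,
   never auto-detected).

A plausibility check compares the median measured/planned dose ratio over
the high-dose region (≥ 50% of the denominator); a deviation beyond 5%
raises a `calibration-suspect` warning. This is what catches the documented
real-world failure mode of subfilms accidentally irradiated above their
nominal 2 Gy: the calibration then maps plateau ODs to systematically low
doses, the rate collapses, and the ratio check points at the calibration
rather than the delivery.

## Array pipeline

ArcCHECK is modeled as a helical lattice on a cylinder: 10 mm arc spacing
along the helix and 10 mm axial pitch between turns. The radius (104 mm)
and cylinder length are vendor constants, not protocol values; they are
overridable configuration recorded in every report. Analysis happens on the
unwrapped surface, `(u, v) = (r·θ, z)`, arc length zero at the posterior
column, z zero at the isocenter; the unwrap is an isometry along the
surface except across the seam at ±πr. The planned comparison plane is the
plan sampled trilinearly on a 1 mm unwrap lattice mapped back to the
cylinder.

Delta4 is modeled as two orthogonal planes through the isocenter, labelled
coronal and sagittal, 5 mm pitch inside the central 60 × 60 mm (boundary
inclusive) and 10 mm outside. Detectors on the shared axis line are
assigned to the coronal board only, so positions and ids are unique. Gamma
is computed per plane against the extracted isocenter plane, and the
passing rate is pooled over all evaluated detectors of both planes —
audits report one rate per dataset; whether the original analysis pooled
or gated per plane is unknown, pooling is this package's documented choice.

Measured data arrive in a text dialect this package defines (one
`id<TAB>dose_gy` line per detector after `key: value` headers): vendor
export formats vary too much to parse faithfully, and converters are out of
scope. Parsing is strict — malformed lines abort with the line number,
unknown and duplicate detector ids are validation errors.

## Gamma engine

Roles are fixed: **measured = reference** (the points that are scored),
**planned = evaluated** (the distribution searched). The threshold applies
to the reference dose and is a percentage of the same denominator as the
dose criterion; for `max` mode the denominator is the maximum of the
evaluated *plane* being compared (for Delta4, per plane). Points below
threshold carry `NA` gamma and do not enter the statistics. Both the γ ≤ 1
comparison and the rate ≥ tolerance comparison are inclusive.

The engine minimizes over a square lattice of candidate offsets within a
search cap (default 3·Δd), with the evaluated dose interpolated bilinearly.
The lattice step defaults to Δd/50. A coarser Δd/10 step was considered and
rejected: the lattice bias near the optimum is of order `(step/Δd)²/(2γ)`,
which at Δd/10 is a few 1e-3 γ units — visible against the exhaustive
oracle — while the distance-sorted early exit (stop as soon as the pure
distance term exceeds the current best γ²) makes the fine step essentially
free for passing points, whose search radius is a fraction of Δd. The
brute-force oracle (`gamma_bruteforce`) scans every candidate with no
ordering, pruning or early exit, and stays deliberately naive; the two
routes agreeing to 1e-3 on ≥ 99% of points over seeded random fields is a
standing test. Candidates outside the evaluated support (or touching an
`NA` cell) are skipped; a reference point whose entire search disc is
unsupported is reported `NA` and excluded.

## Synthetic study conditions

The generator's defaults are the study conditions, chosen once:

* **Target**: annular 270° arc, inner/outer radii 15/35 mm, Gaussian edge
  σ = 4 mm, 2 Gy plateau; longitudinal plateau half-length 20 mm with
  σ = 6 mm falloff; a broad low-dose bath (half the plateau, σ = 110 mm)
  stands in for entrance/exit dose so that surface detectors (ArcCHECK at
  r = 104 mm) see dose above the 10% threshold, as they do under real
  rotational deliveries. The analytic field satisfies the plan constraints
  (max < 110%, core < 60% of 2 Gy) by construction and is verified by test;
  it synthesizes a plan-*like* dose field, not a deliverable plan.
* **Film forward model**: `PV = 65535 · 10^-(OD_base + g + x(D))` with film
  base OD 0.05, a shared scanner gradient `g` (0.02 OD peak-to-peak), and
  `x(D)` the monotone inverse of the calibration truth
  `D(x) = 3.5x + 1.5x² + 2x³` (red-channel-like response, ~0.44 OD at
  2 Gy). Multiplicative Gaussian pixel noise, σ = 0.5%. The truth being a
  cubic while three subfilms support only a constrained quadratic
  reproduces a real and instructive ~0.7% mid-range calibration bias —
  exact at the 0/0.5/2 Gy anchors, hence invisible at the plateau.
* **Detectors**: additive Gaussian noise σ = 0.005 Gy.
* **Planted errors**: `subfilm_overdose` (layout still declares 2 Gy),
  `dose_scale`, `shift`, `rotation` — each maps to one documented failure
  mode of the credentialing literature.

Every writer is byte-deterministic under the scenario seed. Problem sizes
throughout (a 160 mm film-grid at 2 mm, a 230 mm array grid at 2.5 mm,
41×41 oracle fields, 20 calibration repetitions) were chosen as the
smallest sizes at which the respective property is cleanly exhibited.

What the synthetic bed does **not** emulate: film grain and scanning
artifacts beyond the stated noise, lateral scanner response beyond an
additive OD field, triple-channel dosimetry, detector angular response and
calibration factors, and real TPS dose calculation. Passing tests therefore
demonstrate the correctness of the *analysis* chain under controlled
conditions, not the clinical performance of any specific film or detector
model.

## Degenerate inputs and tie-breaks

* Grids with non-positive spacing, non-finite or negative dose never
  construct; errors are typed conditions (`vaudit_*_error`).
* A gamma analysis with no reference point above threshold is an
  `empty-analysis` error, not an empty result.
* Fiducial ambiguity (two comparable blobs) and missing marks abort naming
  the side; rotation beyond ±10° aborts.
* Exactly-on-boundary conventions: the Delta4 central zone is inclusive at
  |u| = |v| = 30 mm; γ = 1 passes; rate exactly at tolerance passes.
* The gamma search breaks candidate ties by first-found in
  distance-sorted order; the minimum value is order-independent.

## Known limitations

* Global gamma only, 2-D per comparison plane; no local gamma, no 3-D
  volumetric gamma.
* Film registration assumes four usable marks; there is no content-based
  (deformable or mutual-information) fallback.
* The DICOM subset reads well-formed explicit/implicit little-endian
  part-10 files only.
* The audit compares one delivered fraction; dose summation across beams
  or fractions is out of scope.
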