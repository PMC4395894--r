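---
title: "Corneal deformation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal deformation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`corvistk` turns a time sequence of Scheimpflug cross-sections of the cornea,
recorded while an air puff deforms the eye, into contours, deformation
components and scalar biomechanical parameters. This vignette is the package's
account of the underlying model, the numerical choices, and what the test
suite does and does not establish.

## Imaging model and coordinates

A recording is a stack of grayscale frames, by default 140 frames of
200 × 576 px taken every 231 μs (sampling rate ≈ 4329 Hz), with a spatial
calibration of 0.15 mm/px. Both calibration constants are configuration
values; nothing downstream hard-codes them.

Rows are numbered from 0 at the top of the image and increase downward;
columns from 0 at the left; frames from 0. All positions are pixel-centre
coordinates: the sample stored in row *r* sits at coordinate *r* and
integrates the scene over \[*r* − 0.5, *r* + 0.5). A contour value of 56.5
therefore means the edge lies exactly between the centres of rows 56 and 57.
The synthetic renderer uses the same convention (a pixel's intensity is the
exact coverage of the corneal band over its extent), which is what makes
sub-pixel contour tolerances meaningful.

## Contour detection

The cornea images as a bright band on a dark background, so the outer and
inner corneal surfaces are the strongest brightness transitions in each
column. Per column the detector:

1. smooths the intensity profile with a 3-tap binomial kernel (stabilises
   the argmax under sensor noise without displacing a symmetric edge),
2. takes the central-difference gradient along rows,
3. outer edge: the first local maximum of the rising (dark→bright) gradient
   scanning from the top that exceeds `min_gradient` (default 8 grey
   levels/px); ties go to the smaller row,
4. inner edge: the strongest falling peak within `max_thickness_px`
   (default 40 px) below the outer edge,
5. refines each peak by parabolic interpolation of the gradient at the peak
   and its two neighbours, clamped to ±0.5 px.

Columns that fail the threshold are flagged invalid; a frame with more than
half its columns invalid fails as a whole. Outliers — columns deviating more
than `jump_tol` (10 px) from the running median over `w_med` (11) columns —
are invalidated, and all invalid runs are filled by linear interpolation
(nearest-value extension at the edges). Whole failed frames (up to
`max_failed_frames`, default 5) are interpolated in time and flagged.

Polynomial approximation of the contour is deliberately not offered: a cubic
or quartic fit can manufacture contour segments where the data have none and
oversmooths the deformation waveform. The gradient operator sits behind a
single internal function, so alternative operators can be swapped in without
touching the pipeline.

## Deformation decomposition

With outer contour `y(t, x)`:

* **baseline** `b(x)`: mean of the first `baseline_frames` frames
  (default 10 — the puff in the synthetic schedule, and in typical
  recordings, begins no earlier than ~20 frames in; the instrument triggers
  recording slightly before the pulse);
* **full deformation** `d(t, x) = y(t, x) − b(x)`, positive inward (larger
  row = pushed away from the camera);
* **eyeball response** `e(t, x)`: per frame, the mean of `d` over the
  `scleral_margin` (50) leftmost and rightmost columns gives two anchors
  `L(t)`, `R(t)`; `e` interpolates linearly between the anchor centres. A
  scalar per frame cannot represent the tilt seen in real recordings, and
  the per-side anchors are exactly what the asymmetry parameters need, so
  the linear field is the simplest adequate model of rigid retraction plus
  tilt. Its corollary: any corneal deformation that does not vanish at the
  margins is partly absorbed into `e` — the synthetic tests demonstrate
  both the clean case and this leak;
* **corneal deformation** `c = d − e`, exact by construction;
* **vibration** `v`: per column, the temporal FFT of `c` with every bin
  below `cutoff_hz` (100) zeroed — including DC, so `v` has zero mean —
  and inverted. Conjugate symmetry is preserved, so `v` is real and there
  is no phase distortion, unlike an IIR high-pass. `c_low = c − v`.

Both identities `d = e + c` and `c = c_low + v` hold element-wise to machine
precision on every input, and every stage is linear; the suite asserts both
properties directly.

No temporal window is applied before the FFT: at 140 samples a window would
bias the amplitudes that the parameters report. The cost is spectral
leakage, which is treated as part of the contract: the test suite pins the
high-pass residue of a slow ramp to an explicit DFT-matrix oracle (the ramp
is a sawtooth to the DFT, and its Gibbs ripple in the pass band legitimately
reaches ~2 px at the window edges for a 5 px ramp).

The median filter of the original workflow (masks none/3/5/9/11/23, applied
to the frame × column deformation map with replicated edges, after which all
parameters are recomputed) is implemented as an exact median — an available
constant-time approximate filter was rejected because it quantizes — and
verified against a brute-force oracle.

## Biomechanical parameters

* **Applanation 1/2**: per frame, the applanation length is the longest run
  of consecutive columns (within ±150 columns of the apex) whose outer
  contour stays within `flatness_tol` (0.4 px) of its own least-squares
  line. The run search is a forward two-pointer sweep, which is exact under
  the assumption that sub-runs of a flat run are flat — true for the smooth
  contours seen here. The contour is boxcar-smoothed over 5 columns first;
  without it, sensor noise tightens the effective tolerance and can shift
  the event by a frame. Applanation 1 is the first frame at or before
  highest concavity whose run reaches `min_applanation_len_px` (60
  columns); applanation 2 the first such frame after. Velocity is the
  central-difference apex displacement rate at the event frame. The 0.4 px
  / 60 px defaults are package conventions pinned by the tests, not
  instrument constants.
* **Highest concavity**: the frame of maximal corneal deformation at the
  apex (the column where the corneal component peaks; for an undeformed
  field, the highest baseline point). The two flanking crests are the
  per-side minima of the contour row at that frame; their column distance
  is the peak distance, and an algebraic (Kasa) least-squares circle fit to
  the contour between them gives the radius, flagged infinite when the
  points are collinear. A geometric (iterative) circle refinement is out of
  scope; on exact arcs the algebraic fit is already exact.
* **Amplitudes**: maxima of the full, corneal and |corneal| fields; the
  eyeball amplitude is the maximum over frames of the mean eyeball
  displacement; the deformation difference is the extreme of the
  frame-to-frame difference of the corneal component.
* **Corneal length change**: polyline arc length of the outer contour
  (unit column spacing) minus the baseline's. Translation-invariant;
  validated against adaptive quadrature of the analytic profile.
* **Ratios**: maximum corneal deformation over maximum arc-length change,
  and over the baseline apex row. Both denominators are package
  conventions, recorded in the report's `conventions` block. A zero
  deformation yields 0; a vanishing denominator with nonzero deformation
  yields NA.
* **Vibration metrics**: maximum |v| and the count of frames whose
  column-maximum |v| exceeds `vibration_threshold_px` (0.5).
* **First harmonic**: the most *prominent* local maximum of the single-sided
  amplitude spectrum of `c` over all columns and bins ≥ 100 Hz, where
  prominence is the amplitude above the median of bins k ± 4 (excluding
  k ± 1). The choice needs explaining: the air-puff pulse itself — tens of
  pixels over tens of milliseconds — carries real spectral content above
  100 Hz that decays smoothly through the band at amplitudes (≈1.5 px near
  120 Hz, ≈0.2 px sidelobes through 250 Hz) well above a physiological
  vibration line of ~0.2 px. A global argmax, and even a bare local-max
  rule, therefore returns pulse tail features, not the harmonic; prominence
  separates a narrow line from the decaying background by an order of
  magnitude in the synthetic reference case. This is also why the maximum
  vibration amplitude (±1–2 px: pulse energy passing the 100 Hz cut) is an
  order of magnitude larger than the first-harmonic amplitude.
* **Asymmetry and side**: the anchor difference `L − R` at the frame where
  its magnitude peaks (so mirroring the image negates it); |score| below
  `side_threshold` (0.5 px) is "undetermined". Which anatomical side a
  positive score denotes is a labelling convention — the package has no
  basis to verify the anatomical mapping.
* **Pachymetry**: baseline inner-minus-outer contour distance at the apex,
  in px. This is a geometric image measurement, not the instrument's
  optical pachymetry, and is labelled as such in the report.
* **Unit conversion**: spatial × 0.15 mm/px, temporal × 0.231 ms/frame,
  rounding half away from zero at the requested precision. The worked
  examples (29 → 6.7 ms, 96 → 22.2 ms, 66.6 → 10 mm, 20.7 → 3.1 mm,
  0.2 → 0.03 mm, 323 → 74.6 ms) are asserted exactly.

## Synthetic sequences and what the tests show

The generator renders a circular-arc cornea (radius 450 px, apex row 50 —
chosen so the arc's own flatness run stays below the applanation criterion
while the band stays inside the frame), thickness 15 px, band intensity 200
on background 20, with three ground-truth components: a central inward
Gaussian bump (σ = 60 px) with raised-cosine temporal envelope, a linear
eyeball field with per-side peak translations, and a sinusoidal vibration
with Gaussian spatial profile and optional tapered active range. Additive
Gaussian noise (σ = 2 grey levels, clipped to [0, 255]) emulates the sensor;
the seed controls only the noise, never the ground truth. Anti-aliasing is
exact coverage, so the true edge position is well defined to arbitrary
precision.

`make_paper_like_config()` reproduces the magnitudes of the reference
recording: bump 66.6 px, vibration 309 Hz at 0.2 px (309 Hz sits essentially
on an FFT bin centre at 140 × 231 μs, minimising leakage), eyeball 29/19 px.
The envelope onset and offset are calibrated in closed form against the
analytic flatness window of the geometry so that the flatness-run criterion
is first met between frames 28/29 (inward) and 95/96 (outward) — i.e. the
detector should report applanations at frames 29 and 96, which the
end-to-end tests confirm from the rendered images.

Problem sizes in the suite were chosen once: property-style loops run on
64-frame, 120 × 240 px sequences (20 seeds for the additivity identity,
8 randomized draws for parameter recovery), and the reference-magnitude
checks run on the full 140-frame, 200 × 576 px geometry.

What the synthetic model does **not** emulate: real Scheimpflug optics
(refraction, depth-dependent blur), iris/lens structures behind the cornea,
speckle and illumination gradients, eyelid intrusions, or a physiological
relationship between puff pressure and deformation. Passing tests show the
*algorithms* recover known ground truth under realistic geometry and noise;
they do not validate clinical accuracy on patient data.

## Degenerate inputs and tie-breaks

Constant frames equalize to a single grey level; a constant column has no
edge; collinear contours give an infinite radius; an undeformed field
reports zero amplitudes and zero ratios; gradient ties resolve to the
smaller row; a flat static contour reports applanation at frame 0 with zero
velocity. Each of these is pinned by a test.

## Known limitations

* The eyeball model is linear in the column coordinate; a strongly curved
  scleral response would be misattributed to the cornea.
* Deformation components that do not vanish at the scleral margins leak
  into the eyeball estimate (quantified in the tests).
* The applanation thresholds are conventions; absolute comparability with
  instrument-reported applanation values is limited by that choice.
* The first-harmonic picker assumes the vibration is narrow-band relative
  to the pulse background; a broadband vibration would be attributed to the
  pulse tail.
* AVI support covers uncompressed 8-bit palettized and 24-bit DIB streams
  only — the variant the package itself writes; compressed exports must be
  converted to image directories first.
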