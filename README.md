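# corvistk

Corneal deformation analysis for air-puff (Corvis-type) tonometer image
sequences.

## The problem

An air-puff tonometer fires a calibrated air pulse at the eye and films the
corneal cross-section with an ultra-high-speed Scheimpflug camera — typically
140 frames of 200 × 576 px recorded every 231 μs. The instrument's own
software reports intraocular pressure and little else, yet the image sequence
contains far more: the full 3D history of the corneal deformation, the slower
whole-eye (eyeball) retraction, and high-frequency (>100 Hz) corneal
vibrations. `corvistk` extracts all of it automatically:

1. **Contour detection** — for every image column, the outer corneal edge is
   the first peak of the brightness gradient scanning from the top (the inner
   edge is the strongest opposite-polarity peak below it), refined to
   sub-pixel position by parabolic interpolation and repaired with a
   running-median outlier filter.
2. **Decomposition** — with the outer contour `y(t, x)` and its pre-puff
   baseline `b(x)` (mean of the first *K* frames), the full deformation is
   `d(t, x) = y(t, x) − b(x)`. A per-frame linear field anchored at the two
   scleral margins models the eyeball response `e(t, x)`; the corneal
   deformation is the exact remainder `c(t, x) = d − e`. A temporal FFT
   high-pass (all bins below 100 Hz zeroed) splits `c` into a slow component
   and the vibration `v(t, x)`, so `d = e + c` and `c = c_low + v` hold to
   machine precision.
3. **Parameters** — applanation 1/2 time, length and velocity (flatness-run
   criterion on the apex region), highest-concavity time, peak distance and
   concave radius (algebraic circle fit), deformation amplitudes, corneal
   arc-length changes and ratios, vibration amplitude/duration, the first
   harmonic (most prominent spectral line ≥100 Hz), scleral asymmetry and
   eye-side label — in px/frames and, via the 0.15 mm/px and 231 μs/frame
   calibration, in mm/ms.
4. **Synthetic sequences** — a renderer with exact ground truth (circular-arc
   cornea, Gaussian air-puff bump with raised-cosine envelope, eyeball
   translation/tilt, sinusoidal vibration, sensor noise) makes every stage
   testable without patient data.

Input is a directory of numbered JPEG/PNG frames or an uncompressed AVI;
results are cached next to the input (`.cdk`) so re-analysis is instant.

## Worked example

```r
library(corvistk)

cfg <- make_paper_like_config(seed = 1)   # reference-magnitude synthetic case
r   <- render_sequence(cfg)
an  <- analyze_sequence(r$sequence)
an$report
```

```
Biomechanical report (px/frames; converted values in $converted):
  applanation 1 / 2 time: 29 / 96 frames
  highest concavity time: 62 frames
  peak distance: 247 px, radius: 163 px
  max deformation (full/cornea/eyeball): 84.51 / 66.61 / 24.01 px
  first harmonic: 309.2 Hz, 0.197 px (resolution 30.9 Hz)
  vibration: max 1.600 px, duration 101 frames
  asymmetry: 9.145 px (left eye)
```

The two applanations at frames 29 and 96 convert to 6.7 ms and 22.2 ms; the
66.6 px maximum corneal deformation is 10 mm; the 0.197 px first harmonic at
309 Hz is 0.03 mm:

```r
convert_units(96, "temporal", decimals = 1)    # 22.2 (ms)
convert_units(66.6, "spatial", decimals = 1)   # 10  (mm)
```

The same pipeline runs from the shell:

```sh
Rscript inst/cli/corvis.R simulate --out sim --paper-like --seed 1
Rscript inst/cli/corvis.R analyze  --input sim/frames --out results
Rscript inst/cli/corvis.R convert 96 --axis temporal   # 22.2 ms
```

`analyze` writes `report.json`/`report.csv`, per-component deformation maps
and spectra as CSV, and a summary panel figure.

## Scope

No intraocular-pressure estimation (internal to the device), no GUI, no
clinical interpretation or population statistics. See the methods vignette
(`vignettes/corvis-deformation-analysis.Rmd`) for the model, parameter
defaults and limitations.
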