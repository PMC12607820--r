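---
title: "Markerless video stabilometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless video stabilometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaybalance)
```

## What the package measures

Quiet-stance balance is conventionally quantified from the centre of
pressure (COP), the application point of the ground-reaction force
recorded by a force plate, because the centre of mass (COM) itself is
hard to measure directly.  `swaybalance` implements a low-cost
alternative: a static camera films the standing subject against a plain
background, and the trunk's motion is segmented frame by frame.  Both
modalities are reduced to the same nine stabilometric parameters, so
their agreement (concurrent validity) can be quantified by correlation
and regression.

For a 2-D trajectory sampled at rate $f$ (either the silhouette
centroid in pixels or the COP in mm), with per-step increments
$d_a[i]$ along axis $a \in \{x, y, r\}$ (mediolateral, anteroposterior,
radial with $d_r = \sqrt{d_x^2 + d_y^2}$), the parameters are

* $V_{mean,a} = \mathrm{mean}(|d_a| \cdot f)$ — average oscillation
  velocity (units/s),
* $V_{std,a} = \mathrm{sd}(|d_a| \cdot f)$ — variability of the
  instantaneous speed (sample SD, $n-1$),
* $C_{total,a} = \sum |d_a|$ — total path length (units).

These definitions force $V_{mean,a} \cdot T = C_{total,a}$ for trial
duration $T$, which the test suite asserts to $10^{-9}$ relative on
random inputs.  Two readings of the field's loose phrasing were
resolved deliberately: "mean velocity" is the mean *absolute* step
velocity (the signed mean of zero-mean sway is identically zero and
clinically empty), and "standard deviation velocity" is the SD of the
speed series rather than of position, because the quantity is named a
velocity.  "Total displacement" is cumulative path length, not range,
which is what makes the $V_{mean} \cdot T$ identity hold.

## The video chain

1. **Crop and normalize.** A user-supplied rectangular region of
   interest (0-based, half-open bounds) isolates the trunk; each frame
   is then independently min–max normalized to $[0,1]$.  Per-frame
   normalization neutralizes global flicker and auto-exposure drift,
   which is the stated purpose of the normalization step; a global
   scheme would preserve slow luminance trends instead.
2. **Frame differencing.** A pixel is *moving* when the absolute
   intensity change between consecutive frames exceeds the threshold
   (default 0.15 on the $[0,1]$ scale).  A difference exactly equal to
   the threshold counts as static — a measure-zero event fixed for
   determinism.
3. **Morphological denoising.** Opening (disc, radius
   `morph_open_radius`), closing (disc, radius `morph_close_radius`,
   default 2), then removal of 8-connected components below
   `min_component_area` px (default 20).
4. **Centroid tracking.** The centroid (mean row/column of moving
   pixels) of the mask from frames $(i-1, i)$ is the COM sample for
   frame $i$: $N$ frames give $N-1$ samples at the frame rate.  Image
   axes are reported as-is: $x$ = column = mediolateral; $y$ = row,
   which in a frontal view mixes vertical motion with anteroposterior
   sway — the method's own proxy, left to the user to interpret.

**Why opening defaults to radius 0.**  Between consecutive frames at
30 fps, band-limited sway typically moves the silhouette by a fraction
of a pixel.  The pixels that can exceed a fixed threshold $\tau$ under
a sub-pixel shift $d$ are those where $|\nabla I| \cdot d > \tau$, and
since intensity is bounded by 1, the changed band along the gradient
direction is at most $\sim d/\tau$ px wide — one or two pixels.  Any
opening erases bands thinner than its diameter, so a radius-1 opening
systematically deletes the entire sub-pixel motion signal (measured
end-to-end tracking correlation drops from >0.98 to ~0.5).  The
component-area filter already removes isolated specks, which is the
purpose opening would serve.  Opening remains available for high-noise
footage where motion between frames is several pixels.

**Empty masks.**  When nothing moves above threshold, the default
`carry_forward` policy repeats the last valid centroid (leading gaps
are back-filled); `mark_missing` interpolates linearly instead and is
provided for sensitivity analysis.  A trial in which *every* mask is
empty raises an error suggesting a threshold or texture review.

## The force-plate chain

COP recordings (mm, two channels) are expected at 100 Hz and
conditioned with a fourth-order low-pass Butterworth at 10 Hz.  Whether
the original analysis filtered causally or with zero phase is not
documented; both modes are implemented, and zero-phase
(forward–backward) is the default because phase lag would distort
sample-level comparisons — at the cost of squaring the magnitude
response, so the gain at the cutoff is 0.5 rather than $1/\sqrt{2}$.
The test suite checks the measured gains (1.000 at 1 Hz, 0.500 at
10 Hz, <0.01 at 30 Hz) against the analytic response.  Edge handling is
odd-reflection padding of $3(n+1)$ samples with the filter state
initialised at steady state for the first padded sample; this makes
results bit-reproducible and keeps startup transients off the data
(variance is never amplified, asserted on random inputs).

Pixel measurements can be converted to mm by an explicit
`mm_per_pixel` calibration factor (e.g. a metre stick spanning a known
pixel count).  No exact calibration recipe is prescribed by the
original method; all correlation-based validity statistics are
scale-invariant, so the factor affects only the units of reported
parameters, never the validity conclusions.

## The statistics workflow

Per stance condition, `run_validation()`:

1. compares every image parameter between groups with the Mann–Whitney
   U test (exact p from the null U distribution for tie-free groups
   with $n_1 n_2 \le 400$, otherwise normal approximation with
   continuity and tie correction; the exact route is verified against
   full enumeration of rank assignments for all $n_1, n_2 \le 8$);
2. screens every parameter with Shapiro–Wilk and log-transforms
   non-normal ones (natural log; zeros offset by the smallest positive
   value, recorded).  Skewness, kurtosis and CV are reported
   descriptively but do not gate the verdict, keeping the decision a
   deterministic function of one statistic and one cutoff;
3. computes the full image-by-plate Pearson correlation matrix with
   strength labels (|r| bands of 0.2, right-closed, "very weak" to
   "very strong"), both pooled and within the atypical group alone —
   pooling two groups of different sway magnitude can inflate r, so
   both views are reported;
4. selects predictors per plate outcome (|r| > 0.25 and p < 0.05;
   among pairs intercorrelated above 0.80 the weaker outcome correlate
   is dropped, ties broken by canonical column order) and fits an
   Enter-method OLS with all survivors, labelling $R^2$ by Cohen's
   bands (0.02 / 0.13 / 0.26).  A single survivor yields a simple
   regression, which is the only reading consistent with the selection
   rule; $R^2 = r^2$ is asserted to $10^{-12}$ there.

No multiple-testing correction is applied, matching the source
workflow; a Benjamini–Hochberg column can be added by the user from
the raw p-values in `correlations.csv`.

## The synthetic cohort generator

The generator exists so the entire chain can be exercised with known
ground truth.  Sway per axis is **band-limited Gaussian noise**: white
noise filtered (zero-phase, corner at 80% of the declared bandwidth so
the stated band genuinely contains >95% of realized power), mean
centred, rescaled so the sample SD equals the requested amplitude
exactly.  This is the simplest stationary model with independently
controllable amplitude and bandwidth — a deliberate *non*-claim about
physiology (no rambling/trembling decomposition, no intermittent
control), because the quantities under test are stationary summaries.

Key defaults and why:

* `duration_s = 30`, `rate_hz = 30` — the standard trial length and a
  smartphone-typical frame rate (the source camera's rate is not
  documented).
* `bandwidth_hz = 2` — postural sway power concentrates below ~1 Hz in
  healthy adults but extends toward 2 Hz in children and in cerebral
  palsy; 2 Hz also keeps inter-frame displacement at 30 fps comparable
  to the pixel pitch of the deliberately small test frames, so the
  test surface exercises the detector in its intended regime.
* Renderer: ellipse of intensity 0.45 on a 0.95 background with a
  rigid sinusoidal texture (contrast 0.45, period 5 px) and a ~1 px
  anti-aliased edge emulating camera point-spread blur.  A hard-edged,
  weakly textured blob is *not* a faithful camera model: under
  sub-pixel motion it changes almost no pixel by more than 0.15, which
  real optics do not exhibit.  Texture and softness are configurable,
  including texture 0 (edge-only signal) and softness 0 (binary edge).
* Cohort structure: two groups (atypical "cp" at
  `cp_amplitude_multiplier` = 2 by default vs control) by four stance
  conditions (eyes open/closed crossed with feet apart/together,
  multipliers 1 / 1.3 / 1.6 / 2 — sway grows with task difficulty).
  Subjects carry a trait-like lognormal amplitude factor
  (`subject_amplitude_sdlog` = 0.35, truncated at ±2 SD): without
  between-subject variability the true within-group variance is zero
  and cohort-level correlations are degenerate.
* COP coupling: the COM trajectory linearly interpolated to 100 Hz,
  scaled by `pixel_to_mm`, plus white coupling noise (the dial that
  sets the ground-truth video–plate association) plus a supra-cutoff
  30 Hz tremor that the Butterworth stage must remove.
* When rendering, a trial whose Gaussian extremes would leave the
  frame is shrunk minimally to fit; the shrunk trajectory *is* that
  trial's ground truth (its COP is generated from it), so comparisons
  remain exact.

What passing synthetic tests do **not** show: robustness to cluttered
or moving backgrounds, shadows, clothing deformation, camera shake,
perspective and lens distortion, or genuinely pathological sway
dynamics.  The generator's videos are easier than real footage in all
these respects; results on synthetic cohorts certify the computational
chain, not field performance.

## Numerical choices and degenerate inputs

* Threshold ties classify as static; constant frames normalize to
  zero instead of dividing by zero; constant samples are rejected by
  the normality and correlation routines with explicit errors.
* 8-connectivity for component areas is obtained by merging
  4-connected labels that touch diagonally (union–find over the label
  graph).
* Trajectories shorter than 2 samples, empty groups, rank-deficient
  regression designs and out-of-bounds ROIs all raise informative
  errors naming the offending field or key.
* All generators are pure functions of `(parameters, seed)` and
  restore the caller's RNG state.

## Problem sizes used by the tests

The default test and verification runs use 10-s trials at 64×96 px to
96×128 px frames, cohorts of up to 20+20 subjects across four
conditions (160 rendered trials), 100-cohort detection-rate
simulations at the parameter level, and 1000-replicate null
simulations for the rank test — sizes chosen so the full suite
completes in minutes on a single core while leaving every statistical
assertion comfortably powered.

## File formats

Videos are read and written as RIFF/AVI containers holding
uncompressed 24-bit frames ("full frames" DIB), the one video format
that needs no codec library; MP4 input must be re-encoded first
(`ffmpeg -i in.mp4 -vcodec rawvideo -pix_fmt bgr24 out.avi`).  COP
recordings, trajectories and parameter tables travel as plain CSV with
documented column names (`time_s`, `cop_x_mm`, `cop_y_mm`;
`Vmean_COMx` … `Ctotal_COPr`).  Pipeline runs are driven by YAML
configs and leave a JSON manifest (package version, full config, input
checksums) beside their outputs.

## Known limitations

* The anteroposterior image axis is a proxy; a frontal camera cannot
  separate vertical from fore–aft motion.
* No automatic ROI/person detection, no pose estimation, no
  multi-camera fusion — by design.
* Test–retest reliability of the video method is outside scope, as is
  computing COP from raw force/moment channels.
* Compressed video decoding requires external re-encoding.
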