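---
title: "How fishbeat derives a heart rate from a bright-field well video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How fishbeat derives a heart rate from a bright-field well video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3)
set.seed(1)
```

fishbeat measures the heart rate of embryonic zebrafish (~2 days
post-fertilization) recorded in bright field, several embryos to a
microplate well, without anesthesia, restraint, fluorescent reporters or
manual positioning. The measurable signal is simple: heart tissue is more
opaque than the static background it beats against, so within a small
region of interest (ROI) over the heart, each contraction raises the mean
pixel intensity and each relaxation lowers it. A 10 s video at 16.5
frames/s therefore yields, per embryo, a ~165-point intensity series
oscillating at the heart rate, and the rate is read off the dominant peak
of its Fourier spectrum. Everything else in the package exists to place
that ROI automatically and to make the spectral readout robust.

```{r pipeline}
library(fishbeat)
spec <- phantom_spec(embryos = list(
  phantom_embryo(center = c(180, 180), theta = 0.4, f_true = 2.0),
  phantom_embryo(center = c(350, 330), theta = 3.5, f_true = 2.5)),
  noise_sd = 2, seed = 7)
ph <- generate_phantom(spec)
wr <- process_video(ph$stack, run_config(), well_id = "demo")
tidy(wr)
```

## Finding each embryo

Processing is restricted to the illuminated well interior
(`build_well_mask()`): the brightest circular region of the first frame is
fitted with a disc; if nothing convincingly circular exists, a centered
disc of radius `well_fraction` (default 0.95) times half the frame's short
side is used and flagged. Inside the well, embryos are dark objects on a
bright background. `segment_embryos()` thresholds the well-interior pixels
with Otsu's method (a fixed threshold can be configured), closes and
hole-fills the binary mask, labels 8-connected components, and then
removes everything that cannot be an embryo:

* components smaller than `min_area` (default 2000 px² at the reference
  3.24 µm/px, 2× magnification scale) — lint, dust, debris;
* components larger than `max_area` (default 200000 px²);
* components reaching within `boundary_margin` (default 5 px) of the well
  edge, where the darker wall shading corrupts both the threshold and the
  silhouette.

Kept blobs larger than `max_single_area` (default 30000 px²) are flagged
`merged-blob`: two overlapping embryos segment as one component, and ROI
placement on such a component is unreliable, so the flag travels with the
result rather than silently producing a bad rate. Surviving blobs are
numbered 1, 2, … by centroid position (top-to-bottom, then
left-to-right); these identifiers name the embryos everywhere downstream.
Segmentation uses the first frame only — the assay requires stationary
embryos, and the ROI placed once is applied to all frames.

## Locating the heart geometrically

The heart of a laterally- or ventrally-lying embryo sits on the ventral
surface, rostral to (toward the head from) the yolk sac. fishbeat
reconstructs this from the silhouette alone:

1. **Body axis.** `compute_feret()` finds the Feret diameter — the longest
   line between two boundary points, snout to tail tip. It is computed
   exactly on the convex hull of the boundary (the diameter of a point set
   is attained at hull vertices), with ties broken lexicographically.
2. **Yolk sac.** `find_yolk_circle()` takes the largest circular object
   inside the embryo to be the yolk, operationalized as the maximum
   inscribed circle of the mask: the center is the Euclidean
   distance-transform argmax (ties broken at the smallest `(row, col)`),
   the radius is that distance. We chose the distance transform over Hough
   circle detection deliberately — it is parameter-free and depends only
   on the silhouette, whereas Hough voting is fragile on the low-contrast
   interior texture of a bright-field embryo.
3. **Head side.** The yolk lies rostral of the body midline, so the
   perpendicular projection of the circle center onto the Feret line
   splits the diameter into a shorter (head) and longer (tail) segment.
   Projection onto the line is used rather than the circle–chord
   intersection points because it stays well-defined even when the chord
   misses the circle. An exactly central projection is reported as an
   `ambiguous-orientation` error rather than guessed.
4. **ROI.** A ray from the circle center toward the head endpoint crosses
   the circle perimeter at the tangency point. `place_roi()` puts a
   rectangle of width `scale_w × radius` (along the tangent) and height
   `scale_h × radius` (outward, away from the yolk) with its inner long
   edge tangent at that point, centered laterally on it. The defaults
   `scale_w = 1`, `scale_h = 1/3` size the ROI to cover mostly ventricular
   wall plus some static background; both are adjustable. Because every
   step is built from the blob's own landmarks, the construction is
   equivariant under rotation and translation — embryo orientation in the
   image plane does not matter, which the test suite verifies to half a
   pixel.

The rectangle is rasterized by pixel-center inclusion, and
`extract_intensity()` averages the fixed pixel set in every frame.

## From trace to beats per minute

Two signal steps separate the raw trace from a rate:

**Baseline drift correction** (`correct_baseline_drift()`). Illumination
and focus drift move the ROI baseline slowly relative to the beat. The
trace is cut into `segment_count = 10` contiguous segments (segment *i* of
an *N*-point trace covers indices ⌊(i−1)N/S⌋+1 … ⌊iN/S⌋, so 165 points
split 16/17 alternating); each segment after the first is shifted by the
difference between its mean and segment 1's mean. After correction all
segment means are equal to machine precision, which removes any
segment-constant (staircase) drift exactly and slow monotone drift to a
good approximation, while a ~2–3 Hz beat averages out of every ~1 s
segment mean and is untouched.

**Spectral estimation** (`estimate_heart_rate()`). The series is demeaned
(forcing the DC bin to zero), transformed with the FFT, and the magnitude
is scaled by the sampling interval Δt. The one-sided spectrum from 0 to
the Nyquist frequency (frame_rate/2) is searched only over bins whose
frequency corresponds to a biologically plausible embryonic zebrafish
rate — 50 to 200 bpm by default, both configurable — and the dominant
bin's frequency × 60 is the heart rate; ties go to the lowest frequency.
No window or peak interpolation is applied by default, so estimates are
quantized to the bin width 60·frame_rate/N = 6 bpm at 165 samples; an
optional parabolic refinement was considered and left out to keep the
estimator's quantization behavior transparent and exactly testable. A
constant trace is returned invalid with a `zero-signal` flag; an empty
search band is flagged `bounds`. The estimator is invariant under affine
intensity maps a·x + b (a > 0), so camera gain and offset are irrelevant.

`well_average()` gives the assay's unit of analysis: the mean rate over
all validly captured embryos in the well.

## The phantom generator

Because every stage is geometric or spectral, all of it can be tested on
synthetic wells with known ground truth (`phantom_spec()`,
`generate_phantom()`). A phantom renders: a bright well disc on a dark
plate; for each embryo a dark body ellipse, a darker yolk disc centered
on the body axis rostral of the midpoint (so the head side is the shorter
Feret segment, as in the real anatomy), and a small heart disc just
rostral of the yolk tangency point whose intensity oscillates as
baseline + amplitude·sin(2πf·t); optional dark dust specks; an optional
whole-frame drift offset (vector or function of time); and i.i.d.
Gaussian sensor noise, deterministic per seed. The default scene — 512 px
well, body semi-axes 80 × 28 px, yolk radius 32 px, heart radius 9 px,
intensities on a 0–255 scale with noise SD 2, 165 frames at 16.5
frames/s — matches the scale of the real acquisition at 3.24 µm/px with a
2× objective.

The heart is modeled as an *intensity*-oscillating disc rather than a
deforming chamber, because the measured signal is exactly a mean-opacity
oscillation; no pigmentation, defocus, or non-stationary embryo is
simulated. Passing phantom tests therefore certifies the geometry and
signal chain under the stated optics, not robustness to motion artifacts
or pigment interference, which only real videos can probe.
`random_phantom_spec()` draws embryo positions in jittered angular
sectors of the well rather than uniformly — uniform draws with a
no-overlap rejection rule become infeasible at smaller well sizes, and
real two-per-well layouts spread around the well anyway; overlapping
embryos are exercised by a deliberate fixture instead.

Test problem sizes: property suites and the acceptance checks run
phantoms at 256 × 256 px with all lengths halved and area gates quartered
(`phantom_detection_params()`); 100 two-embryo wells with true rates
drawn uniformly from 1.0–3.3 Hz are processed end-to-end, and ≥ 95% of
the 200 rates must land within one DFT bin (6 bpm) of truth. Geometric
operators are checked against brute-force oracles (all-pairs boundary
distances for the Feret diameter; exhaustive min-distance-to-background
for the inscribed circle) on dozens of random masks.

## Supporting statistics

`anova_sample_size()` works the assay's design arithmetic: effect size
d = expected effect / control SD (15/12 = 1.25 bpm/bpm), Cohen's
f = d/2 = 0.63 (two decimals, half-up), then the continuous per-group n
at which one-way-ANOVA power reaches the target, solved from the
noncentral-F distribution with noncentrality λ = f²·k·n by root-finding
on the power equation (n is continuous here by construction, hence values
like 7.03). The final well count adds one sample to ⌈n⌉ and a 25% loss
allowance: ⌈(8+1)·1.25⌉ = 12 wells/group. Among the rounding orders that
reach 12, this one is fixed and documented. `stats::power.anova.test`,
which parameterizes the noncentrality through the between-group variance
on a k−1 divisor, serves as an independent cross-check in the tests
(between.var = f²k/(k−1)).

`bland_altman()` quantifies method disagreement (bias, 1.96·SD limits of
agreement, and the fraction of exactly-zero differences — natural when
both methods quantize to the same 6 bpm grid);
`exclude_control_outliers()` applies the pre-registered ±2 pilot-SD
closed-interval rule, valid for control groups only; `potency_slope()`
returns the OLS slope, its SE and residual df of heart rate against
exposure concentration, the inputs a downstream comparison of potencies
needs.

## Limitations

The pipeline assumes stationary, laterally- or ventrally-oriented,
non-overlapping embryos on a bright, evenly lit well; it flags rather
than repairs violations (merged blobs, failed geometry, empty spectra).
It reports one rate per embryo per video — no arrhythmia,
beat-to-beat variability, or separate atrial/ventricular rates. Rates are
quantized to the DFT bin width, so a 10 s window resolves 6 bpm; longer
recordings sharpen this linearly. Deciding whether an embryo was alive,
in focus and morphologically normal remains a human call; the package
only reports its own detection and signal failures.
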