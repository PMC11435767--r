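---
title: "Methods: wavelet stroke segmentation and its validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet stroke segmentation and its validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokewave)
```

## The model

A rowing hull's forward acceleration repeats a stereotyped pattern every
stroke: a positive hump late in the recovery, a deep negative trough at the
catch (the recovery-to-drive transition), a positive peak during the drive,
and a negative valley as the blades extract. These landmarks define the
cycle start $C_S$, drive start $D_S$ and drive end $D_E$ of each stroke,
and thence drive time $DT = (D_E - D_S)/f_s$ and stroke time
$ST(i) = (D_E(i{+}1) - D_E(i))/f_s$.

Rather than tuning lowpass filters and amplitude thresholds per boat class,
the signal is decomposed with a 9-level undecimated wavelet transform using
the biorthogonal 4.4 filter pair. The undecimated (à-trous) construction
convolves the running approximation with the analysis filters upsampled by
$2^{j-1}$ at level $j$ and never downsamples, so every coefficient array
has the input's length and, after phase compensation, its timing. The
level-3 approximation $cA_3$ (passband roughly 0–12.5 Hz at 200 Hz
sampling) isolates the stroke-scale waveform for the trough and hump
searches; the slightly wider level-2 band $cA_2$ (0–25 Hz) retains enough
sharpness to place the post-drive valley.

Detection is a fixed cascade with no per-class tuning:

1. $D_S$ = peaks of $-cA_3$, subject to a minimum separation and a
   prominence floor;
2. consecutive $D_S$ indices segment the session; within each segment the
   *last* prominent peak of $cA_3$ (equivalently the first peak of the
   time-reversed segment) is the $C_S$ of the stroke whose trough closes
   the segment;
3. within each $[C_S(i), C_S(i{+}1))$ window, the global maximum of $cA_2$
   is the drive peak and the first sufficiently prominent local minimum
   after it is $D_E$, refined to the vertex of a local least-squares
   parabola.

"Reversed" admits two readings (negation vs time reversal). Negation is
used for $D_S$ — the stated intent is to find acceleration *minima* — and
time reversal for $C_S$, whose anatomical anchor is the last peak before
the catch; $D_E$ is operationalised directly from its anchor, "the minimum
after the peak drive acceleration". Each reading is isolated in its own
small function so the alternative could be swapped in one place.

## Transform details

* **Filters.** The biorthogonal 4/4 spline bank (10 taps). The analysis
  lowpass sums to $\sqrt 2$, so approximations are divided by $2^{L/2}$ to
  give unit DC gain: a constant signal maps to itself at every level, which
  keeps prominence heuristics level-independent.
* **Phase compensation.** Both analysis filters are linear-phase with
  integer symmetry centres (5 and 4 taps). A causal circular convolution
  therefore delays by exactly the centre index, and the level-$L$ lowpass
  cascade by $5(2^L - 1)$ samples; each coefficient array is rotated left
  by its cascade delay. Correctness is asserted by the impulse property
  (the aligned $|cA_L|$ peaks at the impulse for all $L$) and by a ramp
  passing through unchanged.
* **Padding.** The default mirror-extends the signal to the next multiple
  of $2^9$ so the circular wrap falls in reflected samples rather than
  splicing the session's end onto its start; `padding = "periodic"`
  transforms the signal as-is and is exactly shift-equivariant, which the
  property tests exploit. Samples within a cascade filter length
  ($\approx$ 2300 samples at level 9) of either boundary are
  boundary-affected in symmetric mode; interior samples reconstruct to
  machine precision via the redundant synthesis identity
  $x = \mathrm{shift}((cA * \tilde h + cD * \tilde g)/2)$ applied level by
  level.
* All 9 levels are computed even though only $cA_2$/$cA_3$ are consumed,
  mirroring the published procedure; the cost is negligible.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_separation_s` | 60/`max_stroke_rate_spm` = 1.0 | s | one cycle at the fastest admissible rate (60 spm); suppresses double-detection within a stroke |
| `min_prominence_frac` | 0.25 | – | prominence floor as a fraction of the coefficient's 5th–95th percentile span; scale-free, hence amplitude invariance |
| `refine_halfwidth_s` | 0.125 | s | half-width of the parabola fit that localises the broad drive-end valley; 0 disables |
| `levels`, `wavelet` | 9, `bior4.4` | – | fixed by the published procedure |
| `rise/fall_threshold_N` | 30 | N | force drive-time surrogate; the commercial algorithm's true thresholds are proprietary, these are explicitly non-canonical |

The accelerometer is expected at 200 Hz (±16 g); other rates are accepted
with a warning because the level-to-band mapping scales with $f_s$ and
would demand different approximation levels.

The drive-end minimum must clear the same relative prominence floor as
every other landmark. A literal parameter-free "first local minimum" is
untenable at realistic noise: residual noise in the 0–25 Hz band puts
shallow dips on the descending drive slope and produced ~400 ms drive-time
errors in development. The parabola refinement exists for the same reason —
the valley floor is flat, so the raw first-minimum index carries ~20 ms of
noise jitter that the vertex fit reduces to ~10 ms; both choices follow
from the noise analysis, not from fitting any acceptance number.

## The force reference

All gate forces are summed, one dominant peak per stroke is detected, and
the force-derived drive end $D_{EF}$ is the first positive-to-negative zero
crossing after the peak, linearly interpolated between the bracketing 50 Hz
samples (a raw-sample crossing would quantise at 20 ms against 5 ms
accelerometer events). Force stroke time is the consecutive difference of
$D_{EF}$. The drive-time surrogate thresholds each gate at 30 N around its
in-stroke peak and averages the per-gate drive times. Strokes are paired
across systems by nearest drive-end time within half the median force
stroke period, one-to-one; unmatched strokes are dropped and counted.

## Agreement battery

ICC is computed from the two-way ANOVA mean squares for $k = 2$ raters.
Sports-validation reports often conflate the one-way random-effects model
with the ICC(2,k) label even though ICC(2,k) is two-way random, so both
ICC(1,k) and ICC(2,k) (absolute agreement, average measures) are reported,
ICC(2,k) by default, each named explicitly. Confidence bounds follow the
McGraw–Wong F-distribution construction (Satterthwaite degrees of freedom
for the two-way model, Spearman–Brown conversion of the single-measure
bounds); the implementation reproduces the reference Python implementation
(`pingouin`) exactly on fixtures. Interpretation bands: below 0.50 poor,
0.50–0.75 moderate, 0.75 through 0.90 good, above 0.90 excellent (0.90
itself reads "good" under the literal inequalities). Bland–Altman
differences are taken accelerometer-minus-force (candidate minus
criterion), fixed in configuration; limits of agreement are
$\mathrm{bias} \pm 1.96\,\mathrm{SD}$ with the sample SD. Regression is OLS
of the accelerometer measure on the force measure (criterion as predictor);
$r^2$ equals the squared Pearson correlation.

## What the synthetic generator does and does not establish

Each stroke is a sum of four narrow Gaussian bumps (hump +1.5, trough −4,
drive peak +2.5, valley −1 m/s²) placed by per-stroke periods drawn from
the boat-class stroke-rate distribution, plus white Gaussian noise
(0.3 m/s²). Bumps sit ≥3σ apart so the noiseless composite's extrema
coincide with the landmark centres to within a sample, giving exact ground
truth. Per-stroke drive fraction is 0.42 of the cycle with SD 0.015,
drawn independently of the period — drive and recovery durations vary
semi-independently in real rowing, and without this the drive-time
between-stroke variance would be unrealistically small. Gate forces are
half-sine pulses spanning each drive, peak 800 N (upper range of elite
women's sweep oarlock force), with per-gate onset jitter (SD 5 ms)
emulating imperfect crew synchronisation; the sine continues past its zero
crossing to a 20% undershoot before relaxing to a −5 N recovery baseline,
so the crossing sits on a smooth inflection and interpolates cleanly. Boat
classes: W8+ (37.88 ± 1.46 spm, 8 gates, 221 strokes), W4− (36.72 ± 1.90,
4 gates, 183), W1x (31.90 ± 1.61, 2 gates, 181); scaled-down stroke counts
are used in time-budgeted tests.

A green cohort test establishes that the cascade recovers landmarks of the
*stated* waveform topology under white noise and rate/drive-fraction
variability. It does not establish performance on real water: swell and
drift, rigging vibration, per-crew waveform idiosyncrasies, and the true
spectral content of hull acceleration (never published per class) are all
outside the generator. Two further caveats. First, amplitude invariance
forces a scale-free prominence floor, and the lowpassed version of
matched-variance white noise has peak prominences comparable to its own
amplitude span — so pure noise yields some spurious "strokes" (well below
one per separation window) rather than none; no threshold can separate the
two without breaking scale invariance. Second, the threshold drive-time
surrogate is structurally shorter than the accelerometer drive time by
$(2/\pi)\,\mathrm{asin}(30/800) \approx 2.4\%$ per stroke (≈19 ms for the
slowest class), so the cross-system drive-time bias sits near the 20 ms
acceptance bound by geometry, not by noise.

## Numerical and convention choices

* Indices are 1-based (R convention); the time of sample $k$ is
  $t_0 + (k-1)/f_s$. CSV outputs carry both indices and seconds.
* Acceleration is SI (m/s²) internally; g-inputs are scaled by 9.80665.
* Plateau extrema resolve to their earliest sample; separation conflicts
  resolve tallest-first, earliest on ties. Detection is fully
  deterministic — all randomness lives in the generator, keyed by a single
  integer seed.
* Degenerate inputs degrade explicitly: no cycle-start peak falls back to
  the segment end, no drive-end minimum to the window midpoint (both
  logged); strokes violating the event-ordering invariant are dropped and
  counted; fewer than two troughs is a hard "no strokes" error.
* Zero between-subject variance flags the ICC as undefined rather than
  returning 0/0.

## Known limitations

* Only the `bior4.4` bank ships; the phase-compensation scheme assumes
  linear-phase filters with integer symmetry centres.
* The C_S search window is the inter-trough segment; a window centred on
  each trough (unspecified in the source procedure) could behave
  differently at extreme rate changes.
* The pairing heuristic assumes rates ≤ 60 spm; interleaved missed strokes
  degrade stroke-time pairs (consecutive-in-both-systems pairs only).
* Boundary strokes (first and last) are discarded by design; sessions
  shorter than three complete strokes yield no comparable metrics.
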