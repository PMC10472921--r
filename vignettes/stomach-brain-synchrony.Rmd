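---
title: "Quantifying stomach-brain phase synchrony with gastroSync"
author: "gastroSync authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stomach-brain phase synchrony with gastroSync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastroSync)
```

## The problem

The stomach generates a slow myoelectrical rhythm (the gastric slow wave,
about three cycles per minute) that can be recorded non-invasively with
cutaneous electrogastrography (EGG). A network of brain regions shows BOLD
fluctuations that are phase-locked to this rhythm. gastroSync implements a
complete, testable pipeline for estimating that coupling from concurrent
EGG-fMRI recordings: EGG preprocessing and quality grading, BOLD nuisance
control, voxelwise phase-locking with a circular-shift surrogate null,
group-level cluster-mass permutation inference, spatial-overlap spin tests,
confound-synchrony analyses, and a test-retest reliability battery. A
seeded synthetic-cohort generator reproduces the statistical structure the
analysis assumes, so every stage can be validated end to end without any
recorded data.

## The coupling measure

For a gastric phase series $\theta_x(t)$ and a voxel phase series
$\theta_y(t)$, both sampled on the volume grid, the phase-locking value is

$$\mathrm{PLV}_{x,y} \;=\; \left| \frac{1}{T} \sum_{t=1}^{T}
  e^{\,i\,(\theta_x(t) - \theta_y(t))} \right| ,$$

which is 1 when the two series hold a perfectly consistent phase lag and
falls toward $\sqrt{\pi}/(2\sqrt{T})$ for unrelated phases. Phases come
from the Hilbert transform of band-passed signals: the selected EGG channel
is filtered to its spectral peak $\pm 0.015$ Hz at 10 Hz, each voxel is
filtered with the same design at the BOLD rate ($1/\mathrm{TR}$), and the
gastric phase is then decimated to the volume grid. The first 15 volumes
(30 s at TR = 2 s) are excluded before the sum.

Because the PLV of any two narrow-band signals is biased away from zero,
the empirical value is referenced to a surrogate null: the gastric phase
series is circularly rotated on the full volume grid by every admissible
lag, the PLV is recomputed per rotation, and the per-voxel median of those
surrogate PLVs is subtracted ("PLV-delta"). Admissible lags keep the
surrogate at least 60 s away from the true alignment on either side, with
the 15-volume trim added to the guard; on this grid a 15-minute run yields
exactly 360 surrogates and a 10-minute run 210. Internally the whole
lag sweep is computed as one circular cross-correlation of unit phasors
via the FFT; the result is identical (to ~1e-12) to explicitly rotating,
trimming and re-averaging, which the test suite verifies against a
scalar-loop oracle.

## EGG preprocessing and quality grading

Spectra are estimated with Welch's method (200 s Hann windows, 150 s
overlap, resolution 1/200 Hz). The analysis channel is the one with the
largest spectral peak inside the normogastric band (0.033-0.066 Hz); when
the runner-up channel carries a strictly better quality grade it is
preferred, and an explicit override always wins. Recordings are graded on
three criteria -- a clear in-band peak, cross-channel agreement of the peak
frequency, and cross-run agreement -- onto levels 1 (all three), 2 (clear
peak with an inconsistency) and 3 (no clear peak; excluded from synchrony
analyses). The source text behind this battery does not quantify "clear"
or "consistent", so the package declares them: a peak is clear when it is
an interior local maximum whose power is at least 4 times the median
in-band power, and peaks are consistent within 0.01 Hz. Both thresholds
are exposed (`promThreshold`, `freqTol`) rather than hard-coded, and
consistency is judged among channels that themselves show a clear peak.

## BOLD preparation

Nuisance regression supports four documented variants: the strict recipe
(intercept, global signal, framewise displacement, six motion estimates,
their backward-difference derivatives, the squares of both, and six
aCompCor components), the same without the global signal, the strict
recipe plus six cardiac RETROICOR regressors built from pulse-oximetry
peaks, and a minimal recipe with CSF as the only regressor. The published
regressor list does not enumerate the expansion exactly; the package
scopes derivatives and squares to the six motion estimates and records the
realised column set in the design object. Residualisation is per-voxel
OLS; rank-deficient designs drop collinear columns with a warning.
Smoothing is a separable 3-D Gaussian (FWHM 3 mm by default) normalised by
the smoothed mask so edge voxels are not dimmed. The stage order --
regression, then smoothing, then gastric-band filtering -- is fixed; the
stages are not interchangeable and the order is recorded in the output.
Runs whose mean framewise displacement exceeds the group mean by more than
two group standard deviations are excluded, applied per run.

## Group inference

Run-level empirical and median-null PLV maps are averaged within subject,
and a paired t-map is formed across subjects. Clusters of $t > 2.3$ under
26-connectivity are scored by their mass (the sum of suprathreshold
t-values) and referenced to the maximum-mass distribution over 10,000
sign-flip permutations (each subject's difference map multiplied by an
independent random sign), with the +1-corrected permutation p-value.
Cluster-forming threshold, connectivity and the permutation count are
configurable; connectivity, sidedness (positive only) and the p-value
convention are declared defaults since the source analysis does not state
them. Spatial overlap between binary maps uses Dice similarity, and its
significance uses a hemisphere-symmetric spin test: a Haar-uniform random
rotation is applied to the right-hemisphere sphere and the sagittally
mirrored rotation ($x \to -x$) to the left, after which every vertex
inherits the label of its nearest rotated vertex. The inverse
nearest-neighbour convention preserves the labelled area in expectation;
a forward projection of labelled vertices was rejected because collisions
shrink the rotated map and bias the null Dice downward.

Two properties of this test are worth knowing. First, when the two maps
fail to overlap at all, the Dice statistic ties at zero with a large share
of the rotation null, and tie-counting makes the permutation p
conservative (it piles up at 1); with small maps zero overlap is common,
so calibration statements apply to maps large enough that the overlap is
almost surely positive. Second, because one rotation drives both
hemispheres (mirrored sagittally), the null preserves bilateral symmetry;
its exchangeability guarantee — hence exact uniformity of p under no
association — holds for bilaterally symmetric maps, which is the regime
the mirrored design targets. For asymmetric maps the test remains valid
but approximate. The calibration suite therefore uses symmetric random
patches covering 35% of each hemisphere.

## Confound synchrony and preprocessing variants

Ten nuisance series (CSF, white matter, global signal, framewise
displacement, three translations, three rotations) are each treated
exactly like a voxel -- band-passed around the gastric peak at the BOLD
rate, phase-extracted, compared to the gastric phase empirically and under
every circular shift -- because that is the only treatment that makes
their PLV comparable to the voxelwise one. Paired t-tests across runs
(Benjamini-Hochberg corrected across the ten series) flag synchronised
confounds, and Spearman correlations relate each confound's synchrony to
the brain-wide mean PLV-delta, computed once on minimally preprocessed
data and once after strict regression. The run, not the subject, is the
unit of correlation (configurable).

## The synthetic cohort

The generators emulate the data the pipeline expects, with ground truth
stored alongside:

* **Gastric oscillator** -- a sinusoid with Ornstein-Uhlenbeck phase
  drift, per-subject peak frequency drawn from N(0.05, 0.005) Hz truncated
  to the normogastric band. The drift defaults (stationary SD 1.3 rad,
  relaxation 150 s) were chosen once so that the two properties real
  recordings display are both present: the Welch peak is clear
  (prominence above 4 in essentially every seed) *and* the rhythm's phase
  decorrelates under circular shifts beyond 60 s (median self-surrogate
  PLV about 0.3). A much weaker drift would make every circular shift a
  near-perfect copy and void the surrogate null; a much stronger one would
  smear the spectral peak that channel selection relies on.
* **EGG channels** -- four channels share the oscillator at amplitudes
  (3, 2, 1.5, 1.2) with 1/f noise (best-channel SNR 8) and a weak 1.2 Hz
  cardiac bleed.
* **Coupled BOLD voxels** -- a centred block follows
  $\cos(\theta_g + \mathrm{lag} + A\cos(2\pi f_m t + \psi))$. The slow
  phase-modulation tone ($f_m = 0.005$ Hz, inside the gastric passband)
  realises a target PLV through the closed form
  $\mathrm{PLV} = |J_0(A)|$; an i.i.d. angular jitter would be broadband
  and stripped by the pipeline's own $\pm 0.015$ Hz filter, overshooting
  the target, whereas the in-band tone survives filtering and its time
  average converges to $J_0(A)$ deterministically. A zero target omits
  the gastric carrier entirely. Uncoupled voxels are AR(1)-plus-white
  noise ($\rho = 0.3$) mixed with five subject-specific latent time
  courses that give each subject a recognisable connectivity fingerprint.
* **Confounds and PPG** -- ten nuisance columns plus six aCompCor columns;
  with `confoundCoupling > 0` a gastric-locked motion artifact is injected
  into the global signal and the x-translation/x,z-rotation columns and
  shared with every BOLD voxel, and an independent gastric-locked series
  into CSF. The artifact dominates the motion columns (motion estimates
  measure the shared motion almost noise-free in real preprocessing), and
  its per-run amplitude is drawn from U(0.05, 1) so contamination spans
  negligible to strong across runs -- the between-run variability that the
  synchrony-versus-inflation correlation analyses presuppose. The PPG
  trace has Gaussian systolic pulses at known beat times (70 bpm, mild
  variability).
* **Stability switch** -- `subjectStability` controls whether peak
  frequency, coupling strength and the connectivity mixing are drawn once
  per subject or afresh per run, which is what the reliability battery
  recovers or correctly fails to recover.

What the generator does *not* emulate: biophysical gastric
electrophysiology, hemodynamic convolution, spatially structured noise,
susceptibility artifacts, or real head-motion dynamics. Passing tests
therefore show that the estimator chain is correct and calibrated under
the stated statistical structure, not that any particular empirical result
generalises to recorded data.

## Numerical choices

* FIR band-pass: Hamming-windowed sinc spanning six cycles of the peak
  frequency, applied with zero net phase shift (the effective kernel is
  the taps' autocorrelation) and reflect padding of one filter length;
  zero phase matters because a phase-shifting filter would bias the PLV.
* Resampling: explicit zero-phase anti-alias low-pass at 0.45 of the
  output rate, then integer decimation (rational ratios fall back to
  polyphase resampling).
* Hilbert transform: FFT method, no taper; edge samples are retained.
* Degenerate inputs are first-class: constant series have undefined phase
  and are refused (voxels) or flagged and excluded (confounds);
  zero-variance voxels get t = 0 with a flag; empty cluster sets are valid
  outcomes; Dice of two empty maps is defined as 0 with a message.
* Permutation p-values use the +1 correction and so never reach zero.
* The paired one-sample t over run-pair correlations reports df = number
  of pairs - 1 (1034 for 46 runs); published counterparts print 1033 for
  the same design, a convention difference we document rather than match.

## Problem sizes used in validation

The shipped suites run at desk scale, chosen once: null calibration uses
100 cohorts of 8 subjects on a 12x12x12 grid (450 volumes, 500 sign-flip
permutations); coupling recovery 20 cohorts of the same geometry with a
27-voxel block at target PLV 0.5; the confound-inflation contrast 20
eight-subject cohorts on an 8x8x8 grid; reliability 23-subject two-run
cohorts (15-minute runs, summarised within the detected significant
cluster) on a 6x6x6 grid plus 200 small cohorts for the fingerprint null;
spin calibration 200 repetitions on 1000-vertex spheres. The acceptance
script repeats the same computations at reduced replication counts and
reports the numbers it obtains.

## Known limitations

* The surrogate-referenced delta is not exactly symmetric under the null
  (the empirical PLV is one draw from a right-skewed family referenced to
  a median), so the sign-flip test can be mildly conservative; the
  calibration suite bounds the realised family-wise rate rather than
  assuming exactness.
* Cross-run heterogeneity is limited to 15- versus 10-minute runs via the
  per-run surrogate specification; richer designs (more than two runs,
  multi-session models, ICC variants) are out of scope.
* The spin test operates on synthetic or user-supplied sphere
  annotations; no real cortical surface geometry ships with the package.
```
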