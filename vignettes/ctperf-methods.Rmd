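---
title: "Methods: CNN-corrected arterial input functions for CT perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN-corrected arterial input functions for CT perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctperf)
```

## The model

Dynamic CT perfusion treats each brain voxel as a linear, stationary
system: the tissue contrast-concentration curve is the convolution of the
arterial input function (AIF) with a flow-scaled residue function,
`C(t) = Ca(t) ⊛ R(t)`. Deconvolution recovers `R`; its maximum is
proportional to cerebral blood flow (`CBF = scale · max R`, with
`scale = 6000` converting a per-second flow fraction to mL/100 g/min, i.e.
the 100·60 factor for per-100-g and per-minute units), and the time of the
maximum is `Tmax`, a marker of bolus delay. Core is thresholded at
relative CBF < 30% of a normal-tissue reference, penumbra at Tmax > 6 s;
the surrounding threshold families (20/30/38%, 4/6/8/10 s) are also
reported.

The AIF first passage is modelled by the gamma-variate function
`K (t − AT)^α exp(−(t − AT)/β)` for `t > AT`, zero before arrival. Its peak
sits at `AT + αβ` with value `K (αβ)^α e^{−α}`. A full arterial curve is
this first passage plus a delayed, dispersed second gamma passage
(recirculation).

The package's central component is a compact 1D convolutional network that
maps a raw, distorted, spline-interpolated 500-point AIF to its
gamma-variate-fitted counterpart, so that deconvolution always receives a
clean, parametric-shaped kernel.

## Assumptions

* Linearity and stationarity of the tissue response; attenuation change is
  proportional to contrast concentration (standard in CTP).
* The AIF describes every voxel's input up to delay and dispersion; only
  delay is modelled (the block-circulant formulation makes the estimates
  delay-insensitive).
* Tissue residues are exponential `exp(−t/MTT)` (default) or boxcar;
  both are standard simplifications.
* Relative CBF needs a reference. The paper-style "relative CBF" leaves
  the reference implicit; here it is the median CBF of the hemisphere
  contralateral to the lesion (identified as the one with the higher
  median), restricted to voxels with Tmax ≤ 6 s, falling back to the
  whole-brain median with a warning when everything is hypoperfused. This
  was a genuinely open design point; the contralateral-median rule is the
  package's documented choice.

## Deconvolution and its regularisation

`deconvolve()` solves the zero-padded block-circulant system
`ct = dt · A r` by truncated SVD. Padding to twice the curve length makes
the operator delay-insensitive, but it also makes the system inconsistent
whenever the convolution tail extends past the acquisition window; a
truncation threshold therefore has to balance fidelity against
wrap-around artifacts, and no single fixed threshold serves both noiseless
and noisy data (the classical fixed 0.15·σmax cut biases noiseless CBF by
30–50% here, which is why it is available but not the default).

The default rule is oscillation-index-adaptive truncation: thresholds on
an ascending ladder (10⁻⁴ … 0.5) are tried and the first whose residue has
oscillation index `Σ|Δ²R| / (M · max|R|)` below `oi_limit = 0.03` is kept.
The limit was calibrated once against forward-simulated noiseless voxels:
physiologic residue shapes score below 0.01 on the padded grid while
wrap-around and noise artifacts score above 0.05, so 0.03 separates the
two regimes. With it, worst-case noiseless CBF error over boxcar and
exponential residues (delays 0–10 s, MTT 4–8 s) is under 10%, and Tmax
lands within one frame of the true argmax. For boxcar residues the true
argmax is the whole plateau — any exact solver may return any point on
it — so Tmax accuracy is stated as distance to the argmax *set*.

Per-voxel baselines (mean of the frames before the AIF reaches 10% of its
peak) are subtracted before deconvolution; non-uniform time stamps are
linearly resampled to the median frame interval.

## The correction network

Architecture (as configured by `cnn_config()`): input 500 →
conv(kernel 2, 8 filters, ReLU) → conv(kernel 2, 16 filters, ReLU) →
average pooling (2) → flatten → dense(36) → dense(500) with softmax.
Training uses RMSprop (learning rate 0.001, decay 0.9), batch 32. The
filter counts and pool size are the package's own compact choices; the
parameter count (162,256) is therefore not meaningful to compare with any
particular reference implementation.

The softmax output is interpreted as a *normalised curve shape*: labels
are gamma-fit curves normalised to unit sum, the loss is the cross-entropy
between label and softmax output (reported as KL divergence so a perfect
fit scores zero), and at inference the shape is rescaled to physical units
by the input curve's first-pass area, computed after removing a linear
baseline fitted to the pre-arrival samples. Inputs are peak-normalised.
This reconciles a probability-map output head with a regression target,
and makes the amplitude convention explicit: the corrected AIF inherits
the measured first-pass area, so a globally attenuated bolus stays
attenuated — which is harmless downstream because core/penumbra thresholds
are relative.

Augmentation produces exactly three variants per source pair — mirrored,
rotated, mirrored+rotated — applied identically to input and label.
"Mirroring" is time reversal of the sampled curve: unlike reflection about
the peak with clipping, it is an exact involution, which is also what the
double-mirror identity demands. "Rotation" turns the axis-normalised
(t, value) polyline by an angle drawn uniformly in ±5° about its centroid
and re-interpolates onto the grid, clipping only rotation-induced
negatives. These are the package's concrete definitions of image-style
transforms for 1D curves.

Bolus landmark detection (`first_passage()`) underpins both labelling and
rescaling, so it is deliberately robust: landmarks are read off a lightly
smoothed curve; the first-pass peak is the *earliest* local maximum rising
at least half the global excursion above the early baseline (a drifting
baseline plus recirculation can otherwise out-peak a strongly attenuated
bolus); the window ends at washout to 20% of peak height or at a valley
confirmed by a genuine second passage.

## The digital phantom

`generate_phantom()` builds a 64×64×4 voxel brain (3×3×10 mm spacing,
≈ 1 L) with an ellipsoidal penumbra containing a core in one hemisphere
and a small arterial block in the other, sampled for 90 frames at 1 s.
The window length covers bolus washout — with recirculation arriving near
30 s and lesion delays up to 10 s, a shorter window leaves so much
convolution tail outside the acquisition that deconvolution of even
noiseless data becomes badly inconsistent. Tissue classes follow stroke
physiology: healthy CBF 60 mL/100 g/min, MTT 4 s, no delay; penumbra
30 / 8 s / 8 s; core 12 / 12 s / 10 s — so the standard thresholds recover
the built-in geometry. The clean AIF peaks at 10 a.u. (AT 5 s, α 3,
β 1.5 s) with a 20%-amplitude recirculation; Gaussian noise
(SD 0.02 a.u. by default) is added inside the brain. Identical seeds give
bit-identical phantoms.

Measured-AIF distortion follows the three error classes of real curves:
baseline drift and noise; multiplicative first-pass attenuation; and a
replaced, jittered recirculation passage. All-zero strengths reproduce the
input exactly. Synthetic severity scores are monotone links to the truth:
NIHSS = clamp(round(0.15 · penumbra mL)), ASPECTS = clamp(10 −
round(0.2 · core mL)), with optional noise — enough to exercise the
volume–score agreement statistics, with no claim of clinical realism.

What the phantom does *not* emulate: anatomy (no skull, gray/white
contrast, partial volume, beam hardening), spatially correlated CT noise,
patient motion, or dispersion of the bolus between artery and tissue.
Passing phantom tests therefore demonstrates the numerical correctness and
the qualitative rescue behaviour of the pipeline, not clinical accuracy.

## Study sizes and numerical choices

The shipped experiments use desk-scale sizes chosen once: a training bank
of 128 synthetic cases × 3 AIF candidates (384 sources, 1152 pairs after
augmentation), 50 training epochs, 102 held-out curves from unseen
generator seeds (34 cases × 3 — a three-AIF bank needs 34 cases to pass
100 curves), 20 phantoms for the paired branch comparison, 40 phantoms for
the score correlations, and 1000 replicates for the signed-rank null
calibration. The gamma-fit identity grid spans K ∈ {0.5, 1, 2},
AT ∈ {2, 5, 10} s, α ∈ {2, 3, 5}, β ∈ {1, 1.5, 3} s.

Other numerical decisions:

* Gamma fitting is bounded Levenberg–Marquardt least squares
  (`minpack.lm`), 500 iterations, parameter tolerance 1e-8, started from a
  log-linearisation of the model; the default window is the detected first
  passage, so recirculation never enters the fit. Degenerate (flat)
  curves are rejected; non-convergence returns best-so-far parameters
  with a warning.
* At a bolus signal-to-noise ratio of 20 (peak/σ), the shape and timing
  parameters (AT, α, β) and the fitted peak value are recoverable to
  better than 10% in median, but the raw scale factor K is not — its
  Cramér–Rao bound already exceeds 10% because K trades off against α and
  β along a near-flat ridge. Noise-robustness statements are therefore
  made about the identifiable quantities, not K.
* Ties in Tmax (`argmax R`) break to the earliest time. Lesion thresholds
  are strict inequalities. No morphological cleanup is applied to masks.
* Spearman correlation is Pearson on ranks (tie-corrected) with a
  t-approximation p-value; Bland–Altman limits use the n−1 sample SD;
  the signed-rank test drops zero differences and is exact up to 25
  untied differences, tie-corrected normal with continuity correction
  beyond. Two-sided p-values throughout.
* The AIF selector excludes voxels below 20% of the ROI peak, unit-area
  normalises, k-means (k = 5) on curves, keeps the cluster with the lowest
  mean first moment, recurses to ≤ 10 voxels or 5 rounds, and returns the
  three highest-peak survivors — the package's concrete instantiation of
  recursive-clustering AIF detection, with curve roughness as the
  tie-break.

## Known limitations

* Absolute CBF is nominal: CT concentrations are in arbitrary units and
  no hematocrit/density corrections are applied. All thresholds are
  relative, so this does not affect lesion volumes.
* Under heavy noise the adaptive truncation smooths aggressively and
  compresses CBF contrast; the phantom experiments show exactly this
  regime as the mechanism by which distorted AIFs erase the core.
* The network is trained on the synthetic distortion families above;
  distortions far outside them (e.g. step artifacts from motion) have no
  training support.
* A curve bank stores inputs and labels only; per-curve generator
  parameters stay in memory (`make_curve_bank()$meta`) and are not
  serialised.
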