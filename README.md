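# cestlab

Synthetic CEST-MRI phantoms and a denoising laboratory for R.

Chemical exchange saturation transfer (CEST) MRI measures dilute labile
protons through the water signal: saturating at a series of frequency
offsets yields a per-voxel *Z-spectrum* `Z(Δω) = M_z(Δω)/M_0`, and the
contrast of interest is the asymmetry

```
MTR_asym(Δω) = Z(−Δω) − Z(+Δω)   (averaged over a metabolite window, in %)
```

— a small difference of numbers near one, which makes CEST quantification
acutely noise-sensitive. `cestlab` provides everything needed to study
denoising for this modality without scanner data, for MR physicists and
image-analysis researchers:

* **Phantom simulation** — randomized layered 2D label maps; per-region
  2–5-pool systems drawn from protocol ranges (water T1 0.5–2.5 s, T2
  40–500 ms; solute T2 1–20 ms, exchange 50–4000 Hz, 0–800 mM, shifts
  0.5–5 ppm); voxel-wise Z-spectra from the multi-pool Bloch–McConnell
  equations `dM/dt = A·M + b` under trains of Gaussian saturation pulses,
  solved by exact matrix-exponential propagation (RcppArmadillo).
* **Noise model** — Gaussian noise of standard deviation σ added to the
  real and imaginary k-space channels (unitary FFT), magnitude
  reconstruction; robust wavelet-MAD noise estimation.
* **Analytical denoisers** — spectral PCA with *median*, *Nelson* and
  *Malinowski* component-selection criteria; non-local means
  (`NLM BW_21_SW_5` naming); two-pass BM3D (`BM3D WS_11_BS_4` naming).
* **Neural denoisers** — U-Net and residual U-Net autoencoders (offsets
  as channels) in noise-estimation (`NE-yes`, predicts the noise) and
  direct (`NE-no`) modes, with a pure-R/Rcpp training stack (exact
  backprop, Adam, ReduceLROnPlateau) — no external deep-learning
  dependency.
* **Evaluation** — pooled PSNR (`10·log10(1/MSE)`, MAX = 1), WASSR-style
  B0 self-correction, MTR_asym maps with per-ROI statistics, and a fully
  seeded benchmark harness (σ sweep × methods × phantoms).

## Worked example

```r
library(cestlab)

# 1. a 64x64 phantom: geometry, pool parameters, Bloch-McConnell render
lm      <- sample_label_map(1, grid = c(64, 64), n_layers = 12)
phantom <- sample_pool_maps(lm, rng_seed = 2)
clean   <- simulate_dataset(phantom, rng_seed = 3)
clean
#> CEST volume: 64 x 64 x 50 offsets [-4.34, 4.34] ppm, 1976 foreground voxels

# 2. corrupt with k-space noise at sigma = 0.1 and re-estimate sigma
noisy <- add_kspace_noise(clean, sigma = 0.1, seed = 4)
estimate_sigma(noisy)
#> [1] 0.1001813
psnr(clean, noisy)
#> [1] 18.21132

# 3. spectral PCA denoising with the median criterion
den <- pca_denoise(noisy, "median")
den$k
#> [1] 2
psnr(clean, den$volume)
#> [1] 19.71264

# 4. MTR_asym quantification over the creatine window
m <- mtr_asym_map(den$volume, range_ppm = c(1.5, 2.5))
m$roi_stats
#>    roi     mean       sd    n
#> 1 mask 4.373008 4.558969 1976
```

The noise estimator recovers the injected σ = 0.1 to 0.2%. On this small
phantom spectral PCA kept `k = 2` components and gained ~1.5 dB — at
desk scale the analytical methods are modest, mirroring the reference
benchmark where they trail the neural models; the MTR_asym mean of ~4%
reflects the solute pools this particular phantom drew. A
smoke-trained residual U-Net (see `smoke_train_config()` and the methods
vignette) gains ≥ 5 dB over the noisy baseline on held-out phantoms; the
full-scale training preset (`train_config()`: 30 epochs, batch 40,
lr 0.01, σ ~ U(0, 0.2), 41-of-50 offset crop) is unchanged from the
reference protocol and runs as-is on capable hardware.

A command-line interface covering generate / noisify / denoise /
evaluate / benchmark / train lives at `inst/cli/cest`; see
`?cestlab::cest_cli`.

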