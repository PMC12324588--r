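# flimpca

Noise-corrected PCA (NC-PCA) denoising and phasor analysis for
time-domain fluorescence lifetime imaging (FLIM).

FLIM records, per pixel, a photon-count histogram of the fluorescence decay
across `N` time bins inside one laser repetition period `T`. At the frame
counts compatible with live imaging, Poisson shot noise (variance = mean)
dominates the per-pixel decays, which broadens phasor distributions and
breaks per-pixel exponential fitting. This package denoises the
`n_pixels x n_bins` count matrix `X` by:

1. **Poisson-weighted scaling** `X'_{ij} = X_{ij} / sqrt(a_i b_j)`, with
   `a_i` the pixel mean and `b_j` the bin mean (stored for exact inversion),
   flattening the count-dependent noise variance;
2. **rank-k PCA reconstruction** (columns mean-centered, economy SVD,
   `k = 3` by default) — decays are low-rank across pixels, shot noise is
   not, so only ~`k/N` of the noise survives;
3. **inverse scaling** back to photon units (negatives clipped), followed by
   the same minimum-total-count threshold used by the thresholded (TPA) and
   median-filtered (FPA) phasor baselines, which are also provided.

Downstream analysis: the phasor transform
`G = Σ I_j cos(ω t_j) / Σ I_j`, `S = Σ I_j sin(ω t_j) / Σ I_j`
(`ω = 2πn/T`, bin-center times) with reference calibration, 2D phasor
histograms with FWHM/peak-separation analytics, NADH fraction-bound maps,
per-pixel single-exponential lifetime fitting, a synthetic FLIM cell
phantom with Poisson noise, and ground-truth fidelity metrics (per-pixel
SNR/MSE maps, median-ratio summaries, data-preservation maps).

## Worked example

Simulate the 200-photon phantom at desk scale, denoise, and measure
fidelity against the noise-free ground truth:

```r
library(flimpca)

sim <- simulate_phantom(shape = c(128, 128), count_level = 200, seed = 1)
den <- nc_pca_denoise(sim$noisy)
den
#> <denoise_result> k = 3 (poisson-weighted), 24.02% variance retained

raw_maps <- pixel_snr_mse(sim$noisy, sim$truth)
rec_maps <- pixel_snr_mse(den$reconstructed, sim$truth)
median(raw_maps$snr_db[raw_maps$valid])   # 1.97 dB
median(rec_maps$snr_db[rec_maps$valid])   # 20.59 dB
snr_ratio(rec_maps, raw_maps)             # 18.61 dB improvement
median(raw_maps$mse)                      # 0.829 photons^2
median(rec_maps$mse)                      # 0.0212 photons^2
mse_ratio(rec_maps, raw_maps)             # 0.0255  (~39x lower MSE)
```

The three retained components carry ~24% of the total variance of the
scaled matrix — the rest is the flat shot-noise spectrum that NC-PCA
discards — and the reconstruction raises the median per-pixel SNR by
~19 dB while cutting the median MSE ~40-fold at this photon level.

Phasor analysis of any stack (real stacks are read from multi-page TIFF
with a JSON metadata sidecar via `read_stack()`):

```r
pf <- phasor_transform(den$reconstructed)
h  <- phasor_histogram(pf)              # 256x256 over G in [0,1], S in [0,0.6]
fwhm_profile(h, axis = "G")             # linewidth through the peak
fraction_bound(pf)                      # per-pixel NADH fraction bound
```

A thin command-line wrapper (`simulate`, `denoise`, `phasor`, `metrics`,
`fit-exp`, `repro-fig2`, `repro-two-state`) ships at
`system.file("cli", "flim.R", package = "flimpca")`.

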