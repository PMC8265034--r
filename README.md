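# mrfepi

Joint quantitative mapping and white-matter lesion probability estimation
for magnetic resonance fingerprinting with an echo-planar readout
(MRF-EPI).

## The problem

MRF-EPI acquires a train of magnitude baseline images (35 frames here)
with varying flip angle, TE and TR; every voxel's signal evolution — its
*fingerprint* — encodes the relaxation times T1 and T2\*. The conventional
processing chain matches each voxel against a pre-computed dictionary of
simulated fingerprints over a (T1, T2\*, B1+) grid, after Marchenko–Pastur
PCA denoising, and then segments tissue and white-matter lesions in
separate steps. This package implements that chain **and** the deep-learning
shortcut it is compared against: a multi-output regression U-net that maps
the 35 baseline images directly to five channels — T1, T2\*, and NAWM-,
GM- and lesion-probability maps — in one pass. It is aimed at quantitative
MRI researchers who want a self-contained, fully seeded sandbox for the
method: a digital brain phantom with MS-like lesions supplies every
ground-truth map, so the whole pipeline runs without patient data.

## What is inside

* **Signal model** — spoiled gradient-echo recursion with inversion
  preparation:
  `s_i = |Mz⁻(i)| · sin(b1·α_i) · exp(−TE_i/T2*) · M0`,
  `Mz⁻(i+1) = 1 + (Mz⁻(i)·cos(b1·α_i) − 1) · exp(−TR_i/T1)`,
  over a 35-frame schedule spanning α 34–86°, TE 16–76.5 ms,
  TR 3530–6370 ms.
* **Digital phantom** — concentric-ellipsoid brain (CSF rim, GM ribbon, WM,
  ventricles), soft probability maps, Poisson-count ellipsoidal lesions
  that raise T1/T2\* by 10–60 %, smooth B1+ field, Rician noise.
* **Dictionary matching** — T1 300–3500 ms and T2\* 10–2500 ms in exact 5 %
  geometric steps, B1+ scale 0.6–1.4 in steps of 0.1; maximal normalized
  inner product, verified against a brute-force oracle.
* **MPPCA denoising** — sliding-window PCA with Marchenko–Pastur rank and
  noise estimation.
* **U-net** — encoder depth 3, eight variants (MSE/MAE/LCL/DICE losses ×
  5-channel or lesion-only output, plus a 2-channel reference network),
  patch training with lesion-slice augmentation, collapse detection for
  runs that converge to empty lesion predictions. Convolutions and
  backpropagation are implemented in compiled code (no external DL
  framework), gradient-checked against finite differences.
* **Evaluation** — dice, lesion detection rate, threshold sweeps,
  per-lesion statistics, relaxation-increase profiles.
* **Orchestration** — `run_experiment()` chains
  simulate → denoise → reconstruct → train → predict → evaluate with
  per-stage caching, seeding, and CSV/JSON reports. A thin CLI wrapper
  lives in `inst/cli/mrfepi.R`.

## Worked example

```r
library(mrfepi)

# 1. a small digital phantom with MS-like lesions
cfg <- phantom_config(shape = c(64L, 64L, 6L))
phantom <- generate_phantom(cfg, seed = 7)
phantom
#> phantom_volume: 64 x 64 x 6 voxels, 2578 lesion voxels in 1 component(s), seed 7

# 2. simulate its 35-frame MRF-EPI acquisition and add Rician noise
schedule <- default_schedule()
schedule
#> MRF-EPI schedule: 35 frames, flip 34.0-86.0 deg, TE 16.0-76.5 ms,
#> TR 3530-6370 ms, inversion on
stack <- add_rician_noise(simulate_baseline_stack(phantom, schedule),
                          snr = 40, seed = 7)

# 3. denoise and reconstruct T1/T2*/B1+ by dictionary matching
denoised <- mppca_denoise(stack, window = 5)$denoised
dict <- build_dictionary(schedule, parameter_grid())
dict
#> mrf_dictionary: 53820 atoms (52 T1 x 115 T2* x 9 B1), 35 frames
maps <- reconstruct_maps(denoised, dict, phantom$brain_mask)
round(c(
  t2s_rel_dev = mean_relative_deviation(maps$t2s_ms, phantom$t2s_map,
                                        phantom$brain_mask),
  median_corr = median(maps$correlation[phantom$brain_mask])), 4)
#> t2s_rel_dev median_corr
#>      0.0614      1.0000

# 4. lesion evaluation of a perturbed annotation (intra-observer emulation)
second <- perturb_lesion_mask(phantom$lesion_mask, seed = 1)
round(c(dice = dice(phantom$lesion_mask, second),
        detection = lesion_detection_rate(phantom$lesion_mask, second)), 3)
#>      dice detection
#>     0.704     1.000
```

The reconstructed maps match the phantom with a mean relative T2\*
deviation of 6.1 % at SNR 40 (after the 5 % grid quantization and noise),
with near-perfect match correlations; the perturbed second annotation
overlaps the first at dice 0.70, emulating human intra-observer
variability. Network training is driven the same way — see
`?build_training_set`, `?train` and `?run_experiment`, and the methods
vignette (`vignettes/mrfepi-methods.Rmd`) for the model, parameter and
design documentation.

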