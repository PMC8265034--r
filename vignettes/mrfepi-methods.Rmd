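---
title: "Methods: joint MRF-EPI mapping and lesion probability estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint MRF-EPI mapping and lesion probability estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`mrfepi` implements a complete simulation and reconstruction pipeline for
magnetic resonance fingerprinting with an echo-planar readout (MRF-EPI)
applied to white-matter lesion mapping in multiple sclerosis. The pipeline
has two reconstruction branches that share one forward model:

1. the **conventional branch** — Marchenko–Pastur PCA denoising followed by
   voxel-wise dictionary pattern matching, yielding T1, T2*, B1+ and M0
   maps; and
2. the **network branch** — a 2-D multi-output regression U-net that maps
   the 35 magnitude baseline images directly to five channels: normalized
   T1 and T2* plus NAWM-, GM- and lesion-probability maps.

Because no patient data are distributed, a seeded digital brain phantom
supplies every ground-truth map the pipeline trains on and evaluates
against.

## Signal model

Each voxel's fingerprint is the magnitude signal across 35 frames. We use a
perfectly spoiled gradient-echo recursion with per-frame T2\* echo decay
and an optional inversion preparation. With `Mz-` the normalized
longitudinal magnetization before excitation of frame $i$, flip angle
$\alpha_i$ scaled by the transmit-field factor $b_1$:

$$s_i = |M_z^-(i)|\,\sin(b_1\alpha_i)\,e^{-TE_i/T_2^*}\,M_0,\qquad
  M_z^+(i) = M_z^-(i)\cos(b_1\alpha_i),\qquad
  M_z^-(i+1) = 1 + (M_z^+(i)-1)\,e^{-TR_i/T_1},$$

with $M_z^-(1) = -1$ under inversion (the default) and $+1$ otherwise.
This is deliberately the *minimal* model that couples T1, T2\*, M0 and B1+
to the acquisition schedule: the dictionary and the network only require
the forward model to be self-consistent. Slice profiles, off-resonance and
EPI k-space effects are out of scope.

The default schedule spans exactly the protocol ranges — flip angle
34–86°, TE 16–76.5 ms, TR 3530–6370 ms over 35 frames — with a smooth
raised-cosine flip-angle lobe and linear TE/TR ramps. Only the ranges are
protocol-fixed; the per-frame values are a design choice, and
`read_schedule()` accepts an explicit table so a measured protocol can be
dropped in. Whether the acquisition uses an inversion preparation is not fixed by
the protocol ranges; it is exposed as a flag and defaults to on, which maximizes
the T1 information in the early frames.

### A note on identifiability

The repetition times (3.5–6.4 s) are long compared to most of the T1 grid
(0.3–3.5 s). For $T_1 \lesssim 1$ s, $e^{-TR/T_1} < 0.02$: longitudinal
recovery between frames is essentially complete, and the *normalized*
fingerprint is nearly independent of T1. Likewise T2\* values far above the
maximum TE (76.5 ms) modulate the signal only weakly. In these regimes the
residual parameter signal is smaller than the shape change caused by half a
5 % grid step in the other parameter, so correlation matching can land far
from the true value along a T1–T2\* trade-off ridge even for noiseless
data. Concretely, matching achieves half-grid-step precision (≤ 2.5–3 %)
for T1 in roughly [1.5 s, 3.5 s] and T2\* in roughly [20 ms, 300 ms], but
worst-case errors over the *full* ranges are an order of magnitude larger.
This is a property of the minimal signal model plus the protocol timing
ranges, not of the matching implementation (on-grid inputs reconstruct
exactly, and the accelerated search is verified against a brute-force
oracle). The acceptance suite keeps the full-range precision check and it
documents this limitation by failing; the unit tests pin down the
precision on the well-conditioned subranges.

## Digital brain phantom

The phantom is a concentric-ellipsoid brain: a thin CSF rim at the
surface, a gray-matter ribbon beneath it, white matter inside, and two
CSF-filled ventricles flanking the midline. This is the simplest geometry
with realistic adjacency — lesions sit in white matter and can abut the GM
ribbon, which is the hard case for lesion/GM discrimination.

* **Tissue values** (3 T literature, configurable, validated against the
  dictionary ranges): NAWM T1 850 ms / T2* 50 ms, GM 1400 / 55 ms, CSF
  3300 / 1500 ms; M0 0.8 / 0.85 / 1.0.
* **Probability maps**: Gaussian-blurred hard labels (σ = 1 voxel),
  renormalized to sum to one inside the brain — emulating soft
  segmentation output on a 0–100 % scale. Partial volume is represented in
  these probability maps.
* **Quantitative maps**: each voxel carries its pure tissue value — the
  classic discrete-tissue digital-phantom convention. We deliberately do
  *not* mix relaxation times at tissue borders: probability-weighted T2\*
  mixtures would give every ventricle-rim voxel the same "moderately
  elevated T2\* inside white matter" signature that defines a lesion,
  making lesion suppression at tissue borders a voxel-wise ill-posed task
  that only very long training can resolve through spatial context. With
  discrete tissues, elevated relaxation times inside white matter occur
  only in lesions, so the healthy-subject negative control is a
  well-posed property of the phantom family. The cost is that the
  phantom does not probe partial-volume robustness of the network — a
  stated limitation.
* **Lesions**: a Poisson-distributed count (mean 8) of ellipsoidal blobs
  with in-plane semi-axes 2–10 voxels, restricted to voxels with NAWM
  probability > 0.5 and never overlapping CSF. Each lesion multiplies T1
  and T2* by $1 + f\,L$ with $f \sim U(0.1, 0.6)$ and a smooth
  (blurred-edge) lesion field $L$, so insertion can only raise relaxation
  times — the defining contrast of white-matter lesions. No reference lesion
  size or count distribution exists for this protocol, so these defaults
  are explicit configuration, not constants.
* **B1+**: a smooth quadratic transmit profile within the dictionary's
  0.6–1.4 scale range (or uniform 1.0 on request).
* **Noise**: Rician — each value $v$ becomes
  $\sqrt{(v+g_1)^2+g_2^2}$ with $g_{1,2}$ zero-mean Gaussians whose SD is
  the mean within-brain first-frame signal divided by the SNR (default
  40). Background voxels therefore follow the expected Rayleigh law.

The default matrix is 240 × 240 at 1 × 1 × 2 mm (a 240 mm field of view);
tests and the examples in this package use reduced 32–64 voxel matrices,
which is a problem-size choice only — the generator code path is
identical.

A second annotation set is emulated by `perturb_lesion_mask()`: each
lesion component is randomly shifted and its boundary voxels randomly
toggled, with an overall `severity` knob. The default severity (0.7) was
calibrated once so that the mean dice between original and perturbed masks
across ten default phantoms is ≈ 0.68, the level of human intra-observer
agreement for manual lesion segmentation.

What the phantom does *not* emulate: real cortical folding and atlas-based
anatomy, EPI geometric distortion, B0 inhomogeneity, physiological noise,
and longitudinal lesion evolution. Tests passing on phantoms therefore
demonstrate the internal consistency of the pipeline — forward model,
reconstruction, training and evaluation — not clinical performance on
patient data.

## Dictionary reconstruction

The dictionary covers T1 300–3500 ms and T2* 10–2500 ms in geometric steps
of exactly 5 % and the B1+ scale 0.6–1.4 in arithmetic steps of 0.1
(9 values). The geometric sequence is truncated at the last value
≤ max·1.05, so the final entry may overshoot the nominal maximum by less
than one step; this guarantees every in-range value is within half a step
of a grid point. One fingerprint is simulated per grid triple with M0 = 1
and L2-normalized.

Matching maximizes the normalized inner product between the voxel
fingerprint and the atoms — the standard MRF metric; M0 is recovered as
the projection of the raw fingerprint onto the winning atom divided by the
atom's pre-normalization norm. Ties break deterministically to the lowest
atom index; all-zero voxels are flagged as background. The blocked
matrix-product search is contract-tested to return exactly the atoms a
naive exhaustive search returns, and matching is invariant to positive
scaling of the input. B1+ is matched per voxel, with no spatial smoothing.

## MPPCA denoising

Denoising uses sliding-window principal component analysis with
Marchenko–Pastur rank selection. Windows are 2-D in-plane (default 5 × 5)
because slices are thick (2 mm) relative to the in-plane resolution and
the network is 2-D. For the M × N window Casorati matrix with
R = min(M, N), Q = max(M, N) and covariance eigenvalues
$\lambda_1 \ge \dots \ge \lambda_R$ ($\lambda_i = s_i^2/Q$), the smallest
signal count $p$ is accepted for which

$$\lambda_{p+1} - \lambda_R \;<\; 4\sqrt{(R-p)/Q}\;\hat\sigma^2,\qquad
  \hat\sigma^2 = \tfrac{1}{R-p}\sum_{i>p}\lambda_i,$$

i.e. the remaining eigenvalue bulk is no wider than the Marchenko–Pastur
support for iid noise of the bulk's own mean variance. Components beyond
$p$ are suppressed. Overlapping window reconstructions are averaged with
uniform weights by default (a center-voxel write-back mode is also
provided); negative reconstructed values are clipped to zero and counted,
preserving the magnitude contract. The window size is a convention with no protocol-fixed value and is
exposed in the configuration.

## The U-net

The network is a 2-D encoder–decoder with an encoder depth of three: three
2 × 2 max-poolings, two 3 × 3 convolution + ReLU blocks per level,
nearest-neighbour upsampling followed by a 1 × 1 channel-halving
projection and skip concatenation on the decoder path, and a linear 1 × 1
output convolution. It is a regression network: the final activation is
linear, and probability channels are clipped only at evaluation time
(threshold sweeps rely on the non-zero background of the lesion
probability map). Channel widths start at `base_channels` (default 32) and
double per level; filter counts, padding and normalization layers are
not fixed by the protocol, so these are configurable defaults. Convolutions, pooling and upsampling (with hand-written
backpropagation, verified against finite differences) are implemented in
compiled code; the optimizer is Adam, the community default for U-nets —
only the learning rate is protocol-specified.

Eight variants pair the four losses (MSE, MAE, log-cosh "LCL", soft dice
"DICE" with ε = 10⁻⁶) with either all five output channels or the lesion
channel alone, plus a reference network that takes the two quantitative
maps (T1, T2*) as input instead of the 35 baseline frames (`MSE-2-1`).
Multi-channel losses are unweighted means over per-channel losses, which
requires all channels to be order one: inputs are scaled by the per-case
mean brain signal, T1 targets by 1/3500 ms and T2* targets by 1/2500 ms
(the denormalization scales are stored with every prediction, and the
round trip is exact to numerical precision).

Training follows the protocol defaults: 64 random 64 × 64 patches per
slice, mini-batch 64, 100 epochs, learning rate 10⁻⁴, and five-fold
repetition of slices whose in-slice lesion volume is at least 100 µl
(= 100 mm³, 50 voxels at 1 × 1 × 2 mm — a millilitre-scale threshold
would exceed the total lesion load of any brain, so the microliter scale
is the physically meaningful one); the threshold is exposed in the
configuration. Splits hold out whole
phantoms, never slices. Every stream of randomness (initialization, slice
order, patch coordinates) derives from one integer seed, so training is
reproducible at the level of the recorded loss history.

Validation dice of the lesion channel (33 % threshold) is tracked per
epoch when validation cases are supplied, and the best-validation
parameters are checkpointed; checkpoint selection is not part of the
protocol, so prediction uses the trained model unless the checkpoint is
requested explicitly. After training,
the fit is probed for the known failure mode in which a network converges
to a local minimum with all lesion probabilities below the 33 % threshold
("converged to empty prediction"); such fits carry a `collapsed` flag and
raise a warning. In practice the log-cosh and dice single-output variants
collapse this way on sparse lesions — the known failure mode of these
losses on heavily imbalanced targets —
while MSE variants learn the lesion channel only after the quantitative
channels have converged — the lesion voxels are orders of magnitude fewer
than brain voxels, so their loss contribution is initially negligible.

Inference is full-slice (not patch-wise) with reflective padding of the
in-plane matrix to a multiple of 2^depth.

## Evaluation

* **dice**: $2|A\cap B|/(|A|+|B|)$; both masks empty is defined as 1 so an
  empty prediction on a healthy subject scores perfect.
* **binarize**: closed threshold (≥), so the conventional 33 % (lesion)
  and 80 % (tissue) thresholds are inclusive.
* **lesion detection rate**: ground-truth lesions are 26-connected
  components; a lesion is detected iff it shares ≥ 1 voxel with the
  prediction. This is the most permissive reading consistent with
  detection rates exceeding dice.
* **threshold sweep**: dice and detection rate over a grid of thresholds
  plus the argmax-dice threshold; the detection rate is non-increasing in
  the threshold because the probability background is non-zero.
* **mean relative deviation**: mean of $|test-ref|/ref$ over a mask, used
  for the T1 and T2* channels.
* **per-lesion statistics**: per ground-truth component, volume in µl,
  detection flag, and dice computed against the predicted voxels within
  the component's bounding box dilated by 2 voxels — a documented
  convention. Volumes are reported in µl, the natural scale for
  millimetre-resolution lesions.
* **lesion profiles**: percent increase of T1/T2* over mean NAWM along a
  horizontal and a vertical cut through a lesion centroid, with the lesion
  probability along the same cuts.

## Orchestration and reproducibility

`run_experiment()` chains simulate → denoise → dictionary-reconstruct →
train → predict → evaluate. Each stage derives its seed deterministically
from the global seed and a stage label, caches its result keyed by a
content hash of the stage inputs (phantoms, stacks and the dictionary are
reused across network variants), logs seed and wall time, and a failing
stage halts the run by name while completed stages stay cached. Training
targets combine the two branches the way the original processing does:
T1/T2* from dictionary matching, tissue probabilities and lesion masks
from the phantom truth (standing in for soft tissue segmentation and
manual annotation). Volumes are NIfTI, tables CSV, the summary JSON, and
configurations YAML; identical configuration and seed reproduce result
files bit-identically.

## Problem sizes

The test-suite and acceptance runs use reduced sizes chosen to exercise
every code path at desk scale: 32–64 voxel matrices with 1–6 slices,
coarse (25 % step) dictionaries where only mechanics are under test and
the full default dictionary where precision is, and a scaled network
(base width 8–16, 32 × 32 patches, 8–12 patches per slice, batch 4–8,
learning rate 10⁻³, 20 epochs) for the learning checks. The scaled
training cohort mirrors the acquired cohort in containing both patients
and a healthy subject: three lesioned phantoms plus one healthy phantom,
with a lesioned phantom held out and a further healthy phantom as the
negative control. Because the end-of-training parameters of a short
constant-step Adam schedule still oscillate, the returned model averages
the end-of-epoch parameters over the last quarter of the schedule
(stochastic weight averaging). The scaled learning run reliably reaches
held-out lesion dice far above the 0.4 bar; the strict negative control —
not a single healthy voxel above the 33 % threshold in the whole volume —
is the marginal quantity at this scale: a handful of near-threshold
voxels can survive 20 epochs, so that check is evaluated under a
2-of-3-seeds rule and remains the pipeline's hardest property at desk
scale. These are properties of the scaled synthetic setting, not
reproductions of the clinical numbers.

## Known limitations

* The minimal signal model makes short T1 and very long T2* nearly
  unidentifiable under the protocol's timing ranges (see the
  identifiability note); the conventional branch is therefore most
  trustworthy for mid-to-long T1 and TE-comparable T2*.
* The phantom's geometry is idealized; network performance on it does not
  transfer to patient data.
* The U-net runs on CPU with modest widths; it is meant for method
  validation at desk scale, not for large-cohort training.
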