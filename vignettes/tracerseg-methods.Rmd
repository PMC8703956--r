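---
title: "tracerseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tracerseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tracerseg` implements a pipelined, tracer-aware approach to lesion
segmentation in bilateral breast DCE-MRI. This vignette records the model,
the assumptions, and the design decisions that were genuinely open, in the
order the pipeline runs.

## The problem and the pipeline

A DCE-MRI study is a 4D acquisition: one pre-contrast 3D volume and several
post-contrast volumes acquired while a paramagnetic contrast agent washes in
and out of tissue. Malignant lesions typically enhance fast and *wash out*;
healthy parenchyma enhances slowly towards a plateau. The pipeline exploits
this kinetic difference in five stages:

1. **Breast masking** — zero every voxel outside breast parenchyma, either by
   fusing per-plane model outputs (weighted voxel-wise mean, threshold 0.5)
   or by a deterministic geometric fallback (Otsu threshold on the
   pre-contrast volume, anterior connected components, hole filling).
2. **Motion correction** — register every post-contrast series to the
   pre-contrast reference with an intensity-based method (NCC by default),
   so a voxel's time course reflects physiology rather than patient motion.
3. **3TP slice extraction** — keep only the three acquisitions nearest 0 s,
   120 s and 360 s post-injection and stack homologous slices into
   three-channel images, making the input protocol-independent; slices are
   taken perpendicular to the axis of *largest* voxel spacing and the volume
   is split at the mid-`x` plane so each breast is analysed separately.
4. **Segmentation** — a modified U-Net maps each per-breast 3TP slice to a
   probability map, binarized at 0.5.
5. **Eras/epochs training** — a chunked scheduler that balances the rare
   lesion slices against the abundant healthy slices at every step.

## Axis and resampling conventions

Arrays use the spatial order `(z, y, x)` with the series index *last*
(`volumes[z, y, x, series]`): R is column-major, and the pipeline constantly
needs whole series as contiguous memory. `x` is the patient left–right axis
(the bilateral split cuts at `x = X/2`), `y` runs anterior to posterior, and
a series' acquisition time is its start in seconds relative to injection
(the default 56 s protocol gives `-56, 56, 112, ..., 504`). Spatial
transforms act by *pull* resampling, `out[p] = in[p + shift]`, with linear
interpolation and zero fill outside the field of view; consequently the
transform that corrects a volume whose content was shifted by `s` has
`shift_vox ≈ -s`.

## Time-point selection

`select_time_points()` picks the latest pre-contrast series for t0 and the
post-contrast series nearest the 120 s and 360 s targets, with two
deliberate rules the protocol leaves open: equidistant ties resolve to the
*earlier* series (earlier frames carry less accumulated motion), and the
t2 search excludes the series already chosen for t1, so the three channels
are always distinct acquisitions. Targets are configurable because the
reliability of the canonical time points across vendors is an open research
question; the defaults follow the three-time-point method.

## The modified U-Net

The network departs from the classical U-Net in three ways, all kept
faithfully: a *single* output channel with a sigmoid (so a threshold —
0.5 — produces the binary mask), size-preserving zero padding (breast tissue
never touches the border, and output masks must align with input slices),
and batch normalization placed *after* each ReLU, not before. Filters double
per level from `base_filters`. The default width is 32: the architecture
figure inherited "64 component feature vectors" from the original U-Net,
but only a 32-base five-level network with BN reproduces the stated ~7.7 M
parameter budget (a 64-base network has ~31 M), and the parameter count is
taken as authoritative. `count_parameters()` enumerates every trainable
tensor; the test suite checks it against an independently written
closed-form layer sum, and the default spec lands at 7,765,985.

Training follows the stated protocol: ADAM (`beta1 = 0.9`, `beta2 = 0.999`),
learning rate `1e-4`, weights drawn from `N(0, 2/(fan_in + fan_out))` with
`fan = k²·channels`, all convolution biases at the constant 0.1. The loss is
`1 - DSC` with a *soft* Dice computed from probability sums over the whole
batch (not per-image averages — the simplest reading of a count-based DSC),
with smoothing constant 1 in numerator and denominator so empty masks are
well-defined; on binary inputs with smoothing 0 it reduces exactly to
`1 - dice_coefficient()`. Two empty masks score DSC 1 (a healthy slice
predicted healthy is a perfect outcome). Binarization uses the `>=`
convention, so an exactly-0.5 probability is foreground.

All layers (im2col convolutions, 2×2 max-pooling, non-overlapping 2×2
transposed convolutions, batch norm with population statistics) are
implemented in C++ and verified against central finite differences through
the full composed network; batch-norm running statistics use momentum 0.1
and `eps = 1e-5`.

## The eras/epochs scheduler

Lesion slices (a slice with at least one lesion voxel) are typically <10%
of all slices. The scheduler redefines an *epoch* as "the network has seen
all minority samples plus an equal-sized chunk of the majority class" and an
*era* as "all chunks", i.e. every majority sample. Per era the majority
indices are reshuffled (seeded by `(seed, era_index)`) and cut into
`ceiling(M/m)` chunks of exactly `m`; a short final chunk is padded by
resampling, without replacement, indices already assigned earlier. The
padding is a deliberate choice: the contract only demands every majority
index be assigned at least once, and padding keeps *every* epoch exactly
balanced at `2m` samples. One consequence is that the per-era sample count
is `2m·ceiling(M/m)`, which need not match any externally reported figure
whose underlying class split is unpublished; the closed forms are exposed in
`era_accounting()` so users can audit their own datasets. Chunks are
re-partitioned every era — that is the augmentation-without-fake-data
effect: later eras pair the minority set with fresh majority contexts.

## Motion correction

The native registration is deliberately simple and deterministic: a
resolution pyramid with an exhaustive integer-shift search at the coarsest
level followed by shrinking-step coordinate descent (steps 1 → 1/16 voxel)
on the full-resolution metric; `rigid` adds three angles refined by
Nelder-Mead from the translation solution, and `bspline` optimizes a coarse
control-point displacement grid. NCC is the default metric; when a breast
mask is available the metric is evaluated inside it only, which largely
decouples alignment from contrast-driven intensity change. No single
motion-correction technique wins universally, so the stage also exposes an
external-tool adapter (`motion_correct_external()`) with a plain
NIfTI-in/NIfTI-out command contract. The native method is *not* a port of
any specific external registration package.

## The phantom: what it emulates, and what it does not

`generate_study()` builds bilateral coronal volumes (default 80 slices of
128 × 256, voxels 2 × 1.45 × 1.45 mm, 1 pre + 9 post series 56 s apart):
two ellipsoidal breast compartments in the anterior half separated about the
mid-`x` plane, a posterior chest/muscle band, exact-zero air, and spherical
lesions placed fully inside breast tissue. Enhancement follows a
bi-exponential curve `e(t) = A·(1 − e^{−k_in t})·e^{−k_out t}`:
lesions use `A ≈ 1.8`, `k_in = 1/40 s⁻¹`, `k_out = 1/600 s⁻¹` (peak near
110 s, visible washout by 360 s); parenchyma uses `A ≈ 0.8`,
`k_in = 1/180 s⁻¹`, `k_out = 0` (plateau); muscle a weak plateau. Baselines
are 100 (breast) and 80 (muscle) intensity units, with ±10% per-patient
jitter on rates and gains, additive Gaussian noise (default σ = 5, i.e. 5%
of baseline) on tissue voxels only, and a smooth multiplicative texture
field (default ±15%, control points every 8 voxels) emulating parenchymal
heterogeneity. The texture is not cosmetic: without it the pre-contrast
breast is piecewise constant and intensity-based registration is degenerate
by construction — there is no anatomy to lock onto. Optional motion injects
a seeded uniform sub-voxel translation (up to `motion_amplitude_vox`) into
each post-contrast series; ground-truth masks stay in the motion-free
reference frame.

The phantom does **not** emulate: realistic breast texture statistics,
B0/B1 bias fields, Rician magnitude noise (additive Gaussian is used; the
pipeline exploits no magnitude-signal statistics), pharmacokinetic (Tofts)
fidelity, deformable motion, or partial-volume effects at lesion borders. A
green end-to-end test therefore establishes that the implementation wiring
is correct and that the architecture can learn washout-vs-plateau kinetics
from 3TP channels — it does not predict clinical performance.

## Experimental protocol

Cross-validation is patient-wise: folds are drawn over patients, never
slices. With 33 patients and `k = 10` the folds have sizes 4 and 3, and a
repetition with 3 + 3 held-out patients reproduces the 4320/480/480 slice
split at 160 slices per patient. The validation fold selects the best-era
checkpoint by median DSC (the protocol declares a validation fold without
fixing its use; checkpoint selection is the standard reading). Z-score
normalization is fitted on the training fold only — and only on in-breast
pixels, because the masked background is a synthetic 0 that would bias the
mean — then applied unchanged to validation and test; the population (n)
estimator is used. Evaluation stacks per-breast predictions back to the
study grid and computes one DSC per patient; `lesion_slices_only` restricts
both prediction and ground truth to slices with lesion pixels, reproducing
the evaluation convention that hides false positives on healthy slices.
Ranking tables use competition ranking ("1224") since table positions are
exclusive.

## Desk-scale training: why 80 slices and batch 2

The reference protocol trains ~8,000 balanced slices per era for 20 eras at
a fixed learning rate of `1e-4` — on the order of 10⁴–10⁵ ADAM steps. At a
fixed learning rate, attainable progress is bounded by the *number of
steps*, not by dataset size; a desk-scale run must therefore preserve the
step budget, not just the cohort shape. The package's end-to-end check uses
8 patients with the protocol's own 80 slices per study (64 × 64 per-breast
slices, `base_filters = 8`, 5 eras) and batch size 2 — the protocol never
states a batch size; 2 is the smallest size compatible with batch
normalization (size 1 makes batch statistics degenerate) and maximizes
steps per era (~900 here, ~4,500 over 5 eras). Under this world the
held-out median DSC crosses 0.7 within the 5-era budget on a single CPU in
minutes. Absolute DSC values on phantoms are not comparable to any value
reported on clinical data.

## Numerical choices, degenerate inputs, tie-breaks

* Soft-Dice smoothing constant 1; BN `eps = 1e-5`; ADAM `eps = 1e-8`.
* Otsu on a constant volume, an empty foreground, all-zero fusion weights,
  a registration metric with zero variance everywhere, an empty training
  class, and zero normalization variance all raise immediate errors rather
  than propagating NaNs.
* Ties: time-point selection → earlier series; slicing plane → `z > y > x`;
  ranking → competition ranking; probability 0.5 → foreground.
* Bilateral split of an odd `x` extent gives `floor(X/2)` left columns.
* Multiple pre-contrast series: the latest is the reference (closest to
  injection, least physiological drift); the protocol assumes exactly one.
* Slices with no breast voxels are still emitted (label healthy) — at
  inference the whole breast must be scanned.

## Known limitations

* The learned per-plane masking route ships untrained; the geometric
  fallback is the default mask source. Reproducing a trained multi-planar
  masking model is out of scope.
* The B-spline registration model is a coarse control-grid refinement under
  a capped optimizer; it is tested for "never worsens the metric", not for
  deformable accuracy.
* NIfTI support covers the subset the pipeline writes (little-endian,
  3D, five datatypes, pixdim spacing); orientation matrices are ignored.
  One test cross-checks round-trips against an independent reader.
* Training is CPU-bound R/C++; it is meant for method study and testing at
  reduced scale, not for full-resolution clinical training runs.
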