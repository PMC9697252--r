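---
title: "Multi-perspective hierarchical deep-fusion classification of 3D nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-perspective hierarchical deep-fusion classification of 3D nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hierfusion` classifies small 3D structures — pulmonary nodules against
confusable non-nodule structures in CT — by fusing decisions
hierarchically rather than training one monolithic 3D network. A volume
of interest (VOI) is represented by three orthogonal stacks of 2D
slices: transverse (XY, called V1), coronal (XZ, V2) and sagittal (YZ,
V3). Decisions are then made at three levels:

1. **Slice level.** One compact CNN per perspective (the slice module,
   MS) scores every slice of its perspective with a nodule probability.
   The architecture is four blocks of 3×3 same-padding convolution +
   ReLU + 2×2 max-pooling with 8/16/32/64 filters (spatial trace
   56 → 28 → 14 → 7 → 3 for the 56×56 input), a 32-unit fully connected
   ReLU layer and a 2-class softmax head, trained with Adam on the
   cross-entropy loss.
2. **Perspective level.** A perspective module (MP, one per view)
   re-arranges the slice scores of one stack into a feature vector
   (length 6 by default) and maps it to a single perspective score with
   a one-hidden-layer feedforward classifier.
3. **Volume level.** The volume module (MV) fuses the three perspective
   scores into the final nodule probability, again with a
   one-hidden-layer feedforward classifier.

Training is strictly **modular**: each level is trained separately on
the frozen outputs of the level below, never jointly by end-to-end
backpropagation. This is the core design commitment of the scheme — each
fusion stage is itself a supervised learner over the previous stage's
decisions, so the fusion weights are *learned* rather than fixed
(averaging, voting or product rules).

Two extensions share the same skeleton:

* **Single-feature models** replace the raw slices with feature images
  produced by one of four filters — Laplacian of Gaussian (LoG), Gabor,
  bilateral, or the trilateral filter — before slice-level training.
* **Multi-feature fusion** adds a fourth hierarchy level: several
  complete hierarchies (typically the four feature-image models plus the
  raw-image one) each produce a volume score, and a top fusion module is
  trained over the member scores.

## The feature-image filters

All filters operate on individual 56×56 slices with reflect padding.

* **LoG**: convolution with the sampled closed form
  $-\frac{1}{\pi\sigma^4}\bigl(1-\frac{x^2+y^2}{2\sigma^2}\bigr)
  e^{-(x^2+y^2)/2\sigma^2}$, kernel radius $\lceil 3\sigma\rceil$
  (capturing essentially all kernel mass). Default $\sigma = 2$.
* **Gabor**: convolution with the real part of
  $\frac{1}{2\pi\sigma_x\sigma_y}
  e^{-\frac12(x^2/\sigma_x^2+y^2/\sigma_y^2)}
  e^{i2\pi(\omega_{x0}x+\omega_{y0}y)}$; a magnitude response (both
  quadratures) is available by configuration. Defaults
  $\sigma_x=\sigma_y=2$, $\omega_{x0}=\omega_{y0}=0.1$ cycles/pixel — a
  single filter, not an orientation bank.
* **Bilateral**: per-pixel weighted mean over an $N{\times}N$ window
  with a spatial Gaussian on pixel distance ($\sigma_S$) and a range
  Gaussian on intensity difference from the center ($\sigma_R$),
  normalized by the weight sum.
* **Trilateral**: the bilateral filter with a *third* multiplicative
  Gaussian range kernel on the difference of discrete Laplacian
  responses between neighbor and center ($\sigma_L$), penalizing
  gradient-variation mismatch; as $\sigma_L \to \infty$ it reduces to
  the bilateral filter. A difference-of-trilateral operator (two spatial
  scales $k\sigma_S$ and $\sigma_S$, $k=\sqrt2$) is provided as well.

Numerical choices worth stating: the discrete Laplacian is the
4-neighbor stencil (center −4, cross +1), computed once on the input
slice; the trilateral normalization is the sum of the full trilateral
weights, so a constant image is reproduced exactly; window defaults are
$N=7$, $\sigma_S=2$, $\sigma_R=0.1$ and $\sigma_L=0.1$ on [0, 1]
intensities. Every windowed filter is verified in the test suite against
a nested-loop direct evaluation of its definition at $10^{-10}$, and the
three limit reductions (trilateral→bilateral, bilateral→Gaussian
smoothing, Gabor→Gaussian) at $10^{-6}$.

## Data preparation

Real multi-reader annotations disagree; the package reproduces the
standard consensus pipeline in physical units:

* **Consensus**: same-kind annotations of one scan closer than a
  distance threshold are merged by single-linkage clustering (the
  simplest order-independent realization) into one object with the
  arithmetic-mean center and an approval count. The threshold default is
  5 mm — above plausible reader jitter, below typical inter-lesion
  spacing; no canonical value exists, so it is exposed in configuration
  together with the minimum approval count (default 1).
* **Conflict elimination**: any nodule/non-nodule consensus pair closer
  than the threshold is removed entirely (both members), since the same
  structure was called both ways.
* **VOI extraction**: a 30 mm cube (the largest expected lesion axis)
  around the consensus center is cropped — `round(30 / spacing)` native
  voxels per axis — resampled to 56³ by trilinear interpolation and
  min–max normalized to [0, 1]. A center too close to the scan border
  shifts the crop window inside the volume instead of zero-padding,
  which on phantoms would leak label information through artificial
  black borders; numerically constant crops map to all zeros
  (divide-by-zero guard).
* **Slice selection**: six planes per perspective at equal intervals
  over the object's span — from the annotated extent for nodules, the
  full 56 planes for non-nodules (which carry no boundary annotation) —
  as `round(seq(start, end, length.out = 6))`, endpoints included,
  1-based. Equal-interval selection across the whole object keeps the
  slices mutually informative; center-packed selection would make them
  redundant for large lesions. Degenerate spans repeat boundary planes
  with a warning.
* **Split**: stratified 70/30 with the training size exactly
  `floor(0.7 n)`, apportioned per class by largest remainder so both
  splits stay balanced within one object (604 objects → 422/182).

## The synthetic phantom generator

The package ships a seeded phantom generator so the entire pipeline is
testable without any imaging archive. Each scan is a 96³ voxel grid at
0.6 mm isotropic spacing (the smallest grid that exercises the 50 → 56
resampling with margin) with Gaussian background noise (mean 0.2, sd
0.05). Nodules are bright quasi-spherical anisotropic Gaussian blobs
(diameter 8–24 mm, per-axis anisotropy 0.85–1.15); non-nodules cycle
through three distractor kinds — elongated tubes (vessel-like, Gaussian
cross-section, length/width ratio 4), dim blobs and speckle patches.
Four simulated readers annotate each object with 1 mm isotropic center
jitter and miss probability 0.25 (at least one annotation always
retained), mirroring a four-reader variable-approval panel. The jitter
magnitude is bounded at 2.5 mm (truncated Gaussian): annotations of one
object then stay within 5 mm of each other, so the default consensus
threshold can never split a true object into two, and with object
centers placed at least ~12 mm apart it can never merge two objects —
the consensus stage passes phantom objects through one-to-one by
construction.

Two difficulty settings control class separability through the peak
intensity bands: under **easy**, the nodule peak (0.6–0.9) is at least
3× the distractor peak (0.1–0.2) over the same background noise, and a
brute-force threshold on central intensity separates the classes almost
perfectly; under **hard** the bands overlap (0.3–0.5 vs 0.25–0.45) and
the same oracle stays at or below 0.85. These bands were fixed once,
from the stated 3× contract and the overlap construction, before any
end-to-end run.

What the phantoms deliberately do **not** model: CT physics (beam
hardening, reconstruction kernels, Hounsfield calibration), anatomy
(vessel trees, pleural attachment), texture heterogeneity inside
lesions, and annotation biases beyond isotropic jitter. Passing the
end-to-end tests therefore shows that the hierarchy, its modular
training and its evaluation machinery work and can recover a known
signal — not that the model reaches any particular performance on real
CT archives.

## Training defaults and problem sizes

Slice CNN defaults: Adam, learning rate $10^{-3}$, batch 32, up to 30
epochs with early stopping (patience 5) on a 10% validation split of
the training slices; seeded variance-scaled initialization; the
log(0) guard clips probabilities at $10^{-12}$. The fusion classifiers
use one hidden layer of 8 units (the smallest reasonable realization of
a "regular feedforward" fusion stage — its exact size is an open
choice), fitted by `nnet` with three seeded restarts keeping the best
training fit and a small L2 weight decay (1e-3) — without it the fusion
stages saturate at exactly 0/1 on separable data, which degrades their
ROC curves to a single operating point. Slice labels are inherited from the parent VOI; no
per-slice relabeling is attempted.

The package's benchmark runs (test suite and `scripts/acceptance.R`)
use 604 objects from 151 scans with a 70/30 split, three training seeds
and a reduced epoch budget of 8 with patience 3 — on the easy phantoms
the slice CNNs converge within a few epochs, so the longer default
schedule adds nothing there. The per-level decision threshold is the
argmax (0.5 on the nodule probability); ROC analysis uses the
continuous scores with midpoint tie credit, and false positives per
scan are normalized by the number of distinct scans evaluated
(phantom scans here, so the value is not comparable to archive-scale
reports).

A caveat on the shuffled-label chance control: a slice CNN trained on
randomly permuted labels outputs nearly constant probabilities (as it
should — it has nothing to learn), but rank-based AUC evaluated on a
near-constant scorer is driven entirely by the residual score
variation, which tends to be monotone in slice brightness with an
arbitrary, seed-dependent sign. Individual control AUCs can therefore
land far from 0.5 in either direction even though the control is
genuinely uninformative — and the 0.5-threshold accuracy inherits the
same artifact whenever the score cluster straddles the threshold. The
stable signature of an uninformative control is the score spread
itself, which the acceptance script reports alongside the control AUC:
an order of magnitude below the trained model's, i.e. the control
effectively abstains on every slice.

Another known statistical caveat, inherited from the protocol: the
perspective, volume and top modules are trained on scores computed over
the *same* objects used to train the level below, not on a held-out
stacking split. On separable data this is harmless; on harder data it
risks optimistic fusion weights, and a stacking split would be the
first thing to add.

## A worked example

```{r example}
library(hierfusion)

records <- phantomStackDataset(nScans = 30, objectsPerScan = 4,
                               separability = "easy", seed = 11)
split <- splitDataset(records, 0.7, seed = 3)
cfg <- mpfConfig(dcnn = dcnnConfig(epochs = 8, patience = 3))

model <- trainMpf(records[split$train], cfg, seed = 5)
report <- levelReport(model, records[split$test])
report
```

A single-feature model only changes the front end:

```{r sfmpf}
triModel <- trainMpf(records[split$train], cfg, seed = 5,
                     featureSpec = filterSpec("trilateral"))
```

and several trained hierarchies fuse at the top level with
`trainMfmpf(list(model, triModel, ...), records[split$train], cfg)`.

## Limitations

The scheme is not rotation invariant (slice CNNs see axis-aligned
planes); elongated objects rotated out of alignment are the expected
failure mode. The Gabor front end uses a single scale and orientation.
Perspective-level fusion of multiple feature types (rather than
volume-level) is out of scope, as is end-to-end joint training, which
would contradict the modular protocol.
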