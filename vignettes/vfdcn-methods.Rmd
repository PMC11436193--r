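---
title: "Methods: Log-Gabor diamond convolutional features for finger-vein recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Log-Gabor diamond convolutional features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfdcn)
```

## The problem

Near-infrared finger imaging shows subcutaneous veins as dark curvilinear
strokes on a brighter background, because hemoglobin absorbs the
illumination. A finger's vein topology is stable and hard to forge, which
makes it a useful biometric. The task this package addresses is turning a
small grayscale finger ROI into a fixed-length feature vector that is
discriminative enough for identification (who is this?) and verification
(is this claimed identity correct?), without any supervised training.

## The model

The extractor is a two-layer convolutional network whose kernels are not
learned by backpropagation but *selected* from a fixed mathematical family:
2D Log-Gabor filters, constructed in the polar frequency domain as a product
of two factors,

$$\mathrm{logG}(r,\theta) \;=\;
  \exp\!\left(-\frac{(\ln (r/f_0))^2}{2\,(\ln \sigma_r)^2}\right)\cdot
  \exp\!\left(-\frac{(\theta-\theta_0)^2}{2\,\sigma_\theta^2}\right),$$

a Gaussian on the *logarithmic* radial frequency axis times a Gaussian on
the polar angle. Unlike a Gabor filter, a Log-Gabor filter has exactly zero
DC response, so uniform illumination contributes nothing, and its log-axis
symmetry matches the roughly logarithmic frequency sensitivity of early
human vision.

The pipeline per ROI is:

1. **Layer 1** — convolve (circularly, via the FFT) with $K_1$ selected
   filters; keep the signed real part of each response.
2. **Layer 2** — convolve each layer-1 map with each of $K_2$ filters,
   keeping the grouping by parent map ($K_1 \times K_2$ maps).
3. **Binary hashing** — per parent, threshold its $K_2$ maps with the
   Heaviside step ($1$ iff strictly positive) and combine bits with weights
   $2^{k-1}$ into one integer-coded map in $[0, 2^{K_2}-1]$.
4. **Block-wise histograms** — partition each coded map into $B$
   non-overlapping blocks, histogram each block over all $2^{K_2}$ codes,
   and concatenate: a sparse nonnegative vector of conceptual length
   $2^{K_2} K_1 B$ whose entries sum to $K_1$ times the pixel count.

Matching uses plain Euclidean distance on the sparse vectors; 1-NN gives
rank-1 identification and the genuine/imposter distance distributions give
FAR/FRR curves and the equal error rate.

## Orientation selection and the diamond structure

The only "trained" component is *which* orientations survive at each scale.
For each scale of a candidate bank (`Nscale = 4` scales × `Nori = 10`
orientations by default), every training ROI is filtered with all candidate
orientations; per pixel, the orientation with the largest absolute response
wins, and the per-image histogram of winners (normalized so each image
counts equally regardless of dynamic range) is accumulated over the training
set. The `n_S` highest-weight orientations are kept at scale `S`, ties going
to the lower orientation index. The default allocation `c(2, 7, 7, 2)` keeps
few orientations at the extreme scales, whose responses are blurry or
aliased, and many at the two middle scales where vein-width structure
lives — plotted per scale, the retained counts trace a diamond.

The per-pixel winner rule deserves a note: traversing the globally sorted
response records and letting each pixel contribute only on its first
appearance is equivalent to a per-pixel argmax, and the test suite holds the
traversal implementation to that independent oracle exactly. A bookkeeping
variant that marks visited (orientation, pixel) pairs instead would credit
every orientation once per pixel and make the histogram uniform by
construction, so it cannot be what "most-used orientation" means; we
implement the per-pixel reading.

**Angle convention.** $\theta_0$ is the angle of the filter's lobe in the
frequency plane, i.e. the direction of the *wave vector* it passes. A
sinusoidal grating whose wave vector points at $\theta_0$ excites exactly
the $\theta_0$ filter, while a dark *stroke* drawn along spatial angle
$\alpha$ concentrates its energy perpendicular to itself and therefore
selects the candidate nearest $\alpha + \pi/2 \pmod{\pi}$. Tests of the
selection lever use this physically consistent reading.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `Wmin` | 2 | px | wavelength of the finest scale; 2 px is the Nyquist limit |
| `M` | 2.2 | — | geometric wavelength ratio between scales |
| `Nscale` | 4 | — | number of radial scales (wavelengths 2, 4.4, 9.68, 21.3 px) |
| `sigma_r` | 0.55 | — | radial bandwidth ratio; 0.55 ≈ 2 octaves, 0.75 ≈ 1 octave |
| `Nori` | 10 | — | candidate orientations, evenly spaced on $[0,\pi)$ |
| `T` | 1.3 | — | angular scaling; $\sigma_\theta = T\pi/N_{ori}$, larger ⇒ more overlap |
| `per_scale_counts` | 2,7,7,2 | — | orientations retained per scale ($K_1 = K_2 = 18$) |
| `block_shape` | 8×8 | px | histogram blocks; B = 16 on a 32×32 ROI |
| ROI size | 32×32 | px | network input after preprocessing |

The half-amplitude radial bandwidth has the closed form
$2\sqrt{2\ln 2}\,|\ln\sigma_r|/\ln 2$ octaves; the package checks this
against numeric root finding on the transfer function, and the two
reference values ($\sigma_r = 0.75 \to 0.98$ oct, $0.55 \to 2.03$ oct)
anchor the implementation's denominator convention: the published form of
the radial Gaussian is typographically ambiguous between
$2(\ln\sigma_r)^2$ and $2\sigma_r^2$ in the denominator, and only the
former reproduces these octave correspondences, so that is what is
implemented.

## Numerical choices

* **Frequency grid** — per-axis normalized frequencies in cycles/pixel,
  range $[-0.5, 0.5)$, FFT layout (DC at index 1), radius
  $\sqrt{u^2+v^2}$. Filters are applied by frequency-domain multiplication,
  so boundaries are circular; no padding or windowing is applied anywhere
  in the two layers.
* **DC singularity** — the radius at DC is replaced by 1 before the
  logarithm and the transfer value at DC is then forced to 0.
* **Angular wrap** — the angular difference is wrapped with
  $\mathrm{atan2}(\sin\Delta, \cos\Delta)$ so the Gaussian is continuous
  across $\pm\pi$.
* **One-sided lobes** — the angular lobe is not symmetrized about the
  origin, so spatial kernels are complex; the signed real part is what
  flows between layers and into the Heaviside, and imaginary parts are
  discarded.
* **Heaviside at zero** — exactly-zero responses hash to bit 0, so a
  constant image encodes to code 0 everywhere.
* **Sparse features** — with $K_2 = 18$ the conceptual histogram has
  $2^{18}$ bins per block ($\approx 7.5\times 10^7$ entries per vector);
  vectors are stored as (index, count) pairs and Euclidean distance is
  computed on the sparse form. An alternative with grouped hash bits
  (PCANet-style ≤ 8-bit groups) would shrink the code range but is not the
  default because the plain $2^{K_2}$ coding is the reference behaviour;
  raw counts are kept (no per-block normalization).
* **Block divisibility** — block shapes that do not divide the ROI are
  rejected rather than silently padded or truncated.
* **Ties** — response sorting is stable (enumeration order:
  orientation-major, then row, then column); selection ties go to the
  lower orientation index; 1-NN ties go to the lower gallery index. All
  three rules make every pipeline stage bit-reproducible.
* **EER** — all distinct scores serve as thresholds; accept iff distance
  ≤ threshold; the FAR/FRR crossing is located by linear interpolation
  between the bracketing thresholds.

## Preprocessing

ROI localization combines the Kirsch compass gradient (maximum response
over the eight 3×3 compass masks with coefficients 5/−3, reflective
borders) with a three-level dynamic threshold at $\mu_g + k\sigma_g$,
$k \in \{1,2,3\}$ of the gradient distribution. The three levels are
nested; the automatic rule picks the smallest $k$ whose edge density is at
most 10% of pixels, so cleaner images get the more permissive threshold.
The upper and lower finger boundaries are taken as the rows with the
longest horizontal edge runs in the top and bottom halves; the interior
band is cropped with a 5% horizontal margin and resized bilinearly to the
network input. If no boundary pair is found the full frame is used with a
warning. Datasets that ship pre-cropped ROIs should bypass localization
(`bypass = TRUE`), which is also the default path in the CLI. The mapping
from threshold levels to image-quality classes used by the original ROI
procedure is not fully published; the edge-density rule here is this
package's own fully specified stand-in.

## The synthetic benchmark

Because the public finger-vein databases cannot be redistributed, the
package ships a generator of synthetic labeled datasets: each class owns a
fixed set of 3–5 smooth dark strokes (soft-edged ridges along slightly
curved paths) with widths 2–6 px on a background of intensity 0.75;
samples within a class differ by a rigid jitter of ±1 px translation and
±0.06 rad rotation plus additive Gaussian noise with σ = 0.04, clipped to
[0, 1]. Stroke geometry derives deterministically from (class key, global
seed) and the jitter/noise from (class key, sample index, seed), so
regeneration is byte-identical. Widths of 2–6 px at 32×32 put most stroke
energy into the two middle scales, which is the regime the diamond
allocation is designed for; a fixed-orientation spec makes the selection
lever testable (all strokes at $\alpha$ ⇒ the candidate nearest
$\alpha+\pi/2$ dominates the mid scales).

What the generator does *not* emulate: illumination gradients, scattering
blur, sensor fixed-pattern noise, perspective and elastic deformation of a
real finger, or session-to-session placement drift. Synthetic classes are
therefore more separable than real ones; passing the end-to-end test shows
the pipeline is wired correctly and discriminates geometric vein layouts,
not that real-database error rates would be matched. On this benchmark the
finest-scale-only ablation `[10,0,0,0]` degrades severely while all
configurations containing mid scales saturate near zero error, so only
part of the published scale ordering is observable here.

## Evaluation protocol

`evaluate_recognition()` uses an open-set protocol: identities (never
samples) are split, by default 50/50, filter selection sees only training
identities, and all scoring happens on test identities. Genuine scores are
all intra-class test pairs, imposter scores all inter-class pairs
(uniformly subsampled above a configurable budget, default $10^6$).
Rank-1 accuracy uses leave-one-out 1-NN over the test set, the most
symmetric convention when no gallery/probe split is prescribed. Results
average over `n_iterations` random splits (default 5, matching the usual
practice for this protocol); the whole run is a deterministic function of
(data, configuration, seed).

Problem sizes used by the shipped checks: the end-to-end benchmark is 20
classes × 6 samples at 32×32 with one fixed-seed split; oracle
equivalences run on 8×8 images and map sets up to 8×8 × 8 orientations;
EER limit cases use $10^5$ samples per score set.

## Known limitations

* No BMP reader is available; convert BMP datasets to PNG first.
* The two layers share one selected filter set by default
  (`relearn_layer2 = TRUE` enables an independent second-layer selection
  on layer-1 responses; with shared selection $K_1 = K_2$).
* The number of orientations retained per scale is configuration, not
  inference — the algorithm chooses *which* angles, not how many.
* Circular convolution wraps content across opposite ROI borders; for
  tightly cropped vein ROIs this is the standard choice, but ROIs with
  strong border structure may see wrap-around artifacts.
* Feature vectors grow as $2^{K_2}$ conceptually; sparsity keeps memory
  proportional to $K_1 \cdot$ pixels, but extremely large $K_2$ (> ~30)
  would overflow the integer index space.
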