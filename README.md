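# vfdcn — Log-Gabor diamond convolutional features for finger-vein recognition

Finger-vein recognition identifies people by the pattern of subcutaneous
veins, which near-infrared imaging renders as dark curvilinear strokes on a
brighter background. `vfdcn` implements an *unsupervised* feature extractor
for such images: a two-layer convolutional network whose kernels are 2D
Log-Gabor filters

```
logG(r, θ) = exp( −(ln(r/f0))² / (2 (ln σr)²) ) · exp( −(θ−θ0)² / (2 σθ²) )
```

built in the polar frequency domain (radial Gaussian on a log-frequency
axis × angular Gaussian), followed by PCANet-style binary hashing
(`T = Σ_k 2^(k−1) · H(response_k)`) and block-wise histogram pooling into a
sparse vector of conceptual length `2^K2 · K1 · B`. The one data-driven
step is *orientation selection*: per scale, the orientations that most
often carry a pixel's maximum response over a training set are retained —
few at the extreme scales, many at the middle ones, the "diamond"
allocation (default `[2,7,7,2]`, so K1 = K2 = 18). Matching is Euclidean
distance; evaluation reports FAR/FRR curves, equal error rate (EER) and
rank-1 accuracy under a class-disjoint open-set protocol.

The package is for biometrics and image-analysis researchers who want a
lightweight, fully reproducible baseline that trains without labels and
without backpropagation, plus the surrounding tooling: Kirsch + 3σ ROI
preprocessing, a synthetic vein-image generator for dependency-free
experiments, parameter sweeps, and a small CLI.

## Worked example

Generate a synthetic labeled dataset (20 identities × 6 samples of 32×32
vein-like images), fit the extractor on half the identities, and evaluate
open-set recognition on the other half:

```r
library(vfdcn)

cfg <- lg_config()          # Wmin=2, M=2.2, sigma_r=0.55, T=1.3, 4x10 bank
cfg
#> Log-Gabor bank configuration
#>   scales: 4 (Wmin = 2 px, M = 2.2)
#>   orientations: 10 (T = 1.3, sigma_theta = 0.4084 rad)
#>   sigma_r = 0.55 (2.03 octaves)
#>   image shape: 32 x 32

ds <- synth_images(synth_spec())
sp <- open_set_split(ds$labels, 0.5, seed = 1)
model <- vfdcn(ds$images[ds$labels %in% sp$train_classes], cfg)
model
#> Log-Gabor diamond convolutional feature extractor
#>   input: 32 x 32; layers: K1 = 18, K2 = 18 filters
#>   diamond structure: [2,7,7,2] over 10 candidate orientations
#>   pooling: 8 x 8 blocks (B = 16); feature length 2^18 * 18 * 16 = 75,497,472

rep <- evaluate_recognition(ds$images, ds$labels, cfg, n_iterations = 5, seed = 1)
rep
#> Open-set recognition evaluation
#>   EER: 0.00%   rank-1 ACC: 100.00%  (mean of 5 iterations)
#>   first split: 150 genuine / 1620 imposter pairs
```

Reading the output: the bank's `sigma_r = 0.55` gives each radial filter a
half-amplitude bandwidth of about two octaves; the fitted model keeps 18 of
the 40 candidate filters in the diamond allocation; and on the synthetic
benchmark every test probe is identified correctly (rank-1 ACC 100%) with
genuine and imposter distance distributions fully separated (EER 0%) in
each of the five random identity splits. Real NIR databases are far less
separable than the generator's output, so these numbers characterize the
pipeline's correctness, not expected field performance.

Individual stages are exported too — `build_bank()`, `select_orientations()`,
`extract_feature()`, `match_distance()`, `compute_eer()`,
`extract_roi()` / `kirsch_gradient()` / `threshold_3sigma()` — and
`summary(model)` shows the per-scale selection weights. `write_vfdcn()` /
`read_vfdcn()` round-trip a fitted model through JSON exactly.

A thin command-line wrapper ships in `inst/cli/vfdcn.R`:

```sh
Rscript inst/cli/vfdcn.R synth --out ds --classes 20 --samples 6 --seed 42
Rscript inst/cli/vfdcn.R train --data ds --out model.json
Rscript inst/cli/vfdcn.R evaluate --data ds --out report.json --csv roc.csv
Rscript inst/cli/vfdcn.R sweep --data ds --param diamond \
        --values "10,0,0,0;0,10,0,0;0,0,10,0;0,0,0,10;2,7,7,2" --out sweep.csv
Rscript inst/cli/vfdcn.R bank-render --out bank.png
```

See `vignettes/vfdcn-methods.Rmd` for the model, its assumptions, every
tunable parameter, and the design and numerical choices.

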