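# ipghsi

Semi-supervised hyperspectral image classification from a handful of
labelled pixels per class, via iterative pseudo-label generation with a
promptable segmenter.

## The problem and who this is for

Hyperspectral scenes (crop fields, urban land cover) carry a spectrum of
tens to hundreds of bands per pixel, but annotated pixels are scarce —
often five per class. Classical self-training generates pseudo-labels from
a classifier that has not yet learned anything, so early label noise
compounds. This package takes the structural route instead: a promptable,
category-agnostic segmenter is seeded with the few labelled points,
per-band-group masks are fused by spectral voting, and only
high-confidence, low-uncertainty pixels are admitted as pseudo-labels and
fed back as new prompts. The audience is remote-sensing and plant-science
researchers who want a reproducible, dependency-light testbed for this
family of methods in R.

## The method in brief

For a cube `M ∈ R^{H×W×C}` with `K` categories:

* every three adjacent bands form one of `C−2` overlapping three-channel
  groups; each group is segmented per category with one-vs-rest point
  prompts (own seeds foreground, all other seeds background);
* per-pixel, per-category votes `T(a,i)` count positive masks over groups;
  each pixel takes `argmax_i T(a,i)`;
* with cosine similarities `S_aj` between a pixel's feature `f_a` and the
  `n` prompt features of category `i`, confidence is
  `p = mean_j S_aj` and uncertainty `u = mean_j (S_aj − p)^2`; the gate
  `1[u ≤ κ_h]·1[p ≥ τ_h]` (defaults `τ_h = 0.8`, `τ_l = 0.5`,
  `κ_h = 0.2`) admits one pseudo-label per class per iteration, for 50
  iterations;
* a trainable `D×D` projection of the features takes one gradient step per
  iteration on the spatial-information-consistency loss
  `−Σ_a g_a [log p_a^(i) + Σ_{j≠i} log(1 − p_a^(j))]`;
* seeds plus admitted pseudo-labels train a small patch-based 2D CNN
  (9×9 patches, SGD with lr 0.05, momentum 0.7, weight decay 1e-4), scored
  by overall accuracy (OA), average accuracy (AA) and Cohen's kappa
  `(OA − Pe)/(1 − Pe)`.

A synthetic-scene generator (contiguous class regions, smooth spectral
signatures, Gaussian noise) and an oracle segmenter backend (ground-truth
masks with controllable boundary flip noise) make the whole pipeline
runnable and testable without external scenes or pretrained weights. See
`vignettes/ipg-methods.Rmd` for the full methods account.

## Worked example

```r
library(ipghsi)

pl <- ipg_pipeline(seed = 1)   # 64x64x24 scene, K = 4, 5 seeds/class, 50 iterations
pl
#> IPG pipeline on synthetic scene
#> <synthetic_scene> 64x64, 24 bands, 4 classes (blobs regions), noise sd 0.05
#>   pseudo-labels: 200 (precision vs truth: 1.0000)
#>   OA seeds+pseudo: 99.10%   OA seeds only: 98.12%

pl$report
#> Per-class accuracy (%):
#>  category accuracy
#>         1    98.62
#>         2    99.71
#>         3    99.42
#>         4    98.79
#> OA (%)    99.10
#> AA (%)    99.14
#> Kappa (%) 98.66
```

Reading this: the iterative loop admitted 200 pseudo-labels (one per class
per iteration, all of them correct here), and the classifier trained on
seeds plus pseudo-labels reaches 99.10% overall accuracy on the held-out
pixels versus 98.12% for the same classifier trained on the 20 seeds
alone — the pseudo-label benefit the framework exists to deliver. The
lower-level interface (`generate_scene()`, `oracle_segmenter()`, `ipg()`,
`hsi_cnn()`, `metric_report()`) exposes each stage separately, and
`inst/cli/ipg.R` drives the same stages from the shell with a YAML
configuration:

```sh
Rscript inst/cli/ipg.R all --config run.yaml --seed 1 --output-dir out/
```

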