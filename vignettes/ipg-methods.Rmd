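---
title: "Iterative pseudo-label generation for hyperspectral scenes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative pseudo-label generation for hyperspectral scenes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipghsi)
```

## The problem

Hyperspectral classification assigns a land-cover or crop category to every
pixel of an image whose pixels carry tens to hundreds of narrow spectral
bands. Annotation is the bottleneck: field campaigns yield a handful of
labelled pixels per class, while deep classifiers want thousands.
Semi-supervised self-training fills the gap with pseudo-labels, but early
in training the classifier has no prior knowledge, so its early
pseudo-labels are noisy and the noise compounds.

`ipghsi` implements a different route to pseudo-labels: instead of asking
the (still ignorant) classifier, it asks a promptable segmenter — a
category-agnostic model that turns a few point prompts into a mask, thereby
contributing structural prior knowledge about region shape that the few
labelled pixels cannot supply on their own. The framework is iterative:
masks give candidate labels, confidence gates admit a few of them, admitted
labels become new prompts, and better prompts give better masks.

## The procedure

For a cube $M \in \mathbb{R}^{H\times W\times C}$ with $K$ categories and a
seed set of five labelled pixels per category:

1. **Band-group decomposition.** Every three adjacent bands form a
   three-channel image, giving $C-2$ overlapping groups. A three-channel
   rendering is what an RGB-native segmenter can consume, and the two-band
   overlap between neighbouring groups makes their predictions strongly
   correlated for true structure but not for rendering artefacts.
2. **One-vs-rest prompting.** For category $i$, the seed pixels of $i$ are
   foreground prompts and all other categories' seeds are background
   prompts; the segmenter predicts one binary mask per (group, category).
3. **Spectral voting.** With masks $N(a,i) \in \{0,1\}$ per group, the
   tally $T(a,i)$ counts positive predictions over the $C-2$ groups, and
   each pixel takes the category with the highest count. Ties break toward
   the smallest category index; a pixel whose best count is below
   `min_votes` stays unassigned.
4. **Confidence and uncertainty.** Each pixel has a feature vector $f_a$;
   category $i$ has the features $F_i = \{f_{i1},\dots,f_{in}\}$ of its
   current prompt points. With cosine similarities
   $S_{aj} = \langle f_a, f_{ij}\rangle / (\lVert f_a\rVert\,\lVert f_{ij}\rVert)$,
   the confidence is $p_a^{(i)} = \tfrac1n \sum_j S_{aj}$ and the
   uncertainty $u = \tfrac1n \sum_j (S_{aj} - p_a^{(i)})^2$ — the
   population variance of the similarities. A pixel close to some prompts
   and far from others is suspect even when its mean similarity is high.
5. **Gating and admission.** The gate is
   $g_a^{(i)} = \mathbf{1}[u \le \kappa_h]\,\mathbf{1}[p_a^{(i)} \ge \tau_h]$;
   among gated pixels of each category's voted region, the
   `selections_per_class` most confident (ties in row-major pixel order)
   are admitted as hard pseudo-labels and become foreground prompts for the
   next iteration. Background prompts stay frozen at the seed
   configuration.
6. **Consistency training.** The only trainable part of the prompt pathway
   is a $D\times D$ projection applied to features before similarities.
   One gradient step per iteration minimises the negated
   spatial-information-consistency log-likelihood
   $\mathcal{L}_i = -\sum_a g_a^{(i)}\bigl[\log p_a^{(i)} +
   \sum_{j\ne i}\log(1-p_a^{(j)})\bigr]$, pulling gated pixels toward
   their own category's prompts and away from the others'.
7. After `iterations` rounds, the ledger of admitted pseudo-labels joins
   the seeds to train a small patch-based 2D CNN, which predicts the final
   per-pixel map, scored by overall accuracy (OA), average accuracy (AA)
   and Cohen's kappa.

## Reading the printed formulas charitably

Three places in the published description of this procedure do not parse
literally, and the implementation resolves them as follows:

* The tally is written once as $T(a)=\sum_j N_i(a,i)$ and then used as
  $T(a,i)$ under an argmax over $i$. Only the per-category reading — count
  positives per category over groups, then argmax — is consistent with the
  argmax and with "each pixel undergoes $C-2$ predictions for every
  category", so that is what `vote_tally()`/`vote_assign()` compute.
* The confidence and uncertainty sums are printed with bounds $j=0..n$
  while dividing by $n$; they are computed over the $n$ prompt features.
* The consistency objective as printed is a log-likelihood (higher is
  better); it is implemented as its negation so that "minimise the loss"
  means what it says. Confidences are clipped to $[\varepsilon,
  1-\varepsilon]$, $\varepsilon = 10^{-7}$, before the logarithms, since a
  mean cosine can be negative; clipped coordinates get zero gradient.
* "We set $p_a^{(i)}=1$" for reliable labels is implemented as hard-label
  admission — the pixel enters training with weight one — rather than
  overwriting the stored confidence, which would corrupt both the loss and
  the audit trail. The ledger keeps the measured $p$ and $u$ of every
  admitted label so the gate can be re-checked after the fact.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tau_h` | 0.8 | minimum confidence for foreground / admission |
| `tau_l` | 0.5 | maximum confidence for background |
| `kappa_h` | 0.2 | maximum similarity variance of an admitted label |
| `iterations` | 50 | refinement rounds; more rounds make pseudo-labels collapse onto the seeds |
| `selections_per_class` | 1 | admissions per category per round |
| `per_class` (seeds) | 5 | labelled pixels per category |
| patch size | 9 | CNN input window, mirror-padded at scene borders |
| SGD | lr 0.05, momentum 0.7, weight decay $10^{-4}$ | classifier optimiser |

The defaults are the reference operating point of the framework. Epoch
count (100) and batch size (64) are not pinned by that reference setting
and are exposed in `train_config()`. The projection learning rate (0.01,
with the gradient clipped to Frobenius norm 1 for scale robustness across
scene sizes) is likewise an exposed choice: the reference description
trains its prompt encoder by backpropagation but does not state a rate.

## The synthetic scenes and the oracle segmenter

Real benchmark scenes and pretrained segmenter weights are external
artefacts; the package instead ships a generator and an oracle backend so
the whole pipeline runs, and is tested, from code alone.

`generate_scene()` emulates the features the method exploits: $K$ spatially
contiguous class regions (random 4-connected region growing, or a Voronoi
partition), smooth per-class signature curves over the $C$ bands (mixtures
of band-indexed Gaussian bumps, peak-normalised), a minimum pairwise
angular separation $\theta_{\min}$ between signatures (rejection sampling;
default 30°, i.e. cross-class cosine at most 0.866), and i.i.d. additive
Gaussian noise. The desk-scale default is a $64\times 64$ scene with
$C=24$ bands (22 groups) and $K=4$ classes at noise s.d. 0.05 relative to
unit-peak signatures — large enough for the voting concentration to be
visible, small enough that a full pipeline runs in well under a minute.

The oracle backend derives each requested mask from the ground truth of
the prompted category (read off the majority truth label under the
foreground prompts) and then corrupts it where real promptable segmenters
actually err: independent per-pixel flips at rate `flip_rate` (default
0.15) inside a band of `band_width` (default 3) pixels around region
boundaries, plus optional whole-mask dilation. Flips are drawn
deterministically per (scene seed, band group, category), so groups err
independently — the premise of majority voting — while the backend stays a
pure function of its inputs. Its embedding field is the observed spectrum
of each pixel (class signature plus scene noise), so at zero noise
same-class pixels have identical features and cross-class cosines respect
the $\theta_{\min}$ bound.

What passing tests on these scenes does **not** show: robustness to
spatially correlated sensor noise, mixed pixels, intra-class spectral
variability (moisture, illumination), or the particular failure modes of a
real foundation segmenter on false-colour renderings. The oracle's flip
noise is a deliberately simple, analysable stand-in for those.

## Numerical and design choices

* **Mask binarisation** at score 0.5; the oracle emits 0/1 scores.
* **Ties**: voting ties break to the smallest category index; selection
  ties break in row-major pixel order; a pixel gated by two categories in
  one iteration goes to the higher confidence. All deterministic.
* **All-zero tallies** stay unassigned rather than being forced into a
  category; `min_votes` (default 1) raises that bar if desired.
* **Features for the similarity machinery** are the backend's embedding at
  the pixel, passed through the trainable projection; prompt features are
  taken at the prompt pixels the same way, so the loss gradient flows
  through both sides of every cosine.
* **Gradient of the consistency loss** with respect to the projection is
  computed analytically (chain rule through the cosine) and is verified
  against numerical differentiation in the test suite.
* **Projection update order**: admission first, then the gradient step,
  within each iteration.
* **Degenerate inputs**: zero-norm feature vectors are an error (they make
  cosines undefined); constant channels render to 0; a category with no
  gated candidates simply adds nothing that round; `Pe = 1` makes kappa
  undefined and it is reported as such, not as 0.
* **Normalisation for the segmenter** is per-channel min–max to
  $[0,255]$, with a percentile stretch as the alternative; raw radiance
  scaling is otherwise left untouched.
* **Evaluation splits**: test pixels are all labelled pixels minus every
  pixel that entered training (seeds and pseudo-labels), and the paired
  seeds-only baseline is scored on the same test set, so the comparison
  between the two arms is like for like.
* **Seeding**: a single global seed fans out to per-stage seeds through a
  stable string hash (`derive_seed()`), so stages are individually
  reproducible and two runs with one seed are byte-identical.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run, by design, at the generator's
default scale: $64\times64\times24$, $K=4$, five seeds per class, 50
iterations, 100 classifier epochs. The voting-concentration and
pseudo-label-benefit properties are Monte-Carlo checks over 10 generator
seeds at flip rates 0.2 and 0.15 respectively; unit tests use smaller
scenes (down to $24\times24\times8$) for speed. On these scenes the
zero-noise configuration recovers the ground truth exactly (pseudo-label
precision 1.0 and a voted map equal to the truth), which is the designed
sanity anchor of the oracle construction rather than an empirical finding
about real data.

## Known limitations

* The foundation-segmenter adapter is out of the shipped scope; the
  backend contract (`segment()`, `embed_features()`) is where such an
  adapter plugs in.
* The spectral-voting fusion assumes per-group errors that are roughly
  independent and unbiased inside the flip band; systematically wrong
  groups (e.g. water-absorption bands) would need weighting, which the
  voting deliberately does not do (votes are binary by design).
* With frozen background prompts, background evidence never grows;
  categories that shrink relative to their seeds' implied extent are
  recovered only through the confidence gate, not through negative
  prompting.
* The 2D CNN is intentionally small (two 3×3 blocks, widths 32/64, global
  average pooling); it is the training-stage vehicle for measuring the
  pseudo-label benefit, not a state-of-the-art classifier.
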