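---
title: "Counting dense field objects by context-augmented local count regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting dense field objects by context-augmented local count regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecount)
```

## The counting problem

Counting wheat spikes (or maize tassels, or people in a crowd) in field
images is hard for detection-style methods: objects are small, elongated,
mutually occluding, blurred and unevenly lit, and a single image can hold
over a thousand instances. The supervision that scales to such data is the
*dot annotation* — one point per object — and the family of methods that
works best on it regresses *local counts*: the number of annotated dots
inside a fixed window, predicted from the pixels of that window.

`spikecount` implements a context-augmented local-count regressor in two
equivalent forms, together with everything around it: ground-truth
generation from dots, overlapping-window inference, analytic architecture
accounting, evaluation metrics, and a seeded synthetic scene generator so
the whole pipeline runs end-to-end without any external dataset.

## From dots to regression targets

A dot set $\{(x_i, y_i)\}$ becomes a density map
$D(p) = \sum_i \mathcal{N}(p;\, (x_i, y_i),\, \sigma^2 I)$ with every
kernel truncated at $4\sigma$ and renormalized to unit mass, so
$\int D = N$ regardless of truncation or border clipping. The default
bandwidth is $\sigma = 4$ px, the setting tuned for wheat-spike imagery.
Renormalization after clipping is a deliberate choice: local-count
learning is attractive precisely because the targets should not depend on
the exact kernel, and un-renormalized boundary kernels would re-introduce
that dependence. Local counts are then window integrals of $D$ over
$64 \times 64$ windows sliding with stride 16, computed exactly with a
summed-area table.

Coordinates are 0-based pixel centers ($x$ = column, $y$ = row) and all
windows are half-open, so a window "anchored at 0 of size 64" covers
pixels 0–63 exactly once.

## The networks

All variants share one AlexNet-like stack (`canonical_spec()`): five
$3\times3$ convolutions interleaved with three $2\times2$ max-pools, then
an $8\times8$ stride-2 convolution and two $1\times1$ convolutions ending
in a single count channel. Batch normalization and ReLU follow every
convolution except the final read-out. The geometry recursions

$$r_l = r_{l-1} + (k_l - 1)\,j_{l-1}, \qquad j_l = j_{l-1}s_l, \qquad
p_l = p_{l-1} + \mathrm{pad}_l\, j_{l-1}$$

give a receptive field of $94 \times 94$, an output stride of
$2^4 = 16$, and (with padding 1 on the five $3\times3$ layers) an
accumulated zero padding of 15 per border. The stack carries 638,000
convolution weights regardless of padding.

The variants differ only in what a unit sees and what it regresses:

* `tasselnet` — padded convolutions, $64\times64$ patch in, the patch's
  own count out. The receptive field is nominally 94 px but everything
  beyond the patch is zeros: two thirds of it is wasted.
* `tasselnet_ctx` — the same stack with all padding removed, $94\times94$
  patch in, count of the **central** $64\times64$ window out. The
  15-pixel annulus is *context*: visible to the network, not part of the
  target.
* `tasselnetv2` — the padded stack run fully convolutionally on the whole
  image. Per-layer paddings accumulate to exactly the 15-pixel border
  that keeps every local area $94\times94$, and each output cell equals
  the `tasselnet_ctx` prediction for the corresponding crop (the package
  tests this equivalence to $10^{-4}$ on interior cells). One forward
  pass replaces hundreds of patch passes; the analytic FLOPs calculator
  (`count_mult_flops()`) quantifies the saving.
* `tasselnetv2_del_c` — an ablation: same network, but the target is the
  count of the whole $94\times94$ receptive field. It exists to show that
  treating the annulus as context (rather than as counted area) is what
  makes the method work.

## Inference: merge and normalize

Each output cell's count $c$ is spread uniformly over its $64\times64$
window footprint ($c/4096$ per pixel, windows clipped to the canvas), the
contributions are accumulated, and each pixel is divided by its coverage
multiplicity — the number of windows covering it, computed after
clipping. In the interior every pixel is covered by $(64/16)^2 = 16$
windows. The resulting count map integrates to the image count estimate.

Two numerical facts shape the tests. First, coverage reaches its full
value of 16 only beyond $\mathrm{window} + 2 \cdot \mathrm{stride} = 96$ px
from the border, so exact count conservation holds for objects at least
that deep in the interior; nearer the border the map is mildly biased
(as is the method itself). Second, merging and re-integrating applies a
mass-preserving tent-kernel smoothing to the count grid, so round-trip
identities are stated for regional integrals, not per cell. Canvases
whose size is not stride-aligned (i.e. $H - 64$ not a multiple of 16)
leave a remainder strip no window covers; the merge step treats that as
an internal error rather than guessing.

## Training

Training follows the original recipe where it is stated: improved-Xavier
(He) initialization, plain SGD with initial learning rate 0.1 reduced
$\times 0.1$ when validation MAE stagnates (patience 10 epochs by
default), batch normalization after every convolution before ReLU,
per-channel mean subtraction estimated on the training split, a 90/10
train/validation split, and no augmentation. The loss is the mean
absolute deviation between predicted and target local counts ($\ell_1$;
$\ell_2$ is available) — the loss is not stated in the source and
$\ell_1$ follows the local-count lineage. Negative outputs are clamped to
zero at inference only; training sees raw values. The
best-validation-MAE weights are retained.

Two implementation details matter on small hardware. Batch-norm
statistics pool over the minibatch *and* all spatial positions; for patch
training this is essential, because the deepest feature maps of a single
$64\times64$ patch are $1\times1$ and a per-sample variance would be
identically zero (and the running variance would collapse, making
inference explode). Patch variants therefore train on minibatches (8
patches by default) sampled from the same stride-16 grid the
fully convolutional output uses, so both modes see identical supervision.
Gradient correctness of the hand-written backward passes is verified
against central finite differences in the test suite.

## The synthetic generator

`generate_scene()` emulates the statistical structure of field imagery,
not its photographic appearance: elongated Gaussian-profile ellipses
(length 15–60 px, aspect 2–5, random orientation) rendered back-to-front
with alpha compositing over a low-frequency canopy background, centers
from a Thomas-style cluster process (Poisson parents, Gaussian offspring)
to mimic row planting, plus global gain/gamma jitter, Gaussian blur
($\sigma \in [0,3]$) and sensor noise. Defaults match the source
imagery's sub-image canvas ($912 \times 1216$, which exercises the
canonical $54 \times 73$ output grid verbatim) and per-image counts
0–1462. Every scene is a pure function of (config, seed).

What passing tests on these scenes shows: that the geometry, targets,
training dynamics and inference pipeline behave as designed, and that the
*orderings* between variants hold under controlled conditions. What they
do not show: absolute errors transfer to real wheat imagery — real spikes
have structured texture, perspective scaling and annotation noise the
generator deliberately omits.

## The desk-scale benchmark

The ablation benchmark (`run_benchmark()`) trains the variant pairs under
identical conditions on scenes of $192 \times 192$ px (stride-aligned,
$9 \times 9$ output grid) with 10–50 objects each: 18 training scenes
(split 16/2), 8 test scenes. Fully convolutional variants train 14 epochs
in image minibatches of 4; patch variants train 10 epochs sampling 12
grid cells per image in minibatches of 8. These sizes were chosen so the
full four-variant comparison trains in minutes on one CPU core while
leaving each pair's comparison matched; both members of a pair always
share their configuration exactly. Expected (and tested) directions:
`tasselnetv2` beats `tasselnetv2_del_c`, and `tasselnet_ctx` beats
`tasselnet`.

```{r benchmark, eval = FALSE}
res <- run_benchmark(seed = 1)
res
#>             variant       mae     rmse
#> 1       tasselnetv2  8.925889 10.43421
#> 2 tasselnetv2_del_c 11.199335 14.13530
#> 3         tasselnet 10.233760 12.28991
#> 4     tasselnet_ctx 10.067206 11.57895
```

Read these numbers for their *ordering*, not their absolute size: a few
minutes of single-core training leaves every variant far from converged
(at this scale the best MAE is close to what a constant mean-count
predictor achieves on the same scenes), yet the two directions the
method's design predicts — context kept as context beats context counted
(`tasselnetv2` vs `tasselnetv2_del_c`), and context seen in training
beats no context at all (`tasselnet_ctx` vs `tasselnet`) — already
emerge. The del-c handicap is visible in the raw predictions as a
systematic undercount: its border cells regress targets clipped at the
image edge.

## Evaluation

`count_mae()` and `count_rmse()` are the standard per-image counting
errors
$\mathrm{MAE} = \frac{1}{N}\sum_i |C^{pre}_i - C^{gt}_i|$ and
$\mathrm{RMSE} = \sqrt{\frac{1}{N}\sum_i (C^{pre}_i - C^{gt}_i)^2}$.
`relative_accuracy()` is $100(1 - \mathrm{MAE}/\overline{C^{gt}})$; this
closed form is reverse-engineered — it reproduces the published headline
accuracy from its MAE and the test-set mean count — and is labeled as
such.

## Degenerate inputs, tie-breaks and other small print

* Images smaller than one receptive field (after padding) raise a
  geometry error naming the first offending layer.
* Zero-dot images are legal everywhere (density zero, targets zero,
  relative accuracy refuses a zero-mean ground truth).
* Max-pool ties resolve to the first maximum in column-major scan order —
  fixed, so forward passes are bit-reproducible.
* Evaluating a no-context model on context patches is a geometry error
  unless the model is explicitly converted with
  `with_test_time_context()`; the silent version of that mismatch is the
  "information asymmetry" failure mode and should never happen by
  accident.
* All randomness (weights, splits, patch sampling, scenes) flows from
  user-supplied integer seeds through R's RNG; repeated runs are
  identical to floating-point determinism.

## Known limitations

* The renderer makes no attempt at photo-realism; absolute benchmark
  errors are not comparable to field results.
* Patch-mode inference is exact but deliberately redundant (it exists as
  the baseline the fully convolutional form is compared against).
* Training is single-threaded CPU R + BLAS; the engine is sized for
  desk-scale experiments, not for 1764-image datasets.
* Only sequential architectures are representable; the VGG16-backboned
  variant of the method is out of scope.
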