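---
title: "Attention-based multiple instance learning for patient-level image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple instance learning for patient-level image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonomil)
```

## The model

A patient's examination is a bag $X = \{x_1, \dots, x_N\}$ of $N \ge 1$
images with a single binary label $Y$ under the standard MIL assumption:
$Y = \max_i y_i$ over (unobserved) instance labels $y_i$. The classifier
is a composition of three stages.

**Instance encoding.** A convolutional backbone maps each image to a
feature vector; the deepest feature maps are pooled spatially (adaptive
average pooling by default) to $h_i \in \mathbb{R}^{512}$, so the encoder
accepts any input resolution and any bag size and always yields
$H \in \mathbb{R}^{N \times 512}$. Two backbones are provided: `tinycnn`,
a compact from-scratch network (a stem 2×2 average pool, then three 3×3
convolution blocks of 8, 16 and 512 channels, each followed by ReLU and
2×2 average pooling), and the VGG13 convolution stack. ImageNet-pretrained
VGG13 weights cannot be shipped with the package, so requesting
`pretrained = TRUE` is an explicit capability error and `tinycnn` is the
default everywhere; a randomly initialized VGG13 remains available so the
encoder interface stays pluggable.

**Attention aggregation.** Instance scores use two fully connected layers
with a tanh bottleneck,
$$s_i = W_2^\top \tanh(W_1^\top h_i + b_1) + b_2, \qquad
  a = \mathrm{softmax}(s), \qquad M = \sum_{i=1}^N a_i h_i,$$
with $W_1 \in \mathbb{R}^{512\times128}$, $W_2 \in \mathbb{R}^{128\times1}$,
$b_1 \in \mathbb{R}^{128}$ and scalar $b_2$. Since $W_2$ produces one
scalar score per instance, only a scalar $b_2$ makes the softmax over
instances well-defined — and any constant $b_2$ cancels in the softmax, so
its value is immaterial. The softmax subtracts the maximum score before
exponentiation, making arbitrary finite scores numerically safe. Setting
$W_2 = 0$ recovers exact mean pooling; element-wise max and mean pooling
are provided as the ablation baselines. The aggregation is permutation
invariant by construction.

**Bag head.** $P(Y = 1 \mid X) = \sigma(w^\top M + b)$.

## Training

Training follows a bag-level recipe: Adam, batch size of one patient
(variable $N$ precludes naive batching), binary cross-entropy on the bag
probability. The `train_config()` defaults (learning rate $5\cdot10^{-5}$,
100 epochs) are the settings appropriate for fine-tuning a pretrained
backbone. For the from-scratch `tinycnn` used in the synthetic experiments
the package's documented choice is Adam at $10^{-3}$ — the conventional
default for training small CNNs from random initialization — with 10–20
epochs; the synthetic task converges within a handful of epochs. A
stratified 15% of the training bags is held out by default for
best-by-validation-AUC checkpoint selection (the test split is never
touched); set `val_frac = 0` to train on everything and keep the final
model. Fixed seeds make the loss trajectory bit-reproducible.

The whole network — convolution via im2col and BLAS matrix products,
pooling, attention, the head — and its exact analytic backward pass are
implemented in the package; gradient correctness is pinned by
finite-difference tests at $10^{-4}$ relative tolerance.

## The simulator

`generate_dataset()` draws bags that obey the MIL assumption exactly:
`round(n_bags * class_balance)` positive bags; a positive bag of size $N$
contains `max(1, round(witness_rate * N))` positive instances; negative
bags contain none. Negative instances show a regular, homogeneous,
mildly hypoechoic ellipse on Gaussian speckle; positive instances add an
irregular (harmonically perturbed) lesion at `lesion_contrast` above
background plus 3–8 bright punctate spots whose brightness scales with the
same contrast dial, echoing the qualitative sonographic features of
benign vs suspicious nodules (regular/homogeneous vs irregular margins
with microcalcifications). Defaults: 4–12 images per bag (about 8 on
average, matching the order of frames per real examination), 64×64 pixels
(512 is available), contrast 0.5, speckle SD 0.05. Labels and bag sizes
are drawn first from the dataset seed; each bag then renders under a
counter-derived sub-seed, so datasets are bit-reproducible and the size
draws can be replayed independently.

What the simulator does *not* emulate: physical speckle statistics,
anatomical context, probe/vendor variability, operator-dependent framing,
or inter-image heterogeneity of benign tissue. Passing tests therefore
demonstrate that the machinery is correct and that the method behaves as
designed under controlled conditions — not clinical performance.

## Evaluation protocol

`compute_metrics()` reports accuracy, precision, recall, F1 (positive
class = high-risk; probabilities at the threshold count as positive, with
0.5 the default cutoff) and rank-based AUC (ties one half; identical to
the trapezoid area under the empirical ROC — asserted against an
$O(n^2)$ pair-count oracle). Confidence intervals come from a stratified
patient-level percentile bootstrap (1000 resamples, seeded); this is the
least-assumption construction for "CIs based on the prediction results"
when only one test set exists. For model comparison,
`paired_comparison()` runs a two-sided paired t-test and paired-data
Cohen's d (mean difference over SD of differences) with effect bands at
the conventional |d| cutoffs 0.2 / 0.5 / 0.8; the pairing unit in
`ablation_run()` is the per-resample metric on a *shared* bootstrap
resample index, the only construction that makes two models' metrics
genuinely paired. Degenerate cases are explicit: single-class truth is an
error for AUC, zero predicted positives reports precision 0 with a
warning flag, zero-variance differences yield a degenerate comparison
with `p = NA`.

## Interpretability

Two complementary outputs, deliberately kept distinct: **attention
weights** rank whole images within the bag (`attention_report()`, ties
broken deterministically by index), and **Grad-CAM** localizes evidence
inside one image: channel weights are spatial means of the gradient of
the logit with respect to the deepest post-activation convolution maps,
the map is the ReLU of the weighted activation sum, max-normalized and
bilinearly upsampled.

`grad_cam()` offers two gradient targets. `"bag"` differentiates the full
bag logit — the printed formula, verified against an analytic closed form
on a linear one-convolution network. But on a trained attention model the
bag-coupled gradient reaching a *low-attention* instance reverses sign
whenever that instance's evidence sits below the attention-weighted bag
average (softmax saturation), so the ReLU suppresses exactly the lesion:
in our synthetic runs bag-coupled maps localize essentially always on
high-attention instances and essentially never on low-attention positive
ones. This is a known property of bag-coupled CAMs in attention MIL, and
the standard practice is to rank images by attention and localize with
per-image maps. `target = "instance"` (the default) therefore applies the
identical Grad-CAM computation to the image as its own singleton bag,
whose logit is the model's evidence for that image alone; per-image maps
localize the simulated lesion in essentially all positive instances. A
dead gradient returns a flat zero map with a warning flag rather than an
error.

## Numerical and design choices

- 2×2 *average* pooling inside `tinycnn` (exact, fully vectorized
  backward); the VGG13 variant keeps max pooling as in the original
  architecture.
- Softmax with max-subtraction; BCE probabilities clamped at $10^{-7}$.
- Max-pooling backward splits gradient evenly among tied maxima.
- Ties at the decision threshold are called positive (fixes the constant-
  classifier corner case deterministically).
- Augmentation (flip, contrast jitter, rotation, scale, translation) is
  drawn independently per image from a seeded stream and applied at
  preprocessing time; a limitation relative to re-drawing augmentations
  every epoch.
- Bilinear resampling is used for resize, affine warps and heatmap
  upsampling; background fill is 0.
- Stratified splits use per-class floor allocation with largest-remainder
  top-up, so a 3:1 split of 100 balanced bags is exactly 75/25.

## Problem sizes used in the shipped checks

The test suite trains at desk scale, chosen once: learnability uses 200
training / 50 held-out bags, 64×64 images, witness rate 0.5, contrast
0.5, 20 epochs, three seeds (held-out AUC ≥ 0.9 expected in at least two);
the pooling ablation uses 105/35 bags at witness rate 0.2 over five seeds,
10 epochs; bootstrap-coverage checks use 100 replicates of 500 patients.
On this simulator the ablation's attention and mean-pooling arms both
saturate (AUC 1.0) even at witness rate 0.1: simulated negative instances
are feature-homogeneous, so the mean over 8–16 embeddings still shifts
detectably with a single witness. The ablation check therefore
establishes "attention is at least as good", not a strict gap; producing
a strict gap would require heterogeneous distractor instances, which the
generator deliberately does not model.

## Known limitations

- No GPU path; the engine is single-threaded BLAS. Fine at 64×64, slow at
  512×512 for large studies.
- `vgg13` is architecture-only (no pretrained weights), so transfer
  learning — central to the clinical-scale result this design follows —
  cannot be exercised here.
- Static (per-dataset) augmentation, no learning-rate schedules beyond a
  constant rate, no gradient accumulation.
- Bootstrap CIs on saturated metrics (estimate 1.0) are degenerate
  one-point intervals; expected on the easy synthetic regime.
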