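# sonomil

Attention-based multiple instance learning (MIL) for patient-level risk
classification from variable-length sets of ultrasound-like images.

## The problem

An ultrasound examination yields a variable number of frames per patient,
but the clinically meaningful label — low-risk vs high-risk — exists only at
the patient level. Labeling every frame is expensive and noisy; many frames
of a high-risk patient show nothing suspicious. `sonomil` treats each
patient as a **bag** of image **instances** under the standard MIL
assumption (a bag is positive iff it contains at least one positive
instance) and learns from bag labels alone:

1. a convolutional encoder maps each image to a feature vector
   h<sub>i</sub> ∈ R<sup>512</sup>;
2. a tanh-scored attention module assigns each instance a weight

   a<sub>i</sub> = softmax<sub>i</sub>( W₂ᵀ tanh(W₁ᵀ h<sub>i</sub> + b₁) + b₂ ),
   with W₁ ∈ R<sup>512×128</sup>, W₂ ∈ R<sup>128×1</sup>;

3. the bag feature M = Σ<sub>i</sub> a<sub>i</sub> h<sub>i</sub> is passed
   through a linear layer and a sigmoid to give the high-risk probability.

Max and mean pooling are available as ablation baselines, Grad-CAM maps
localize evidence within single images, and the evaluation module provides
accuracy/precision/recall/F1/AUC with stratified patient-bootstrap 95%
confidence intervals plus paired t-tests and Cohen's d for model
comparison. The network forward and backward passes are implemented
directly on BLAS matrix products (im2col convolution), so no external deep
learning runtime is needed — everything runs on a plain CPU.

A procedural simulator generates grayscale "nodule" bags with controllable
bag size, witness rate, lesion contrast and speckle noise, so the entire
pipeline is testable without clinical data. Real data enter through a
simple `patient_id,label,image_path` manifest CSV pointing at PNG/JPEG
files.

## Worked example

```r
library(sonomil)

# 60 synthetic patients, 4-12 images each, half high-risk
bags <- generate_dataset(sim_config(n_bags = 60, image_size = 64, seed = 1))
sp   <- split_by_patient(bags, train_frac = 0.75, seed = 1)
pp   <- preprocess_spec(target_size = 64)
train <- preprocess_bags(sp$train, pp, rng_seed = 1)
test  <- preprocess_bags(sp$test,  pp, rng_seed = 2)

fit <- train_mil(train, mil_model(pooling = "attention", seed = 1),
                 train_config(lr = 1e-3, epochs = 10, seed = 1))
compute_metrics(predict_bags(fit$model, test))
#> metrics (threshold 0.50, 95% bootstrap CI):
#>   accuracy  1.0000  [1.0000, 1.0000]
#>   precision 1.0000  [1.0000, 1.0000]
#>   recall    1.0000  [1.0000, 1.0000]
#>   f1        1.0000  [1.0000, 1.0000]
#>   auc       1.0000  [1.0000, 1.0000]

pred <- predict_bag(fit$model, test[[1]])
pred
#> bag prediction: p(high-risk) = 0.9525 (logit 2.9977)
#> attention weights: 0.117 0.311 0.000 0.000 0.064 0.000 0.000 0.000 0.222 0.130 0.156 0.000
test[[1]]$instance_labels     # simulator ground truth, unseen by the model
#> [1] 1 1 0 0 1 0 0 0 1 1 1 0
attention_report(pred, top_k = 2)   # which images drove the call
hm <- grad_cam(fit$model, test[[1]], instance_index = 2)
render_overlay(test[[1]]$images[[2]] * 0.25 + 0.5, hm, "cam.png")
```

At these easy simulator settings (lesion contrast 0.5, witness rate 0.5)
the task is separable and held-out metrics saturate at 1.0. The attention
weights concentrate on exactly the truly positive images — every instance
the simulator marked positive receives weight ≥ 0.06 and every negative
instance ~2.5e-5 — and the saliency map highlights the lesion region.
Lower `lesion_contrast` / `witness_rate` make the task arbitrarily harder.

A command-line front end wrapping the same functions ships at
`system.file("cli", "sonomil.R", package = "sonomil")` with subcommands
`simulate`, `train`, `eval`, `predict`, `explain` and `ablate`, driven by a
YAML config (see `?cli_main`).

## Scope notes

The package implements and tests the method on simulated data; the
simulator mimics qualitative ultrasound features (regular homogeneous
nodules vs irregular lesions with bright punctate spots) without claiming
clinical realism. Pretrained VGG13 weights are not distributable with the
package, so the `vgg13` backbone is available in randomly initialized form
only; the compact `tinycnn` backbone is the default throughout.
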