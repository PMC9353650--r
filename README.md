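# atsvit

Semi-supervised vision transformer with adaptive token sampling for
breast-image classification, implemented end to end in R.

## What problem this addresses

Breast ultrasound and histopathology datasets are small, imbalanced, and
expensive to annotate. Two ideas help a vision transformer (ViT) in that
regime, and this package implements both:

- **Adaptive token sampling (ATS).** A ViT's cost grows quadratically with the
  number of image-patch tokens, and most patches of a medical image are
  background. In every encoder block, patch token *j* is scored from the CLS
  row of the attention matrix,

  *S<sub>j</sub>* = *A*<sub>1,j</sub>‖*V*<sub>j</sub>‖ / Σ<sub>i≥2</sub> *A*<sub>1,i</sub>‖*V*<sub>i</sub>‖,  with *A* = softmax(*QK*ᵀ/√d),

  and up to *K* tokens are kept by inverse transform sampling through the
  score CDF (generalized inverse, duplicates removed, so *K′* ≤ *K*). The
  retained tokens — the informative patches — flow to the next block, with an
  index map back to pixel coordinates for visualization.

- **Consistency training (CT).** Unlabeled images are used through two
  augmentation-invariance losses next to the supervised one-vs-all
  binary cross-entropy *L<sub>CE</sub>*: a pseudo-label MSE
  *L<sub>MSE</sub>* between class probabilities of an image and its randomly
  augmented twin (clean branch detached), and an Earth Mover's distance
  *L<sub>EM</sub>* between their final-block token sequences, solved exactly
  as an optimal assignment. The objective is the plain sum
  *L* = *L<sub>CE</sub>* + *L<sub>MSE</sub>* + *L<sub>EM</sub>*, optimized by
  Adam with a single shared parameter set.

The package also provides macro-averaged evaluation metrics for imbalanced
classes, PNG image-folder I/O, a YAML run configuration mirroring the
reference hyperparameters (learning rate 2e-5, eps 1e-8, batch 64, 300
epochs, 256×256 inputs, token schedule 256/128/64/32/16/8), and a synthetic
lesion-image generator whose samples carry ground-truth masks of the
informative region — so token selection can be validated geometrically.

It is written for method study at desk scale: the transformer forward *and*
backward passes are plain R matrix algebra (gradients are verified against
finite differences in the test suite), every intermediate object is
inspectable, and all experiments run on one CPU core in minutes.

## Worked example

Train the compact benchmark model (64×64 grayscale lesions, 16 tokens,
3 blocks, schedule 16/8/4) with 20% of training labels hidden and used only
through the consistency losses:

```r
library(atsvit)

data <- desk_dataset(seed = 1)          # 200 train / 50 val / 50 test, 2 classes
ct <- run_desk_experiment(seed = 1, epochs = 30, ssl = TRUE, data = data)
print(ct$metrics)
#> Acc: 100.00%  Pre: 100.00%  Rec: 100.00%  F1: 100.00%

mean(ct$localization)
#> [1] 0.465
```

The first line reports test-set accuracy and macro precision/recall/F1 on
the held-out test images. The localization number is the average fraction of
patches surviving into the last encoder block that overlap the ground-truth
lesion mask; the lesion covers roughly a third of the patch grid, so 0.465
means the sampler's final token budget leans toward the lesion well beyond
its area share.

Inspect where the model looks by overlaying the most significant retained
patches on the image:

```r
boxes <- top_tokens(ct$model, data$test$x[[1]], k = 4)
overlay <- draw_token_overlay(data$test$x[[1]], boxes)
png::writePNG(overlay, "overlay.png")
```

A command-line wrapper covering dataset generation, training, evaluation and
token visualization is installed at `inst/cli/atsvit.R`:

```sh
Rscript inst/cli/atsvit.R generate-data --out data/synth --size 64 --counts 130,70
Rscript inst/cli/atsvit.R train --data data/synth --out runs/demo
```

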