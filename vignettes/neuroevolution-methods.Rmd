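---
title: "Training a convolutional classifier by neuroevolution: model, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training a convolutional classifier by neuroevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evocnn)
```

## The problem and the model

`evocnn` implements a binary image classifier for histopathology slides —
benign versus malignant tissue — built as a small convolutional neural
network whose weights can be trained three ways: mini-batch gradient
descent, Adam, and a real-coded genetic algorithm (GA) that treats the
entire flattened weight vector as a chromosome. The interesting scientific
question is whether a population-based, gradient-free search can train a
CNN competitively with gradient methods on this task; the package makes
that comparison runnable end-to-end on any machine, with no data download,
via a synthetic two-class texture generator.

The reference architecture takes 210×210 RGB inputs through eight 3×3
"valid" (stride-1, no-padding) convolutions with 8, 8, 16, 16, 24, 24, 32,
32 filters. Every convolution is followed by a ReLU, and a 2×2 stride-2
average pool follows every second convolution. The resulting 9×9×32 map is
flattened (2592 features) into a dense hidden layer (default width 100,
ReLU) and a final dense layer with two outputs normalized to class scores.
With biases this is 288,678 trainable parameters:

```{r}
spec <- build_network()
spec
```

### Choices the architecture description left open

Several details of the layer chain are not uniquely determined by a prose
description of "eight convolutions with pooling and ReLU", and we fixed
them as follows:

* **Pooling placement.** Pooling after *every* convolution is impossible
  for a 210-pixel input and eight 3×3 convolutions (the map reaches zero
  size). We pool after every second convolution (`pool_every = 2`),
  which keeps all eight layers valid: 210 → 208 → 206 → 103 → 101 → 99 →
  49 → 47 → 45 → 22 → 20 → 18 → 9. `pool_every` is configurable.
* **Filter depth.** Filters span all input channels (the standard
  convention), so a layer with F filters on a C-channel map holds
  F·3·3·C weights.
* **Odd pooling edges.** Floor division: a trailing row/column that does
  not fill a 2×2 block is dropped.
* **ReLU after pooling.** Average-pooled ReLU outputs are already
  non-negative, so a post-pool ReLU would be the identity; we apply ReLU
  after convolutions and after the hidden dense layer only.
* **Output normalization.** The output layer has two logits. We use a
  two-logit softmax by default — required for a differentiable
  cross-entropy loss — with an optional independent per-logit sigmoid
  mode (`output = "sigmoid"`, renormalized for prediction).
* **Biases.** Included by default for every conv and dense layer (the
  affine unit y = w·x + b); `use_bias = FALSE` gives the ablation.
* **Initialization.** Uniform on \[−0.1, 0.1\] or normal(0, 0.1²),
  seeded; both ranges configurable.

A note on parameter counting: `count_weights()` enumerates exactly the
tensors implied by the conventions above. Published counts for comparable
architectures sometimes disagree with any such enumeration (under- or
over-counting channel depth or the hidden layer); we deliberately report
only our own reproducible count.

## The genetic algorithm

The GA's chromosome is the flat weight vector produced by
`flatten_weights()` — a frozen serialization (conv layers in order,
filter-major, row-major, then dense layers, weights before biases) whose
inverse `restore_weights()` is bit-exact, so genotype and phenotype are
interchangeable.

Per generation:

1. **Fitness** of every chromosome is the classification **error rate**
   (FP + FN)/N on the evaluation batch — the GA optimizes the
   non-differentiable objective directly, which is exactly the freedom a
   gradient method does not have.
2. **Selection**: the `num_parents` (default 8) lowest-error members
   survive unchanged (elitism), ties to the lower index.
3. **Crossover**: parents are paired cyclically (1–2, 2–3, …) and each
   pair produces one offspring by single-point crossover at a uniform
   random cut in \[1, L−1\] (a both-offspring mode exists).
4. **Mutation**: with probability `mutation_rate` (default 0.1) an
   offspring has exactly one uniformly chosen gene incremented by
   uniform(−`mutation_range`, +`mutation_range`) (default range 1).

Two readings of "mutate a single gene with probability 0.1" are possible —
per offspring or per gene. We default to **per offspring** (matching the
notion of "number of solutions mutated per generation") and expose
`mutation_mode = "per_gene"` as the alternative. Elitism plus a fixed
full-batch evaluation set makes the best fitness provably non-increasing;
with mini-batch fitness (`fitness_mode = "minibatch"`, batches cycling
through a seeded shuffle of the training set) fitness is noisy, so
`train_ga()` reports the best-ever member by recorded fitness rather than
the final generation's best.

## Gradient baselines

Both gradient trainers minimize mean softmax cross-entropy — the error
rate itself is not differentiable, so a surrogate is unavoidable; softmax
cross-entropy is the standard choice for a two-class CNN. The backward
pass is an exact reverse-mode differentiation through dense, ReLU,
flatten, average-pool and convolution layers, written against the same
C++ kernels as the forward pass and verified against central finite
differences (max relative error ≤ 1e−4 over randomly probed parameters).
One "iteration" is one mini-batch update. Gradient descent uses
w ← w − αg with α = 0.001 by default; Adam uses the standard
bias-corrected moment estimates (β₁ = 0.9, β₂ = 0.999, ε = 1e−8). At the
default rate, plain GD moves the loss only slowly on our fixtures —
consistent with the motivating comparison, where GD trails Adam and the
GA by a wide margin.

## Data handling

`read_image_folder()` ingests PNG/JPEG folders whose filenames follow the
BreakHis-style grammar `BIOPSY_CLASS_SUBTYPE-YEAR-SLIDE-MAG-SEQ.EXT`
(decoding and bilinear resizing are delegated to EBImage; pixels are
scaled to \[0,1\]; no stain normalization). Because slides from one
patient are strongly correlated, random image-level splits leak
patient-specific texture into the test set; `split_patientwise()` instead
shuffles *patients* (seeded) and assigns whole patients greedily to the
training set until it first reaches the target image fraction (default
0.7). Exact 70/30 by images is generally impossible patient-wise; the
greedy rule overshoots by at most one patient. If the threshold would
swallow every patient, the last one is held back so the test set is never
empty. Magnification is parsed and retained as metadata but ignored for
labeling.

## The synthetic test bed

`generate_synthetic_dataset()` emulates the *structure* of a two-class,
multi-patient histology collection at configurable resolution: benign
images are a few large pale blobs (mean 6, Poisson) on a light pink
background; malignant images are many small dark-purple blobs with
over-dispersed counts (mean 25, negative binomial, size 6) on a slightly
darker background. Each image gets a random overall luminance factor
(uniform 0.70–1.20, emulating stain/illumination variation) and additive
Gaussian noise (sd 0.02), and is assigned to one of `n_patients`
synthetic patients split evenly between classes, with grammar-conforming
filenames so a written folder round-trips through the reader.

What this fixture does show: that every training path can learn a
texture/color-separable two-class problem from pixels, that patient-wise
splitting works, and that the three optimizers can be compared end to
end. What it does not show: anything about real histopathology — real
tissue has structured morphology, staining artifacts, and much weaker
class separability. One consequence worth stating explicitly: because the
classes differ in color, a randomly initialized network is a *sign coin
flip* — its test accuracy lands near 0 or near 1 depending on the
initialization, and only its expectation over initializations is ~0.5. We
therefore quote the untrained baseline as the mean accuracy over several
random initializations.

## Problem sizes and numerical choices

The end-to-end experiments shipped with the package use 200 images at
32×32 over 4 patients, with a reduced architecture chosen *a priori* for
that scale: two convolutions of 4 filters, pooling after each, no hidden
layer — 550 parameters. The reduction is deliberate: GA search quality
degrades sharply with chromosome length at fixed population size, and 550
genes is a scale where a population of 20 over 200 generations searches
meaningfully. On this configuration Adam (300 iterations, batch 32)
and the GA (population 20, 8 parents, 200 full-batch generations) both
exceed 0.9 training accuracy and beat the untrained baseline on held-out
patients, and GD improves its loss at the default rate.

Other numerical details: sigmoid is computed in the numerically stable
two-branch form (no overflow for large |x|); softmax subtracts the max
logit; cross-entropy clips probabilities at 1e−300 before the log;
predicted labels are the score argmax with ties resolved toward the
benign class; convolution and pooling kernels are C++ (with an unrolled
3×3 path) and are tested against a brute-force R loop oracle to 1e−12.
Checkpoints are JSON with 17-significant-digit numbers, which round-trips
IEEE doubles exactly. All stochastic steps — initialization, batch
cycling, crossover points, mutation draws, patient shuffles, blob
placement — derive from explicit integer seeds, and every train function
restores the caller's RNG state.

## Limitations

* The GA scales poorly to the full 288,678-parameter reference network;
  reproducing full-scale results requires the real dataset and long runs,
  both out of scope here.
* Single-threaded by design; no im2col/FFT convolution, no GPU.
* The loss surrogate (cross-entropy) and the GA objective (error rate)
  differ, so loss-based and fitness-based histories are not directly
  comparable across optimizers.
* The synthetic generator is a fixture, not a simulator of histology.
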