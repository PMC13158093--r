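---
title: "Methods: hybrid 3D CNN/transformer grading of multi-sequence brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid 3D CNN/transformer grading of multi-sequence brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvit3d)
```

## The problem

Preoperative grading of pediatric brain tumors — low grade (WHO I/II) versus
high grade (WHO III/IV) — guides whether surgery alone is curative or whether
radio/chemotherapy must follow. Multi-parametric MRI carries the relevant
signal: dense high-grade tumors restrict water diffusion (low ADC), show
heterogeneous T2 signal with necrosis and edema, enhance strongly at the rim,
and have blurred infiltrative borders; low-grade tumors are more uniform with
sharp boundaries. `cvit3d` implements a hybrid 3D convolutional/transformer
classifier ("3D C-Vit") over five co-registered sequences (CE-T1WI, T1WI,
T2WI, FLAIR, ADC), plus the analytic, statistical and feature-selection
machinery around it, and a synthetic phantom generator so the whole pipeline
is exercisable with no clinical data.

Because the R scientific stack ships no deep-learning framework, the network
is implemented in the package itself: forward *and* backward passes, with the
grouped 3D convolution kernels in compiled code (`src/`) and the transformer
in base-R matrix algebra. Every gradient path is validated against central
finite differences in the test suite.

## The model

**Fusion stem (CAEFF).** Each sequence enters its own 3x3x3 convolutional
path (stride 2). The T1WI path — the anatomically most stable reference — is
followed by squeeze-and-excitation (SE) channel attention: global average
pooling per channel, a two-layer bottleneck perceptron (reduction 16 in the
full-size preset, 2 at desk scale — it must divide the path's channel
count), a sigmoid, and
channel-wise rescaling. Every other sequence is routed by a gating network
(pool, affine map, sigmoid) between a standard convolution and a depthwise
separable group convolution (DSGC). The original description routes each
channel *hard* to one path depending on feature importance; a hard routing
has no usable gradient, so the stem computes the convex blend

  `out_c = g_c * StandardConv(x_c) + (1 - g_c) * DSGC(x_c)`, `g_c in (0, 1)`,

which recovers the hard behaviour when the gate saturates, and an explicit
hard-routing inference mode (`hard_gates = TRUE`, threshold 0.5) is provided.
The blend endpoints are verified exactly in the tests.

**DSGC.** A per-channel (depthwise) 3x3x3 convolution followed by a 1x1x1
pointwise convolution whose channels are grouped by `gcd(C_in, C_out)`.
Output extents follow `floor((in + 2P - K)/S) + 1` per axis. Multiply counts
are `K^3 C_in C_out V` for the standard convolution and
`K^3 C_in V + V C_out C_in / gcd(C_in, C_out)` for DSGC (`V` = output voxel
count), giving the reduction ratio `1/C_out + 1/(gcd * K^3)`. The
`complexity` functions evaluate these in exact whole-number arithmetic
(doubles, exact to 2^53) and are tested against an instrumented naive loop.
By convention FLOPs = multiplies; a multiply-add (x2) toggle is provided.
Attention/MLP costs count the QKV projections, the two attention products,
the output projection and the two MLP products; biases, softmax and
normalization are not counted.

**Extraction stages (MSFE).** Each stage recalibrates its input by the
gating network's per-channel weights (element-wise multiplication), then
applies a stride-2 DSGC. One fusion stem followed by two extraction stages
is the default; the stage count is configurable because the original
description does not fix it.

**Transformer encoder.** The final feature map is tokenized: one token per
spatial position via linear projection to the embedding width, a learnable
CLS token prepended, learnable positional embeddings added. Encoder blocks
are *pre-norm* (LayerNorm before attention and before the MLP) with residual
connections — the original description says only "residual connections and
normalization", and pre-norm is the stabler choice at these depths. The MLP
uses GELU with hidden width `mlp_ratio * embed_dim`. Attention rows are
checked to sum to one, and the multi-head computation is verified against a
naive per-head oracle.

**Head.** The original text describes "two layer scaling" with normalization
after the first; we interpret this as
`linear(E -> E) -> LayerNorm -> linear(E -> E/2) -> linear(-> 1)` on the CLS
state, a single logit, and a sigmoid read as the high-grade probability.

## Presets and the parameter-count discrepancy

Two presets ship. `"paper"` keeps the originally stated encoder verbatim:
width 768, depth 8, 12 heads — head size 768/12 = 64. Those dimensions
cannot be reconciled with the originally reported total of 1.82 M
parameters (eight encoder blocks at width 768 alone exceed that by more
than an order of magnitude), so the reported parameter/FLOP totals are
treated as irreproducible and are *not* targets; the preset documents the
stated dimensions rather than silently "fixing" them. `"desk"` is the
CPU-scale configuration used throughout the tests: input 16 x 64 x 64
voxels (the in-plane 0.5 mm / 5 mm slice protocol makes anisotropic grids
with few slices natural; the original input size is unstated), 4 stem
channels per path, extraction stages of 32 and 64 channels, width 96,
depth 2, 4 heads, MLP ratio 2, SE reduction 2. `count_params()` computes
the per-layer count analytically and is required by the tests to equal the
instantiated model's allocation exactly.

Initialization: truncated normal (sd 0.02, clipped at 2 sd) for all
projections and embeddings, Kaiming-normal for convolution kernels, unit
layer-norm gains; every draw flows through one seed, and the seeded
pipeline is bitwise reproducible on one CPU.

## Training

`train()` uses binary cross-entropy on logits, Adam (0.9/0.999, no weight
decay — the optimizer is our choice; the original description names only
the loss and schedule), minibatches of 16, and cosine annealing
`lr(e) = base_lr (1 + cos(pi e / E)) / 2` from `base_lr` to zero. Defaults
(100 epochs, base_lr 1e-4) mirror the original protocol. The run log
records loss, learning rate and accuracies per epoch, and the logged rate
must equal the closed form exactly. With a validation set, the parameters
at the best validation AUC are retained. The desk-scale overfit exercise —
60 phantoms, 30 epochs, base_lr 1e-3 (a deliberate desk-scale choice:
about 120 optimizer steps are too few for 1e-4 to converge) — reaches at
least 0.95 training accuracy and is the package's end-to-end trainability
check.

## Evaluation statistics

AUC is the rank statistic `(sum of positive midranks - M(M+1)/2) / (MN)`;
ties get midranks (the original formula is silent on ties), and equivalence
with the exhaustive pairwise count (wins + half ties) is asserted on
hundreds of random score vectors. Confusion counts use a default 0.5
probability threshold (unstated in the original). Accuracy, precision,
recall and F1 follow their defining formulas, with zero-denominator cases
reported as `NA` plus a warning, never as 0. DeLong's test for correlated
ROC curves uses the fast midrank structural-component covariance with a
two-sided normal p-value; it is cross-checked against an independent
reference implementation and a paired-bootstrap oracle, and its null
rejection rate at alpha = 0.05 is required to sit in [0.03, 0.07] over
1,000 simulations. Cohort tables use Pearson chi-square *without* Yates
correction by default (flag available) and the Welch unequal-variance
t-test; both delegate to the standard R implementations, with the tests
verifying the O/E summation and textbook formulas independently.

## Radiomics screening

`first_order_features()` computes a minimal first-order set (mean,
population variance, skewness, kurtosis, energy, 32-bin histogram entropy,
10th/90th percentiles, voxel count, physical volume) over a masked region;
degenerate constant regions report zero skewness/kurtosis with an explicit
flag. The univariate chi-square filter dichotomizes each continuous feature
at its median (how a chi-square was applied to continuous features is not
specified in the original; the median split is ours) and its type-I error is
simulation-checked against alpha. Multivariate selection is an L1-penalized
logistic path (via `glmnet`): 100 lambdas spanning four decades below the
all-zero lambda, 5-fold cross-validated binomial deviance, `lambda.min`
rule. Internal standardization makes selection invariant to column scaling.
One practical caveat: the coordinate-descent path can swap single variables
in and out locally, so the selected-set size is monotone in lambda only up
to small local dips; the tests assert the global-growth property rather
than strict monotonicity.

## The phantom generator

`generate_phantom()` builds all five contrasts from one ellipsoidal tumor:
rim enhancement on CE-T1WI (amplitude 1.2 for HG vs 0.6 for LG), mild T1
hypointensity (-0.4), T2 hyperintensity (+0.8) with HG-only smoothed-noise
heterogeneity (3 noise SDs) and a necrotic core, a FLAIR edema band (HG
default), and an ADC map whose in-tumor mean sits `adc_gap` (default 1.0)
noise SDs lower for HG than LG. Boundaries are Gaussian-blurred (sigma 1.5
voxels HG, 0.5 LG — encoding infiltrative vs sharp borders) while the
returned mask stays the exact ellipsoid indicator. Noise is Gaussian
(sigma 0.1 in normalized units). All effect sizes were fixed once for
desk-scale learnability and are configurable. A Monte-Carlo test confirms
the encoded contrasts are statistically recoverable (lower HG ADC in at
least 99/100 phantom pairs, higher HG T2 variance in at least 95/100) and
that a linear classifier on {ADC mean, T2 variance} separates the grades.

What the phantoms do *not* emulate: anatomy, scanner/protocol effects, bias
fields, registration error, inter-site variation, or the texture families
real radiomics features respond to. A model that aces the phantoms has
demonstrated optimization and plumbing correctness, not clinical validity.

`generate_cohort()` draws covariates (gender, location, type, necrosis,
edema, Ki-67, age) from grade-conditional distributions mirroring a
340-subject cohort structure, including the near-deterministic Ki-67/grade
coupling. `stratified_split()` allocates `round(ratio * N)` subjects per
split by largest-remainder quotas across classes, keeping every split's
class composition within one subject of proportionality; the historical
237/51/52 split of 340 is not reproducible by any standard rounding and is
not treated as a target.

## Preprocessing stand-ins

Bias correction and registration are upstream responsibilities: the reader
refuses sequences on mismatched grids rather than registering them.
Intensity normalization is a modal-window z-score — the volume is z-scored
by the mean/SD of voxels within +/-5% (of the intensity range) of the
256-bin histogram mode — standing in for white-matter-referenced
normalization, which would require tissue modelling; the transform is
exactly invariant to affine intensity changes and is flagged as
`modal_zscore` in its audit record. Resampling is trilinear for intensities
and nearest-neighbor for masks, with the output grid
`ceil(extent / spacing)` and the voxel-1 center preserved as world origin.

## Problem sizes

The suite runs everything at desk scale: 6-8 voxel grids for layer oracles,
60 phantoms of 16 x 64 x 64 for the training exercise, 200-500 random cases
for the analytic oracles, 1,000 simulations for the statistical
calibrations, 50 replicates (n = 300, p = 50) for the support-recovery
check. These sizes were chosen as the smallest at which each property is
statistically meaningful.

## Known limitations

- The network is CPU-bound R/Rcpp; it is a reference implementation for
  method study, not a production trainer.
- Hard routing is inference-only; training always uses the soft blend.
- Dropout is accepted in the configuration but the desk protocol trains
  with 0; regularization was unnecessary at phantom scale.
- The radiomics module implements only first-order features; texture and
  wavelet families are out of scope, and the selection pipeline accepts any
  externally computed feature table (deep CLS features included).
- Phantom realism limits stated above.
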