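---
title: "Searching compact networks for dental age estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching compact networks for dental age estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Chronological age can be estimated from orthopantomograms (OPGs, panoramic
dental radiographs) because teeth change monotonically with age: eruption
completes through childhood, crowns abrade, secondary dentin narrows the
pulp chamber, and roots become radiolucent. `agenas` implements a
neural-architecture-search (NAS) toolkit around this task: two search
engines over radiograph-specific search spaces, builders for the searched
architectures (AGENet and AGE-SPOS), an expected-value age head, analytic
complexity accounting, the standard evaluation metrics, and a synthetic
pseudo-OPG generator so that the entire pipeline is testable without
clinical images.

Clinical OPG collections are not redistributable, so the package's role is
methodological: the algorithms, the search spaces, the published
architectures and their complexity are all reproduced and testable; the
headline clinical error rates (1.6-1.8 years MAE on tens of thousands of
OPGs) are not, since they require the original hospital data and GPU-scale
training.

# The age model

Every network ends in a 76-way softmax over integer age labels
$l_k = k,\; k = 0, \dots, 75$. The age estimate is the expectation of the
predicted distribution,

$$\hat{y} = \sum_k p_k\, l_k ,$$

which is continuous even though the labels are discrete, and always lies in
$[0, 75]$. Training minimizes cross-entropy against label-smoothed targets:
mass $1-\varepsilon$ on the true bin and $\varepsilon/(K-1)$ elsewhere, with
$\varepsilon = 0.1$. The expectation is used only at inference. At test time
a prediction can be averaged with the prediction on the horizontally
mirrored image (`predict_with_mirror()`); for a symmetric image this is
exactly the plain prediction.

Ages above 75 are clamped to 75 with a warning. The label range follows the
expectation head's index set; clinical collections reach older ages, and the
clamping policy is this package's resolution of that tension, not a claim
about the data.

Evaluation uses the mean absolute error in years, the cumulative score
$CS(j)$ (the percentage of images with error at most $j$ years), and MAE
per age decade.

# The two search engines

## Differentiable cell search with partial channel connections

The first engine relaxes discrete operator choice into a softmax-weighted
mixture. A cell is a DAG: nodes are feature maps, and the edge $(i, j)$
carries

$$f_{i,j}(x_i) = \sum_{o \in O} \frac{e^{\alpha_o^{(i,j)}}}{\sum_{o'} e^{\alpha_{o'}^{(i,j)}}}\; o(x_i).$$

To keep memory manageable, only a sampled fraction of channels (a binary
mask $S_{i,j}$, resampled every forward pass) is routed through the mixture;
the remaining channels bypass it unchanged and are recombined in their
original order. Because partial connections destabilize edge comparison, a
second softmax over per-edge weights $\beta^{(i,j)}$ normalizes the
combination of a node's incoming edges. Network weights and architecture
weights $(\alpha, \beta)$ are optimized alternately — momentum SGD on a 60%
training split, an adaptive-moment method on the remaining 40%.

The operator set has 11 members: a 3x3 standard convolution; 3x3 and 5x5
separable convolutions (each applied twice); 3x3 and 5x5 group convolutions
with 9 groups; two-stage asymmetric group convolutions (1x3 then 3x1, and
1x7 then 7x1, groups 9); 3x3 max and average pooling; identity; and zero
(no connection). Every group convolution is followed by a pointwise
convolution. Asymmetric kernels are included because radiographic features
extend very differently along the two image axes.

After search, `derive_genotype()` keeps, per edge, the strongest non-zero
operator, and per node the two incoming edges with the largest
$\mathrm{softmax}(\beta) \times$ (best operator weight), ties resolved
toward the lower source index. `build_agenet()` stacks eight cells —
reductions at slots 1, 3 and 6 double the channels and halve the grid — with
initial channel count 36 (AGENet-Small) or 54 (AGENet-Large).

Printed forms of the mixture equation in the source literature carry an
obvious typo (identical numerator and denominator); the standard softmax is
implemented. $\beta$ is a per-edge scalar, as the node-combination equation
requires.

## Single-path one-shot supernet

The second engine targets lightweight deployment. The space stacks 16
choice layers; each layer offers three candidate blocks that share input and
output shape:

* an inverted-residual (MBConv) block with a 3x3 depthwise kernel,
* the same with a 5x5 kernel,
* a **parallel asymmetric convolution block**: after the 1x1 expansion, the
  expanded channels split into two equal halves processed in parallel by a
  1x7 and a 7x1 depthwise convolution, then concatenate and project.

All three have exactly three weighted stages, so every realized network has
depth $1 + 16 \times 3 + 1 = 50$ (the classification head — a 1x1
feature-mixing convolution plus the pooled linear classifier — counts as one
stage, the "final classification layer").

The depthwise stage of the parallel block costs 7 multiply-accumulate taps
per expanded channel, giving the closed-form block cost

$$F'_m = \mathrm{EXP2}\,(C_{in}^2 + C_{in} C_{out} + 7 C_{in})\, h w,
\qquad
\frac{F'_m}{F_m} = \frac{C_{in} + C_{out} + 7}{C_{in} + C_{out} + k^2} < 1
\;\; (k \in \{3, 5\}).$$

This closed form dictates the block's internal wiring: a sequential 1x7 then
7x1 depthwise pair would cost 14 taps per channel, so the two branches must
see complementary halves. Whether the published block feeds both branches
identical or complementary halves is not stated; complementary halves are
the only reading consistent with the printed cost.

The supernet trains by uniform single-path sampling: each mini-batch
activates one random block per layer and updates only those parameters (plus
the shared stem and head), with momentum SGD, cosine-decayed learning rate
and the label-smoothed DEX objective. The discrete search stage is an
evolutionary algorithm over 16-way choice vectors (population 50,
20 generations, per-locus mutation 0.1, single-point crossover at full
scale), ranking candidates by validation MAE among those whose realized
FLOPs fit a budget. The search method itself is unnamed in the source; the
evolutionary configuration follows the cited one-shot literature.

# The stage plan and the reconstruction of the published complexity

The per-layer widths of AGE-SPOS are published only as a figure, so the
package reconstructs the plan from two constraints: the space is "a
MobileNetV2-style schedule with 16 blocks", and the printed complexity table
gives FLOPs and parameters at width multipliers 0.5, 1.0 and 1.5.

* **Blocks.** MobileNetV2's (t, c, n, s) schedule with the 96-channel stage
  trimmed from three blocks to two gives exactly 16 blocks and matches the
  quadratic component of the printed parameter column (~1.64 M at width 1.0)
  and FLOPs column (~0.72 G) almost exactly; trimming any other stage
  misses one or both.
* **Head width.** Decomposing the printed parameter column into quadratic,
  linear and constant components in the width multiplier yields a head-conv
  width of ≈1150 from the linear term and ≈1150 again from the constant
  (classifier) term. The package therefore ships a 1152-wide head
  convolution (not MobileNetV2's 1280), unscaled by the width multiplier.
* **Width rounding.** Channel counts scale by the multiplier and round to
  multiples of 4. Rounding to multiples of 8 would inflate the 0.5x model
  (24 channels would round to 16 rather than 12) by roughly 10% FLOPs,
  contradicting the printed 0.29 G.
* **FLOPs convention.** Pure convolution + fully-connected
  multiply-accumulates undercount the printed table by ~8% (MobileNetV2 at
  384x384 gives 0.88 G against a printed 0.96 G). The printed values match
  the common profiler convention that also counts normalization and
  activation element operations; `count_network()` uses that convention by
  default and offers `convention = "macs_only"` for the closed-form
  comparisons, which are defined over convolution MACs alone. Parameters
  always include normalization affine terms.

With these choices the counter reproduces all published
FLOPs/parameter values within 3% (parameters within 1.5%), e.g. 0.927 G /
2.173 M for AGE-SPOS (1.0x) against printed 0.95 / 2.17. The exact block
order of the published path (which 8 of the 16 slots hold parallel
asymmetric blocks) is likewise available only as a figure;
`agespos_published_path()` is a synthetic transcription — asymmetric blocks
in the eight even slots, 3x3/5x5 MBConv alternating in the odd slots — and
the tested fact is the textual one: 8 of 16.

# The layer library

No deep-learning framework is available to R here, and the search engines
need gradients of real networks, so the package ships a compact
reverse-mode layer library: im2col convolutions (grouped and asymmetric
kernels included), shift-accumulate depthwise convolutions, batch
normalization, ReLU6/ReLU/sigmoid, 3x3 max/average pooling (average pooling
excludes padded cells from its divisor), global average pooling, linear
layers, a Squeeze-Excitation module, and SGD-with-momentum and Adam
optimizers. Feature maps are arrays with dimensions (height, width, batch,
channel), which makes every per-channel operation a column operation and
lets patch matrices feed BLAS directly. Every backward pass is verified
against central finite differences in the test suite; the architecture
gradients (through the mixture softmax and the edge normalization) are
verified the same way.

Convolutions are bias-free when followed by normalization; blocks follow the
MobileNetV2 convention (BN + ReLU6 after expansion and depthwise stages,
linear projection); "same" padding everywhere, stride-s outputs of size
ceil(n/s), which the residual condition and the closed forms assume. The SE
module sits between the depthwise stage and the projection, reduction 4,
with biases in its bottleneck. Pooling operators in search cells carry no
weights and are followed by batch normalization.

# The synthetic generator

`generate_sample(age, cfg, seed)` renders a square grayscale image with a
dark background, a jaw band, and two rows of teeth around an occlusal
plane. Four visual proxies are monotone in age by construction:

| proxy | rendered as | direction |
|---|---|---|
| eruption | tooth count ramps 8 → 28 over ages 0-12 | up, then flat |
| abrasion | crown height shrinks linearly | down |
| secondary dentin | dark pulp-chamber core shrinks | down |
| root transparency | intensity fade along roots steepens | up |

Additive Gaussian noise (default sd 0.02) is applied last; everything is
bitwise-determined by (age, seed, config). Ages are drawn uniformly or from
a right-skewed discrete distribution (a floor-discretized gamma with shape
2 and scale 16, truncated to 0-75) whose median of ≈27 years mimics a
clinical age mix. A small measurement routine recovers the four proxies
from the rendered image, and ordinary least squares of age on those
features reaches R² > 0.9 — the generator is learnable by construction.

What passing tests on this generator do **not** show: robustness to
projection geometry, exposure variation, restorations and prosthetics,
missing teeth, or any pathology — the things that make clinical OPGs hard.
The generator validates the machinery (search, training, metrics,
complexity), not clinical performance.

# Problem sizes and numerical choices

Desk-scale defaults keep the whole suite on one CPU: search tests run one
or two cells at 4-8 channels on 32x32 images; supernet tests use two or
three choice layers; the end-to-end learnability check trains a
four-stage network (~40k parameters) on 2,000 synthetic 64x64 images for
four epochs (Adam, learning rate 1e-3, batch 32) and requires held-out MAE
under 8 years against ≈19 years for the best constant predictor (it
reaches ≈4.5). Full-scale settings from the source protocol (batch 16,
learning rate 0.1 for search; 20,000 supernet mini-batches; Adam at 1e-4
for 100 epochs of final training; 384x384 inputs) are the documented
defaults of the corresponding functions where they are cheap to honour and
configuration knobs where they are not.

Printed hyperparameters that are internally inconsistent are resolved as
follows: weight decays "1e4" and "4e5" are read as 1e-4 (differentiable
engine) and 4e-5 (one-shot engine); a garbled batch-size pair is read as
64; the label-smoothing mass, unstated, is 0.1. The partial-channel
sampling fraction defaults to 1/4 and the cell topology to 2 input + 4
intermediate nodes with concatenated output, the conventions of the cited
partial-channel search method.

Degenerate inputs are handled explicitly: empty data splits, infeasible
FLOPs budgets (an explicit error after 1,000 rejected samples), unreadable
images (skipped with a warning), ages outside the label range (clamped
with a warning), and channel counts indivisible by an operator's group
count (a configuration error).

# Known limitations

* Pure-R training is orders of magnitude slower than a GPU framework; the
  full 384x384 / 20,000-mini-batch protocol is expressible but not
  practical here. The engines are validated at desk scale.
* ImageNet pre-training is out of scope; a weight-loading hook
  (`saveRDS`/`readRDS` of trained models) stands in for it.
* The published cell genotypes and exact block order exist only as figures;
  the packaged constants are labelled synthetic transcriptions and the
  tests assert only the textual facts.
* The SE-module ablation direction on clinical data (helpful when wide,
  harmful when narrow) depends on the unavailable dataset; only the SE
  module's mechanics and its parameter/FLOPs accounting are asserted.
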