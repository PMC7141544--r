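---
title: "Residual-mesh segmentation of chest radiographs: model and methods"
author: "cxrmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-mesh segmentation of chest radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrmesh)
```

## The problem

Frontal chest radiographs carry the anatomy needed to screen several
cardiothoracic conditions. Cardiomegaly in particular is assessed from
the cardiothoracic ratio (CTR): the maximal horizontal extent of the
heart shadow divided by the maximal horizontal extent across both lung
fields. Reading these extents by hand is slow and operator-dependent;
an automatic pipeline needs a per-pixel segmentation of the lungs,
heart, and (on some datasets) clavicles, from which the CTR is a
two-line computation. `cxrmesh` implements the full chain: a compact
encoder--decoder segmentation network, its training recipe, evaluation
metrics, the CTR computation, and a synthetic phantom generator that
makes every stage testable without external imaging data.

## The network

The model is a fully convolutional encoder--decoder. The encoder has
four blocks; block $i$ applies two $3\times3$ convolutions. Writing
$T(E_i)$ for the raw output of the first convolution (with input
$E_i$) and $K(E_i)$ for the output of the second, the block output
before pooling is

$$\tilde R_i = \big(T(E_i) + K(E_i)\big)^\sim,$$

where $(\cdot)^\sim$ denotes batch normalization followed by ReLU, and
the elementwise addition is the block's *inner identity stream* (IIS).
The first convolution's output is also passed through its own
$(\cdot)^\sim$ stage before feeding the second convolution, so blocks
mix pre- and post-activation. Each block ends with a $2\times2$,
stride-2 max-pooling that records the linear coordinates of every
retained maximum.

The decoder mirrors this structure. Block $j$ starts with a
max-unpooling that places its input values at the coordinates recorded
by the paired encoder pooling (block $5-j$), then applies two
$3\times3$ convolutions and sums three terms:

$$\tilde S_j = \big(E_i + K(D_j) + F(T(D_j))\big)^\sim.$$

$K(D_j)$ is the second convolution's output; $F$ projects the first
convolution's raw output to the matching channel width through a
bias-free $1\times1$ convolution in decoder blocks 1--3 (the *inner
non-identity streams*, INIS) and is the identity in block 4, where
widths already agree. $E_i$ arrives over an *outer identity stream*
(OIS) from the encoder: the outputs of pooling layers 3, 2, and 1 feed
decoder blocks 1, 2, and 3, and the activated output of the very first
convolution feeds decoder block 4, so the first layer's edge
information reaches the end of the network directly. A final
$3\times3$ mask convolution with one channel per class and a per-pixel
softmax produce the class scores.

Counting streams gives the residual mesh: 4 IIS + 4 OIS + 1 decoder
identity = 9 identity paths, plus 3 non-identity projections, 12 paths
total; `census_residual_paths()` enumerates them. Counting kernels
gives 17 $3\times3$ convolutions (8 encoder, 8 decoder, 1 mask). Both
censuses are invariant to the width multiplier.

### Widths, variants, and the layer table

The encoder width chain is $[64, 128, 256, 512]$ scaled by a width
multiplier (variant 1 uses 1.0, variant 2 uses 0.5) and rounded to at
least one filter. The per-block decoder widths are reconstructed as:
the first convolution keeps its block's width, the second halves it
down the chain ($512{\to}256$, $256{\to}128$, $128{\to}64$,
$64{\to}64$), which is the only assignment that keeps every residual
addition channel-compatible with the OIS sources above. Under this
table, variant 1 totals 9,586,564 trainable parameters and variant 2
totals 2,400,196 (convolution kernels and biases plus batch-norm
scale/shift), a 75.0% reduction; `count_parameters()` computes these
from the assembled tensors. Whether published totals for such
architectures include batch-norm parameters is often ambiguous; here
they contribute less than 1% and are included.

With stride-2 pooling and floor semantics on odd sizes, a
$350\times350$ input reaches a $21\times21$ deepest feature map
($350 \to 175 \to 87 \to 43 \to 21$); unpooling restores the recorded
pre-pool sizes exactly, so the output mask always matches the input
resolution. Inputs below 16 pixels per side are rejected (a fifth of
the chain would vanish).

## Augmentation cascade

Training sets are expanded by a deterministic five-stage cascade, each
stage appending a transformed copy of the running set: (1) translate
$(+5, -5)$ pixels; (2) horizontal flip; (3) translate $(-5, +5)$ with
flip; (4) two branches, translate $(\pm10, \pm10)$ with flip, each
appended to the stage-3 set; (5) the final set is the concatenation of
both branches. Cardinalities run $n \to 2n \to 4n \to 8n \to 32n$; for
the 124-image folds typical of public chest-radiograph sets this is
$124 \to 992 \to 3968$. The concatenation retains the stage-3 pairs
twice — the only reading under which those printed counts are
arithmetically consistent. Images are resampled bilinearly, masks by
nearest neighbour (labels must stay in the alphabet), and vacated
borders are filled with intensity 0 / background label 0.

## Training recipe

Training is from scratch (He-normal kernels, no pretrained weights)
with Adam at learning rate $3\times10^{-4}$ ($\beta_1 = 0.9$,
$\beta_2 = 0.999$), minibatches of 17 images, and 20 epochs by
default. Gradients are clipped by their *global* L2 norm: if the norm
$g$ over all tensors exceeds the threshold (6), every gradient is
scaled by $6/(g + 10^{-6})$. Iteration counts per epoch are always
derived as $\lceil n / \text{minibatch} \rceil$ from the actual
dataset, never asserted.

The loss is cross-entropy with median frequency balancing. For class
$c$, the frequency $f_c$ is its pixel count divided by the total
pixels of the images in which it appears, and its weight is
$w_c = \operatorname{median}(f)/f_c$ (0 for absent classes), following
the convention of the encoder--decoder segmentation lineage that
popularized the technique. The loss over $N$ pixels is
$-\tfrac{1}{N}\sum w_{y}\log p_{y}$. Thin structures such as clavicles
(≈0.5% of pixels) would otherwise be ignored by the optimizer.

Batch normalization uses batch statistics during training (momentum
0.1 running updates, $\epsilon = 10^{-5}$) and running statistics at
inference. Max-pooling breaks ties by the first maximum in
column-major window order, so forward passes are deterministic; with a
fixed seed and fixed BLAS threading, whole training runs are
reproducible.

## Metrics

Per class, with one-vs-rest pixel counts,

$$\mathrm{Acc} = \frac{TP + TN}{TP+FP+FN+TN},\qquad
  J = \frac{TP}{TP+FP+FN},\qquad
  D = \frac{2TP}{2TP+FP+FN},$$

so $D = 2J/(1+J)$ identically — the suite checks this algebra
numerically. A class absent from both prediction and truth is scored
$J = D = 1$ (a correctly absent structure is a perfect prediction, and
this avoids 0/0). Summary means cover foreground classes by default;
two-fold cross-validation reports the arithmetic mean of the two fold
reports.

## CTR and cardiomegaly

From a multiclass mask, `compute_ctr()` takes
$AB = x_{\max}(\text{heart}) - x_{\min}(\text{heart})$ and
$CD = x_{\max}(\text{lungs}) - x_{\min}(\text{lungs})$ (both lungs
pooled) and returns $\mathrm{CTR} = AB/CD$. Extents are coordinate
*differences*, not pixel counts: the reference worked example with
$AB = 130$ and $CD = 302$ gives $0.4305$ under this convention and
would not under the $+1$ counting variant. A mask without heart or
lung pixels raises an explicit undefined-CTR error rather than
returning 0. The cardiomegaly flag compares the CTR against a
configurable threshold (default 0.5 — clinical cutoffs vary by age
group). By default all class pixels enter the extremes; an optional
largest-component mode filters speckle in noisy predicted masks.

## The phantom generator

`generate_phantom()` renders a minimal frontal chest scene: two
vertically elongated elliptical lung fields, one elliptical heart
shadow overlapping the medial-lower lungs (heart label wins where they
overlap), optionally two thin oblique clavicle bars near the apex,
Gaussian intensity noise (clipped to $[0,1]$), and a configurable
heart/lung intensity gap at the heart border, which is the weakest
contrast in real radiographs and the hardest boundary for a segmenter.
The horizontal extents of the heart and lung pair are pinned exactly
to the configured values, so the ground-truth CTR is
`heart_extent / thorax_extent` by construction and
`compute_ctr(mask)` returns it exactly — a round-trip the tests rely
on. Because extents are coordinate differences, `thorax_extent` is
capped at `width - 1`.

`generate_dataset()` perturbs the geometry per sample: thorax width
uniform in 88--100% of the base, CTR uniform in $[0.36, 0.56]$
(straddling the 0.5 decision threshold), whole-scene shifts of up to
±3%, and an independent noise realization, all driven by one integer
seed.

What the phantom does *not* emulate: rib cages, mediastinal structure,
exposure gradients, pathology, patient positioning, or the texture
statistics of real radiographs. Tests that pass on phantoms therefore
validate the machinery (wiring, gradients, protocol, CTR chain) and
the network's capacity to learn shapes with weak boundary contrast —
they say nothing about clinical performance, which requires the public
radiograph datasets and full-scale training, both outside this
package's test surface.

## Desk-scale problem sizes

The test suite trains the quarter-width network (multiplier 0.25,
widths 16--128) on 200 phantoms at $96\times96$ with the default
optimizer settings, evaluating mean foreground Jaccard on 50 held-out
phantoms; unit tests use a 1/32-width network at $16\times16$ to
$64\times64$. These sizes were chosen as the smallest at which the
mesh's behaviour (all twelve paths carrying gradient, pooling-index
round trips, convergence well above an untrained baseline) is
observable; the full-width network is assembled and run forward, but
never trained in the tests.

## Numerical choices and limitations

* He-normal initialization with fan-in $9 \cdot C_{\text{in}}$; biases
  and batch-norm shifts start at zero, scales at one.
* Convolution is im2col + GEMM in compiled code, in double precision;
  results are deterministic on a fixed BLAS.
* Pooling of odd sizes floors (the last row/column does not pool);
  unpooling restores the recorded size, so shape round-trips are exact.
* The softmax subtracts the per-pixel maximum before exponentiation;
  the loss clamps probabilities away from zero before the log.
* Bias parameters of convolutions that feed straight into batch norm
  are redundant (their gradient is analytically zero); they are kept
  because the parameter-count conventions for this architecture family
  include them.
* `run_protocol()` accepts a `segmenter` override so the evaluation
  protocol can be validated against a ground-truth oracle (which must
  score exactly 1) independently of model quality.
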