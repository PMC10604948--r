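---
title: "Heatmap regression for cephalometric landmarks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatmap regression for cephalometric landmarks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephmark)
```

## The problem

Orthodontic cephalometric analysis starts from 19 named reference points
(sella, nasion, orbitale, ..., articulare) marked on a lateral skull
radiograph. On scanned analog films the contrast is poor — soft tissue
especially — and manual annotation is slow and observer-dependent. The
package automates the two steps of that workflow: detecting the 19
landmarks, and converting them into the seven standard clinical
measurements (ANB, SNB, SNA, ODI, APDI, FHI, FMA) with an anatomical-type
classification for each.

## Heatmap encoding

Rather than regressing coordinates directly, each landmark
$L_i = (L_i^x, L_i^y)$ becomes a dense target map

$$H(x, y; L_i, \sigma) \;=\; \frac{\phi}{\sigma\sqrt{2\pi}}
  \exp\!\left[-\frac{(x - L_i^x)^2 + (y - L_i^y)^2}{2\sigma^2}\right],$$

clamped to $[0, 1]$, with a 20th background channel
$\max(0, 1 - \sum_i H_i)$ so the 20 channels approximate a per-pixel
distribution that a softmax output can match. The amplitude defaults to
$\phi = 5$. The peak value of the Gaussian is $\phi / (\sigma\sqrt{2\pi})$;
since the encoding is also required to read as a probability with value
exactly 1 at the landmark, the default standard deviation is the unique
value that makes both statements true simultaneously,
$\sigma = \phi/\sqrt{2\pi} \approx 1.995$ px. Both parameters are
configurable through `heatmap_spec()`. Decoding is the per-channel argmax
(no sub-pixel refinement), with ties broken in row-major order so the
decoder is a deterministic function of the stack.

## The network

`build_network()` assembles a chain of three tied encoder–decoder FCNs
(3×3 conv + batch norm + ReLU blocks, 2×2 max pooling down, 2×2 stride-2
transposed convolutions up, skip connections at every level; widths
16→32→64→128 by default, the last being the bridge). Three structural
modules distinguish it from a plain stacked U-Net:

* **Multi-scale inputs (MSI).** The input image is average-pooled by 2, 4
  and 8, passed through one conv block each, and concatenated with the
  down-sampled features at the matching encoder levels of the first stage.
* **Dual attention (SAM + CAM)** at the first stage's bridge. The spatial
  branch forms an $N \times N$ position-affinity map ($N = H W$ at bridge
  resolution) from two pointwise projections, softmax-normalised over
  source positions, and uses it to aggregate a third projection; the
  channel branch does the analogue over the $C \times C$ channel-affinity
  map computed from the features directly, with no learned projections.
  Each branch output is $\gamma \cdot \text{aggregate} + F$ with its gain
  $\gamma$ initialised to exactly 0, so both branches start as identity
  maps and the attention strength is learned.
* **Multi-path convolution (MCM)** at the bridges of stages 2 and 3: a
  plain 3×3 path and a dilated 3×3 path (rates 2 and 3 respectively) are
  concatenated and reduced back to the bridge width, widening the
  receptive field without extra pooling.

Every stage ends in a 3×3 convolution and per-pixel softmax over 20
channels; all three outputs are supervised during training (the loss is
the sum of the three cross-entropies), and only the last stage's output is
decoded at inference.

Where the architecture description leaves choices open, the package takes
the following positions (recorded here because they are design decisions,
not derivations):

* Stage-to-stage handoff: stage $k{+}1$ consumes the concatenation of
  stage $k$'s final decoder feature map with the raw image, keeping both
  learned context and the original intensity evidence.
* The two attention branch outputs are summed to form the first stage's
  decoder input; the un-resampled branch outputs are concatenated at the
  bridges of stages 2 and 3 (all bridges share one spatial resolution, so
  no resampling is involved).
* SAM projections are 1×1 convolutions with the score projections at
  $C/8$ channels (minimum 1) and the value projection at $C$ channels.
* One conv block per encoder/decoder level; MSI feeds the first stage
  only; the affinity softmaxes normalise over the aggregation index, so
  every row of the returned attention map sums to 1.
* Weight initialisation is He-uniform for convolutions, scale 1 / shift 0
  for batch norm (momentum 0.9, eps 1e-3), gains 0 for attention. The
  background channel of each output layer's bias starts at the log-prior
  of the overwhelmingly-background targets (+6), so the softmax begins
  near the marginal label distribution and the optimiser spends its steps
  on localisation rather than on discovering the class prior.

The convolution kernels run through an im2col + BLAS GEMM path in C++; the
GEMM is evaluated in single precision (activations and weights are
order-1 quantities, and stochastic-gradient training has a far larger
intrinsic noise floor), with a double-precision switch
(`options(cephmark.conv_double = TRUE)`) used by the finite-difference
tests.

## Training

`fit()` minimises the deep-supervision cross-entropy (`fcel()`, the exact
sum of the three per-stage `cel()` terms) with RMSprop (lr $10^{-4}$,
$\rho = 0.9$, batch 8 by default), reducing the learning rate by 0.5
whenever the validation loss fails to strictly improve for 25 consecutive
epochs (no lower bound). The checkpoint with the lowest validation loss is
kept. Augmentation (when enabled) draws rotation in $[-10°, 10°]$, zoom in
$[0.95, 1.05]$ and a multiplicative intensity factor in $[0.5, 1.5]$ per
sample, applies the same affine map to image (bilinear, edge padding) and
landmarks, and re-encodes the heatmap targets from the transformed
landmarks — targets are never warped. A draw that pushes a landmark out of
the frame is retried up to 10 times, then the sample is skipped with a log
record. The loss averages over elements (not pixels), so its scale is
robust to batch-size changes; augmentation is applied on the fly each
epoch rather than as a pre-expanded set.

## Evaluation

Radial errors are Euclidean distances in millimetres. Because the resize
from the scanned frame (2400×3000 at 0.1 mm/px) to the network frame
(576×736) is anisotropic (factors 25/6 and 375/92), coordinates are always
mapped back to the original frame before applying the isotropic
millimetre factor; computing distances in resized pixels is deliberately
not offered. `sdr()` counts errors *strictly below* each threshold (the
boundary rule is configurable and recorded in the report), and the
reported spread is the population standard deviation. `mre()`,
`cumulative_curve()` and `stratified_report()` are thin, oracle-tested
group-by operations on the same error table.

## Clinical measurements and classification

`compute_measurements()` evaluates the three nasion angles and the
composite indicators from the printed point/plane definitions, with every
plane angle taken between directed vectors ordered exactly as "from X to
Y" (an undirected mode exists but is off by default, since no sign
conventions are printed). FMA is implemented as the angle between the S–N
and Go–Gn lines — exactly as defined, even though the name suggests the
porion–orbitale plane. All seven values are invariant to rigid motion and
uniform scaling, so they can be computed in any frame.

The class thresholds ship as an editable JSON table in two variants. The
printed table contains three internally inconsistent rows (SNB class 3
"<78.7°" overlaps class 1; ODI class 2 "<80.5°" overlaps classes 1 and 3;
APDI class 2 ">77.6°" overlaps class 1) and one gap (SNA between 83.2° and
83.5°). The default `corrected` variant completes each row into a monotone
partition — inside the interval is class 1, and the two sides take the
class labels oriented by the unambiguous rows — while `literal`
applies the predicates verbatim with precedence 1→2→3, flagging overlap
hits and refusing (with an `unclassifiable` flag, never silently) values
that satisfy no predicate. The ANB overlap (class 1 from 3.2°, class 3
below 3.5°) is resolved by class-1 precedence in both variants. Reports
carry the variant name.

## The phantom generator

Real scanned cephalograms are restricted clinical data, so the package ships a
seed-deterministic generator of cephalogram-like scenes: cranial vault and
base, sella ring, orbit, mandible, palatal line, incisors and a fainter
soft-tissue profile, rendered as anti-aliased strokes through 19
analytically placed landmark points, then blurred and corrupted with
Gaussian noise. Every sample is a pure function of (spec, index, seed) via
counter-based substreams, so datasets are bitwise reproducible and
order-independent. Landmark placement is exact, which makes detector error
on phantoms attributable entirely to the model.

Two presets exist. `realistic` emulates the scanned-film regime the
detector is meant for: low bone contrast, much lower soft-tissue contrast,
stronger blur and noise. `easy` is the preset the desk-scale learning
experiments use, and its design follows from an optimiser-budget argument:
at learning rate $10^{-4}$ with 160 training images, batch 8 and at most
30 epochs, RMSprop moves each weight by at most roughly
$600 \times 10^{-4} = 0.06$, which is far too little to learn global
position context from scratch. A preset is only "learnable" under that
budget if landmark identity is decodable from a small neighbourhood by an
almost-linear readout. The easy preset therefore marks each landmark with
a high-gradient blob whose intensity encodes its index (a graded ramp)
plus a short tick at a per-landmark angle — locally unambiguous,
high-gradient points. Consequences worth stating plainly: passing the
desk-scale learning experiment shows the full optimisation/decoding
pipeline works end to end, and that the attention/MSI modules help on this
family of images; it does not demonstrate clinical-grade accuracy on real
radiographs, which differ exactly in that landmark identity there *does*
require global anatomical context. The "age" stratum attached to each
phantom is a covariate derived from the global size parameter — useful for
exercising stratified reports, with no biological meaning.

Numerical details: strokes are composited by per-pixel maximum (roughly a
maximum-intensity projection), the blur reuses the package's own
convolution kernel, and images are 8-bit PNG on disk. Desk-scale
experiments use 96×128-pixel phantoms with widths [8, 16, 32, 64]; at that
size one training epoch (20 RMSprop steps) takes on the order of half a
minute on one CPU core.

## Known limitations

* The phantom family is far simpler than scanned films: no superimposed
  bilateral structures, no film-grain artefacts, no true anatomical shape
  variation; results on phantoms bound nothing about patient data.
* Argmax decoding quantises predictions to integer pixels, contributing up
  to ~0.7 px of error at the decoded resolution.
* The spatial attention map is materialised as a dense $N \times N$
  matrix; inputs whose bridge exceeds the configured budget are rejected
  with a capacity error rather than approximated.
* Training is single-threaded CPU; the default full-size configuration
  (576×736, widths 16–128) is provided for completeness and forward
  passes, but sustained training at that size calls for more compute than
  a desk experiment.
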