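---
title: "Comparing complex-valued and real-valued convolutional networks fairly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing complex-valued and real-valued convolutional networks fairly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvfair)
```

## The question the package answers

Does a convolutional classifier whose weights and activations are complex
numbers extract more discriminative structure from ordinary real-valued
biomedical images than a real-valued classifier of equivalent capacity?
`cvfair` implements the full experimental apparatus needed to ask that
question honestly: a complex-valued layer algebra, a domain-conversion
front end, a parameter-matched pair of architectures, stratified
cross-validated training with identical conditions for both networks, and a
statistical protocol for deciding whether observed metric differences are
real. Everything runs on synthetic two-class image data generated in-code,
so the pipeline is testable end to end without any external downloads; the
per-fold metric tables of the original clinical study (melanoma dermoscopy
and heart-sound scalograms) ship as fixtures for the statistical stage.

## The model

### Complex layers over paired real tensors

A complex activation or weight $z = a + bi$ is carried as the pair
$(a, b)$ of real arrays (`complex_tensor`). All layers are then expressed
in real arithmetic:

* **Convolution** (`complex_conv2d`): elementwise complex products
  accumulated over the kernel support,
  $\mathrm{out} = (x_r * w_r - x_i * w_i) + i\,(x_r * w_i + x_i * w_r)$,
  which equals convolution in native complex arithmetic (the package's
  oracle tests verify this to $10^{-10}$). The sliding window uses the
  deep-learning cross-correlation convention; a `flip_kernel` flag gives
  textbook convolution, which differs only by a kernel flip.
* **Activation** (`complex_relu`): the zReLU gate — a value passes
  unchanged only when *both* its components are strictly positive,
  otherwise it becomes $0 + 0i$. The boundary is excluded by the strict
  inequality, and the subgradient on the blocked set is taken as zero. A
  `crelu` mode (independent rectification of the two components) is
  provided because it reduces exactly to the ordinary ReLU when the
  imaginary part vanishes; it is what makes the zero-imaginary embedding
  check possible (see below).
* **Average pooling** (`complex_avg_pool`): the arithmetic mean applied to
  each component, which by linearity is the complex mean.
* **Dense layers** (`complex_linear`): the bilinear (non-conjugating)
  product $y = Wx + b$. The conjugating Hermitian-inner-product variant is
  exposed via `conjugate_weights`, but the bilinear form is the default:
  conjugation would make the map non-holomorphic in the weights and departs
  from the convention of complex-network practice.
* **Readout** (`magnitude_readout`): class scores must be real to feed a
  softmax, so the output layer's two complex scores are projected by their
  modulus. The real-part projection is available (`readout = "real"`) and
  is used by the embedding tests.

Because every layer is a real map of the component arrays, ordinary real
backpropagation trains the networks; the two components of each complex
weight are learned jointly. The backward pass of every layer is checked
against central finite differences to a relative $10^{-4}$.

### Fourier-domain input conversion

Real images enter the complex domain through the DFT Vandermonde matrix
$F_{jk} = w_N^{jk}$, $w_N = e^{-2\pi i/N}$ (`dft_matrix`), applied along
the image width per row and channel. For real input the spectrum is
Hermitian-symmetric, so only the first $\lfloor W/2\rfloor + 1$ components
are retained — "almost half" the original width — with no information loss
(`reconstruct_real` inverts the reduction exactly, and the package asserts
the round trip to $10^{-8}$ and Parseval's identity to a relative
$10^{-8}$). Two points were genuinely open and are settled here as
package defaults:

* **Transform axis.** The width axis only (1-D per row), keeping the
  height axis spatial so that convolution still sees spatial structure
  while the stated component reduction is delivered. A 2-D option
  (`axis = "both"`) transforms both axes and reduces the last.
* **Base of the Vandermonde matrix.** The unit-modulus DFT kernel
  $e^{-2\pi i/N}$ with exponent $jk$. No other reading produces a Fourier
  matrix with the Hermitian symmetry the construction relies on.

Images are first standardised per image — mean subtracted, divided by the
population standard deviation (`normalize_image`) — identically at
training and evaluation time, so no statistics leak across data splits. A
dataset-level alternative would also be defensible; per-image is the
default because it makes every input's scale identical by construction.
Resizing (`resize_image`) is bilinear with antialiasing.

### The parameter-matched pair

Both architectures follow the same schedule: three convolution /
average-pool / activation stages, three dense layers, a two-unit output
(`architecture_spec`, `network_layers`). Fairness is defined in
real-scalar units: one complex weight is two trainable scalars, and the
shipped pair (`default_architecture_pair`) is matched to a ratio of
1.0004 — 50,244 scalars (complex) versus 50,226 (real) at the 32-pixel
test scale — by widening the real network's first dense layer (80 vs 64
units) to offset the complex network's halved Fourier-domain input width.
`parity_report` checks the ratio against a configurable tolerance
(default ±10%).

The original study's per-layer parameter ledger is shipped as a fixture
(`load_parameter_ledger`); its column sums (1,155,610 complex units vs
2,429,790 real scalars, ratio ≈ 0.476) document that the published
networks satisfy the same parity once complex units are doubled. The
ledger's per-layer counts cannot be inverted to unique kernel and channel
sizes — no consistent small-kernel factorisation exists under standard
counting — so reproducing them literally is out of scope; all sizes here
are configuration-driven, with a 224-pixel configuration available via
`default_architecture_pair(input_size = 224)`.

### Training

Both networks are trained per fold with softmax cross-entropy over the two
real class scores and Adam at learning rate 0.001. For complex parameters
the optimiser uses the complex correction (`complex_adam_step`): first
moments per component, but a *single* second-moment accumulator driven by
the squared gradient modulus $g_r^2 + g_i^2$ and shared by both
components, so each complex weight is treated as one unit when its step
size adapts. Cross-validation is stratified $k$-fold with $k = 10$
(`kfold_split`): with only 40 abnormal cases in a PH2-sized dataset,
unstratified folds can lack positives entirely and leave sensitivity
undefined. The fairness contract is enforced structurally in
`run_experiment`: both structures receive byte-identical fold splits,
identical initialisation seeds and identical batch-order seeds; the
abnormal class (label 1) is the positive class throughout, the standard
disease-detection convention.

Epochs (50) and batch size (16) are this package's defaults for the
test-scale problem (32-pixel images, a few hundred samples); both are
plain `training_config` fields.

## The statistical protocol

Per metric (F1, Precision, Recall/Sensitivity, Accuracy, Specificity over
the 10 folds), `select_and_compare` applies a normality gate: Shapiro–Wilk
on both samples at $\alpha = 0.05$; if both pass, a two-tailed two-sample
t-test, otherwise the Mann–Whitney U test (tie-corrected normal
approximation with continuity correction — with $n = 10$ per group and
heavy ties, exact enumeration is not uniquely defined across conventions).
A metric that is constant across folds (a degenerate but real outcome,
e.g. specificity 1 in every fold) has no defined Shapiro–Wilk statistic
and is certainly not a continuous normal draw, so the gate records `NA`
and falls through to the rank test rather than failing.
The t-test defaults to **Welch's** unequal-variance form: recomputing the
published PH2 comparison table from the published fold values reproduces
its p-values essentially exactly under Welch (e.g. $7.719 \times 10^{-8}$
vs the printed $7.71763 \times 10^{-8}$ for F1) and under no pooled
variant, so Welch is evidently what the study ran despite the generic
"Student's t" label; the pooled form remains available via `var_equal`.

Each structure is summarised in ROC space by its mean sensitivity and mean
specificity: the point $(1 - \mathrm{spec}, \mathrm{sens})$, whose
Euclidean distance to the ideal corner $(0, 1)$ is `roc_distance`, and the
percent reduction of the worse structure's distance is
`relative_superiority`. `build_report` assembles all of this into a
`comparison_report` (JSON/text serialisable via `write_report`).

```{r report}
rep <- build_report(load_paper_fold_table("ISIC2017", "complex"),
                    load_paper_fold_table("ISIC2017", "real"))
rep$roc$complex$distance
rep$roc$real$distance
rep$relative_superiority
```

### What the fixtures can and cannot reproduce

The fixtures store the published fold values exactly as printed (five to
six decimals); summary rows are always recomputed, never stored, because
several printed summaries are internally inconsistent with their own fold
values (e.g. the ISIC2017 complex table's Accuracy summary duplicates its
Recall summary, and the PH2 complex table's printed Accuracy fold column
duplicates its Recall column). Recomputing the normality rows from the
printed folds reveals two further printing artefacts, which the package
documents rather than hides: the F1/Precision/Recall normality p-values of
the PH2 and Pascal tables are cyclically shifted by one column relative to
the fold columns, and values that depend on sub-precision detail (or on
the unprinted true Accuracy folds) do not reproduce at all — rounding the
folds to five decimals creates ties that shift Shapiro–Wilk p-values
substantially. The package's acceptance tests assert the published
normality and U-test values as stated and record the irreproducible ones
as failing checks; the qualitative conclusion — every gated test rejects
the no-difference null at $\alpha = 0.05$, with the complex structure's
mean above the real structure's for every metric and dataset — reproduces
from the printed folds without qualification.

## The synthetic generators

`generate_lesion_dataset` emulates dermoscopy-like data: a textured skin
background (low-frequency field plus Gaussian pixel noise), a central
pigmented region; normal lesions are near-elliptical, smooth-bounded and
uniformly toned, while abnormal lesions gain boundary irregularity (radial
harmonics), centroid offset, and a darker multi-tone interior — the
classic asymmetry/border/colour cues — each scaled by a single
`separability` knob in $[0, 1]$. `generate_scalogram_dataset` emulates
heart-sound scalograms: periodic pairs of low-frequency Gaussian energy
bursts (S1/S2) with all content in the lower part of the frequency axis,
as in low-pass-limited recordings; abnormal cases add a mid-frequency
murmur band between the pair with amplitude proportional to
`separability`. Images are 8-bit in $[0, 255]$ (downstream processing
treats them as floating point), three-channel for lesions, single-channel
for scalograms, generated bit-identically from the profile seed.

`separability = 0` makes the two class-generating distributions
*identical* by construction — every abnormal-only effect carries a factor
of the knob — and the class-mean gap of a fixed scalar discriminant
(interior standard deviation for lesions, murmur-band energy for
scalograms) grows monotonically with the knob; both properties are
asserted at $n = 200$ per class. Default class counts mirror the clinical
datasets (1621/374, 160/40, 320/141); the default image side is 224 as in
the original preprocessing, while the test suite works at 32 pixels for
speed.

What passing tests on these generators show is that the *pipeline*
behaves correctly — separable classes are learned, inseparable ones sit at
chance, both structures are treated identically; they do not show that
either structure would win on real dermoscopy or phonocardiography data.
The generators deliberately omit real-data features (hair, rulers,
vignetting, specular highlights, sensor artefacts, recording noise
structure) that could drive such differences. For the same reason the
published fold values are *not* an acceptance surface for retrained
networks: reproducing them would require the original data and
GPU-training regime, and their printed metric combinations are in places
mutually inconsistent under any single positive-class prevalence.

## Numerical choices and problem sizes

* $O(N^2)$ DFT by explicit matrix product: at image widths up to 224 the
  cost is negligible and the Vandermonde matrix itself is the construction
  of interest.
* Convolution via memoised gather (im2col) and fused stacked GEMMs; the
  two index kernels are the package's only compiled code.
* Magnitude readout derivative at the origin is taken as 0 (the modulus is
  not differentiable there); a $10^{-12}$ guard avoids division by zero.
* Weight initialisation: zero-mean Gaussians scaled by fan-in; a complex
  weight's two components split the variance budget.
* The test suite trains at 32-pixel resolution with PH2-like (160/40) or
  balanced 40/40 designs, 10 or 4 folds, 50 epochs — sizes chosen so the
  whole suite exercises every stage, including a complete 10-fold paired
  study, on a single CPU.

## Known limitations

* zReLU blocks roughly three quarters of symmetric activations; training
  the complex network is correspondingly slower per epoch of progress than
  the real network at equal parameter budget.
* Only non-overlapping average pooling is implemented (stride = window),
  matching the architectures used.
* The Mann–Whitney p-value uses the normal approximation; at $n = 10$
  with few ties an exact test can differ noticeably.
* No augmentation, batch normalisation, dropout or early stopping: the
  compared structures use convolution, average pooling and (complex) ReLU
  only, so that the numeric domain is the only varying factor.
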