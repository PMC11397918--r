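---
title: "Staging liver fibrosis from ultrasound RF signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging liver fibrosis from ultrasound RF signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the approach

Liver fibrosis is scored on the METAVIR scale F0 (none) to F4 (cirrhosis),
with biopsy as the reference standard. Quantitative ultrasound offers a
non-invasive alternative: the raw backscattered radiofrequency (RF) signal,
recorded before envelope detection, carries information about tissue
microstructure that the displayed B-mode image discards.

`rfstage` implements a two-step pipeline over RF frames of 1247 axial
samples x 256 scan lines (3 MHz centre frequency, 12 MHz sampling):

1. **Liver ROI segmentation.** The frame is reconstructed into a B-mode
   image (Hilbert envelope, 40 dB log compression, no scan conversion),
   resized to 192 x 256, and segmented by a 2D encoder-decoder CNN (U-Net or
   Attention U-Net). The predicted binary mask is resized back to the
   1247 x 256 signal grid.
2. **Spectral classification.** Each scan line's full-length FFT yields an
   amplitude, phase, or power spectrum; the frame of spectra is multiplied by
   the binary liver mask, min-max normalised, cut into 768-point gated
   segments (gate step 20), assembled into 768 x 256 windows, and classified
   line-by-line by a small 1D CNN for each binary stage dichotomy
   (>=F1, >=F2, >=F3, >=F4). A frame is called correct when the fraction of
   its 256 per-line predictions that agree with the label exceeds 0.5
   (strictly).

Because clinical RF data of this kind are not publicly deposited, the package
ships a synthetic phantom simulator so that every stage is trainable and
testable end to end. All reported numbers in the package's tests and in
`scripts/acceptance.R` are computed on that synthetic data; they demonstrate
that the pipeline machinery recovers known structure, not that it reproduces
clinical performance.

## The phantom simulator

Each scan line is an impulse train convolved with a Gaussian-enveloped cosine
pulse (unit peak, fractional -6 dB bandwidth 0.6 by default). The axial
resolution cell is the -6 dB pulse length (about 5.9 samples at the default
settings). Three tissue components are simulated per line:

* **Diffuse liver speckle.** Scatterer count ~ Poisson(density x band
  length), depths uniform, amplitude magnitudes gamma-distributed with mean 1
  and a stage-dependent coefficient of variation, random sign. At high
  density this produces fully developed speckle: the envelope SNR
  (mean/standard deviation) converges to the Rayleigh value
  `sqrt(pi/(4-pi)) = 1.913`, which the test suite verifies by Monte Carlo.
* **Coherent septa-like reflectors.** A quasi-periodic train (spacing 60
  samples, Gaussian position jitter of 3 samples) whose amplitude grows
  linearly with stage. This component is the package's own modelling choice
  and deserves explanation. Per-frame min-max normalisation removes the
  global scale of a spectrum frame, and a purely diffuse scatterer field is,
  in the many-scatterers limit, a circular Gaussian process whose spectrum
  differs across stages *only* by scale: after normalisation the amplitude
  distribution is nearly stage-invariant and the phase spectrum is exactly
  uniform noise at every stage. A density/variability change alone therefore
  cannot make the phase-spectrum classifier work. Regularly spaced coherent
  reflectors — a crude but physically motivated stand-in for fibrotic septa —
  concentrate energy in spectral combs and lock the phase near those combs,
  so both the amplitude *shape* and the phase *structure* become monotone in
  stage. The amplitude is parameterised relative to the diffuse energy per
  spacing period: `coherent_slope = 0.25` means the coherent component
  reaches parity with the diffuse field at F4.
* **Abdominal-wall-like surround.** Outside the liver band, scatterers with
  2.5x amplitude produce the bright non-liver region the segmenter must
  exclude.

Default stage maps: density per cell `10 * (1 + 0.4 s)`, amplitude CV
`0.3 * (1 + 0.3 s)`, coherent ratio `0.25 s`, all monotone so class
separation is controlled; a single `stage_effect` multiplier scales all three
slopes (0 = indistinguishable stages).

The liver band is delimited by two cosine-perturbed depth curves. The nominal
ranges are top in [150, 350] and bottom in [900, 1200] samples, but the two
draws are coupled: the bottom is drawn above
`top + min_band + 2 x wobble + 4` (with `min_band = 772`) so that every line
admits at least one 768-point gate. Uncoupled draws would leave an
appreciable fraction of frames without a single eligible line, which would
make the gating stage fail by construction rather than by data quality.

What the simulator deliberately does *not* model: lateral point-spread
coupling (each line is convolved independently), frequency-dependent
attenuation, nonlinear propagation, and scan geometry. Passing tests on this
phantom show that the networks, the gating arithmetic, and the evaluation
machinery behave correctly; they say nothing about contrast or effect sizes
in clinical livers.

## B-mode reconstruction and augmentation

The envelope is the magnitude of the analytic signal, computed by the
standard FFT construction (zero the negative frequencies, double the positive
ones); no installed package exposes this primitive, so it is implemented
directly and tested against the tone-envelope identity. Log compression maps
an envelope frame to `clip((20 log10(env/env_max) + DR)/DR, 0, 1)` with
DR = 40 dB by default: the frame maximum maps to 1, anything DR below it to
0. This is the standard B-mode display convention; only the dynamic range is
specified by the source method, the clip-to-[0,1] mapping is the package's
choice and a config knob. Note that because the reference is the *frame*
maximum, compression is order-preserving within a frame but not across
frames.

Dataset splitting shuffles participant identifiers with a seed and takes
`floor(r1 N)` for training and `floor(r2 N)` for validation, with the
remainder as test — the only rounding convention that yields 367/122/124
from 613 at 60:20:20.

Augmentation appends exactly one transformed copy per training or validation
pair: a rotation drawn from {0, 90, 180, 270} degrees, a random crop of
80-100% area resized back, and +-10% brightness/contrast jitter applied to
the image only. Three choices here were genuinely open and are resolved as
follows: 90/270-degree rotations of a non-square image are resized back to
the original shape so batches stay rectangular; the photometric ranges and
the crop geometry are explicit defaults, not claims about the original
protocol; saturation jitter is a no-op on single-channel images and is
omitted. Masks are re-binarised at 0.5 after any interpolation. All resizing
is separable bicubic interpolation with the Keys kernel (a = -0.5) and edge
clamping, which reproduces constants exactly and linear ramps to within
interpolation error.

## The segmentation networks

Both networks follow the classical encoder-decoder layout: per level two 3x3
convolutions (each batch-normalised then ReLU), 2x2 max pooling between
levels, transpose-convolution (2x2, stride 2) up-sampling, skip connections,
and a 1x1 convolution with sigmoid as the head. The Attention variant gates
each skip tensor with additive attention: 1x1 maps of the skip and the
(up-sampled) gating tensor are summed, ReLU'd, projected to one channel and
squashed to per-pixel coefficients in (0,1) that multiply the skip tensor.
Channel widths are configurable; (32, 64, 128, 256, 512) is the default and
(8, 16, 32, 64) is used throughout the tests, where the band-versus-wall
geometry is easy enough for a small network.

Training is mini-batch Adam (batch 2, lr 2e-4, betas 0.9/0.999) on binary
cross-entropy, with the best-validation-loss parameters retained; where the
source method is silent, model selection by validation loss and a 0.5 output
threshold are the package's choices. Because no deep-learning framework is
available in this R environment, the networks are implemented directly:
im2col + BLAS matrix products (RcppArmadillo) for the convolutions, manual
backpropagation, and batch-norm running statistics with momentum 0.1 and
eps 1e-5. Every kernel's gradient is verified against finite differences in
the test suite, and whole-network gradients are spot-checked the same way;
training is bit-deterministic for a fixed seed because all randomness flows
through R's RNG.

Predicted 192 x 256 masks are resized back to 1247 x 256 bicubically and
re-binarised at 0.5 (bicubic output is not binary; the threshold is the
package's choice).

## ROI spectra, gating and balancing

Spectra are computed by a full-length FFT of each 1247-sample line: no
windowing, no zero padding, standard bin order, `angle(0)` defined as 0.
The depth-axis liver mask is multiplied into the frequency-axis spectrum
elementwise. This is a faithful implementation of the source pipeline rather
than a physically motivated operation — the mask indexes samples, the
spectrum indexes frequency bins — and the package preserves it deliberately;
the normalisation (frame-wide min-max to [0,1], masked zeros included)
happens after masking and before gating, in the order the pipeline implies.

Gating: a line is eligible when its longest contiguous liver run is at least
768 points ("more than 768" is read inclusively so that an exactly fitting
gate yields one segment; a strict reading is available via `strict = TRUE`).
Eligible runs are cut into 768-point segments at offsets 0, 20, 40, ...,
giving `floor((L - 768)/20) + 1` segments per line, concatenated laterally in
line order then offset order. A 768 x 256 window then slides over the gated
matrix in steps of `max(1, floor((L_lateral - 256)/n_aug))`, emitting exactly
`n_aug` windows with start columns clipped to fit (the exact quotient in the
source is generally non-integral; flooring with clipping is the package's
resolution). Frames narrower than 256 columns are an error by default, with
optional reflect padding behind a flag.

Class balancing augments only the training minority:
`n_aug = round(N_major/N_minor)` windows per minority frame (nearest-integer
rounding of a generally non-integral quotient), one window for everything
else including all validation and test frames. Two deliberate deviations are
baked in here. First, frames are split *before* augmentation — augmenting
first and splitting afterwards would place near-duplicate windows of one
participant across parts and leak information, while splitting first
preserves participant purity. Second, the split is stratified by class
(per-class floor/floor/remainder after a seeded shuffle): at desk-scale
cohort sizes an unstratified shuffle routinely leaves a class absent from a
part, which is an error condition. A class missing from train or test is
still a hard error; a validation part without both classes only warns, and
with an empty validation set model selection falls back to training loss
(necessary for very small smoke-test cohorts, where two minority frames
cannot populate three parts).

## The 1D classifier and whole-frame voting

Each of the 256 lines in a gated window is an independent instance with the
window's label. The network is four 1D convolutions (tanh) each followed by
max pooling, then a flattened vector through four fully-connected layers
(tanh on the hidden ones) to 2 logits; softmax cross-entropy, Adam (batch
256, lr 2e-4), best-validation-loss selection. The layer sizes are not fixed
by the source method; the defaults — channels (4, 8, 16, 32), kernels
(7, 5, 5, 3), pools (4, 4, 2, 2), fully-connected (64, 32, 16, 2) — were
chosen once for single-CPU training at the package's test scale and are all
configurable. The 4+4+4/tanh structure itself is a tested contract.

Voting: `p = n_c/(n_c + n_w)` over the 256 per-line predictions;
`frame_correct` iff `p > 0.5` strictly, so a 128:128 tie counts as incorrect
and the majority class of a tied frame is defined as the class opposite the
true label, keeping the two views consistent. For ROC analysis the frame
score is the mean positive-class probability across lines (the source
reports AUC without defining a frame score; the mean is the package's
choice, order-invariant and in [0,1] by construction).

## Metrics

Segmentation uses the pixel-set definitions of Jaccard, Dice, accuracy,
sensitivity, precision and specificity. Two empty masks count as a perfect
pair (flagged); undefined ratios are NaN. Cohort values are macro-averaged
per image by default, with a micro (pooled-pixel) mode available, since the
aggregation convention is not stated by the source. Dice and Jaccard obey
`DSC = 2 JSC/(1 + JSC)` exactly, which the suite checks to 1e-12.

Classification uses the confusion-count definitions of accuracy, sensitivity
and specificity on whole-frame predictions. The ROC curve is a threshold
sweep over unique scores with ties grouped into single steps; the AUC is its
trapezoidal area and equals the Mann-Whitney probability (ties counted 1/2),
verified against a brute-force pairwise oracle and against pROC.

## Orchestration, seeds and reproducibility

`run_pipeline()` executes the whole chain from one declarative config (R
list or YAML) into an output directory, one artifact per stage, each stamped
with the config hash; `resume = TRUE` reuses artifacts whose hash matches.
Every stage seed derives from one master seed, and all stochastic components
draw from R's RNG, so a config reproduces its reports byte-for-byte. If a
predicted mask yields fewer gated segments than one window width, that frame
falls back to an all-ones mask (no ROI restriction) and the report counts
the fallback — segmentation quality then degrades classification gracefully
instead of aborting the run.

## Problem sizes used by the tests

The test-suite and acceptance-script sizes are the package's own desk-scale
study design: classifier recovery uses 40 frames (20 each of F0 and F4, the
default `stage_effect = 1`), phase spectra, ground-truth masks, 30 training
epochs, majority over 3 split/initialisation seeds; segmentation recovery
uses 80 frames (60/10/10) at 96 x 128 with widths (8, 16, 32, 64) for 20
epochs, for both architectures; the end-to-end smoke configuration uses 10
frames with 1-epoch trainings for all four tasks. With the default phantom
these sizes recover labels essentially perfectly (frame accuracy and AUC at
or near 1.0) and masks at Dice around 0.98; the thresholds asserted by the
tests (accuracy >= 0.9, AUC >= 0.95, Dice >= 0.85, architectures within 0.05
Dice) leave room for seed-to-seed variation, not for weak recovery.

## Known limitations

* The simulator's stage effect is a stand-in; its magnitude is not
  calibrated to clinical contrast, and nothing here validates clinical
  performance.
* The depth-mask-times-frequency-spectrum operation is preserved from the
  source pipeline as-is; physically it mixes axes, and the package makes no
  attempt to reinterpret it.
* The CNN engine is minimal by design: stride-1 'same' convolutions,
  2x2/stride-2 transpose convolutions, max pooling, batch norm, additive
  attention. It is not a general autodiff framework.
* Batch-norm statistics with batch size 2 are noisy; inference uses running
  averages (momentum 0.1), and very short trainings (a few steps) can leave
  them far from the batch statistics.
* The literal stated invariant "log compression is monotone across frames"
  holds only within a frame, because the decibel reference is the frame
  maximum; the suite tests the within-frame property.
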