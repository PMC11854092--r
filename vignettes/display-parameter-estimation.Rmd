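---
title: "Estimating surgical display parameters from microscope frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating surgical display parameters from microscope frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During cataract surgery on a 3-D heads-up display, the surgeon tunes eight
screen controls — brightness, saturation, contrast, cyan, gamma, magenta,
hue and yellow — until the illuminated surgical field (the pupil /
red-reflex area) is optimally visible for the current stage of surgery.
The tuning is manual, per patient, and time-consuming. `surgiview`
implements a two-stage learning system that proposes those eight values
automatically from a single raw frame:

1. **ROI extraction.** The illuminated field is segmented from the full
   frame by grayscale conversion, histogram (Otsu) thresholding,
   binarization, small-object removal, selection of the largest connected
   component, and a bounding-box crop resized to a square working
   resolution (512 px at full scale).
2. **Pseudo-optimal image synthesis.** A conditional image-to-image
   (Pix2Pix-style) generator, trained on (raw ROI, surgeon-tuned
   reference) pairs, produces a "fake" image that mimics what the tuned
   display would show.
3. **Ensemble regression.** Two residual-network feature extractors — one
   fed the raw ROI, one the fake — are pooled (global average pooling),
   concatenated raw-branch-first, and a fully connected affine head
   predicts the eight parameters on a normalized [0, 1] scale.
4. **Evaluation.** Rendering the raw ROI with the predicted parameters
   and comparing against the reference with NRMSE, PSNR and SSIM, plus
   brightness/contrast/sharpness comparisons with paired t-tests.

The real surgical datasets behind the original study are private; the
package therefore ships a seeded synthetic ocular-scene generator with
known ground truth so that every stage is trainable and testable at desk
scale.

## The parameter model and renderer

The true transfer functions of a surgical display's knobs are
proprietary, so the package defines a fixed, deterministic,
parameter-identifiable stand-in (`render_params()`), applied in a pinned
order: CMY colour balance (cyan subtracts from red, magenta from green,
yellow from blue, in gray levels), hue rotation (degrees, HSV), saturation
scaling (`1 + s/100`), contrast scaling about mid-gray
(`127.5 + (1 + c/100)(v - 127.5)`), additive brightness, and display
gamma `255 (v/255)^{1/\gamma}` (gamma above 1 brightens mid-tones).
Arithmetic is floating point with one clip-and-quantize at the end; the
identity setting (all offsets 0, scales 1, `gamma = 1`) reproduces the
input bit-exactly, which anchors the ground-truth closure test
`reference == render(roi(raw), params)`.

Native ranges are a configuration concern (only the normalized view
reaches the network): ±100 for the additive/scaling controls, 0.2–3.0
for gamma, ±180° for hue. Normalization is the per-parameter affine map
onto [0, 1] and round-trips exactly.

## The generator architecture, reconstructed from parameter counts

The published architecture table lists 22 layers with output shapes and
trainable parameter counts but no wiring. The counts pin the topology
unambiguously: every decoder convolution's input channel count equals the
previous decoder output *plus the encoder activation at the same
resolution*, which means the skip concatenation happens after each
decoder convolution (at its output resolution) and the concatenated
tensor is upsampled into the next convolution — equivalently, the table's
`UpSampling2D` rows show only the main branch and omit the concatenate
steps. For example, layer 15 has 4·4·1024·256 + 256 = 4,194,560
parameters, which forces a 1024-channel input at 64×64 even though the
same-resolution encoder stage has only 256 channels. The innermost
decoder convolution (index 9, 512 input channels) takes no skip, exactly
as the counts require. `generator_spec()` reproduces the table
row-for-row at 512 px and `build_generator()` audits realized array
lengths against it, erroring on any mismatch.

Smaller builds (64/128/256 px) reuse the same logic: stride-2 4×4 encoder
convolutions with channel plan `min(64·2^{i-1}, 512)` down to a 4×4
bottleneck, then 2× nearest upsampling + 4×4 stride-1 convolutions back
up. The discriminator is the canonical conditional patch design (6-channel
input pair; 64/128/256 at stride 2, then 512 and 1 at stride 1; LeakyReLU;
a spatial grid of logits). Training follows the canonical recipe: BCE with
logits + λ·L1 (λ = 100), Adam at 2·10⁻⁴ with β₁ = 0.5, dropout omitted
(the table lists none), inputs scaled to [−1, 1] for the Tanh head.

Because no deep-learning framework exists in the target environment, the
convolution engine (im2col + BLAS, analytic gradients, Adam) is part of
the package. The training path runs in single precision — roughly twice
the speed of double on one CPU, ample for optimization — while exact
consumers such as the SSIM moments use the double-precision kernels. Unit
tests pin the kernels against naive direct convolution and central
differences.

## The ensemble regressor

Feature tap: global average pooling of the final convolutional stage, the
standard residual-network feature (D = 2048 for the full 50-layer build,
which the package constructs and runs; batch normalization is omitted in
favour of biased convolutions since the backbones here train from scratch
and no pretrained weights can be shipped). For desk-scale work
`resnet_small` is a shallow-and-wide reduced backbone (stride-2 stem and
three residual stages, widths 32/64/128, D = 128): keeping the network
shallow preserves first-order image statistics — channel means, local
contrast — in the pooled feature, which is what the display parameters
act on most directly, and measurably improves linear readout over a
deeper narrow variant.

The head is affine ("linear regression"): no output nonlinearity, values
clipped to [0, 1] only at the application boundary with the raw output
retrievable. Training minimizes MSE on the normalized parameters.
Features are standardized on each training fold; the head is warm-started
with its closed-form ridge solution (the L2 weight `weight_decay` plays
the ridge penalty) and then refined by Adam, keeping the best-validation
epoch (the warm start counts as epoch 0, so refinement can only help).
With `freeze_backbones = FALSE` (the library default) both branches are
fine-tuned jointly through the same objective; the two backbones are
never weight-shared, matching the "independently trained" reading.
Folding is grouped by patient by default — 1,199 frames from 95 patients
are correlated samples, and grouped folds are the leakage-safe choice.

## The synthetic world

Each scene contains one bright elliptical pupil (mild eccentricity,
quadratic radial falloff, reddish-orange base colour (205, 125, 70) as in
a red-reflex image), a dimmer concentric scleral ellipse, a dark
periphery (level 25), optional white UI glyphs at the borders, optional
small bright instrument-like distractor blobs placed clear of the field,
and Gaussian pixel noise (σ = 2 by default). The generator also emits the
true pupil mask purely so segmentation accuracy can be scored.

Ground-truth parameters must be statistically identifiable from the
images — otherwise no regressor, including the original one, could beat
the constant mean predictor. The default `"scene_linked"` mode therefore
draws per-patient latent degradations — an illumination factor
(0.55–1.05), a veiling-glare contrast factor (0.65–1.15, applied as
channel-coupled recentring about the frame mean, the way scattering media
reduce contrast), per-channel colour casts (red/blue 0.82–1.18, green
0.9–1.1, reflecting the warm–cool axis of illumination colour variation),
a chroma factor (0.55–1.2) and a hue shift (±25°) — jitters them slightly
per frame, and sets the "surgeon's" parameters as compensating affine
functions of the frame's own latents plus tuning noise (3 native units,
0.04 for gamma), clamped to the central 90% of each range. A `"uniform"`
mode draws parameters independently instead.

What a green test does and does not establish: the synthetic world
exercises the full machinery — segmentation topology, closure, training
dynamics, identifiability — but its optics are cartoon-simple (no
instrument motion, no specular highlights, no anatomy), so success here
says nothing about clinical image quality; conversely the published
full-scale metric values require the private data and are out of reach by
construction.

One stated-world consequence is worth recording: the green cast spans
half the range of the other casts while the veiling-glare factor couples
an additive, sample-dependent offset into every channel. The magenta
parameter (which compensates the green cast) is then close to the edge of
identifiability at desk scale — diagnostic fits using ideal channel
statistics, log-ratio features, and fine-tuned backbones all hover at or
slightly above the mean-predictor MSE for magenta while clearing the
baseline comfortably for the other seven parameters. Recovering it
requires a learned nonlinear inversion (dividing out illumination and
glare), which the full-scale method may achieve but a 200-sample desk run
cannot reliably. The generator settings nevertheless stay as designed;
the acceptance suite reports magenta as it falls.

## Numerical and procedural choices

- "Histogram analysis" is implemented as Otsu's threshold; ties across a
  flat between-class-variance plateau resolve to the plateau midpoint.
- Components use 8-connectivity; equal-area largest-component ties break
  by the smallest (top, left) anchor; boxes are 0-based, half-open.
- The small-object size default is 1% of the frame area.
- Resizing is bilinear with half-pixel-centre sampling.
- Grayscale uses ITU-R BT.601 weights.
- NRMSE uses the printed sum denominator `I_max + I_min` by default with
  a `"range"` switch; PSNR is `10·log10(I_max²/MSE)` in dB with an `Inf`
  sentinel for identical images; SSIM uses the standard stabilized forms
  (C1 = (0.01·255)², C2 = (0.03·255)², C3 = C2/2, α = 1, 11×11 Gaussian
  window with σ = 1.5) on luminance.
- Contrast is the mean absolute difference over adjacent pixel pairs;
  sharpness is the population variance of the interior 4-neighbour
  Laplacian (a linear ramp scores exactly zero).
- A fixed patient-grouped test split (10%) is carved out before folding;
  per-fold image-to-image retraining is the default (`shared_pix2pix`
  reproduces the cheaper alternative); the fixed test set is evaluated
  with the best-validation fold's models, and results are reported per
  fold and pooled.
- Every stochastic step derives its seed from the master seed; identical
  configurations are bit-reproducible (single-threaded BLAS).

## Desk-scale configuration

The default `pipeline_config()` describes the scaled experiment used by
the acceptance suite: 200 scenes of 64 px from 20 patients (about the
study's frames-per-patient ratio), 3 folds, 3 image-to-image epochs per
fold at batch 4, and the regressor schedule selected by pooled validation
MSE. On one CPU the whole run takes roughly ten minutes. Image I/O uses
ASCII portable pixmaps (PPM/PGM) because the environment provides no
compressed-image reader for R.

## Known limitations

- The renderer is a stand-in, not a device model; predicted native values
  are only meaningful relative to it.
- No pretrained backbone weights are available offline; `pretrained =
  TRUE` errors by design, and random-initialization results should not be
  compared against transfer-learning numbers.
- The engine is CPU-only and sized for desk-scale experiments; a 512-px
  full training run is possible but slow.
- The paper-faithful NRMSE denominator (`I_max + I_min`) differs from the
  conventional range normalization; comparisons across software must pick
  one convention explicitly.
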