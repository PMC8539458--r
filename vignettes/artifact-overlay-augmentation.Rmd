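---
title: "Artifact-overlay augmentation for particle segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact-overlay augmentation for particle segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(particleaug)
```

## The problem

Surface-plasmon-resonance sensors such as PAMONO render individual
nanoparticles (for instance virus-like particles) as bright spots in
preprocessed image streams with intensities in $[0,1]$. Detecting and
counting those spots is the measurement. The difficulty is that recordings
are disturbed by artifacts whose character changes between — and within —
experiments: structureless pixel noise ("uncorrelated" artifacts) and
structured disturbances such as waves and lines ("correlated" artifacts).
A segmentation network trained on one low-artifact recording degrades
sharply when deployed on streams whose artifacts it has never seen, and
wave-like artifacts are the worst offenders: they resemble chains of faint
particles and generate both missed detections and spurious ones.

Because particle-bearing recordings are expensive while *reference*
recordings — streams with artifacts but no particles of interest — are
cheap, the data-centric remedy implemented here overlays clean, annotated
training images with artifact signals taken from interchangeable sources,
leaving the model architecture and the labels untouched.

## Signal model

Every frame of a stream is modelled additively,

$$I_t(x,y) = P_t(x,y) + B_t + C_t(x,y) + U_t(x,y),$$

with particle signal $P \ge 0$, a background $B$ that is constant within a
frame, a correlated artifact $C$ and uncorrelated noise $U$ ($C$ and $U$
may leave $[0,1]$; the emitted frame is clipped once). The segmentation
target is the binary map $M(x,y) = \mathbf 1[P(x,y) > 0]$. A reference
frame is the same model with $P \equiv 0$.

`simulate_stream()` emulates preprocessed sensor streams under exactly this
model and returns the unclipped decomposition next to each frame, so every
downstream stage can be tested against ground truth that is true by
construction. Particles are isotropic Gaussian spots (sd $= r/3$, hard
support cut at radius $r$, so the mask support is a pixel disc), constant
in intensity over a lifetime of several consecutive frames — the simplest
model consistent with multi-frame visibility; spot shape is otherwise
unconstrained by the application. Uncorrelated noise is zero-mean Gaussian
per pixel and frame, standing in for the shot/readout/thermal family.
A "line" recipe renders a static softened band (Gaussian cross-profile),
emulating washed-out line artifacts. The real sensor's artifact amplitudes
are not published, so simulator defaults are chosen for visual
plausibility, not fitted to recordings — conclusions from the synthetic
testbed transfer as *trends*, not as absolute scores.

## Artifact sources

**Procedural waves.** A single wave with centre $c_w$, frequency $\sigma$
(radians/pixel) and phase $\omega$ has amplitude
$h(x,y) = \sin(d(x,y,c_w)\,\sigma + \omega)$ with $d$ the Euclidean
distance. Real waves fade across the image, so $h$ is multiplied by
$e(x,y) = 1 - d(x,y,c_f)^\beta / \max_{\text{grid}} d^\beta$, which is 1 at
an independent fade centre $c_f$ and 0 at the grid point farthest from it;
$\beta \in [0,1]$ controls how uniformly the fade acts. $n_w$ faded waves
are summed with weight $\gamma / n_w$, so no pixel moves by more than the
strength $\gamma$ — a bound the test suite checks by brute force. Because
the denominator maximum runs over a convex function on a rectangle, it is
attained at one of the four grid corners, which is how `fade_factor()`
evaluates it exactly. The degenerate $0^0$ case ($\beta = 0$, $d = 0$) is
defined as 1 and excluded from default sampling intervals.

Parameters are drawn uniformly from restricted intervals
(`wave_intervals()`). The intervals are not published for the original
sensor, so the defaults ($n_w \in \{1..4\}$, $\sigma \in [0.05, 0.6]$
rad/px, $\omega \in [0, 2\pi)$, $\beta \in [0.3, 1]$,
$\gamma \in [0.05, 0.3]$, centres sampled over the image extended by 50%
per side so origins may lie off-frame) were chosen once to span the
visually observed regimes from slow swells to high-frequency ripples, and
are fully configurable. Each wave samples its own fade centre, matching
the per-wave indexing of the composition.

**Tiles.** Full-frame overlays are mosaics of $v \times w$ tiles, butted
edge to edge row-major with the rightmost/bottom tiles cropped when the
tile size does not divide the frame — no feathering, keeping the
composition rule exactly invertible (split-then-compose is the identity,
also a test). Tiles come from a `tile_source`:

* `real_cutout_source()` cuts random windows from a reference stream and
  zero-centres each one by subtracting its scalar mean — the estimate of
  the constant background under the zero-centred-artifact assumption.
* `directory_tile_source()` adapts externally generated artifact images
  (e.g. the output of a generative model trained on reference tiles); files
  are read, converted to grayscale, cropped top-left to $v \times w$ and
  re-centred. Re-centring is applied uniformly across sources for
  comparability. Training a generative model is outside this package's
  scope by design; any producer that writes image files can be plugged in.

The default tile side is 128 px at full sensor resolution; the desk-scale
experiments below use 32 px tiles on 64 px frames, preserving the 2x2+
mosaic structure. Overlays are applied per training image per epoch, fresh
each time, by pointwise addition followed by a single clip to $[0,1]$ —
clipping keeps the augmented inputs in the same domain as real
preprocessed frames. Added Gaussian noise on top of tile overlays defaults
to zero because real and generated tiles already carry pixel noise;
double-counting it is avoided. Labels are never touched by overlays.

**Size augmentation.** The per-dataset median area of annotated particle
regions (median, to absorb annotation outliers) defines, across datasets,
a scale-factor interval $[s_{\min}/s_{\text{med}},
s_{\max}/s_{\text{med}}]$. Training images are rescaled by per-axis
factors drawn from that interval — independently per axis by default,
since the protocol scales the two sides separately; a shared-factor
isotropic mode is available behind a flag. Intensities are resampled
bilinearly, masks by nearest neighbour (so they stay binary), and boxes
with floored minima and ceiled maxima so every rescaled mask pixel remains
inside its rescaled box. Size augmentation is included in every overlay
regime, as it combines well with the artifact overlays.

## Network and training

The segmentation network is a compact, fully convolutional U-Net: 5
resolution levels, 16 filters in the first level doubling per level (so
16→256), two 3x3 convolutions per level, 2x2 max pooling down and
nearest-neighbour upsampling with skip concatenation up, and a 1x1 sigmoid
head. Convolution, pooling and upsampling kernels are implemented in
compiled code (im2col plus BLAS matrix products); the backward pass is
verified against numeric differentiation in the test suite. Inputs whose
sides are not multiples of 16 are symmetrically zero-padded and cropped
back, which also lets the network train at one size and infer at another —
necessary because size augmentation changes shapes.

Two implementation choices matter for trainability with the dice loss
$1 - (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$
(smoothing $\varepsilon = 1$ keeps empty-mask frames stable). Particle
masks are heavily class-imbalanced (1–3% foreground), and dice-only
optimisation has a saturated all-background local minimum that a plain
conv/ReLU stack falls into readily. First, each convolution is followed by
per-image instance normalisation (no learnable affine), which keeps
feature scales stable and removes that collapse mode. Second, the output
bias is initialised to the logit of a foreground prior (default 0.1) so
the initial prediction is roughly calibrated rather than 0.5 everywhere.
Both are architecture-internal numerical choices; the model's interface
and capacity are unchanged across all augmentation regimes, which is the
point of a data-centric comparison.

Optimisation is Adam on the dice loss. The reference protocol — initial
learning rate $3\times10^{-5}$, halved after every 15 epochs without
improvement of the validation dice loss, stop after 30 epochs without
improvement, best-validation weights returned — is the default of
`train_config()` and is enforced by an explicit state machine
(`protocol_state()` / `protocol_update()`) that the unit tests drive with
scripted losses: the rate halves exactly at the 15th consecutive
non-improving epoch and training ends exactly at the 30th. "No
improvement" means not strictly below the best seen; the counter resets on
any improvement.

At desk scale (64x64 frames, a dozen training frames, minutes of CPU) that
learning rate is far too small for the few hundred optimiser steps
available, so the bundled experiments use `lr = 1e-3`, batch size 2 and a
hard cap of 10 epochs. These are stated problem-size choices of this
package's synthetic testbed, kept fixed across all regimes; paper-scale
settings remain plain arguments.

## Detection and evaluation

Predicted soft masks are binarised at 0.5 (configurable; detection on the
soft map is available via `soft = TRUE`) and turned into detections by
Difference-of-Gaussians blob detection: a geometric ladder of Gaussian
blurs ($\sigma$ from 1 to 8 px over 6 scales, spanning the simulated spot
radii), consecutive blurs subtracted and normalised by the ladder step,
local maxima over space and scale above 0.05 kept, box side
$2\sqrt2\sigma$, same-frame boxes merged at IoU > 0.5 keeping the stronger
response. Detections on consecutive frames are linked greedily into
traces: a detection joins the previous-frame detection of maximal box IoU
if that IoU reaches 0.3, ties broken by the lower detection index, one
detection per trace per frame, and traces break on a missing frame. The
blob and linking thresholds are not prescribed by the application, so they
are exposed in the configuration; the defaults were calibrated once on
simulator ground-truth masks (where the expected answer is known by
construction) and then frozen.

Evaluation is at the trace level. A predicted trace is a true positive if
its aggregate bounding box (union over frames; frame-wise matching is
available behind a flag) overlaps an annotated trace's box with IoU at
least 0.3 *and* their frame spans intersect; the rule is non-injective, so
two predictions over one annotation are both true positives. The scores
are the object-level F1, $tp / (tp + 0.5(fp + fn))$, and the count
exactness $1 - |n_a - n_p| / \max(n_a, n_p)$; particle-free streams
report false-positive traces per image. The degenerate empty cases
($F1(0,0,0)$ and $e(0,0)$) are defined as 1 so that a silent model on a
particle-free stream scores perfectly. Both formulas are checked
exhaustively against an independent precision/recall implementation for
all integer inputs up to 20.

## The bundled experiment

`run_experiment()` ties the stages together: per repeat it simulates a
low-artifact training and validation stream, three test groups
(`highly_visible` like the training data, `wave_like` with strong waves,
`particle_free` with waves and no particles) and a wave-bearing reference
stream; per regime it builds the augmentation source, trains, detects,
links and evaluates. Data seeds depend only on the repeat, so all regimes
see identical streams; training seeds depend on regime and repeat; every
seed derives deterministically from one master seed. Each regime runs
three times and the run with the median overall F1 (mean F1 across
particle-bearing test streams) is selected as its representative — the
same repeat-and-select rule as the reference protocol.

The size-factor interval is computed from the repeat's own particle-bearing
streams (their per-stream median particle areas), not hand-set, so the
"direct augmentation" component follows the published construction even at
desk scale.

What passing trends on this testbed do show: training with wave or
real-tile overlays makes the fixed network markedly more robust on
wave-disturbed test streams and reduces false positives on particle-free
streams, with the unaugmented baseline failing in exactly the expected way
(artifact structures detected as particles). What they do not show:
absolute scores comparable to full-scale results on real recordings —
real artifact statistics, 500-image training sets, generatively modelled
tile quality and long training schedules all sit beyond what a
minutes-long CPU experiment can emulate.

## Known limitations

* Waves are spatially structured but temporally incoherent (fresh
  parameters per frame); time-consistent artifact generation is future
  work.
* The simulator's artifact amplitudes are plausible, not fitted; absolute
  scores on it should not be quoted as sensor performance.
* Blob detection assumes roughly isotropic spots; elongated particles
  would need an oriented detector.
* Training is CPU-bound and single-image; at full sensor resolution a GPU
  framework would be the practical choice, with this package's sources and
  evaluation unchanged.
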