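---
title: "Semantic preprocessing and active deep learning for section labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic preprocessing and active deep learning for section labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fluorescence microscopy of sectioned mouse hearts after experimental
myocardial infarction produces pairs of co-registered whole-section
images: a nuclear stain delimiting tissue against the slide, and a
lectin-488 channel marking perfused ("normal") myocardium.  The analysis
goal is a per-pixel three-class map — `none` (slide), `risk`
(ischemic area-at-risk, i.e. tissue without perfusion signal) and
`normal` — and the bottleneck is expert ground truth: hand-painting one
~10,000-px section takes hours.

Active deep learning (ADL) attacks the bottleneck by letting a snapshot
ensemble label unlabeled sections automatically and asking the expert
only for an accept/reject verdict.  In practice the ensemble's
confidence score selects samples that resemble the training
distribution, and acquisition drift between imaging sessions (exposure,
gamma, bleed-through) pushes whole cohorts out of distribution, so few
sections ever clear the confidence bar.  `semprep` implements the fix
this package is built around: *semantic preprocessing*, which adjusts
each unknown image so that class-conditional intensity statistics match
those of a reference section, using the model's own (initially
approximate) segmentation to define the class areas, and iterating
adjustment and re-prediction to a joint fixed point.

## The semantic metric and the searches

For one channel, a binary mask splits the image into foreground and
background.  The *semantic metric* is the vector of per-region
statistics on the 0–255 scale: `(bg_mean, fg_mean)` for the plain
search, `(bg_mean, fg_mean, bg_std, fg_std)` for the gradient-descent
variant.  Quality of adjustment is the Euclidean distance to the metric
of an expert-designated reference section.

Two searches move an image toward the target:

* `sp_gamma_search()` — greedy walk over whole-image gamma in
  multiplicative 5% steps (`g*1.05` / `g*0.95`), stopping when neither
  direction strictly reduces the 2-D distance.  The percent step is
  interpreted multiplicatively because it is scale-free and symmetric in
  log-gamma; an additive reading would make the reachable set depend on
  the current gamma's magnitude.
* `gd_search()` — annealed greedy descent over contrast, brightness and
  gamma.  At step size `s` (initially 0.10) all six signed single-knob
  moves are appended tentatively to the current chain, the whole chain
  is re-rendered from the raw image, and the move with the greatest
  strict reduction of the 4-D distance is kept.  When no move improves,
  `s` anneals down 0.01 at a time; the search terminates once it would
  drop below 0.01.  Both signs of every knob are probed (the directional
  phrasing of the plain search does not carry over, and probing both
  signs is never worse).  Ties break by the fixed order contrast,
  brightness, gamma, `+` before `-`, for determinism.

Numerical choices: chains are always re-rendered from the raw image in
floating point, with a single 8-bit quantization at final render.  This
matches the re-application-to-raw rule of the bootstrap (an erroneous
adjustment can always be undone) and avoids cumulative rounding drift.
Strict improvement uses a `1e-9` tolerance so float noise cannot loop
the searches.  Degenerate situations — a constant image (no Otsu
threshold), or a mask with an empty region — skip adjustment for that
channel with a warning, since the correlated-intensity assumption
behind the metric has no support there.  Step sizes anneal in integer
hundredths, so no floating-point drift can skip the 1% floor.

## Bootstrapping (BSP / GDBSP)

`bsp_iterate()` alternates adjustment and prediction for `bootstrap_iters
= 5` iterations per section.  Iteration 0 seeds per-channel masks with
binary Otsu thresholds (`otsu_binary()`, the exact between-class-variance
sweep over all 255 cuts).  Each iteration then searches per channel from
the *raw* image, renders the adjusted channels, predicts a class map,
and derives the next masks from the prediction: the nuclear channel's
foreground is everything not `none`, the lectin channel's foreground is
`normal`.  The two channels are adjusted fully independently.  With a
perfect segmenter the loop reaches a fixed point after the first
mask correction, which is what the convergence tests assert.

## The segmenter and the ensemble

`build_model()` constructs a U-Net-style encoder–decoder: paired 3×3
convolutions with ReLU, 2×2 max pooling, nearest-neighbour upsampling,
skip connections, and a 1×1 head emitting three class logits.  At the
full-scale defaults (depth 4) the channel width is chosen so the
trainable parameter count lands nearest 2 million (width 15 →
1,897,323).  The engine is implemented in the package itself — im2col
patch extraction in C++, BLAS matrix products, hand-derived
backpropagation — and is verified against numerical gradients in the
test suite.  Training uses Adadelta (decay 0.9, epsilon 1e-6),
categorical cross-entropy, global gradient-norm clipping at 1.0, and
inputs scaled to [0, 1].

Adadelta's step multiplier (`lr`) is 1.0 at full scale.  Desk-scale
presets use `lr = 8`: the self-tuning accumulators need a few thousand
updates to reach their working scale, and a compressed schedule (10
epochs over ~100 patches, versus 110 epochs over thousands) does not
provide them; a larger multiplier restores the effective step size for
short schedules.  Desk presets likewise augment training patches with a
half-window shifted copy of the sampling grid (`train_offsets`),
quadrupling updates per epoch without touching the prediction path; the
plain non-overlapping grid remains the full-scale default.

`train_snapshots()` saves ensemble members at the configured epochs
(full scale: 90/100/110 of 110; desk scale: 8/9/10 of 10).
`ensemble_vote()` takes the per-pixel plurality and its vote fraction.
With three voters and three classes a 1/1/1 split is possible — an odd
member count does not in fact prevent ties — and it resolves to the
most-trained member's class at confidence 1/3, since that member also
drives preprocessing and primary prediction.  The section score `f` is
the mean winning-vote fraction over all pixels.

## Whole-section prediction

Sections are far larger than a network window, and patch borders starve
for context, so `predict_section()` uses patch-wise interpolation:
windows slide at half-window stride, only each output's central
`stride × stride` block is kept (discarding a `trim`-pixel buffer on all
sides), and the centers tile the section exactly once
(`sliding_windows()` / `stitch_centers()`).  Borders are reflect-padded
by `trim` so edge centers exist with plausible context (zero padding is
available; reflection preserves intensity statistics near tissue
borders), and the section is zero-padded to a stride multiple on the
right/bottom, cropped after stitching.  The round-trip is bit-exact by
construction, which the suite asserts for both pad modes.  Coordinates
are 0-based and half-open throughout.

## The ADL loop and its accounting

`adl_iteration()` performs one pass of the protocol: train every fold's
snapshot ensemble (accepted sections join every fold's training set),
cross-validate, pick the *least overfit* fold (lowest test Dice — an
overfit fold votes confidently on poor labels), have its most-trained
member preprocess and predict the pending active set, let the remaining
members vote on the adjusted inputs, threshold section confidences
(`choose_threshold()`: the capacity-th largest `f`, never below the
0.90 floor; the stricter 0.97 verification preset is a configuration,
not a rule), and submit qualifying sections to the expert.

On synthetic data the expert is simulated: accept iff macro Dice against
the withheld truth reaches 0.90 (boundary inclusive), 5 minutes per
accepted review, 1 minute per rejection.  The manual-labeling
equivalent is 2 hours per accepted section, the ratio implied by the
full-scale campaign accounting this model mirrors (164 h for 82
sections).  Rejected
sections stay in the active set and may be re-presented — each
presentation costs review time, which is why a full run's hours can
exceed the terminal accept/reject counts alone.  The per-iteration
ledger records presented/accepted/rejected counts, `f_thresh`, mean
active confidence, cumulative samples and sections, dataset size as a
percent of the base sample count, and the expert-time model.

## The synthetic cohorts

`generate_section()` builds a star-shaped tissue blob on a dark slide,
a perfused sub-region traced by random smooth vessel strokes with a
Gaussian cross-profile, bright nuclei speckle in the nuclear channel,
and a diffuse perfusion halo in the lectin channel.  Ground truth
follows the margin rule: `normal` is the vessel signal dilated by the
margin radius (26 µm at 541.67 nm/px ≈ 48 px full scale;
`margin_radius_px()`), `risk` is the remaining tissue.  Desk-scale
sections are 256×256 with a 4-px margin — the same geometry at roughly
one-tenth scale.

Acquisition inconsistency is a per-section gamma/brightness chain drawn
from the cohort spec and rendered through the package's own transform
code, plus independent base-level jitter.  The jitter is sized from the
shared-exposure standard deviation and the target foreground/background
mean correlation (`fg_bg_corr`, default 0.65, matching the correlations
reported for real cohorts of about 0.6–0.7); a 0.7 calibration factor
compensates for the unshared variance the gamma draw contributes.  The
default three-cohort layout gives cohort 1 mild variability (the
curated base), cohort 2 strongly brighter exposures, and cohort 3 a
30% nuclear-signal bleed-through into the lectin channel — the two
failure modes that defeat raw-input ADL.

What the generator does *not* emulate: real tissue texture and
staining heterogeneity, sectioning artifacts (folds, dust, smears),
spatially varying illumination, and the sheer size of real sections.
Passing tests therefore demonstrate the mechanics and the directional
claims — normalization restores out-of-distribution cohorts to
acceptability while raw inputs fail — not instrument-grade accuracy on
real slides.

## Problem sizes used by the test and acceptance suites

Desk-scale runs use 256×256 sections, 64-px windows (stride 32, trim
16), a depth-2/width-4 segmenter (~8k parameters), 10 epochs with
snapshots {8, 9, 10}, two folds over six base sections, and an active
set of four sections across cohorts 2 and 3.  Search and bootstrap tests
use 64–128-px sections.  The full-scale defaults (512/256/128 windows,
110 epochs, ~2M parameters, 541.67 nm/px) remain the documented
configuration for real data.

## Known limitations

* The gradient-descent search is greedy over single-knob moves; it can
  stall in metric-space corners a joint move would escape.  The anneal
  mitigates but does not eliminate this.
* The semantic target always comes from one hand-picked reference
  section; the package deliberately does not learn or pool targets.
* The engine is CPU-bound and single-threaded; full-scale 110-epoch
  training of a 2M-parameter model is out of its intended use.
* Benchmark preprocessors depend on parameters (DoG sigmas, CLAHE
  window/clip) whose values full-scale comparisons rarely state; the defaults
  here (1/10 px, 1/8-min-dimension window, 0.01 clip) are reasonable,
  not reproductions.
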