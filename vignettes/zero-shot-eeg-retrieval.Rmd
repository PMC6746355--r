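---
title: "Zero-shot EEG image retrieval: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot EEG image retrieval: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The decoding model and its assumptions

The core assumption is a *linear* forward relationship between the
stimulus's position in a fused visuo-semantic feature space and the
evoked, preprocessed EEG: each trial's epoch is treated as a noisy linear
image of the stimulus feature vector. Decoding inverts this with a ridge
regression per image-feature column, fitted on z-scored EEG features. L2
(not L1) regularisation is used deliberately: neighbouring sensors and
timepoints are strongly collinear, and ridge distributes weight across
correlated predictors instead of arbitrarily selecting among them.

Zero-shot generalisation is enforced by leave-one-class-out
cross-validation: every epoch of one stimulus is withheld per fold, and
everything fitted — the z-scaler, the stability scores, the EEG feature
mask, the ridge map, the per-column training R² — uses training epochs
only. The withheld stimulus's *image features* are still available at
ranking time; that is the nature of retrieval (the gallery is known), and
no EEG information leaks. Likewise the PCA defining the fused space is
fitted on the full gallery's image features: gallery images are public
inputs, and the EEG never touches the PCA.

### Identifiability of zero-shot linear decoding

One property discovered while validating the pipeline deserves emphasis,
because it constrains every user of this protocol. PCA scores are
column-centred, so the `nS` gallery vectors sum to zero; the withheld
class's vector is therefore exactly `-(nS-1)` times the mean of the
training classes — it always lies *off* the training classes' affine
hull. If the feature dimension `p` satisfies `p + 1 > nS - 1`, the
training classes cannot pin down the affine map along the off-hull
direction; ridge shrinks that component to zero, every fold's prediction
collapses toward the training mean, and ranks drop to (or below) chance
even with noise-free data. Zero-shot recovery of a linear forward model
therefore needs `p + 1 <= nS - 1`, with margin. The package keeps the
spec-style default for the PCA dimension (retain 99% of variance, capped
at `nS - 1`) because with realistic image corpora the 99% criterion stops
far below the cap; synthetic fixtures, whose block variance is spread
nearly uniformly, set `pca_components` explicitly (12 components for a
30-stimulus gallery, 4 for 10) as an a-priori identifiability constraint,
not a tuned value.

## Preprocessing parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| band-pass | 1–40 | Hz | removes drift below 1 Hz and mains/EMG above 40 Hz |
| z threshold | 3 | SD | statistical-thresholding cutoff for every flagging rule |
| epoch window | [0, 1000) | ms | encompasses the informative evoked response |
| baseline | [-500, 0) | ms | per-channel pre-stimulus mean subtraction |
| target rate | 120 | Hz | dimensionality reduction before learning; nT = 120 |
| ICA components | nC − interpolated | — | interpolation reduces rank |

Numerical choices worth knowing:

* **Filter**: zero-phase windowed-sinc FIR (Hamming), ~1 Hz transition
  band, applied by FFT convolution with exact group-delay compensation.
  Zero phase matters because ERP latencies are the signal.
* **Outlier rule**: |z| ≥ 3 two-sided, with the *population* SD and an
  inclusive cutoff. Among n scores the largest attainable |z| is
  √(n−1) (population) or (n−1)/√n (sample); a strict `>` on the sample SD
  could never fire for n ≤ 10, and the canonical worked example (nine
  zeros and one extreme value) sits exactly at z = 3. This also means
  single-outlier detection among few items (e.g. flagging one of ≤ 10 ICA
  components) is mathematically marginal — a genuine property of the
  thresholding family, visible in the tests.
* **The rule has a designed false-positive rate.** On perfectly clean
  data, roughly the expected tail mass of each metric distribution will
  still be flagged; the test suite asserts repairs stay within ~1% of
  epoch × channel slots rather than pretending the rate is zero.
* **Spherical spline** interpolation uses the classical stiffness-4
  truncated Legendre series (50 terms) with a small ridge on the solve;
  the unpenalised constant term reproduces constant fields exactly.
* **Hurst exponent**: rescaled-range over dyadic block sizes, slope of
  the log–log fit — chosen because it is classical and easily checked
  against an independent implementation.
* **Downsampling** is rational-rate polyphase resampling expressed as a
  windowed-sinc resampling matrix whose rows are normalised to sum to
  one, so DC is preserved exactly; never naive decimation.
* **ICA** is a symmetric FastICA (tanh contrast, PCA whitening, fixed
  seed). It runs on the epoched, artefact-rejected data, after epoch
  rejection and before within-epoch repair — the stage order is fixed and
  the whole pipeline is deterministic given `ica_seed`.
* **Ocular proxy**: with no dedicated EOG sensor, the most anterior
  channel by layout (largest y coordinate, ties to the lower index)
  stands in.

## EEG feature selection

Stability scoring needs every stimulus to retain at least two
presentations; stimuli below that are excluded with a warning. After
epoch rejection, presentation counts are unequal, so missing presentation
slots are `NA` (never zero-filled) and each feature's score averages only
its usable presentation pairs, with the pair count recorded. Features are
flattened channel-major (feature f ↦ channel (f−1) %/% nT + 1, timepoint
(f−1) %% nT + 1) so masks are interpretable as (channel, time) pairs.
Stability is computed on z-scored training epochs by default — z-scoring
is per-feature affine and Pearson correlation is affine-invariant, so
this choice affects nothing downstream, but it is exposed as
`stability_on_zscored` for completeness. The retained count k has no
single canonical value and is grid-searched (25…3000 by default).

## Image feature space

* **Gabor bank**: 8 orientations × 4 sigmas (2–5), 31×31 kernels, λ = 6,
  γ = 0.5, ψ = 0. The orientation grid is evenly spaced on [0, π) (π/8
  steps); a π/7-spacing variant is available as
  `orientation_spacing = "pi7"` since both readings of "evenly spaced"
  appear in the literature this models. Responses are the sum over pixels
  of the real-part convolution on the standardised (zero-mean, unit-SD)
  grayscale image; a magnitude aggregation is a config switch.
* **Dense SIFT**: 128-dimensional (8 orientations × 4 × 4 cells, 16 px
  support) descriptors on an 8 px grid, L2-normalised with 0.2 clipping.
  Keypoints are *not* detected; the grid makes descriptor counts uniform
  across images.
* **VBOW codebook**: k-means (k = 1000 by default at corpus scale; the
  shipped fixtures train k = 50 on synthetic images) with a fixed seed.
  The codebook trainer is corpus-agnostic: any image directory works.
* **HSV histogram**: 16 bins per channel (4-bit quantisation), channels
  concatenated H, S, V; each channel's bins sum to the pixel count.
* **Semantics**: word-vector lookup with case-folded tokens; multi-word
  names average their component words' vectors.
* **Fusion**: each block is row range-normalised (per feature set, not
  over the concatenated row), concatenated in the fixed order gabor,
  hsv, sift, sem, centred, and PCA-reduced.

Images are resized bilinearly to 256×256 (fixtures use smaller sizes for
speed) and converted to grayscale with BT.601 luma weights before Gabor
and SIFT; the stimulus sets this models vary in native resolution, and a
fixed working size makes the visual blocks comparable across galleries.

## Decoding parameters

| Parameter | Default | Rationale |
|---|---|---|
| alpha | 10 | centre of the canonical grid {1e-2 … 1e2} |
| k (EEG features) | 500 | mid-grid; grid-searched per recording |
| keep_fraction | 0.5 | fraction of image-feature columns kept after R² masking |

R² is computed per column on each fold's *training* data and averaged
across folds into one global mask applied at ranking time, so the mask is
built entirely without the withheld epochs. Distance ties at ranking are
broken by gallery index — deterministic, and measure-zero for continuous
features. Each epoch is ranked individually (no averaging of repeated
presentations): every presentation is a retrieval trial.

## The synthetic generator

`synth_recording()` realises exactly the assumption the decoder makes: a
per-stimulus spatiotemporal template, drawn once per seed as a linear
transform of the fused feature vector, confined to 100–600 ms post-onset
(so stability profiles peak inside the epoch), scaled to a target
template-SD/noise-SD ratio, and added to Gaussian background noise at
each scheduled presentation. Planted artefacts are available: ocular
blinks (a single source with an anterior-pole topography decaying across
the scalp — deliberately multi-channel, so the artefact reaches the ICA
stage as one coherent component instead of being interpolated away as a
single bad channel), one dead channel, and 50 Hz line noise.

What passing tests on this generator *do* show: the pipeline's stages are
individually correct against independent oracles, the full chain recovers
a known linear forward model at high SNR, detects the planted artefacts,
and sits at chance under label permutation. What they *do not* show:
performance on real EEG, whose noise is neither white nor Gaussian
(1/f background, volume conduction, non-stationarity), whose evoked
responses are not identical across presentations (adaptation, attention),
and whose image-feature relationship is at best approximately linear.
Accuracies on the generator are upper bounds, not forecasts.

Fixture scales used by the test suite were chosen to exercise every code
path at realistic proportions: the standard bench is 10 stimuli × 4
presentations on 16 channels at 250 Hz, and the parameter-recovery run is
30 stimuli × 6 presentations on 32 channels at 500 Hz with SNR 10 and a
20-seed permutation null.

## Known limitations

* Zero-shot linear decoding degrades as the PCA dimension approaches
  `nS - 1` (see identifiability above); the package warns nobody about
  this automatically — choose `pca_components` consciously.
* The FastICA implementation is symmetric with a tanh contrast only;
  extended-infomax source models (sub-Gaussian sources) are not covered.
* EEGLAB `.set` files are not read (MATLAB container); BrainVision and
  EDF readers cover the common interchange cases, and the packed
  float32 + JSON format is the canonical round-trip format. BrainVision
  and EDF carry no 3-D sensor positions, so spline-dependent stages
  require attaching a layout first.
* Mutual-information or wrapper feature selection, spatial-redundancy
  pruning of stability-selected features, CNN feature spaces and
  alternative word embeddings are out of scope.
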