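---
title: "Hierarchical frequency tagging: models, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical frequency tagging: models, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftag)
```

## The problem this package addresses

Visual perception mixes bottom-up, stimulus-driven signals with top-down,
prediction-driven signals, and the two can be tagged separately in EEG by
driving them at different frequencies. A global sinusoidal contrast
modulation at F1 = 10 Hz entrains low-level visual cortex (the steady-state
visual evoked potential, SSVEP). Cyclic wavelet-domain image scrambling
(SWIFT) modulates the *recognizability* of an image at F2 = 1.3 Hz while
holding local luminance, contrast and spatial-frequency content constant,
so only semantically sensitive, higher-tier areas follow that rhythm. When
the two signals meet in a nonlinear neural operation, the response spectrum
acquires intermodulation (IM) components at n1·f1 + n2·f2 — frequencies
that neither input contains, and that therefore index *integration* of the
two processing streams. Varying the predictability of the upcoming image
(the proportion of face vs house cycles in a trial, "certainty")
manipulates the precision of top-down predictions and modulates these
signatures.

`hftag` implements the full chain: stimulus construction, a synthetic EEG
forward model, the spectral SNR statistics, quality control, and the
linear mixed-effects certainty analysis.

## SWIFT scrambling

A grayscale image (square, side a power of two) is decomposed with an
orthonormal discrete Meyer wavelet transform at six levels. At every scale
and location the three detail coefficients (horizontal, vertical,
diagonal) form a 3-vector whose length encodes local contrast energy and
whose direction encodes contour orientation. For each such vector we draw
two random vectors of the same length; the unique circle through the three
points lies on the sphere of that radius, so rotating the vector along the
circle changes contour orientation while *exactly* conserving its norm.
One cycle of `frames_per_cycle` frames sweeps the common rotation phase
uniformly from 0 around to 1; the intact image reappears at the peak
frame.

Numerical design choices:

* **The transform is implemented in the frequency domain.** The Meyer
  quadrature-mirror pair is evaluated exactly on each dyadic DFT grid, so
  the periodic transform is exactly orthonormal and
  `swift_reconstruct(swift_decompose(x))` is lossless to machine
  precision (~1e-15 for a 256×256 image). Scrambling is then the *only*
  source of frame differences; mean luminance (approximation band,
  untouched) and RMS contrast (total energy) are conserved exactly rather
  than approximately.
* **Degenerate vectors** with norm < 1e-12 are held fixed: there is no
  contour to scramble, and normalizing them would amplify noise.
* **Phase schedule**: uniform angular speed. The speed profile within a
  cycle is not prescribed by the method; uniform is the minimal
  assumption, and peak-frame timing is configurable.
* **Common phase, independent geometry**: all locations share one rotation
  phase (so the whole image peaks together) but each has its own random
  circle. A shared geometry would impose correlated distortions across
  scales with no evident justification.
* **`scramble_distance`** is pixel-space L2. The "most scrambled" frame
  selection only needs a premetric that is 0 at identity and grows with
  distortion; L2 is stated and swappable.

## Trial assembly

A 50 s trial holds 65 cycles (`floor(50 × 1.3)`). Each image cycle is
alpha-blended 50/50 with the *noise* cycle of the other category — a SWIFT
cycle regenerated from the most scrambled frame of that category's cycle —
so low-level statistics are constant across the trial no matter which
image each cycle carries. Cycle categories follow a uniformly random
permutation of `round_half_up(p_dominant × 65)` dominant labels.

Because 769.23 ms cycles are not an integer number of 120 Hz display
frames, the movie is assembled by time: the frame at time *t* shows
scheduled cycle `floor(t·F2) + 1` at rotation phase `t·F2 mod 1`,
quantized to the cycle's frame grid — exactly what a display looping a
92-frame stack does. The global contrast gain is
`(1 − d/2) + (d/2)·sin(2π·F1·t)` about mid-grey (background 0.5), with
depth d = 1 by default so the gain spans [0, 1]. Whether the original
study modulated about mid-grey or about each frame's own mean is not
stated; mid-grey matches presentation "over a grey background", and the
alternative only rescales the DC term.

## The synthetic EEG forward model

No real recordings are distributed, so analysis correctness is established
against a forward model with known ground truth:

* bottom-up source `b(t) = a1·sin(2πf1t) + 0.3·a1·sin(4πf1t)`;
* top-down source `s(t) = a2(c)·Σₖ (1/k)·sin(2πk·f2·t)`, k = 1..8 — the
  1/k harmonic series mimics the observed SWIFT harmonic ladder; the true
  cortical waveform is unknown;
* interaction `i(t) = g(c)·b(t)·s(t)` — a single multiplicative stage, the
  minimal mechanism producing IMs. Because `b` carries a second harmonic,
  this one stage already generates the full observed IM set including
  n1 = 2 components (18.7, 22.6 Hz). Whether a cascade is needed to match
  *relative* IM magnitudes is left open; the package only relies on
  presence and monotonicity.
* certainty `c ∈ [0.5, 1]` enters linearly:
  `a2 = a2_base + a2_slope·(c − 0.5)` (default 3 → 1.5 µV, falling) and
  `g = g_base + g_slope·(c − 0.5)` (default 0.05 → 0.40, rising). Only the
  monotone directions are empirically grounded; linearity is the simplest
  coding. The defaults were fixed once so that posterior-ROI SNRs
  reproduce the qualitative ordering reported for the paradigm
  (SSVEP ≈ 20–40 ≫ SWIFT ≈ 3–9 > IM ≈ 1.5–6), with the g slope chosen
  large enough that the *product* g·a2 (the IM amplitude) rises
  essentially monotonically over the certainty range.
* Topographies are dipolar region-wise gain profiles: bottom-up and
  interaction sources strongest occipitally, top-down strongest
  temporo/centro-parietally, anterior channels negative — so average
  referencing removes little signal, as for physiological far-field
  patterns. The interaction map deliberately shadows the bottom-up map
  (the empirical finding the topography comparison is meant to detect).
* Noise is 1/f-power-shaped Gaussian noise, independent across channels
  (no spatial covariance — documented simplification), parameterized by
  the expected amplitude-spectrum floor at 10 Hz (default 0.1 µV) so SNR
  levels are directly interpretable and invariant to trial duration.

What a green test does **not** establish: realism of waveform shape,
between-channel noise correlation, volume conduction, eye/muscle
artifacts other than the injected caricatures, or any quantitative match
to group statistics published for this paradigm (no dataset is publicly
available to match against).

## Spectral statistics

Amplitude spectra use the one-sided 2/N convention (unit sinusoid → 1.0 at
its bin; 50 s at 500 Hz → 0.02 Hz resolution). The SNR at a tagged bin is
its amplitude divided by the mean over the 10 bins on each side (20
neighbours, ±0.02–0.2 Hz at canonical resolution); frequencies must lie
exactly on the grid — no interpolation. Group-level testing is a one-sided
one-sample t-test of participant-mean SNR against 1 (the reported
direction is "greater than one"; two-sided available), Benjamini–Hochberg
FDR across the tested family. SNR is computed per trial and then
averaged; averaging amplitude before the ratio is a documented
alternative.

Preprocessing: exact FFT-domain decimation from 1000 to 500 Hz, a
zero-phase high-pass at 0.6 Hz implemented as the squared 4th-order
Butterworth magnitude applied in the frequency domain (the
forward–backward response; < 1 % attenuation at 10 Hz), then average
reference. The filter family is a choice; only the cutoff is prescribed.

## Quality control

Sample screening per channel: |x| > 80 µV, step > 40 µV from the previous
sample, or > 6 SD from the channel's trial mean (computed before any
replacement). A cycle is noisy when flagged points, *pooled over
channels*, exceed 2 % strictly — pooling matches the subsequent
all-channel replacement; per-channel flagging is available. Flagged cycles
are replaced by each channel's trial mean. Participants are excluded for
counting-accuracy r < 0.9 or > 10 % noisy cycles (both strict); trials
whose *signed* counting error lies beyond 2.5 SD of the participant's mean
error are dropped (descriptions of this criterion alternate between the
signed "difference" and the absolute "distance"; signed is implemented,
absolute behind a switch).

## Certainty analysis

Trials are binned into ten left-closed 5-percentage-point certainty bins
(p = 1 closes bin 10). The dependent variable is log2(SNR) over the
30-electrode posterior ROI; non-positive SNR is rejected rather than
silently producing non-finite values. Three model levels, all fitted by
maximum likelihood (models differing in fixed effects must not be
compared under REML) and tested by likelihood-ratio chi-square:

1. per frequency: `log2snr ~ certainty + (1 + certainty | participant/channel)`;
2. per category: random effects additionally nest frequency;
3. between categories: `certainty * category`, nesting frequency within
   category; the interaction term carries the contrast against the
   reference category.

The certainty predictor is the bin index 1–10 (results for this paradigm
are conventionally reported by bin; a continuous-proportion coding is
available). Singular fits are refitted with diagonal random-effect
covariances with a warning — a package choice, since no convention exists
for this case; small simulated sessions may request
the diagonal structure directly (`re_cov = "diag"`). Scalp-map similarity
is compared with Fisher's r-to-z and
`z = (atanh(r1) − atanh(r2)) / sqrt(2/(n − 3))` across n = 64 channels,
FDR over the four IM components; the overlap of the two correlations
(shared IM map) makes this an approximation, inherited knowingly.

## The scaled-down test world

Acceptance simulations keep every scientific constant at its default —
50 s trials, the 0.02 Hz grid, 1.3/10 Hz tagging, default effect sizes —
but run at 100 Hz sampling on the 16-channel montage with 5 participants
× 16 trials. Lowering the sampling rate preserves the spectral geometry
exactly (same bins, same ±0.2 Hz SNR window); shortening the trial
instead would widen the neighbour window to the point where SWIFT
harmonics at 9.1/10.4 Hz leak into the 10 Hz window and manufacture a
spurious SSVEP certainty effect. Two testing conventions were fixed
before the acceptance suite was frozen: "null SSVEP slope" means LRT
p > 0.01 (a p > 0.05 reading would make a ≥ 95/100 criterion a coin flip
by construction), and null IM calibration counts the fraction of
significant IM-bin tests at the FDR-adjusted 1 % rule across 100
noise-only replicates.

## Known limitations

* Wavelet transform is periodic (circular boundary handling); fine for
  the windowed photographic stimuli it is meant for.
* No biophysical head model; topographies are stylized regional gains.
* No EDF/BDF or PNG/TIFF I/O — the offline toolchain has no readers;
  plain-text matrices plus JSON sidecars are the interchange format.
* The LME machinery assumes balanced-ish designs as produced by the
  session simulator; heavily unbalanced real data may need the
  `re_cov`/ROI switches.
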