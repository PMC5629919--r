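---
title: "Methods: streaming fNIRS analysis in rtnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streaming fNIRS analysis in rtnirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnirs)
```

`rtnirs` reconstructs the numerical path of a real-time fNIRS system as a
library. This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
establish about behavior on real recordings.

## Design constraints

Two constraints shape every function:

1. **Strict causality.** Output at sample $t$ may depend only on samples
   $\le t$ and on fixed initial state. There is no zero-phase
   (forward–backward) filtering, no retrospective re-centering, and no
   look-ahead anywhere. Every streaming stage satisfies the *truncation
   property* — processing the first $k$ samples yields exactly the first
   $k$ outputs of processing the full series — and the test suite asserts
   this bit-for-bit for each stage.
2. **One code path.** Offline analysis, replayed streaming
   (`stream_engine()`/`stream_feed()`), and live use run the identical
   arithmetic in the identical order, so offline reanalysis reproduces an
   online session exactly. This is tested as bit-identity between
   `run_offline()` and a frame-by-frame replay.

## From raw intensities to hemoglobin

The modified Beer–Lambert law is applied differentially against a
streaming baseline: the mean intensity over a configurable window,
by default the first 200 received samples. Nothing is emitted before the
window completes; at completion, the baseline-period frames are converted
retroactively, which keeps online and offline outputs identical. Optical
density uses base-10 logarithms (the standard differential MBLL
formulation); with extinction coefficients in l·cm⁻¹·mmol⁻¹ and
source–detector distances in cm, concentration changes are in mmol/l.
The default distance is 3.0 cm — a standard adult scalp separation —
overridable per channel in the montage, since absolute concentration
scale (not shape) depends on it. Nonpositive intensities yield flagged
missing samples rather than errors: a real-time pipeline must not halt on
a bad frame, and dead channels (zero baseline intensity) are excluded
rather than fatal.

## Causal preprocessing

**Detrending.** The raw-data detrend subtracts, at each sample, the
ordinary least-squares line fitted to all samples received so far,
updated from running sums in O(1) per sample. The first sample passes
through unchanged (one point determines no line); from the second sample
on the fit is exact, so constants map to zero immediately. A linear
causal fit was chosen over a high-pass filter because it is parameter
free and removes drift without a transient of its own.

**Moving-average smoothing** divides by the number of samples actually in
the (possibly partial) window, so the DC gain is exactly 1 from the first
sample. The order parameter (1–5) cascades the same window repeatedly.
When derived from a cutoff, the window defaults to
`max(1, round(fs / (2 * f_c)))`.

**IIR filter bank.** Butterworth, Chebyshev I/II, and elliptic designs
come from the `signal` package; the RBJ biquad follows the standard
audio-EQ cookbook (default $Q = 1/\sqrt2$); Bessel prototypes are built
from reverse Bessel polynomials with the cutoff renormalized numerically
to the −3 dB point; Legendre (optimum-monotonic) prototypes use the
published characteristic polynomials up to order 5 — higher orders are
refused rather than extrapolated. Band transformations exist for the
biquad and the `signal`-backed families; Bessel and Legendre are
low/high-pass only. All realizations are applied in direct-form-II
transposed with explicit per-channel state, start from zero state (the
initial transient is visible, as it must be in real time), and are
rejected at design time if any pole lies on or outside the unit circle.
Note one analytic subtlety the tests respect: even-order Chebyshev-I and
elliptic low-pass responses sit at the bottom of their ripple band at DC
— their "DC gain 1" only holds within the specified ripple.

**Motion correction** exploits the expected anti-correlation of HbO and
Hb. The scale ratio $\alpha = \mathrm{sd(HbO)}/\mathrm{sd(Hb)}$ is
maintained from streaming moments over the whole history (the method
needs causality, not a window; a windowed variant would be a
straightforward extension, and the whole-history choice is the
conservative default). Corrected signals are
$\mathrm{HbO}' = (\mathrm{HbO} - \alpha\,\mathrm{Hb})/2$ and
$\mathrm{Hb}' = -\mathrm{HbO}'/\alpha$; common-mode artifacts cancel
exactly when $\alpha$ is frozen and to first order while it adapts.
Channels pass through until two distinct samples have been observed.

## The recursive least-squares GLM

`rlsglm()` is the package's model object. Initialization waits for the
first design prefix of full rank with condition number below $10^{10}$
and solves that prefix directly; before that, no coefficients are
emitted (reporting betas from a rank-deficient design would be
arbitrary). From then on, rank-1 recursions advance the shared
$P = (X'X)^{-1}$ once per sample and the coefficients per channel, at
constant cost $O(p^2 + \text{channels}\cdot p)$ per sample. Equality
with batch OLS at *every* post-initialization sample — not just the last
— is the core correctness property and is tested against an independent
QR-based solve at tolerance $10^{-8}$.

Floating-point drift of $P$ is bounded by insurance: the Gram matrix is
also maintained incrementally (an $O(p^2)$ update), and every 1000
updates $P$ is compared against its direct inverse and refreshed if the
relative deviation exceeds $10^{-8}$. This keeps the drift check itself
O(1) amortized, preserving the flat per-sample cost over multi-hour
runs; the suite verifies the operation count has zero slope in $t$.

The HRF is a canonical double gamma (peak 6 s, undershoot 16 s,
peak:undershoot ratio 6, support 32 s), normalized to unit peak;
predictors are additionally rescaled to unit peak after convolution so a
beta reads directly as response amplitude in signal units. All HRF
parameters are exposed (`hrf_params`) since fNIRS response timing varies
across cortex and age groups. Reported statistics are betas and
contrasts of betas; t-values are available but labeled
autocorrelation-naive — at fNIRS sampling rates serial correlation
inflates naive t-values substantially, and prewhitening is deliberately
out of scope.

## Single-trial estimation and decoding

Each trial window spans from 2 s before block onset to 12 s after block
offset (defaults; the pre-stimulus margin anchors the baseline, the
post-stimulus margin captures the delayed response and undershoot). Per
channel, the window is z-normalized by default (removing scale
differences between channels), then an OLS fit with a constant, an
optional linear trend, and one HRF-convolved single-trial boxcar yields
the estimate: the main beta (default), its t-value, or the
percent-signal beta $100\,\beta_{\text{main}}/\beta_{\text{constant}}$.
The percent option interacts badly with z-normalization (the constant
beta can be near zero); when $|\beta_{\text{constant}}| < 10^{-8}$ the
raw beta is returned with a warning rather than an unstable ratio.
Zero-variance windows produce a flagged zero feature, and singular trial
designs drop the trial with a warning.

Classification uses a linear one-vs-one SVM with $C = 1$ (`e1071`,
without internal rescaling — features are already z-scored by
construction), the common default for block-design decoding where
patterns are low-dimensional and nearly separable. Evaluation is
leave-one-run-out; the permutation test shuffles class labels within
each run, retrains per fold, and scores the held-out run against its
true labels, with $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$.

One property of this null deserves a note. On strongly separable data
the null distribution is discrete with an atom at 100%: a within-run
shuffle that happens to remain net-aligned with the true labeling (or
consistently inverted across the training runs) still trains a perfect
decoder. At the simulator's default signal-to-noise ratio this atom
carries roughly 1–1.5% of the mass, so a 1000-permutation $p$ for a
perfect observed accuracy lands near 0.01 and can fall on either side of
it depending on the permutation stream. Noisier (more realistic) data
shrink the atom and the $p$-value with it; this granularity is a known
small-sample property of permutation tests, not an implementation
artifact.

## Neurofeedback

Feedback values are deviations of the channel-averaged preprocessed
signal from the most recent baseline level, with Hb inverted so that the
expected task-related Hb decrease produces positive feedback; the
combined mode is the mean of the two. Baseline windows are shifted to
respect hemodynamic delay: by default 5 s forward at block onset
(protecting against the decaying previous response) and 1 s past block
offset (the new response rises only after ~2–3 s) — so a 50–70 s
baseline block becomes the 55–71 s window. Windows shorter than 4 s are
invalid and suppress output entirely (10 s or more is recommended).
Because the end-shift extends the baseline into the modulation block,
the block's first second(s) cannot produce feedback; emission starts
once the baseline is complete, preserving causality. The thermometer
maps $\mathrm{clamp}(fb/\text{max\_val}, 0, 1)$ onto $0..\text{levels}$
rectangles, rounding half away from zero (the natural reading of "0.25
of 0.5 half-fills 10 rectangles"); negative feedback clamps to an empty
display rather than a signed one. `max_val` is in the units of the
preprocessed signal and should be calibrated from localizer runs.

## The simulator: what it emulates, what it does not

`simulate_concentration()` builds ground truth as HRF-convolved condition
boxcars scaled by a per-condition, per-channel amplitude map, with Hb
defaulting to $-\tfrac13$ of HbO (the typical inverse deflection, which
also makes the motion-correction model assumption approximately hold).
Noise comprises white Gaussian noise, linear drift, three sinusoidal
physiological bands (cardiac ≈ 1.0 Hz, respiratory ≈ 0.3 Hz, Mayer
≈ 0.1 Hz) with random per-channel phases, and optional common-mode
motion spikes. `to_raw_intensities()` pushes the concentrations through
the Beer–Lambert forward model so the full pipeline — baseline, MBLL,
filtering, GLM — can be validated by parameter recovery.

Default study conditions for the finger-tapping preset, fixed once:
20 channels (8 sources, 8 detectors; channels 1–10 left hemisphere,
11–20 right, source-major order with channel #1 = source 2/detector 1);
7.8125 Hz sampling; three runs of 12 trials per condition, 10 s task /
20 s rest, 30 s lead-in; contralateral response amplitude 0.001 mmol/l;
white noise SD 5 × 10⁻⁴ mmol/l (per-sample SNR 2 at the response peak —
a clean but attainable motor-cortex recording); oscillation amplitudes
10% of the peak response; drift 10⁻⁶ mmol/l/s; motion spikes off for the
compliant-subject preset (available via `spike_rate_hz`). All randomness
is seed-derived and sessions are byte-reproducible.

What the simulator does **not** emulate: superficial/systemic physiology
shared across channels (scalp blood flow), spatially correlated noise,
serial correlation beyond the injected oscillations, optode-coupling
changes, heterogeneous per-channel HRFs, and photon-transport effects
(partial volume, wavelength cross-talk). Passing recovery and decoding
tests on this generator therefore demonstrates correctness of the
arithmetic and the causal contracts, and plausibility of the defaults —
not decoding performance on in-vivo data, where systemic confounds
typically dominate.

## Numerical choices and problem sizes

Protocols use half-open `[onset, offset)` intervals in seconds, mapped
to samples by `floor`; this is fixed and documented because on/off
conventions are a chronic source of off-by-one disagreements between
acquisition and analysis software. The test suite and the acceptance
script run at deliberately desk-sized problems — 64 channels × ~4 min
for the online/offline GLM agreement, 3 × 12-trial runs for decoding,
1000 permutations — chosen so the whole verification completes in a few
minutes while still crossing every initialization, refresh, and
retroactive-conversion boundary in the code.

## Known limitations

No prewhitening/precoloring for serial correlation (betas are the
supported statistic); no wavelet or spline motion correction and no
short-separation regression; two wavelengths only; no absolute oximetry;
no group-level models; the network service is a minimal line protocol,
not a hardware SDK emulation; real-time pacing (sleeping between frames)
is best-effort and untested because it is timer-dependent — ordering and
content, which are testable, are what the replay tests assert.
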