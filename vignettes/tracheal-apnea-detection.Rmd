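---
title: "Detecting apnea from tracheal sounds with adaptive noise cancellation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting apnea from tracheal sounds with adaptive noise cancellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneasound)
```

## The problem

A microphone taped over the trachea picks up breath sounds whose short-time
energy rises and falls with every inspiration and expiration. When breathing
stops, the trachea goes quiet: an absence of breath sounds lasting more than
15 seconds is an apnea event. This makes tracheal audio an attractive,
low-cost alternative to full polysomnography for respiratory monitoring — but
only in a quiet room. Talking, television, and machine alarms leak into the
tracheal microphone, masquerade as breath sounds during a real apnea, and
destroy the detector's sensitivity.

`apneasound` implements the two-microphone answer: a *primary* microphone
(tracheal sounds plus ambient noise) and a *reference* microphone (ambient
noise only) feed a normalized least-mean-squares (NLMS) adaptive noise
canceller; breath and apnea detection then run on the denoised signal.

## The adaptive filter

With primary input $d(n)$ and reference input $x(n)$, the canceller maintains
a tap-weight vector $w(n)$ over the most recent $L$ reference samples
$\mathbf{x}(n)$ and computes, per sample,

$$y(n) = \mathbf{x}^T(n)\,w(n), \qquad e(n) = d(n) - y(n),$$
$$w(n+1) = w(n) + \frac{\mu}{\mathbf{x}^T(n)\mathbf{x}(n) + \psi}\; e(n)\,\mathbf{x}(n),$$

where $\mu$ is the step size and $\psi$ a small regularizer that keeps the
normalizing denominator strictly positive. The error signal $e(n)$ *is* the
output: whatever part of the primary channel the filter can predict from the
reference channel (the coupled ambient noise) is subtracted, and the
unpredictable part (the tracheal sound) remains.

Defaults are $\mu = 0.08$, $\psi = 0.02$, $L = 64$ taps
(`nlms_config()`). Design choices a reader may want to know:

* **Weights start at zero**, which makes the zero-reference case an exact
  identity: with a silent reference channel the output equals the input
  sample for sample. This matters in practice — in a quiet room the canceller
  must not degrade an already-clean recording.
* **The tap buffer is zero-padded** for the first $L$ samples rather than the
  first $L$ output samples being trimmed, preserving alignment between the
  filtered signal and external annotations.
* **The normalization energy $\mathbf{x}^T(n)\mathbf{x}(n)$ is computed over
  the current tap buffer only**, and is recomputed from the buffer each
  sample rather than maintained as a running sum, avoiding accumulation
  drift over multi-million-sample records.
* **The whole recursion runs in double precision** (compiled code, but a
  straight per-sample loop — the test suite checks it against an independent
  pure-R reference recursion to 1e-9 relative error).
* **Weights are reset at the start of every record.** Whether state should
  persist across records is an open design point; per-record reset is the
  reproducible choice.

## Breath detection

Detection runs on the (optionally denoised) signal in four stages
(`detect_record()`):

1. **Band-pass**: 5th-order Butterworth, 150–800 Hz, applied
   forward–backward (zero phase). The band keeps breath-sound energy while
   rejecting heart sounds and low-frequency rumble below and hiss above; the
   zero-phase application keeps event timestamps unshifted. Filtering is
   delegated to the `signal` package; at 22 050 Hz the 10th-order
   transfer-function realization is comfortably stable (largest pole modulus
   0.991).
2. **Log-variance**: the band-passed signal is cut into 20 ms windows with
   75% overlap (5 ms hop) and each window is summarized by the log of its
   variance. Window and hop lengths in samples are `round(0.020 * rate)` and
   `round(window * 0.25)`; the trailing partial window is dropped. The
   variance is clamped below at `1e-12` (signals are normalized to unit full
   scale) so digital silence stays finite.
3. **Threshold**: one threshold per record, from 2-class 1-D k-means on the
   record's log-variance values with deterministic initialization at the
   10th and 90th percentiles; the threshold is the midpoint of the two
   cluster centers. The silence/breath contrast makes the distribution
   strongly bimodal, which this rule exploits with no tunable parameters.
   If the two centers end up closer than 1 log-variance unit the record is
   effectively unimodal and the threshold is set above the maximum — nothing
   is marked as breath, the conservative reading of a contrast-free record.
4. **Run extraction**: maximal runs of supra-threshold windows become breath
   events. Runs separated by less than 0.25 s are merged first (single-window
   dropouts are common at a 5 ms hop, and a quarter second is far below any
   physiologic pause); runs shorter than 0.5 s are then discarded. Event
   boundaries are the window-center times of the run.

An **apnea** is any gap in the breath timeline strictly longer than 15 s
(`detect_apneas()`), including gaps against the record boundaries — a record
that starts or ends mid-breath-hold is flagged, and scorers can exclude
boundary events downstream if they prefer the bracketed convention.

## Scoring

`score_events()` compares detected against reference apnea events. Any
positive temporal overlap qualifies a detected/reference pair; pairs are
assigned one-to-one greedily by decreasing overlap, so a single long detected
event spanning two reference events scores one true positive and one false
negative. Detected events overlapping nothing are false positives. True
negatives are time-quantized: the total time in which *neither* method flags
apnea, divided by 15 s and floored. Flooring is the conservative choice — a
fractional "count" has no place in a contingency table. Intervals are
half-open `[onset, offset)`, so abutting events do not overlap.

`compute_metrics()` derives sensitivity, specificity, PPV, NPV, accuracy and
Cohen's kappa ($\kappa = (p_o - p_e)/(1 - p_e)$, $p_e$ from the table
marginals). A metric with a zero denominator is `NA`, never a silent 0 or 1.

## SNR evaluation

For filter evaluation on synthetic mixtures, `mix_signals()` forms
$s(n) = B(n) + G_i\,x(n)$ from a clean segment $B$ and noise $x$, with $G_i$
the noise proportion, and

$$\mathrm{SNR} = 10\log_{10}\frac{\mathrm{var}(B)}{\mathrm{var}(s - B)}$$

evaluated before (`snr_before()`, on $s$) and after (`snr_after()`, on the
filter output $e$) cancellation. Variances are population (1/N) variances —
over a 20 s segment at 22 050 Hz the biased/unbiased difference is
negligible, and fixing the estimator makes results bit-reproducible. A
direct consequence of the mixing model is the exact spacing
$\mathrm{SNRo}(G_i) = \mathrm{SNRo}(1) - 20\log_{10} G_i$: anchored at
$-1.35$ dB for $G_i = 1$, the mixture sits at $-4.87$ dB for $G_i = 1.5$
and $-7.37$ dB for $G_i = 2$, which the acceptance script recomputes.

## The synthetic record generator

Real two-microphone recordings cannot ship with a package, so
`generate_record()` builds records that emulate the breath-hold protocol the
detector is meant for: after a 2-minute lead-in of normal breathing, ten
20 s breath-holds repeated every 40 s, then normal breathing to the end of a
15-minute record (all configurable via `synth_protocol()`).

* **Breath sounds** are white noise band-passed to 150–800 Hz under
  raised-cosine burst envelopes: per 4 s breathing cycle, a 1 s inspiration
  burst, a 0.5 s pause, a 1 s expiration burst, and a 1.5 s pause. This
  places all signal energy inside the detector band; it does not attempt
  physiologic spectral detail. The carrier is filtered causally — its phase
  carries no timing information — while detection itself always filters
  zero-phase.
* **Ambient noise** (`noise_kind = "speech_like"`) is white noise shaped by a
  low-order all-pole spectrum (resonances near 350 and 1200 Hz) with 2–8 Hz
  syllabic amplitude modulation — the cadence of a talker or television —
  or plain white noise. The reference channel carries this process directly.
* **Coupling**: the noise reaches the primary microphone through a random
  unit-norm 64-tap FIR path, matched to the canceller's modeling capacity:
  the filter *can* cancel it, but must adapt to do so. `target_snr_db`
  solves the noise gain from the clean/coupled variance ratio so the mixture
  sits at a requested SNR.
* **Determinism**: a record is a pure function of its protocol, including
  the seed; the generator saves and restores the caller's RNG state.

What passing tests on these records shows — and does not. The generator
reproduces the *structure* the detector relies on (band-limited bursts,
silent holds, reference-coupled noise); it omits heart sounds, snoring,
body-movement artifacts, microphone nonlinearity, and reference-channel
leakage of the tracheal sound itself. Perfect recovery on clean synthetic
records validates the algorithmic chain, not clinical performance.

## Numerical and scale choices

Sample-count arithmetic uses explicit rounding (see above) to prevent
off-by-one drift. Thresholding is deterministic for a fixed record. The
package's validation runs use 15-minute records at 22 050 Hz for the
full-protocol checks (ten noise-free records for parameter recovery; five
noisy records at −5 dB for the filtering-rescue comparison) and shorter
30–300 s records for unit-level properties.

## Known limitations

* The default per-record threshold assumes the noise level is roughly
  stationary within a record. `logvar_threshold(sliding_window = ...)`
  offers a chunked variant for drifting noise floors (chunks without
  silence/breath contrast inherit the record-level threshold), but the
  per-record rule remains the default and the validated configuration.
* Detection runs at the native sampling rate; no decimation stage is
  provided.
* Hypopnea (partial airflow reduction) is out of scope: the detector finds
  complete absences of breath sounds.
* Inspiration and expiration are marked identically; no phase labeling.
* The >15 s rule is strict (`> 15`, not `>= 15`); sleep-medicine contexts
  that use a 10 s criterion can set `apnea_min_gap = 10`.
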