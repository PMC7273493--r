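# apneasound

Apnea detection from tracheal breath sounds, with two-microphone adaptive
noise cancellation.

A microphone over the trachea hears every inspiration and expiration as a
burst of band-limited sound energy; a silence longer than 15 seconds is an
apnea. That simple acoustic criterion works well in a quiet room and fails
badly next to a television: ambient noise leaking into the tracheal
microphone is detected as "breathing" exactly when a real apnea occurs. This
package implements the standard fix — a second, reference microphone that
hears only the ambient noise drives a normalized least-mean-squares (NLMS)
adaptive canceller which subtracts the predictable noise component from the
primary channel before detection. It is aimed at researchers in respiratory
acoustics who need a tested, reproducible reference implementation of this
pipeline plus a ground-truthed simulator to evaluate it on.

## The method in brief

**Adaptive filter.** With primary input *d(n)* (tracheal sound + noise) and
reference input *x(n)* (noise), per sample:

    y(n) = xᵀ(n) w(n)
    e(n) = d(n) − y(n)
    w(n+1) = w(n) + μ / (xᵀ(n) x(n) + ψ) · e(n) x(n)

with step size μ = 0.08, regularizer ψ = 0.02 and 64 taps by default. The
error signal *e(n)* is the denoised tracheal sound.

**Breath/apnea detection.** Zero-phase 5th-order Butterworth band-pass
(150–800 Hz) → log-variance in 20 ms windows with 75% overlap → per-record
threshold from 2-class k-means → supra-threshold runs ≥ 0.5 s are breaths →
breath gaps > 15 s are apneas.

**Scoring.** Detected vs reference apnea events: greedy one-to-one matching
by overlap gives TP/FN/FP; time with neither method flagging apnea, divided
by 15 s and floored, gives TN; then sensitivity, specificity, PPV, NPV,
accuracy and Cohen's kappa.

**SNR evaluation.** Mixtures s(n) = B(n) + Gᵢ·x(n) scored by
SNR = 10·log10(var(B)/var(s−B)) before and after filtering.

See `vignette("tracheal-apnea-detection")` for assumptions, parameter
rationale, and limitations.

## Worked example

Simulate a 5-minute record with four 20 s breath-holds under speech-like
ambient noise at −5 dB SNR, then detect apneas with and without the adaptive
filter:

```r
library(apneasound)

rec <- generate_record(synth_protocol(
  total_duration = 300, apnea_count = 4, lead_in = 60,
  noise_kind = "speech_like", target_snr_db = -5, seed = 42
))

run_pipeline(rec$primary, truth = rec$true_apneas, use_af = FALSE)
#> <apnea_pipeline> AF off | 1 breaths | 0 apneas
#> <apnea_metrics>
#>   sensitivity 0.0%  specificity 100.0%  PPV NA
#>   NPV 77.8%  accuracy 77.8%  kappa 0.000
#>   (TP 0, FP 0, FN 4, TN 14)

run_pipeline(rec$primary, rec$reference, truth = rec$true_apneas, use_af = TRUE)
#> <apnea_pipeline> AF on | 110 breaths | 4 apneas
#> <apnea_metrics>
#>   sensitivity 100.0%  specificity 100.0%  PPV 100.0%
#>   NPV 100.0%  accuracy 100.0%  kappa 1.000
#>   (TP 4, FP 0, FN 0, TN 14)
```

Without filtering, the noise is loud enough that breath detection collapses
(one spurious "breath" run covering the whole record, no gaps, all four
apneas missed). With the reference channel and NLMS cancellation the breath
train is recovered (110 inspiration/expiration events) and all four
scheduled apneas are found with no false alarms; the 14 true negatives are
the 220 s of correctly unflagged time in 15 s units. `tidy()` and `glance()`
return the metrics as tibbles; `autoplot()` on the detection object shows
the log-variance trace, threshold, and events.

The same stages are scriptable from a shell via
`inst/cli/apneasound.R` (`simulate`, `filter`, `detect`, `score`,
`evaluate`, `pipeline`).

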