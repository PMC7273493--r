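#' Build a weighted noise mixture
#'
#' Forms the synthetic contaminated signal \eqn{s(n) = B(n) + G_i \, x(n)},
#' where \eqn{G_i} sets the proportion of noise in the mixture. The study
#' values of interest are \eqn{G_i \in \{1, 1.5, 2\}}.
#'
#' @param clean [audio_signal()] \eqn{B(n)}: uncontaminated tracheal sound.
#' @param noise [audio_signal()] \eqn{x(n)}: ambient noise; same length/rate.
#' @param gain Noise proportion \eqn{G_i \ge 0}.
#' @return The mixture as an [audio_signal()].
#' @export
mix_signals <- function(clean, noise, gain) {
  check_aligned(clean, noise, "clean", "noise")
  if (!is.numeric(gain) || length(gain) != 1 || !is.finite(gain) || gain < 0) {
    abort("`gain` must be a single non-negative number.", class = "apneasound_invalid_input")
  }
  audio_signal(clean$samples + gain * noise$samples, clean$rate)
}

#' Signal-to-noise ratio against the clean signal
#'
#' \deqn{\mathrm{SNR} = 10 \log_{10} \frac{\mathrm{var}(B(n))}{\mathrm{var}(s(n) - B(n))}}
#' with population (1/N) variances. `snr_before()` evaluates the mixture
#' before filtering (SNRo); `snr_after()` evaluates the adaptive-filter output
#' against the same clean signal (SNRf). A residual with zero variance —
#' perfect recovery — yields `+Inf`, not an error.
#'
#' @param clean [audio_signal()] \eqn{B(n)}.
#' @param mixed [audio_signal()]: the contaminated signal \eqn{s(n)} (for
#'   `snr_before`) or the filtered signal \eqn{e(n)} (for `snr_after`).
#' @return SNR in dB.
#' @export
snr_before <- function(clean, mixed) {
  check_aligned(clean, mixed, "clean", "mixed")
  resid <- mixed$samples - clean$samples
  vb <- pop_var(clean$samples)
  vr <- pop_var(resid)
  if (vr == 0) return(Inf)
  10 * log10(vb / vr)
}

#' @rdname snr_before
#' @param filtered [audio_signal()]: adaptive-filter output \eqn{e(n)}.
#' @export
snr_after <- function(clean, filtered) {
  snr_before(clean, filtered)
}

#' Evaluate adaptive-filter SNR improvement across noise proportions
#'
#' For each noise gain, builds the mixture \eqn{s = B + G_i x}, runs the NLMS
#' canceller with \eqn{G_i x} as the reference input, and reports SNR before
#' (SNRo) and after (SNRf) filtering plus the improvement.
#'
#' @param clean [audio_signal()] \eqn{B(n)}.
#' @param noise [audio_signal()] \eqn{x(n)}; same length and rate.
#' @param gains Numeric vector of noise proportions \eqn{G_i}.
#' @param config An [nlms_config()].
#' @return A tibble with columns `gain`, `snr_before_db`, `snr_after_db`,
#'   `improvement_db`, one row per gain.
#' @export
evaluate_snr <- function(clean, noise, gains = c(1, 1.5, 2),
                         config = nlms_config()) {
  check_aligned(clean, noise, "clean", "noise")
  purrr::map_dfr(gains, function(g) {
    mixed <- mix_signals(clean, noise, g)
    ref <- audio_signal(g * noise$samples, noise$rate)
    filt <- nlms_cancel(mixed, ref, config)
    before <- snr_before(clean, mixed)
    after <- snr_after(clean, filt)
    tibble::tibble(gain = g, snr_before_db = before, snr_after_db = after,
                   improvement_db = after - before)
  })
}
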