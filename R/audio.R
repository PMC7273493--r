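#' Construct an audio signal
#'
#' The carrier object passed between every stage of the pipeline: a uniformly
#' sampled waveform in arbitrary linear amplitude units plus its sampling rate.
#'
#' @param samples Numeric vector of finite amplitude values.
#' @param rate Sampling rate in samples per second (Hz); must be positive.
#'
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate`.
#' @examples
#' sig <- audio_signal(sin(2 * pi * 400 * seq(0, 1, by = 1 / 22050)), 22050)
#' sig
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.double(samples)
  rate <- as.double(rate)
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number.", class = "apneasound_invalid_input")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).", class = "apneasound_invalid_input")
  }
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    length(x$samples), x$rate, duration(x),
    if (length(x$samples)) min(x$samples) else NA, if (length(x$samples)) max(x$samples) else NA
  ))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Length in seconds (`n_samples / rate`).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$rate
}

is_audio_signal <- function(x) inherits(x, "audio_signal")

# Shared precondition: two signals that must be sample-aligned.
check_aligned <- function(a, b, a_name = "primary", b_name = "reference") {
  if (!is_audio_signal(a) || !is_audio_signal(b)) {
    abort("Both inputs must be `audio_signal` objects.", class = "apneasound_invalid_input")
  }
  if (length(a$samples) != length(b$samples)) {
    abort(
      sprintf("`%s` and `%s` must have equal length (%d vs %d).",
              a_name, b_name, length(a$samples), length(b$samples)),
      class = "apneasound_invalid_input"
    )
  }
  if (a$rate != b$rate) {
    abort(
      sprintf("`%s` and `%s` must share a sampling rate (%g vs %g Hz).",
              a_name, b_name, a$rate, b$rate),
      class = "apneasound_invalid_input"
    )
  }
  invisible(TRUE)
}

# Population (1/N) variance; stated once so every SNR formula uses the same
# estimator.
pop_var <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  m <- sum(x) / n
  sum((x - m)^2) / n
}
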