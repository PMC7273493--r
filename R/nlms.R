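#' NLMS adaptive-filter configuration
#'
#' Parameters of the normalized least-mean-squares (NLMS) noise canceller.
#' The defaults are the preset used throughout this package: step size
#' \eqn{\mu = 0.08}, regularizer \eqn{\psi = 0.02}, and 64 filter taps.
#' \eqn{\psi} keeps the normalizing denominator strictly positive even when
#' the reference tap buffer is all zero.
#'
#' @param mu Adaptation step size; dimensionless, > 0.
#' @param psi Regularizer added to the tap energy in the step-size
#'   normalization; dimensionless, > 0.
#' @param order Number of filter taps; positive integer.
#' @return A list of class `nlms_config`.
#' @export
nlms_config <- function(mu = 0.08, psi = 0.02, order = 64) {
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) || mu <= 0) {
    abort("`mu` must be a single positive number.", class = "apneasound_invalid_input")
  }
  if (!is.numeric(psi) || length(psi) != 1 || !is.finite(psi) || psi <= 0) {
    abort("`psi` must be a single positive number.", class = "apneasound_invalid_input")
  }
  order <- as.integer(order)
  if (length(order) != 1 || is.na(order) || order < 1) {
    abort("`order` must be a positive integer.", class = "apneasound_invalid_input")
  }
  structure(list(mu = mu, psi = psi, order = order), class = "nlms_config")
}

#' @export
print.nlms_config <- function(x, ...) {
  cat(sprintf("<nlms_config> mu = %g, psi = %g, order = %d\n", x$mu, x$psi, x$order))
  invisible(x)
}

#' NLMS adaptive noise cancellation
#'
#' Removes the ambient-noise component of the primary (tracheal) channel by
#' adaptively estimating it from the reference (ambient) channel. At each
#' sample the reference tap vector is filtered by the current weights to
#' predict the noise leaking into the primary channel; the prediction error
#' \eqn{e(n) = d(n) - y(n)} is both the output (the denoised tracheal sound)
#' and the update signal for the weights:
#' \deqn{w(n+1) = w(n) + \frac{\mu}{x^T(n)x(n) + \psi}\, e(n)\, x(n).}
#' Weights start at zero, so a zero reference channel leaves the primary
#' untouched. Reference samples before the first tap-buffer fill are
#' zero-padded, preserving sample alignment with annotations.
#'
#' @param primary [audio_signal()]: tracheal sounds mixed with noise, d(n).
#' @param reference [audio_signal()]: ambient noise, x(n); same length and
#'   rate as `primary`.
#' @param config An [nlms_config()].
#' @return An [audio_signal()] holding e(n), same length and rate as
#'   `primary`.
#' @examples
#' fs <- 8000
#' noise <- audio_signal(rnorm(fs), fs)
#' clean <- audio_signal(sin(2 * pi * 300 * seq_len(fs) / fs) * 0.2, fs)
#' primary <- audio_signal(clean$samples + 0.8 * noise$samples, fs)
#' denoised <- nlms_cancel(primary, noise, nlms_config())
#' @export
nlms_cancel <- function(primary, reference, config = nlms_config()) {
  check_aligned(primary, reference)
  stopifnot(inherits(config, "nlms_config"))
  e <- nlms_core(primary$samples, reference$samples,
                 config$mu, config$psi, config$order)
  audio_signal(e, primary$rate)
}
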