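#' Synthetic recording protocol
#'
#' Parameters of the simulated breath-hold protocol: after a resting lead-in
#' of normal breathing, the subject holds their breath for `apnea_duration`
#' seconds once per `apnea_cycle`-second cycle, `apnea_count` times, then
#' breathes normally to the end of the record. Defaults give a 15-minute
#' record with ten 20 s holds repeated every 40 s after a 2-minute lead-in.
#'
#' @param total_duration Record length in seconds.
#' @param breath_period Breathing-cycle period in seconds; each cycle carries
#'   a 1 s inspiration burst and a 1 s expiration burst.
#' @param apnea_duration Breath-hold length in seconds.
#' @param apnea_cycle Interval between consecutive hold onsets in seconds.
#' @param apnea_count Number of holds.
#' @param lead_in Normal breathing before the first hold, in seconds.
#' @param noise_kind `"none"`, `"speech_like"` (all-pole shaped noise with
#'   2-8 Hz syllabic amplitude modulation, mimicking a nearby talker or TV),
#'   or `"white"`.
#' @param noise_gain Linear gain applied to the coupled noise in the primary
#'   channel. Ignored when `target_snr_db` is given.
#' @param target_snr_db If non-`NULL`, `noise_gain` is solved from the
#'   clean/coupled variance ratio so that the mixture SNR (clean vs
#'   primary-minus-clean) equals this value in dB.
#' @param coupling_taps Length of the random unit-norm FIR path through which
#'   the reference noise leaks into the primary microphone. The default 64
#'   matches the adaptive filter's modeling capacity.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; records are bit-identical given the same seed.
#' @return A list of class `synth_protocol`.
#' @export
synth_protocol <- function(total_duration = 900, breath_period = 4,
                           apnea_duration = 20, apnea_cycle = 40,
                           apnea_count = 10, lead_in = 120,
                           noise_kind = c("none", "speech_like", "white"),
                           noise_gain = 1, target_snr_db = NULL,
                           coupling_taps = 64, rate = 22050, seed = 1) {
  noise_kind <- match.arg(noise_kind)
  if (any(c(total_duration, breath_period, apnea_duration, apnea_cycle) <= 0)) {
    abort("All durations must be positive.", class = "apneasound_invalid_protocol")
  }
  if (apnea_duration >= apnea_cycle) {
    abort("`apnea_duration` must be shorter than `apnea_cycle`.",
          class = "apneasound_invalid_protocol")
  }
  if (lead_in + apnea_count * apnea_cycle > total_duration) {
    abort("Schedule does not fit: lead_in + apnea_count * apnea_cycle exceeds total_duration.",
          class = "apneasound_invalid_protocol")
  }
  structure(
    list(total_duration = total_duration, breath_period = breath_period,
         apnea_duration = apnea_duration, apnea_cycle = apnea_cycle,
         apnea_count = apnea_count, lead_in = lead_in,
         noise_kind = noise_kind, noise_gain = noise_gain,
         target_snr_db = target_snr_db, coupling_taps = as.integer(coupling_taps),
         rate = rate, seed = as.integer(seed)),
    class = "synth_protocol"
  )
}

#' Generate a synthetic two-channel tracheal recording
#'
#' Builds a record emulating the breath-hold protocol: the clean tracheal
#' sound is band-limited (150-800 Hz) noise under raised-cosine burst
#' envelopes — one inspiration and one expiration burst per breathing cycle,
#' silent during scheduled holds. The reference channel carries the ambient
#' noise process; the primary channel is the clean sound plus the reference
#' noise passed through a random unit-norm FIR coupling path and scaled by
#' the noise gain. Ground-truth breath and apnea annotations come from the
#' schedule itself.
#'
#' @param protocol A [synth_protocol()].
#' @return A list of class `synth_record` with elements `primary`,
#'   `reference`, `clean` ([audio_signal()]s), `true_breaths`, `true_apneas`
#'   (event tibbles), `noise_gain` (the gain actually applied) and
#'   `protocol`.
#' @examples
#' rec <- generate_record(synth_protocol(total_duration = 120, apnea_count = 2,
#'                                       lead_in = 20, seed = 7))
#' rec$true_apneas
#' @export
generate_record <- function(protocol) {
  stopifnot(inherits(protocol, "synth_protocol"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(protocol$seed)

  fs <- protocol$rate
  n <- round(protocol$total_duration * fs)
  t_end <- protocol$total_duration

  apnea_on <- protocol$lead_in + (seq_len(protocol$apnea_count) - 1) * protocol$apnea_cycle
  true_apneas <- tibble::tibble(
    onset_s = apnea_on,
    offset_s = apnea_on + protocol$apnea_duration,
    label = "apnea"
  )

  # breathing intervals = complement of the holds
  breathe_start <- c(0, true_apneas$offset_s)
  breathe_end <- c(true_apneas$onset_s, t_end)
  bursts <- purrr::map_dfr(seq_along(breathe_start), function(i) {
    burst_schedule(breathe_start[i], breathe_end[i], protocol$breath_period)
  })
  true_breaths <- tibble::tibble(onset_s = bursts$onset,
                                 offset_s = bursts$offset, label = "breath")

  # burst envelope (raised cosine per burst), then band-limited carrier
  env <- numeric(n)
  for (i in seq_len(nrow(bursts))) {
    i0 <- floor(bursts$onset[i] * fs) + 1
    i1 <- min(n, ceiling(bursts$offset[i] * fs))
    k <- i0:i1
    env[k] <- 0.5 - 0.5 * cos(2 * pi * (k - i0) / (i1 - i0))
  }
  # causal band-pass is enough here: the carrier is a noise process, so its
  # phase carries no timing information (detection still filters zero-phase)
  bt <- signal::butter(5, c(150, 800) / (fs / 2), type = "pass")
  carrier <- as.numeric(signal::filter(bt, rnorm(n)))
  carrier_samples <- carrier / sqrt(pop_var(carrier))
  clean <- 0.15 * env * carrier_samples

  if (protocol$noise_kind == "none") {
    reference <- numeric(n)
    coupled <- numeric(n)
    gain <- 0
  } else {
    reference <- switch(protocol$noise_kind,
                        white = rnorm(n),
                        speech_like = speech_like_noise(n, fs))
    h <- rnorm(protocol$coupling_taps)
    h <- h / sqrt(sum(h^2))
    coupled <- as.numeric(signal::filter(h, 1, reference))
    gain <- protocol$noise_gain
    if (!is.null(protocol$target_snr_db)) {
      gain <- sqrt(pop_var(clean) /
                     (pop_var(coupled) * 10^(protocol$target_snr_db / 10)))
    }
  }
  primary <- clean + gain * coupled

  structure(
    list(primary = audio_signal(primary, fs),
         reference = audio_signal(reference, fs),
         clean = audio_signal(clean, fs),
         true_breaths = true_breaths,
         true_apneas = true_apneas,
         noise_gain = gain,
         protocol = protocol),
    class = "synth_record"
  )
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf(
    "<synth_record> %.0f s @ %g Hz, %d apneas of %g s, noise = %s (gain %.4g)\n",
    x$protocol$total_duration, x$protocol$rate, nrow(x$true_apneas),
    x$protocol$apnea_duration, x$protocol$noise_kind, x$noise_gain
  ))
  invisible(x)
}

# Inspiration/expiration burst times for one breathing interval: per
# breath_period cycle, a 1 s inspiration burst, 0.5 s pause, 1 s expiration
# burst; only bursts fully inside the interval are emitted.
burst_schedule <- function(from, to, period) {
  insp_len <- 1
  exp_len <- 1
  pause <- 0.5
  starts <- seq(from, to, by = period)
  out <- list()
  for (s in starts) {
    if (s + insp_len <= to) {
      out[[length(out) + 1]] <- c(s, s + insp_len)
    }
    e0 <- s + insp_len + pause
    if (e0 + exp_len <= to) {
      out[[length(out) + 1]] <- c(e0, e0 + exp_len)
    }
  }
  if (length(out) == 0) return(tibble::tibble(onset = double(), offset = double()))
  m <- do.call(rbind, out)
  tibble::tibble(onset = m[, 1], offset = m[, 2])
}

# Speech-like ambient noise: white noise through a low-order all-pole filter
# (two resonances giving a speech-band spectral tilt), amplitude-modulated at
# syllabic rates (2-8 Hz), normalized to unit variance.
speech_like_noise <- function(n, fs) {
  pole <- function(f, r) c(1, -2 * r * cos(2 * pi * f / fs), r^2)
  a <- convolve(pole(350, 0.97), rev(pole(1200, 0.90)), type = "open")
  shaped <- as.numeric(signal::filter(1, a, rnorm(n)))
  tt <- seq_len(n) / fs
  f_mod <- runif(3, 2, 8)
  ph <- runif(3, 0, 2 * pi)
  m <- sin(2 * pi * f_mod[1] * tt + ph[1]) + sin(2 * pi * f_mod[2] * tt + ph[2]) +
    sin(2 * pi * f_mod[3] * tt + ph[3])
  m <- (m - min(m)) / (max(m) - min(m))
  env <- 0.15 + 0.85 * m
  out <- shaped * env
  out / sqrt(pop_var(out))
}
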