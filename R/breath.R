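#' Breath-detector configuration
#'
#' Parameters of the log-variance breath detector. Defaults follow the
#' standard tracheal-sound recipe: a 5th-order Butterworth band-pass between
#' 150 and 800 Hz (suppressing heart sounds, muscle noise and high-frequency
#' hiss), 20 ms analysis windows with 75% overlap (5 ms hop), and a 0.5 s
#' minimum duration for a supra-threshold run to count as an inspiration or
#' expiration.
#'
#' @param band_low,band_high Passband edges in Hz.
#' @param butter_order Butterworth prototype order (per band edge).
#' @param window_len Analysis window length in seconds.
#' @param window_overlap Fractional overlap between adjacent windows, in
#'   `[0, 1)`.
#' @param min_breath_dur Minimum duration (s) of a supra-threshold run for it
#'   to be marked as a breath.
#' @param merge_gap Sub-threshold gaps shorter than this (s) are bridged
#'   before the minimum-duration test; single-window dropouts are common at a
#'   5 ms hop and a quarter second is well below any physiologic pause.
#' @param variance_floor Lower clamp on the window variance before the log,
#'   keeping the feature finite on digital silence (signals are normalized to
#'   unit full scale).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(band_low = 150, band_high = 800, butter_order = 5,
                            window_len = 0.020, window_overlap = 0.75,
                            min_breath_dur = 0.5, merge_gap = 0.25,
                            variance_floor = 1e-12) {
  if (band_low <= 0 || band_high <= band_low) {
    abort("Require 0 < band_low < band_high.", class = "apneasound_invalid_input")
  }
  if (window_overlap < 0 || window_overlap >= 1) {
    abort("`window_overlap` must be in [0, 1).", class = "apneasound_invalid_input")
  }
  if (min_breath_dur <= 0 || window_len <= 0) {
    abort("Durations must be positive.", class = "apneasound_invalid_input")
  }
  structure(
    list(band_low = band_low, band_high = band_high, butter_order = butter_order,
         window_len = window_len, window_overlap = window_overlap,
         min_breath_dur = min_breath_dur, merge_gap = merge_gap,
         variance_floor = variance_floor),
    class = "detector_config"
  )
}

#' Zero-phase Butterworth band-pass
#'
#' Forward-backward (zero-phase) application of the Butterworth band-pass, so
#' filtering does not shift event timestamps relative to the reference
#' annotations.
#'
#' @param signal An [audio_signal()]; its rate must exceed twice `band_high`.
#' @param config A [detector_config()].
#' @return A filtered [audio_signal()] of the same length and rate.
#' @export
bandpass <- function(signal, config = detector_config()) {
  stopifnot(is_audio_signal(signal), inherits(config, "detector_config"))
  if (signal$rate <= 2 * config$band_high) {
    abort(sprintf("Sampling rate %g Hz too low for a %g Hz band edge.",
                  signal$rate, config$band_high),
          class = "apneasound_invalid_rate")
  }
  bt <- signal::butter(config$butter_order,
                       c(config$band_low, config$band_high) / (signal$rate / 2),
                       type = "pass")
  audio_signal(signal::filtfilt(bt, signal$samples), signal$rate)
}

# Window geometry shared by log_variance() and tests: sample counts from
# explicit rounding so window placement is identical across implementations.
window_geometry <- function(rate, config) {
  win <- round(config$window_len * rate)
  hop <- round(win * (1 - config$window_overlap))
  list(win = as.integer(win), hop = as.integer(max(1, hop)))
}

#' Windowed log-variance series
#'
#' Segments the (band-passed) signal into overlapping windows and returns the
#' log of the within-window variance — the detection feature: breath sounds
#' raise the short-time variance by orders of magnitude over the silence
#' floor, and the log makes the threshold additive in dB-like units.
#' Variance is clamped at `config$variance_floor` before the log. The trailing
#' partial window is dropped.
#'
#' @param signal An [audio_signal()].
#' @param config A [detector_config()].
#' @return A tibble of class `logvar_series` with columns `time`
#'   (window-center seconds) and `logvar`.
#' @export
log_variance <- function(signal, config = detector_config()) {
  stopifnot(is_audio_signal(signal), inherits(config, "detector_config"))
  g <- window_geometry(signal$rate, config)
  x <- signal$samples
  n <- length(x)
  if (n < g$win) {
    abort("Signal shorter than one analysis window.", class = "apneasound_empty_series")
  }
  starts <- seq.int(1L, n - g$win + 1L, by = g$hop)
  # windowed sums via cumulative sums: O(n) for any overlap
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x * x))
  ends <- starts + g$win - 1L
  s1 <- c1[ends + 1L] - c1[starts]
  s2 <- c2[ends + 1L] - c2[starts]
  v <- s2 / g$win - (s1 / g$win)^2
  v <- pmax(v, config$variance_floor)
  out <- tibble::tibble(
    time = (starts - 1 + (g$win - 1) / 2) / signal$rate,
    logvar = log(v)
  )
  structure(out, class = c("logvar_series", class(out)),
            hop_s = g$hop / signal$rate, window_s = g$win / signal$rate)
}

#' Log-variance detection threshold
#'
#' The breath/silence decision threshold for a record, computed from the
#' record's own log-variance distribution: 2-class 1-D k-means with
#' deterministic initialization at the 10th and 90th percentiles, threshold at
#' the midpoint of the two cluster centers. Records whose log-variance is
#' effectively unimodal (cluster centers closer than `min_separation`) get a
#' threshold above the maximum value, so nothing is marked as breath — the
#' conservative reading of a record with no silence/breath contrast.
#'
#' A sliding variant is available for records whose noise level drifts:
#' with `sliding_window` set, the rule is applied per consecutive chunk of
#' that many seconds, and chunks without bimodal contrast (e.g. uninterrupted
#' breathing) inherit the whole-record threshold. The default remains the
#' single per-record threshold.
#'
#' @param series A `logvar_series` from [log_variance()].
#' @param min_separation Minimum distance (log-variance units) between cluster
#'   centers for the record to count as bimodal.
#' @param margin Offset added to the maximum value in the unimodal fallback.
#' @param sliding_window Optional chunk length in seconds; when given, the
#'   return value is a per-window threshold vector instead of a scalar.
#' @return A single numeric threshold in log-variance units, or a vector with
#'   one threshold per window when `sliding_window` is set.
#' @export
logvar_threshold <- function(series, min_separation = 1.0, margin = 1.0,
                             sliding_window = NULL) {
  stopifnot(inherits(series, "logvar_series"))
  v <- series$logvar
  if (length(v) == 0) {
    abort("Empty log-variance series.", class = "apneasound_empty_series")
  }
  if (!is.null(sliding_window)) {
    global <- cluster_threshold(v, min_separation, margin)
    chunk <- findInterval(series$time, seq(min(series$time),
                                           max(series$time) + sliding_window,
                                           by = sliding_window))
    th <- vapply(split(v, chunk), function(vv) {
      local <- cluster_threshold(vv, min_separation, margin)
      # a chunk without silence/breath contrast inherits the record threshold
      if (local > max(vv)) global else local
    }, numeric(1))
    return(unname(th[as.character(chunk)]))
  }
  cluster_threshold(v, min_separation, margin)
}

# the 2-class 1-D k-means midpoint rule on one set of log-var values
cluster_threshold <- function(v, min_separation, margin) {
  q <- unname(quantile(v, c(0.10, 0.90), type = 7))
  if (diff(q) < .Machine$double.eps^0.5) {
    return(max(v) + margin)
  }
  km <- tryCatch(kmeans(v, centers = matrix(q, ncol = 1)),
                 error = function(e) NULL)
  if (is.null(km)) return(max(v) + margin)
  centers <- sort(km$centers[, 1])
  if (diff(centers) < min_separation) {
    return(max(v) + margin)
  }
  mean(centers)
}

#' Detect breath events from a log-variance series
#'
#' Marks maximal runs of windows whose log-variance exceeds the threshold as
#' inspirations/expirations. Runs separated by sub-threshold gaps shorter than
#' `config$merge_gap` are bridged first; runs shorter than
#' `config$min_breath_dur` are then discarded. Event boundaries are the
#' window-center times of the first and last window of the run.
#'
#' @param series A `logvar_series` from [log_variance()].
#' @param threshold Decision threshold in log-variance units, typically from
#'   [logvar_threshold()]; either a scalar or a per-window vector (the
#'   sliding variant).
#' @param config A [detector_config()].
#' @return A tibble with columns `onset_s`, `offset_s`, `label` (`"breath"`);
#'   zero rows when nothing crosses the threshold. Events are disjoint and
#'   sorted.
#' @export
detect_breaths <- function(series, threshold, config = detector_config()) {
  stopifnot(inherits(series, "logvar_series"))
  if (!length(threshold) %in% c(1L, nrow(series))) {
    abort("`threshold` must be a scalar or one value per window.",
          class = "apneasound_invalid_input")
  }
  above <- series$logvar > threshold
  empty <- tibble::tibble(onset_s = double(), offset_s = double(), label = character())
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(start = series$time[starts[r$values]],
                         end = series$time[ends[r$values]])

  # bridge short dropouts, then apply the minimum-duration rule
  merged <- list()
  cur <- c(runs$start[1], runs$end[1])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - cur[2] < config$merge_gap) {
        cur[2] <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- c(runs$start[i], runs$end[i])
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  keep <- (m[, 2] - m[, 1]) >= config$min_breath_dur
  if (!any(keep)) return(empty)
  tibble::tibble(onset_s = m[keep, 1], offset_s = m[keep, 2], label = "breath")
}
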