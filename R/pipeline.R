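#' Run the breath/apnea detector on one signal
#'
#' Chains the detection stages on a (possibly already denoised) tracheal
#' signal: zero-phase band-pass, windowed log-variance, per-record threshold,
#' breath-run extraction, and the >15 s breath-absence rule.
#'
#' @param signal An [audio_signal()].
#' @param detector A [detector_config()].
#' @param apnea_min_gap Breath-absence threshold in seconds (strict).
#' @return A list of class `apnea_detection` with elements `breaths`,
#'   `apneas` (event tibbles), `threshold`, and `series` (the log-variance
#'   tibble).
#' @export
detect_record <- function(signal, detector = detector_config(),
                          apnea_min_gap = 15) {
  filtered <- bandpass(signal, detector)
  series <- log_variance(filtered, detector)
  threshold <- logvar_threshold(series)
  breaths <- detect_breaths(series, threshold, detector)
  apneas <- detect_apneas(breaths, 0, duration(signal), min_gap = apnea_min_gap)
  structure(list(breaths = breaths, apneas = apneas, threshold = threshold,
                 series = series),
            class = "apnea_detection")
}

#' @export
print.apnea_detection <- function(x, ...) {
  cat(sprintf("<apnea_detection> %d breaths, %d apneas (log-var threshold %.2f)\n",
              nrow(x$breaths), nrow(x$apneas), x$threshold))
  invisible(x)
}

#' Full two-microphone apnea-detection pipeline
#'
#' Optionally denoises the primary channel with the NLMS adaptive filter
#' (using the reference channel), runs breath and apnea detection, and — when
#' reference annotations are supplied — scores the detected apneas against
#' them.
#'
#' @param primary [audio_signal()]: the tracheal-microphone channel.
#' @param reference Optional [audio_signal()]: the ambient-noise microphone
#'   channel; required when `use_af = TRUE`.
#' @param truth Optional data frame of reference apnea events (`onset_s`,
#'   `offset_s`) to score against.
#' @param use_af Apply adaptive filtering before detection?
#' @param nlms An [nlms_config()].
#' @param detector A [detector_config()].
#' @param apnea_min_gap Breath-absence threshold in seconds.
#' @param tn_quantum True-negative time quantum in seconds for scoring.
#' @return A list of class `apnea_pipeline`: the `detection`
#'   (`apnea_detection`), `metrics` (`apnea_metrics` or `NULL`), the
#'   `filtered` signal when AF ran, and `params`, a provenance list of every
#'   parameter used.
#' @export
run_pipeline <- function(primary, reference = NULL, truth = NULL,
                         use_af = !is.null(reference),
                         nlms = nlms_config(), detector = detector_config(),
                         apnea_min_gap = 15, tn_quantum = 15) {
  stopifnot(is_audio_signal(primary))
  filtered <- NULL
  if (use_af) {
    if (is.null(reference)) {
      abort("Adaptive filtering requested but no reference channel given.",
            class = "apneasound_config_error")
    }
    filtered <- nlms_cancel(primary, reference, nlms)
  }
  detection <- detect_record(if (use_af) filtered else primary,
                             detector, apnea_min_gap)
  metrics <- NULL
  if (!is.null(truth)) {
    tab <- score_events(detection$apneas, truth, duration(primary),
                        tn_quantum = tn_quantum)
    metrics <- compute_metrics(tab)
  }
  params <- list(
    use_af = use_af,
    nlms = unclass(nlms),
    detector = unclass(detector),
    apnea_min_gap = apnea_min_gap,
    tn_quantum = tn_quantum,
    rate = primary$rate,
    n_samples = length(primary$samples)
  )
  structure(list(detection = detection, metrics = metrics,
                 filtered = filtered, params = params),
            class = "apnea_pipeline")
}

#' @export
print.apnea_pipeline <- function(x, ...) {
  cat(sprintf("<apnea_pipeline> AF %s | %d breaths | %d apneas\n",
              if (x$params$use_af) "on" else "off",
              nrow(x$detection$breaths), nrow(x$detection$apneas)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @rdname tidy.apnea_metrics
#' @export
tidy.apnea_pipeline <- function(x, ...) {
  if (is.null(x$metrics)) {
    abort("Pipeline ran without reference annotations; no metrics to tidy.",
          class = "apneasound_invalid_input")
  }
  tidy(x$metrics)
}

#' @rdname glance.apnea_metrics
#' @export
glance.apnea_pipeline <- function(x, ...) {
  out <- if (is.null(x$metrics)) {
    tibble::tibble(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                   tn = NA_integer_, sensitivity = NA_real_,
                   specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                   accuracy = NA_real_, kappa = NA_real_)
  } else {
    glance(x$metrics)
  }
  dplyr::mutate(out,
                use_af = x$params$use_af,
                n_breaths = nrow(x$detection$breaths),
                n_apneas = nrow(x$detection$apneas),
                .before = 1)
}
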