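#' Match detected apneas against reference apneas
#'
#' Event-level contingency counting against gold-standard annotations. A
#' reference event is a true positive when a detected event overlaps it
#' (overlap must exceed `min_overlap` seconds); detected events are assigned
#' to reference events one-to-one, greedily by decreasing overlap, so one
#' detected event spanning two reference events scores a single TP. Reference
#' events left unmatched are false negatives; detected events overlapping no
#' reference event at all are false positives. True negatives follow the
#' time-quantized rule: the total time in which neither method flags apnea,
#' divided by `tn_quantum` seconds and floored to an integer count.
#'
#' Intervals are half-open `[onset, offset)` seconds from record start, so
#' abutting events do not overlap.
#'
#' @param detected,reference Data frames of apnea events (columns `onset_s`,
#'   `offset_s`), each internally disjoint and within `[0, record_duration]`.
#' @param record_duration Record length in seconds.
#' @param tn_quantum Width in seconds of one true-negative unit. Default 15.
#' @param min_overlap Minimum overlap (s) for a detected/reference pair to
#'   match; the default 0 accepts any positive overlap.
#' @return A list of class `contingency_table` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
score_events <- function(detected, reference, record_duration,
                         tn_quantum = 15, min_overlap = 0) {
  stopifnot(is.data.frame(detected), is.data.frame(reference))
  for (ev in list(detected, reference)) {
    if (nrow(ev) > 0 &&
        (min(ev$onset_s) < 0 || max(ev$offset_s) > record_duration)) {
      abort("Events fall outside [0, record_duration].",
            class = "apneasound_invalid_input")
    }
  }

  nd <- nrow(detected)
  nr <- nrow(reference)
  tp <- 0L
  fp <- 0L
  if (nd > 0 && nr > 0) {
    ov <- tidyr::expand_grid(d = seq_len(nd), r = seq_len(nr)) |>
      dplyr::mutate(
        overlap = pmin(detected$offset_s[.data$d], reference$offset_s[.data$r]) -
          pmax(detected$onset_s[.data$d], reference$onset_s[.data$r])
      ) |>
      dplyr::filter(.data$overlap > min_overlap) |>
      dplyr::arrange(dplyr::desc(.data$overlap))
    used_d <- logical(nd)
    used_r <- logical(nr)
    for (i in seq_len(nrow(ov))) {
      di <- ov$d[i]; ri <- ov$r[i]
      if (!used_d[di] && !used_r[ri]) {
        used_d[di] <- TRUE
        used_r[ri] <- TRUE
        tp <- tp + 1L
      }
    }
    touches_ref <- unique(ov$d)
    fp <- sum(!seq_len(nd) %in% touches_ref)
  } else if (nd > 0) {
    fp <- nd
  }
  fn <- nr - tp

  flagged <- dplyr::bind_rows(
    detected[, c("onset_s", "offset_s")],
    reference[, c("onset_s", "offset_s")]
  )
  quiet_time <- record_duration - union_length(flagged)
  tn <- as.integer(floor(quiet_time / tn_quantum))

  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = tn),
            class = "contingency_table")
}

# total length of the union of possibly overlapping [onset, offset) intervals
union_length <- function(events) {
  if (nrow(events) == 0) return(0)
  ev <- dplyr::arrange(events, .data$onset_s)
  total <- 0
  cur_s <- ev$onset_s[1]
  cur_e <- ev$offset_s[1]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$onset_s[i] <= cur_e) {
        cur_e <- max(cur_e, ev$offset_s[i])
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- ev$onset_s[i]
        cur_e <- ev$offset_s[i]
      }
    }
  }
  total + (cur_e - cur_s)
}

#' Construct a contingency table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A list of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.", class = "apneasound_invalid_input")
  }
  structure(lapply(as.list(counts), as.integer), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> TP %d | FP %d | FN %d | TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Performance metrics from a contingency table
#'
#' Computes the six event-level detection metrics:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, accuracy
#' `(TP+TN)/N`, and Cohen's kappa
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with \eqn{p_o} the accuracy and
#' \eqn{p_e} the chance agreement from the table's row/column marginals.
#' A metric whose denominator is zero is reported as `NA`, never silently as
#' 0 or 1.
#'
#' @param table A `contingency_table` (from [score_events()] or
#'   [contingency_table()]).
#' @return A list of class `apnea_metrics` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `kappa`, plus the input counts.
#' @examples
#' compute_metrics(contingency_table(tp = 485, fp = 1, fn = 14, tn = 2487))
#' @export
compute_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- tp + fp + fn + tn
  if (n == 0) {
    abort("All-zero contingency table: metrics undefined.",
          class = "apneasound_undefined_metrics")
  }
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  structure(
    list(
      sensitivity = frac(tp, tp + fn),
      specificity = frac(tn, tn + fp),
      ppv = frac(tp, tp + fp),
      npv = frac(tn, tn + fn),
      accuracy = p_o,
      kappa = kappa,
      tp = tp, fp = fp, fn = fn, tn = tn
    ),
    class = "apnea_metrics"
  )
}

#' @export
print.apnea_metrics <- function(x, ...) {
  cat("<apnea_metrics>\n")
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity), fmt_pct(x$ppv)))
  cat(sprintf("  NPV %s  accuracy %s  kappa %s\n",
              fmt_pct(x$npv), fmt_pct(x$accuracy),
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa))))
  cat(sprintf("  (TP %d, FP %d, FN %d, TN %d)\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

fmt_pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", 100 * v))

#' Tidy an apnea-metrics object into one row per metric
#'
#' @param x An `apnea_metrics` object.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @export
tidy.apnea_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy", "kappa"),
    value = c(x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy, x$kappa)
  )
}

#' One-row summary of an apnea-metrics object
#'
#' @param x An `apnea_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the counts and all six metrics.
#' @export
glance.apnea_metrics <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv, accuracy = x$accuracy, kappa = x$kappa
  )
}
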