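#' Detect apnea events from a breath timeline
#'
#' An apnea is an absence of inspiration or expiration for more than
#' `min_gap` seconds (strictly: a gap of exactly `min_gap` is not an event).
#' Gaps are measured between consecutive breath events and against the record
#' boundaries, so a record that starts or ends inside a breath-hold is
#' flagged; scorers that want to exclude boundary events can filter on
#' `onset_s`/`offset_s`.
#'
#' @param breaths A data frame of breath events with columns `onset_s` and
#'   `offset_s` (e.g. from [detect_breaths()]); must be sorted, disjoint and
#'   within the record.
#' @param record_start,record_end Record extent in seconds.
#' @param min_gap Minimum breath-absence duration in seconds; gaps must
#'   strictly exceed it. Default 15.
#' @return A tibble with columns `onset_s`, `offset_s`, `label` (`"apnea"`);
#'   each row spans from the end of the last breath before the gap (or record
#'   start) to the start of the next breath (or record end).
#' @examples
#' breaths <- tibble::tibble(onset_s = c(5, 44), offset_s = c(20, 45))
#' detect_apneas(breaths, 0, 60) # the 24 s gap [20, 44] is an apnea
#' @export
detect_apneas <- function(breaths, record_start, record_end, min_gap = 15) {
  if (record_end <= record_start) {
    abort("`record_end` must exceed `record_start`.", class = "apneasound_invalid_range")
  }
  stopifnot(is.data.frame(breaths))
  if (nrow(breaths) > 0) {
    if (is.unsorted(breaths$onset_s) ||
        any(breaths$onset_s[-1] < breaths$offset_s[-nrow(breaths)])) {
      abort("`breaths` must be sorted and disjoint.", class = "apneasound_invalid_input")
    }
    if (min(breaths$onset_s) < record_start || max(breaths$offset_s) > record_end) {
      abort("Breath events fall outside the record.", class = "apneasound_invalid_input")
    }
  }
  gap_start <- c(record_start, breaths$offset_s)
  gap_end <- c(breaths$onset_s, record_end)
  keep <- (gap_end - gap_start) > min_gap
  tibble::tibble(onset_s = gap_start[keep], offset_s = gap_end[keep], label = "apnea")
}
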