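#' Read and write event tables
#'
#' Event tables are plain CSV with columns `onset_s`, `offset_s`, `label`;
#' timestamps are seconds from record start and intervals are half-open
#' `[onset, offset)`. Reading validates the invariant `onset_s < offset_s`
#' and round-trips losslessly with [write_events()].
#'
#' @param path CSV file path.
#' @return A tibble with columns `onset_s`, `offset_s`, `label`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Event table not found: %s", path), class = "apneasound_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("onset_s", "offset_s")
  if (!all(required %in% names(df))) {
    abort("Event table needs columns onset_s and offset_s.",
          class = "apneasound_format_error")
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- tibble::as_tibble(df[, c("onset_s", "offset_s", "label")])
  if (any(df$onset_s >= df$offset_s)) {
    abort("Every event must satisfy onset_s < offset_s.",
          class = "apneasound_invalid_input")
  }
  dplyr::arrange(df, .data$onset_s)
}

#' @rdname read_events
#' @param events A data frame with columns `onset_s`, `offset_s` and
#'   optionally `label`.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
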