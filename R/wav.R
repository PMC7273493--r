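#' Read a WAV file into an audio signal
#'
#' Minimal RIFF/WAVE reader covering the encodings used for tracheal-sound
#' recordings: 16-bit integer PCM, 32-bit integer PCM, and 32-bit IEEE float,
#' mono or multi-channel. Integer samples are normalized to full scale
#' \eqn{[-1, 1]} on read, so downstream variance-based features are
#' encoding-independent. The sampling rate is taken from the file header.
#'
#' @param path Path to a `.wav` file.
#' @param channel For multi-channel files, which channel (1-based) to extract.
#'   Must be given explicitly for files with more than one channel; a silent
#'   default would invite primary/reference swaps.
#'
#' @return An [audio_signal()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, channel = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("WAV file not found: %s", path), class = "apneasound_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little") # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("Not a RIFF/WAVE file: %s", path), class = "apneasound_format_error")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size) # skip LIST/fact/other chunks
    }
    if (size %% 2 == 1) readBin(con, "raw", 1) # chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("Missing fmt/data chunk in %s", path), class = "apneasound_format_error")
  }

  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; the subformat is not parsed, but PCM
  # extensible files still decode by bit depth.
  if (!fmt$audio_format %in% c(1L, 3L, 65534L)) {
    abort(sprintf("Unsupported WAV encoding (format tag %d).", fmt$audio_format),
          class = "apneasound_format_error")
  }

  samples <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "32" = if (fmt$audio_format == 3L) {
      readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) / 4, 4, endian = "little") / 2147483648
    },
    abort(sprintf("Unsupported bit depth: %d.", fmt$bits), class = "apneasound_format_error")
  )

  nc <- fmt$n_channels
  if (nc > 1) {
    if (is.null(channel)) {
      abort(sprintf("File has %d channels; pass `channel` explicitly.", nc),
            class = "apneasound_invalid_input")
    }
    if (channel < 1 || channel > nc) {
      abort(sprintf("`channel` must be in 1..%d.", nc), class = "apneasound_invalid_input")
    }
    samples <- samples[seq(channel, length(samples), by = nc)]
  }
  audio_signal(samples, fmt$sample_rate)
}

#' Write an audio signal to a WAV file
#'
#' Writes mono WAV, either 16-bit integer PCM (default; values clipped to
#' \eqn{[-1, 1]} and quantized) or 32-bit IEEE float (lossless for doubles
#' within float precision).
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
  stopifnot(is_audio_signal(signal))
  if (!bit_depth %in% c(16, 32)) {
    abort("`bit_depth` must be 16 or 32.", class = "apneasound_invalid_input")
  }
  n <- length(signal$samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fmt_tag <- if (bit_depth == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little") # mono
  writeBin(as.integer(signal$rate), con, 4, endian = "little")
  writeBin(as.integer(signal$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16) {
    # same 1/32768 full-scale step as the reader, clamped at the int16 limits
    q <- as.integer(pmax(-32768, pmin(32767, round(signal$samples * 32768))))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(signal$samples, con, 4, endian = "little")
  }
  invisible(path)
}
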