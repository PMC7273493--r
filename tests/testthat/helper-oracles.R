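# Independent reference implementations and fixture builders used across the
# suite. These stay deliberately naive: straight per-sample loops and direct
# arithmetic, so they can serve as oracles for the package's optimized paths.

# Per-sample NLMS recursion, pure R. Mirrors the defining equations directly:
# y(n) = w'x(n); e(n) = d(n) - y(n); w <- w + mu/(x'x + psi) e(n) x(n),
# with the tap vector holding the most recent `order` reference samples
# (zero-padded at the start).
nlms_oracle <- function(d, x, mu = 0.08, psi = 0.02, order = 64) {
  n <- length(d)
  w <- numeric(order)
  xp <- c(numeric(order), x)
  e <- numeric(n)
  for (i in seq_len(n)) {
    taps <- xp[(order + i):(i + 1)] # x(i), x(i-1), ..., x(i-order+1)
    y <- sum(w * taps)
    e[i] <- d[i] - y
    w <- w + mu / (sum(taps^2) + psi) * e[i] * taps
  }
  e
}

# population (1/N) variance, restated independently of the package internals
pvar <- function(x) mean((x - mean(x))^2)

# A short band-limited breath-like burst plus a noise channel, used as the
# standard small mixture fixture.
make_mixture_fixture <- function(seed, dur = 2, fs = 22050) {
  set.seed(seed)
  n <- dur * fs
  t <- seq_len(n) / fs
  burst <- sin(2 * pi * 400 * t) * exp(-((t - dur / 2) / (dur / 4))^2)
  noise <- rnorm(n)
  h <- rnorm(64)
  h <- h / sqrt(sum(h^2))
  coupled <- as.numeric(stats::filter(noise, h, method = "convolution", sides = 1))
  coupled[is.na(coupled)] <- 0
  list(
    clean = audio_signal(burst * 0.2, fs),
    noise = audio_signal(noise, fs),
    coupled = coupled,
    fs = fs
  )
}

# Synthetic log-variance series with a given hop, for detector unit tests.
make_logvar_series <- function(values, hop = 0.005) {
  s <- tibble::tibble(time = (seq_along(values) - 1) * hop, logvar = values)
  structure(s, class = c("logvar_series", class(s)), hop_s = hop, window_s = 0.02)
}

# Interleaved 16-bit stereo WAV writer (the package itself only writes mono).
write_stereo_wav <- function(left, right, rate, path) {
  n <- length(left)
  inter <- as.vector(rbind(
    as.integer(round(pmax(-1, pmin(1, left)) * 32767)),
    as.integer(round(pmax(-1, pmin(1, right)) * 32767))
  ))
  data_size <- n * 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 4), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  invisible(path)
}
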