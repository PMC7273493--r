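fs <- 22050

test_that("band-pass passes mid-band tones and rejects out-of-band tones", {
  t <- seq_len(fs) / fs
  cfg <- detector_config()
  mid <- audio_signal(sin(2 * pi * 400 * t), fs)
  low <- audio_signal(sin(2 * pi * 100 * t), fs)
  core <- 2000:20000 # avoid edge transients when comparing RMS
  gain_db <- function(inp, out) 20 * log10(sd(out$samples[core]) / sd(inp$samples[core]))
  expect_lt(abs(gain_db(mid, bandpass(mid, cfg))), 1)
  expect_lt(gain_db(low, bandpass(low, cfg)), -20)
})

test_that("band-pass preserves length, maps silence to silence, checks the rate", {
  z <- audio_signal(numeric(5000), fs)
  out <- bandpass(z)
  expect_length(out$samples, 5000)
  expect_true(all(out$samples == 0))
  expect_error(bandpass(audio_signal(rnorm(1000), 1500)),
               class = "apneasound_invalid_rate")
})

test_that("log-variance window geometry and values match direct enumeration", {
  cfg <- detector_config()
  # 20 ms at 22050 Hz -> 441-sample windows, 110-sample hop; a 1 s signal
  # yields floor((22050 - 441)/110) + 1 = 197 windows
  s <- log_variance(audio_signal(rnorm(fs), fs), cfg)
  expect_equal(nrow(s), 197)
  expect_equal(attr(s, "hop_s"), 110 / fs)
  expect_equal(diff(s$time)[1], 110 / fs)

  # constant signal: zero variance everywhere, clamped at the floor
  const <- log_variance(audio_signal(rep(0.3, fs), fs), cfg)
  expect_true(all(const$logvar == log(cfg$variance_floor)))

  # unit-variance white noise: mean log window-variance near log(1) = 0
  set.seed(5)
  wn <- log_variance(audio_signal(rnorm(5 * fs), fs), cfg)
  expect_lt(abs(mean(wn$logvar)), 0.05)

  expect_error(log_variance(audio_signal(rnorm(100), fs), cfg),
               class = "apneasound_empty_series")
})

test_that("threshold lands between the modes of a bimodal record", {
  set.seed(42)
  v <- c(rnorm(500, -8, 0.2), rnorm(500, -2, 0.2))
  th <- logvar_threshold(make_logvar_series(v))
  expect_gt(th, -7)
  expect_lt(th, -3)
})

test_that("degenerate records detect nothing", {
  flat <- make_logvar_series(rep(-9, 200))
  th <- logvar_threshold(flat)
  expect_true(all(flat$logvar < th))
  expect_equal(nrow(detect_breaths(flat, th)), 0)
  # near-unimodal (centers closer than the separation limit) also detects nothing
  set.seed(7)
  tight <- make_logvar_series(rnorm(400, -5, 0.1))
  expect_true(all(tight$logvar < logvar_threshold(tight)))
})

test_that("sliding threshold tracks a drifting noise floor", {
  hop <- 0.005
  set.seed(30)
  # first half: quiet floor at -10 with bursts at -2; second half: raised
  # floor at -4 with bursts at +4 — a single global threshold cannot serve both
  n_half <- 6000
  v <- c(rnorm(n_half, -10, 0.2), rnorm(n_half, -4, 0.2))
  burst_at <- seq(200, 2 * n_half - 200, by = 800)
  for (b in burst_at) v[b:(b + 200)] <- v[b:(b + 200)] + 8
  s <- make_logvar_series(v, hop)
  th <- logvar_threshold(s, sliding_window = 10)
  expect_length(th, nrow(s))
  # per-chunk thresholds sit between floor and bursts in both halves
  expect_true(all(th[1:n_half] > -9 & th[1:n_half] < -3))
  expect_true(all(th[(n_half + 1):(2 * n_half)] > -3.5 & th[(n_half + 1):(2 * n_half)] < 3))
  ev <- detect_breaths(s, th)
  expect_equal(nrow(ev), length(burst_at))
  expect_error(detect_breaths(s, c(-6, -6)), class = "apneasound_invalid_input")
})

test_that("breath runs obey the minimum-duration and merge rules", {
  hop <- 0.005
  base <- rep(-10, 2000)

  # 0.3 s burst (61 windows spanning 0.3 s): below the 0.5 s minimum
  v <- base
  v[100:160] <- -2
  expect_equal(nrow(detect_breaths(make_logvar_series(v, hop), -6)), 0)

  # ten 1 s bursts spaced 4 s apart -> exactly ten events
  v2 <- rep(-10, 10 * 4 / hop)
  for (k in 0:9) {
    i0 <- k * 800 + 1
    v2[i0:(i0 + 200)] <- -2
  }
  ev <- detect_breaths(make_logvar_series(v2, hop), -6)
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$offset_s - ev$onset_s >= 0.5))

  # all below threshold -> empty
  expect_equal(nrow(detect_breaths(make_logvar_series(base, hop), -6)), 0)

  # a 0.1 s dropout inside a long run is bridged; a 0.3 s one is not
  v3 <- rep(-10, 2000)
  v3[100:300] <- -2; v3[321:500] <- -2       # 0.1 s gap -> one event
  expect_equal(nrow(detect_breaths(make_logvar_series(v3, hop), -6)), 1)
  v4 <- rep(-10, 2000)
  v4[100:300] <- -2; v4[361:500] <- -2       # 0.3 s gap -> two events
  expect_equal(nrow(detect_breaths(make_logvar_series(v4, hop), -6)), 2)
})

test_that("detected events are disjoint, sorted, and shrink as the threshold rises", {
  set.seed(9)
  v <- rnorm(4000, -6, 2)
  s <- make_logvar_series(v)
  prev_total <- Inf
  for (th in c(-8, -6, -4, -2)) {
    ev <- detect_breaths(s, th)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$onset_s) > 0))
      expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
    }
    total <- sum(ev$offset_s - ev$onset_s)
    expect_lte(total, prev_total)
    prev_total <- total
  }
})
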