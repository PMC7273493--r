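test_that("zero reference leaves the primary untouched (identity case)", {
  fs <- 22050
  set.seed(11)
  primary <- audio_signal(rnorm(fs), fs)
  silence <- audio_signal(numeric(fs), fs)
  out <- nlms_cancel(primary, silence, nlms_config())
  expect_identical(out$samples, primary$samples)
  expect_equal(out$rate, fs)
})

test_that("single-tap constant inputs follow the closed-form geometric recursion", {
  # order = 1, reference constant c, primary a*c: the weight obeys
  # w[n+1] = w[n] + mu c^2/(c^2+psi) (a - w[n]), a scalar geometric recursion
  # converging to a, so e[n] = (a - w[n]) c shrinks geometrically.
  a <- 0.7
  cc <- 1.3
  mu <- 0.08
  psi <- 0.02
  n <- 200
  w <- 0
  expected_e <- numeric(n)
  for (i in seq_len(n)) {
    expected_e[i] <- (a - w) * cc
    w <- w + mu * cc^2 / (cc^2 + psi) * (a - w)
  }
  out <- nlms_cancel(
    audio_signal(rep(a * cc, n), 1000),
    audio_signal(rep(cc, n), 1000),
    nlms_config(mu = mu, psi = psi, order = 1)
  )
  expect_equal(out$samples, expected_e, tolerance = 1e-12)
  # geometric convergence: the tail error is essentially gone
  expect_lt(abs(out$samples[n]), 1e-6)
})

test_that("compiled recursion matches the per-sample oracle to 1e-9 relative", {
  fs <- 22050
  fix <- make_mixture_fixture(seed = 21, dur = 1)
  primary <- audio_signal(fix$clean$samples + 0.8 * fix$coupled, fs)
  out <- nlms_cancel(primary, fix$noise, nlms_config())
  oracle <- nlms_oracle(primary$samples, fix$noise$samples,
                        mu = 0.08, psi = 0.02, order = 64)
  rel <- max(abs(out$samples - oracle)) / max(abs(oracle))
  expect_lt(rel, 1e-9)
  expect_length(out$samples, length(primary$samples))
})

test_that("update stays finite when the tap buffer is all zero", {
  fs <- 1000
  ref <- audio_signal(c(numeric(500), rnorm(500)), fs)
  pri <- audio_signal(rnorm(1000), fs)
  out <- nlms_cancel(pri, ref)
  expect_true(all(is.finite(out$samples)))
  # while the reference is silent the output equals the primary
  expect_identical(out$samples[1:500], pri$samples[1:500])
})

test_that("misaligned or non-finite inputs are rejected", {
  a <- audio_signal(rnorm(100), 1000)
  expect_error(nlms_cancel(a, audio_signal(rnorm(99), 1000)),
               class = "apneasound_invalid_input")
  expect_error(nlms_cancel(a, audio_signal(rnorm(100), 2000)),
               class = "apneasound_invalid_input")
  expect_error(audio_signal(c(1, NA), 1000), class = "apneasound_invalid_input")
  expect_error(audio_signal(c(1, Inf), 1000), class = "apneasound_invalid_input")
  expect_error(nlms_config(mu = 0), class = "apneasound_invalid_input")
  expect_error(nlms_config(psi = -1), class = "apneasound_invalid_input")
  expect_error(nlms_config(order = 0), class = "apneasound_invalid_input")
})

test_that("cancelling FIR-coupled noise improves SNR on random mixtures", {
  # primary = clean + unknown 64-tap FIR of the reference; the default-preset
  # filter should recover a positive SNR improvement on nearly every draw
  improvements <- vapply(1:10, function(seed) {
    fix <- make_mixture_fixture(seed, dur = 2)
    primary <- audio_signal(fix$clean$samples + fix$coupled, fix$fs)
    filtered <- nlms_cancel(primary, fix$noise, nlms_config())
    snr_after(fix$clean, filtered) - snr_before(fix$clean, primary)
  }, numeric(1))
  expect_gte(sum(improvements > 0), 9)
})
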