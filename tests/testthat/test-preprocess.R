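# Signal conditioning: alias folding, FIR design and application, decimation,
# normalization and the sensor quality check.

test_that("alias_frequency folds mains components as observed at 51.2 Hz", {
  expect_equal(alias_frequency(50.032, 51.2), 1.168, tolerance = 1e-9)
  expect_equal(alias_frequency(100.064, 51.2), 2.336, tolerance = 1e-9)
  expect_equal(alias_frequency(10, 51.2), 10)
  expect_error(alias_frequency(10, -1), "positive")
  expect_error(alias_frequency(-5, 51.2), "non-negative")
})

test_that("alias_frequency output is in [0, fs/2] and fs-periodic in f", {
  set.seed(7)
  f <- runif(200, 0, 500)
  fs <- runif(200, 1, 200)
  a <- alias_frequency(f, 51.2)
  expect_true(all(a >= 0 & a <= 25.6 + 1e-12))
  for (k in c(1, 3, 10))
    expect_equal(alias_frequency(f + k * 51.2, 51.2), a, tolerance = 1e-9)
  expect_true(all(mapply(alias_frequency, f, fs) <= fs / 2 + 1e-12))
})

test_that("default low-pass design passes DC exactly and crushes 50 Hz mains", {
  b <- design_lowpass(512)
  expect_equal(sum(b), 1, tolerance = 1e-12)
  expect_lt(fir_response(b, 50, 512), 0.01)
  expect_lt(20 * log10(fir_response(b, 50, 512)), -40)
  expect_gt(fir_response(b, 1, 512), 0.999)
  expect_error(design_lowpass(512, cutoff = 300), "Nyquist")
  expect_error(design_lowpass(512, n_taps = 256), "odd")
})

test_that("apply_fir is delay-compensated, passes DC and removes mains", {
  fs <- 512
  b <- design_lowpass(fs)
  n <- 4096
  t <- (0:(n - 1)) / fs
  # constant passthrough in the interior
  y <- apply_fir(rep(3, n), b)
  interior <- (attr(y, "edge_samples") + 1):(n - attr(y, "edge_samples"))
  expect_lt(max(abs(y[interior] - 3)), 1e-6)
  # 50.032 Hz tone suppressed
  y2 <- apply_fir(sin(2 * pi * 50.032 * t), b)
  expect_lt(sqrt(2 * mean(y2[interior]^2)), 0.01)
  # 1 Hz component of a mixed tone recovered with amplitude error <= 2%
  x <- sin(2 * pi * 1 * t) + 0.8 * sin(2 * pi * 50 * t)
  y3 <- apply_fir(x, b)[interior]
  amp <- 2 * abs(sum(y3 * exp(-2i * pi * 1 * t[interior]))) / length(y3)
  expect_lt(abs(amp - 1), 0.02)
  # alignment: filtered 1 Hz tone in phase with the input
  expect_gt(stats::cor(y3, sin(2 * pi * t[interior])), 0.999)
  expect_error(apply_fir(1:10, b), "longer")
})

test_that("decimation keeps index-0 phase and composes multiplicatively", {
  expect_identical(decimate_signal(c(0, 1, 2, 3, 4, 5), 2), c(0, 2, 4))
  x <- rnorm(1000)
  expect_identical(decimate_signal(x, 1), x)
  expect_equal(length(decimate_signal(x, 7)), ceiling(1000 / 7))
  expect_identical(decimate_signal(x, 6), decimate_signal(decimate_signal(x, 2), 3))
  expect_error(decimate_signal(x, 0), "positive")
})

test_that("filter + decimate preserves an in-band tone (amplitude and frequency)", {
  fs <- 512
  n <- fs * 8
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 50.032 * t)
  y <- decimate_signal(as.numeric(apply_fir(x, design_lowpass(fs))), 10)
  p <- psd_estimate(y[52:(51 + 256)], 51.2)
  expect_equal(p$frequencies[which.max(p$power)], 5)
  td <- t[seq(1, n, by = 10)][52:(51 + 256)]
  amp <- 2 * abs(sum(y[52:(51 + 256)] * exp(-2i * pi * 5 * td))) / 256
  expect_lt(abs(amp - 1), 0.02)
})

test_that("normalization matches its definitions and guards constants", {
  expect_equal(normalize_signal(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  expect_equal(normalize_signal(c(0, 10), "zscore"), c(-1, 1) / sqrt(2),
               tolerance = 1e-6)
  expect_warning(z <- normalize_signal(c(1, 1, 1), "minmax"), "constant")
  expect_identical(z, c(0, 0, 0))
  set.seed(3)
  for (i in 1:20) {
    z <- normalize_signal(rnorm(50, sd = runif(1, 0.1, 10)), "zscore")
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
})

test_that("reference-response check detects a breath-elicited spike", {
  fs <- 51.2
  flat <- rep(5, round(20 * fs))
  expect_false(check_reference_response(flat, fs, breath_time = 5)$ok)
  spike <- make_scr_trace(fs, 20, onsets = 7, amps = 0.5)
  res <- check_reference_response(spike, fs, breath_time = 5)
  expect_true(res$ok)
  expect_lt(abs(res$latency_s - 2), 1)  # injected 2 s after the breath
  small <- make_scr_trace(fs, 20, onsets = 7, amps = 0.01)
  expect_false(check_reference_response(small, fs, breath_time = 5)$ok)
  expect_error(check_reference_response(flat, fs, breath_time = 18), "outside")
})

test_that("preprocess_recording decimates 512 Hz to 51.2 Hz and warns at-rate data", {
  fs <- 512
  n <- fs * 10
  t <- (0:(n - 1)) / fs
  gsr <- 5 + 0.5 * sin(2 * pi * 0.2 * t) + 0.1 * sin(2 * pi * 50.032 * t)
  rec <- raw_recording(gsr, rep(70, n), fs)
  out <- preprocess_recording(rec)
  expect_equal(out$fs, 51.2)
  expect_equal(length(out$gsr), n / 10)
  rec2 <- raw_recording(rep(5, 512), rep(70, 512), 51.2)
  expect_warning(out2 <- preprocess_recording(rec2), "alias")
  expect_identical(out2$gsr, rec2$gsr)
})
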