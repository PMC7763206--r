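# The 32-feature set: time-domain statistics, event features, spectral
# features and heart-rate features.

test_that("time-domain features match their definitions on hand-computed cases", {
  expect_equal(feat_mav(c(1, -1, 1, -1)), 1)
  expect_equal(feat_mav(c(2, 4, 6)), 4)
  expect_equal(feat_mav(c(0.5, 1.5, 1.0)), 1)
  expect_error(feat_mav(numeric(0)), "empty")

  expect_equal(feat_mar(c(2, 4, 6), 2), 2)
  expect_equal(feat_mar(c(3, 3), 3), 1)
  expect_error(feat_mar(c(1, 2), 0), "positive")

  expect_equal(feat_std(c(5, 5, 5)), 0)
  expect_equal(feat_std(c(0, 10)), 7.0711, tolerance = 1e-4)
  x <- rnorm(50)
  expect_equal(feat_std(x + 3), feat_std(x))
  expect_error(feat_std(1), "2 samples")

  expect_equal(feat_wl(rep(2, 10)), 0)
  expect_equal(feat_wl(c(0, 1, 0, 1)), 3)
  expect_equal(feat_wl(c(0, 2, 4)), 8)
  expect_equal(feat_wl(c(0, 2, 4), absolute = TRUE), 4)

  expect_equal(feat_ssc(c(1, 2, 3, 4)), 0)
  expect_equal(feat_ssc(c(0, 1, 0, 1)), 2)
  expect_equal(feat_ssc(c(0, 1, 1.0005, 1)), 0)  # sub-eps slopes suppressed
  expect_error(feat_ssc(c(1, 2)), "3 samples")

  expect_equal(feat_wamp(rep(1, 5)), 0)
  expect_equal(feat_wamp(c(0, 1, 0, 1)), 3)
  expect_equal(feat_wamp(c(0, 0.4, 0.8)), 0)
})

test_that("time-domain features agree with brute-force loop oracles", {
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(sample(10:80, 1), sd = runif(1, 0.05, 3))
    expect_equal(feat_mav(x), naive_mav(x), tolerance = 1e-9)
    expect_equal(feat_std(x), naive_std(x), tolerance = 1e-9)
    expect_equal(feat_wl(x), naive_wl(x), tolerance = 1e-9)
    expect_identical(feat_ssc(x), naive_ssc(x))
    expect_identical(feat_wamp(x), naive_wamp(x))
  }
})

test_that("scaling and shift behaviour of the time-domain features", {
  set.seed(2)
  x <- abs(rnorm(100))
  a <- 2.5
  expect_equal(feat_mav(a * x), a * feat_mav(x))
  expect_equal(feat_std(a * x), a * feat_std(x))
  expect_equal(feat_wl(a * x), a^2 * feat_wl(x))
  expect_identical(feat_ssc(x + 7), feat_ssc(x))
  expect_identical(feat_wamp(x + 7), feat_wamp(x))
})

test_that("event features summarize NR / AVRA / MAXRA with the zero-event convention", {
  expect_equal(event_features(data.frame(amplitude_uS = numeric(0))),
               c(nr = 0, avra = 0, maxra = 0))
  expect_equal(event_features(data.frame(amplitude_uS = c(0.2, 0.6))),
               c(nr = 2, avra = 0.4, maxra = 0.6))
  expect_equal(event_features(data.frame(amplitude_uS = 0.1)),
               c(nr = 1, avra = 0.1, maxra = 0.1))
})

test_that("PSD lands on the canonical 0-25.6 Hz grid and is Parseval-consistent", {
  fs <- 51.2
  t <- (0:255) / fs
  p <- psd_estimate(sin(2 * pi * 5 * t), fs)
  expect_length(p$frequencies, 513L)
  expect_equal(p$frequencies[c(1, 513)], c(0, 25.6))
  expect_equal(diff(p$frequencies)[1], 0.05)
  expect_equal(p$frequencies[which.max(p$power)], 5)
  expect_true(all(p$power >= 0))
  # Parseval: integrated one-sided power equals the mean square
  set.seed(8)
  x <- rnorm(256)
  p2 <- psd_estimate(x, fs)
  expect_lt(abs(sum(p2$power) * 0.05 - mean(x^2)) / mean(x^2), 0.05)
  expect_identical(max(psd_estimate(rep(0, 256), fs)$power), 0)
  expect_warning(psd_estimate(x, 40), "grid")
})

test_that("spectral median and mean follow the printed definitions", {
  flat <- structure(list(frequencies = seq(0, 25.6, by = 0.05),
                         power = rep(1, 513)), class = "psd_estimate")
  expect_equal(feat_fmd(flat), 12.8)
  expect_equal(feat_fmn(flat), 12.8)
  single <- structure(list(frequencies = seq(0, 25.6, by = 0.05),
                           power = c(rep(0, 60), 4, rep(0, 452))), class = "psd_estimate")
  expect_equal(feat_fmd(single), 3)  # all power at 3 Hz
  expect_equal(feat_fmn(single), 3)
  tiny <- structure(list(frequencies = c(0, 0.05, 0.1), power = c(1, 1, 2)),
                    class = "psd_estimate")
  expect_equal(feat_fmd(tiny), 0.1)
  two <- structure(list(frequencies = c(0, 1), power = c(1, 3)), class = "psd_estimate")
  expect_equal(feat_fmn(two), 0.75)
  zero <- structure(list(frequencies = c(0, 1), power = c(0, 0)), class = "psd_estimate")
  expect_error(feat_fmd(zero), "zero")
  expect_error(feat_fmn(zero), "zero")
  # concentration bound: all mass below f0 keeps the centroid below f0
  low <- structure(list(frequencies = seq(0, 25.6, by = 0.05),
                        power = c(runif(100), rep(0, 413))), class = "psd_estimate")
  expect_lte(feat_fmn(low), 100 * 0.05)
  expect_true(feat_fmd(low) >= 0 && feat_fmd(low) <= 25.6)
})

test_that("heart-rate time features use the window's own sample count", {
  expect_equal(hr_time_features(rep(70, 10)), c(hr_mav = 70, hr_std = 0))
  expect_equal(hr_time_features(c(60, 80)), c(hr_mav = 70, hr_std = 14.142),
               tolerance = 1e-4)
  x <- 70 + rnorm(20)
  expect_equal(hr_time_features(x + 5)[["hr_std"]], hr_time_features(x)[["hr_std"]])
  expect_error(hr_time_features(65), "2 HR")
})

test_that("LF/HF band filters separate the variability bands", {
  fs <- 51.2
  # steady-state response magnitudes of the two 3rd-order Butterworth filters
  Hmag <- function(band, f) {
    flt <- signal::butter(3, band / (fs / 2), type = "pass")
    z <- exp(2i * pi * f / fs)
    abs(sum(flt$b * z^-(seq_along(flt$b) - 1)) / sum(flt$a * z^-(seq_along(flt$a) - 1)))
  }
  expect_gt(Hmag(c(0.04, 0.15), 0.1), 0.9)   # 0.1 Hz passes the LF band
  expect_lt(Hmag(c(0.15, 0.4), 0.1), 0.2)    # and leaks little into HF
  expect_gt(Hmag(c(0.15, 0.4), 0.3), 0.9)    # 0.3 Hz passes the HF band
  expect_gt(Hmag(c(0.15, 0.4), 0.3) / Hmag(c(0.04, 0.15), 0.3), 10)
  # DC input decays to zero in both outputs
  b <- hr_band_decompose(rep(70, round(120 * fs)), fs)
  n <- length(b$h_low)
  expect_lt(max(abs(b$h_low[(n - 100):n])), 1e-3)
  expect_lt(max(abs(b$h_high[(n - 100):n])), 1e-3)
  expect_error(hr_band_decompose(rep(70, 100), 0.5), "too low")
})

test_that("band intensities and their ratio follow the printed formulas", {
  x <- sin(seq(0, 20, by = 0.1))
  expect_equal(hr_freq_features(x, x)[["hlr"]], 1)
  r <- hr_freq_features(2 * x, x)
  expect_equal(r[["hlr"]], 0.25)
  expect_equal(r[["lfi"]], mean((2 * x)^2))
  expect_error(hr_freq_features(rep(0, 10), x), "undefined")
})

test_that("the full vector has the 32 canonical features with expected degeneracies", {
  expect_length(feature_names(), 32L)
  expect_identical(anyDuplicated(feature_names()), 0L)
  fs <- 51.2
  bl <- list(xb_gsr = 5, xb_scl = 4.5, xb_scr = 0.5)
  set.seed(4)
  w <- make_window(runif(256, 4, 6), hr = 70 + rnorm(256))
  f <- extract_features(w, bl)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  # constant GSR and HR: variation features vanish, HLR guard fires
  wc <- make_window(rep(5, 256), scl = rep(4.5, 256), scr = rep(0.5, 256),
                    hr = rep(70, 256))
  fc <- suppressWarnings(extract_features(wc, bl))
  expect_true(all(fc[c("GSR_std", "GSR_wl", "GSR_ssc", "GSR_wamp",
                       "SCL_std", "SCR_std", "HR_std", "GSR_nr")] == 0))
  # window equal to the baseline statistics: all MAR features are 1
  expect_equal(unname(fc[c("GSR_mar", "SCL_mar", "SCR_mar")]), c(1, 1, 1))
})
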