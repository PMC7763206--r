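# The 32-feature set computed from one 5-s labeled window: electrodermal
# time-domain, event-related and frequency-domain features on GSR/SCL/SCR,
# plus heart-rate time- and frequency-domain features.

#' Canonical feature names
#'
#' The fixed ordering of the 32 features: six time-domain statistics (MAV,
#' MAR, STD, WL, SSC, WAMP) for each of GSR, SCL and SCR; three event-related
#' features (NR, AVRA, MAXRA) computed from detected SCRs; spectral median
#' and mean (FMD, FMN) for each electrodermal signal; and heart-rate MAV,
#' STD, LFI, HFI and HLR.
#'
#' @return Character vector of length 32.
#' @export
feature_names <- function() {
  sigs <- c("GSR", "SCL", "SCR")
  c(as.vector(t(outer(sigs, c("mav", "mar", "std", "wl", "ssc", "wamp"),
                      paste, sep = "_"))),
    "GSR_nr", "GSR_avra", "GSR_maxra",
    as.vector(t(outer(sigs, c("fmd", "fmn"), paste, sep = "_"))),
    "HR_mav", "HR_std", "HR_lfi", "HR_hfi", "HR_hlr")
}

#' Time-domain window statistics
#'
#' Elementary descriptors of a windowed signal `x` with samples
#' `x_0 ... x_(N-1)`:
#' * `feat_mav`: mean absolute value, `sum(|x_k|) / N`.
#' * `feat_mar`: mean absolute value relative to a baseline statistic `xb`
#'   (the same signal's MAV over the 60-s rest recording), `mav(x) / xb`.
#' * `feat_std`: sample standard deviation (denominator `N - 1`).
#' * `feat_wl`: waveform length, here the sum of *squared* successive
#'   differences `sum((x_k - x_(k-1))^2)`; set `absolute = TRUE` for the
#'   conventional sum of absolute differences.
#' * `feat_ssc`: slope sign changes -- interior samples where the slope
#'   changes sign and both adjacent steps are at least `eps` (default
#'   0.001 microsiemens).
#' * `feat_wamp`: Willison amplitude -- steps of at least `eps_w` (default
#'   0.5 microsiemens).
#'
#' @param x Numeric window samples.
#' @param xb Baseline statistic (positive).
#' @param eps Slope threshold for `feat_ssc`.
#' @param eps_w Step threshold for `feat_wamp`.
#' @param absolute Use `sum(|dx|)` instead of `sum(dx^2)` in `feat_wl`.
#' @return A scalar statistic (counts for `feat_ssc`/`feat_wamp`).
#' @name time_domain_features
NULL

#' @rdname time_domain_features
#' @export
feat_mav <- function(x) {
  if (length(x) == 0L) stop("empty window", call. = FALSE)
  mean(abs(x))
}

#' @rdname time_domain_features
#' @export
feat_mar <- function(x, xb) {
  if (!is.numeric(xb) || length(xb) != 1L || xb <= 0)
    stop("baseline statistic `xb` must be positive", call. = FALSE)
  feat_mav(x) / xb
}

#' @rdname time_domain_features
#' @export
feat_std <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::sd(x)
}

#' @rdname time_domain_features
#' @export
feat_wl <- function(x, absolute = FALSE) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- diff(x)
  if (absolute) sum(abs(d)) else sum(d^2)
}

#' @rdname time_domain_features
#' @export
feat_ssc <- function(x, eps = 0.001) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  d <- diff(x)
  a <- d[-length(d)]
  b <- d[-1L]
  sum(sign(a) * sign(b) < 0 & abs(a) >= eps & abs(b) >= eps)
}

#' @rdname time_domain_features
#' @export
feat_wamp <- function(x, eps_w = 0.5) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  sum(abs(diff(x)) >= eps_w)
}

#' Event-related features of a window
#'
#' Counts and summarizes the SCR events whose onset falls inside the window:
#' NR (number of responses), AVRA (average response amplitude) and MAXRA
#' (maximum response amplitude). With no events AVRA and MAXRA are 0 ("no
#' response" is treated as minimal response so feature vectors stay finite).
#'
#' @param events Data frame with column `amplitude_uS` (may be empty).
#' @return Named numeric vector `c(nr, avra, maxra)`.
#' @export
event_features <- function(events) {
  amps <- events$amplitude_uS
  nr <- length(amps)
  c(nr = nr,
    avra = if (nr > 0L) mean(amps) else 0,
    maxra = if (nr > 0L) max(amps) else 0)
}

#' Power spectral density on the canonical 0-25.6 Hz grid
#'
#' Zero-padded periodogram with a rectangular window. At the 51.2 Hz analysis
#' rate a 1024-point transform yields exactly the frequency grid 0 to 25.6 Hz
#' in 0.05 Hz steps (513 points). The scaling is Parseval-consistent: the
#' one-sided power integrated over the grid equals the window's mean square.
#' For other sampling rates the grid is recomputed to `[0, fs/2]` at the same
#' step, with a warning.
#'
#' @param x Window samples.
#' @param fs Sampling rate (Hz).
#' @return Object of class `psd_estimate`: list with `frequencies` (Hz) and
#'   `power` (non-negative).
#' @export
psd_estimate <- function(x, fs) {
  stop_if_not_scalar_pos(fs, "fs")
  n <- length(x)
  if (n == 0L) stop("empty window", call. = FALSE)
  if (abs(fs - 51.2) > 1e-9)
    warning(sprintf("fs = %g Hz: PSD grid recomputed to [0, %g] Hz at 0.05 Hz",
                    fs, fs / 2), call. = FALSE)
  nfft <- max(2L, as.integer(round(fs / 0.05)))
  if (nfft %% 2L == 1L) nfft <- nfft + 1L
  if (n > nfft) nfft <- nfft * 2^ceiling(log2(n / nfft))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- nfft %/% 2L
  p <- Mod(X[1:(half + 1L)])^2 / (fs * n)
  p[2:half] <- 2 * p[2:half]
  structure(list(frequencies = (0:half) * fs / nfft, power = p),
            class = "psd_estimate")
}

#' Spectral median and mean frequency
#'
#' `feat_fmd` returns the frequency at the split index `M` minimizing
#' `|sum(P_k, k < M) - sum(P_k, k >= M)|` (the frequency that divides the
#' spectrum into halves of equal energy). When several split points tie --
#' e.g. all power in a single bin -- the largest minimizer whose lower-half
#' mass does not exceed half the total is taken, so the median lands on the
#' occupied bin. `feat_fmn` is the power-weighted mean frequency
#' `sum(f_k P_k) / sum(P_k)`.
#'
#' @param p A [psd_estimate()].
#' @return Frequency in Hz.
#' @export
feat_fmd <- function(p) {
  stopifnot(inherits(p, "psd_estimate"))
  total <- sum(p$power)
  if (total <= 0) stop("zero total power", call. = FALSE)
  cum_below <- c(0, cumsum(p$power))[seq_along(p$power)]  # sum over k < M
  d <- abs(total - 2 * cum_below)
  minimizers <- which(d <= min(d) + 1e-12 * max(total, 1))
  ok <- minimizers[cum_below[minimizers] <= total / 2]
  m <- if (length(ok) > 0L) max(ok) else min(minimizers)
  p$frequencies[m]
}

#' @rdname feat_fmd
#' @export
feat_fmn <- function(p) {
  stopifnot(inherits(p, "psd_estimate"))
  total <- sum(p$power)
  if (total <= 0) stop("zero total power", call. = FALSE)
  sum(p$frequencies * p$power) / total
}

#' Heart-rate time-domain features
#'
#' Mean absolute value and sample standard deviation of the window's
#' heart-rate vector (normalized by the window's own sample count).
#'
#' @param h Heart-rate samples (bpm), at least 2.
#' @return Named vector `c(hr_mav, hr_std)`.
#' @export
hr_time_features <- function(h) {
  if (length(h) < 2L) stop("need at least 2 HR samples", call. = FALSE)
  c(hr_mav = mean(abs(h)), hr_std = stats::sd(h))
}

#' Decompose heart rate into LF and HF variability bands
#'
#' Two third-order band-pass Butterworth filters split the heart-rate signal
#' into its low-frequency (0.04-0.15 Hz, sympathetic + parasympathetic) and
#' high-frequency (0.15-0.4 Hz, parasympathetic/vagal) variability
#' components. Filtering is single-pass causal for real-time compatibility;
#' the window's first sample is subtracted first to shorten the step
#' transient (the band-pass removes DC in steady state anyway).
#'
#' @param h Heart-rate samples (bpm).
#' @param fs Sampling rate (Hz); must exceed 0.8 Hz so both bands resolve.
#' @param lf_band,hf_band Band edges in Hz.
#' @return List with `h_low` and `h_high`, same length as `h`.
#' @export
hr_band_decompose <- function(h, fs, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  if (fs <= 0.8) stop("fs too low to resolve the LF/HF bands", call. = FALSE)
  if (length(h) < 8L) stop("window too short for band filtering", call. = FALSE)
  lo <- signal::butter(3, lf_band / (fs / 2), type = "pass")
  hi <- signal::butter(3, hf_band / (fs / 2), type = "pass")
  x <- h - h[1L]
  list(h_low = as.numeric(signal::filter(lo, x)),
       h_high = as.numeric(signal::filter(hi, x)))
}

#' Heart-rate frequency-domain features
#'
#' Band intensities as mean squared sample values: LFI over the low band,
#' HFI over the high band, and their ratio HLR = HFI / LFI. An exactly zero
#' low-band signal leaves the ratio undefined and raises an error.
#'
#' @param h_low,h_high Band components from [hr_band_decompose()].
#' @return Named vector `c(lfi, hfi, hlr)`.
#' @export
hr_freq_features <- function(h_low, h_high) {
  lfi <- mean(h_low^2)
  hfi <- mean(h_high^2)
  if (lfi == 0) stop("zero low-frequency intensity: HLR undefined", call. = FALSE)
  c(lfi = lfi, hfi = hfi, hlr = hfi / lfi)
}

#' Per-session baseline statistics
#'
#' Mean absolute value of the GSR, SCL and SCR signals over the 60-s rest
#' recording, used as the denominators of the MAR features. Values are
#' floored at `floor_uS` because a fully relaxed baseline can yield an
#' exactly-zero phasic component while the ratio requires a positive
#' denominator.
#'
#' @param baseline A [raw_recording()] of the rest segment.
#' @param decomposition Optional precomputed [continuous_decomposition()] of
#'   the baseline GSR (computed here when omitted).
#' @param floor_uS Lower bound for each statistic (default 0.01).
#' @return List with `xb_gsr`, `xb_scl`, `xb_scr`.
#' @export
baseline_stats <- function(baseline, decomposition = NULL, floor_uS = 0.01) {
  stopifnot(inherits(baseline, "raw_recording"))
  if (is.null(decomposition))
    decomposition <- continuous_decomposition(baseline$gsr, baseline$fs)
  list(xb_gsr = max(feat_mav(baseline$gsr), floor_uS),
       xb_scl = max(feat_mav(decomposition$scl), floor_uS),
       xb_scr = max(feat_mav(decomposition$scr), floor_uS))
}

#' Extract the 32-feature vector of a labeled window
#'
#' Computes, in canonical order ([feature_names()]): the six time-domain
#' statistics for GSR, SCL and SCR; the event-related NR/AVRA/MAXRA from the
#' SCRs detected inside the window; spectral median and mean for the three
#' electrodermal signals; and the heart-rate MAV, STD, LFI, HFI, HLR. A
#' degenerate window whose low-frequency heart-rate component is exactly zero
#' gets HLR = 0 with a warning instead of an error, so constant test windows
#' remain processable.
#'
#' @param window A `labeled_window` from [extract_windows()].
#' @param baseline Baseline statistics from [baseline_stats()].
#' @param ssc_eps,wamp_eps,wl_absolute Thresholds/switch passed to the
#'   time-domain features.
#' @return Named numeric vector of length 32.
#' @export
extract_features <- function(window, baseline, ssc_eps = 0.001, wamp_eps = 0.5,
                             wl_absolute = FALSE) {
  stopifnot(inherits(window, "labeled_window"))
  fs <- window$fs
  sigs <- list(GSR = window$gsr, SCL = window$scl, SCR = window$scr)
  xb <- c(GSR = baseline$xb_gsr, SCL = baseline$xb_scl, SCR = baseline$xb_scr)
  out <- numeric(0)
  for (nm in names(sigs)) {
    x <- sigs[[nm]]
    v <- c(feat_mav(x), feat_mar(x, xb[[nm]]), feat_std(x),
           feat_wl(x, absolute = wl_absolute), feat_ssc(x, eps = ssc_eps),
           feat_wamp(x, eps_w = wamp_eps))
    names(v) <- paste(nm, c("mav", "mar", "std", "wl", "ssc", "wamp"), sep = "_")
    out <- c(out, v)
  }
  ev <- event_features(window$events_in_window)
  out <- c(out, GSR_nr = unname(ev["nr"]), GSR_avra = unname(ev["avra"]),
           GSR_maxra = unname(ev["maxra"]))
  for (nm in names(sigs)) {
    x <- sigs[[nm]]
    p <- psd_estimate(x, fs)
    if (sum(p$power) > 0) {
      v <- c(feat_fmd(p), feat_fmn(p))
    } else v <- c(0, 0)
    names(v) <- paste(nm, c("fmd", "fmn"), sep = "_")
    out <- c(out, v)
  }
  ht <- hr_time_features(window$hr)
  bands <- hr_band_decompose(window$hr, fs)
  lfi <- mean(bands$h_low^2)
  hfi <- mean(bands$h_high^2)
  if (lfi == 0) {
    warning("zero low-frequency HR intensity in window: HLR set to 0", call. = FALSE)
    hlr <- 0
  } else hlr <- hfi / lfi
  out <- c(out, HR_mav = unname(ht["hr_mav"]), HR_std = unname(ht["hr_std"]),
           HR_lfi = lfi, HR_hfi = hfi, HR_hlr = hlr)
  out[feature_names()]
}
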