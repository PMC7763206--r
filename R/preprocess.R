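# Conditioning of raw biosignals: alias accounting, FIR low-pass filtering,
# decimation, normalization and the protocol's sensor quality check.

#' Raw synchronized GSR + heart-rate recording
#'
#' Container for one session's synchronized skin-conductance and heart-rate
#' streams. Heart rate is reported by the acquisition device at the same
#' sample grid (lower-rate devices are forward-filled by [read_recording_csv()]).
#'
#' @param gsr Numeric vector of skin conductance samples (microsiemens).
#' @param hr Numeric vector of heart-rate samples (bpm), same length as `gsr`.
#' @param fs Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `raw_recording`: a list with elements `gsr`,
#'   `hr`, `fs`, `start_time`.
#' @export
raw_recording <- function(gsr, hr, fs, start_time = 0) {
  stop_if_not_scalar_pos(fs, "fs")
  gsr <- as.numeric(gsr)
  hr <- as.numeric(hr)
  if (length(hr) != length(gsr))
    stop("`gsr` and `hr` must have the same length", call. = FALSE)
  if (!all(is.finite(gsr)) || !all(is.finite(hr)))
    stop("all samples must be finite", call. = FALSE)
  if (any(gsr < 0))
    stop("`gsr` samples must be non-negative (conductance)", call. = FALSE)
  structure(list(gsr = gsr, hr = hr, fs = fs, start_time = start_time),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %g Hz (%.1f s), GSR %.2f-%.2f uS, HR %.0f-%.0f bpm\n",
              length(x$gsr), x$fs, length(x$gsr) / x$fs,
              min(x$gsr), max(x$gsr), min(x$hr), max(x$hr)))
  invisible(x)
}

#' Folded (alias) frequency after sampling
#'
#' Frequency at which a tone of frequency `f` appears when sampled at rate
#' `fs`: the fold `|f - fs * round(f / fs)|`, always inside `[0, fs/2]`.
#' A 50.032 Hz mains fundamental sampled at 51.2 Hz aliases to 1.168 Hz, and
#' its second harmonic to 2.336 Hz; this is why mains interference can appear
#' inside the electrodermal band when the acquisition rate is too low.
#'
#' @param f Frequency (Hz), scalar or vector, `>= 0`.
#' @param fs Sampling rate (Hz), positive scalar.
#'
#' @return The folded frequency (Hz), same length as `f`.
#' @examples
#' alias_frequency(50.032, 51.2)  # 1.168
#' @export
alias_frequency <- function(f, fs) {
  stop_if_not_scalar_pos(fs, "fs")
  if (any(!is.finite(f)) || any(f < 0))
    stop("`f` must be non-negative and finite", call. = FALSE)
  abs(f - fs * round(f / fs))
}

#' Design a linear-phase FIR low-pass filter
#'
#' Windowed-sinc design (Hamming or Blackman window) with an odd tap count so
#' that the group delay is an integer number of samples; the taps are scaled
#' for exactly unit gain at DC. The default (25 Hz cutoff, 257 taps at a
#' 512 Hz acquisition rate) attenuates 50 Hz mains interference by more than
#' 40 dB before decimation to 51.2 Hz.
#'
#' @param fs Sampling rate (Hz) the filter will operate at.
#' @param cutoff Cutoff frequency (Hz), strictly below `fs/2`.
#' @param n_taps Odd number of taps.
#' @param window Design window, `"hamming"` (default) or `"blackman"`.
#'
#' @return Numeric vector of filter coefficients with attributes `cutoff`,
#'   `fs` and `n_taps`.
#' @export
design_lowpass <- function(fs, cutoff = 25, n_taps = 257, window = c("hamming", "blackman")) {
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(cutoff, "cutoff")
  window <- match.arg(window)
  n_taps <- as.integer(n_taps)
  if (n_taps < 3L || n_taps %% 2L == 0L)
    stop("`n_taps` must be an odd integer >= 3", call. = FALSE)
  if (cutoff >= fs / 2)
    stop("`cutoff` must be below the Nyquist frequency fs/2", call. = FALSE)
  win <- switch(window, hamming = signal::hamming(n_taps), blackman = signal::blackman(n_taps))
  b <- signal::fir1(n_taps - 1L, cutoff / (fs / 2), type = "low", window = win)
  b <- as.numeric(b) / sum(b)  # exact unit DC gain
  structure(b, cutoff = cutoff, fs = fs, n_taps = n_taps)
}

#' Frequency response magnitude of FIR coefficients
#'
#' @param coeffs FIR coefficients from [design_lowpass()].
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz).
#' @return `|H(f)|`, same length as `f`.
#' @export
fir_response <- function(coeffs, f, fs) {
  k <- seq_along(coeffs) - 1
  vapply(f, function(fi) abs(sum(coeffs * exp(-2i * pi * fi * k / fs))), 0)
}

#' Apply a linear-phase FIR filter with group-delay compensation
#'
#' Zero-padded convolution followed by a shift of `(n_taps - 1) / 2` samples so
#' the output is aligned to the input timeline and has the same length. The
#' `(n_taps - 1) / 2` samples at each end are affected by the zero padding;
#' their count is flagged in the `edge_samples` attribute rather than
#' extrapolated.
#'
#' @param x Signal, longer than the filter.
#' @param coeffs FIR coefficients.
#' @return Filtered signal, same length as `x`, with attribute `edge_samples`.
#' @export
apply_fir <- function(x, coeffs) {
  x <- as.numeric(x)
  nb <- length(coeffs)
  if (length(x) <= nb)
    stop("signal must be longer than the filter", call. = FALSE)
  delay <- (nb - 1L) %/% 2L
  full <- stats::convolve(x, rev(as.numeric(coeffs)), type = "open")
  y <- full[(delay + 1L):(delay + length(x))]
  attr(y, "edge_samples") <- delay
  y
}

#' Decimate a signal by an integer factor
#'
#' Keeps every `factor`-th sample starting at the first (index-0 phase), so
#' the output length is `ceiling(length(x) / factor)`. The caller is
#' responsible for low-pass filtering first so that the reduced Nyquist rate
#' still covers the signal bandwidth (see [design_lowpass()]); decimating a
#' 512 Hz recording by 10 yields the 51.2 Hz rate used throughout the
#' feature stage.
#'
#' @param x Signal.
#' @param factor Positive integer decimation factor.
#' @return The decimated signal.
#' @export
decimate_signal <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  x[seq(1L, length(x), by = factor)]
}

#' Normalize a signal to standard values
#'
#' `minmax` rescales into `[0, 1]`; `zscore` centers to mean 0 and scales to
#' unit sample standard deviation (denominator `N - 1`). A constant signal
#' cannot be scaled: all zeros are returned with a warning.
#'
#' @param x Non-empty signal.
#' @param method `"minmax"` or `"zscore"`.
#' @return The normalized signal.
#' @export
normalize_signal <- function(x, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  rng <- diff(range(x))
  if (rng == 0) {
    warning("constant signal: returning zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  switch(method,
    minmax = (x - min(x)) / rng,
    zscore = (x - mean(x)) / stats::sd(x)
  )
}

#' Sensor reference-response quality check
#'
#' After the baseline recording the participant takes a deep breath; a healthy
#' electrode contact produces a skin-conductance spike within 2-3 s. This
#' check tests whether conductance rises by at least `min_rise_uS` within
#' `response_window_s` seconds of the breath.
#'
#' @param gsr Skin conductance samples (microsiemens).
#' @param fs Sampling rate (Hz).
#' @param breath_time Breath onset (seconds, relative to `start_time`).
#' @param min_rise_uS Minimum rise to accept (default 0.05 microsiemens).
#' @param response_window_s Window after the breath to search (default 3 s).
#' @param start_time Time of the first sample (seconds).
#'
#' @return A list with `ok` (logical) and `latency_s` (seconds from the breath
#'   to the first sample reaching the rise threshold; `NA` when `ok` is FALSE).
#' @export
check_reference_response <- function(gsr, fs, breath_time, min_rise_uS = 0.05,
                                     response_window_s = 3, start_time = 0) {
  stop_if_not_scalar_pos(fs, "fs")
  n <- length(gsr)
  dur <- n / fs
  rel <- breath_time - start_time
  if (rel < 0 || rel + 5 > dur)
    stop("breath window [breath_time, breath_time + 5 s] is outside the recording",
         call. = FALSE)
  i0 <- floor(rel * fs) + 1L
  i1 <- min(n, i0 + as.integer(round(response_window_s * fs)))
  seg <- gsr[i0:i1]
  rise <- seg - seg[1L]
  hit <- which(rise >= min_rise_uS)
  ok <- length(hit) > 0L
  list(ok = ok, latency_s = if (ok) (hit[1L] - 1L) / fs else NA_real_)
}

#' Condition a raw recording to the 51.2 Hz analysis rate
#'
#' FIR low-pass filters the skin-conductance stream and decimates both streams
#' to `fs_target`. Heart rate arrives pre-filtered from the acquisition
#' device, so it is only decimated. A recording already at `fs_target` is
#' passed through unchanged with a warning, because mains interference that
#' was sampled below twice its frequency has already folded into the
#' electrodermal band (e.g. 50.032 Hz at 51.2 Hz appears at 1.168 Hz) and
#' cannot be removed by filtering.
#'
#' @param rec A [raw_recording()].
#' @param fs_target Analysis rate (Hz), default 51.2.
#' @param cutoff,n_taps,window Low-pass design, see [design_lowpass()].
#' @return A [raw_recording()] at `fs_target`.
#' @export
preprocess_recording <- function(rec, fs_target = 51.2, cutoff = 25,
                                 n_taps = 257, window = "hamming") {
  stopifnot(inherits(rec, "raw_recording"))
  if (abs(rec$fs - fs_target) < 1e-9) {
    warning(sprintf(paste0("recording already at %g Hz: filtering/decimation skipped; ",
                           "mains aliases (e.g. %.3f Hz) may be present"),
                    fs_target, alias_frequency(50.032, fs_target)), call. = FALSE)
    return(rec)
  }
  factor <- rec$fs / fs_target
  if (abs(factor - round(factor)) > 1e-6)
    stop("`fs / fs_target` must be an integer decimation factor", call. = FALSE)
  factor <- as.integer(round(factor))
  b <- design_lowpass(rec$fs, cutoff = cutoff, n_taps = n_taps, window = window)
  gsr <- decimate_signal(pmax(0, as.numeric(apply_fir(rec$gsr, b))), factor)
  hr <- decimate_signal(rec$hr, factor)
  raw_recording(gsr, hr, fs_target, rec$start_time)
}
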