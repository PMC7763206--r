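# Seeded generator of synthetic VR-exposure sessions with ground truth.
# Emulates the physiological ranges of electrodermal and cardiac activity --
# tonic levels of 2-20 uS with slow drift, Bateman-shaped SCRs, non-specific
# SCR rates rising from a resting 1-3/min to over 20/min under high arousal,
# mains interference that aliases when sampled at 51.2 Hz, and heart rate
# with LF/HF variability whose HF component shrinks as anxiety grows (vagal
# withdrawal). Every draw flows from one seeded generator, so cohorts are
# fully reproducible.

#' Synthetic session configuration
#'
#' Defaults mirror the study conditions: seven subjects, fifteen rated events
#' per session, skin conductance sampled at 51.2 Hz with a 50.032 Hz mains
#' fundamental (which aliases to 1.168 Hz at that rate), tonic level around
#' 6 uS inside the physiological 2-20 uS range, SCR amplitudes of 0.1-3 uS,
#' non-specific SCR rates of 2/min at rest to 20/min under high arousal, and
#' a resting heart rate of 65 bpm with LF (0.1 Hz) and HF (0.25 Hz)
#' variability.
#'
#' @param duration Session length (s).
#' @param fs Sampling rate (Hz).
#' @param n_events Rated stimulus events per session.
#' @param n_subjects Cohort size.
#' @param scl_base Mean tonic level (uS), inside `[2, 20]`.
#' @param scl_drift_sd Tonic random-walk innovation (uS per sqrt-second).
#' @param scl_anx_gain Tonic rise per anxiety unit (uS).
#' @param scr_amp_range SCR amplitude range (uS).
#' @param nsscr_rate_rest,nsscr_rate_arousal Non-specific SCR rates (per
#'   minute) at anxiety 0 and 10.
#' @param tau_rise,tau_decay Bateman kernel time constants (s).
#' @param mains_freq Mains fundamental (Hz).
#' @param mains_harmonics Number of harmonics.
#' @param mains_amp Mains amplitude (uS); 0 disables interference.
#' @param hr_base Resting heart rate (bpm).
#' @param hr_anx_gain Heart-rate rise per anxiety unit (bpm).
#' @param lf_freq,hf_freq LF/HF variability frequencies (Hz), inside the
#'   0.04-0.15 and 0.15-0.4 bands.
#' @param lf_amp,hf_amp Variability amplitudes (bpm).
#' @param hr_noise_sd Heart-rate measurement noise (bpm).
#' @param sud_noise If `TRUE` (default), ratings get uniform(-0.5, 0.5)
#'   reporting noise before rounding.
#' @param seed Integer seed.
#' @return A list of class `session_config`.
#' @export
session_config <- function(duration = 360, fs = 51.2, n_events = 15,
                           n_subjects = 7, scl_base = 6, scl_drift_sd = 0.05,
                           scl_anx_gain = 0.15, scr_amp_range = c(0.1, 3),
                           nsscr_rate_rest = 2, nsscr_rate_arousal = 20,
                           tau_rise = 1, tau_decay = 3.75,
                           mains_freq = 50.032, mains_harmonics = 2,
                           mains_amp = 0.05, hr_base = 65, hr_anx_gain = 3,
                           lf_freq = 0.1, hf_freq = 0.25, lf_amp = 2,
                           hf_amp = 3, hr_noise_sd = 0.5, sud_noise = TRUE,
                           seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$scl_base < 2 || cfg$scl_base > 20)
    stop("`scl_base` must lie in the physiological range [2, 20] uS", call. = FALSE)
  if (cfg$n_events < 1 || cfg$n_subjects < 1)
    stop("need at least one event and one subject", call. = FALSE)
  structure(cfg, class = "session_config")
}

#' Mains interference signal
#'
#' Sum of sinusoids at the fundamental and its harmonics with `1/k` amplitude
#' decay and seeded random phases. Sampled at 51.2 Hz, a 50.032 Hz
#' fundamental folds to 1.168 Hz -- the disturbance that motivates acquiring
#' at a higher rate and low-pass filtering before decimation.
#'
#' @param fs Sampling rate (Hz).
#' @param duration Length (s).
#' @param fundamental Mains frequency (Hz).
#' @param n_harmonics Number of harmonics (1 = fundamental only).
#' @param amplitude Fundamental amplitude (uS).
#' @param seed Optional seed for the phases.
#' @return Numeric samples of length `round(duration * fs)`.
#' @export
gen_mains_noise <- function(fs, duration, fundamental = 50.032, n_harmonics = 2,
                            amplitude = 0.05, seed = NULL) {
  n <- as.integer(round(duration * fs))
  if (amplitude == 0) return(rep(0, n))
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    phases <- stats::runif(n_harmonics, 0, 2 * pi)
    out <- rep(0, n)
    for (k in seq_len(n_harmonics))
      out <- out + (amplitude / k) * sin(2 * pi * k * fundamental * t + phases[k])
    out
  })
}

# Anxiety trajectory as a per-sample vector from either a function of time,
# a vector, or a constant.
anx_at_samples <- function(anxiety, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  a <- if (is.function(anxiety)) anxiety(t)
       else if (length(anxiety) == 1L) rep(anxiety, n)
       else if (length(anxiety) == n) as.numeric(anxiety)
       else stats::approx(seq(0, (n - 1L) / fs, length.out = length(anxiety)),
                          anxiety, xout = t, rule = 2)$y
  pmin(10, pmax(0, a))
}

#' Generate a synthetic electrodermal trace
#'
#' Tonic drift (a slow random walk around `scl_base`, clipped to the 2-20 uS
#' physiological range, plus a rise with anxiety) superimposed with
#' Bateman-shaped SCRs drawn from an inhomogeneous Poisson process whose rate
#' interpolates from the resting to the high-arousal non-specific SCR rate
#' with anxiety. SCR amplitudes also scale with anxiety inside
#' `scr_amp_range`. Thinning uses a shared uniform stream, so raising the
#' anxiety trajectory under the same seed can only add response events, never
#' remove them.
#'
#' @param config A [session_config()].
#' @param anxiety Anxiety trajectory in `[0, 10]`: constant, vector or
#'   function of time (s).
#' @param seed Seed (defaults to `config$seed`).
#' @param duration Override of `config$duration` (s).
#' @return List with `gsr` (samples) and `scr_schedule` (data frame
#'   `onset_s`, `amplitude_uS`).
#' @export
gen_eda <- function(config, anxiety = 0, seed = config$seed,
                    duration = config$duration) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$fs
  n <- as.integer(round(duration * fs))
  anx <- anx_at_samples(anxiety, n, fs)
  with_seed(seed, {
    drift <- cumsum(stats::rnorm(n, 0, config$scl_drift_sd / sqrt(fs)))
    tonic <- config$scl_base + config$scl_anx_gain * anx + drift
    tonic <- pmin(20, pmax(2, tonic))
    # inhomogeneous Poisson SCR schedule by thinning
    rate_s <- (config$nsscr_rate_rest +
                 (config$nsscr_rate_arousal - config$nsscr_rate_rest) * anx / 10) / 60
    rate_max <- max((config$nsscr_rate_arousal / 60), max(rate_s), 1e-9)
    onsets <- numeric(0)
    amps <- numeric(0)
    if (max(rate_s) > 0) {
      t_cand <- 0
      repeat {
        t_cand <- t_cand + stats::rexp(1, rate_max)
        if (t_cand >= duration) break
        u <- stats::runif(1)
        a_u <- stats::runif(1)  # drawn unconditionally: same stream regardless of thinning
        i <- min(n, floor(t_cand * fs) + 1L)
        if (u < rate_s[i] / rate_max) {
          onsets <- c(onsets, t_cand)
          lo <- config$scr_amp_range[1]
          hi <- config$scr_amp_range[2]
          amps <- c(amps, lo + (hi - lo) * a_u * (0.2 + 0.8 * anx[i] / 10))
        }
      }
    }
    gsr <- tonic
    if (length(onsets) > 0) {
      k <- bateman_kernel(fs, config$tau_rise, config$tau_decay)
      for (e in seq_along(onsets)) {
        i0 <- as.integer(floor(onsets[e] * fs)) + 1L
        len <- min(length(k), n - i0 + 1L)
        if (len > 0)
          gsr[i0:(i0 + len - 1L)] <- gsr[i0:(i0 + len - 1L)] + amps[e] * k[seq_len(len)]
      }
    }
    gsr <- gsr + gen_mains_noise(fs, duration, config$mains_freq,
                                 config$mains_harmonics, config$mains_amp)
    list(gsr = pmax(0, gsr),
         scr_schedule = data.frame(onset_s = onsets, amplitude_uS = amps))
  })
}

#' Generate a synthetic heart-rate trace
#'
#' `hr(t) = hr_base + hr_anx_gain * anxiety(t) + LF sinusoid + HF sinusoid +
#' noise`, where the HF (vagal) amplitude shrinks with anxiety -- the vagal
#' withdrawal that lowers heart-rate variability under threat.
#'
#' @inheritParams gen_eda
#' @return Numeric heart-rate samples (bpm).
#' @export
gen_hr <- function(config, anxiety = 0, seed = config$seed,
                   duration = config$duration) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$fs
  n <- as.integer(round(duration * fs))
  anx <- anx_at_samples(anxiety, n, fs)
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    ph <- stats::runif(2, 0, 2 * pi)
    noise <- if (config$hr_noise_sd > 0) stats::rnorm(n, 0, config$hr_noise_sd) else rep(0, n)
    config$hr_base + config$hr_anx_gain * anx +
      config$lf_amp * sin(2 * pi * config$lf_freq * t + ph[1]) +
      config$hf_amp * (1 - 0.8 * anx / 10) * sin(2 * pi * config$hf_freq * t + ph[2]) +
      noise
  })
}

#' Generate a synthetic exposure cohort with ground truth
#'
#' For each subject: a piecewise-constant latent anxiety trajectory (one
#' plateau per "floor" episode of the exposure scenario), a full-session
#' recording, a 60-s relaxed baseline recording, `n_events` rated events and
#' the generating ground truth. Ratings are the latent anxiety at the event,
#' with optional uniform(-0.5, 0.5) reporting noise, rounded to the 11-point
#' SUD scale.
#'
#' When `sud_histogram` is given (counts for levels 0-10 summing to
#' `n_subjects * n_events`), the latent trajectories are shaped so that the
#' cohort's rating marginal matches it exactly: the rating multiset is
#' shuffled across subject-events and each trajectory plateau is pinned to
#' its event's rating (reporting noise is disabled in this mode).
#'
#' @param config A [session_config()].
#' @param sud_histogram Optional 11 counts for ratings 0-10.
#' @return Object of class `synthetic_cohort`: list of `subjects` (each with
#'   `recording`, `baseline`, `events`, `truth`) plus `config`.
#' @export
gen_cohort <- function(config = session_config(), sud_histogram = NULL) {
  stopifnot(inherits(config, "session_config"))
  ns <- config$n_subjects
  ne <- config$n_events
  forced <- NULL
  if (!is.null(sud_histogram)) {
    if (length(sud_histogram) != 11L || any(sud_histogram < 0) ||
        sum(sud_histogram) != ns * ne)
      stop(sprintf("`sud_histogram` must be 11 non-negative counts summing to %d",
                   ns * ne), call. = FALSE)
    pool <- rep(0:10, times = sud_histogram)
    forced <- with_seed(config$seed,
                        matrix(sample(pool), nrow = ns, ncol = ne, byrow = TRUE))
  }
  subjects <- lapply(seq_len(ns), function(s) {
    sseed <- config$seed + 1000L * s
    # event times: margin at both ends, jittered even spacing
    ev_t <- with_seed(sseed, {
      base <- seq(30, config$duration - 10, length.out = ne)
      gap <- if (ne > 1) diff(base)[1] else config$duration - 40
      sort(base + stats::runif(ne, -0.2, 0.2) * gap)
    })
    anx_ev <- if (!is.null(forced)) {
      as.numeric(forced[s, ])
    } else {
      with_seed(sseed + 1L, {
        severity <- stats::runif(1, 0.3, 1)
        floors <- pmin(10, pmax(0, severity * c(0.5, 3, 6, 9) +
                                  stats::rnorm(4, 0, 0.5)))
        floors[1L + (floor((seq_len(ne) - 1L) / ceiling(ne / 4)))]
      })
    }
    # piecewise-constant latent trajectory: each event's plateau spans the
    # interval around it
    knots_t <- c(0, (utils::head(ev_t, -1) + utils::tail(ev_t, -1)) / 2, config$duration)
    anx_fun <- stats::stepfun(knots_t[-1L], c(anx_ev, anx_ev[ne]))
    eda <- gen_eda(config, anx_fun, seed = sseed + 2L)
    hr <- gen_hr(config, anx_fun, seed = sseed + 3L)
    rec <- raw_recording(eda$gsr, hr, config$fs)
    bl_eda <- gen_eda(config, 0, seed = sseed + 4L, duration = 60)
    bl_hr <- gen_hr(config, 0, seed = sseed + 5L, duration = 60)
    baseline <- raw_recording(bl_eda$gsr, bl_hr, config$fs)
    sud <- if (!is.null(forced)) {
      as.integer(anx_ev)
    } else {
      with_seed(sseed + 6L, {
        noise <- if (config$sud_noise) stats::runif(ne, -0.5, 0.5) else 0
        as.integer(pmin(10, pmax(0, round_half_away(anx_fun(ev_t) + noise))))
      })
    }
    list(recording = rec, baseline = baseline,
         events = data.frame(time_s = ev_t, sud = sud),
         truth = list(anx_fun = anx_fun, anx_at_events = anx_ev,
                      scr_schedule = eda$scr_schedule))
  })
  structure(list(subjects = subjects, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %d events @ %g Hz, %g s sessions\n",
              length(x$subjects), x$config$n_events, x$config$fs, x$config$duration))
  invisible(x)
}
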