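# End-to-end orchestration: cohort -> decomposition -> windows -> features ->
# split -> exhaustive search -> classification, plus a sliding-window
# streaming estimator.

#' Build the feature dataset of a cohort
#'
#' Runs the signal chain for every subject: continuous decomposition of the
#' session and baseline skin conductance, baseline statistics, event-locked
#' 5-s windows and the 32-feature extraction; then assembles the per-window
#' dataset.
#'
#' @param cohort A [gen_cohort()] result, or a list with the same shape
#'   (`subjects`, each holding `recording`, `baseline`, `events`).
#' @param window_len Window length (s).
#' @param min_amplitude SCR significance threshold (uS).
#' @param ... Further arguments to [continuous_decomposition()].
#' @return The feature dataset (see [assemble_dataset()]).
#' @export
build_feature_dataset <- function(cohort, window_len = 5, min_amplitude = 0.05, ...) {
  all_windows <- list()
  all_features <- list()
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    dec <- continuous_decomposition(sub$recording$gsr, sub$recording$fs,
                                    min_amplitude = min_amplitude, ...)
    bl_dec <- continuous_decomposition(sub$baseline$gsr, sub$baseline$fs,
                                       min_amplitude = min_amplitude, ...)
    bl <- baseline_stats(sub$baseline, decomposition = bl_dec)
    wins <- extract_windows(sub$recording, dec, sub$events,
                            window_len = window_len, subject_id = s)
    feats <- lapply(wins, extract_features, baseline = bl)
    all_windows <- c(all_windows, wins)
    all_features <- c(all_features, feats)
  }
  assemble_dataset(all_windows, all_features)
}

#' Run the full anxiety-estimation pipeline
#'
#' Either generates a synthetic cohort or takes one supplied by the caller,
#' builds the feature dataset, splits it with a distribution-matched
#' identification/validation split, runs the exhaustive subset search for
#' every model size from 1 to `max_p`, and evaluates the best (largest)
#' model's threshold classification under the 2- and 3-level schemes.
#'
#' @param config A [session_config()] (used when `cohort` is not given).
#' @param cohort Optional pre-built cohort (overrides `config`-based
#'   generation).
#' @param dataset Optional pre-built feature dataset (skips the signal
#'   stages).
#' @param max_p Largest feature-subset size to search (default 3; the full
#'   seven-feature search over choose(32, 7) subsets is a long-running mode).
#' @param seed Seed for the split (defaults to `config$seed`).
#' @param train_fraction Identification fraction (default 6/7).
#' @param pool Feature pool for the search (default: all 32).
#' @param keep_log Keep per-subset logs in each search.
#'
#' @return Object of class `run_report`: list with `dataset`, `split`,
#'   `search_table` (one row per subset size: subset, S on IS/VS/all and
#'   per-point values), `searches`, `best_model`, `estimates`,
#'   `confusion_2`, `confusion_3`.
#' @export
run_pipeline <- function(config = session_config(), cohort = NULL,
                         dataset = NULL, max_p = 3, seed = config$seed,
                         train_fraction = 6 / 7, pool = NULL, keep_log = FALSE) {
  if (is.null(dataset)) {
    if (is.null(cohort)) cohort <- gen_cohort(config)
    dataset <- build_feature_dataset(cohort)
  }
  split <- stratified_split(dataset$anx, train_fraction = train_fraction,
                            seed = seed)
  searches <- lapply(seq_len(max_p), function(p)
    exhaustive_search(dataset, split, p, pool = pool, keep_log = keep_log))
  n_is <- length(split$identification_indices)
  n_vs <- length(split$validation_indices)
  search_table <- do.call(rbind, lapply(searches, function(s) data.frame(
    p = s$p,
    subset = paste(s$best_subset, collapse = ", "),
    ssr_identification = s$ssr_identification,
    ssr_validation = s$ssr_validation,
    ssr_all = s$ssr_all,
    ssr_identification_per_point = s$ssr_identification / n_is,
    ssr_validation_per_point = if (n_vs > 0) s$ssr_validation / n_vs else NA_real_,
    evaluated_count = s$evaluated_count)))
  best <- searches[[max_p]]
  est <- predict(best$best_model, dataset)
  truth2 <- classify_anxiety(dataset$anx, class_scheme(2))
  truth3 <- classify_anxiety(dataset$anx, class_scheme(3))
  structure(list(
    dataset = dataset, split = split, searches = searches,
    search_table = search_table, best_model = best$best_model,
    estimates = est,
    confusion_2 = confusion_report(truth2, classify_anxiety(est, class_scheme(2)),
                                   class_scheme(2)),
    confusion_3 = confusion_report(truth3, classify_anxiety(est, class_scheme(3)),
                                   class_scheme(3))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$search_table[c("p", "subset", "ssr_identification", "ssr_validation")],
        row.names = FALSE)
  cat(sprintf("2-level accuracy: %.2f%%   3-level accuracy: %.2f%%\n",
              x$confusion_2$overall_accuracy, x$confusion_3$overall_accuracy))
  invisible(x)
}

#' Rolling real-time anxiety estimate over a recording
#'
#' Slides a window of `window_len` seconds over the recording with the given
#' stride, extracts the feature subset of the fitted model from each window
#' and evaluates the estimator. Positions before the first complete window
#' report `ready = FALSE` with an `NA` estimate rather than an error.
#'
#' @param model A fitted `poly_model`.
#' @param recording A [raw_recording()] at the analysis rate.
#' @param baseline Baseline statistics ([baseline_stats()]) of the session.
#' @param stride_s Update stride (s, default 1).
#' @param window_len Window length (s, default 5).
#' @param ... Further arguments to [continuous_decomposition()].
#' @return Data frame with `time_s`, `estimate`, `ready`.
#' @export
estimate_stream <- function(model, recording, baseline, stride_s = 1,
                            window_len = 5, ...) {
  stopifnot(inherits(model, "poly_model"), inherits(recording, "raw_recording"))
  fs <- recording$fs
  dec <- continuous_decomposition(recording$gsr, fs, ...)
  n <- length(recording$gsr)
  times <- seq(stride_s, n / fs, by = stride_s)
  rows <- lapply(times, function(tt) {
    if (tt < window_len)
      return(data.frame(time_s = tt, estimate = NA_real_, ready = FALSE))
    w <- suppressWarnings(
      extract_windows(recording, dec,
                      data.frame(time_s = tt + recording$start_time, sud = 0),
                      window_len = window_len))
    if (length(w) == 0L)
      return(data.frame(time_s = tt, estimate = NA_real_, ready = FALSE))
    f <- extract_features(w[[1L]], baseline)
    data.frame(time_s = tt,
               estimate = predict(model, f[model$features]),
               ready = TRUE)
  })
  do.call(rbind, rows)
}

#' Simulate a cohort whose ratings follow a known feature quadratic
#'
#' Generates a synthetic cohort, runs the signal chain to obtain its feature
#' dataset, and then replaces the ratings with a known second-order
#' polynomial of three of the *measured* features (plus optional Gaussian
#' noise), affinely mapped into `[0.5, 9.5]`. The generative link runs from
#' anxiety to physiology while the target is computed from the extracted
#' features, so the estimator's subset-recovery and coefficient-recovery
#' properties can be tested against exact ground truth.
#'
#' The planted subset must be identifiable: because the skin-conductance
#' trace is the sum of its tonic and phasic components, amplitude-level
#' features of GSR, SCL and SCR (MAV, MAR, STD, WL) are near-collinear
#' across the three channels, and rival subsets span nearly the same
#' function space. The default therefore plants one feature per independent
#' physiological axis -- tonic spectral content (`SCL_fmn`), mean cardiac
#' level (`HR_mav`) and heart-rate variability (`HR_std`).
#'
#' @param config A [session_config()].
#' @param subset Three canonical feature names.
#' @param noise_sd Gaussian noise added to the target (rating units).
#' @param seed Seed controlling cohort generation, the quadratic draw and the
#'   noise.
#' @return List with `dataset` (ratings replaced by the synthetic target),
#'   `truth` (subset, term coefficients on raw features, noise_sd) and
#'   `cohort`.
#' @export
simulate_quadratic_cohort <- function(config = session_config(),
                                      subset = c("SCL_fmn", "HR_mav", "HR_std"),
                                      noise_sd = 0, seed = config$seed) {
  config$seed <- seed
  cohort <- gen_cohort(config)
  dataset <- build_feature_dataset(cohort)
  X <- as.matrix(dataset[subset])
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  if (any(sdev == 0)) stop("degenerate feature in `subset`", call. = FALSE)
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  coefs <- with_seed(seed + 7L, stats::rnorm(n_coefficients(3L), 0, 1))
  raw <- as.numeric(poly_term_matrix(Z) %*% coefs)
  a <- 9 / diff(range(raw))
  b <- 0.5 - a * min(raw)
  target <- a * raw + b
  noise <- if (noise_sd > 0) with_seed(seed + 8L, stats::rnorm(length(target), 0, noise_sd)) else 0
  dataset$anx <- target + noise
  # express the generating coefficients on the raw feature scale: the target
  # is a quadratic in Z, and Z is affine in X, so it is a quadratic in X too
  true_model <- fit_poly_model(X, target, feature_names = subset)
  list(dataset = dataset,
       truth = list(subset = subset, model = true_model, noise_sd = noise_sd,
                    scale = c(a = a, b = b)),
       cohort = cohort)
}
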