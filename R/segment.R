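# Event-locked windowing: cut 5-s pre-stimulus segments from all signal
# streams, attach the self-reported anxiety rating (SUD), and assemble the
# per-window feature dataset.

#' Cut event-locked analysis windows
#'
#' For every stimulus event (a rated coin pickup) the half-open interval
#' `[time - window_len, time)` is cut from the GSR, SCL, SCR and HR streams:
#' the pickup sample itself is excluded, so the window is strictly
#' pre-stimulus. SCR events are attributed to a window when their onset falls
#' inside it. Events whose window would start before the recording are
#' skipped with a warning. Windows may overlap when stimuli are closer than
#' `window_len`.
#'
#' @param recording A [raw_recording()] (at the analysis rate).
#' @param decomposition Matching [continuous_decomposition()] result.
#' @param events Data frame with columns `time_s` (same time base as the
#'   recording) and `sud` (self-reported rating, 0-10).
#' @param window_len Window length in seconds (default 5).
#' @param subject_id Identifier stored in each window.
#'
#' @return A list of `labeled_window` objects, each a list with `subject_id`,
#'   `window_index`, `gsr`, `scl`, `scr`, `hr`, `events_in_window`, `anx`,
#'   `fs`.
#' @export
extract_windows <- function(recording, decomposition, events, window_len = 5,
                            subject_id = 1L) {
  stopifnot(inherits(recording, "raw_recording"),
            inherits(decomposition, "eda_decomposition"))
  if (length(decomposition$scl) != length(recording$gsr))
    stop("decomposition is not aligned to the recording", call. = FALSE)
  if (!all(c("time_s", "sud") %in% names(events)))
    stop("`events` must have columns `time_s` and `sud`", call. = FALSE)
  if (any(events$sud < 0 | events$sud > 10))
    stop("`sud` ratings must lie in [0, 10]", call. = FALSE)
  fs <- recording$fs
  n <- length(recording$gsr)
  n_win <- as.integer(round(window_len * fs))
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(events))) {
    t_ev <- events$time_s[i] - recording$start_time
    i_end <- as.integer(ceiling(t_ev * fs - 1e-9))  # last sample strictly before t_ev
    i_start <- i_end - n_win + 1L
    if (i_start < 1L || i_end > n) {
      skipped <- skipped + 1L
      next
    }
    idx <- i_start:i_end
    t_lo <- t_ev - window_len
    ev_in <- decomposition$events[
      decomposition$events$onset_s >= t_lo & decomposition$events$onset_s < t_ev, ,
      drop = FALSE]
    out[[length(out) + 1L]] <- structure(list(
      subject_id = subject_id,
      window_index = length(out) + 1L,
      gsr = recording$gsr[idx],
      scl = decomposition$scl[idx],
      scr = decomposition$scr[idx],
      hr = recording$hr[idx],
      events_in_window = ev_in,
      anx = events$sud[i],
      fs = fs
    ), class = "labeled_window")
  }
  if (skipped > 0L)
    warning(sprintf("%d event(s) skipped: window precedes recording start or exceeds its end",
                    skipped), call. = FALSE)
  out
}

#' Assemble the per-window feature dataset
#'
#' One row per labeled window: subject id, window index, the reported anxiety
#' level (ANX) and the 32 features in canonical order (see
#' [feature_names()]). Rows are sorted by subject, then window index.
#'
#' @param windows List of `labeled_window` objects.
#' @param features List of feature vectors (one per window, each a named
#'   32-vector from [extract_features()]).
#'
#' @return A data frame with columns `subject`, `window`, `anx` and the 32
#'   feature columns.
#' @export
assemble_dataset <- function(windows, features) {
  if (length(windows) != length(features))
    stop("`windows` and `features` must have the same length", call. = FALSE)
  if (length(windows) == 0L) {
    out <- data.frame(subject = integer(0), window = integer(0), anx = numeric(0))
    for (nm in feature_names()) out[[nm]] <- numeric(0)
    return(out)
  }
  canon <- feature_names()
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    f <- features[[i]]
    if (!all(canon %in% names(f)))
      stop("feature vector ", i, " is missing canonical features", call. = FALSE)
    cbind(data.frame(subject = w$subject_id, window = w$window_index, anx = w$anx),
          as.data.frame(as.list(f[canon])))
  })
  out <- do.call(rbind, rows)
  key <- paste(out$subject, out$window)
  if (anyDuplicated(key))
    stop("duplicate (subject, window) pairs in dataset", call. = FALSE)
  out <- out[order(out$subject, out$window), , drop = FALSE]
  rownames(out) <- NULL
  out
}
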