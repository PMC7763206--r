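# Plain-text interchange: per-sample CSV recordings, event CSVs, component
# exports and the model JSON.

#' Read a recording CSV
#'
#' Expects a header `time_s,gsr_uS,hr_bpm` (UTF-8, '.' decimal separator),
#' one row per sample. Devices that report heart rate at a lower rate leave
#' cells empty; these are forward-filled (samples before the first reported
#' value take that value).
#'
#' @param path CSV file.
#' @param fs Sampling rate (Hz); inferred from the time column when omitted.
#' @return A [raw_recording()].
#' @export
read_recording_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "gsr_uS", "hr_bpm")
  if (!all(need %in% names(d)))
    stop("recording CSV must have columns time_s,gsr_uS,hr_bpm", call. = FALSE)
  if (is.null(fs)) {
    dt <- stats::median(diff(d$time_s))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate", call. = FALSE)
    fs <- 1 / dt
  }
  hr <- d$hr_bpm
  if (anyNA(hr)) {
    idx <- which(!is.na(hr))
    if (length(idx) == 0L) stop("heart-rate column is entirely empty", call. = FALSE)
    hr <- hr[idx][findInterval(seq_along(hr), idx, left.open = FALSE)]
    hr[seq_len(idx[1L] - 1L)] <- hr[idx[1L]]
  }
  raw_recording(d$gsr_uS, hr, fs, start_time = d$time_s[1L])
}

#' @rdname read_recording_csv
#' @param rec A [raw_recording()].
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- length(rec$gsr)
  utils::write.csv(data.frame(time_s = rec$start_time + (seq_len(n) - 1L) / rec$fs,
                              gsr_uS = rec$gsr, hr_bpm = rec$hr),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a stimulus-events CSV (`time_s,sud`)
#'
#' @param path CSV file.
#' @return Data frame with `time_s` and `sud`.
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "sud") %in% names(d)))
    stop("events CSV must have columns time_s,sud", call. = FALSE)
  d
}

#' @rdname read_events_csv
#' @param events Data frame with `time_s` and `sud`.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[c("time_s", "sud")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a decomposition and its events as CSV
#'
#' Writes `time_s,gsr_uS,scl_uS,scr_uS` to `path` and, when `events_path` is
#' given, `onset_s,amplitude_uS` of the detected SCR events.
#'
#' @param decomposition An `eda_decomposition`.
#' @param path Output CSV for the component traces.
#' @param events_path Optional output CSV for the events.
#' @export
write_decomposition_csv <- function(decomposition, path, events_path = NULL) {
  utils::write.csv(as.data.frame(decomposition), path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path))
    utils::write.csv(decomposition$events, events_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted polynomial model as JSON
#'
#' The JSON object carries `features`, `alpha` (keys `"i,j"` over the upper
#' triangle), `beta` (keyed by feature name), `gamma` and `p`.
#'
#' @param model A `poly_model`.
#' @param path JSON file.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "poly_model"))
  obj <- list(features = model$features, alpha = model$alpha,
              beta = as.list(model$beta), gamma = model$gamma, p = model$p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- as.integer(obj$p)
  features <- unlist(obj$features)
  tp <- term_pairs(p)
  alpha <- vapply(paste(tp[, "i"], tp[, "j"], sep = ","),
                  function(k) as.numeric(obj$alpha[[k]]), 0)
  beta <- vapply(features, function(k) as.numeric(obj$beta[[k]]), 0)
  cf <- c(alpha, beta, as.numeric(obj$gamma))
  structure(list(features = features, coef = unname(cf),
                 alpha = as.list(unname(alpha)) |>
                   stats::setNames(paste(tp[, "i"], tp[, "j"], sep = ",")),
                 beta = stats::setNames(unname(beta), features),
                 gamma = as.numeric(obj$gamma), p = p),
            class = "poly_model")
}

#' Write a feature dataset CSV (`subject,window,anx,<32 features>`)
#'
#' @param dataset Feature dataset from [assemble_dataset()].
#' @param path Output CSV.
#' @export
write_feature_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "window", "anx") %in% names(d)))
    stop("feature CSV must have columns subject,window,anx", call. = FALSE)
  d
}
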