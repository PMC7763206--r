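# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use plain loops so they share no code with
# the implementations they check.

naive_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

naive_std <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

naive_wl <- function(x) {
  s <- 0
  for (k in 2:length(x)) s <- s + (x[k] - x[k - 1])^2
  s
}

naive_ssc <- function(x, eps = 0.001) {
  n <- 0L
  for (k in 2:(length(x) - 1)) {
    a <- x[k] - x[k - 1]
    b <- x[k + 1] - x[k]
    if (sign(a) * sign(b) < 0 && abs(a) >= eps && abs(b) >= eps) n <- n + 1L
  }
  n
}

naive_wamp <- function(x, eps_w = 0.5) {
  n <- 0L
  for (k in 2:length(x)) if (abs(x[k] - x[k - 1]) >= eps_w) n <- n + 1L
  n
}

# Naive exhaustive enumerator over a feature pool: fits every subset with
# lm() on the quadratic expansion and returns the winner + its SSR.
naive_search <- function(dataset, is_idx, p, pool) {
  combs <- utils::combn(pool, p)
  best <- NULL
  best_s <- Inf
  all_s <- numeric(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    fts <- combs[, j]
    X <- as.matrix(dataset[is_idx, fts, drop = FALSE])
    terms <- list()
    for (a in seq_len(p)) for (b in a:p)
      terms[[length(terms) + 1L]] <- X[, a] * X[, b]
    for (a in seq_len(p)) terms[[length(terms) + 1L]] <- X[, a]
    D <- do.call(cbind, terms)
    fit <- stats::lm(dataset$anx[is_idx] ~ D)
    s <- sum(stats::residuals(fit)^2)
    all_s[j] <- s
    if (s < best_s) {
      best_s <- s
      best <- fts
    }
  }
  list(subset = best, ssr = best_s, all_ssr = all_s)
}

# Flat-tonic trace with Bateman responses injected at known onsets.
make_scr_trace <- function(fs, duration, onsets, amps, tonic = 5) {
  n <- round(duration * fs)
  k <- bateman_kernel(fs)
  x <- rep(tonic, n)
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1
    len <- min(length(k), n - i0 + 1)
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] + amps[i] * k[seq_len(len)]
  }
  x
}

# Minimal labeled window for direct feature tests.
make_window <- function(gsr, scl = gsr * 0.9, scr = gsr * 0.1, hr = rep(70, length(gsr)),
                        events = data.frame(onset_s = numeric(0), amplitude_uS = numeric(0)),
                        anx = 0, fs = 51.2) {
  structure(list(subject_id = 1L, window_index = 1L, gsr = gsr, scl = scl,
                 scr = scr, hr = hr, events_in_window = events, anx = anx, fs = fs),
            class = "labeled_window")
}

# A small cached synthetic cohort shared by segment/pipeline tests.
cached_cohort <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- gen_cohort(session_config(seed = 101L))
    val
  }
})

table4_totals <- c(41L, 16L, 12L, 9L, 7L, 4L, 4L, 2L, 5L, 2L, 3L)
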