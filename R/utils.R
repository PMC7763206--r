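# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Round half away from zero (round(0.5) -> 1, round(-0.5) -> -1), unlike base
# round()'s round-half-even. Fixed convention so stratified splits are
# reproducible across platforms.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generator calls do not perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Centered moving average with edge replication; n is forced odd.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L || length(x) < 2L) return(x)
  pad <- (n - 1L) %/% 2L
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 2))[(pad + 1L):(pad + length(x))]
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
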