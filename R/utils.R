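# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this so that
# identical arguments (including seed) give identical output.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Truncated-normal draws by rejection (lower bound only); adequate for the
# mild truncations used by the generators.
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
  }
  out[out < lower] <- lower
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive finite number", what), call. = FALSE)
  }
  invisible(x)
}
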