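# Run code with a local, restored RNG state so generators are pure functions
# of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

params_with <- function(params, ...) {
  p <- unclass(params)
  p$kd_protF <- NULL
  dots <- list(...)
  p[names(dots)] <- dots
  do.call(chap_params, p)
}

# Fast field update for hot loops: skips re-validation and class dispatch.
# Callers must keep fields valid (positive rates, non-negative synthesis).
params_mut <- function(params, ...) {
  dots <- list(...)
  params[names(dots)] <- dots
  params$kd_protF <- params$beta * params$kd_protU
  params
}
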