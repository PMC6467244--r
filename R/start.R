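#' Start-analysis configuration
#'
#' @param cln3f_crit Critical folded-Cln3 copy number triggering Start
#'   (default 25 molecules).
#' @param vol_range Volume search interval (fl), within the controlled range
#'   10-100 fl.
#' @param tol Relative tolerance of the critical-volume bisection.
#' @return A list of class `start_config`.
#' @export
start_config <- function(cln3f_crit = 25, vol_range = c(10, 100), tol = 1e-3) {
  if (cln3f_crit <= 0) stop("cln3f_crit must be positive", call. = FALSE)
  if (length(vol_range) != 2L || diff(vol_range) <= 0)
    stop("vol_range must be an increasing interval", call. = FALSE)
  if (vol_range[1] < 10 || vol_range[2] > 100)
    stop("vol_range must lie within the controlled range [10, 100] fl",
         call. = FALSE)
  structure(list(cln3f_crit = cln3f_crit, vol_range = vol_range, tol = tol),
            class = "start_config")
}

ss_cln3f_at <- function(params, vol) {
  steady_state_exact(params_mut(params, vol = vol))[["cln3_f"]]
}

#' Critical budding volume at a given growth rate
#'
#' Cells growing at rate `s_vol` commit to Start at the volume where the
#' steady-state folded-Cln3 pool reaches the critical threshold. The solver
#' bisects on volume over `cfg$vol_range`, after verifying by an endpoint
#' check that steady-state Cln3F brackets the threshold (Cln3F is
#' non-decreasing in volume for valid parameter sets).
#'
#' @param params A `chap_params` object; its `s_prot` and `vol` fields are
#'   overridden during the search.
#' @param s_vol Specific volume growth rate (equal to the protein synthesis
#'   density via gamma = 1).
#' @param cfg A [start_config()].
#' @return Critical volume (fl), to relative tolerance `cfg$tol`.
#' @export
critical_volume <- function(params, s_vol, cfg = start_config()) {
  stopifnot(inherits(params, "chap_params"))
  if (!is.finite(s_vol) || s_vol < 0) stop("invalid s_vol", call. = FALSE)
  params <- params_mut(params, s_prot = s_vol)
  lo <- cfg$vol_range[1]; hi <- cfg$vol_range[2]
  f_lo <- ss_cln3f_at(params, lo) - cfg$cln3f_crit
  f_hi <- ss_cln3f_at(params, hi) - cfg$cln3f_crit
  if (f_lo > f_hi)
    stop("steady-state Cln3F is not non-decreasing in volume", call. = FALSE)
  if (f_hi < 0)
    stop("threshold not reached: Cln3F(vol_max) < cln3f_crit", call. = FALSE)
  if (f_lo > 0)
    stop("already past Start: Cln3F(vol_min) > cln3f_crit", call. = FALSE)
  while ((hi - lo) > cfg$tol * lo) {
    mid <- (lo + hi) / 2
    if (ss_cln3f_at(params, mid) - cfg$cln3f_crit < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Ensemble response curves versus growth rate
#'
#' For each growth rate on `s_vol_grid` and each parameter set of the
#' ensemble, computes the requested observable at steady state and returns the
#' per-grid-point mean and sample standard deviation (the ensemble band of the
#' growth-rate response plots).
#'
#' @param ensemble List of `chap_params` objects.
#' @param s_vol_grid Growth-rate grid.
#' @param observable One of `"critical_volume"`, `"dsim"` or
#'   `"cln3_f_at_vol"`.
#' @param cfg A [start_config()].
#' @param vol Fixed volume (fl) used for `"dsim"` and `"cln3_f_at_vol"`.
#' @return Data frame with columns `s_vol`, `mean`, `sd`, `n`.
#' @export
growth_rate_response <- function(ensemble, s_vol_grid,
                                 observable = c("critical_volume", "dsim",
                                                "cln3_f_at_vol"),
                                 cfg = start_config(), vol = 50) {
  observable <- match.arg(observable)
  if (length(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  if (inherits(ensemble, "chap_params")) ensemble <- list(ensemble)
  eval_one <- function(pars, s) {
    p <- unclass(pars); p$kd_protF <- NULL; p$s_prot <- s; p$vol <- vol
    pars_s <- do.call(chap_params, p)
    switch(observable,
           critical_volume = critical_volume(pars, s, cfg),
           dsim = dsim(steady_state(pars_s)),
           cln3_f_at_vol = steady_state(pars_s)[["cln3_f"]])
  }
  out <- lapply(s_vol_grid, function(s) {
    vals <- vapply(ensemble, function(pars) {
      tryCatch(eval_one(pars, s), error = function(e) {
        warning("ensemble member skipped at s_vol = ", s, ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L)
      stop("all ensemble members failed at s_vol = ", s, call. = FALSE)
    data.frame(s_vol = s, mean = mean(vals),
               sd = if (length(vals) > 1L) stats::sd(vals) else 0,
               n = length(vals))
  })
  do.call(rbind, out)
}

#' Fourfold kb/kr band ensemble
#'
#' Samples parameter sets with the Ydj1 binding and release rates (`kb`,
#' `kr`) drawn log-uniformly within a `fold`-range centred (in log space) on
#' the base values, i.e. within `[x/sqrt(fold), x*sqrt(fold)]`; all other
#' fields are copied. Used to draw prediction bands around the reference set.
#'
#' @param base A `chap_params` object.
#' @param fold Total multiplicative range (default 4).
#' @param n Number of ensemble members.
#' @param seed Integer seed (reproducible).
#' @return List of `chap_params` objects.
#' @export
kbkr_band_ensemble <- function(base, fold = 4, n = 100, seed = 1) {
  stopifnot(inherits(base, "chap_params"))
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  with_seed(seed, {
    half <- log(fold) / 2
    lapply(seq_len(n), function(i) {
      kb <- base$kb * exp(stats::runif(1, -half, half))
      kr <- base$kr * exp(stats::runif(1, -half, half))
      p <- unclass(base); p$kd_protF <- NULL
      p$kb <- kb; p$kr <- kr
      do.call(chap_params, p)
    })
  })
}
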