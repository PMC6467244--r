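#' Synthetic-data configuration
#'
#' Study conditions for the seeded generators: growth rates span the
#' controlled range 0.01-1 molec s^-1 fl^-1 drawn log-uniformly, volumes span
#' 10-100 fl, the generating truth is the reference fitted parameter set, and
#' positive observables carry multiplicative lognormal noise with unit mean
#' and coefficient of variation `noise_cv` (default 0.1, a conventional
#' single-cell measurement error).
#'
#' @param seed Integer seed.
#' @param n_cells Number of synthetic cells.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param s_vol_range Growth-rate span.
#' @param vol_range Volume span (fl).
#' @param truth Generating `chap_params`.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_cells = 100L, noise_cv = 0.1,
                         s_vol_range = c(0.01, 1), vol_range = c(10, 100),
                         truth = param_set_3114()) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (s_vol_range[1] < 0.01 || s_vol_range[2] > 1)
    stop("s_vol_range must lie within [0.01, 1]", call. = FALSE)
  if (vol_range[1] < 10 || vol_range[2] > 100)
    stop("vol_range must lie within [10, 100] fl", call. = FALSE)
  structure(list(seed = seed, n_cells = n_cells, noise_cv = noise_cv,
                 s_vol_range = s_vol_range, vol_range = vol_range,
                 truth = truth), class = "synth_config")
}

#' Generate per-cell growth observations
#'
#' For each synthetic cell a growth rate is drawn log-uniformly over the
#' configured span; a diffusion record is the steady-state weighted-average
#' diffusion observable of the truth at a uniformly drawn volume, and a
#' budding-volume record is the truth's critical volume at that growth rate,
#' each multiplied by unit-mean lognormal noise. The reported `sigma` is the
#' noise standard deviation of each record (`noise_cv` times the true value),
#' floored at 1% of the true value so noise-free tables remain usable with
#' sigma weighting.
#'
#' @param cfg A [synth_config()].
#' @param cfg_start A [start_config()] used for the budding records.
#' @return An [observation_table()] with `2 * n_cells` records.
#' @export
gen_growth_observations <- function(cfg = synth_config(),
                                    cfg_start = start_config()) {
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    s_vol <- exp(stats::runif(n, log(cfg$s_vol_range[1]), log(cfg$s_vol_range[2])))
    vols <- stats::runif(n, cfg$vol_range[1], cfg$vol_range[2])
    d_true <- vapply(seq_len(n), function(i) {
      dsim(steady_state(params_with(cfg$truth, s_prot = s_vol[i], vol = vols[i])))
    }, numeric(1))
    v_true <- vapply(s_vol, function(s) {
      tryCatch(critical_volume(cfg$truth, s, cfg_start),
               error = function(e) stop("generation failed: ",
                                        conditionMessage(e), call. = FALSE))
    }, numeric(1))
    d_obs <- d_true * rlnorm_cv(n, cfg$noise_cv)
    v_obs <- v_true * rlnorm_cv(n, cfg$noise_cv)
    # sigma is floored at 1% of the true value so noise-free tables keep a
    # well-conditioned weighting
    cv_eff <- max(cfg$noise_cv, 0.01)
    rbind(
      observation_table(s_vol, d_obs, sigma = cv_eff * d_true,
                        kind = "diffusion_um2_min", vol = vols),
      observation_table(s_vol, v_obs, sigma = cv_eff * v_true,
                        kind = "budding_volume_fl"))
  })
}

#' Generate a two-compartment FLIP trace
#'
#' Forward-integrates the linear exchange/bleach system
#' `dFn/dt = Ki*Fc - (Ke + Kb)*Fn`, `dFc/dt = Ke*Fn - Ki*Fc` (bleach term
#' active during the bleach phase only), starting from the import/export
#' equilibrium `Fn/Fc = Ki/Ke`, and adds multiplicative noise. A matched
#' reference-channel trace decaying at `k_b / bleach_factor` is returned in
#' column `f_ref`.
#'
#' @param k_i,k_e,k_b Import, export and GFP-channel bleaching rate constants
#'   (s^-1).
#' @param dt Sampling interval (s).
#' @param duration Total duration (s).
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param protocol `"continuous_bleach"` (bleach for the whole trace) or
#'   `"bleach_then_recover"` (bleach for `bleach_time`, then recovery).
#' @param bleach_time Bleach-phase length (s) for the two-phase protocol.
#' @param bleach_factor GFP/reference bleaching factor for the reference
#'   trace.
#' @return Data frame with columns `time_s`, `f_n`, `f_c`, `f_ref`, `phase`.
#' @export
gen_flip_trace <- function(k_i, k_e, k_b, dt = 0.5, duration = 60,
                           noise_cv = 0, seed = 1L,
                           protocol = c("continuous_bleach",
                                        "bleach_then_recover"),
                           bleach_time = duration / 2, bleach_factor = 1.94) {
  protocol <- match.arg(protocol)
  if (any(c(k_e, k_b) <= 0) || k_i < 0)
    stop("rates must be positive (k_i may be 0)", call. = FALSE)
  times <- seq(0, duration, by = dt)
  step <- function(y, kb_active, h) {
    A <- matrix(c(-(k_e + kb_active), k_i, k_e, -k_i), 2, 2, byrow = TRUE)
    as.numeric(Matrix_expm(A * h) %*% y)
  }
  bleach_on <- if (protocol == "continuous_bleach") rep(TRUE, length(times))
               else times <= bleach_time
  y <- c(if (k_i > 0) k_i / k_e else 0, 1)  # start at import/export equilibrium
  fn <- numeric(length(times)); fc <- numeric(length(times))
  fn[1] <- y[1]; fc[1] <- y[2]
  for (j in 2:length(times)) {
    y <- step(y, if (bleach_on[j]) k_b else 0, times[j] - times[j - 1])
    fn[j] <- y[1]; fc[j] <- y[2]
  }
  with_seed(seed, {
    data.frame(time_s = times,
               f_n = fn * rlnorm_cv(length(times), noise_cv),
               f_c = fc * rlnorm_cv(length(times), noise_cv),
               f_ref = exp(-(k_b / bleach_factor) * times) *
                 rlnorm_cv(length(times), noise_cv),
               phase = ifelse(bleach_on, "bleach", "recovery"))
  })
}

# 2x2 matrix exponential via eigendecomposition (real distinct eigenvalues for
# these exchange systems), with a series fallback.
Matrix_expm <- function(M) {
  e <- eigen(M)
  if (all(abs(Im(e$values)) < 1e-12) && abs(det(e$vectors)) > 1e-12) {
    Re(e$vectors %*% diag(exp(Re(e$values))) %*% solve(e$vectors))
  } else {
    S <- diag(nrow(M)); term <- diag(nrow(M))
    for (i in 1:30) { term <- term %*% M / i; S <- S + term }
    S
  }
}

#' Generate an FCS autocorrelation curve
#'
#' Evaluates the single-component anomalous-diffusion model on a log-spaced
#' lag grid spanning 10 us - 100 ms and adds multiplicative noise.
#'
#' @param d Diffusion coefficient (um^2/min).
#' @param w0 Lateral focal radius (um).
#' @param alpha Anomaly exponent.
#' @param n_lags Number of lag points.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param g0 Amplitude (intercept).
#' @param s Structure parameter.
#' @return Data frame with columns `lag_s`, `g`.
#' @export
gen_fcs_curve <- function(d, w0 = 0.25, alpha = 0.5, n_lags = 100L,
                          noise_cv = 0, seed = 1L, g0 = 1, s = 5) {
  if (d <= 0 || w0 <= 0) stop("d and w0 must be positive", call. = FALSE)
  lag <- 10^seq(log10(1e-5), log10(1e-1), length.out = n_lags)
  tau_d <- w0^2 / (4 * d / 60)
  g <- fcs_model(lag, tau_d, g0 = g0, alpha = alpha, s = s)
  with_seed(seed, data.frame(lag_s = lag,
                             g = g * rlnorm_cv(n_lags, noise_cv)))
}

#' Generate a stress mobility time course
#'
#' Simulates the diffusion observable after a stress event (see
#' [simulate_stress()]), maps model time to experimental minutes with the
#' time-scale factor `tau` (model seconds per experimental minute) and samples
#' it with multiplicative noise. Following the acquisition protocol the
#' measurements emulate, duplicate measurements are taken at every time point
#' (`n_replicates = 2`); the default sampling grid is dense at early times
#' because the sequestration transient is fast relative to the recovery.
#'
#' @param truth Generating `chap_params`.
#' @param fraction Unfolding fraction in [0, 1].
#' @param ydj1_synth_factor Ydj1 synthesis multiplier (1 salt, 2.9 heat).
#' @param tau Time-scale factor (model s per experimental min).
#' @param sample_times Sampling times (minutes).
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param n_replicates Measurements per time point (default 2, duplicates).
#' @return Data frame with columns `time` (min) and `d` (um^2/min), one row
#'   per measurement.
#' @export
gen_stress_mobility <- function(truth = param_set_3114(), fraction = 0.6,
                                ydj1_synth_factor = 1, tau = 300,
                                sample_times = c(0, 0.005, 0.01, 0.015, 0.02,
                                                 0.025, 0.03, 0.04, 0.05,
                                                 0.075, 0.1, 0.15, 0.2, 0.3,
                                                 0.4, 0.5, 0.75, 1, 1.5, 2, 3,
                                                 4, 6, 8, 12, 20, 30),
                                noise_cv = 0.05, seed = 1L,
                                n_replicates = 2L) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  if (fraction == 0 && ydj1_synth_factor == 1) {
    d_true <- rep(dsim(steady_state(truth)), length(sample_times))
  } else {
    prot <- stress_protocol(fraction, ydj1_synth_factor,
                            duration = max(tau * max(sample_times), 1))
    times <- c(0, 10^seq(-2, log10(prot$duration), length.out = 500L))
    tr <- simulate_stress(truth, prot, times = times)
    dfun <- stats::approxfun(tr$time_s, tr$dsim, rule = 2)
    d_true <- dfun(tau * sample_times)
  }
  n <- length(sample_times) * n_replicates
  with_seed(seed, data.frame(
    time = rep(sample_times, n_replicates),
    d = rep(d_true, n_replicates) * rlnorm_cv(n, noise_cv)))
}
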