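#' Nuclear/cytoplasmic concentration ratio from projected-area fluorescence
#'
#' Wide-field microscopy collects, over the nuclear projected area, a
#' fluorescence column containing both nuclear and cytoplasmic fluorophore.
#' Modelling that column as a cylinder of the nuclear diameter through the
#' whole cell height and the nucleus as a sphere, the nuclear-to-cytoplasmic
#' concentration ratio is
#' `N/C = 1 + k * (f_r - 3/2) / (r_r - f_r * r_r^3)`,
#' where `f_r` is the ratio of mean fluorescence signal in the nuclear and
#' cell projected areas, `r_r` the nuclear/cell radius ratio and `k` the
#' z-axis cell-radius correction. A uniformly distributed fluorophore gives
#' `f_r = 3/2` and hence `N/C = 1` for any geometry.
#'
#' @param f_r Nuclear/cell projected-area mean-signal ratio (> 0).
#' @param r_r Nuclear/cell radius ratio, in (0, 1).
#' @param k Z-axis radius correction (> 0).
#' @return The nuclear/cytoplasmic concentration ratio.
#' @seealso [nc_project()] for the forward geometric model.
#' @export
nc_ratio <- function(f_r, r_r, k = 1) {
  if (f_r <= 0 || r_r <= 0 || r_r >= 1 || k <= 0)
    stop("invalid geometry parameters", call. = FALSE)
  den <- r_r - f_r * r_r^3
  if (abs(den) < 1e-12 * r_r)
    stop("degenerate geometry: f_r equals 1 / r_r^2", call. = FALSE)
  1 + k * (f_r - 3 / 2) / den
}

#' Forward projection of the nuclear/cell signal ratio
#'
#' Computes the projected-area mean-signal ratio `f_r` produced by a true
#' nuclear/cytoplasmic concentration ratio under the cylinder-column /
#' spherical-nucleus geometry (cell height `2 * k * r_c`):
#' `f_r = (3/2 * k + (nc - 1) * r_r) / (k + (nc - 1) * r_r^3)`.
#' [nc_ratio()] is its exact inverse.
#'
#' @param nc True nuclear/cytoplasmic concentration ratio.
#' @param r_r Nuclear/cell radius ratio, in (0, 1).
#' @param k Z-axis radius correction.
#' @return The signal ratio `f_r`.
#' @export
nc_project <- function(nc, r_r, k = 1) {
  (1.5 * k + (nc - 1) * r_r) / (k + (nc - 1) * r_r^3)
}

#' FLIP rate constants
#'
#' Constants of the two-compartment nuclear FLIP analysis: the export rate
#' `k_e` (assumed constant among G1 cells, default 0.199 s^-1), the bleaching
#' rate measured on the reference fluorophore, and the bleaching factor
#' converting it to the GFP channel (default 1.94).
#'
#' @param k_e Export rate constant (s^-1).
#' @param k_b_ref Reference-channel bleaching rate (s^-1).
#' @param bleach_factor GFP/reference bleaching-rate factor.
#' @return List of class `flip_constants`.
#' @export
flip_constants <- function(k_e = 0.199, k_b_ref = NULL, bleach_factor = 1.94) {
  if (k_e <= 0 || bleach_factor <= 0 ||
      (!is.null(k_b_ref) && k_b_ref <= 0))
    stop("FLIP constants must be positive", call. = FALSE)
  structure(list(k_e = k_e, k_b_ref = k_b_ref, bleach_factor = bleach_factor),
            class = "flip_constants")
}

# Exponential decay rate of a positive signal, by log-linear least squares.
decay_rate <- function(time, signal) {
  ok <- signal > 0
  if (sum(ok) < 2L) return(0)
  -stats::coef(stats::lm(log(signal[ok]) ~ time[ok]))[[2L]]
}

#' Nuclear import rate from a FLIP trace
#'
#' During continuous nuclear photobleaching the nuclear/cytoplasmic signal
#' ratio settles to a plateau; the import rate follows from
#' `k_i = (f_n/f_c)_ss * (k_e + k_b/2)`. The GFP-channel bleaching rate `k_b`
#' is `bleach_factor` times the rate fitted to the reference-channel trace
#' (or taken from `consts$k_b_ref` directly when no reference trace is in the
#' data).
#'
#' @param trace Data frame with columns `time_s`, `f_n`, `f_c` and optionally
#'   `f_ref` (reference-channel signal used to fit the bleaching rate).
#' @param consts A [flip_constants()]; `k_b_ref` is required when the trace
#'   has no `f_ref` column.
#' @param equilibration Seconds discarded from the start of the trace before
#'   averaging the plateau ratio (default 10).
#' @return Import rate `k_i` (s^-1).
#' @export
import_rate_flip <- function(trace, consts = flip_constants(),
                             equilibration = 10) {
  if (!is.null(trace$f_ref)) {
    k_b_ref <- decay_rate(trace$time_s, trace$f_ref)
  } else if (!is.null(consts$k_b_ref)) {
    k_b_ref <- consts$k_b_ref
  } else stop("no reference-channel bleach rate available", call. = FALSE)
  k_b <- consts$bleach_factor * k_b_ref
  post <- trace$time_s > equilibration
  if (!any(post)) stop("no samples after the equilibration window", call. = FALSE)
  ratio <- mean(trace$f_n[post] / trace$f_c[post])
  ratio * (consts$k_e + k_b / 2)
}

#' Nuclear export rate from bleach and recovery plateau ratios
#'
#' In the two-phase FLIP protocol the nuclear region is bleached briefly and
#' then allowed to recover. Both phases settle to a steady nuclear/cytoplasmic
#' ratio, and equating the import rate inferred from each yields the export
#' rate. Two estimators are provided. `"exact"` (default) inverts the exact
#' asymptotic ratio of the two-compartment bleach equations
#' (`dFn/dt = Ki*Fc - (Ke+Kb)*Fn`, `dFc/dt = Ke*Fn - Ki*Fc`), whose bleach
#' plateau solves `Ke*r1^2 + (Ke+Kb-Ki)*r1 - Ki = 0` while the recovery
#' plateau is `r2 = Ki/Ke`, giving
#' `k_e = k_b * r1 / ((r2 - r1) * (1 + r1))`.
#' `"linear"` is the classical small-bleach approximation
#' `k_e = r1 * k_b / (2 * (r2 - r1))`, which agrees with `"exact"` as
#' `r1 -> 1` (the regime of weak bleaching relative to exchange).
#'
#' @param ratio_bleach Plateau `f_n/f_c` during bleaching (r1).
#' @param ratio_recovery Plateau `f_n/f_c` after recovery (r2), > r1.
#' @param k_b GFP-channel bleaching rate (s^-1).
#' @param method `"exact"` or `"linear"`.
#' @return Export rate `k_e` (s^-1).
#' @export
export_rate_flip <- function(ratio_bleach, ratio_recovery, k_b,
                             method = c("exact", "linear")) {
  method <- match.arg(method)
  if (ratio_bleach <= 0 || ratio_recovery <= 0)
    stop("ratios must be positive", call. = FALSE)
  if (ratio_recovery <= ratio_bleach)
    stop("indeterminate: recovery ratio must exceed bleach ratio", call. = FALSE)
  r1 <- ratio_bleach; r2 <- ratio_recovery
  switch(method,
         exact = k_b * r1 / ((r2 - r1) * (1 + r1)),
         linear = r1 * k_b / (2 * (r2 - r1)))
}

#' Mobility index of a FLIP decay trace
#'
#' Fluorescence of an unbleached region, normalized to its first point, is
#' fitted with a decaying exponential; the mobility index is the inverse of
#' the fitted half-life (s^-1). A constant trace has index 0; an increasing
#' trace yields a warning and index 0.
#'
#' @param time Time points (s), >= 5 values.
#' @param signal Fluorescence values; first value must be positive.
#' @return Mobility index (s^-1).
#' @export
mobility_index <- function(time, signal) {
  if (length(time) < 5L) stop("need at least 5 points", call. = FALSE)
  if (signal[1L] <= 0) stop("initial value must be positive", call. = FALSE)
  y <- signal / signal[1L]
  k <- decay_rate(time, y)
  if (k < 0) {
    warning("increasing trace; mobility index set to 0")
    return(0)
  }
  if (k == 0) return(0)
  k / log(2)
}

#' Anomalous-diffusion model for FCS autocorrelation
#'
#' Single-component 3D anomalous-diffusion autocorrelation,
#' `g(tau) = g0 / ((1 + (tau/tau_d)^alpha) * sqrt(1 + (tau/tau_d)^alpha / s^2))`,
#' with anomaly exponent `alpha` (0.5 by default) and structure parameter `s`.
#'
#' @param lag Lag times (s).
#' @param tau_d Characteristic diffusion time (s).
#' @param g0 Amplitude (fitted intercept).
#' @param alpha Anomaly exponent.
#' @param s Structure parameter (axial/lateral focal radius ratio).
#' @return Autocorrelation values.
#' @export
fcs_model <- function(lag, tau_d, g0 = 1, alpha = 0.5, s = 5) {
  x <- (lag / tau_d)^alpha
  g0 / ((1 + x) * sqrt(1 + x / s^2))
}

#' Fit an FCS autocorrelation curve
#'
#' Levenberg-Marquardt fit of the single-component anomalous-diffusion model
#' with fixed anomaly exponent over the canonical 10 us - 100 ms lag range.
#' The diffusion coefficient is `D = w0^2 / (4 * tau_d)`, reported in
#' um^2/min. Following the acquisition quality rules, the curve is flagged as
#' an outlier when the relative standard error of the fitted diffusion time
#' exceeds 50% or the fitted intercept exceeds 1.01.
#'
#' @param curve Data frame with columns `lag_s` (increasing, positive) and
#'   `g`.
#' @param alpha Fixed anomaly exponent (default 0.5).
#' @param fit_range Lag range (s) used for fitting.
#' @param w0 Lateral focal radius (um) converting `tau_d` to a diffusion
#'   coefficient.
#' @param s Structure parameter.
#' @return List with `d` (um^2/min), `tau_d` (s), `intercept`, `rel_se`,
#'   `outlier_flag`.
#' @export
fit_fcs <- function(curve, alpha = 0.5, fit_range = c(1e-5, 1e-1),
                    w0 = 0.25, s = 5) {
  keep <- curve$lag_s >= fit_range[1] & curve$lag_s <= fit_range[2]
  if (sum(keep) < 10L)
    stop("need at least 10 points inside the fit range", call. = FALSE)
  lag <- curve$lag_s[keep]; g <- curve$g[keep]
  fn <- function(p) g - fcs_model(lag, tau_d = exp(p[1]), g0 = p[2],
                                  alpha = alpha, s = s)
  tau0 <- lag[which.min(abs(g - g[1L] / 2))]
  fit <- minpack.lm::nls.lm(par = c(log(tau0), max(g)), fn = fn)
  if (!fit$info %in% 1:4)
    stop("FCS fit failed to converge: ", fit$message, call. = FALSE)
  tau_d <- exp(fit$par[1]); g0 <- fit$par[2]
  dof <- length(lag) - 2L
  cov <- tryCatch(sum(fit$fvec^2) / dof * solve(fit$hessian),
                  error = function(e) NULL)
  # se of log(tau_d) is directly the relative se of tau_d
  rel_se <- if (is.null(cov)) Inf else sqrt(abs(cov[1L, 1L]))
  d_um2_min <- w0^2 / (4 * tau_d) * 60
  list(d = d_um2_min, tau_d = tau_d, intercept = g0, rel_se = rel_se,
       outlier_flag = rel_se > 0.5 || g0 > 1.01)
}

#' Remove isolated outliers from a repeated-measurement series
#'
#' An interior point is removed when its relative difference to both
#' neighbours exceeds 50% (relative to the neighbour's value). Endpoints are
#' kept.
#'
#' @param x Numeric series (length >= 3).
#' @return List with `filtered` (values kept) and `removed` (indices
#'   removed).
#' @export
neighbor_outlier_filter <- function(x) {
  if (length(x) < 3L) stop("series must have at least 3 points", call. = FALSE)
  rel <- function(a, b) abs(a - b) / abs(b)
  removed <- integer(0)
  for (i in 2:(length(x) - 1L)) {
    if (rel(x[i], x[i - 1L]) > 0.5 && rel(x[i], x[i + 1L]) > 0.5)
      removed <- c(removed, i)
  }
  list(filtered = if (length(removed)) x[-removed] else x, removed = removed)
}
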