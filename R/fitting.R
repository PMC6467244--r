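#' Observation tables
#'
#' Per-cell observations used for fitting: each record carries a growth rate
#' `s_vol`, an observed `value`, an uncertainty `sigma` (NA allowed when raw
#' weighting is used), a `kind` (`"budding_volume_fl"` or
#' `"diffusion_um2_min"`) and, for diffusion records, the cell volume `vol`
#' (fl) at which the diffusion coefficient was measured.
#'
#' @param s_vol,value,sigma,kind,vol Column vectors (recycled where scalar).
#' @return Data frame of class `obs_table`.
#' @export
observation_table <- function(s_vol, value, sigma = NA_real_, kind, vol = NA_real_) {
  d <- data.frame(s_vol = s_vol, value = value, sigma = sigma,
                  kind = kind, vol = vol)
  bad <- !d$kind %in% c("budding_volume_fl", "diffusion_um2_min")
  if (any(bad)) stop("unknown observation kind: ", unique(d$kind[bad]),
                     call. = FALSE)
  if (any(d$s_vol <= 0)) stop("s_vol must be positive", call. = FALSE)
  if (any(!is.na(d$sigma) & d$sigma <= 0))
    stop("sigma must be positive when given", call. = FALSE)
  if (any(d$kind == "diffusion_um2_min" & !is.finite(d$vol)))
    stop("diffusion records require a volume", call. = FALSE)
  class(d) <- c("obs_table", "data.frame")
  d
}

#' Read / write observation tables as CSV
#'
#' CSV dialect: header `s_vol, value, sigma, kind, vol`.
#'
#' @param data An `obs_table`.
#' @param path File path.
#' @return `write_observations` returns `path` invisibly; `read_observations`
#'   returns an `obs_table`.
#' @export
write_observations <- function(data, path) {
  utils::write.csv(as.data.frame(data)[, c("s_vol", "value", "sigma", "kind", "vol")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  observation_table(d$s_vol, d$value, d$sigma, d$kind, d$vol)
}

# Residual scale per record: sigma when available and requested, otherwise the
# data mean of the record's observable kind (keeps fl^2 and (um^2/min)^2 terms
# commensurate); "raw" mode uses scale 1 (plain squared sums).
residual_scales <- function(data, weighting) {
  if (weighting == "raw") return(rep(1, nrow(data)))
  sc <- data$sigma
  for (k in unique(data$kind)) {
    idx <- data$kind == k & !is.finite(sc)
    if (any(idx)) sc[idx] <- mean(abs(data$value[data$kind == k]))
  }
  sc
}

# Penalty residual magnitude for records whose model evaluation is infeasible
# (threshold not reached, steady-state failure): large but finite so samplers
# and optimizers keep moving.
penalty_residual <- function(scale) 1e6

# Signed residual vector (observed - simulated)/scale over all records.
combined_residuals <- function(theta, data, cfg = start_config(),
                               base = param_set_3114(),
                               weighting = c("sigma", "raw")) {
  weighting <- match.arg(weighting)
  pars <- set_free_params(base, theta)
  # a tight bisection tolerance keeps the loss surface smooth for
  # finite-difference Jacobians and samplers
  cfg_fit <- cfg
  cfg_fit$tol <- min(cfg$tol, 1e-8)
  sc <- residual_scales(data, weighting)
  # critical volume depends only on s_vol; diffusion on (s_vol, vol)
  r <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    sim <- tryCatch({
      if (data$kind[i] == "budding_volume_fl") {
        critical_volume(pars, data$s_vol[i], cfg_fit)
      } else {
        st <- steady_state_exact(params_mut(pars, s_prot = data$s_vol[i],
                                            vol = data$vol[i]))
        dsim(st)
      }
    }, error = function(e) NA_real_)
    r[i] <- if (is.finite(sim)) (data$value[i] - sim) / sc[i]
            else penalty_residual(sc[i])
  }
  r
}

#' Budding-volume and diffusion loss functions
#'
#' `loss_budding` is the sum of squared differences between observed budding
#' volumes and the model critical volume at each record's growth rate;
#' `loss_diffusion` is the analogous sum over diffusion records comparing the
#' observed coefficient with the weighted-average diffusion observable at
#' steady state. In the default `"sigma"` weighting each residual is divided
#' by its uncertainty (or by the data mean of its observable when sigma is
#' absent); `"raw"` reproduces unnormalized squared residuals. Records whose
#' simulation is infeasible contribute a large finite penalty.
#'
#' @param theta Named free-parameter vector (natural scale): any of `s_cln3`,
#'   `s_ydj1`, `kd_protU`, `kb`, `kr`.
#' @param data An [observation_table()].
#' @param cfg A [start_config()].
#' @param base Parameter set supplying the non-free fields.
#' @param weighting `"sigma"` (default) or `"raw"`.
#' @return Scalar loss.
#' @export
loss_budding <- function(theta, data, cfg = start_config(),
                         base = param_set_3114(),
                         weighting = c("sigma", "raw")) {
  d <- data[data$kind == "budding_volume_fl", , drop = FALSE]
  if (nrow(d) == 0L) stop("no budding-volume records", call. = FALSE)
  sum(combined_residuals(theta, d, cfg, base, match.arg(weighting))^2)
}

#' @rdname loss_budding
#' @export
loss_diffusion <- function(theta, data, cfg = start_config(),
                           base = param_set_3114(),
                           weighting = c("sigma", "raw")) {
  d <- data[data$kind == "diffusion_um2_min", , drop = FALSE]
  if (nrow(d) == 0L) stop("no diffusion records", call. = FALSE)
  sum(combined_residuals(theta, d, cfg, base, match.arg(weighting))^2)
}

#' Combined point estimation of the five free parameters
#'
#' Minimizes the combined budding-volume plus diffusion loss with the
#' Levenberg-Marquardt algorithm ([minpack.lm::nls.lm()]) over the free
#' parameters in log10 space, box-constrained to the fitted ranges.
#'
#' @param theta0 Named starting vector (natural scale, all five free
#'   parameters).
#' @param data An [observation_table()] containing both record kinds.
#' @param cfg A [start_config()].
#' @param base Parameter set supplying the non-free fields.
#' @param weighting Residual weighting mode.
#' @param maxiter Maximum LM iterations.
#' @return List with elements `theta` (natural scale), `loss`, `converged`,
#'   `niter`, `message` and `jacobian_condition` (condition number of the
#'   final residual Jacobian).
#' @export
fit_point <- function(theta0, data, cfg = start_config(),
                      base = param_set_3114(),
                      weighting = c("sigma", "raw"), maxiter = 50L) {
  weighting <- match.arg(weighting)
  b <- free_param_bounds()
  nm <- free_param_names()
  theta0 <- theta0[nm]
  if (any(theta0 < b["lower", ] | theta0 > b["upper", ]))
    stop("theta0 outside fitted bounds", call. = FALSE)
  fn <- function(lt) {
    th <- 10^lt
    names(th) <- nm
    combined_residuals(th, data, cfg, base, weighting)
  }
  fit <- minpack.lm::nls.lm(par = log10(theta0), lower = log10(b["lower", ]),
                            upper = log10(b["upper", ]), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-12, ptol = 1e-10,
                              epsfcn = 1e-6))
  theta <- 10^fit$par
  names(theta) <- nm
  jc <- tryCatch(kappa(fit$hessian), error = function(e) NA_real_)
  list(theta = theta, loss = fit$deviance,
       converged = fit$info %in% 1:4, niter = fit$niter,
       message = fit$message, jacobian_condition = jc)
}

#' Hill-equation binding fit
#'
#' Fits `y = x^n / (T^n + x^n)` by least squares and reports the Hill
#' coefficient `n`, the half-saturation `T` and the dissociation constant
#' `Kd = T^n`.
#'
#' @param x Positive concentrations.
#' @param y Bound fractions in `[0, 1)`.
#' @return List with elements `n`, `T`, `kd`.
#' @export
hill_fit <- function(x, y) {
  if (any(x <= 0)) stop("x must be positive", call. = FALSE)
  if (any(y < 0 | y >= 1)) stop("y must lie in [0, 1)", call. = FALSE)
  if (stats::sd(y) < 1e-12)
    stop("fit failure: response is constant (non-identifiable)", call. = FALSE)
  fn <- function(p) y - x^exp(p[1]) / (exp(p[2])^exp(p[1]) + x^exp(p[1]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(0, log(stats::median(x))), fn = fn),
    error = function(e) stop("fit failure: ", conditionMessage(e), call. = FALSE))
  if (fit$deviance > max(1e-6, 0.5 * sum((y - mean(y))^2)) &&
      kappa(fit$hessian) > 1e12)
    stop("fit failure: non-identifiable Hill parameters", call. = FALSE)
  n <- exp(fit$par[1]); Tt <- exp(fit$par[2])
  list(n = n, T = Tt, kd = Tt^n)
}
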