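#' Cycloheximide (CHX) protocol
#'
#' Translation inhibition is modelled as a sustained fold-reduction of the
#' three synthesis densities (`s_prot`, `s_cln3`, `s_ydj1`) applied at t = 0.
#' Canonical fold factors bracket the experimentally measured 5.9-fold
#' synthesis decrease: 3, 4.5, 6, 9 and 12.
#'
#' @param fold Synthesis reduction factor (>= 1).
#' @param duration Simulation window (seconds).
#' @return List of class `chx_protocol`.
#' @export
chx_protocol <- function(fold = 6, duration = 3600) {
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  structure(list(fold = fold, duration = duration), class = "chx_protocol")
}

#' Stress protocol
#'
#' A stress event transfers a fraction of the folded pools (`prot_f` ->
#' `prot_u` and, unless `transfer_cln3 = FALSE`, `cln3_f` -> `cln3_u`) to the
#' unfolded population at t = 0, and multiplies the Ydj1 synthesis density by
#' `ydj1_synth_factor` for the rest of the window (1.0 for salt stress, 2.9
#' for heat stress, which up-regulates Ydj1 transcription). In
#' `mode = "independent"` Cln3 folding is served by a private duplicate Ydj1
#' pool not loaded by bulk protein, removing cross-competition.
#'
#' @param unfold_fraction Fraction of the folded pools unfolded at t = 0
#'   (canonical grid 0.2-0.8).
#' @param ydj1_synth_factor Multiplier on `s_ydj1` (> 0).
#' @param duration Simulation window (seconds).
#' @param mode `"competing"` (shared chaperone pool) or `"independent"`.
#' @param transfer_cln3 Also transfer folded Cln3 (default TRUE); FALSE
#'   restricts the transfer to bulk protein for sensitivity checks.
#' @return List of class `stress_protocol`.
#' @export
stress_protocol <- function(unfold_fraction, ydj1_synth_factor = 1,
                            duration = 7200,
                            mode = c("competing", "independent"),
                            transfer_cln3 = TRUE) {
  if (unfold_fraction < 0 || unfold_fraction > 1)
    stop("unfold_fraction must lie in [0, 1]", call. = FALSE)
  if (ydj1_synth_factor <= 0)
    stop("ydj1_synth_factor must be positive", call. = FALSE)
  structure(list(unfold_fraction = unfold_fraction,
                 ydj1_synth_factor = ydj1_synth_factor,
                 duration = duration, mode = match.arg(mode),
                 transfer_cln3 = transfer_cln3),
            class = "stress_protocol")
}

#' Simulate a cycloheximide treatment
#'
#' Starts from the pre-perturbation steady state of `params`, divides the
#' three synthesis densities by `protocol$fold` at t = 0 and integrates the
#' model over `times`.
#'
#' @param params A `chap_params` object.
#' @param protocol A [chx_protocol()].
#' @param times Output time grid (seconds); defaults to 200 points over the
#'   protocol duration.
#' @return A `chap_trajectory` with additional columns `dsim` and
#'   `cln3_f_rel` (folded Cln3 normalized to its pre-perturbation steady
#'   state).
#' @export
simulate_chx <- function(params, protocol = chx_protocol(), times = NULL) {
  stopifnot(inherits(protocol, "chx_protocol"))
  if (is.null(times)) times <- seq(0, protocol$duration, length.out = 200L)
  ss0 <- steady_state(params)
  reduced <- params_with(params,
                         s_prot = params$s_prot / protocol$fold,
                         s_cln3 = params$s_cln3 / protocol$fold,
                         s_ydj1 = params$s_ydj1 / protocol$fold)
  tr <- if (length(times) > 1L) integrate_model(reduced, ss0, times) else {
    d <- as.data.frame(as.list(ss0)); cbind(time_s = times, d)
  }
  annotate_trajectory(tr, ss0)
}

annotate_trajectory <- function(tr, ss0) {
  tr$dsim <- apply(tr[, state_names()], 1L, function(r) dsim(r))
  tr$cln3_f_rel <- tr$cln3_f / ss0[["cln3_f"]]
  attr(tr, "pre_steady_state") <- ss0
  class(tr) <- c("chap_trajectory", "data.frame")
  tr
}

# Independent-scenario dynamics: the Cln3 branch uses a private duplicate of
# the Ydj1 pool with identical parameters and no bulk-protein load, while the
# bulk branch keeps its own pool. State: the 7 shared names plus ydj1_a2 (the
# private pool). Bulk species interact with ydj1_a only; Cln3 species with
# ydj1_a2 only.
rhs_independent <- function(state, p) {
  a <- p$kb / p$vol
  P <- state[["prot_u"]]; YP <- state[["yp"]]; PF <- state[["prot_f"]]
  C <- state[["cln3_u"]]; YC <- state[["yc"]]; CF <- state[["cln3_f"]]
  Y <- state[["ydj1_a"]]; Y2 <- state[["ydj1_a2"]]
  c(prot_u = p$s_prot * p$vol - a * P * Y - p$kd_protU * P + p$kd_ydj1 * YP,
    yp     = a * P * Y - (p$kr + p$kd_ydj1 + p$kd_protU) * YP,
    prot_f = p$kr * YP - p$beta * p$kd_protU * PF,
    cln3_u = p$s_cln3 * p$vol - a * C * Y2 - p$kd_cln3U * C + p$kd_ydj1 * YC,
    yc     = a * C * Y2 - (p$kr + p$kd_ydj1 + p$kd_cln3U) * YC,
    cln3_f = p$kr * YC - p$kd_cln3F * CF,
    ydj1_a = p$s_ydj1 * p$vol - a * P * Y + p$kr * YP - p$kd_ydj1 * Y +
      p$kd_protU * YP,
    ydj1_a2 = p$s_ydj1 * p$vol - a * C * Y2 + p$kr * YC - p$kd_ydj1 * Y2 +
      p$kd_cln3U * YC)
}

steady_state_independent <- function(params) {
  # bulk branch: exact reduction with the Cln3 load removed; Cln3 branch:
  # exact reduction with the bulk load removed.
  bulk <- steady_state(params_with(params, s_cln3 = 0))
  cln  <- steady_state(params_with(params, s_prot = 0))
  s <- c(prot_u = bulk[["prot_u"]], yp = bulk[["yp"]], prot_f = bulk[["prot_f"]],
         cln3_u = cln[["cln3_u"]], yc = cln[["yc"]], cln3_f = cln[["cln3_f"]],
         ydj1_a = bulk[["ydj1_a"]], ydj1_a2 = cln[["ydj1_a"]])
  s
}

#' Simulate a stress event
#'
#' Starts from the pre-stress steady state, instantaneously transfers
#' `unfold_fraction` of the folded pools to the unfolded pools (conserving
#' totals), applies the Ydj1 synthesis multiplier and integrates. In the
#' independent mode the Cln3 branch is folded by a private duplicate chaperone
#' pool (see [stress_protocol()]); the returned normalized Cln3F refers to the
#' scenario's own pre-stress steady state.
#'
#' @param params A `chap_params` object.
#' @param protocol A [stress_protocol()].
#' @param times Output time grid (seconds).
#' @return A `chap_trajectory` with `dsim` and `cln3_f_rel` columns. For the
#'   independent mode `dsim` refers to the bulk-serving pool.
#' @export
simulate_stress <- function(params, protocol, times = NULL) {
  stopifnot(inherits(protocol, "stress_protocol"))
  if (is.null(times)) times <- seq(0, protocol$duration, length.out = 200L)
  stressed <- params_with(params,
                          s_ydj1 = params$s_ydj1 * protocol$ydj1_synth_factor)
  frac <- protocol$unfold_fraction
  if (protocol$mode == "competing") {
    ss0 <- steady_state(params)
    y0 <- ss0
    y0[["prot_u"]] <- y0[["prot_u"]] + frac * y0[["prot_f"]]
    y0[["prot_f"]] <- (1 - frac) * y0[["prot_f"]]
    if (protocol$transfer_cln3) {
      y0[["cln3_u"]] <- y0[["cln3_u"]] + frac * y0[["cln3_f"]]
      y0[["cln3_f"]] <- (1 - frac) * y0[["cln3_f"]]
    }
    tr <- integrate_model(stressed, y0, times)
    return(annotate_trajectory(tr, ss0))
  }
  ss0 <- steady_state_independent(params)
  y0 <- ss0
  y0[["prot_u"]] <- y0[["prot_u"]] + frac * y0[["prot_f"]]
  y0[["prot_f"]] <- (1 - frac) * y0[["prot_f"]]
  if (protocol$transfer_cln3) {
    y0[["cln3_u"]] <- y0[["cln3_u"]] + frac * y0[["cln3_f"]]
    y0[["cln3_f"]] <- (1 - frac) * y0[["cln3_f"]]
  }
  f <- function(t, y, parms) list(rhs_independent(y, parms))
  out <- deSolve::ode(y = y0, times = times, func = f, parms = stressed,
                      rtol = 1e-8, atol = 1e-10)
  tr <- as.data.frame(out)
  names(tr)[1L] <- "time_s"
  vals <- as.matrix(tr[, c(state_names(), "ydj1_a2")])
  vals[vals < 0 & vals > -1e-8] <- 0
  tr[, c(state_names(), "ydj1_a2")] <- vals
  tr$dsim <- apply(tr[, state_names()], 1L, function(r) dsim(r))
  tr$cln3_f_rel <- tr$cln3_f / ss0[["cln3_f"]]
  attr(tr, "pre_steady_state") <- ss0
  class(tr) <- c("chap_trajectory", "data.frame")
  tr
}

#' Fit the stress time scale and unfolding fraction to mobility data
#'
#' For each candidate unfolding fraction, simulates the stress response,
#' fits a single time-scale factor `tau` (model seconds per experimental
#' minute: the mobility value at experimental time t is the model diffusion
#' observable at model time `tau * t`) by least squares on log mobility
#' (matching the multiplicative error structure of diffusion measurements),
#' and returns the candidate with the smallest sum of squared errors. The
#' time-scale search scans a coarse logarithmic grid before local refinement,
#' so secondary minima in tau do not distort the fraction comparison.
#'
#' @param params A `chap_params` object.
#' @param mobility_data Data frame with columns `time` (minutes) and `d`
#'   (um^2/min), spanning the drop and recovery (>= 4 points).
#' @param candidate_fractions Grid of unfolding fractions (default
#'   `c(0.2, 0.4, 0.6, 0.8)`).
#' @param ydj1_synth_factor Ydj1 synthesis multiplier of the stress being
#'   fitted (1 salt, 2.9 heat).
#' @param tau_range Search interval for `tau` (model s per experimental min).
#' @return List with `fraction`, `tau`, `sse` for the best candidate and a
#'   data frame `grid` with the per-candidate results.
#' @export
fit_stress_timescale <- function(params, mobility_data,
                                 candidate_fractions = c(0.2, 0.4, 0.6, 0.8),
                                 ydj1_synth_factor = 1,
                                 tau_range = c(10, 3000)) {
  if (nrow(mobility_data) < 4L)
    stop("mobility series must have at least 4 points", call. = FALSE)
  if (stats::sd(mobility_data$d) < 1e-12)
    stop("fit failure: mobility series is constant", call. = FALSE)
  if (any(mobility_data$d <= 0))
    stop("mobility values must be positive", call. = FALSE)
  tmax_min <- max(mobility_data$time)
  grid <- lapply(candidate_fractions, function(frac) {
    prot <- stress_protocol(frac, ydj1_synth_factor,
                            duration = tau_range[2] * tmax_min)
    # log-spaced grid: the sequestration transient is fast (seconds) while the
    # recovery is slow (minutes-hours of model time)
    times <- c(0, 10^seq(-2, log10(prot$duration), length.out = 500L))
    tr <- simulate_stress(params, prot, times = times)
    dfun <- stats::approxfun(tr$time_s, tr$dsim, rule = 2)
    sse_of <- function(log_tau)
      sum((log(mobility_data$d) - log(dfun(exp(log_tau) * mobility_data$time)))^2)
    lts <- seq(log(tau_range[1]), log(tau_range[2]), length.out = 60L)
    vals <- vapply(lts, sse_of, numeric(1))
    i <- which.min(vals)
    opt <- stats::optimize(sse_of, c(lts[max(1L, i - 1L)],
                                     lts[min(length(lts), i + 1L)]))
    data.frame(fraction = frac, tau = exp(opt$minimum), sse = opt$objective)
  })
  grid <- do.call(rbind, grid)
  best <- grid[which.min(grid$sse), ]
  list(fraction = best$fraction, tau = best$tau, sse = best$sse, grid = grid)
}
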