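#' @details
#' The core model tracks seven molecular-count state variables: unfolded bulk
#' protein (`prot_u`), Ydj1-bound bulk protein (`yp`), folded bulk protein
#' (`prot_f`), unfolded Cln3 (`cln3_u`), Ydj1-bound Cln3 (`yc`), folded Cln3
#' (`cln3_f`) and free available Ydj1 (`ydj1_a`). Synthesis (zero-order) terms
#' scale with cell volume and binding (second-order) terms scale with 1/volume
#' because states are counts, not concentrations.
#' @keywords internal
"_PACKAGE"

state_names <- function() {
  c("prot_u", "yp", "prot_f", "cln3_u", "yc", "cln3_f", "ydj1_a")
}

#' Construct a model state
#'
#' @param prot_u,yp,prot_f,cln3_u,yc,cln3_f,ydj1_a Molecule counts
#'   (continuous, non-negative).
#' @return Named numeric vector of class `chap_state`.
#' @export
chap_state <- function(prot_u = 0, yp = 0, prot_f = 0, cln3_u = 0, yc = 0,
                       cln3_f = 0, ydj1_a = 0) {
  s <- c(prot_u = prot_u, yp = yp, prot_f = prot_f, cln3_u = cln3_u,
         yc = yc, cln3_f = cln3_f, ydj1_a = ydj1_a)
  if (any(!is.finite(s))) stop("state components must be finite", call. = FALSE)
  if (any(s < 0)) stop("state components must be non-negative", call. = FALSE)
  class(s) <- "chap_state"
  s
}

as_chap_state <- function(x) {
  s <- x[state_names()]
  class(s) <- "chap_state"
  s
}

#' Total Ydj1 and total Cln3 of a state
#'
#' `ydj1_total` sums free Ydj1 and both client complexes; `cln3_total` sums
#' unfolded, Ydj1-bound and folded Cln3.
#'
#' @param state Named state vector (see [chap_state()]).
#' @return Numeric scalar.
#' @export
ydj1_total <- function(state) {
  unname(state[["ydj1_a"]] + state[["yp"]] + state[["yc"]])
}

#' @rdname ydj1_total
#' @export
cln3_total <- function(state) {
  unname(state[["cln3_u"]] + state[["yc"]] + state[["cln3_f"]])
}

#' Time derivatives of the competition model
#'
#' Evaluates the right-hand side of the seven coupled rate equations. Binding
#' of unfolded clients to free Ydj1 is second order and scaled by 1/vol;
#' synthesis is zero order and scaled by vol; complexes decay with the rates
#' of both partners, the chaperone moiety being returned to the free pool when
#' the client is degraded.
#'
#' @param state Named non-negative state vector.
#' @param params A `chap_params` object.
#' @return Named numeric vector of derivatives (molecules s^-1).
#' @export
model_rhs <- function(state, params) {
  stopifnot(inherits(params, "chap_params"))
  if (any(!is.finite(state))) stop("non-finite state component", call. = FALSE)
  p <- params
  a <- p$kb / p$vol
  P <- state[["prot_u"]]; YP <- state[["yp"]]; PF <- state[["prot_f"]]
  C <- state[["cln3_u"]]; YC <- state[["yc"]]; CF <- state[["cln3_f"]]
  Y <- state[["ydj1_a"]]
  c(prot_u = p$s_prot * p$vol - a * P * Y - p$kd_protU * P + p$kd_ydj1 * YP,
    yp     = a * P * Y - (p$kr + p$kd_ydj1 + p$kd_protU) * YP,
    prot_f = p$kr * YP - p$beta * p$kd_protU * PF,
    cln3_u = p$s_cln3 * p$vol - a * C * Y - p$kd_cln3U * C + p$kd_ydj1 * YC,
    yc     = a * C * Y - (p$kr + p$kd_ydj1 + p$kd_cln3U) * YC,
    cln3_f = p$kr * YC - p$kd_cln3F * CF,
    ydj1_a = p$s_ydj1 * p$vol - a * P * Y - a * C * Y + p$kr * (YP + YC) -
      p$kd_ydj1 * Y + p$kd_cln3U * YC + p$kd_protU * YP)
}

# Analytic Jacobian of model_rhs with respect to the state; used by the stiff
# integrator and the Newton polish.
model_jacobian <- function(state, params) {
  p <- params
  a <- p$kb / p$vol
  P <- state[["prot_u"]]; C <- state[["cln3_u"]]; Y <- state[["ydj1_a"]]
  dP <- p$kr + p$kd_ydj1 + p$kd_protU
  dC <- p$kr + p$kd_ydj1 + p$kd_cln3U
  J <- matrix(0, 7, 7, dimnames = list(state_names(), state_names()))
  J["prot_u", "prot_u"] <- -a * Y - p$kd_protU
  J["prot_u", "yp"]     <- p$kd_ydj1
  J["prot_u", "ydj1_a"] <- -a * P
  J["yp", "prot_u"] <- a * Y
  J["yp", "yp"]     <- -dP
  J["yp", "ydj1_a"] <- a * P
  J["prot_f", "yp"]     <- p$kr
  J["prot_f", "prot_f"] <- -p$beta * p$kd_protU
  J["cln3_u", "cln3_u"] <- -a * Y - p$kd_cln3U
  J["cln3_u", "yc"]     <- p$kd_ydj1
  J["cln3_u", "ydj1_a"] <- -a * C
  J["yc", "cln3_u"] <- a * Y
  J["yc", "yc"]     <- -dC
  J["yc", "ydj1_a"] <- a * C
  J["cln3_f", "yc"]     <- p$kr
  J["cln3_f", "cln3_f"] <- -p$kd_cln3F
  J["ydj1_a", "prot_u"] <- -a * Y
  J["ydj1_a", "yp"]     <- p$kr + p$kd_protU
  J["ydj1_a", "cln3_u"] <- -a * Y
  J["ydj1_a", "yc"]     <- p$kr + p$kd_cln3U
  J["ydj1_a", "ydj1_a"] <- -a * (P + C) - p$kd_ydj1
  J
}

#' Integrate the model
#'
#' Solves the rate equations with [deSolve::ode()] (`lsoda`, which switches
#' between stiff and non-stiff methods) using the analytic Jacobian. Small
#' negative solver undershoots (above -1e-8) are clipped to zero with a
#' warning; larger negative excursions raise an error.
#'
#' @param params A `chap_params` object.
#' @param initial Named non-negative initial state.
#' @param times Strictly increasing vector of output times (seconds).
#' @param rtol,atol Solver tolerances.
#' @return A `chap_trajectory`: data frame with columns `time_s` and the seven
#'   state variables.
#' @export
integrate_model <- function(params, initial, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "chap_params"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(initial)) || any(initial < 0))
    stop("initial state must be finite and non-negative", call. = FALSE)
  y0 <- as.numeric(initial[state_names()])
  names(y0) <- state_names()
  f <- function(t, y, parms) list(model_rhs(y, parms))
  jac <- function(t, y, parms) model_jacobian(y, parms)
  out <- deSolve::ode(y = y0, times = times, func = f, parms = params,
                      jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed; last valid time ", max(out[, "time"]),
         call. = FALSE)
  m <- as.data.frame(out)
  names(m)[1L] <- "time_s"
  vals <- as.matrix(m[, state_names()])
  if (any(vals < -1e-8))
    stop("integrator produced strongly negative state (< -1e-8)", call. = FALSE)
  if (any(vals < 0)) {
    warning("small negative solver undershoot clipped to 0")
    vals[vals < 0] <- 0
    m[, state_names()] <- vals
  }
  class(m) <- c("chap_trajectory", "data.frame")
  m
}

# Exact steady state reduced to one scalar equation in free Ydj1.
#
# At steady state the complex balances give yp = a*P*Y/dP and yc = a*C*Y/dC
# (a = kb/vol, dX = kr + kd_ydj1 + kd_clientU). Substituting into the client
# balances yields P and C explicitly as functions of Y, and the Ydj1
# conservation law Y + yp + yc = s_ydj1*vol/kd_ydj1 becomes a monotone scalar
# equation g(Y) = 0 on [0, total].
steady_state_exact <- function(params) {
  p <- params
  kb <- p$kb; kr <- p$kr; vol <- p$vol
  sP <- p$s_prot; sC <- p$s_cln3; sY <- p$s_ydj1
  kdP <- p$kd_protU; kdCU <- p$kd_cln3U; kdCF <- p$kd_cln3F
  kdY <- p$kd_ydj1; beta <- p$beta
  tot <- sY * vol / kdY
  a <- kb / vol
  dP <- kr + kdY + kdP
  dC <- kr + kdY + kdCU
  # scalar balance g(Y) = Y + a*Y*(P(Y)/dP + C(Y)/dC) - tot with
  # P(Y) = sP*vol/(kdP + alP*Y), C(Y) = sC*vol/(kdCU + alC*Y);
  # g is strictly increasing on [0, tot], solved by safeguarded Newton
  alP <- (kr + kdP) * a / dP
  alC <- (kr + kdCU) * a / dC
  cP <- a * sP * vol / dP
  cC <- a * sC * vol / dC
  if (tot == 0) {
    Y <- 0
  } else {
    lo <- 0; hi <- tot
    Y <- tot / 2
    for (it in 1:100) {
      gv <- Y + cP * Y / (kdP + alP * Y) + cC * Y / (kdCU + alC * Y) - tot
      if (gv > 0) hi <- Y else lo <- Y
      if (abs(gv) <= 1e-13 * tot) break
      dg <- 1 + cP * kdP / (kdP + alP * Y)^2 + cC * kdCU / (kdCU + alC * Y)^2
      Yn <- Y - gv / dg
      Y <- if (Yn <= lo || Yn >= hi) (lo + hi) / 2 else Yn
    }
  }
  P <- sP * vol / (kdP + alP * Y)
  C <- sC * vol / (kdCU + alC * Y)
  YP <- a * P * Y / dP
  YC <- a * C * Y / dC
  c(prot_u = P, yp = YP, prot_f = kr * YP / (beta * kdP),
    cln3_u = C, yc = YC, cln3_f = kr * YC / kdCF, ydj1_a = Y)
}

# Damped Newton iterations on model_rhs = 0, projecting onto the non-negative
# orthant. Used both to polish the exact reduction and after long integration.
newton_polish <- function(state, params, max_iter = 25L) {
  s <- pmax(as.numeric(state[state_names()]), 0)
  names(s) <- state_names()
  tol <- function(s) 1e-12 * max(1, sqrt(sum(s^2)))
  for (i in seq_len(max_iter)) {
    f <- model_rhs(s, params)
    if (sqrt(sum(f^2)) <= tol(s)) break
    J <- model_jacobian(s, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    f0 <- sum(f^2)
    repeat {
      cand <- pmax(s + lam * step, 0)
      fc <- model_rhs(cand, params)
      if (sum(fc^2) < f0 || lam < 1e-4) break
      lam <- lam / 2
    }
    if (sum(fc^2) >= f0) break
    s <- cand
  }
  s
}

#' Steady state of the competition model
#'
#' The default `"exact"` method reduces the steady-state conditions to a
#' single monotone scalar equation in free Ydj1 (derived from the Ydj1
#' conservation law) solved by Brent's method, then polishes the full
#' seven-dimensional root by damped Newton iteration. The `"integrate"`
#' method follows the long-integration route: integrate from the all-zero
#' state to `t_end` (default 1e7 s), then apply the same Newton polish. Both
#' satisfy `||rhs|| <= 1e-9 * max(1, ||state||)`.
#'
#' @param params A `chap_params` object.
#' @param method `"exact"` (default) or `"integrate"`.
#' @param initial Initial state for the integration route (default all zero).
#' @param t_end Integration horizon (s) for the integration route.
#' @return Named steady-state vector (class `chap_state`).
#' @export
steady_state <- function(params, method = c("exact", "integrate"),
                         initial = NULL, t_end = 1e7) {
  stopifnot(inherits(params, "chap_params"))
  method <- match.arg(method)
  s <- if (method == "exact") {
    newton_polish(steady_state_exact(params), params)
  } else {
    y0 <- if (is.null(initial)) chap_state() else initial
    tr <- integrate_model(params, y0, c(0, 10^seq(0, log10(t_end), length.out = 40L)))
    newton_polish(as_chap_state(tr[nrow(tr), ]), params)
  }
  res <- model_rhs(s, params)
  if (sqrt(sum(res^2)) > 1e-9 * max(1, sqrt(sum(s^2))) || any(s < 0))
    stop("steady-state search failed to converge to a non-negative root",
         call. = FALSE)
  class(s) <- "chap_state"
  s
}

#' Simulated Ydj1 diffusion coefficient
#'
#' Weighted-average diffusion coefficient over the Ydj1 species: the free pool
#' diffuses at `d_free` and client-bound pools (`yp + yc`) at `d_bound`.
#' Defaults are the calibrated limits d_free = 30 um^2/min (free GFP corrected
#' by Stokes radius) and d_bound = 1 um^2/min (chaperone-sequestering AZC
#' treatment).
#'
#' @param state Named state vector with positive total Ydj1.
#' @param d_free,d_bound Diffusion coefficients (um^2/min).
#' @return Diffusion coefficient (um^2/min).
#' @export
dsim <- function(state, d_free = 30, d_bound = 1) {
  tot <- ydj1_total(state)
  if (tot <= 0) stop("diffusion undefined: total Ydj1 is zero", call. = FALSE)
  (state[["ydj1_a"]] / tot) * d_free +
    ((state[["yp"]] + state[["yc"]]) / tot) * d_bound
}

#' Write a trajectory or steady state to CSV
#'
#' @param x A `chap_trajectory` or a state vector.
#' @param path Output path; header is `time_s, prot_u, yp, prot_f, cln3_u,
#'   yc, cln3_f, ydj1_a`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  if (!is.data.frame(x)) {
    x <- as.data.frame(as.list(x[state_names()]))
    x <- cbind(time_s = 0, x)
  }
  utils::write.csv(x[, c("time_s", state_names())], path, row.names = FALSE)
  invisible(path)
}
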