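#' Posterior sampling with an affine-invariant ensemble sampler
#'
#' Samples the posterior of the five free parameters,
#' proportional to `exp(-(L1 + L2) / (2 * sigma^2))` under independent
#' log-uniform priors on the fitted ranges, using the Goodman-Weare stretch
#' move (the affine-invariant ensemble scheme popularized by emcee). Walkers
#' move in log10 parameter space; draws accumulate walker-by-walker within
#' each step, the first `burn_in` draws are discarded and `n_keep` draws are
#' retained by uniform thinning of the remainder.
#'
#' @param data An [observation_table()] with budding-volume and/or diffusion
#'   records.
#' @param cfg A [start_config()].
#' @param base Parameter set supplying the non-free fields.
#' @param n_walkers Number of walkers (ensemble size).
#' @param n_steps Number of ensemble steps; total draws are
#'   `n_walkers * n_steps`.
#' @param burn_in Draws discarded from the start of the flattened chain
#'   (default 3000).
#' @param n_keep Retained draws after thinning (default 1500).
#' @param seed Integer seed.
#' @param sigma Likelihood scale in normalized-residual space (default 1).
#' @param weighting Residual weighting mode, see [loss_budding()].
#' @param theta0 Named centre (natural scale) of the walker initialization
#'   ball; defaults to the log-midpoint of the fitted ranges.
#' @param init_spread Standard deviation (dex) of the initialization ball.
#' @param stretch Stretch-move scale parameter `a` (default 2).
#' @return A `posterior_ensemble`: list with `log10_theta` (n_keep x 5
#'   matrix), `loss`, `acceptance`, `seed`, `burn_in`, `n_keep`, `n_walkers`,
#'   `n_steps`.
#' @export
mcmc_sample <- function(data, cfg = start_config(), base = param_set_3114(),
                        n_walkers = 32L, n_steps = 200L, burn_in = 3000L,
                        n_keep = 1500L, seed = 1L, sigma = 1,
                        weighting = c("sigma", "raw"), theta0 = NULL,
                        init_spread = 0.05, stretch = 2) {
  weighting <- match.arg(weighting)
  total <- n_walkers * n_steps
  if (total <= burn_in + n_keep)
    stop("n_walkers * n_steps must exceed burn_in + n_keep", call. = FALSE)
  b <- log10(free_param_bounds())
  nm <- free_param_names()
  k <- length(nm)
  loss_of <- function(lt) {
    th <- 10^lt
    names(th) <- nm
    sum(combined_residuals(th, data, cfg, base, weighting)^2)
  }
  log_post <- function(lt) {
    if (any(lt < b["lower", ] | lt > b["upper", ])) return(-Inf)
    -loss_of(lt) / (2 * sigma^2)
  }
  centre <- if (is.null(theta0)) colMeans(b) else log10(theta0[nm])
  with_seed(seed, {
    pos <- matrix(stats::rnorm(n_walkers * k, mean = rep(centre, each = n_walkers),
                               sd = init_spread), n_walkers, k)
    pos <- pmin(pmax(pos, rep(b["lower", ], each = n_walkers)),
                rep(b["upper", ], each = n_walkers))
    lp <- apply(pos, 1L, log_post)
    chain <- matrix(NA_real_, total, k, dimnames = list(NULL, nm))
    chain_lp <- numeric(total)
    accepted <- 0L
    idx <- 0L
    for (step in seq_len(n_steps)) {
      for (w in seq_len(n_walkers)) {
        other <- sample(seq_len(n_walkers)[-w], 1L)
        z <- ((stretch - 1) * stats::runif(1) + 1)^2 / stretch
        prop <- pos[other, ] + z * (pos[w, ] - pos[other, ])
        lp_prop <- log_post(prop)
        log_ratio <- (k - 1) * log(z) + lp_prop - lp[w]
        if (is.finite(lp_prop) && log(stats::runif(1)) < log_ratio) {
          pos[w, ] <- prop
          lp[w] <- lp_prop
          accepted <- accepted + 1L
        }
        idx <- idx + 1L
        chain[idx, ] <- pos[w, ]
        chain_lp[idx] <- lp[w]
      }
    }
    acc <- accepted / total
    if (acc < 0.05)
      warning("low acceptance fraction (", signif(acc, 2), ")")
    keep_idx <- round(seq(burn_in + 1L, total, length.out = n_keep))
    structure(list(log10_theta = chain[keep_idx, , drop = FALSE],
                   loss = -2 * sigma^2 * chain_lp[keep_idx],
                   acceptance = acc, seed = seed, burn_in = burn_in,
                   n_keep = n_keep, n_walkers = n_walkers, n_steps = n_steps),
              class = "posterior_ensemble")
  })
}

#' Convert posterior draws to parameter sets
#'
#' @param ensemble A `posterior_ensemble`.
#' @param base Parameter set supplying the non-free fields.
#' @param which Row indices (default all retained draws).
#' @return List of `chap_params` objects.
#' @export
ensemble_params <- function(ensemble, base = param_set_3114(),
                            which = seq_len(nrow(ensemble$log10_theta))) {
  lapply(which, function(i) {
    th <- 10^ensemble$log10_theta[i, ]
    set_free_params(base, th)
  })
}

#' Write / read a posterior ensemble
#'
#' Draws are stored as JSON lines (one log10 parameter vector per line) next
#' to a summary JSON carrying losses, acceptance and sampling configuration.
#'
#' @param ensemble A `posterior_ensemble`.
#' @param path Path of the JSON-lines draw file; the summary is written to
#'   `<path>.summary.json`.
#' @return `write_posterior` returns `path` invisibly; `read_posterior`
#'   returns a `posterior_ensemble`.
#' @export
write_posterior <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ensemble$log10_theta)))
    writeLines(jsonlite::toJSON(as.list(ensemble$log10_theta[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  summ <- ensemble[setdiff(names(ensemble), "log10_theta")]
  jsonlite::write_json(summ, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  lines <- readLines(path)
  draws <- do.call(rbind, lapply(lines, function(l)
    unlist(jsonlite::fromJSON(l))))
  summ <- jsonlite::read_json(paste0(path, ".summary.json"),
                              simplifyVector = TRUE)
  structure(c(list(log10_theta = draws), summ), class = "posterior_ensemble")
}
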