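test_that("observation tables validate and round-trip through CSV", {
  expect_error(observation_table(0.1, 10, kind = "weight"), "unknown")
  expect_error(observation_table(-0.1, 10, kind = "budding_volume_fl"),
               "positive")
  expect_error(observation_table(0.1, 10, sigma = 0,
                                 kind = "budding_volume_fl"), "sigma")
  expect_error(observation_table(0.1, 10, kind = "diffusion_um2_min"),
               "volume")
  d <- small_obs_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(d, path)
  expect_equal(as.data.frame(read_observations(path)), as.data.frame(d),
               tolerance = 1e-12)
})

test_that("losses reduce to hand-summed squared residuals", {
  p <- param_set_3114()
  cfg <- start_config()
  truth <- truth_free_params()
  svals <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  # expected values at the tight tolerance the loss functions solve with
  cvs <- vapply(svals, function(s)
    critical_volume(p, s, start_config(tol = 1e-8)), numeric(1))
  # one record with residual 2 in raw mode
  one <- observation_table(0.1, cvs[3] + 2, kind = "budding_volume_fl")
  expect_equal(loss_budding(truth, one, cfg, weighting = "raw"), 4,
               tolerance = 1e-4)
  # five records: direct summation oracle
  resid <- c(1.5, -2, 0.5, 3, -1)
  tab <- observation_table(svals, cvs + resid, kind = "budding_volume_fl")
  expect_equal(loss_budding(truth, tab, cfg, weighting = "raw"), sum(resid^2),
               tolerance = 1e-4)
  # self-consistency: data generated from theta itself
  self <- observation_table(svals, cvs, kind = "budding_volume_fl")
  expect_lt(loss_budding(truth, self, cfg, weighting = "raw"), 1e-8)
  # diffusion records, same three patterns
  vols <- c(20, 35, 50, 65, 80)
  ds <- vapply(seq_along(svals), function(i)
    dsim(steady_state(chapcomp:::params_with(p, s_prot = svals[i],
                                             vol = vols[i]))), numeric(1))
  dtab <- observation_table(svals, ds + resid, kind = "diffusion_um2_min",
                            vol = vols)
  expect_equal(loss_diffusion(truth, dtab, weighting = "raw"), sum(resid^2),
               tolerance = 1e-6)
  dself <- observation_table(svals, ds, kind = "diffusion_um2_min", vol = vols)
  expect_lt(loss_diffusion(truth, dself, weighting = "raw"), 1e-10)
  # record order does not change the combined loss
  both <- rbind(tab, dtab)
  shuf <- both[c(7, 2, 9, 4, 1, 10, 3, 8, 5, 6), ]
  expect_equal(
    sum(chapcomp:::combined_residuals(truth, both, cfg, p, "raw")^2),
    sum(chapcomp:::combined_residuals(truth, shuf, cfg, p, "raw")^2),
    tolerance = 1e-12)
})

test_that("infeasible parameter vectors receive a finite penalty", {
  # at the lower s_cln3 bound Start is unreachable at high growth rate
  theta_bad <- truth_free_params()
  theta_bad["s_cln3"] <- 4.9e-2
  tab <- observation_table(0.3, 60, kind = "budding_volume_fl")
  l <- loss_budding(theta_bad, tab, weighting = "raw")
  expect_true(is.finite(l))
  expect_gt(l, 1e10)
})

test_that("point estimation recovers a planted truth", {
  truth <- truth_free_params()
  obs <- gen_growth_observations(
    synth_config(seed = 11, n_cells = 6, noise_cv = 0,
                 s_vol_range = obs_s_vol_range))
  fit <- fit_point(truth * 1.5, obs)
  expect_true(fit$converged)
  expect_true(all(abs(fit$theta / truth - 1) < 0.05))
  # starting exactly at the optimum stays there
  fit0 <- fit_point(fit$theta, obs)
  expect_true(all(abs(fit0$theta / fit$theta - 1) < 1e-3))
  expect_lte(fit0$niter, 5L)
  expect_error(fit_point(truth * 1e3, obs), "bounds")
})

test_that("the Hill binding fit recovers planted parameters and Kd = T^n", {
  x <- seq(0.1, 4, length.out = 12)
  h1 <- hill_fit(x, x / (1 + x))
  expect_equal(h1$kd, 1, tolerance = 1e-6)
  expect_equal(h1$n, 1, tolerance = 1e-6)
  y2 <- x^2 / (0.5^2 + x^2)
  h2 <- hill_fit(x, y2)
  expect_equal(h2$n, 2, tolerance = 1e-6)
  expect_equal(h2$T, 0.5, tolerance = 1e-6)
  expect_equal(h2$kd, 0.25, tolerance = 1e-6)
  expect_error(hill_fit(x, rep(0.4, 12)), "constant")
  expect_error(hill_fit(x, c(rep(0.5, 11), 1.2)), "\\[0, 1\\)")
  expect_error(hill_fit(c(-1, x[-1]), y2), "positive")
})

test_that("the ensemble sampler respects its configuration contract", {
  obs <- small_obs_table(seed = 3, n_cells = 3)
  truth <- truth_free_params()
  expect_error(mcmc_sample(obs, n_walkers = 8, n_steps = 10, burn_in = 100,
                           n_keep = 50), "exceed")
  e1 <- mcmc_sample(obs, n_walkers = 8L, n_steps = 25L, burn_in = 50L,
                    n_keep = 100L, seed = 4, theta0 = truth)
  e2 <- mcmc_sample(obs, n_walkers = 8L, n_steps = 25L, burn_in = 50L,
                    n_keep = 100L, seed = 4, theta0 = truth)
  expect_identical(e1$log10_theta, e2$log10_theta)
  expect_identical(nrow(e1$log10_theta), 100L)
  b <- log10(free_param_bounds())
  for (j in 1:5) {
    expect_true(all(e1$log10_theta[, j] >= b["lower", j] &
                      e1$log10_theta[, j] <= b["upper", j]))
  }
  # draws convert to valid parameter sets
  ps <- ensemble_params(e1, which = 1:5)
  expect_true(all(vapply(ps, inherits, logical(1), "chap_params")))
  # ensemble serialization round-trip
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_posterior(e1, path)
  back <- read_posterior(path)
  expect_equal(back$log10_theta, e1$log10_theta, ignore_attr = TRUE)
  expect_equal(back$acceptance, e1$acceptance)
})
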