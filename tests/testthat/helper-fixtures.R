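# Shared fixtures: the reference fitted parameter vector and small builders.

truth_free_params <- function() {
  c(s_cln3 = 0.126, s_ydj1 = 9.19e-4, kd_protU = 7.26e-2,
    kb = 0.891, kr = 0.388)
}

# Growth-rate span covered by the single-cell data the generators emulate;
# budding volumes are unobservable (beyond 100 fl) at higher rates.
obs_s_vol_range <- c(0.01, 0.4)

small_obs_table <- function(seed = 11L, n_cells = 6L, noise_cv = 0.05) {
  gen_growth_observations(synth_config(seed = seed, n_cells = n_cells,
                                       noise_cv = noise_cv,
                                       s_vol_range = obs_s_vol_range))
}

random_valid_params <- function() {
  b <- free_param_bounds()
  # keep draws in the central half of each log-range so steady states are
  # well-scaled
  th <- 10^(stats::runif(5, log10(b["lower", ]) * 0.75 + log10(b["upper", ]) * 0.25,
                         log10(b["lower", ]) * 0.25 + log10(b["upper", ]) * 0.75))
  names(th) <- colnames(b)
  set_free_params(param_set_3114(s_prot = stats::runif(1, 0.01, 1),
                                 vol = stats::runif(1, 10, 100)), th)
}
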