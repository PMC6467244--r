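#' Run the analysis pipeline
#'
#' Executes the requested stages in order against a single output directory.
#' Supported stages: `"synth"` (write synthetic observation tables),
#' `"fit"` (point estimation of the five free parameters from the observation
#' table), `"mcmc"` (posterior ensemble), `"predict"` (critical-volume and
#' diffusion response curves of the fitted parameters). Each stage reads and
#' writes only the documented CSV/JSON formats, and every run writes a
#' manifest recording the configuration, its hash, the seed and the package
#' version. Stages never mutate their inputs.
#'
#' @param config Named list with elements `stages` (character vector),
#'   `seed`, `out_dir`, and optional stage settings: `n_cells`, `noise_cv`,
#'   `s_vol_range` (synth; defaults to the span over which budding volumes
#'   are observable for the reference truth); `obs_file` (fit/mcmc, defaults
#'   to the synth output);
#'   `theta0` (fit start, natural scale); `weighting`; `n_walkers`,
#'   `n_steps`, `burn_in`, `n_keep` (mcmc); `s_vol_grid` (predict).
#' @return The output directory path, invisibly; artifacts are written inside
#'   it (`observations.csv`, `fit.json`, `posterior.jsonl`, `predict_*.csv`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  weighting <- config$weighting %||% "sigma"
  cfg_start <- start_config()
  obs_path <- config$obs_file %||% file.path(config$out_dir, "observations.csv")
  log_msg <- function(...) message("[chapcomp] ", ...)
  fit_res <- NULL
  for (stage in stages) {
    t0 <- Sys.time()
    switch(stage,
      synth = {
        sc <- synth_config(seed = config$seed,
                           n_cells = config$n_cells %||% 100L,
                           noise_cv = config$noise_cv %||% 0.1,
                           s_vol_range = config$s_vol_range %||% c(0.01, 0.4))
        obs <- gen_growth_observations(sc, cfg_start)
        write_observations(obs, obs_path)
        log_msg("synth: ", nrow(obs), " records -> ", obs_path)
      },
      fit = {
        if (!file.exists(obs_path))
          stop("stage 'fit' requires the observation file '", obs_path,
               "' (run 'synth' or set config$obs_file)", call. = FALSE)
        obs <- read_observations(obs_path)
        theta0 <- config$theta0 %||% {
          b <- free_param_bounds()
          10^colMeans(log10(b))
        }
        fit_res <- fit_point(theta0, obs, cfg_start, weighting = weighting)
        jsonlite::write_json(
          list(theta = as.list(fit_res$theta), loss = fit_res$loss,
               converged = fit_res$converged, niter = fit_res$niter),
          file.path(config$out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
        log_msg("fit: loss ", signif(fit_res$loss, 4), " in ", fit_res$niter,
                " iterations")
      },
      mcmc = {
        if (!file.exists(obs_path))
          stop("stage 'mcmc' requires the observation file '", obs_path, "'",
               call. = FALSE)
        obs <- read_observations(obs_path)
        theta0 <- if (!is.null(fit_res)) fit_res$theta else config$theta0
        ens <- mcmc_sample(obs, cfg_start, n_walkers = config$n_walkers %||% 32L,
                           n_steps = config$n_steps %||% 200L,
                           burn_in = config$burn_in %||% 3000L,
                           n_keep = config$n_keep %||% 1500L,
                           seed = config$seed, weighting = weighting,
                           theta0 = theta0)
        write_posterior(ens, file.path(config$out_dir, "posterior.jsonl"))
        log_msg("mcmc: acceptance ", signif(ens$acceptance, 3))
      },
      predict = {
        fit_file <- file.path(config$out_dir, "fit.json")
        theta <- if (!is.null(fit_res)) fit_res$theta
          else if (file.exists(fit_file))
            unlist(jsonlite::read_json(fit_file, simplifyVector = TRUE)$theta)
          else stop("stage 'predict' requires a prior 'fit' stage or fit.json",
                    call. = FALSE)
        pars <- set_free_params(param_set_3114(), theta)
        grid <- config$s_vol_grid %||% exp(seq(log(0.02), log(0.4), length.out = 12L))
        cv <- growth_rate_response(list(pars), grid, "critical_volume", cfg_start)
        di <- growth_rate_response(list(pars), grid, "dsim", cfg_start)
        utils::write.csv(cv, file.path(config$out_dir, "predict_critical_volume.csv"),
                         row.names = FALSE)
        utils::write.csv(di, file.path(config$out_dir, "predict_dsim.csv"),
                         row.names = FALSE)
        log_msg("predict: ", length(grid), " grid points")
      },
      stop("unknown stage '", stage, "'", call. = FALSE))
    log_msg(stage, " done in ",
            signif(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3), " s")
  }
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   config_hash = rlang::hash(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("chapcomp")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
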