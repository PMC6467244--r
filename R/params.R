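#' Model parameter set
#'
#' Construct a validated parameter set for the chaperone-competition model.
#' All rates are first-order rate constants in s^-1 unless noted; synthesis
#' terms are densities in molecules s^-1 fl^-1; `kb` is a second-order rate in
#' fl molecule^-1 s^-1; `vol` is the cell volume in fl, treated as a frozen
#' pseudo-parameter during simulations. The degradation rate of folded bulk
#' protein is derived as `beta * kd_protU` and is not a free field.
#'
#' @param kb Ydj1 binding rate (fl molecule^-1 s^-1).
#' @param kr Release-from-Ydj1 rate (s^-1).
#' @param s_prot Bulk protein synthesis density; equals the specific volume
#'   growth rate via the conversion factor `gamma` (fixed at 1).
#' @param s_cln3 Cln3 synthesis density.
#' @param s_ydj1 Ydj1 synthesis density.
#' @param kd_protU Unfolded bulk-protein degradation rate.
#' @param kd_cln3U Unfolded Cln3 degradation rate.
#' @param kd_cln3F Folded Cln3 degradation rate.
#' @param kd_ydj1 Ydj1 degradation rate.
#' @param beta Folded/unfolded bulk-protein degradation scaling, in (0, 1].
#' @param gamma Protein-synthesis-to-volume-growth conversion factor (fixed 1).
#' @param vol Cell volume (fl).
#' @return An object of class `chap_params` (a named list with the fields
#'   above plus the derived `kd_protF`).
#' @seealso [param_set_3114()], [param_defaults()]
#' @export
chap_params <- function(kb, kr, s_prot, s_cln3, s_ydj1, kd_protU,
                        kd_cln3U = 6.93e-2, kd_cln3F = 3.85e-2,
                        kd_ydj1 = 5.77e-3, beta = 0.01, gamma = 1,
                        vol = 50) {
  p <- list(kb = kb, kr = kr, s_prot = s_prot, s_cln3 = s_cln3,
            s_ydj1 = s_ydj1, kd_protU = kd_protU, kd_cln3U = kd_cln3U,
            kd_cln3F = kd_cln3F, kd_ydj1 = kd_ydj1, beta = beta,
            gamma = gamma, vol = vol)
  validate_params(p)
  p$kd_protF <- p$beta * p$kd_protU
  class(p) <- "chap_params"
  p
}

validate_params <- function(p) {
  num <- c("kb", "kr", "s_prot", "s_cln3", "s_ydj1", "kd_protU",
           "kd_cln3U", "kd_cln3F", "kd_ydj1", "beta", "gamma", "vol")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a finite numeric scalar", call. = FALSE)
  }
  pos <- setdiff(num, c("s_prot", "s_cln3", "s_ydj1"))
  for (f in pos) if (p[[f]] <= 0)
    stop("parameter '", f, "' must be strictly positive", call. = FALSE)
  for (f in c("s_prot", "s_cln3", "s_ydj1")) if (p[[f]] < 0)
    stop("parameter '", f, "' must be non-negative", call. = FALSE)
  if (p$beta > 1) stop("'beta' must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Default (fixed) model parameters
#'
#' Parameter set carrying the fixed degradation rates of the model
#' (`kd_cln3U` = 6.93e-2 s^-1, `kd_cln3F` = 3.85e-2 s^-1,
#' `kd_ydj1` = 5.77e-3 s^-1, `beta` = 0.01, `gamma` = 1) with caller-supplied
#' free parameters.
#'
#' @inheritParams chap_params
#' @return A `chap_params` object.
#' @export
param_defaults <- function(kb, kr, s_cln3, s_ydj1, kd_protU,
                           s_prot = 0.1, vol = 50) {
  chap_params(kb = kb, kr = kr, s_prot = s_prot, s_cln3 = s_cln3,
              s_ydj1 = s_ydj1, kd_protU = kd_protU, vol = vol)
}

#' Reference fitted parameter set ("set 3114")
#'
#' The minimal-loss parameter vector of the published ensemble, used for all
#' headline simulations: `s_cln3` = 0.126, `s_ydj1` = 9.19e-4 molec s^-1 fl^-1,
#' `kd_protU` = 7.26e-2 s^-1, `kb` = 0.891 fl molec^-1 s^-1, `kr` = 0.388 s^-1,
#' on top of the fixed rates of [param_defaults()].
#'
#' @param s_prot Protein synthesis density (controlled variable), default 0.1.
#' @param vol Cell volume (fl), default 50.
#' @return A `chap_params` object.
#' @export
param_set_3114 <- function(s_prot = 0.1, vol = 50) {
  param_defaults(kb = 0.891, kr = 0.388, s_cln3 = 0.126, s_ydj1 = 9.19e-4,
                 kd_protU = 7.26e-2, s_prot = s_prot, vol = vol)
}

#' Bounds of the five fitted parameters
#'
#' Lower and upper bounds (natural scale) of the free parameters used for
#' prior support and box constraints: `s_cln3` in [4.9e-2, 4.8],
#' `s_ydj1` in [4.8e-5, 6.0e-2], `kd_protU` in [6.4e-3, 31.5],
#' `kb` in [1.4e-2, 26.7], `kr` in [2.8e-3, 7.7].
#'
#' @return A 2 x 5 matrix with rows `lower`, `upper` and the free-parameter
#'   names as columns.
#' @export
free_param_bounds <- function() {
  m <- rbind(lower = c(s_cln3 = 4.9e-2, s_ydj1 = 4.8e-5, kd_protU = 6.4e-3,
                       kb = 1.4e-2, kr = 2.8e-3),
             upper = c(s_cln3 = 4.8, s_ydj1 = 6.0e-2, kd_protU = 31.5,
                       kb = 26.7, kr = 7.7))
  m
}

free_param_names <- function() colnames(free_param_bounds())

#' Insert free-parameter values into a parameter set
#'
#' @param base A `chap_params` object providing all other fields.
#' @param theta Named vector of the five free parameters on the natural scale
#'   (`s_cln3`, `s_ydj1`, `kd_protU`, `kb`, `kr`), or a subset.
#' @return A `chap_params` object.
#' @export
set_free_params <- function(base, theta) {
  stopifnot(inherits(base, "chap_params"))
  nm <- names(theta)
  if (is.null(nm) || !all(nm %in% free_param_names()))
    stop("theta must be named with free-parameter names", call. = FALSE)
  args <- unclass(base)
  args$kd_protF <- NULL
  args[nm] <- as.list(unname(theta))
  do.call(chap_params, args)
}

#' @export
print.chap_params <- function(x, ...) {
  cat("chaperone-competition parameter set\n")
  flds <- setdiff(names(x), "kd_protF")
  for (f in flds) cat(sprintf("  %-9s %g\n", f, x[[f]]))
  cat(sprintf("  %-9s %g (derived beta * kd_protU)\n", "kd_protF", x$kd_protF))
  invisible(x)
}

#' Read / write a parameter set as flat JSON
#'
#' The JSON object holds the constructor fields by name; the derived
#' `kd_protF` is omitted on write and ignored on read. The reader re-validates
#' all bounds.
#'
#' @param params A `chap_params` object.
#' @param path File path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns a `chap_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "chap_params"))
  x <- unclass(params)
  x$kd_protF <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$kd_protF <- NULL
  do.call(chap_params, x)
}
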