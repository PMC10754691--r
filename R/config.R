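# Run configuration: every physical constant, physiological input and
# solver setting in one overridable block.

#' Default run configuration
#'
#' Returns the full nested configuration used by [nose_model()] and
#' [run_case()]. Physiological defaults are the reference seal inputs
#' (tidal volume 6.3 L, cycle 3.09 s, body 36 C at 100% humidity, ambient
#' at 90% humidity, 10 um mucus lining, 180 kg body mass). Every value can
#' be overridden via `...` or with [modify_config()].
#'
#' @param ... named overrides applied on top of the defaults; nested lists
#'   are merged recursively (e.g. `solver = list(Ns = 12)` only replaces
#'   `Ns`).
#' @return a nested list of class `turbsim_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    ambient = list(T_C = -30, phi = 0.90),
    body    = list(T_C = 36, phi = 1.00),
    pattern = list(Vt = 6.3e-3, t_br = 3.09, M = 180,
                   pi_correction = FALSE),
    air     = list(p = 101325, cp_a = 1006, cp_v = 1907),
    mucus   = list(rho_m = 1000, cp_w = 4181, d_m = 1e-5),
    tissue  = list(rho_it = 1060, cp_it = 3600, d_it = 2e-4,
                   frac_art = 0.15, frac_ven = 0.15,
                   perim_frac_art = 0.2, perim_frac_ven = 0.2),
    blood   = list(rho_b = 1060, cp_b = 3850, F_blood = 5e-4),
    coeffs  = list(h_q_if = 150, k_w_if = 0.05, use_film = FALSE,
                   Nu = 7.54, Sh = 7.54, k_air = 0.0255, D_wv = 2.5e-5,
                   q_star = -2.4e5,
                   h_m_it = 500, h_it_art = 500, h_it_ven = 500),
    solver  = list(Ns = 24, rel_tol = 1e-5, abs_tol_T = 1e-4,
                   abs_tol_w = 1e-8, max_cycles = 400,
                   convergence_eps = 1e-4, n_monitor = 25, n_dense = 61))
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "turbsim_config"
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Modify a configuration
#'
#' @param cfg a configuration from [default_config()].
#' @param ... named overrides, merged recursively.
#' @return the modified configuration.
#' @export
modify_config <- function(cfg, ...) {
  out <- merge_config(unclass(cfg), list(...))
  class(out) <- "turbsim_config"
  out
}

#' Load a configuration from a YAML file
#'
#' Values in the file override the defaults; anything not given keeps its
#' default.
#'
#' @param path YAML file path.
#' @return a `turbsim_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  over <- yaml::read_yaml(path)
  out <- merge_config(unclass(default_config()), over)
  class(out) <- "turbsim_config"
  out
}

coeffs_from_config <- function(cfg) {
  do.call(transport_coefficients, cfg$coeffs)
}
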