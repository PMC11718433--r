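#' Kinetic and transport parameters for the pellet oxygen model
#'
#' Bundles all constants of the 1D spherical diffusion-consumption model:
#' bulk diffusivity and the hindrance exponent of the mycelial network,
#' hyphal dry-weight density, the oxygen-related biomass yield, Monod
#' constants for growth and maintenance, the critical concentration below
#' which no net biomass is formed, the maximum maintenance coefficient, and
#' the maximum specific growth rate. Defaults are literature values for
#' *Aspergillus niger* at 37 degC.
#'
#' Units follow the model's internal system: metres, hours, kg m^-3.
#' Concentration I/O elsewhere in the package is mg L^-1 (1 mg L^-1 =
#' 1e-3 kg m^-3).
#'
#' @param d_bulk bulk oxygen diffusion coefficient, m^2 h^-1 (default
#'   8.7e-6, oxygen in medium at 37 degC).
#' @param a dimensionless hindrance exponent of the effective-diffusivity
#'   power law (default 1.76, mycelial networks).
#' @param rho_h hyphal dry-weight density, kg m^-3 (default 150).
#' @param y_xo2 biomass yield on oxygen, kg biomass (kg O2)^-1 (default 2.77).
#' @param k_xo Monod constant for growth-linked consumption, kg m^-3
#'   (default 2.5e-5).
#' @param k_mo Monod constant for maintenance consumption, kg m^-3
#'   (default 1.5e-5).
#' @param c_crit critical oxygen concentration up to which biomass
#'   production occurs, kg m^-3 (default 1e-5).
#' @param m_o2_max maximum maintenance coefficient, kg O2 (kg biomass)^-1
#'   h^-1 (default 7.2e-3).
#' @param mu_max maximum specific growth rate, h^-1 (default 0.16 for the
#'   regular-branching strain; the hyperbranching strain uses 0.24).
#' @param variant consumption model: `"growth_only"` (Monod growth term
#'   only) or `"growth_plus_maintenance"` (adds maintenance metabolism and
#'   the critical-concentration floor on the growth term).
#' @return object of class `kinetic_params`.
#' @seealso [effective_diffusion()], [q_growth()], [q_maintenance_variant()],
#'   [steady_state_profile()]
#' @export
kinetic_params <- function(d_bulk = 8.7e-6,
                           a = 1.76,
                           rho_h = 150,
                           y_xo2 = 2.77,
                           k_xo = 2.5e-5,
                           k_mo = 1.5e-5,
                           c_crit = 1e-5,
                           m_o2_max = 7.2e-3,
                           mu_max = 0.16,
                           variant = c("growth_only", "growth_plus_maintenance")) {
  variant <- match.arg(variant)
  p <- list(d_bulk = d_bulk, a = a, rho_h = rho_h, y_xo2 = y_xo2,
            k_xo = k_xo, k_mo = k_mo, c_crit = c_crit,
            m_o2_max = m_o2_max, mu_max = mu_max, variant = variant)
  num <- p[setdiff(names(p), "variant")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop_pellet("all kinetic parameters must be finite scalars")
  if (any(unlist(num) < 0)) stop_pellet("kinetic parameters must be nonnegative")
  if (p$y_xo2 <= 0) stop_pellet("y_xo2 must be positive")
  structure(p, class = "kinetic_params")
}

#' Strain presets for the kinetic parameters
#'
#' Literature defaults with the strain-specific maximum growth rate:
#' 0.16 h^-1 for the regular-branching strain ("R"), 0.24 h^-1 for the
#' hyperbranching strain ("H").
#'
#' @param strain `"R"` or `"H"`.
#' @param variant consumption model variant, see [kinetic_params()].
#' @return a `kinetic_params` object.
#' @export
strain_params <- function(strain = c("R", "H"),
                          variant = c("growth_only", "growth_plus_maintenance")) {
  strain <- match.arg(strain)
  kinetic_params(mu_max = if (strain == "R") 0.16 else 0.24,
                 variant = match.arg(variant))
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", x$variant, ")\n", sep = "")
  cat(sprintf("  D_bulk  %.3g m^2/h   a      %.3g\n", x$d_bulk, x$a))
  cat(sprintf("  rho_h   %.3g kg/m^3  Y_X/O2 %.3g kg/kg\n", x$rho_h, x$y_xo2))
  cat(sprintf("  K_XO    %.3g kg/m^3  K_MO   %.3g kg/m^3\n", x$k_xo, x$k_mo))
  cat(sprintf("  c_crit  %.3g kg/m^3  m_O2   %.3g kg/kg/h\n", x$c_crit, x$m_o2_max))
  cat(sprintf("  mu_max  %.3g 1/h\n", x$mu_max))
  invisible(x)
}

#' Read or write kinetic parameters as JSON
#'
#' @param params a `kinetic_params` object.
#' @param path file path.
#' @return `read_params_json` returns a `kinetic_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kinetic_params, x)
}
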