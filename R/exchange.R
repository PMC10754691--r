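# Radial flux laws between the five subsystems: the coupled
# nonequilibrium-thermodynamics force-flux law at the air-mucus interface,
# and linear conductive exchanges for mucus-tissue and tissue-blood.

#' Transport coefficients for the radial exchanges
#'
#' The air-mucus interface is described by a symmetric, positive
#' semi-definite resistance matrix linking the thermodynamic forces to the
#' measurable heat flux `Jq'` and the water flux `Jw`:
#' `X_q = r_qq Jq' + r_qw Jw`, `X_w = r_qw Jq' + r_ww Jw`.
#' The dominant term is an interfacial (kinetic-theory-style) resistance,
#' expressed as the constant conductances `h_q_if` (W/(m^2 K), heat) and
#' `k_w_if` (m/s, water); these are material properties of the evaporating
#' surface and independent of the duct geometry, which is what makes the
#' exchange insensitive to changes of the airflow cross section at fixed
#' perimeter. A bulk-air film resistance (constant Nusselt/Sherwood numbers
#' on the hydraulic diameter `Dh = 4 Aa / gamma_a`) can be added in series
#' with `use_film = TRUE`; it is off by default. The heat-mass coupling is
#' parameterized by a heat of transfer `q_star` (J/kg),
#' `r_qw = -q_star * r_qq`; Onsager symmetry is structural (a single
#' `r_qw` is stored). Tissue and blood exchanges are plain linear
#' conductances.
#'
#' @param h_q_if interfacial heat conductance, W/(m^2 K).
#' @param k_w_if interfacial water-transfer coefficient, m/s.
#' @param use_film add the laminar-duct film resistance in series.
#' @param Nu,Sh parallel-plate laminar Nusselt and Sherwood numbers used
#'   when `use_film = TRUE`.
#' @param k_air thermal conductivity of air, W/(m K).
#' @param D_wv binary diffusivity of water vapor in air, m^2/s.
#' @param q_star heat of transfer, J/kg; sets the coupling resistivity.
#' @param h_m_it,h_it_art,h_it_ven heat conductances for mucus-tissue and
#'   tissue-blood exchange, W/(m^2 K).
#' @return object of class `transport_coefficients`.
#' @export
transport_coefficients <- function(h_q_if = 150, k_w_if = 0.05,
                                   use_film = FALSE,
                                   Nu = 7.54, Sh = 7.54,
                                   k_air = 0.0255, D_wv = 2.5e-5,
                                   q_star = -2.4e5,
                                   h_m_it = 500,
                                   h_it_art = 500, h_it_ven = 500) {
  stopifnot(h_q_if > 0, k_w_if > 0, Nu > 0, Sh > 0, k_air > 0, D_wv > 0,
            h_m_it > 0, h_it_art > 0, h_it_ven > 0)
  co <- structure(list(h_q_if = h_q_if, k_w_if = k_w_if,
                       use_film = isTRUE(use_film), Nu = Nu, Sh = Sh,
                       k_air = k_air, D_wv = D_wv, q_star = q_star,
                       h_m_it = h_m_it, h_it_art = h_it_art,
                       h_it_ven = h_it_ven),
                  class = "transport_coefficients")
  # The resistance matrix must be positive definite over the whole working
  # range; reject a singular/indefinite parameterization at construction.
  Tm_check <- seq(220, 325, by = 5)
  r <- resolve_resistivities(co, Tm = Tm_check,
                             Aa = 1e-4, gamma_a = 11.1)
  det_r <- r$r_qq * r$r_ww - r$r_qw^2
  if (any(det_r <= 0))
    stop("singular or indefinite resistance matrix: |q_star| too large ",
         "for the given interface conductances")
  co
}

#' @export
print.transport_coefficients <- function(x, ...) {
  cat("transport coefficients (air-mucus interface + conductances)\n")
  cat(sprintf("  interface: h_q_if = %.0f W/(m^2 K), k_w_if = %.3g m/s, q_star = %.3g J/kg\n",
              x$h_q_if, x$k_w_if, x$q_star))
  cat(sprintf("  film term %s (Nu = %.2f, Sh = %.2f, k_air = %.4g, D_wv = %.3g)\n",
              if (x$use_film) "in series" else "off", x$Nu, x$Sh,
              x$k_air, x$D_wv))
  cat(sprintf("  conductances: h_m_it = %.0f, h_it_art = %.0f, h_it_ven = %.0f W/(m^2 K)\n",
              x$h_m_it, x$h_it_art, x$h_it_ven))
  invisible(x)
}

#' Resolve the interface resistivities at a local state
#'
#' Vectorized over nodes. `r_qq` carries the `1/T^2` scaling implied by the
#' force convention `X_q = 1/Tm - 1/Ta`; `r_ww` follows from the water
#' transfer coefficient and the saturation vapor concentration at the mucus
#' temperature.
#'
#' @param coeffs a [transport_coefficients()].
#' @param Tm mucus temperature, K.
#' @param Aa,gamma_a local airflow area (m^2) and perimeter (m); only used
#'   for the optional film term.
#' @return list with `r_qq`, `r_ww`, `r_qw` and the effective conductances
#'   `h_q` (W/(m^2 K)) and `k_w` (m/s).
#' @export
resolve_resistivities <- function(coeffs, Tm, Aa, gamma_a) {
  inv_h <- 1 / coeffs$h_q_if
  inv_k <- 1 / coeffs$k_w_if
  if (coeffs$use_film) {
    Dh <- 4 * Aa / gamma_a
    inv_h <- inv_h + Dh / (coeffs$Nu * coeffs$k_air)
    inv_k <- inv_k + Dh / (coeffs$Sh * coeffs$D_wv)
  }
  c_sat <- p_sat_clamped(Tm) * M_WATER / (R_GAS * Tm)   # kg/m^3 at saturation
  r_qq <- inv_h / Tm^2
  r_ww <- R_W * inv_k / c_sat
  r_qw <- -coeffs$q_star * r_qq
  list(r_qq = r_qq, r_ww = r_ww, r_qw = r_qw,
       h_q = 1 / inv_h, k_w = 1 / inv_k)
}

# Vectorized force-flux kernel used by both the public wrapper and the
# solver RHS. Inputs are per-node vectors; returns fluxes and forces.
# Sign conventions: Jq_am and Jw are positive from air to mucus; X_q =
# (1/Tm - 1/Ta); X_w = R_w ln(phi_a) + h_wa (1/Tm - 1/Ta), the combination
# of chemical-potential and enthalpy terms with saturation-referenced
# chemical potentials (mu_w = 0 for the saturated mucus surface). The
# enthalpy coefficient is the latent heat at the mean interface temperature,
# the Gibbs-Helmholtz companion of that reference choice, which makes X_w
# vanish when the vapor pressure equals saturation at the mucus temperature.
flux_air_mucus <- function(Ta, wa, Tm, coeffs, Aa, gamma_a, p = P_ATM) {
  x_w <- w_to_x(pmax(wa, 1e-10))
  p_w <- x_w * p
  phi_a <- p_w / p_sat_clamped(Ta)
  h_wa <- delta_vap_h(0.5 * (Ta + Tm))
  X_q <- 1 / Tm - 1 / Ta
  X_w <- R_W * log(phi_a) + h_wa * X_q
  r <- resolve_resistivities(coeffs, Tm, Aa, gamma_a)
  det_r <- r$r_qq * r$r_ww - r$r_qw^2
  Jq <- (r$r_ww * X_q - r$r_qw * X_w) / det_r
  Jw <- (-r$r_qw * X_q + r$r_qq * X_w) / det_r
  list(Jq_am = Jq, Jw = Jw, X_q = X_q, X_w = X_w)
}

#' Coupled heat and water fluxes at the air-mucus interface
#'
#' Solves the linear force-flux system for the measurable heat flux
#' `Jq_am` and the water flux `Jw` (both positive from air to mucus; a
#' positive `Jw` is condensation onto the lining). The mucus surface is
#' saturated liquid water at `Tm`. The implied local entropy production
#' `Jq_am * X_q + Jw * X_w` is non-negative by construction because the
#' resistance matrix is symmetric positive definite.
#'
#' @param air a [air_state()] for the bulk air at the node.
#' @param Tm mucus temperature, K.
#' @param coeffs a [transport_coefficients()].
#' @param geom_node list with local `Aa` (m^2) and `gamma_a` (m).
#' @return list with `Jq_am` (W/m^2), `Jw` (kg/(m^2 s)) and the forces
#'   `X_q`, `X_w`.
#' @export
air_mucus_fluxes <- function(air, Tm, coeffs, geom_node) {
  stopifnot(inherits(air, "moist_air_state"),
            inherits(coeffs, "transport_coefficients"))
  flux_air_mucus(Ta = air$T, wa = air$wa, Tm = Tm, coeffs = coeffs,
                 Aa = geom_node$Aa, gamma_a = geom_node$gamma_a, p = air$p)
}

#' Linear conductive heat flux between two compartments
#'
#' @param T_i,T_j compartment temperatures, K.
#' @param h_ij heat conductance, W/(m^2 K), > 0.
#' @return heat flux `h_ij (T_i - T_j)`, W/m^2, positive from i to j.
#' @export
conductive_flux <- function(T_i, T_j, h_ij) {
  stopifnot(all(h_ij > 0))
  h_ij * (T_i - T_j)
}

#' Mucus water replenishment from the underlying tissue
#'
#' The mucus layer keeps a constant thickness and density, so the liquid
#' water flux from the tissue instantaneously balances the interface water
#' flux: `Jm = -Jw` (evaporation is resupplied; condensate drains).
#'
#' @param Jw interface water flux, kg/(m^2 s), positive air to mucus.
#' @return `Jm`, kg/(m^2 s), positive tissue to mucus.
#' @export
mucus_replenishment <- function(Jw) {
  -Jw
}
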