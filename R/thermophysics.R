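# Thermophysical properties of moist air, water/mucus, tissue and blood,
# plus the sinusoidal breathing-flow forcing.

R_GAS <- 8.314462618       # J/(mol K)
M_WATER <- 0.018015        # kg/mol
M_DRYAIR <- 0.028964       # kg/mol
R_W <- R_GAS / M_WATER     # specific gas constant of water vapor, J/(kg K)
P_ATM <- 101325            # Pa; pressure fixed along the channel

# Peng-Robinson critical constants: dry air as a pseudo-component, water.
PR_PARAMS <- list(
  air   = list(Tc = 132.45, Pc = 37.74e5, omega = 0.0335, M = M_DRYAIR),
  water = list(Tc = 647.10, Pc = 220.64e5, omega = 0.3449, M = M_WATER))

#' Saturation vapor pressure of liquid water
#'
#' Antoine-type (Buck) correlation over liquid water, used down to
#' supercooled temperatures because the mucus lining stays liquid:
#' `p_sat = 611.21 * exp((18.678 - t/234.5) * t / (257.14 + t))` with `t`
#' in degrees Celsius. Strictly increasing in temperature.
#'
#' @param T_K temperature in K, within (200, 380).
#' @return saturation pressure in Pa.
#' @export
p_sat <- function(T_K) {
  if (any(T_K <= 200 | T_K >= 380))
    stop("p_sat: temperature out of range (200, 380) K")
  p_sat_raw(T_K)
}

# correlation without the range guard; solver internals clamp instead of
# erroring so that transient predictor probes of the stiff integrator
# cannot abort a physical run
p_sat_raw <- function(T_K) {
  tc <- T_K - 273.15
  611.21 * exp((18.678 - tc / 234.5) * tc / (257.14 + tc))
}
p_sat_clamped <- function(T_K) {
  p_sat_raw(pmin(pmax(T_K, 201), 379))
}

#' Enthalpy of vaporization of water
#'
#' Linear correlation `2.501e6 - 2361 * (T - 273.15)` J/kg, adequate over
#' the physiological and ambient range of the model.
#'
#' @param T_K temperature in K.
#' @return latent heat, J/kg.
#' @export
delta_vap_h <- function(T_K) {
  2.501e6 - 2361 * (T_K - 273.15)
}

# Partial specific enthalpy of water vapor (liquid water at 273.15 K as the
# zero), and of liquid water, consistent so that h_w - h_liquid ~ delta_vap_h.
h_w_vapor <- function(T_K, cp_vap = 1907) {
  delta_vap_h(273.15) + cp_vap * (T_K - 273.15)
}
h_w_liquid <- function(T_K, cp_w = 4181) {
  cp_w * (T_K - 273.15)
}

# Vapor-phase compressibility factor of an air-water mixture from the
# Peng-Robinson cubic equation of state (van der Waals one-fluid mixing,
# k_ij = 0). Vectorized Newton iteration from the ideal-gas root.
pr_compressibility <- function(T_K, p_Pa, x_w) {
  kappa <- function(w) 0.37464 + 1.54226 * w - 0.26992 * w^2
  a_of <- function(pp) {
    al <- (1 + kappa(pp$omega) * (1 - sqrt(T_K / pp$Tc)))^2
    0.45724 * R_GAS^2 * pp$Tc^2 / pp$Pc * al
  }
  b_of <- function(pp) 0.07780 * R_GAS * pp$Tc / pp$Pc
  a1 <- a_of(PR_PARAMS$air);   b1 <- b_of(PR_PARAMS$air)
  a2 <- a_of(PR_PARAMS$water); b2 <- b_of(PR_PARAMS$water)
  x1 <- 1 - x_w
  a_mix <- x1^2 * a1 + 2 * x1 * x_w * sqrt(a1 * a2) + x_w^2 * a2
  b_mix <- x1 * b1 + x_w * b2
  A <- a_mix * p_Pa / (R_GAS * T_K)^2
  B <- b_mix * p_Pa / (R_GAS * T_K)
  # cubic: Z^3 - (1-B) Z^2 + (A - 3B^2 - 2B) Z - (AB - B^2 - B^3) = 0
  c2 <- -(1 - B); c1 <- A - 3 * B^2 - 2 * B; c0 <- -(A * B - B^2 - B^3)
  Z <- rep_len(1, length(c0 + c1 + c2 + T_K + p_Pa + x_w))
  for (i in 1:12) {
    f <- Z^3 + c2 * Z^2 + c1 * Z + c0
    fp <- 3 * Z^2 + 2 * c2 * Z + c1
    Z <- Z - f / fp
  }
  Z
}

# Moist-air density, kg/m^3, from the Peng-Robinson EOS (vectorized).
rho_moist_air <- function(T_K, p_Pa, x_w) {
  M_mix <- x_w * M_WATER + (1 - x_w) * M_DRYAIR
  Z <- pr_compressibility(T_K, p_Pa, x_w)
  p_Pa * M_mix / (Z * R_GAS * T_K)
}

# Conversions between water mole fraction and water mass fraction.
x_to_w <- function(x_w) {
  x_w * M_WATER / (x_w * M_WATER + (1 - x_w) * M_DRYAIR)
}
w_to_x <- function(wa) {
  (wa / M_WATER) / (wa / M_WATER + (1 - wa) / M_DRYAIR)
}

#' Thermodynamic state of humid air
#'
#' The local state used throughout the model: temperature, pressure and
#' relative humidity determine the water mole and mass fractions, the
#' mixture density (Peng-Robinson equation of state), the specific chemical
#' potential of the water vapor relative to saturation at the same
#' temperature (`mu_w = (R/M_w) T log(phi)`, zero at saturation), and the
#' partial specific enthalpy of the vapor.
#'
#' @param T_K temperature, K.
#' @param p_Pa total pressure, Pa (default atmospheric).
#' @param phi relative humidity fraction in `[0, 1]`; supersaturated states
#'   are rejected on construction.
#' @return an object of class `moist_air_state` with fields `T`, `p`,
#'   `phi`, `x_w`, `wa`, `rho_a`, `mu_w`, `h_w`.
#' @export
air_state <- function(T_K, p_Pa = P_ATM, phi) {
  if (phi < 0 || phi > 1)
    stop("air_state: relative humidity must be in [0, 1]; ",
         "supersaturation is not modeled")
  ps <- p_sat(T_K)
  x_w <- phi * ps / p_Pa
  wa <- x_to_w(x_w)
  structure(list(
    T = T_K, p = p_Pa, phi = phi, x_w = x_w, wa = wa,
    rho_a = rho_moist_air(T_K, p_Pa, x_w),
    mu_w = R_W * T_K * log(phi),
    h_w = h_w_vapor(T_K)), class = "moist_air_state")
}

#' @export
print.moist_air_state <- function(x, ...) {
  cat(sprintf(
    "moist air: T = %.2f K, p = %.0f Pa, phi = %.3f\n  wa = %.5f, rho = %.4f kg/m^3, mu_w = %.1f J/kg\n",
    x$T, x$p, x$phi, x$wa, x$rho_a, x$mu_w))
  invisible(x)
}

#' Breathing pattern
#'
#' Tidal breathing is modeled as a sinusoidal mass flow
#' `Fa(t) = Fa_max sin(2 pi t / t_br)` with `Fa_max = rho_a Vt / t_br`,
#' where `rho_a` is the air density at the stated reference (ambient inlet)
#' state. The first half-cycle (`Fa > 0`) is inhalation in the +z direction.
#' Note that integrating `Fa` over the inhalation half-cycle gives an
#' inhaled mass `rho_a Vt / pi` rather than `rho_a Vt`; `pi_correction`
#' rescales `Fa_max` by `pi` so that the inhaled mass per breath equals the
#' nominal tidal mass.
#'
#' @param Vt tidal volume, m^3.
#' @param t_br duration of one breathing cycle, s.
#' @param rho_ref reference air density (ambient inlet state), kg/m^3.
#' @param M body mass, kg (metadata only).
#' @param pi_correction logical; rescale `Fa_max` by `pi` (default FALSE,
#'   the sinusoidal law taken literally).
#' @return object of class `breathing_pattern` with `Vt`, `t_br`, `Fa_max`,
#'   `M`.
#' @export
breathing_pattern <- function(Vt, t_br, rho_ref, M = NA_real_,
                              pi_correction = FALSE) {
  stopifnot(Vt > 0, t_br > 0, rho_ref > 0)
  Fa_max <- rho_ref * Vt / t_br
  if (pi_correction) Fa_max <- Fa_max * pi
  structure(list(Vt = Vt, t_br = t_br, Fa_max = Fa_max, M = M,
                 rho_ref = rho_ref),
            class = "breathing_pattern")
}

#' Instantaneous breathing mass flow
#'
#' @param t time, s (>= 0).
#' @param pattern a [breathing_pattern()].
#' @return signed air mass flow, kg/s; positive is the inhalation (+z)
#'   direction.
#' @export
breathing_flow <- function(t, pattern) {
  stopifnot(inherits(pattern, "breathing_pattern"), all(t >= 0))
  pattern$Fa_max * sin(2 * pi * t / pattern$t_br)
}
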