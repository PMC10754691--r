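# Post-processing of a breathing solution: local and cycle-integrated
# entropy production, lost work, heat and water loss/recovery, and the
# expired-air temperature regression.

# Per-node entropy-production profiles (W/(K m)) at one instant, from the
# fields alone (fluxes are algebraic functions of the state).
sigma_profiles <- function(model, Ta, Tm, Tit, Tart, Tven, wa) {
  g <- model$grid
  fl <- flux_air_mucus(Ta, wa, Tm, model$coeffs, g$Aa, g$gamma_a,
                       p = model$config$air$p)
  Jq_mit <- model$coeffs$h_m_it * (Tm - Tit)
  Jq_itart <- model$coeffs$h_it_art * (Tit - Tart)
  Jq_itven <- model$coeffs$h_it_ven * (Tit - Tven)
  s_am_q <- g$gamma_a * fl$Jq_am * fl$X_q
  s_am_w <- g$gamma_a * fl$Jw * fl$X_w
  s_mit <- g$gamma_a * Jq_mit * (1 / Tit - 1 / Tm)
  s_itart <- model$gamma_art * Jq_itart * (1 / Tart - 1 / Tit)
  s_itven <- model$gamma_ven * Jq_itven * (1 / Tven - 1 / Tit)
  list(sigma_am_q = s_am_q, sigma_am_w = s_am_w,
       sigma_am = s_am_q + s_am_w,
       sigma_mit = s_mit, sigma_itart = s_itart, sigma_itven = s_itven,
       sigma_total = s_am_q + s_am_w + s_mit + s_itart + s_itven,
       fluxes = list(Jq_am = fl$Jq_am, Jw = fl$Jw,
                     Jm = mucus_replenishment(fl$Jw),
                     Jq_mit = Jq_mit, Jq_itart = Jq_itart,
                     Jq_itven = Jq_itven),
       forces = list(X_q = fl$X_q, X_w = fl$X_w))
}

#' Local entropy-production terms at one node and instant
#'
#' Returns the per-interface local entropy-production contributions
#' (W/(K m)) together with the fluxes and conjugate forces retained for
#' audit. The air-mucus contribution decomposes exactly as
#' `sigma_am = sigma_am_q + sigma_am_w`.
#'
#' @param solution a [run_to_cyclic_steady_state()] result.
#' @param node grid-node index.
#' @param t_index index into `solution$times`.
#' @return list of sigma terms, fluxes and forces at (node, t).
#' @export
local_entropy <- function(solution, node, t_index) {
  stopifnot(inherits(solution, "breathing_solution"))
  n_t <- length(solution$times)
  Ns <- length(solution$grid$z_star)
  stopifnot(t_index >= 1, t_index <= n_t, node >= 1, node <= Ns)
  s <- sigma_profiles(solution$model,
                      solution$Ta[t_index, ], solution$Tm[t_index, ],
                      solution$Tit[t_index, ], solution$Tart[t_index, ],
                      solution$Tven[t_index, ], solution$wa[t_index, ])
  pick <- function(v) if (is.list(v)) lapply(v, function(u) u[node]) else v[node]
  lapply(s, pick)
}

#' Cycle-integrated entropy production
#'
#' Trapezoidal integration of the local entropy production over the final
#' cycle in time and over the MT domain in space. Returns the per-interface
#' components, their sum `Sigma_irr` (J/(K cycle)) and the lost work
#' `W_lost = T_amb * Sigma_irr` (J/cycle).
#'
#' @param solution a converged [run_to_cyclic_steady_state()] result.
#' @return object of class `entropy_breakdown`.
#' @export
total_entropy <- function(solution) {
  stopifnot(inherits(solution, "breathing_solution"))
  if (!isTRUE(solution$converged))
    stop("total_entropy needs a converged solution")
  model <- solution$model
  wz <- trapz_weights(model$grid$z)
  wt <- trapz_weights(solution$times)
  n_t <- length(solution$times)
  comp_names <- c("sigma_am_q", "sigma_am_w", "sigma_am", "sigma_mit",
                  "sigma_itart", "sigma_itven", "sigma_total")
  series <- matrix(0, n_t, length(comp_names),
                   dimnames = list(NULL, comp_names))
  z_profile <- matrix(0, length(wz), length(comp_names),
                      dimnames = list(NULL, comp_names))
  for (i in seq_len(n_t)) {
    s <- sigma_profiles(model, solution$Ta[i, ], solution$Tm[i, ],
                        solution$Tit[i, ], solution$Tart[i, ],
                        solution$Tven[i, ], solution$wa[i, ])
    for (nm in comp_names) {
      series[i, nm] <- sum(wz * s[[nm]])
      z_profile[, nm] <- z_profile[, nm] + wt[i] * s[[nm]]
    }
  }
  Sg <- colSums(wt * series)
  out <- structure(list(
    Sigma_am_q = Sg[["sigma_am_q"]], Sigma_am_w = Sg[["sigma_am_w"]],
    Sigma_am = Sg[["sigma_am"]], Sigma_mit = Sg[["sigma_mit"]],
    Sigma_itart = Sg[["sigma_itart"]], Sigma_itven = Sg[["sigma_itven"]],
    Sigma_irr = Sg[["sigma_total"]],
    T_amb = model$T_amb,
    W_lost = lost_work(max(Sg[["sigma_total"]], 0), model$T_amb),
    sigma_series = series, sigma_profile_z = z_profile,
    z_star = model$grid$z_star), class = "entropy_breakdown")
  out
}

#' @export
print.entropy_breakdown <- function(x, ...) {
  cat("entropy production over one breathing cycle (J/(K cyc)):\n")
  cat(sprintf("  air-mucus   %.4g  (heat %.4g + water %.4g)\n",
              x$Sigma_am, x$Sigma_am_q, x$Sigma_am_w))
  cat(sprintf("  mucus-tissue %.4g; tissue-artery %.4g; tissue-vein %.4g\n",
              x$Sigma_mit, x$Sigma_itart, x$Sigma_itven))
  cat(sprintf("  total Sigma_irr = %.4g; W_lost = %.3g J/cyc at T_amb = %.2f K\n",
              x$Sigma_irr, x$W_lost, x$T_amb))
  invisible(x)
}

#' Lost work of a breathing cycle
#'
#' The energy irreversibly dissipated per cycle: the product of the total
#' entropy production and the absolute temperature of the surroundings.
#'
#' @param Sigma_irr total entropy production, J/(K cycle), >= 0.
#' @param T_amb ambient absolute temperature, K.
#' @return lost work, J/cycle.
#' @export
lost_work <- function(Sigma_irr, T_amb) {
  stopifnot(all(Sigma_irr >= 0), all(T_amb > 0))
  T_amb * Sigma_irr
}

#' Lost work as dissipation rates
#'
#' @param W_lost_per_cycle lost work, J/cycle.
#' @param t_br cycle duration, s (> 0).
#' @return list with `kJ_per_h` and `kJ_per_day`.
#' @export
dissipation_rates <- function(W_lost_per_cycle, t_br) {
  stopifnot(t_br > 0)
  rate <- W_lost_per_cycle / t_br          # W
  list(kJ_per_h = rate * 3600 / 1000, kJ_per_day = rate * 86400 / 1000)
}

#' Heat and water loss and recovery over one breathing cycle
#'
#' Losses are referenced to the ambient inlet state: what the animal
#' irreversibly gives to the environment per cycle through the nostril
#' opening. The no-recovery baseline re-evaluates the export assuming the
#' expired air left at deep-body temperature and humidity, and
#' `recovery = 100 (1 - loss / baseline)`, so recovery is 100% when the
#' expired air re-equals the inhaled air and 0% when it leaves at body
#' conditions. Sensible heat uses `cp_a (Ta - T_amb)`; latent heat is
#' evaluated at the expired-air temperature.
#'
#' @param solution a converged [run_to_cyclic_steady_state()] result.
#' @return object of class `exchange_summary` with `heat_loss_J`,
#'   `water_loss_kg`, `heat_recovery_pct`, `water_recovery_pct`,
#'   `expired_T_K`, plus the no-recovery baselines.
#' @export
exchange_summary <- function(solution) {
  stopifnot(inherits(solution, "breathing_solution"))
  model <- solution$model
  cp_a <- model$config$air$cp_a
  ex <- solution$phase == "exhalation"
  tt <- solution$times[ex]
  wt <- trapz_weights(tt)
  m_out <- abs(solution$Fa[ex])            # kg/s leaving through z* = 0
  Ta0 <- solution$Ta[ex, 1]
  wa0 <- solution$wa[ex, 1]
  wa_amb <- model$amb$wa
  T_amb <- model$T_amb
  heat_flux <- function(T_out, w_out)
    m_out * (cp_a * (T_out - T_amb) + (w_out - wa_amb) * delta_vap_h(T_out))
  water_flux <- function(w_out) m_out * (w_out - wa_amb)
  heat_loss <- sum(wt * heat_flux(Ta0, wa0))
  heat_base <- sum(wt * heat_flux(rep(model$T_body, sum(ex)),
                                  rep(model$body$wa, sum(ex))))
  water_loss <- sum(wt * water_flux(wa0))
  water_base <- sum(wt * water_flux(rep(model$body$wa, sum(ex))))
  recovery <- function(loss, base) {
    if (abs(base) < 1e-12) return(NA_real_)   # undefined, flagged as NA
    100 * (1 - loss / base)
  }
  wflow <- wt * m_out
  structure(list(
    heat_loss_J = heat_loss, water_loss_kg = water_loss,
    heat_baseline_J = heat_base, water_baseline_kg = water_base,
    heat_recovery_pct = recovery(heat_loss, heat_base),
    water_recovery_pct = recovery(water_loss, water_base),
    expired_T_K = sum(wflow * Ta0) / sum(wflow)),
    class = "exchange_summary")
}

#' @export
print.exchange_summary <- function(x, ...) {
  cat(sprintf("heat loss  %.4g J/cyc (recovery %.1f%%)\n",
              x$heat_loss_J, x$heat_recovery_pct))
  cat(sprintf("water loss %.4g mg/cyc (recovery %.1f%%)\n",
              x$water_loss_kg * 1e6, x$water_recovery_pct))
  cat(sprintf("expired air temperature %.2f K (%.2f C)\n",
              x$expired_T_K, x$expired_T_K - 273.15))
  invisible(x)
}

#' Regression of expired-air temperature on ambient temperature
#'
#' Ordinary least squares of the expired-air temperature (deg C) on the
#' ambient temperature (deg C). A perfect exchanger gives slope 0, no
#' exchange gives slope 1.
#'
#' @param Tamb_C ambient temperatures, deg C (>= 3 distinct values).
#' @param expired_T_C expired-air temperatures, deg C.
#' @return list with `slope` (dimensionless) and `intercept` (deg C).
#' @export
expired_t_regression <- function(Tamb_C, expired_T_C) {
  if (length(unique(Tamb_C)) < 3)
    stop("regression needs >= 3 distinct ambient temperatures")
  if (length(Tamb_C) != length(expired_T_C))
    stop("input lengths differ")
  fit <- stats::lm(expired_T_C ~ Tamb_C)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}

#' Cycle budget closure diagnostics
#'
#' For a converged (periodic) cycle the storage terms integrate to zero, so
#' the cycle integral of each subsystem's advective transport (evaluated
#' with the discrete differentiation operators the solver actually uses)
#' must balance the cycle integral of its interface sources, node by node,
#' over the freely evolving nodes (boundary-pinned rows are algebraic
#' constraints, not balance equations). Returns the paired integrals and
#' their relative residuals for air water mass, air sensible energy, artery
#' and vein energy; residuals reflect cycle-periodicity and snapshot
#' quadrature error only.
#'
#' @param solution a converged [run_to_cyclic_steady_state()] result.
#' @return list of budget components with relative residuals.
#' @export
cycle_budget <- function(solution) {
  stopifnot(inherits(solution, "breathing_solution"))
  model <- solution$model
  g <- model$grid
  Ns <- length(g$z_star)
  wz <- trapz_weights(g$z)
  wt <- trapz_weights(solution$times)
  n_t <- length(solution$times)
  cp_a <- model$config$air$cp_a
  cp_b <- model$config$blood$cp_b
  F_b <- model$config$blood$F_blood
  Fa <- solution$Fa

  adv_w <- 0; sink_w <- 0
  adv_q <- 0; sink_q <- 0
  adv_art <- 0; src_art <- 0
  adv_ven <- 0; src_ven <- 0
  for (i in seq_len(n_t)) {
    inhal <- solution$phase[i] == "inhalation"
    D_air <- if (inhal) model$D_up else model$D_down
    free_a <- if (inhal) 2:Ns else 1:(Ns - 1)   # inflow air node is pinned
    free_art <- 1:(Ns - 1)                      # artery pinned at body end
    free_ven <- 2:Ns                            # vein node 1 is constrained

    fl <- flux_air_mucus(solution$Ta[i, ], solution$wa[i, ],
                         solution$Tm[i, ], model$coeffs, g$Aa, g$gamma_a,
                         p = model$config$air$p)
    dwa <- as.numeric(D_air %*% solution$wa[i, ])
    dTa <- as.numeric(D_air %*% solution$Ta[i, ])
    adv_w <- adv_w - wt[i] * sum(wz[free_a] * Fa[i] * dwa[free_a])
    sink_w <- sink_w + wt[i] * sum(wz[free_a] * g$gamma_a[free_a] *
                                     fl$Jw[free_a])
    adv_q <- adv_q - wt[i] * sum(wz[free_a] * Fa[i] * cp_a * dTa[free_a])
    sink_q <- sink_q + wt[i] * sum(wz[free_a] * g$gamma_a[free_a] *
                                     fl$Jq_am[free_a])

    Jq_itart <- model$coeffs$h_it_art *
      (solution$Tit[i, ] - solution$Tart[i, ])
    Jq_itven <- model$coeffs$h_it_ven *
      (solution$Tit[i, ] - solution$Tven[i, ])
    dart <- as.numeric(model$D_down %*% solution$Tart[i, ])
    dven <- as.numeric(model$D_up %*% solution$Tven[i, ])
    adv_art <- adv_art + wt[i] * F_b * cp_b * sum(wz[free_art] *
                                                    dart[free_art])
    src_art <- src_art + wt[i] * sum(wz[free_art] *
                                       model$gamma_art[free_art] *
                                       Jq_itart[free_art])
    adv_ven <- adv_ven - wt[i] * F_b * cp_b * sum(wz[free_ven] *
                                                    dven[free_ven])
    src_ven <- src_ven + wt[i] * sum(wz[free_ven] *
                                       model$gamma_ven[free_ven] *
                                       Jq_itven[free_ven])
  }

  relres <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-12)
  list(
    water = list(advective_in = adv_w, interface_sink = sink_w,
                 rel_residual = relres(adv_w, sink_w)),
    air_energy = list(advective_in = adv_q, interface_sink = sink_q,
                      rel_residual = relres(adv_q, sink_q)),
    artery = list(advective_in = adv_art, interface_source = -src_art,
                  rel_residual = relres(adv_art, -src_art)),
    vein = list(advective_in = adv_ven, interface_source = -src_ven,
                rel_residual = relres(adv_ven, -src_ven)))
}
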