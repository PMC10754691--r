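# Method-of-lines solver: assemble the five coupled area-averaged balance
# equations over the MT grid and integrate breathing cycles to cyclic
# steady state with a stiff BDF integrator.

# Finite-difference weights for the first derivative at offset 0 from node
# offsets `o` (in grid units): solves the Vandermonde moment conditions, so
# a 5-point stencil is exact for polynomials up to degree 4.
fd_weights <- function(o) {
  k <- seq_along(o) - 1
  A <- outer(k, o, function(kk, oo) oo^kk)
  b <- as.numeric(k == 1)
  solve(A, b)
}

# Differentiation matrix with fourth-order, five-point upwind-biased
# stencils (dss020-style). flow_sign = +1: flow in +z, stencils biased
# toward -z (three upwind points where available); flow_sign = -1 mirrors.
# The one node adjacent to the inflow boundary cannot have more than one
# upwind neighbor; its clipped five-point row is downwind-heavy and makes
# the semi-discrete advection operator weakly unstable (positive real
# eigenvalues that self-excite at high cell Peclet number), so that single
# row uses a three-point centered closure, which renders the operator
# spectrum strictly dissipative while keeping the fourth-order five-point
# stencils everywhere else.
deriv_matrix <- function(n, dz, flow_sign) {
  if (n < 6L) stop("spatial derivative needs at least 6 nodes")
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (flow_sign >= 0 && i == 2L) {
      idx <- 1:3
    } else if (flow_sign < 0 && i == n - 1L) {
      idx <- (n - 2L):n
    } else {
      lo <- if (flow_sign >= 0) i - 3L else i - 1L
      lo <- min(max(lo, 1L), n - 4L)
      idx <- lo:(lo + 4L)
    }
    D[i, idx] <- fd_weights(idx - i) / dz
  }
  D
}

#' Fourth-order upwinded spatial derivative
#'
#' Five-point, fourth-order biased finite-difference stencils with the bias
#' direction chosen by the flow sign (three upwind points where the domain
#' allows, one-sided closures at the ends). Exact for polynomials of degree
#' <= 4 on a uniform grid.
#'
#' @param field per-node values on a uniform grid (>= 6 nodes).
#' @param dz grid spacing, m.
#' @param flow_sign +1 for flow in +z, -1 for flow in -z.
#' @return per-node derivative, field units per m.
#' @export
spatial_derivative <- function(field, dz, flow_sign = 1) {
  D <- deriv_matrix(length(field), dz, flow_sign)
  as.numeric(D %*% field)
}

#' Assemble a nose model
#'
#' Interpolates the geometry onto the solver grid, resolves the transport
#' coefficients, breathing pattern and boundary states, and precomputes the
#' differentiation matrices and compartment heat capacities. The artery,
#' vein and interstitial-tissue cross sections derive from the configured
#' tissue sleeve thickness `d_it` on the perimeter and the artery/vein
#' volume fractions.
#'
#' @param geom an [mt_geometry()].
#' @param config a [default_config()] configuration.
#' @return an object of class `nose_model`.
#' @export
nose_model <- function(geom, config = default_config()) {
  stopifnot(inherits(geom, "mt_geometry"))
  Ns <- config$solver$Ns
  grid <- geometry_on_grid(geom, Ns)
  coeffs <- coeffs_from_config(config)

  T_amb <- config$ambient$T_C + 273.15
  T_body <- config$body$T_C + 273.15
  amb <- air_state(T_amb, config$air$p, config$ambient$phi)
  body <- air_state(T_body, config$air$p, config$body$phi)
  pattern <- breathing_pattern(config$pattern$Vt, config$pattern$t_br,
                               rho_ref = amb$rho_a, M = config$pattern$M,
                               pi_correction = config$pattern$pi_correction)

  ts <- config$tissue
  A_sleeve <- grid$gamma_a * ts$d_it
  A_art <- A_sleeve * ts$frac_art
  A_ven <- A_sleeve * ts$frac_ven
  A_it <- A_sleeve * (1 - ts$frac_art - ts$frac_ven)
  gamma_art <- grid$gamma_a * ts$perim_frac_art
  gamma_ven <- grid$gamma_a * ts$perim_frac_ven

  structure(list(
    geom = geom, grid = grid, config = config, coeffs = coeffs,
    pattern = pattern, amb = amb, body = body,
    T_amb = T_amb, T_body = T_body,
    A_it = A_it, A_art = A_art, A_ven = A_ven,
    gamma_art = gamma_art, gamma_ven = gamma_ven,
    cap_m = config$mucus$rho_m * config$mucus$cp_w *
      grid$gamma_a * config$mucus$d_m,
    cap_it = ts$rho_it * ts$cp_it * A_it,
    cap_art = config$blood$rho_b * config$blood$cp_b * A_art,
    cap_ven = config$blood$rho_b * config$blood$cp_b * A_ven,
    D_up = deriv_matrix(Ns, grid$dz, +1),
    D_down = deriv_matrix(Ns, grid$dz, -1)),
    class = "nose_model")
}

#' @export
print.nose_model <- function(x, ...) {
  cat("nose model:", x$geom$label, "\n")
  cat(sprintf("  grid: Ns = %d over z* in [%.3f, %.3f], L = %.4g m\n",
              length(x$grid$z_star), x$grid$z_star[1],
              x$grid$z_star[length(x$grid$z_star)], x$grid$L))
  cat(sprintf("  ambient %.1f C / phi %.2f; body %.1f C / phi %.2f\n",
              x$T_amb - 273.15, x$amb$phi, x$T_body - 273.15, x$body$phi))
  cat(sprintf("  Fa_max = %.3g kg/s, t_br = %.3g s\n",
              x$pattern$Fa_max, x$pattern$t_br))
  invisible(x)
}

state_indices <- function(Ns) {
  list(Ta = 1:Ns, Tm = Ns + 1:Ns, Tit = 2 * Ns + 1:Ns,
       Tart = 3 * Ns + 1:Ns, Tven = 4 * Ns + 1:Ns, wa = 5 * Ns + 1:Ns)
}

initial_state <- function(model) {
  Ns <- length(model$grid$z_star)
  c(rep(model$T_body, 4 * Ns + Ns), rep(model$body$wa, Ns))
}

#' Apply phase boundary conditions to a state vector
#'
#' Pins the constrained nodes: during inhalation the distal air node takes
#' the ambient temperature and humidity; during exhalation the proximal air
#' node takes the deep-body values. In both phases, the mucus, tissue and
#' artery at the proximal end are held at body temperature, and the venous
#' inflow at the distal end equals the local arterial temperature.
#'
#' @param phase `"inhalation"` or `"exhalation"`.
#' @param y state vector (see [nose_model()]).
#' @param model a [nose_model()].
#' @return the constrained state vector.
#' @export
apply_boundary_conditions <- function(phase = c("inhalation", "exhalation"),
                                      y, model) {
  phase <- match.arg(phase)
  Ns <- length(model$grid$z_star)
  ix <- state_indices(Ns)
  if (phase == "inhalation") {
    y[ix$Ta[1]] <- model$T_amb
    y[ix$wa[1]] <- model$amb$wa
  } else {
    y[ix$Ta[Ns]] <- model$T_body
    y[ix$wa[Ns]] <- model$body$wa
  }
  y[ix$Tm[Ns]] <- model$T_body
  y[ix$Tit[Ns]] <- model$T_body
  y[ix$Tart[Ns]] <- model$T_body
  y[ix$Tven[1]] <- y[ix$Tart[1]]
  y
}

#' Time derivatives of all fields (method-of-lines right-hand side)
#'
#' Evaluates the area-averaged balance equations at one instant: air water
#' vapor and air energy (advection by the breathing flow plus interface
#' exchange), mucus energy (interface heat + latent heat of the water flux,
#' conduction to the tissue, enthalpy of the replenishment flux), tissue
#' energy, and the countercurrent artery (flowing toward the nostril, -z)
#' and vein (toward the body, +z) energies. Constrained boundary nodes have
#' zero time derivative (algebraic pinning); the venous inflow node tracks
#' the arterial node derivative.
#'
#' @param t time within the cycle, s.
#' @param y state vector.
#' @param model a [nose_model()].
#' @param phase `"inhalation"` or `"exhalation"`.
#' @return list whose first element is the derivative vector (deSolve
#'   convention).
#' @export
rhs <- function(t, y, model, phase = c("inhalation", "exhalation")) {
  phase <- match.arg(phase)
  Ns <- length(model$grid$z_star)
  ix <- state_indices(Ns)
  if (any(!is.finite(y)))
    stop("non-finite state at t = ", signif(t, 6))
  Tfields <- y[1:(5 * Ns)]
  if (any(Tfields < 150) || any(Tfields > 400)) {
    bad <- which(Tfields < 150 | Tfields > 400)[1]
    stop(sprintf("temperature out of physical range at t = %.4g s, state index %d (%.1f K)",
                 t, bad, Tfields[bad]))
  }
  Ta <- y[ix$Ta]; Tm <- y[ix$Tm]; Tit <- y[ix$Tit]
  Tart <- y[ix$Tart]; Tven <- y[ix$Tven]; wa <- pmax(y[ix$wa], 1e-10)

  g <- model$grid
  cfg <- model$config
  cp_a <- cfg$air$cp_a
  cp_b <- cfg$blood$cp_b
  cp_w <- cfg$mucus$cp_w
  F_b <- cfg$blood$F_blood

  Fa <- breathing_flow(t, model$pattern)
  D_air <- if (phase == "inhalation") model$D_up else model$D_down

  x_w <- w_to_x(wa)
  rho_a <- rho_moist_air(Ta, cfg$air$p, x_w)

  fl <- flux_air_mucus(Ta, wa, Tm, model$coeffs, g$Aa, g$gamma_a,
                       p = cfg$air$p)
  Jq_am <- fl$Jq_am
  Jw <- fl$Jw
  Jm <- mucus_replenishment(Jw)
  Jq_mit <- model$coeffs$h_m_it * (Tm - Tit)
  Jq_itart <- model$coeffs$h_it_art * (Tit - Tart)
  Jq_itven <- model$coeffs$h_it_ven * (Tit - Tven)

  dTa <- (-Fa * cp_a * as.numeric(D_air %*% Ta) - g$gamma_a * Jq_am) /
    (rho_a * cp_a * g$Aa)
  dwa <- (-Fa * as.numeric(D_air %*% wa) - g$gamma_a * Jw) /
    (rho_a * g$Aa)
  dTm <- (g$gamma_a * (Jq_am + Jw * delta_vap_h(Tm)) -
            g$gamma_a * Jq_mit +
            g$gamma_a * Jm * cp_w * (Tit - Tm)) / model$cap_m
  dTit <- (g$gamma_a * Jq_mit - model$gamma_art * Jq_itart -
             model$gamma_ven * Jq_itven) / model$cap_it
  dTart <- (F_b * cp_b * as.numeric(model$D_down %*% Tart) +
              model$gamma_art * Jq_itart) / model$cap_art
  dTven <- (-F_b * cp_b * as.numeric(model$D_up %*% Tven) +
              model$gamma_ven * Jq_itven) / model$cap_ven

  # algebraic pinning of the boundary-constrained nodes
  if (phase == "inhalation") {
    dTa[1] <- 0; dwa[1] <- 0
  } else {
    dTa[Ns] <- 0; dwa[Ns] <- 0
  }
  dTm[Ns] <- 0; dTit[Ns] <- 0; dTart[Ns] <- 0
  dTven[1] <- dTart[1]

  list(c(dTa, dTm, dTit, dTart, dTven, dwa))
}

integrate_phase <- function(model, y, phase, t0, t1, n_out) {
  sv <- model$config$solver
  Ns <- length(model$grid$z_star)
  y <- apply_boundary_conditions(phase, y, model)
  atol <- c(rep(sv$abs_tol_T, 5 * Ns), rep(sv$abs_tol_w, Ns))
  tt <- seq(t0, t1, length.out = n_out)
  out <- deSolve::ode(y = y, times = tt,
                      func = function(t, y, p) rhs(t, y, model, phase),
                      parms = NULL, method = "vode",
                      rtol = sv$rel_tol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("stiff integration failed during ", phase)
  out[, -1, drop = FALSE]
}

# trapezoidal weights for possibly non-uniform abscissae
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

run_cycle <- function(model, y, n_out) {
  t2 <- model$pattern$t_br / 2
  out_in <- integrate_phase(model, y, "inhalation", 0, t2, n_out)
  y_mid <- out_in[nrow(out_in), ]
  out_ex <- integrate_phase(model, y_mid, "exhalation", t2,
                            model$pattern$t_br, n_out)
  y_end <- out_ex[nrow(out_ex), ]
  times <- c(seq(0, t2, length.out = n_out),
             seq(t2, model$pattern$t_br, length.out = n_out))
  list(states = rbind(out_in, out_ex), times = times, y_end = y_end,
       phase = rep(c("inhalation", "exhalation"), each = n_out))
}

cycle_monitors <- function(model, cyc) {
  Ns <- length(model$grid$z_star)
  ix <- state_indices(Ns)
  Fa <- breathing_flow(cyc$times, model$pattern)
  ex <- cyc$phase == "exhalation"
  wt <- trapz_weights(cyc$times[ex]) * abs(Fa[ex])
  Ta_ex <- sum(wt * cyc$states[ex, ix$Ta[1]]) / sum(wt)
  sig <- sigma_total_series(model, cyc)
  Sigma_irr <- sum(trapz_weights(cyc$times) * sig)
  list(Ta_ex = Ta_ex, Sigma_irr = Sigma_irr)
}

# total local entropy production integrated over z, one value per stored
# time (W/K); shared by the convergence monitor and the post-processor
sigma_total_series <- function(model, cyc) {
  Ns <- length(model$grid$z_star)
  ix <- state_indices(Ns)
  wz <- trapz_weights(model$grid$z)
  vapply(seq_len(nrow(cyc$states)), function(i) {
    y <- cyc$states[i, ]
    s <- sigma_profiles(model, y[ix$Ta], y[ix$Tm], y[ix$Tit],
                        y[ix$Tart], y[ix$Tven], y[ix$wa])
    sum(wz * s$sigma_total)
  }, numeric(1))
}

#' Integrate breathing cycles to the cyclic steady state
#'
#' Integrates cycle by cycle with a stiff implicit BDF scheme, switching
#' the boundary-condition set at the zeros of the breathing flow, until the
#' relative cycle-to-cycle change of both the flow-weighted expired-air
#' temperature and the total entropy production fall below
#' `convergence_eps`, then records one final cycle densely.
#'
#' @param model a [nose_model()].
#' @param verbose print per-cycle monitors.
#' @return an object of class `breathing_solution`: the final-cycle fields
#'   (`times`, matrices `Ta`, `Tm`, `Tit`, `Tart`, `Tven`, `wa` of size
#'   time x node), the convergence `trace`, `cycles` used and the model.
#' @export
run_to_cyclic_steady_state <- function(model, verbose = FALSE) {
  sv <- model$config$solver
  y <- initial_state(model)
  trace <- data.frame(cycle = integer(), Ta_ex = numeric(),
                      Sigma_irr = numeric(), rel_change = numeric())
  prev <- NULL
  converged <- FALSE
  for (cycle in seq_len(sv$max_cycles)) {
    cyc <- run_cycle(model, y, sv$n_monitor)
    y <- cyc$y_end
    mon <- cycle_monitors(model, cyc)
    # the entropy monitor's denominator is floored well below any physical
    # value so that an equilibrium run (Sigma_irr ~ 0 up to quadrature
    # noise) registers as converged rather than as 0/0 jitter
    rel <- if (is.null(prev)) NA_real_ else max(
      abs(mon$Ta_ex - prev$Ta_ex) / abs(prev$Ta_ex),
      abs(mon$Sigma_irr - prev$Sigma_irr) /
        max(abs(prev$Sigma_irr), 1e-6))
    trace <- rbind(trace, data.frame(cycle = cycle, Ta_ex = mon$Ta_ex,
                                     Sigma_irr = mon$Sigma_irr,
                                     rel_change = rel))
    if (verbose)
      message(sprintf("cycle %3d: Ta_ex = %.3f K, Sigma_irr = %.5g, rel = %.3g",
                      cycle, mon$Ta_ex, mon$Sigma_irr, rel))
    if (!is.na(rel) && rel < sv$convergence_eps) {
      converged <- TRUE
      break
    }
    prev <- mon
  }
  if (!converged)
    stop("no cyclic steady state within ", sv$max_cycles,
         " cycles; last relative change ",
         signif(utils::tail(trace$rel_change, 1), 3),
         " (see the convergence trace)")
  dense <- run_cycle(model, y, sv$n_dense)
  as_breathing_solution(model, dense, trace, cycle)
}

as_breathing_solution <- function(model, cyc, trace, cycles) {
  Ns <- length(model$grid$z_star)
  ix <- state_indices(Ns)
  fields <- lapply(ix, function(jj) {
    m <- cyc$states[, jj, drop = FALSE]
    dimnames(m) <- NULL   # drop the integrator's state-index labels
    m
  })
  structure(list(
    times = cyc$times, t_star = cyc$times / model$pattern$t_br,
    phase = cyc$phase, Fa = breathing_flow(cyc$times, model$pattern),
    Ta = fields$Ta, Tm = fields$Tm, Tit = fields$Tit,
    Tart = fields$Tart, Tven = fields$Tven, wa = fields$wa,
    grid = model$grid, model = model, trace = trace, cycles = cycles,
    converged = TRUE), class = "breathing_solution")
}

#' @export
print.breathing_solution <- function(x, ...) {
  cat("breathing solution:", x$model$geom$label, "\n")
  cat(sprintf("  converged after %d cycles; final Ta_ex = %.2f K\n",
              x$cycles, utils::tail(x$trace$Ta_ex, 1)))
  cat(sprintf("  grid Ns = %d, %d stored snapshots over one cycle\n",
              length(x$grid$z_star), length(x$times)))
  invisible(x)
}

#' Grid-convergence study
#'
#' Repeats the cyclic-steady-state run over a list of grid sizes and
#' reports the expired-air temperature and total entropy production with
#' their relative change from the previous grid level.
#'
#' @param geom an [mt_geometry()].
#' @param config a [default_config()].
#' @param Ns_list integer vector of grid sizes (>= 2 levels).
#' @return data.frame with columns `Ns`, `Ta_ex_K`, `Sigma_irr`,
#'   `rel_change_Ta`, `rel_change_Sigma`.
#' @export
grid_convergence_study <- function(geom, config = default_config(),
                                   Ns_list = c(6, 12, 24, 48)) {
  if (length(Ns_list) < 2L) stop("need at least 2 grid levels")
  rows <- lapply(Ns_list, function(Ns) {
    cfgN <- modify_config(config, solver = list(Ns = as.integer(Ns)))
    sol <- run_to_cyclic_steady_state(nose_model(geom, cfgN))
    eb <- total_entropy(sol)
    data.frame(Ns = Ns,
               Ta_ex_K = utils::tail(sol$trace$Ta_ex, 1),
               Sigma_irr = eb$Sigma_irr)
  })
  out <- do.call(rbind, rows)
  out$rel_change_Ta <- c(NA, abs(diff(out$Ta_ex_K)) /
                           utils::head(out$Ta_ex_K, -1))
  out$rel_change_Sigma <- c(NA, abs(diff(out$Sigma_irr)) /
                              pmax(utils::head(abs(out$Sigma_irr), -1), 1e-12))
  out
}
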