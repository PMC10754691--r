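test_that("upwinded stencils differentiate polynomials exactly", {
  n <- 24
  dz <- 0.0025
  z <- (0:(n - 1)) * dz
  for (sgn in c(1, -1)) {
    # linear and constant fields: exact at every node
    expect_equal(spatial_derivative(3.2 * z + 1, dz, sgn), rep(3.2, n))
    expect_equal(spatial_derivative(rep(2, n), dz, sgn), rep(0, n),
                 tolerance = 1e-12)
    # quadratic: exact everywhere (the centered closure is second order)
    f2 <- 5 * z^2 - z + 2
    d2 <- 10 * z - 1
    expect_equal(spatial_derivative(f2, dz, sgn), d2, tolerance = 1e-9)
    # quartic: exact to round-off at every five-point row; the single
    # stabilized closure row adjacent to the inflow boundary is the
    # documented second-order exception
    f4 <- z^4 - 3 * z^3 + z
    d4 <- 4 * z^3 - 9 * z^2 + 1
    got <- spatial_derivative(f4, dz, sgn)
    closure_row <- if (sgn > 0) 2L else n - 1L
    expect_equal(got[-closure_row], d4[-closure_row], tolerance = 1e-9)
    expect_equal(got[closure_row], d4[closure_row], tolerance = 1e-2)
  }
  expect_error(spatial_derivative(1:5, dz, 1), "at least 6")
})

test_that("the discrete advection operators are dissipative", {
  # all eigenvalues of the flow operator (inflow node removed) must lie in
  # the left half-plane, otherwise the advection scheme self-excites
  g <- tiny_geometry()
  m <- nose_model(g, fast_config())
  Ns <- length(m$grid$z_star)
  v <- m$pattern$Fa_max / (1.3 * m$grid$Aa)
  A_in <- -diag(v) %*% m$D_up
  ev_in <- eigen(A_in[2:Ns, 2:Ns], only.values = TRUE)$values
  expect_lt(max(Re(ev_in)), 0)
  A_ex <- diag(v) %*% m$D_down
  ev_ex <- eigen(A_ex[1:(Ns - 1), 1:(Ns - 1)], only.values = TRUE)$values
  expect_lt(max(Re(ev_ex)), 0)
})

test_that("pure advection translates a pulse at the flow speed", {
  # method-of-characteristics oracle: on a flat geometry with exchange
  # switched off (vanishing interface conductances), a smooth pulse in the
  # air temperature advects at Fa / (rho Aa) without distortion
  g <- synth_geometry(3e-3, 6, 0.05, 0.95, 32, 0.2, edge_fraction = 1)
  cfg <- default_config(
    ambient = list(T_C = 20, phi = 0.5),
    coeffs = list(h_q_if = 1e-9, k_w_if = 1e-12, q_star = 0,
                  h_m_it = 1e-6, h_it_art = 1e-6, h_it_ven = 1e-6),
    solver = list(Ns = 32))
  m <- nose_model(g, cfg)
  Ns <- 32
  ix <- turbsim:::state_indices(Ns)
  y <- turbsim:::initial_state(m)
  z <- m$grid$z
  zc <- z[1] + 0.25 * (z[Ns] - z[1])
  width <- 0.12 * (z[Ns] - z[1])   # ~3.5 cells: resolved by the stencils
  y[ix$Ta] <- 293.15 + 10 * exp(-((z - zc) / width)^2)
  y[ix$wa] <- air_state(293.15, phi = 0.5)$wa

  # integrate over a short window around peak inhalation flow, where the
  # flow is nearly constant at Fa_max
  t0 <- m$pattern$t_br / 4
  dt <- 0.05
  tt <- seq(t0, t0 + dt, length.out = 5)
  out <- deSolve::ode(y = y, times = tt,
                      func = function(t, y, p) rhs(t, y, m, "inhalation"),
                      parms = NULL, method = "vode",
                      rtol = 1e-8, atol = 1e-8)
  Ta_end <- unname(out[nrow(out), 1 + ix$Ta])
  rho <- air_state(293.15, phi = 0.5)$rho_a
  Fa_bar <- mean(breathing_flow(tt, m$pattern))
  shift <- Fa_bar / (rho * m$grid$Aa[1]) * dt
  expected <- 293.15 + 10 * exp(-((z - zc - shift) / width)^2)
  interior <- 5:(Ns - 4)
  expect_equal(Ta_end[interior], expected[interior], tolerance = 2e-3)
})

test_that("the uniform equilibrium state is a fixed point of the dynamics", {
  g <- tiny_geometry()
  cfg <- fast_config(36)
  cfg$ambient$phi <- 1.0
  m <- nose_model(g, cfg)
  y <- turbsim:::initial_state(m)
  for (t_probe in c(0, 0.4, 1.9, 2.8)) {
    phase <- if (t_probe < m$pattern$t_br / 2) "inhalation" else "exhalation"
    dy <- rhs(t_probe, y, m, phase)[[1]]
    expect_equal(max(abs(dy)), 0, tolerance = 1e-8)
  }
})

test_that("boundary conditions pin the correct nodes in each phase", {
  m <- nose_model(tiny_geometry(), fast_config(-30))
  Ns <- length(m$grid$z_star)
  ix <- turbsim:::state_indices(Ns)
  y <- turbsim:::initial_state(m) + 0.5   # not already at the targets
  yin <- apply_boundary_conditions("inhalation", y, m)
  expect_equal(yin[ix$Ta[1]], 243.15)
  expect_equal(yin[ix$wa[1]], m$amb$wa)
  expect_equal(yin[ix$Tm[Ns]], 309.15)
  expect_equal(yin[ix$Tit[Ns]], 309.15)
  expect_equal(yin[ix$Tart[Ns]], 309.15)
  expect_equal(yin[ix$Tven[1]], yin[ix$Tart[1]])

  yex <- apply_boundary_conditions("exhalation", y, m)
  expect_equal(yex[ix$Ta[Ns]], 309.15)
  expect_equal(yex[ix$wa[Ns]], m$body$wa)
  expect_equal(yex[ix$Tven[1]], yex[ix$Tart[1]])
  # the distal air node is free during exhalation
  expect_equal(yex[ix$Ta[1]], y[ix$Ta[1]])
})

test_that("equilibrium boundary conditions converge immediately with no dissipation", {
  sol <- equilibrium_solution()
  expect_lte(sol$cycles, 2)
  eb <- total_entropy(sol)
  expect_equal(eb$Sigma_irr, 0, tolerance = 1e-6)
  expect_equal(max(abs(sol$Ta - 309.15)), 0, tolerance = 1e-3)
})

test_that("a converged arctic run is physical", {
  sol <- arctic_solution()
  expect_true(sol$converged)
  # maximum principle: fields bounded by ambient and body temperatures
  lo <- 243.15 - 0.5
  hi <- 309.15 + 0.5
  for (f in c("Ta", "Tm", "Tit", "Tart", "Tven"))
    expect_true(all(sol[[f]] >= lo & sol[[f]] <= hi), label = f)
  expect_true(all(sol$wa >= 0))
  # expired air leaves warmer than ambient but cooler than the body
  es <- exchange_summary(sol)
  expect_gt(es$expired_T_K, 243.15)
  expect_lt(es$expired_T_K, 309.15)
  # at -30 C the condensation kinetics freeze out over the cold mucus
  # (the water resistivity scales as 1/c_sat), so expired air leaves
  # supersaturated - visible fogging - but boundedly so
  ex <- sol$phase == "exhalation"
  wa_sat <- turbsim:::x_to_w(turbsim:::p_sat_clamped(sol$Ta[ex, 1]) / 101325)
  expect_true(all(sol$wa[ex, 1] <= wa_sat * 2.5))
})

test_that("expired humidity stays near saturation at moderate ambient", {
  sol <- mild_solution()
  ex <- sol$phase == "exhalation"
  wa_sat <- turbsim:::x_to_w(turbsim:::p_sat_clamped(sol$Ta[ex, 1]) / 101325)
  expect_true(all(sol$wa[ex, 1] <= wa_sat * 1.2))
  # flow-weighted expired humidity below saturation at the flow-weighted
  # expired temperature within tolerance
  wflow <- abs(sol$Fa[ex])
  wbar <- sum(wflow * sol$wa[ex, 1]) / sum(wflow)
  Tbar <- sum(wflow * sol$Ta[ex, 1]) / sum(wflow)
  expect_lt(wbar, 1.2 * turbsim:::x_to_w(turbsim:::p_sat_clamped(Tbar) / 101325))
})

test_that("repeated runs are bit-identical (no hidden randomness)", {
  m1 <- nose_model(tiny_geometry(), fast_config(-30))
  s1 <- run_to_cyclic_steady_state(m1)
  m2 <- nose_model(tiny_geometry(), fast_config(-30))
  s2 <- run_to_cyclic_steady_state(m2)
  expect_identical(s1$Ta, s2$Ta)
  expect_identical(s1$wa, s2$wa)
  expect_identical(s1$trace, s2$trace)
})

test_that("the cyclic steady state does not depend on the initial condition", {
  # a thin tissue sleeve makes the slowest (blood/tissue) mode fast, so a
  # tight convergence threshold is affordable and the two starts must meet
  cfg <- default_config(
    ambient = list(T_C = -30),
    tissue = list(d_it = 2e-5),
    solver = list(Ns = 12, convergence_eps = 1e-4, n_monitor = 17,
                  n_dense = 33, max_cycles = 300))
  m <- nose_model(tiny_geometry(), cfg)
  sol_body <- run_to_cyclic_steady_state(m)   # default start: body state

  # start from ambient conditions instead
  Ns <- length(m$grid$z_star)
  y <- c(rep(m$T_amb, 5 * Ns), rep(m$amb$wa, Ns))
  sv <- m$config$solver
  prev <- NULL
  mon <- NULL
  for (cycle in 1:sv$max_cycles) {
    cyc <- turbsim:::run_cycle(m, y, sv$n_monitor)
    y <- cyc$y_end
    mon <- turbsim:::cycle_monitors(m, cyc)
    if (!is.null(prev) &&
        abs(mon$Ta_ex - prev$Ta_ex) / prev$Ta_ex < sv$convergence_eps &&
        abs(mon$Sigma_irr - prev$Sigma_irr) /
          max(prev$Sigma_irr, 1e-6) < sv$convergence_eps) break
    prev <- mon
  }
  tr <- sol_body$trace
  expect_equal(mon$Ta_ex, tr$Ta_ex[nrow(tr)], tolerance = 2e-3)
  expect_equal(mon$Sigma_irr, tr$Sigma_irr[nrow(tr)], tolerance = 0.02)
})

test_that("grid-convergence study reports per-level entropy and changes", {
  g <- tiny_geometry()
  cfg <- default_config(
    ambient = list(T_C = 36, phi = 1.0),
    solver = list(convergence_eps = 1e-3, n_monitor = 9, n_dense = 17,
                  max_cycles = 5))
  tab <- grid_convergence_study(g, cfg, Ns_list = c(6, 12))
  expect_equal(tab$Ns, c(6, 12))
  # the equilibrium case dissipates nothing at any grid size
  expect_equal(tab$Sigma_irr, c(0, 0), tolerance = 1e-6)
  expect_true(is.na(tab$rel_change_Ta[1]))
  expect_lt(tab$rel_change_Ta[2], 1e-6)
  expect_error(grid_convergence_study(g, cfg, Ns_list = 24), "2 grid levels")
})

test_that("non-convergence raises an informative error", {
  cfg <- fast_config(-30)
  cfg$solver$max_cycles <- 2
  cfg$solver$convergence_eps <- 1e-12
  m <- nose_model(tiny_geometry(), cfg)
  expect_error(run_to_cyclic_steady_state(m), "no cyclic steady state")
})
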