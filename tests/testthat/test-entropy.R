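test_that("local entropy terms are non-negative and decompose exactly", {
  sol <- arctic_solution()
  n_t <- length(sol$times)
  Ns <- length(sol$grid$z_star)
  set.seed(11)
  for (k in 1:40) {
    node <- sample(Ns, 1)
    ti <- sample(n_t, 1)
    s <- local_entropy(sol, node, ti)
    # single-force conductive terms are non-negative by construction
    expect_gte(s$sigma_mit, -1e-12)
    expect_gte(s$sigma_itart, -1e-12)
    expect_gte(s$sigma_itven, -1e-12)
    # the coupled air-mucus pair is non-negative as a sum
    expect_gte(s$sigma_am, -1e-12)
    # and decomposes exactly into heat and water parts
    expect_equal(s$sigma_am, s$sigma_am_q + s$sigma_am_w, tolerance = 1e-12)
    expect_gte(s$sigma_total, -1e-12)
  }
})

test_that("equilibrium runs produce no entropy", {
  sol <- equilibrium_solution()
  eb <- total_entropy(sol)
  expect_equal(eb$Sigma_irr, 0, tolerance = 1e-6)
  expect_equal(eb$W_lost, 0, tolerance = 1e-4)
  s <- local_entropy(sol, 3, 5)
  expect_equal(s$sigma_total, 0, tolerance = 1e-9)
})

test_that("cycle-integrated components are non-negative and sum to the total", {
  sol <- arctic_solution()
  eb <- total_entropy(sol)
  for (comp in c("Sigma_am_q", "Sigma_am_w", "Sigma_am", "Sigma_mit",
                 "Sigma_itart", "Sigma_itven"))
    expect_gte(eb[[comp]], 0)
  expect_equal(eb$Sigma_irr,
               eb$Sigma_am + eb$Sigma_mit + eb$Sigma_itart + eb$Sigma_itven,
               tolerance = 1e-10)
  expect_equal(eb$Sigma_am, eb$Sigma_am_q + eb$Sigma_am_w,
               tolerance = 1e-10)
  # the air-mucus interface dominates; blood-side contacts are minor
  expect_gt(eb$Sigma_am, eb$Sigma_itart)
  expect_gt(eb$Sigma_am, eb$Sigma_itven)
  # lost work identity
  expect_equal(eb$W_lost / eb$Sigma_irr, eb$T_amb, tolerance = 1e-10)
})

test_that("lost work reproduces the dissipated-energy arithmetic", {
  # entropy production 0.025 J/(K cyc) at -30 C ambient dissipates ~6 J/cyc
  expect_equal(lost_work(0.025, 243.15), 6.08, tolerance = 0.002)
  # 0.041 at -30 C gives 10.0; 0.004 and 0.007 at 10 C give 1.1 and 2.0
  expect_equal(lost_work(0.041, 243.15), 10.0, tolerance = 0.005)
  expect_equal(lost_work(0.004, 283.15), 1.1, tolerance = 0.03)
  expect_equal(lost_work(0.007, 283.15), 2.0, tolerance = 0.01)
  expect_equal(lost_work(0, 300), 0)
  expect_error(lost_work(-0.1, 300))
})

test_that("dissipation rates convert per-cycle lost work to kJ/h and kJ/day", {
  r <- dissipation_rates(2.0, 3.09)
  expect_equal(r$kJ_per_h, 2.3, tolerance = 0.02)
  expect_equal(r$kJ_per_day, 55.9, tolerance = 0.01)
  expect_equal(dissipation_rates(0, 3.09)$kJ_per_h, 0)
  expect_equal(dissipation_rates(0, 3.09)$kJ_per_day, 0)
})

test_that("recovery definition limits: ambient expiry is 100%, body expiry 0%", {
  sol <- arctic_solution()
  # construct synthetic solutions by overwriting the distal air history
  ex <- sol$phase == "exhalation"
  amb <- sol$model$amb
  body <- sol$model$body

  sol_amb <- sol
  sol_amb$Ta[ex, 1] <- amb$T
  sol_amb$wa[ex, 1] <- amb$wa
  es <- exchange_summary(sol_amb)
  expect_equal(es$heat_loss_J, 0, tolerance = 1e-9)
  expect_equal(es$heat_recovery_pct, 100)
  expect_equal(es$water_recovery_pct, 100)

  sol_body <- sol
  sol_body$Ta[ex, 1] <- body$T
  sol_body$wa[ex, 1] <- body$wa
  es2 <- exchange_summary(sol_body)
  expect_equal(es2$heat_recovery_pct, 0, tolerance = 1e-9)
  expect_equal(es2$water_recovery_pct, 0, tolerance = 1e-9)
  expect_equal(es2$expired_T_K, body$T)

  # internal consistency: recovery recomputed from losses and baselines
  es3 <- exchange_summary(sol)
  expect_equal(es3$heat_recovery_pct,
               100 * (1 - es3$heat_loss_J / es3$heat_baseline_J))
  expect_equal(es3$water_recovery_pct,
               100 * (1 - es3$water_loss_kg / es3$water_baseline_kg))
  expect_true(es3$heat_recovery_pct > 0 && es3$heat_recovery_pct < 100)
})

test_that("expired-temperature regression recovers the limiting slopes", {
  tamb <- c(-30, -20, -10, 0, 10)
  # perfect exchanger: constant expired temperature, slope 0
  fit0 <- expired_t_regression(tamb, rep(30, 5))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$intercept, 30)
  # no exchange: expired equals ambient, slope 1
  fit1 <- expired_t_regression(tamb, tamb)
  expect_equal(fit1$slope, 1)
  # exact recovery of a known affine law
  fit <- expired_t_regression(tamb, 0.42 * tamb + 16.7)
  expect_equal(fit$slope, 0.42)
  expect_equal(fit$intercept, 16.7)
  expect_error(expired_t_regression(c(-10, -10, -10), c(1, 2, 3)),
               ">= 3 distinct")
})

test_that("cycle budgets close for a converged run", {
  sol <- arctic_solution()
  b <- cycle_budget(sol)
  # each subsystem's advective transport balances its interface sources
  # over the cycle, to within periodicity + quadrature tolerance
  expect_lt(b$water$rel_residual, 0.02)
  expect_lt(b$air_energy$rel_residual, 0.02)
  # the blood compartments carry the slowest-converging mode, so their
  # residual is dominated by the cycle-convergence threshold itself
  expect_lt(b$artery$rel_residual, 0.05)
  expect_lt(b$vein$rel_residual, 0.05)
  # water actually moves: the paired integrals are far from zero
  expect_gt(abs(b$water$interface_sink), 1e-7)
})
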