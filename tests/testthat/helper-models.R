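# Shared fixtures: small, fast model configurations used across tests.
# Test runs use a coarser grid and looser cycle-convergence threshold than
# the production defaults to keep the suite quick; the methods vignette
# records the full-resolution settings.

fast_solver <- function(...) {
  list(Ns = 12, convergence_eps = 1e-3, n_monitor = 17, n_dense = 33,
       max_cycles = 200, ...)
}

fast_config <- function(Tamb_C = -30, ...) {
  default_config(ambient = list(T_C = Tamb_C),
                 solver = fast_solver(), ...)
}

tiny_geometry <- function(n_nodes = 24) {
  synth_geometry(Aa_max = 3.55e-3, gamma_max = 11.1, z_lo = 0.14,
                 z_hi = 0.87, n_nodes = n_nodes, L = 0.061,
                 edge_fraction = 0.2, label = "test Eb-like")
}

# cache converged solutions so several test files can share one run
solution_cache <- new.env(parent = emptyenv())

cached_solution <- function(key, builder) {
  if (is.null(solution_cache[[key]]))
    solution_cache[[key]] <- builder()
  solution_cache[[key]]
}

arctic_solution <- function() {
  cached_solution("arctic", function() {
    m <- nose_model(tiny_geometry(), fast_config(-30))
    run_to_cyclic_steady_state(m)
  })
}

mild_solution <- function() {
  cached_solution("mild", function() {
    m <- nose_model(tiny_geometry(), fast_config(10))
    run_to_cyclic_steady_state(m)
  })
}

equilibrium_solution <- function() {
  cached_solution("equilibrium", function() {
    cfg <- default_config(
      ambient = list(T_C = 36, phi = 1.0),
      solver = list(Ns = 12, convergence_eps = 1e-3, n_monitor = 9,
                    n_dense = 17, max_cycles = 5))
    m <- nose_model(tiny_geometry(), cfg)
    run_to_cyclic_steady_state(m)
  })
}
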