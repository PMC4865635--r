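# Shared fixtures. Expensive simulations are run once per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

ncp_params <- function() cached("params", default_ncp_parameters())

field_a_topsoil <- function() ncp_params()$soils$A$horizons[[1]]

grid_a <- function() cached("grid_a", make_default_grid(ncp_params()$soils$A))

# single-horizon loam profile for idealised solver tests
uniform_profile <- function(Ksat = 2, theta_sat = 0.42, theta_res = 0.05,
                            alpha = 0.01, n = 1.4, l = 0.5) {
  cropnsim:::validate_soil_profile(list(
    field = "toy", bulk_density = 1.4,
    horizons = list(list(
      depth_top = 0, depth_bottom = 210, Ksat = Ksat, theta_sat = theta_sat,
      theta_res = theta_res, alpha = alpha, n = n, l = l, humus = 1,
      SOM_fractions = c(0.5, 0.4, 0.1), C_per_N = 10, clay = 0.1))))
}

# the 2-year maize-wheat rotation used by the conservation and
# mineralisation-pattern checks (shared across test files)
rotation_2y <- function() cached("rotation_2y", {
  run_simulation(build_field_fixture("A", n_rate = 400, years = 2, seed = 7))
})
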