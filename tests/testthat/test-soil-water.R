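test_that("default grid matches the profile discretisation", {
  g <- grid_a()
  expect_equal(g$n_cells, 56)               # 30 x 2 cm + 22 x 5 cm + 4 x 10 cm
  expect_equal(max(g$edges), 210)
  expect_equal(sum(g$dz[1:30]), 60)
  short <- uniform_profile()
  short$horizons[[1]]$depth_bottom <- 100
  expect_error(make_default_grid(short), "210")
})

test_that("van Genuchten retention matches the closed form and inverts", {
  hz <- field_a_topsoil()
  expect_equal(vg_theta(0, hz), 0.39)
  # dry limit: theta approaches theta_res (n = 1.332 converges slowly, so
  # the limit is probed far out on the suction axis)
  expect_lt(abs(vg_theta(-1e12, hz) - 0.06), 1e-3)   # absolute volume fraction
  expect_lt(vg_theta(-1e7, hz), 0.07)
  # independent scalar evaluation at pF 2
  m <- 1 - 1 / 1.332
  direct <- 0.06 + (0.39 - 0.06) * (1 + (0.008 * 100)^1.332)^(-m)
  expect_equal(vg_theta(-100, hz), direct, tolerance = 1e-12)
  th <- vg_theta(c(-10, -100, -1000, -15000), hz)
  expect_equal(vg_head(th, hz), c(-10, -100, -1000, -15000), tolerance = 1e-9)
  expect_error(vg_head(0.05, hz), "theta outside")
})

test_that("Mualem conductivity honours the saturated matching point", {
  hz <- field_a_topsoil()
  expect_equal(vg_conductivity(0, hz), 1.56)
  expect_equal(vg_conductivity(10, hz), 1.56)
  expect_lt(vg_conductivity(-1e6, hz), 1e-10)
  # negative tortuosity horizon stays finite and positive at Se = 0.5
  hz2 <- ncp_params()$soils$A$horizons[[2]]
  th_half <- hz2$theta_res + 0.5 * (hz2$theta_sat - hz2$theta_res)
  k_half <- vg_conductivity(vg_head(th_half, hz2), hz2)
  m2 <- 1 - 1 / hz2$n
  direct <- hz2$Ksat * 0.5^hz2$l * (1 - (1 - 0.5^(1 / m2))^m2)^2
  expect_equal(k_half, direct, tolerance = 1e-9)
  expect_gt(k_half, 0)
  expect_true(is.finite(k_half))
})

test_that("hydrostatic equilibrium is a fixed point of the Richards step", {
  g <- grid_a()
  st <- init_soil_water(g, water_table = 300)
  r <- richards_step(st, g, dt = 1, surface_flux = 0,
                     lower_bc = list(type = "no_flow"))
  expect_lt(max(abs(r$state$theta - st$theta)), 1e-6)
  expect_equal(r$bottom_drainage, 0)
})

test_that("gravity drainage monotonically depletes storage", {
  g <- grid_a()
  st <- init_soil_water(g, h = -50)
  s_prev <- water_storage(st, g)
  for (d in 1:5) {
    r <- richards_step(st, g, dt = 1, surface_flux = 0)
    st <- r$state
    s_now <- water_storage(st, g)
    expect_lt(s_now, s_prev)
    s_prev <- s_now
  }
})

test_that("saturated free-draining column leaks at the basal Ksat", {
  # unit-gradient identity while the column is still saturated (short step)
  g <- grid_a()
  st <- init_soil_water(g, h = 0)
  r <- richards_step(st, g, dt = 0.05, surface_flux = 0)
  ks_bottom <- ncp_params()$soils$A$horizons[[4]]$Ksat   # cm/h
  expect_lt(abs(r$bottom_drainage - ks_bottom * 24 * 10 * 0.05),
            0.01 * ks_bottom * 24 * 10 * 0.05)
})

test_that("per-step water balance closes to round-off on varied forcing", {
  g <- grid_a()
  st <- init_soil_water(g, h = -200)
  set.seed(9)
  for (d in 1:25) {
    fl <- sample(c(-4, -2, 0, 6, 25, 60), 1)
    sink <- if (d %% 2) { s <- numeric(g$n_cells); s[1:25] <- 3 / 25; s }
    r <- richards_step(st, g, dt = 1, surface_flux = fl, sink = sink)
    st <- r$state
    expect_lt(abs(r$balance_error), 1e-4)
    expect_true(all(st$theta >= g$hyd$th_r - 1e-6))
    expect_true(all(st$theta <= g$hyd$th_s + 1e-6))
  }
})

test_that("drainage_at_depth reads the edge flux and refuses off-edge depths", {
  g <- grid_a()
  st <- init_soil_water(g, h = -100)
  r <- richards_step(st, g, dt = 1, surface_flux = 0)
  expect_error(drainage_at_depth(r$flux, 101), "not a cell edge")
  d200 <- drainage_at_depth(r$flux, 200)
  # mass-balance oracle: flux past z equals surface input minus storage
  # change above z (no sink)
  i_above <- g$edges[-length(g$edges)] < 200
  dstor <- sum((r$state$w - cropnsim:::vg_w_v(init_soil_water(g, h = -100)$h,
                                              g$hyd))[i_above] *
                 g$dz[i_above]) * 10
  expect_equal(d200, r$actual_surface_flux - dstor, tolerance = 1e-3)
})

test_that("infiltration is self-convergent under grid and step refinement", {
  prof <- uniform_profile()
  g1 <- make_default_grid(prof)
  g2 <- make_default_grid(prof, increments = list(c(0, 60, 1), c(60, 170, 2.5),
                                                  c(170, 210, 5)))
  run <- function(g, ctl) {
    st <- init_soil_water(g, h = -1000)
    tot <- 0
    for (d in 1:3) {
      r <- richards_step(st, g, dt = 1, surface_flux = 15, control = ctl)
      st <- r$state
      tot <- tot + r$infiltration
    }
    tot
  }
  coarse <- run(g1, cropnsim:::richards_control())
  fine <- run(g2, cropnsim:::richards_control(dt_max = 0.5, max_dtheta = 0.005))
  expect_equal(coarse, fine, tolerance = 0.02)
})

test_that("soil temperature is a damped annual sinusoid", {
  # full amplitude at the surface
  t_surf <- soil_temperature_profile(197, 0, annual_mean = 12.5,
                                     annual_amplitude = 14.5,
                                     damping_depth = 180)
  expect_equal(t_surf, 12.5 + 14.5 * sin(2 * pi * (197 - 106) / 365),
               tolerance = 1e-9)
  # deep soil sits at the annual mean
  expect_equal(soil_temperature_profile(1, 1e5), 12.5, tolerance = 1e-6)
  # amplitude falls to 1/e at one damping depth
  amp_d <- max(vapply(1:365, soil_temperature_profile, 0, depth = 180)) - 12.5
  expect_equal(amp_d, 14.5 / exp(1), tolerance = 0.01)
})
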