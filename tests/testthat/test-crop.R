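maize <- function() ncp_params()$crops$maize
wheat <- function() ncp_params()$crops$wheat

test_that("phenology accumulates emergence heat sum then DS at the set rates", {
  cp <- maize()
  st <- init_crop_state(cp, grid_a())
  # EmrTSum 200 at constant 20 degC soil: emergence on day 10
  for (d in 1:9) st <- phenology_step(st, t_soil = 20, t_mean = 20, cp)
  expect_false(st$emerged)
  st <- phenology_step(st, 20, 20, cp)
  expect_true(st$emerged)
  # at the plateau of the temperature response (f_T = 1), DSRate1 = 0.0265:
  # flowering is reached on day ceiling(1/0.0265) = 38 after emergence
  days <- 0
  while (st$DS < 1) {
    st <- phenology_step(st, 25, 25, cp)
    days <- days + 1
  }
  expect_equal(days, ceiling(1 / cp$DSRate1))
  # below the base temperature development stalls
  ds0 <- st$DS
  st <- phenology_step(st, 5, 5, cp)
  expect_equal(st$DS, ds0)
})

test_that("leaf area follows SpLAI and the DS-interpolated modifier", {
  cp <- maize()
  st <- init_crop_state(cp, grid_a())
  st$emerged <- TRUE
  st$dm[["leaf"]] <- 100
  st$DS <- 0.25   # halfway between knots 0 (0.7) and 0.5 (0.8)
  expect_equal(update_leaf_area(st, cp), 100 * 0.02 * 0.75)
  st$DS <- 2
  expect_equal(update_leaf_area(st, cp), 100 * 0.02 * 0.2)
})

test_that("canopy photosynthesis is zero without light or leaves and converges", {
  cp <- maize()
  expect_equal(canopy_gross_photosynthesis(0, 300, 14, 25, 1, 1, 1, cp), 0)
  expect_equal(canopy_gross_photosynthesis(3, 0, 14, 25, 1, 1, 1, cp), 0)
  coarse <- canopy_gross_photosynthesis(3, 200, 14, 25, 0.8, 1, 1, cp)
  fine <- canopy_gross_photosynthesis(3, 200, 14, 25, 0.8, 1, 1, cp,
                                      n_layers = 1000)
  expect_equal(coarse, fine, tolerance = 0.01)
  expect_gt(coarse, 0)
})

test_that("growth respects efficiencies and conserves carbon", {
  cp <- maize()
  st <- init_crop_state(cp, grid_a())
  st$emerged <- TRUE
  # zero assimilate, zero maintenance: no change
  cp0 <- cp
  cp0$r_Leaf <- cp0$r_Stem <- cp0$r_SOrg <- cp0$r_Root <- 0
  st0 <- daily_growth(st, 0, 20, cp0)
  expect_equal(st0$dm, st$dm)
  # all partition to the storage organ at E_SOrg = 0.75
  cp1 <- cp0
  cp1$partitioning_by_DS <- matrix(c(0, 0, 0, 0, 1, 2, 0, 0, 0, 1), 2, 5,
                                   byrow = TRUE,
                                   dimnames = list(NULL, colnames(cp0$partitioning_by_DS)))
  st1 <- st
  st1$DS <- 1
  grown <- daily_growth(st1, 10 * 44 / 30, 20, cp1)   # 10 g CH2O available
  expect_equal(grown$dm[["sorg"]] - st1$dm[["sorg"]], 7.5)
  # carbon ledger: growth/E + maintenance paid = CH2O supplied
  st2 <- daily_growth(st, 40, 22, cp)
  eff <- c(root = cp$E_Leaf, leaf = cp$E_Leaf, stem = cp$E_Stem,
           sorg = cp$E_SOrg)
  consumed <- sum((st2$dm - st$dm) / eff[names(st$dm)]) + st2$maint_paid
  expect_equal(consumed, 40 * 30 / 44, tolerance = 1e-9)
})

test_that("root length is conserved and distributed exponentially", {
  cp <- maize()
  g <- grid_a()
  st <- init_crop_state(cp, g)
  st$emerged <- TRUE
  st$dm[["root"]] <- 80
  st$root_depth <- 57.5   # advances by the penetration rate, capped later
  st <- root_growth_and_distribution(st, g, cp, max_rooting_depth = 190)
  expect_equal(st$root_depth, 60)
  total_cm <- sum(st$rld * g$dz * 1e4)
  expect_equal(total_cm, 80 * cp$SpRtLength * 100, tolerance = 1e-9)
  # closed-form share above half the rooting depth for a = 3/zr
  frac_above <- sum((st$rld * g$dz)[g$edges[-length(g$edges)] < 30]) /
    sum(st$rld * g$dz)
  expect_equal(frac_above, (1 - exp(-1.5)) / (1 - exp(-3)), tolerance = 1e-9)
  # wheat cap: min(MaxPen 210, profile rooting depth 190)
  stw <- init_crop_state(wheat(), g)
  stw$emerged <- TRUE
  stw$root_depth <- 500  # absurd start is clamped
  stw <- root_growth_and_distribution(stw, g, wheat(), 190)
  expect_lte(stw$root_depth, 210)
})

test_that("N uptake is limited by roots, soil supply and crop demand", {
  cp <- maize()
  g <- grid_a()
  st <- init_crop_state(cp, g)
  st$emerged <- TRUE
  st$dm <- c(root = 50, leaf = 120, stem = 100, sorg = 0)
  st$n_organ <- c(root = 0.1, leaf = 0.5, stem = 0.3, sorg = 0)
  sn <- init_soil_n(g, nh4 = 50, no3 = 50)
  # no roots: no uptake
  r0 <- crop_n_uptake(st, sn, g, cp)
  expect_equal(r0$uptake, 0)
  # single rooted cell with abundant N and demand: Mx * length * 24 exactly
  st$rld[5] <- 2
  cell_len <- 2 * g$dz[5] * 1e4
  r1 <- crop_n_uptake(st, sn, g, cp)
  expect_equal(r1$uptake,
               (cp$MxNH4Up + cp$MxNO3Up) * cell_len * 24 * 10,
               tolerance = 1e-9)
  # crop at its target N: demand zero, uptake zero
  st_full <- st
  st_full$n_organ <- st$dm * 0.2
  r2 <- crop_n_uptake(st_full, sn, g, cp)
  expect_equal(r2$uptake, 0)
  # soil never driven negative even under extreme demand
  sn_low <- init_soil_n(g, nh4 = 1e-4, no3 = 1e-4)
  st_hungry <- st
  st_hungry$rld <- rep(5, g$n_cells)
  r3 <- crop_n_uptake(st_hungry, sn_low, g, cp)
  expect_true(all(r3$soil_n$nh4 >= -1e-15))
  expect_true(all(r3$soil_n$no3 >= -1e-15))
})
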