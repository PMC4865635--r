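test_that("organic matter initialisation splits C by the horizon fractions", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  pools <- initialise_som(g, tv)
  # total C over pools equals the computed horizon C
  bd <- 1.4e6
  expected_c1 <- 1.5 / 100 * tv$c_in_humus * bd      # topsoil cell, g C/m3
  expect_equal(sum(pools$C[1, ]), expected_c1, tolerance = 1e-9)
  # split: SMB carved out, remainder by SOM_fractions 0.48/0.42/0.10
  som_c <- expected_c1 * (1 - tv$smb_init_fraction)
  expect_equal(unname(pools$C[1, "SOM1"]), som_c * 0.48)
  expect_equal(unname(pools$C[1, "SOM2"]), som_c * 0.42)
  expect_equal(unname(pools$C[1, "SOM3"]), som_c * 0.10)
  # SMB carries C/N 4.8
  expect_equal(unname(pools$C[1, "SMB1"] / pools$N[1, "SMB1"]), 4.8)
  # deep horizon is fully inert
  deep <- g$n_cells
  expect_equal(unname(pools$C[deep, "SOM1"]), 0)
  expect_gt(unname(pools$C[deep, "SOM3"]), 0)
})

test_that("a fully inert profile does not turn over", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  pools <- initialise_som(g, tv)
  pools$C[] <- 0
  pools$N[] <- 0
  pools$C[, "SOM3"] <- 5000
  pools$N[, "SOM3"] <- 500
  sn <- init_soil_n(g)
  r <- turnover_step(pools, sn, rep(20, g$n_cells), rep(0.3, g$n_cells), g, tv)
  expect_equal(r$pools$C, pools$C)
  expect_equal(r$net_min, 0)
})

test_that("added residue is partitioned with its slow-pool C/N", {
  g <- grid_a()
  pools0 <- initialise_som(g, ncp_params()$turnover)
  # 1000 kg C/ha, half to the slow pool at C/N 60
  pools <- add_organic_matter(pools0, g, c_amount = 1000, n_amount = 20,
                              c_per_n_slow = 60, aom1_fraction = 0.5,
                              depth_range = c(0, 25))
  dzm <- g$dz / 100
  aom1_c <- sum((pools$C[, "AOM1"] - pools0$C[, "AOM1"]) * dzm) * 10
  aom1_n <- sum((pools$N[, "AOM1"] - pools0$N[, "AOM1"]) * dzm) * 10
  expect_equal(aom1_c, 500, tolerance = 1e-9)
  expect_equal(aom1_n, 500 / 60, tolerance = 1e-9)
  # totals conserved
  tot_c <- sum(sweep(pools$C - pools0$C, 1, dzm, `*`)) * 10
  tot_n <- sum(sweep(pools$N - pools0$N, 1, dzm, `*`)) * 10
  expect_equal(tot_c, 1000, tolerance = 1e-9)
  expect_equal(tot_n, 20, tolerance = 1e-9)
  # zero addition is a no-op
  expect_equal(add_organic_matter(pools, g, 0, 0), pools)
})

test_that("turnover conserves N between pools and mineral forms", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  pools <- initialise_som(g, tv)
  pools <- add_organic_matter(pools, g, 2000, 15, c_per_n_slow = 60)
  sn <- init_soil_n(g, nh4 = 1, no3 = 3)
  dzm <- g$dz / 100
  n_before <- sum(rowSums(pools$N) * dzm) * 10 +
    sum((sn$nh4 + sn$no3) * dzm) * 10
  tsoil <- soil_temperature_profile(200, g$zc)
  for (d in 1:10) {
    r <- turnover_step(pools, sn, tsoil, rep(0.28, g$n_cells), g, tv)
    pools <- r$pools; sn <- r$soil_n
  }
  n_after <- sum(rowSums(pools$N) * dzm) * 10 +
    sum((sn$nh4 + sn$no3) * dzm) * 10
  expect_equal(n_after, n_before, tolerance = 1e-9 * n_before)
  expect_true(all(pools$C >= 0))
  expect_true(all(pools$N >= 0))
})

test_that("high C/N straw immobilises mineral N in the first weeks", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  pools <- initialise_som(g, tv)
  sn <- init_soil_n(g, nh4 = 2, no3 = 10)
  tsoil <- soil_temperature_profile(280, g$zc)   # early October
  theta <- rep(0.28, g$n_cells)
  # reference: no straw
  ref_min <- numeric(14)
  p2 <- pools; s2 <- sn
  for (d in 1:14) {
    r <- turnover_step(p2, s2, tsoil, theta, g, tv)
    p2 <- r$pools; s2 <- r$soil_n; ref_min[d] <- r$net_min
  }
  # with incorporated straw at C/N 60
  straw <- add_organic_matter(pools, g, c_amount = 2000, n_amount = 2000 / 60,
                              c_per_n_slow = 60, depth_range = c(0, 20))
  got_min <- numeric(14)
  p3 <- straw; s3 <- sn
  for (d in 1:14) {
    r <- turnover_step(p3, s3, tsoil, theta, g, tv)
    p3 <- r$pools; s3 <- r$soil_n; got_min[d] <- r$net_min
  }
  expect_lt(sum(got_min), sum(ref_min))   # net immobilisation relative to ref
})

test_that("nitrification transfers NH4 to NO3 with an N2O by-product", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  tv$nitrification_rate <- 0.1
  sn <- init_soil_n(g, nh4 = 10, no3 = 0)
  # modifiers at 1: T = 10 degC, relative saturation 0.7
  tsoil <- rep(10, g$n_cells)
  theta <- 0.7 * g$hyd$th_s
  sn0 <- sn
  sn <- nitrification_step(sn, tsoil, theta, g, tv)
  expect_equal(sn$nh4, sn0$nh4 * exp(-0.1), tolerance = 1e-9)
  # mineral N conserved minus the N2O share
  lost <- sum((sn0$nh4 - sn$nh4) * g$dz / 100) * 10
  gained <- sum((sn$no3 - sn0$no3) * g$dz / 100) * 10
  expect_equal(gained, lost * (1 - tv$n2o_fraction_nitrification),
               tolerance = 1e-9)
  # zero NH4: no change
  snz <- init_soil_n(g, nh4 = 0, no3 = 5)
  expect_equal(nitrification_step(snz, tsoil, theta, g, tv)$no3, snz$no3)
})

test_that("denitrification follows the tabulated water factor", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  # below the first knot the factor floors at the tabulated 0.01
  expect_equal(cropnsim:::interp_table(0.5, tv$water_factor), 0.01)
  expect_equal(cropnsim:::interp_table(1.0, tv$water_factor), 0.01)
  sn <- init_soil_n(g, nh4 = 0, no3 = 10)
  r <- denitrification_step(sn, rep(10, g$n_cells), g$hyd$th_s, g, tv)
  expect_equal(r$no3, 10 * exp(-tv$denit_potential_rate * 0.01) *
                 rep(1, g$n_cells), tolerance = 1e-9)
  snz <- init_soil_n(g, nh4 = 5, no3 = 0)
  expect_equal(denitrification_step(snz, rep(10, g$n_cells), g$hyd$th_s,
                                    g, tv)$no3, snz$no3)
})

test_that("fertiliser application volatilises by the dressing-size scheme", {
  g <- grid_a()
  sch <- ncp_params()$volatilisation
  sn <- init_soil_n(g, nh4 = 0, no3 = 0)
  r <- apply_fertiliser(sn, g, 300, "urea", sch)
  expect_equal(unname(r$ledger["volatilisation"]), 51)     # 17% of 300
  added <- sum(r$nh4 * g$dz / 100) * 10
  expect_equal(added, 249, tolerance = 1e-9)
  expect_equal(unname(r$ledger["fertiliser"]), 300)
  expect_equal(apply_fertiliser(sn, g, 0, "urea", sch), sn)
  expect_error(apply_fertiliser(sn, g, 100, "manure", sch), "unknown")
})

test_that("solute transport conserves mass and leaves still water alone", {
  g <- grid_a()
  tv <- ncp_params()$turnover
  sn <- init_soil_n(g, nh4 = 3, no3 = 7)
  theta <- rep(0.3, g$n_cells)
  still <- list(edges = g$edges, flux = rep(0, g$n_cells + 1))
  r0 <- cde_transport_step(sn, still, theta, g, tv)
  expect_equal(r0$soil_n$no3, sn$no3, tolerance = 1e-12)
  expect_equal(r0$leach_no3, 0)
  # steady downward flow: total N (profile + leached) conserved
  fl <- list(edges = g$edges, flux = rep(8, g$n_cells + 1))
  n_tot0 <- sum((sn$nh4 + sn$no3) * g$dz / 100) * 10
  snx <- sn
  leached <- 0
  for (d in 1:15) {
    r <- cde_transport_step(snx, fl, theta, g, tv)
    snx <- r$soil_n
    leached <- leached + r$leach_no3 + r$leach_nh4
  }
  n_tot1 <- sum((snx$nh4 + snx$no3) * g$dz / 100) * 10
  expect_equal(n_tot1 + leached, n_tot0, tolerance = 1e-6 * n_tot0)
  expect_gt(leached, 0)
})
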