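test_that("packaged NCP parameter set carries the calibrated values", {
  ps <- ncp_params()
  top <- ps$soils$A$horizons[[1]]
  expect_equal(top$Ksat, 1.56)
  expect_equal(top$theta_sat, 0.39)
  expect_equal(top$theta_res, 0.06)
  expect_equal(top$alpha, 0.008)
  expect_equal(top$n, 1.332)
  expect_equal(top$SOM_fractions, c(0.48, 0.42, 0.10))
  expect_equal(ps$soils$A$horizons[[2]]$l, -1.26)
  expect_equal(ps$crops$maize$Fm, 7.4)
  expect_equal(ps$crops$maize$QEff, 0.045)
  expect_equal(ps$crops$maize$MaxPen, 150)
  expect_equal(ps$crops$maize$EmrTSum, 200)
  expect_equal(ps$crops$maize$E_SOrg, 0.75)
  expect_equal(ps$crops$maize$C_per_N_slow_residue, 60)
  expect_equal(ps$crops$wheat$MaxPen, 210)
  expect_equal(ps$crops$wheat$QEff, 0.052)
  expect_equal(ps$turnover$smb_C_per_N, 4.8)
  expect_equal(ps$turnover$MaxRootingDepth, 190)
  expect_equal(ps$turnover$annual_C_input$A$total, 1550)
  expect_equal(ps$turnover$annual_C_input$B$root, 600)
  expect_equal(ps$turnover$nonroot_input_depth, 25)
  expect_equal(ps$deposition$wet_nh4, 7.5)
  expect_equal(ps$deposition$wet_no3, 2.5)
  expect_equal(unname(ps$volatilisation$knots[, 1]), c(50, 100, 150, 200, 300))
  expect_equal(unname(ps$volatilisation$knots[, 2]),
               c(0.05, 0.10, 0.12, 0.15, 0.17))
})

test_that("provenance tags are retained per component", {
  ps <- ncp_params()
  prov <- attr(ps$soils$A, "provenance")
  expect_equal(prov$theta_sat, "measured")
  expect_equal(prov$Ksat, "calibrated")
  expect_equal(attr(ps$crops$maize, "provenance")$DSRate2, "default")
})

test_that("invariant violations are rejected with informative errors", {
  h <- field_a_topsoil()
  h$SOM_fractions <- c(0.5, 0.6, 0.1)
  expect_error(cropnsim:::validate_soil_horizon(h), "SOM_fractions")
  h2 <- field_a_topsoil()
  h2$n <- 0.9
  expect_error(cropnsim:::validate_soil_horizon(h2), "n must be > 1")
  h3 <- field_a_topsoil()
  h3$theta_res <- 0.5
  expect_error(cropnsim:::validate_soil_horizon(h3), "theta_res")
  h4 <- field_a_topsoil()
  h4$Ksat <- NULL
  expect_error(cropnsim:::validate_soil_horizon(h4), "missing mandatory")
})

test_that("parameter sets round-trip through write/load exactly", {
  ps <- ncp_params()
  dir <- withr::local_tempdir()
  write_parameter_set(ps, dir)
  ps2 <- load_parameter_set(dir)
  for (f in names(ps$soils))
    for (i in seq_along(ps$soils[[f]]$horizons))
      expect_equal(ps2$soils[[f]]$horizons[[i]], ps$soils[[f]]$horizons[[i]])
  expect_equal(ps2$crops$maize[order(names(ps2$crops$maize))],
               ps$crops$maize[order(names(ps$crops$maize))],
               ignore_attr = TRUE)
  expect_equal(ps2$volatilisation$knots, ps$volatilisation$knots)
  expect_equal(unclass(ps2$deposition), unclass(ps$deposition),
               ignore_attr = TRUE)
})

test_that("volatilisation fraction interpolates the dressing-size scheme", {
  sch <- ncp_params()$volatilisation
  expect_equal(volatilisation_fraction(150, sch), 0.12)
  expect_equal(volatilisation_fraction(300, sch), 0.17)
  expect_equal(volatilisation_fraction(0, sch), 0)
  expect_equal(volatilisation_fraction(75, sch), 0.075)
  expect_equal(volatilisation_fraction(25, sch), 0.025)  # linear from (0, 0)
  expect_equal(volatilisation_fraction(500, sch), 0.17)  # plateau
  expect_error(volatilisation_fraction(-1, sch), ">= 0")
  # monotone non-decreasing and continuous over the whole range
  x <- seq(0, 400, by = 0.5)
  y <- volatilisation_fraction(x, sch)
  expect_true(all(diff(y) >= -1e-15))
  expect_lt(max(abs(diff(y))), 0.001 * 1.1)  # no jumps beyond the local slope
})

test_that("JSON export produces valid provenance records", {
  js <- parameter_set_json(ncp_params())
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$turnover$smb_C_per_N, 4.8)
  expect_equal(parsed$deposition$dry_nh4, 10)
})
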