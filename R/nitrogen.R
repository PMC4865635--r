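#' Soil organic matter turnover, mineral N dynamics and solute transport
#'
#' Carbon and nitrogen cycle through seven pools per soil cell: slow and fast
#' native soil organic matter (SOM1, SOM2) plus an inert SOM3, slow and fast
#' microbial biomass (SMB1, SMB2), and slow and fast added organic matter
#' (AOM1, AOM2) from residues and amendments.  Pools decay by first-order
#' kinetics with temperature, moisture and (for the protected pools) clay
#' modifiers; decayed C is routed through the flow network with a
#' substrate-use efficiency, the balance respired as CO2.  A receiving pool
#' with a lower C/N than its donor immobilises mineral N (NH4 first, then
#' NO3); otherwise surplus N mineralises to NH4.  NH4 nitrifies to NO3
#' (with a small N2O by-product) and both species move with the soil water by
#' convection-dispersion; NO3 may denitrify under wet conditions.
#'
#' @name nitrogen
NULL

POOLS <- c("SOM1", "SOM2", "SOM3", "SMB1", "SMB2", "AOM1", "AOM2")

#' Initialise the organic matter pools from the soil profile
#'
#' Total organic C per cell is `humus/100 * c_in_humus * bulk_density`; a
#' configured fraction seeds the microbial biomass at C/N 4.8 (split 80/20
#' between SMB1 and SMB2) and the remainder is split by the horizon's
#' `SOM_fractions` into SOM1/SOM2/SOM3 with N at the horizon C/N.
#'
#' @param grid a `soil_grid` (carries the profile).
#' @param turnover a `turnover_params`.
#' @return An `om_pools` object: matrices `C` and `N` (g per m3 soil, cells x
#'   pools) plus per-cell receiver C/N vector.
#' @export
initialise_som <- function(grid, turnover) {
  horiz <- grid$profile$horizons[grid$horizon]
  bd <- grid$profile$bulk_density * 1e6        # g soil / m3
  humus <- vapply(horiz, `[[`, 0, "humus")
  cn <- vapply(horiz, `[[`, 0, "C_per_N")
  som_fr <- t(vapply(horiz, `[[`, numeric(3), "SOM_fractions"))
  total_c <- humus / 100 * turnover$c_in_humus * bd
  smb_c <- turnover$smb_init_fraction * total_c
  som_c <- total_c - smb_c
  n <- grid$n_cells
  C <- matrix(0, n, length(POOLS), dimnames = list(NULL, POOLS))
  N <- C
  C[, "SOM1"] <- som_c * som_fr[, 1]
  C[, "SOM2"] <- som_c * som_fr[, 2]
  C[, "SOM3"] <- som_c * som_fr[, 3]
  C[, "SMB1"] <- 0.8 * smb_c
  C[, "SMB2"] <- 0.2 * smb_c
  N[, c("SOM1", "SOM2", "SOM3")] <- C[, c("SOM1", "SOM2", "SOM3")] / cn
  N[, c("SMB1", "SMB2")] <- C[, c("SMB1", "SMB2")] / turnover$smb_C_per_N
  structure(list(C = C, N = N, soil_C_per_N = cn),
            class = "om_pools")
}

#' Initialise the mineral N state
#'
#' @param grid a `soil_grid`.
#' @param nh4,no3 initial concentrations, g N/m3 soil (scalar or per cell).
#' @return A `soil_n_state` with concentration vectors and cumulative flux
#'   ledgers (kg N/ha).
#' @export
init_soil_n <- function(grid, nh4 = 0.5, no3 = 2) {
  ledger <- c(mineralisation = 0, immobilisation = 0, nitrification = 0,
              denitrification = 0, volatilisation = 0, n2o = 0,
              leach_no3 = 0, leach_nh4 = 0, deposition = 0, fertiliser = 0,
              uptake = 0, co2 = 0)
  structure(list(nh4 = rep_len(nh4, grid$n_cells),
                 no3 = rep_len(no3, grid$n_cells),
                 ledger = ledger),
            class = "soil_n_state")
}

# column totals in kg N/ha
mineral_n_total <- function(soil_n, grid, max_depth = Inf) {
  w <- pmin(pmax(max_depth - grid$edges[-length(grid$edges)], 0), grid$dz)
  sum((soil_n$nh4 + soil_n$no3) * w / 100) * KG_HA_PER_G_M2
}

organic_n_total <- function(pools, grid) {
  sum(rowSums(pools$N) * grid$dz / 100) * KG_HA_PER_G_M2
}

organic_c_total <- function(pools, grid) {
  sum(rowSums(pools$C) * grid$dz / 100) * KG_HA_PER_G_M2
}

#' Add organic material (residue, amendment) to the AOM pools
#'
#' Carbon is split between slow AOM1 and fast AOM2 by `aom1_fraction`; AOM1
#' receives N at the material's slow-pool C/N and AOM2 the remainder.  If the
#' material's N cannot satisfy the slow pool at its C/N the AOM1 N is clamped
#' and the shortfall reported.  The addition is distributed uniformly over
#' `depth_range`.
#'
#' @param pools an `om_pools`.
#' @param grid a `soil_grid`.
#' @param c_amount,n_amount added C and N, kg/ha (>= 0).
#' @param c_per_n_slow C/N of the slowly degradable fraction.
#' @param aom1_fraction fraction of C to AOM1 (default 0.5).
#' @param depth_range `c(top, bottom)` cm (default 0-25, the non-root input
#'   depth).
#' @return Updated `om_pools`; attribute `"n_shortfall"` (kg N/ha).
#' @export
add_organic_matter <- function(pools, grid, c_amount, n_amount,
                               c_per_n_slow = 60, aom1_fraction = 0.5,
                               depth_range = c(0, 25)) {
  stopifnot(c_amount >= 0, n_amount >= 0)
  if (c_amount == 0 && n_amount == 0) return(pools)
  w <- pmin(pmax(depth_range[2] - grid$edges[-length(grid$edges)], 0),
            grid$dz) -
       pmin(pmax(depth_range[1] - grid$edges[-length(grid$edges)], 0),
            grid$dz)
  if (sum(w) <= 0) stop_domain("empty incorporation depth range")
  # kg/ha -> g/m2, then per cell volume share (dz in cm -> m: /100)
  frac <- w / sum(w)
  c_g <- c_amount / KG_HA_PER_G_M2
  n_g <- n_amount / KG_HA_PER_G_M2
  aom1_c <- aom1_fraction * c_g
  aom1_n <- min(aom1_c / c_per_n_slow, n_g)
  shortfall <- max(aom1_c / c_per_n_slow - n_g, 0)
  aom2_c <- c_g - aom1_c
  aom2_n <- n_g - aom1_n
  conc <- function(total_g) total_g * frac / (grid$dz / 100)  # g/m3 per cell
  pools$C[, "AOM1"] <- pools$C[, "AOM1"] + conc(aom1_c)
  pools$N[, "AOM1"] <- pools$N[, "AOM1"] + conc(aom1_n)
  pools$C[, "AOM2"] <- pools$C[, "AOM2"] + conc(aom2_c)
  pools$N[, "AOM2"] <- pools$N[, "AOM2"] + conc(aom2_n)
  attr(pools, "n_shortfall") <- shortfall * KG_HA_PER_G_M2
  pools
}

## ---- abiotic rate modifiers ----------------------------------------------

# temperature modifier, 1 at 10 degC, exponential (Q10 ~ 2), 0 below 0 degC
fT_turnover <- function(temp) ifelse(temp <= 0, 0, exp(0.07 * (temp - 10)))

# moisture modifier on relative saturation: optimum near field capacity,
# reduced when dry and when near-saturated (anaerobic)
fW_turnover <- function(rel_sat) {
  interp_table(rel_sat, cbind(c(0, 0.6, 0.8, 1), c(0, 1, 1, 0.2)))
}

# clay protection of SOM1, SOM2 and SMB1
f_clay <- function(clay) pmax(0.2, 1 - 2 * clay)

#' One daily step of the organic matter turnover network
#'
#' @param pools an `om_pools`.
#' @param soil_n a `soil_n_state`.
#' @param temp per-cell soil temperature, degC.
#' @param theta per-cell water content.
#' @param grid a `soil_grid`.
#' @param turnover a `turnover_params`.
#' @param dt step, days (<= 1).
#' @return List `pools`, `soil_n`, `net_min` (net mineralisation this step,
#'   kg N/ha; negative = net immobilisation), `co2` (kg C/ha).
#' @export
turnover_step <- function(pools, soil_n, temp, theta, grid, turnover, dt = 1) {
  stopifnot(dt <= 1)
  nc <- grid$n_cells
  fT <- fT_turnover(temp)
  fW <- fW_turnover(theta / grid$hyd$th_s)
  fC <- f_clay(grid$clay)
  kh <- unlist(turnover$pool_rate_coefficients)[POOLS] * 24  # 1/h -> 1/d
  protected <- c(SOM1 = TRUE, SOM2 = TRUE, SOM3 = FALSE, SMB1 = TRUE,
                 SMB2 = FALSE, AOM1 = FALSE, AOM2 = FALSE)
  # per-cell decay amount of each donor pool (g C/m3)
  decay <- matrix(0, nc, length(POOLS), dimnames = list(NULL, POOLS))
  for (p in POOLS) {
    if (kh[[p]] <= 0) next
    rate <- kh[[p]] * fT * fW * (if (protected[[p]]) fC else 1)
    decay[, p] <- pools$C[, p] * (1 - exp(-rate * dt))
  }
  receiver_cn <- function(r)
    if (r %in% c("SMB1", "SMB2")) rep(turnover$smb_C_per_N, nc)
    else pools$soil_C_per_N
  flows <- turnover$flows
  # provisional N release/demand per cell
  release <- numeric(nc); demand <- numeric(nc)
  for (fl in flows) {
    cf <- decay[, fl$donor] * fl$fraction
    dn <- pools$C[, fl$donor]
    nd <- pools$N[, fl$donor]
    release <- release + ifelse(dn > 0, cf * nd / dn, 0)
    demand <- demand + fl$efficiency * cf / receiver_cn(fl$receiver)
  }
  net <- release - demand                      # g N/m3, positive mineralises
  avail <- soil_n$nh4 + soil_n$no3
  scale <- ifelse(net < 0 & -net > avail,
                  ifelse(demand - release > 0,
                         avail / (demand - release), 1), 1)
  scale <- pmin(pmax(scale, 0), 1)
  co2 <- numeric(nc)
  for (fl in flows) {
    cf <- decay[, fl$donor] * fl$fraction * scale
    dn <- pools$C[, fl$donor]
    nf <- ifelse(dn > 0, cf * pools$N[, fl$donor] / dn, 0)
    pools$C[, fl$donor] <- pools$C[, fl$donor] - cf
    pools$N[, fl$donor] <- pools$N[, fl$donor] - nf
    gain_c <- fl$efficiency * cf
    gain_n <- gain_c / receiver_cn(fl$receiver)
    pools$C[, fl$receiver] <- pools$C[, fl$receiver] + gain_c
    pools$N[, fl$receiver] <- pools$N[, fl$receiver] + gain_n
    co2 <- co2 + (1 - fl$efficiency) * cf
  }
  net <- net * scale
  if (any(pools$C < -1e-9) || any(pools$N < -1e-9))
    stop("internal error: negative pool after turnover step")
  # mineral N exchange: surplus to NH4; immobilisation draws NH4 then NO3
  pos <- pmax(net, 0); neg <- pmax(-net, 0)
  soil_n$nh4 <- soil_n$nh4 + pos
  from_nh4 <- pmin(neg, soil_n$nh4)
  soil_n$nh4 <- soil_n$nh4 - from_nh4
  from_no3 <- pmin(neg - from_nh4, soil_n$no3)
  soil_n$no3 <- soil_n$no3 - from_no3
  dzm <- grid$dz / 100
  to_kg <- function(v) sum(v * dzm) * KG_HA_PER_G_M2
  soil_n$ledger["mineralisation"] <- soil_n$ledger["mineralisation"] + to_kg(pos)
  soil_n$ledger["immobilisation"] <- soil_n$ledger["immobilisation"] +
    to_kg(from_nh4 + from_no3)
  soil_n$ledger["co2"] <- soil_n$ledger["co2"] + to_kg(co2)
  list(pools = pools, soil_n = soil_n,
       net_min = to_kg(pos) - to_kg(from_nh4 + from_no3),
       co2 = to_kg(co2))
}

#' Nitrification step (NH4 to NO3, with an N2O by-product)
#'
#' First-order in NH4 with the turnover temperature and moisture modifiers; a
#' configured fraction of nitrified N is routed to the N2O ledger.
#'
#' @inheritParams turnover_step
#' @return Updated `soil_n_state`.
#' @export
nitrification_step <- function(soil_n, temp, theta, grid, turnover, dt = 1) {
  stopifnot(dt <= 1)
  rate <- turnover$nitrification_rate * fT_turnover(temp) *
    fW_turnover(theta / grid$hyd$th_s)
  dn <- soil_n$nh4 * (1 - exp(-rate * dt))
  f_n2o <- turnover$n2o_fraction_nitrification
  soil_n$nh4 <- soil_n$nh4 - dn
  soil_n$no3 <- soil_n$no3 + dn * (1 - f_n2o)
  dzm <- grid$dz / 100
  amt <- sum(dn * dzm) * KG_HA_PER_G_M2
  soil_n$ledger["nitrification"] <- soil_n$ledger["nitrification"] + amt
  soil_n$ledger["n2o"] <- soil_n$ledger["n2o"] + amt * f_n2o
  soil_n
}

#' Denitrification step (NO3 loss under wet conditions)
#'
#' NO3 is lost at the potential rate scaled by the calibrated water response
#' (interpolated over the tabulated (relative saturation, factor) pairs, with
#' constant extrapolation outside them) and the temperature modifier.
#'
#' @inheritParams turnover_step
#' @return Updated `soil_n_state`.
#' @export
denitrification_step <- function(soil_n, temp, theta, grid, turnover, dt = 1) {
  stopifnot(dt <= 1)
  wf <- interp_table(theta / grid$hyd$th_s, turnover$water_factor)
  rate <- turnover$denit_potential_rate * wf * fT_turnover(temp)
  dn <- soil_n$no3 * (1 - exp(-rate * dt))
  soil_n$no3 <- soil_n$no3 - dn
  soil_n$ledger["denitrification"] <- soil_n$ledger["denitrification"] +
    sum(dn * grid$dz / 100) * KG_HA_PER_G_M2
  soil_n
}

#' Apply mineral fertiliser with ammonia volatilisation
#'
#' Urea and ammonium sources enter the NH4 pool after deducting the
#' volatilised share given by the dressing-size-dependent scheme; nitrate
#' sources enter NO3 without volatilisation.  The remainder is mixed
#' uniformly over the incorporation depth.
#'
#' @param soil_n a `soil_n_state`.
#' @param grid a `soil_grid`.
#' @param amount applied amount, kg N/ha (>= 0).
#' @param type `"urea"`, `"ammonium"` or `"nitrate"`.
#' @param scheme a `volatilisation_scheme`.
#' @param depth incorporation depth, cm (default 5: surface dressing washed
#'   into the plough layer top).
#' @return Updated `soil_n_state`.
#' @export
apply_fertiliser <- function(soil_n, grid, amount, type = "urea",
                             scheme = NULL, depth = 5) {
  stopifnot(amount >= 0)
  if (amount == 0) return(soil_n)
  if (!type %in% c("urea", "ammonium", "nitrate"))
    stop_domain("unknown fertiliser type: ", type)
  vol <- 0
  if (type %in% c("urea", "ammonium") && !is.null(scheme))
    vol <- amount * volatilisation_fraction(amount, scheme)
  to_soil <- amount - vol
  w <- pmin(pmax(depth - grid$edges[-length(grid$edges)], 0), grid$dz)
  frac <- w / sum(w)
  add <- (to_soil / KG_HA_PER_G_M2) * frac / (grid$dz / 100)
  if (type == "nitrate") soil_n$no3 <- soil_n$no3 + add
  else soil_n$nh4 <- soil_n$nh4 + add
  soil_n$ledger["fertiliser"] <- soil_n$ledger["fertiliser"] + amount
  soil_n$ledger["volatilisation"] <- soil_n$ledger["volatilisation"] + vol
  soil_n
}

## ---- convection-dispersion transport --------------------------------------

cde_solve_species <- function(conc_soil, theta, retard, q_edge_m, grid,
                              disp_m, dm_m2, dt) {
  # conc_soil g/m3 soil; transport on water concentration c = conc_soil/theta
  n <- grid$n_cells
  dzm <- grid$dz / 100
  dzim <- diff(grid$zc) / 100
  cw <- conc_soil / (theta * retard)           # dissolved concentration
  wcap <- theta * retard * dzm / dt            # storage coefficient
  th_int <- (theta[-n] + theta[-1]) / 2
  v_int <- q_edge_m[2:n] / th_int              # pore velocity, m/d
  d_int <- disp_m * abs(v_int) + dm_m2         # m2/d
  dcoef <- th_int * d_int / dzim               # dispersive conductance
  qi <- q_edge_m[2:n]
  adv_lo <- pmax(qi, 0)                        # uses upstream (upper) cell
  adv_up <- pmax(-qi, 0)                       # uses downstream cell
  aa <- c(0, -(adv_lo + dcoef))
  cc <- c(-(adv_up + dcoef), 0)
  bb <- wcap + c(adv_lo + dcoef, 0) + c(0, adv_up + dcoef)
  # boundaries: top influent carries no solute, evaporating water leaves none;
  # bottom outflow is upwind on the last cell, inflow (upward bc) ignored
  qb <- q_edge_m[n + 1]
  bb[n] <- bb[n] + max(qb, 0)
  rhs <- wcap * cw
  cw_new <- thomas_solve(aa, bb, cc, rhs)
  leach <- max(qb, 0) * cw_new[n] * dt         # g/m2
  list(conc_soil = cw_new * theta * retard, leach = leach,
       edge_flux = c(0, pmax(qi, 0) * cw_new[-n] + pmin(qi, 0) * cw_new[-1] -
                       dcoef * (cw_new[-1] - cw_new[-n]),
                     max(qb, 0) * cw_new[n]))
}

#' Convection-dispersion step for NH4 and NO3
#'
#' Implicit upwind finite-volume advection with velocity-dependent
#' dispersion (dispersivity times pore velocity plus molecular diffusion),
#' driven by the Darcy flux profile of the same day's soil water solution.
#' NH4 is linearly retarded by sorption (`R = 1 + bulk_density * Kd / theta`).
#' Bottom-edge export is ledgered as leaching; infiltrating rain is assumed
#' solute-free (deposition is added to the surface cell separately).
#'
#' @param soil_n a `soil_n_state`.
#' @param flux the `flux` element of a [richards_step()] result (mm/step).
#' @param theta per-cell water content after the water step.
#' @param grid a `soil_grid`.
#' @param turnover a `turnover_params` (dispersivity, Kd, diffusion).
#' @param dt step, days.
#' @param n_substeps number of implicit substeps (default chosen from the
#'   advective Courant number, capped at 200).
#' @return List `soil_n` (ledger updated), `leach_no3`, `leach_nh4` (kg N/ha
#'   this step), `no3_flux_at` a function(z) giving the NO3 flux (kg N/ha)
#'   past any cell edge this step.
#' @export
cde_transport_step <- function(soil_n, flux, theta, grid, turnover, dt = 1,
                               n_substeps = NULL) {
  q_m <- flux$flux / 1000              # mm/step -> m/step
  n <- grid$n_cells
  dzm <- grid$dz / 100
  bd <- grid$profile$bulk_density      # g/cm3
  r_nh4 <- 1 + bd * turnover$nh4_kd / theta
  disp_m <- turnover$dispersivity / 100
  dm_m2 <- turnover$molecular_diffusion * 24 / 1e4   # cm2/h -> m2/d
  if (is.null(n_substeps)) {
    courant <- max(abs(q_m) / dt) * dt / min(theta * dzm)
    n_substeps <- min(max(1L, ceiling(courant)), 200L)
  }
  if (n_substeps >= 200L && max(abs(q_m) / dt) * (dt / n_substeps) /
        min(theta * dzm) > 5)
    stop_domain("transport Courant number too large even at the substep limit")
  dts <- dt / n_substeps
  qe <- q_m / dt                       # m/d
  no3 <- soil_n$no3; nh4 <- soil_n$nh4
  leach_no3 <- 0; leach_nh4 <- 0
  no3_edge <- numeric(n + 1)
  for (s in seq_len(n_substeps)) {
    r1 <- cde_solve_species(no3, theta, rep(1, n), qe, grid, disp_m, dm_m2, dts)
    no3 <- r1$conc_soil; leach_no3 <- leach_no3 + r1$leach
    no3_edge <- no3_edge + r1$edge_flux * dts
    r2 <- cde_solve_species(nh4, theta, r_nh4, qe, grid, disp_m, dm_m2, dts)
    nh4 <- r2$conc_soil; leach_nh4 <- leach_nh4 + r2$leach
  }
  soil_n$no3 <- no3
  soil_n$nh4 <- nh4
  soil_n$ledger["leach_no3"] <- soil_n$ledger["leach_no3"] +
    leach_no3 * KG_HA_PER_G_M2
  soil_n$ledger["leach_nh4"] <- soil_n$ledger["leach_nh4"] +
    leach_nh4 * KG_HA_PER_G_M2
  edges <- grid$edges
  no3_flux_at <- function(z) {
    i <- which(abs(edges - z) < 1e-9)
    if (!length(i)) stop_domain("depth ", z, " cm is not a cell edge")
    no3_edge[i] * KG_HA_PER_G_M2
  }
  list(soil_n = soil_n, leach_no3 = leach_no3 * KG_HA_PER_G_M2,
       leach_nh4 = leach_nh4 * KG_HA_PER_G_M2, no3_flux_at = no3_flux_at)
}
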