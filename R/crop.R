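#' Crop phenology, canopy assimilation, growth, roots and N uptake
#'
#' Development stage (DS) runs from emergence (0) through flowering (1) to
#' maturity (2), driven by temperature-modified daily development rates.
#' Leaf photosynthesis follows a saturating light-response curve integrated
#' over canopy layers with exponential light extinction and over the daylight
#' period; net assimilate (after growth and maintenance respiration) is
#' partitioned to root, leaf, stem and storage organ by DS-dependent
#' fractions.  Roots deepen at a constant rate and distribute length
#' exponentially with depth; N uptake per cell is capped by root length,
#' mineral N availability and the DS-dependent organ N demand.
#'
#' @name crop
NULL

ORGANS <- c("root", "leaf", "stem", "sorg")

#' Initialise a crop at sowing
#' @param crop_params a `crop_params`.
#' @param grid a `soil_grid`.
#' @param initial_dm small seed reserve, g DM/m2 (to each of leaf/stem/root).
#' @return A `crop_state`.
#' @export
init_crop_state <- function(crop_params, grid, initial_dm = 2) {
  st <- list(crop = crop_params$name, DS = 0, emerged = FALSE, tsum = 0,
             dm = c(root = initial_dm, leaf = initial_dm,
                    stem = initial_dm / 2, sorg = 0),
             n_organ = c(root = initial_dm * 0.015, leaf = initial_dm * 0.05,
                         stem = initial_dm / 2 * 0.03, sorg = 0),
             LAI = 0, root_depth = 2,
             rld = numeric(grid$n_cells),
             stress_water = 1, stress_n = 1, maint_deficit = 0)
  class(st) <- "crop_state"
  st
}

#' Daily phenological development
#'
#' Before emergence the soil temperature sum accumulates (positive part);
#' emergence occurs when it reaches `EmrTSum`.  Thereafter
#' `dDS/dt = DSRate1 * f_T` up to flowering (DS 1) and `DSRate2 * f_T`
#' afterwards, capped at maturity (DS 2); `f_T` is the piecewise-linear
#' development temperature response (zero below the crop's base
#' temperature, which also stalls winter wheat over winter).
#'
#' @param state a `crop_state`.
#' @param t_soil topsoil temperature, degC (drives emergence).
#' @param t_mean air temperature, degC (drives development).
#' @param crop_params a `crop_params`.
#' @return Updated `crop_state`.
#' @export
phenology_step <- function(state, t_soil, t_mean, crop_params) {
  if (!state$emerged) {
    state$tsum <- state$tsum + max(t_soil, 0)
    if (state$tsum >= crop_params$EmrTSum) {
      state$emerged <- TRUE
      state$DS <- 0
      state$LAI <- update_leaf_area(state, crop_params)
    }
    return(state)
  }
  ft <- interp_table(t_mean, crop_params$temp_response_dev)
  rate <- if (state$DS < 1) crop_params$DSRate1 else crop_params$DSRate2
  state$DS <- min(state$DS + rate * ft, 2)
  state
}

#' Canopy-level leaf area index
#'
#' `LAI = leaf_DM * SpLAI * LeafAIMod(DS)` with the modifier interpolated
#' between its tabulated DS knots.
#'
#' @param state a `crop_state`.
#' @param crop_params a `crop_params`.
#' @return LAI, m2/m2.
#' @export
update_leaf_area <- function(state, crop_params) {
  if (!state$emerged) return(0)
  state$dm[["leaf"]] * crop_params$SpLAI *
    interp_table(state$DS, crop_params$LeafAIMod_by_DS)
}

#' Daily canopy gross photosynthesis
#'
#' Leaf response `F(S) = Fm (1 - exp(-QEff S / Fm))` applied to the leaf
#' irradiance `k S0 exp(-k LAI_above)` in each canopy layer (midpoint rule
#' over `n_layers`), integrated over the daylight hours with a sinusoidal
#' diurnal irradiance course, then reduced by the temperature response, a
#' post-flowering senescence factor and `min(water, N)` stress.  `S0` is the
#' photosynthetically active share (0.48) of global radiation.
#'
#' @param LAI canopy leaf area index.
#' @param radiation daily mean global radiation, W/m2 (24 h mean).
#' @param day_len daylight hours.
#' @param t_mean air temperature, degC.
#' @param DS development stage.
#' @param stress_water,stress_n stress fractions in `[0, 1]`.
#' @param crop_params a `crop_params`.
#' @param n_layers canopy layers (default 50).
#' @param n_time diurnal quadrature points (default 5).
#' @param k_ext canopy light extinction coefficient (default 0.6).
#' @return Gross assimilation, g CO2/m2 ground/d.
#' @export
canopy_gross_photosynthesis <- function(LAI, radiation, day_len, t_mean, DS,
                                        stress_water = 1, stress_n = 1,
                                        crop_params, n_layers = 50,
                                        n_time = 5, k_ext = 0.6) {
  if (LAI <= 0 || radiation <= 0 || day_len <= 0) return(0)
  fm <- crop_params$Fm
  qe <- crop_params$QEff
  s_mean_day <- radiation * 24 / day_len * 0.48  # mean daytime PAR, W/m2
  tau <- (seq_len(n_time) - 0.5) / n_time
  s0 <- s_mean_day * (pi / 2) * sin(pi * tau)    # diurnal course
  lai_mid <- (seq_len(n_layers) - 0.5) / n_layers * LAI
  dlai <- LAI / n_layers
  total <- 0
  for (s in s0) {
    s_leaf <- k_ext * s * exp(-k_ext * lai_mid)
    total <- total + sum(fm * (1 - exp(-qe * s_leaf / fm))) * dlai
  }
  hourly <- total / n_time                       # g CO2/m2 ground/h (day avg)
  ft <- if (!is.null(crop_params$temp_response_phot))
    interp_table(t_mean, crop_params$temp_response_phot) else 1
  f_sen <- 1 - 0.4 * max(0, DS - 1)
  hourly * day_len * ft * f_sen * min(stress_water, stress_n)
}

#' Daily growth: respiration and DS-dependent partitioning
#'
#' Gross CO2 assimilate is converted to carbohydrate equivalents (30/44),
#' maintenance respiration `r_organ * DM * Q10^((T-20)/10)` is deducted
#' (truncated at the available assimilate; the unpaid deficit is recorded in
#' `maint_deficit`, no organ shrinks), and the remainder is allocated by the
#' DS-interpolated partitioning fractions with organ-specific conversion
#' efficiencies.
#'
#' @param state an emerged `crop_state`.
#' @param assimilate gross assimilation, g CO2/m2/d.
#' @param t_mean air temperature, degC.
#' @param crop_params a `crop_params`.
#' @param q10 maintenance Q10 (default 2, reference 20 degC).
#' @return Updated `crop_state`.
#' @export
daily_growth <- function(state, assimilate, t_mean, crop_params, q10 = 2) {
  ch2o <- assimilate * 30 / 44
  r <- c(root = crop_params$r_Root, leaf = crop_params$r_Leaf,
         stem = crop_params$r_Stem, sorg = crop_params$r_SOrg)
  maint <- r[ORGANS] * state$dm * q10^((t_mean - 20) / 10)
  maint_total <- sum(maint)
  paid <- min(maint_total, ch2o)
  state$maint_deficit <- state$maint_deficit + (maint_total - paid)
  avail <- ch2o - paid
  pt <- crop_params$partitioning_by_DS
  fr <- vapply(ORGANS, function(o)
    interp_table(state$DS, pt[, c("DS", o)]), 0)
  fr <- fr / sum(fr)
  eff <- c(root = crop_params$E_Leaf, leaf = crop_params$E_Leaf,
           stem = crop_params$E_Stem, sorg = crop_params$E_SOrg)
  growth <- avail * fr * eff[ORGANS]
  state$dm <- state$dm + growth
  state$growth_ch2o <- avail
  state$maint_paid <- paid
  state
}

#' Root penetration and exponential length distribution
#'
#' The rooting front advances at the crop's penetration rate up to
#' `min(MaxPen, MaxRootingDepth)`; total root length
#' (`root_DM * SpRtLength`) is distributed over 0..root_depth with density
#' proportional to `exp(-a z)`, `a = 3 / root_depth` (95 percent of the
#' untruncated exponential lies above the front), renormalised so the
#' distributed length is conserved exactly.
#'
#' @param state an emerged `crop_state`.
#' @param grid a `soil_grid`.
#' @param crop_params a `crop_params`.
#' @param max_rooting_depth profile-level cap, cm.
#' @param dt days.
#' @return Updated `crop_state` (fields `root_depth`, `rld` in cm/cm3).
#' @export
root_growth_and_distribution <- function(state, grid, crop_params,
                                         max_rooting_depth = 190, dt = 1) {
  cap <- min(crop_params$MaxPen, max_rooting_depth)
  if (state$DS < 1.5)
    state$root_depth <- min(state$root_depth +
                              crop_params$root_penetration_rate * dt, cap)
  zr <- state$root_depth
  a <- 3 / zr
  lo <- pmin(grid$edges[-length(grid$edges)], zr)
  hi <- pmin(grid$edges[-1], zr)
  w <- (exp(-a * lo) - exp(-a * hi))           # integral of exp(-a z)
  w[hi <= lo] <- 0
  w <- w / sum(w)
  total_cm <- state$dm[["root"]] * crop_params$SpRtLength * 100  # cm/m2
  state$rld <- total_cm * w / (grid$dz * 1e4)  # cm root / cm3 soil
  state$root_length_cm <- total_cm
  state
}

crop_n_demand <- function(state, crop_params) {
  target <- vapply(ORGANS, function(o)
    interp_table(state$DS, crop_params$n_conc_by_DS[[o]]), 0)
  max(sum(target * state$dm) - sum(state$n_organ), 0)
}

#' Daily crop N uptake from the soil mineral pools
#'
#' Per-cell potential uptake is `MxUp * root_length * 24 h` per species,
#' capped by the cell's mineral N; realised uptake is further capped by the
#' crop's remaining N demand (DS-dependent target organ concentrations) and
#' allocated to organs proportionally to their deficits.  Removals never
#' drive soil N negative.
#'
#' @param state an emerged `crop_state` with root distribution.
#' @param soil_n a `soil_n_state`.
#' @param grid a `soil_grid`.
#' @param crop_params a `crop_params`.
#' @return List `state`, `soil_n`, `uptake` (kg N/ha this day).
#' @export
crop_n_uptake <- function(state, soil_n, grid, crop_params) {
  demand_g <- crop_n_demand(state, crop_params)   # g N/m2
  cell_len <- state$rld * grid$dz * 1e4           # cm root per m2 per cell
  if (demand_g <= 0 || sum(cell_len) <= 0)
    return(list(state = state, soil_n = soil_n, uptake = 0))
  dzm <- grid$dz / 100
  avail_nh4 <- soil_n$nh4 * dzm                   # g N/m2 per cell
  avail_no3 <- soil_n$no3 * dzm
  pot_nh4 <- pmin(crop_params$MxNH4Up * cell_len * 24, avail_nh4)
  pot_no3 <- pmin(crop_params$MxNO3Up * cell_len * 24, avail_no3)
  pot_total <- sum(pot_nh4) + sum(pot_no3)
  if (pot_total <= 0)
    return(list(state = state, soil_n = soil_n, uptake = 0))
  f <- min(demand_g / pot_total, 1)
  take_nh4 <- pot_nh4 * f
  take_no3 <- pot_no3 * f
  soil_n$nh4 <- soil_n$nh4 - take_nh4 / dzm
  soil_n$no3 <- soil_n$no3 - take_no3 / dzm
  got <- sum(take_nh4) + sum(take_no3)
  # allocate to organs by deficit
  target <- vapply(ORGANS, function(o)
    interp_table(state$DS, crop_params$n_conc_by_DS[[o]]), 0)
  deficit <- pmax(target * state$dm - state$n_organ, 0)
  if (sum(deficit) > 0)
    state$n_organ <- state$n_organ + got * deficit / sum(deficit)
  soil_n$ledger["uptake"] <- soil_n$ledger["uptake"] + got * KG_HA_PER_G_M2
  # N status for tomorrow's photosynthesis
  tgt_total <- sum(target * state$dm)
  state$stress_n <- if (tgt_total > 0)
    min(1, sum(state$n_organ) / (0.7 * tgt_total)) else 1
  list(state = state, soil_n = soil_n, uptake = got * KG_HA_PER_G_M2)
}
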