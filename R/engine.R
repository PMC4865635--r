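#' Management scheduling and the daily coupling loop
#'
#' A simulation run is driven by a config bundling weather, a field's soil
#' profile, crop parameterisations, a management schedule (sowing, harvest,
#' fertilisation, irrigation, tillage) and the simulation window including an
#' optional warm-up period used to equilibrate the organic matter pools.
#' Each day the engine applies, in fixed order: weather and deposition,
#' management events, reference ET and its canopy partition, the soil water
#' step, soil temperature, crop development/assimilation/growth/N uptake,
#' organic matter turnover with nitrification and denitrification, and
#' solute transport; all mass fluxes are ledgered so the daily water and N
#' budgets close identically.
#'
#' @name engine
NULL

#' Construct a management event
#'
#' @param date calendar date.
#' @param action one of `"sow"`, `"harvest"`, `"fertilise"`, `"irrigate"`,
#'   `"till"`.
#' @param crop crop name (sow).
#' @param amount kg N/ha (fertilise) or mm (irrigate).
#' @param type fertiliser type (default urea).
#' @param depth incorporation/tillage depth, cm.
#' @param straw_fraction fraction of straw incorporated at harvest.
#' @param stubble_fraction fraction of straw always left as stubble.
#' @param share this dressing's share of the annual N rate (for ladder
#'   rescaling).
#' @return A one-row data frame.
#' @export
mgmt_event <- function(date, action, crop = NA_character_, amount = 0,
                       type = "urea", depth = 5, straw_fraction = 0.8,
                       stubble_fraction = 0.1, share = NA_real_) {
  stopifnot(action %in% c("sow", "harvest", "fertilise", "irrigate", "till"),
            amount >= 0, straw_fraction >= 0, straw_fraction <= 1)
  data.frame(date = as.Date(date), action = action, crop = crop,
             amount = amount, type = type, depth = depth,
             straw_fraction = straw_fraction,
             stubble_fraction = stubble_fraction, share = share,
             stringsAsFactors = FALSE)
}

#' Harvest: remove grain, return residues
#'
#' Grain (plus the removed straw share) leaves the field; the incorporated
#' straw share, the stubble and all roots return as added organic matter.
#' N is conserved: exported plus incorporated N equals the pre-harvest crop N.
#'
#' @param state the standing `crop_state`.
#' @param pools an `om_pools`.
#' @param grid a `soil_grid`.
#' @param crop_params the crop's parameters (residue C/N).
#' @param straw_fraction fraction of (non-stubble) straw incorporated.
#' @param stubble_fraction fraction of straw left standing (always returned).
#' @param c_in_dm carbon content of dry matter (g C/g DM).
#' @return List: `pools` (updated), `grain_dm`, `grain_n`, `straw_dm`,
#'   `residue_c`, `residue_n`, `exported_n` (all g/m2 except dm in g DM/m2).
#' @export
harvest_crop <- function(state, pools, grid, crop_params,
                         straw_fraction = 0.8, stubble_fraction = 0.1,
                         c_in_dm = 0.45) {
  if (is.null(state)) stop_domain("harvest scheduled but no crop is present")
  straw_dm <- state$dm[["leaf"]] + state$dm[["stem"]]
  straw_n <- state$n_organ[["leaf"]] + state$n_organ[["stem"]]
  ret_frac <- stubble_fraction + (1 - stubble_fraction) * straw_fraction
  residue_dm <- straw_dm * ret_frac + state$dm[["root"]]
  residue_n <- straw_n * ret_frac + state$n_organ[["root"]]
  exported_n <- state$n_organ[["sorg"]] + straw_n * (1 - ret_frac)
  residue_c <- residue_dm * c_in_dm
  pools <- add_organic_matter(
    pools, grid,
    c_amount = residue_c * KG_HA_PER_G_M2,
    n_amount = residue_n * KG_HA_PER_G_M2,
    c_per_n_slow = crop_params$C_per_N_slow_residue,
    aom1_fraction = 0.5,
    depth_range = c(0, max(25, min(state$root_depth, 190))))
  list(pools = pools, grain_dm = state$dm[["sorg"]],
       grain_n = state$n_organ[["sorg"]], straw_dm = straw_dm,
       residue_c = residue_c, residue_n = residue_n,
       exported_n = exported_n)
}

till_mix <- function(x, grid, depth) {
  w <- pmin(pmax(depth - grid$edges[-length(grid$edges)], 0), grid$dz)
  idx <- which(w > 0)
  wd <- grid$dz[idx]
  mix <- function(v) { v[idx] <- sum(v[idx] * wd) / sum(wd); v }
  if (is.matrix(x)) { for (j in seq_len(ncol(x))) x[, j] <- mix(x[, j]); x }
  else mix(x)
}

#' Build a simulation config
#'
#' @param weather a `weather_series` covering the whole run (including
#'   warm-up).
#' @param params an `svat_params` (see [default_ncp_parameters()]).
#' @param field field name in `params$soils`.
#' @param management data frame of [mgmt_event()] rows.
#' @param start,end simulation window (warm-up precedes `start`).
#' @param warmup_years years simulated before `start` to equilibrate pools.
#' @param output_depth reference depth for drainage/leaching output, cm.
#' @param annual_n_rate nominal annual fertiliser rate, kg N/ha (used by
#'   ladder rescaling via the events' `share`).
#' @param initial list: `h` (uniform head, cm) or `water_table` (cm), `nh4`,
#'   `no3` (g N/m3).
#' @param soil_temp list `mean`, `amplitude`, `damping`, `phase` for the
#'   analytic soil temperature profile.
#' @param warmup_c_input add the profile's annual warm-up C inputs (monthly)
#'   during warm-up years.
#' @param sampling_dates month-day strings for post-harvest soil sampling.
#' @return A `sim_config`.
#' @export
sim_config <- function(weather, params, field, management, start, end,
                       warmup_years = 0, output_depth = 200,
                       annual_n_rate = NA_real_,
                       initial = list(h = -300, nh4 = 0.5, no3 = 2),
                       soil_temp = list(mean = 12.5, amplitude = 14.5,
                                        damping = 180, phase = 106),
                       warmup_c_input = FALSE,
                       sampling_dates = c("10-06", "06-12")) {
  start <- as.Date(start); end <- as.Date(end)
  if (start >= end) stop_domain("start must precede end")
  if (!field %in% names(params$soils))
    stop_domain("unknown field '", field, "'")
  cfg <- list(weather = weather, params = params, field = field,
              management = management, start = start, end = end,
              warmup_years = warmup_years, output_depth = output_depth,
              annual_n_rate = annual_n_rate, initial = initial,
              soil_temp = soil_temp, warmup_c_input = warmup_c_input,
              sampling_dates = sampling_dates)
  class(cfg) <- "sim_config"
  cfg
}

#' Rescale a config's fertiliser events to a new annual rate
#' @param config a `sim_config` whose fertilise events carry `share`.
#' @param annual_rate new annual N rate, kg N/ha.
#' @return Updated config.
#' @export
rescale_fertilisation <- function(config, annual_rate) {
  m <- config$management
  i <- m$action == "fertilise" & !is.na(m$share)
  m$amount[i] <- m$share[i] * annual_rate
  config$management <- m
  config$annual_n_rate <- annual_rate
  config
}

#' Set the incorporated straw fraction on all harvest events
#' @param config a `sim_config`.
#' @param fraction incorporated fraction in `[0, 1]`.
#' @return Updated config.
#' @export
set_straw_fraction <- function(config, fraction) {
  config$management$straw_fraction[config$management$action == "harvest"] <-
    fraction
  config
}

#' Run the daily simulation
#'
#' @param config a `sim_config`.
#' @return A `sim_output`: `daily` data frame (one row per simulated day,
#'   warm-up included and flagged), `ledger` matrix of cumulative N fluxes
#'   (kg N/ha) per day, `harvests` data frame, `grid`, `config`.
#' @export
run_simulation <- function(config) {
  params <- config$params
  profile <- params$soils[[config$field]]
  grid <- make_default_grid(profile)
  turnover <- params$turnover
  wx <- config$weather
  lat <- attr(wx, "latitude"); alt <- attr(wx, "altitude")
  sim_start <- config$start - round(config$warmup_years * 365.25)
  if (min(wx$date) > sim_start || max(wx$date) < config$end)
    stop_domain("weather series does not cover the simulation window ",
                format(sim_start), " .. ", format(config$end))
  days <- seq(sim_start, config$end, by = "day")
  wxi <- match(days, wx$date)
  # plain vectors: row extraction from a data frame every day is slow
  wv <- list(precipitation = wx$precipitation[wxi], t_mean = wx$t_mean[wxi],
             t_min = wx$t_min[wxi], t_max = wx$t_max[wxi],
             global_radiation = wx$global_radiation[wxi],
             wind_speed = wx$wind_speed[wxi],
             relative_humidity = wx$relative_humidity[wxi])

  sw <- if (!is.null(config$initial$water_table))
    init_soil_water(grid, water_table = config$initial$water_table)
  else init_soil_water(grid, h = config$initial$h %||% -300)
  pools <- initialise_som(grid, turnover)
  soil_n <- init_soil_n(grid, nh4 = config$initial$nh4 %||% 0.5,
                        no3 = config$initial$no3 %||% 2)
  soil_n$ledger <- c(soil_n$ledger, organic_input = 0, export = 0)
  crop <- NULL; crop_par <- NULL
  stp <- config$soil_temp
  c_in <- turnover$annual_C_input[[config$field]]
  dzm <- grid$dz / 100

  nd <- length(days)
  rec <- list(
    date = days, warmup = days < config$start,
    precipitation = numeric(nd), irrigation = numeric(nd),
    et0 = numeric(nd), aet = numeric(nd), evaporation = numeric(nd),
    transpiration = numeric(nd), runoff = numeric(nd),
    drainage = numeric(nd), leaching = numeric(nd),
    bottom_drainage = numeric(nd), net_min = numeric(nd),
    storage = numeric(nd), mineral_n = numeric(nd),
    organic_n = numeric(nd), crop_n = numeric(nd), crop_dm = numeric(nd),
    lai = numeric(nd), ds = rep(NA_real_, nd),
    dm_leaf = numeric(nd), dm_stem = numeric(nd), dm_sorg = numeric(nd),
    system_n = numeric(nd))
  ledgers <- matrix(0, nd, length(soil_n$ledger),
                    dimnames = list(NULL, names(soil_n$ledger)))
  harvests <- list()

  doys <- as.integer(format(days, "%j"))
  mgmt_idx <- split(seq_len(nrow(config$management)),
                    as.character(config$management$date))
  for (d in seq_len(nd)) {
    today <- days[d]
    w <- lapply(wv, `[`, d)
    doy <- doys[d]

    # atmospheric deposition into the surface cell
    dep <- deposition_flux(w$precipitation, today, params$deposition)
    soil_n$nh4[1] <- soil_n$nh4[1] + dep[["nh4"]] / KG_HA_PER_G_M2 / dzm[1]
    soil_n$no3[1] <- soil_n$no3[1] + dep[["no3"]] / KG_HA_PER_G_M2 / dzm[1]
    soil_n$ledger["deposition"] <- soil_n$ledger["deposition"] + sum(dep)

    # warm-up organic C input, monthly portions
    if (config$warmup_c_input && today < config$start &&
        format(today, "%d") == "01" && !is.null(c_in)) {
      nonroot <- (c_in$total - c_in$root) / 12
      pools <- add_organic_matter(pools, grid, nonroot, nonroot / 40,
                                  c_per_n_slow = 60, aom1_fraction = 0.5,
                                  depth_range = c(0, turnover$nonroot_input_depth))
      pools <- add_organic_matter(pools, grid, c_in$root / 12,
                                  c_in$root / 12 / 40,
                                  c_per_n_slow = 60, aom1_fraction = 0.5,
                                  depth_range = c(0, turnover$MaxRootingDepth))
      soil_n$ledger["organic_input"] <- soil_n$ledger["organic_input"] +
        (nonroot + c_in$root / 12) / 40
    }

    # management
    irrigation <- 0
    ev_rows <- mgmt_idx[[as.character(today)]]
    ev_today <- if (is.null(ev_rows)) config$management[0, , drop = FALSE]
                else config$management[ev_rows, , drop = FALSE]
    if (nrow(ev_today)) for (e in seq_len(nrow(ev_today))) {
      ev <- ev_today[e, ]
      if (ev$action == "sow") {
        crop_par <- params$crops[[ev$crop]]
        if (is.null(crop_par)) stop_domain("unknown crop: ", ev$crop)
        crop <- init_crop_state(crop_par, grid)
        # seed reserves enter the system ledger as an organic input
        soil_n$ledger["organic_input"] <- soil_n$ledger["organic_input"] +
          sum(crop$n_organ) * KG_HA_PER_G_M2
      } else if (ev$action == "harvest") {
        if (is.null(crop))
          stop_domain("harvest scheduled on ", format(today),
                      " but no crop is present")
        h <- harvest_crop(crop, pools, grid, crop_par,
                          straw_fraction = ev$straw_fraction,
                          stubble_fraction = ev$stubble_fraction)
        pools <- h$pools
        soil_n$ledger["export"] <- soil_n$ledger["export"] +
          h$exported_n * KG_HA_PER_G_M2
        harvests[[length(harvests) + 1]] <- data.frame(
          date = today, crop = crop$crop, grain_dm = h$grain_dm,
          grain_n = h$grain_n * KG_HA_PER_G_M2, straw_dm = h$straw_dm,
          residue_n = h$residue_n * KG_HA_PER_G_M2,
          exported_n = h$exported_n * KG_HA_PER_G_M2)
        crop <- NULL; crop_par <- NULL
      } else if (ev$action == "fertilise") {
        soil_n <- apply_fertiliser(soil_n, grid, ev$amount, ev$type,
                                   scheme = params$volatilisation,
                                   depth = ev$depth)
      } else if (ev$action == "irrigate") {
        irrigation <- irrigation + ev$amount
      } else if (ev$action == "till") {
        pools$C <- till_mix(pools$C, grid, ev$depth)
        pools$N <- till_mix(pools$N, grid, ev$depth)
        soil_n$nh4 <- till_mix(soil_n$nh4, grid, ev$depth)
        soil_n$no3 <- till_mix(soil_n$no3, grid, ev$depth)
      }
    }

    # reference ET and canopy partition
    et0 <- reference_et_fao56(w$t_mean, w$t_min, w$t_max, w$global_radiation,
                              w$wind_speed, w$relative_humidity,
                              latitude = lat, doy = doy, altitude = alt)
    lai <- if (!is.null(crop)) crop$LAI else 0
    cover <- 1 - exp(-0.6 * lai)
    pet_fac <- if (!is.null(crop) && crop$emerged)
      interp_table(crop$DS, crop_par$pet_factor_by_DS) else 1
    pot_transp <- et0 * cover * pet_fac
    pot_evap <- et0 * (1 - cover)

    # soil water
    sink <- if (!is.null(crop) && crop$emerged && sum(crop$rld) > 0) {
      wgt <- crop$rld * grid$dz
      pot_transp * wgt / sum(wgt)
    } else NULL
    surf <- w$precipitation + irrigation - pot_evap
    res <- richards_step(sw, grid, dt = 1, surface_flux = surf,
                         lower_bc = list(type = "free"), sink = sink)
    sw <- res$state
    transp_act <- sum(res$actual_sink)
    evap_act <- w$precipitation + irrigation - res$actual_surface_flux -
      res$runoff
    stress_w <- if (pot_transp > 1e-9) transp_act / pot_transp else 1

    # soil temperature
    t_soil <- soil_temperature_profile(doy, grid$zc, stp$mean, stp$amplitude,
                                       stp$damping, stp$phase)

    # crop processes
    if (!is.null(crop)) {
      crop <- phenology_step(crop, t_soil[1], w$t_mean, crop_par)
      if (crop$emerged) {
        crop <- root_growth_and_distribution(crop, grid, crop_par,
                                             turnover$MaxRootingDepth)
        crop$LAI <- update_leaf_area(crop, crop_par)
        assim <- canopy_gross_photosynthesis(
          crop$LAI, w$global_radiation, day_length(doy, lat), w$t_mean,
          crop$DS, stress_water = stress_w, stress_n = crop$stress_n,
          crop_params = crop_par)
        crop <- daily_growth(crop, assim, w$t_mean, crop_par)
        up <- crop_n_uptake(crop, soil_n, grid, crop_par)
        crop <- up$state; soil_n <- up$soil_n
        crop$stress_water <- stress_w
      }
    }

    # turnover, nitrification, denitrification
    tv <- turnover_step(pools, soil_n, t_soil, sw$theta, grid, turnover)
    pools <- tv$pools; soil_n <- tv$soil_n
    soil_n <- nitrification_step(soil_n, t_soil, sw$theta, grid, turnover)
    soil_n <- denitrification_step(soil_n, t_soil, sw$theta, grid, turnover)

    # solute transport
    tr <- cde_transport_step(soil_n, res$flux, sw$theta, grid, turnover)
    soil_n <- tr$soil_n

    # records
    rec$precipitation[d] <- w$precipitation
    rec$irrigation[d] <- irrigation
    rec$et0[d] <- et0
    rec$aet[d] <- evap_act + transp_act
    rec$evaporation[d] <- evap_act
    rec$transpiration[d] <- transp_act
    rec$runoff[d] <- res$runoff
    rec$drainage[d] <- drainage_at_depth(res$flux, config$output_depth)
    rec$leaching[d] <- tr$no3_flux_at(config$output_depth)
    rec$bottom_drainage[d] <- res$bottom_drainage
    rec$net_min[d] <- tv$net_min
    rec$storage[d] <- water_storage(sw, grid)
    rec$mineral_n[d] <- mineral_n_total(soil_n, grid, config$output_depth)
    rec$organic_n[d] <- organic_n_total(pools, grid)
    cn <- if (!is.null(crop)) sum(crop$n_organ) * KG_HA_PER_G_M2 else 0
    rec$crop_n[d] <- cn
    rec$crop_dm[d] <- if (!is.null(crop)) sum(crop$dm) else 0
    rec$lai[d] <- if (!is.null(crop)) crop$LAI else 0
    rec$ds[d] <- if (!is.null(crop) && crop$emerged) crop$DS else NA_real_
    rec$dm_leaf[d] <- if (!is.null(crop)) crop$dm[["leaf"]] else 0
    rec$dm_stem[d] <- if (!is.null(crop)) crop$dm[["stem"]] else 0
    rec$dm_sorg[d] <- if (!is.null(crop)) crop$dm[["sorg"]] else 0
    rec$system_n[d] <- rec$organic_n[d] + cn +
      mineral_n_total(soil_n, grid) # full column mineral N
    ledgers[d, ] <- soil_n$ledger
  }

  out <- list(daily = as.data.frame(rec), ledger = ledgers,
              harvests = if (length(harvests)) do.call(rbind, harvests)
                         else data.frame(),
              grid = grid, config = config,
              final = list(soil_water = sw, soil_n = soil_n, pools = pools))
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  d <- x$daily
  cat(sprintf("<sim_output> %s .. %s (%d days, %d harvests)\n",
              format(min(d$date)), format(max(d$date)), nrow(d),
              nrow(x$harvests)))
  invisible(x)
}

#' Daily nitrogen budget closure residual
#'
#' Change in system N (organic + mineral + crop) minus ledgered inputs
#' (deposition, net fertiliser, organic inputs) plus ledgered losses
#' (volatilisation, denitrification, N2O, leaching, harvest export), per day.
#'
#' @param output a `sim_output`.
#' @return Vector of daily residuals, kg N/ha.
#' @export
n_closure_residual <- function(output) {
  led <- output$ledger
  sysn <- output$daily$system_n
  dled <- rbind(led[1, , drop = FALSE] - led[1, ], diff(led))
  dsys <- c(0, diff(sysn))
  inflow <- dled[, "deposition"] +
    (dled[, "fertiliser"] - dled[, "volatilisation"]) +
    dled[, "organic_input"]
  outflow <- dled[, "denitrification"] + dled[, "n2o"] +
    dled[, "leach_no3"] + dled[, "leach_nh4"] + dled[, "export"]
  # day 1 inflow/outflow relative to a zero ledger
  inflow[1] <- led[1, "deposition"] +
    led[1, "fertiliser"] - led[1, "volatilisation"] + led[1, "organic_input"]
  outflow[1] <- led[1, "denitrification"] + led[1, "n2o"] +
    led[1, "leach_no3"] + led[1, "leach_nh4"] + led[1, "export"]
  dsys[1] <- 0                         # no pre-run reference for day 1
  res <- dsys - (inflow - outflow)
  res[1] <- 0
  res
}

#' Annual water budget closure residual
#'
#' `P + I - AET - bottom drainage - runoff - storage change` per calendar
#' year fully inside the output.  Daily storage is recorded after each
#' day's fluxes, so the storage change over a year uses the last storage of
#' the preceding day as the opening value; the first simulated day (which
#' has no predecessor) is excluded.
#'
#' @param output a `sim_output`.
#' @return Data frame `year`, `residual_mm`.
#' @export
water_closure_residual <- function(output) {
  d <- output$daily
  resid_day <- d$precipitation + d$irrigation - d$aet -
    d$bottom_drainage - d$runoff - c(NA, diff(d$storage))
  yr <- as.integer(format(d$date, "%Y"))
  keep <- !is.na(resid_day) & !d$warmup
  full <- names(which(tapply(yr[keep], yr[keep], length) >= 364))
  rows <- lapply(full, function(y) data.frame(
    year = as.integer(y),
    residual_mm = sum(resid_day[keep & yr == as.integer(y)])))
  do.call(rbind, rows)
}

#' Annual N balance table
#'
#' Mirrors the classical field N balance: fertilisation, crop harvest N,
#' leaching past the output depth, atmospheric deposition, ammonia
#' volatilisation, N2O from nitrification, and net mineralisation, for one
#' calendar year of output, plus the closure residual of the full budget at
#' the column base.
#'
#' @param output a `sim_output`.
#' @param year calendar year fully covered by the (non-warm-up) output.
#' @return Data frame `component`, `kg_n_ha`.
#' @export
annual_n_balance <- function(output, year) {
  d <- output$daily[!output$daily$warmup, ]
  yr <- as.integer(format(d$date, "%Y"))
  if (sum(yr == year) < 365)
    stop_domain("year ", year, " is not fully covered by the output")
  idx <- which(!output$daily$warmup)[yr == year]
  led <- output$ledger
  dled <- led[idx[length(idx)], ] - led[max(idx[1] - 1, 1), ]
  if (idx[1] == 1) dled <- led[idx[length(idx)], ]
  harv <- output$harvests
  hN <- if (nrow(harv)) sum(harv$exported_n[as.integer(format(harv$date, "%Y")) == year]) else 0
  data.frame(
    component = c("fertilisation", "crop_harvest_n", "leaching",
                  "deposition", "volatilisation", "n2o",
                  "net_mineralisation", "denitrification"),
    kg_n_ha = c(dled[["fertiliser"]], hN,
                sum(output$daily$leaching[idx]),
                dled[["deposition"]], dled[["volatilisation"]],
                dled[["n2o"]],
                sum(output$daily$net_min[idx]),
                dled[["denitrification"]]))
}

#' Post-harvest 0-2 m soil mineral N samples
#'
#' Extracts the simulated soil mineral N (0 to the output depth) on the
#' configured post-harvest sampling dates (default 6 October after maize,
#' 12 June after wheat), warm-up excluded.
#'
#' @param output a `sim_output`.
#' @return Data frame `date`, `year`, `frac` (fraction of year), `mineral_n`
#'   (kg N/ha).
#' @export
post_harvest_mineral_n <- function(output) {
  d <- output$daily[!output$daily$warmup, ]
  md <- format(d$date, "%m-%d")
  keep <- md %in% output$config$sampling_dates
  dd <- d[keep, ]
  data.frame(date = dd$date,
             year = as.integer(format(dd$date, "%Y")),
             frac = (as.integer(format(dd$date, "%j")) - 1) / 365,
             mineral_n = dd$mineral_n)
}
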