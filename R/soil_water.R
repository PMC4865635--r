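#' Soil grid, van Genuchten-Mualem hydraulics and Richards-equation flow
#'
#' The soil column is discretised into finite-volume cells (by default 2 cm
#' increments to 60 cm, 5 cm to 170 cm and 10 cm to 210 cm).  Water retention
#' follows van Genuchten, unsaturated conductivity the Mualem model with the
#' saturated conductivity as matching point, and vertical flow is solved with
#' an implicit, mass-conservative mixed-form Richards scheme (modified Picard
#' iteration with adaptive sub-daily time stepping).
#'
#' @name soil_water
NULL

## ---- grid -----------------------------------------------------------------

#' Build the soil grid
#'
#' @param profile a validated `soil_profile` whose horizons must cover the
#'   full grid depth.
#' @param increments list of `c(top, bottom, step)` triples in cm; the default
#'   gives 30 cells of 2 cm, 22 of 5 cm and 4 of 10 cm down to 210 cm.
#' @return A `soil_grid`: cell edges, centres, thicknesses, horizon index per
#'   cell and per-cell hydraulic parameter vectors.
#' @export
make_default_grid <- function(profile,
                              increments = list(c(0, 60, 2), c(60, 170, 5),
                                                c(170, 210, 10))) {
  edges <- 0
  for (seg in increments)
    edges <- c(edges, seq(seg[1] + seg[3], seg[2], by = seg[3]))
  edges <- unique(edges)
  bots <- vapply(profile$horizons, `[[`, 0, "depth_bottom")
  if (max(bots) < max(edges))
    stop_domain(sprintf(
      "soil profile ends at %g cm but the grid needs %g cm",
      max(bots), max(edges)))
  zc <- (edges[-1] + edges[-length(edges)]) / 2
  tops <- vapply(profile$horizons, `[[`, 0, "depth_top")
  hidx <- vapply(zc, function(z) which(z >= tops & z < bots)[1], 0L)
  if (anyNA(hidx)) stop_domain("grid cell falls outside all horizons")
  pull <- function(f) vapply(profile$horizons[hidx], `[[`, 0, f)
  g <- list(edges = edges, zc = zc, dz = diff(edges),
            n_cells = length(zc), horizon = hidx,
            hyd = list(th_s = pull("theta_sat"), th_r = pull("theta_res"),
                       alpha = pull("alpha"), n = pull("n"),
                       m = 1 - 1 / pull("n"), l = pull("l"),
                       Ksat = pull("Ksat")),
            clay = pull("clay"),
            profile = profile)
  class(g) <- "soil_grid"
  g
}

## ---- constitutive relations ----------------------------------------------

hp_of <- function(horizon) {
  list(th_s = horizon$theta_sat, th_r = horizon$theta_res,
       alpha = horizon$alpha, n = horizon$n, m = 1 - 1 / horizon$n,
       l = horizon$l, Ksat = horizon$Ksat)
}

vg_theta_v <- function(h, hp) {
  # branch-free: pmax(-h, 0) gives se = 1 exactly at saturation
  se <- (1 + (hp$alpha * pmax.int(-h, 0))^hp$n)^(-hp$m)
  hp$th_r + (hp$th_s - hp$th_r) * se
}

vg_head_v <- function(theta, hp) {
  se <- pmin.int(pmax.int((theta - hp$th_r) / (hp$th_s - hp$th_r), 1e-12), 1)
  ifelse(se >= 1, 0, -(se^(-1 / hp$m) - 1)^(1 / hp$n) / hp$alpha)
}

# storage water content: retention curve below saturation, plus a small
# pressure storage Ss*h above it.  Strictly increasing in h everywhere, so
# the head is always recoverable from the stored water -- the property the
# mixed-form update relies on.
SS_SAT <- 1e-5   # specific storage, 1/cm

vg_w_v <- function(h, hp) {
  vg_theta_v(h, hp) + SS_SAT * pmax.int(h, 0)
}

vg_h_from_w <- function(w, hp) {
  out <- vg_head_v(pmin.int(w, hp$th_s), hp)
  sat <- w >= hp$th_s
  if (any(sat)) out[sat] <- ((w - hp$th_s) / SS_SAT)[sat]
  out
}

vg_cap_v <- function(h, hp) {
  # specific moisture capacity dtheta/dh; small storage term when saturated
  ah <- hp$alpha * abs(h)
  c_unsat <- (hp$th_s - hp$th_r) * hp$alpha * hp$n * hp$m *
    ah^(hp$n - 1) * (1 + ah^hp$n)^(-hp$m - 1)
  c_unsat[h >= 0] <- SS_SAT
  c_unsat
}

vg_k_v <- function(h, hp) {
  se <- (1 + (hp$alpha * pmax.int(-h, 0))^hp$n)^(-hp$m)
  se <- pmax.int(se, 1e-12)
  hp$Ksat * se^hp$l * (1 - (1 - se^(1 / hp$m))^hp$m)^2
}

# solver-internal conductivity with a small air-entry regularisation
# (Vogel-van Genuchten style): K reaches Ksat already at h = -hs and the
# curve is rescaled so K(-hs) = Ksat.  For the low-n horizons of this
# profile the standard Mualem K(h) has a near-vertical drop just below
# saturation that makes the Picard iteration cycle; the regularisation
# bounds that slope while leaving K essentially unchanged for drier states.
vg_k_reg_v <- function(h, hp, hs = 2, scale = NULL) {
  if (is.null(scale)) scale <- hp$Ksat / vg_k_v(rep(-hs, length(h)), hp)
  k <- pmin.int(vg_k_v(h, hp) * scale, hp$Ksat)
  k[h >= -hs] <- hp$Ksat[h >= -hs]
  k
}

#' van Genuchten retention and Mualem conductivity
#'
#' `vg_theta()` maps pressure head to volumetric water content
#' (`theta = theta_res + (theta_sat - theta_res) * (1 + (alpha |h|)^n)^(-m)`,
#' `m = 1 - 1/n`, saturated for `h >= 0`); `vg_head()` is its exact inverse on
#' `(theta_res, theta_sat)`; `vg_conductivity()` is the Mualem model
#' `K = Ksat * Se^l * (1 - (1 - Se^(1/m))^m)^2` with `Ksat` the matching
#' point at saturation (negative tortuosity `l` is permitted).
#'
#' @param h pressure head, cm (negative = unsaturated); vectorised.
#' @param horizon a `SoilHorizon`-style list (fields `theta_sat`, `theta_res`,
#'   `alpha`, `n`, `l`, `Ksat`).
#' @return Water content (volume fraction), head (cm) or conductivity (cm/h).
#' @export
vg_theta <- function(h, horizon) vg_theta_v(h, hp_of(horizon))

#' @rdname vg_theta
#' @param theta volumetric water content.
#' @export
vg_head <- function(theta, horizon) {
  hp <- hp_of(horizon)
  if (any(theta <= hp$th_r | theta > hp$th_s))
    stop_domain(sprintf(
      "theta outside (theta_res, theta_sat] = (%g, %g]", hp$th_r, hp$th_s))
  se <- (theta - hp$th_r) / (hp$th_s - hp$th_r)
  ifelse(se >= 1, 0, -(se^(-1 / hp$m) - 1)^(1 / hp$n) / hp$alpha)
}

#' @rdname vg_theta
#' @export
vg_conductivity <- function(h, horizon) vg_k_v(h, hp_of(horizon))

## ---- state ----------------------------------------------------------------

#' Initialise the soil water state
#'
#' @param grid a `soil_grid`.
#' @param h uniform initial pressure head (cm), or a per-cell vector, or
#'   `NULL` with `water_table` set for hydrostatic equilibrium above a water
#'   table (head `h = z - water_table`).
#' @param water_table water table depth, cm.
#' @return A `soil_water_state` with elements `h` and `theta`.
#' @export
init_soil_water <- function(grid, h = -200, water_table = NULL) {
  hv <- if (!is.null(water_table)) grid$zc - water_table
        else rep_len(h, grid$n_cells)
  st <- list(h = hv, theta = vg_theta_v(hv, grid$hyd))
  class(st) <- "soil_water_state"
  st
}

#' @export
print.soil_water_state <- function(x, ...) {
  cat(sprintf("<soil_water_state> %d cells, storage %.1f mm, h in [%.3g, %.3g] cm\n",
              length(x$h), NA_real_, min(x$h), max(x$h)))
  invisible(x)
}

richards_control <- function(tol_h = 1e-6, max_iter = 40, dt_init = 2,
                             dt_min = 1e-4, dt_max = 6, max_dtheta = 0.02,
                             h_dry = -1e5, h_wilt = -15000, h_lim = -400,
                             h_air_entry = 2) {
  list(tol_h = tol_h, max_iter = max_iter, dt_init = dt_init,
       dt_min = dt_min, dt_max = dt_max, max_dtheta = max_dtheta,
       h_dry = h_dry, h_wilt = h_wilt, h_lim = h_lim,
       h_air_entry = h_air_entry)
}

thomas_solve <- function(a, b, cc, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    den <- b[i] - a[i] * cp[i - 1]
    cp[i] <- cc[i] / den
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / den
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

feddes_alpha <- function(h, ctl) {
  pmin.int(1, pmax.int(0, (h - ctl$h_wilt) / (ctl$h_lim - ctl$h_wilt)))
}

#' One coupling step of the Richards solver
#'
#' Advances soil water over `dt` days under a prescribed net surface flux
#' (infiltration minus soil evaporation demand) and a root extraction demand,
#' using the implicit mixed-form scheme with modified Picard iteration and
#' adaptive sub-stepping.  Infiltration is limited by the profile's intake
#' capacity (excess reported as ponding/runoff, never silently dropped);
#' evaporation is limited by exfiltration against a dry-surface head; root
#' extraction is reduced cell-wise by a Feddes-type pressure-head response.
#'
#' @param state a `soil_water_state`.
#' @param grid a `soil_grid`.
#' @param dt step length, days.
#' @param surface_flux net surface water flux demand, mm per step (positive
#'   downward).
#' @param lower_bc `list(type = "free")` for unit-gradient free drainage
#'   (deep groundwater), `list(type = "fixed_head", head = h)` or
#'   `list(type = "no_flow")`.
#' @param sink per-cell root water extraction demand, mm per step (or NULL).
#' @param control numerics, see `richards_control()`.
#' @return List: updated `state`; `flux` (list `edges`, `flux` mm/step,
#'   downward positive, at every cell edge); `runoff`, `infiltration`,
#'   `actual_surface_flux`, `bottom_drainage`, `actual_sink` (per cell),
#'   `storage_change`, `balance_error` (all mm per step); `n_substeps`.
#' @export
richards_step <- function(state, grid, dt = 1, surface_flux = 0,
                          lower_bc = list(type = "free"), sink = NULL,
                          control = richards_control()) {
  stopifnot(dt > 0)
  hp <- grid$hyd
  n <- grid$n_cells
  dt_h <- dt * 24
  q_demand <- surface_flux / 10 / dt_h          # mm/step -> cm/h
  sink_rate <- if (is.null(sink)) numeric(n) else sink / 10 / dt_h
  ctl <- control
  kreg_scale <- hp$Ksat / vg_k_v(rep(-ctl$h_air_entry, n), hp)
  th_init <- state$w %||% vg_w_v(state$h, hp)
  bc_type <- match(lower_bc$type, c("free", "no_flow", "fixed_head")) - 1L
  if (is.na(bc_type)) stop_domain("unknown lower boundary: ", lower_bc$type)

  res <- .richards_day_cpp(state$h, th_init, hp$th_s, hp$th_r, hp$alpha,
                           hp$n, hp$m, hp$l, hp$Ksat, kreg_scale,
                           grid$dz, grid$zc, diff(grid$zc),
                           dt_h, q_demand, bc_type,
                           lower_bc$head %||% 0, sink_rate,
                           ctl$tol_h, ctl$max_iter, ctl$dt_init, ctl$dt_min,
                           ctl$dt_max, ctl$max_dtheta, ctl$h_dry,
                           ctl$h_wilt, ctl$h_lim, ctl$h_air_entry)
  if (isTRUE(res$failed))
    stop_domain(sprintf(
      "Richards solver failed to converge (t = %.3f h, dt = %.2g h, max |dh| = %.3g cm)",
      res$t_done, res$dt, res$err))

  state$h <- res$h
  state$w <- res$w
  state$theta <- pmin.int(res$w, hp$th_s)
  edge_flux <- res$edge_flux
  sink_acc <- res$sink_acc
  storage_change <- sum((res$w - th_init) * grid$dz) * 10
  balance_error <- storage_change -
    (edge_flux[1] - edge_flux[n + 1] - sum(sink_acc)) * 10
  list(state = state,
       storage_change = storage_change,
       balance_error = balance_error,
       flux = list(edges = grid$edges, flux = edge_flux * 10),
       runoff = res$runoff_cm * 10,
       infiltration = max(edge_flux[1], 0) * 10,
       actual_surface_flux = edge_flux[1] * 10,
       bottom_drainage = edge_flux[n + 1] * 10,
       actual_sink = sink_acc * 10,
       n_substeps = res$n_substeps)
}

#' Drainage (downward Darcy flux) at a reference depth
#'
#' @param flux a `flux` element returned by [richards_step()].
#' @param z reference depth, cm; must coincide with a cell edge.
#' @return Downward-positive flux in mm per step.
#' @export
drainage_at_depth <- function(flux, z) {
  i <- which(abs(flux$edges - z) < 1e-9)
  if (!length(i))
    stop_domain("depth ", z, " cm is not a cell edge; interpolation refused")
  flux$flux[i]
}

#' Analytic soil temperature profile
#'
#' Annual damped sinusoid
#' `T(z, t) = mean + amplitude * exp(-z/d) * sin(2 pi (t - t0)/365 - z/d)`,
#' the classical solution of the conduction equation under a sinusoidal
#' surface temperature; `d` is the damping depth at which the amplitude has
#' fallen to `1/e` of its surface value.
#'
#' @param day_of_year day of year (t).
#' @param depth depth below surface, cm (vectorised).
#' @param annual_mean,annual_amplitude degC.
#' @param damping_depth cm (> 0); default 180 cm is typical of moist loam.
#' @param phase_day upward zero-crossing day of the surface wave.
#' @return Temperature, degC.
#' @export
soil_temperature_profile <- function(day_of_year, depth, annual_mean = 12.5,
                                     annual_amplitude = 14.5,
                                     damping_depth = 180, phase_day = 106) {
  stopifnot(damping_depth > 0)
  annual_mean + annual_amplitude * exp(-depth / damping_depth) *
    sin(2 * pi * (day_of_year - phase_day) / 365 - depth / damping_depth)
}

#' Column water storage
#' @param state a `soil_water_state`; `grid` the matching grid.
#' @param grid a `soil_grid`.
#' @return Stored water, mm.
#' @export
water_storage <- function(state, grid)
  sum((state$w %||% state$theta) * grid$dz) * 10
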