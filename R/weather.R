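#' Weather series, FAO-56 reference evapotranspiration, N deposition, and a
#' synthetic semi-arid monsoonal weather generator
#'
#' Daily forcing for the simulator: air temperature, precipitation, global
#' radiation, wind speed and relative humidity, plus station latitude and
#' altitude.  Atmospheric N enters as wet deposition (concentration in rain)
#' and dry deposition (annual totals spread over the year).
#'
#' @name weather
NULL

WEATHER_COLS <- c("date", "t_mean", "t_min", "t_max", "precipitation",
                  "global_radiation", "wind_speed", "relative_humidity")

validate_weather <- function(df, latitude, altitude) {
  miss <- setdiff(WEATHER_COLS, names(df))
  if (length(miss))
    stop_domain("weather table missing column(s): ",
                paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  gaps <- diff(as.integer(df$date))
  if (any(gaps != 1)) {
    at <- which(gaps != 1)[1]
    stop_domain("weather series has a gap: missing ",
                format(df$date[at] + 1))
  }
  if (any(df$precipitation < 0)) stop_domain("negative precipitation")
  if (any(df$global_radiation < 0)) stop_domain("negative global radiation")
  if (any(df$relative_humidity < 0 | df$relative_humidity > 100))
    stop_domain("relative humidity outside [0, 100]")
  if (any(df$t_min > df$t_mean | df$t_mean > df$t_max))
    stop_domain("need t_min <= t_mean <= t_max on every day")
  structure(df[WEATHER_COLS], latitude = latitude, altitude = altitude,
            class = c("weather_series", "data.frame"))
}

#' Read / write a daily weather file
#'
#' Tab-separated text, one row per day, columns `date, t_mean, t_min, t_max,
#' precipitation, global_radiation, wind_speed, relative_humidity` (degC, mm/d,
#' W/m2, m/s, percent).  Station metadata is carried in `# latitude:` and
#' `# altitude:` header comment lines.  The series must be gap-free; the
#' round-trip `read_weather(write_weather(w, f))` is lossless.
#'
#' @param path file path.
#' @return A `weather_series` data frame with `latitude` and `altitude`
#'   attributes.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop_domain("weather file not found: ", path)
  hdr <- readLines(path, n = 10)
  meta <- function(key, default) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1]))
  }
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_domain("cannot parse weather file: ",
                                    conditionMessage(e)))
  bad <- which(is.na(suppressWarnings(as.numeric(df$t_mean))))
  if (length(bad))
    stop_domain("unparseable t_mean at data line ", bad[1])
  validate_weather(df, latitude = meta("latitude", 37.89),
                   altitude = meta("altitude", 50))
}

#' @rdname read_weather
#' @param series a `weather_series`.
#' @export
write_weather <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# latitude: %.10g", attr(series, "latitude")),
               sprintf("# altitude: %.10g", attr(series, "altitude"))), con)
  df <- as.data.frame(series)
  df$date <- format(df$date)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- solar geometry -------------------------------------------------------

solar_geometry <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(Ra = ra, day_length = 24 * ws / pi)
}

#' Astronomical day length
#' @param doy day of year (1-366).
#' @param latitude station latitude, degrees.
#' @return Hours of daylight.
#' @export
day_length <- function(doy, latitude) solar_geometry(doy, latitude)$day_length

sat_vp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' FAO-56 daily reference evapotranspiration
#'
#' Penman-Monteith reference ET for a hypothetical 0.12 m grass surface
#' (daily formulation): radiation balance with net shortwave at albedo 0.23
#' and net longwave from the cloudiness ratio, plus the aerodynamic
#' vapour-pressure-deficit term with wind at 2 m.  When only a mean relative
#' humidity is available, actual vapour pressure uses the mean-RH
#' approximation; daily RH extremes are used when supplied.  The longwave
#' cloudiness factor is clamped to `[0, 1]`, so a dark saturated calm day
#' returns (near) zero.
#'
#' @param t_mean,t_min,t_max daily air temperatures, degC.
#' @param radiation daily mean global radiation, W/m2.
#' @param wind wind speed at 2 m, m/s.
#' @param rh daily mean relative humidity, percent.
#' @param latitude degrees; `doy` day of year.
#' @param altitude station altitude, m.
#' @param rh_max,rh_min optional daily RH extremes, percent.
#' @return Reference ET0, mm/d (>= 0).
#' @export
reference_et_fao56 <- function(t_mean, t_min, t_max, radiation, wind, rh,
                               latitude, doy, altitude = 50,
                               rh_max = NULL, rh_min = NULL) {
  if (any(rh < 0 | rh > 100)) stop_domain("relative humidity outside [0,100]")
  p_atm <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  gamma <- 0.000665 * p_atm
  delta <- 4098 * sat_vp(t_mean) / (t_mean + 237.3)^2
  es <- (sat_vp(t_min) + sat_vp(t_max)) / 2
  ea <- if (!is.null(rh_max) && !is.null(rh_min)) {
    (sat_vp(t_min) * rh_max / 100 + sat_vp(t_max) * rh_min / 100) / 2
  } else rh / 100 * es
  rs <- radiation * 0.0864              # W/m2 -> MJ/m2/d
  geom <- solar_geometry(doy, latitude)
  rso <- (0.75 + 2e-5 * altitude) * geom$Ra
  cloud <- pmin(1, pmax(0, 1.35 * pmin(rs / pmax(rso, 1e-9), 1) - 0.35))
  rnl <- 4.903e-9 * ((t_max + 273.16)^4 + (t_min + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * cloud
  rn <- (1 - 0.23) * rs - rnl
  num <- 0.408 * delta * rn +
    gamma * 900 / (t_mean + 273) * wind * pmax(es - ea, 0)
  pmax(num / (delta + gamma * (1 + 0.34 * wind)), 0)
}

#' @rdname reference_et_fao56
#' @param day one row of a `weather_series` (list or single-row data frame).
#' @export
reference_et_day <- function(day, latitude, altitude = 50) {
  reference_et_fao56(day$t_mean, day$t_min, day$t_max, day$global_radiation,
                     day$wind_speed, day$relative_humidity,
                     latitude = latitude,
                     doy = as.integer(format(as.Date(day$date), "%j")),
                     altitude = altitude)
}

#' Daily atmospheric N deposition flux
#'
#' Wet deposition is the configured concentration in rain (mg N/L) times the
#' day's precipitation; dry deposition spreads the annual total uniformly
#' over the actual year length (366 days in leap years).
#'
#' @param precipitation mm on the day.
#' @param date calendar date (for the year length).
#' @param config a `deposition_config`.
#' @return Named vector `c(nh4, no3)`, kg N/ha/d.
#' @export
deposition_flux <- function(precipitation, date, config) {
  yr <- as.integer(format(as.Date(date), "%Y"))
  ndays <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
  c(nh4 = config$wet_nh4 * precipitation * MM_MGL_TO_KG_HA +
      config$dry_nh4 / ndays,
    no3 = config$wet_no3 * precipitation * MM_MGL_TO_KG_HA +
      config$dry_no3 / ndays)
}

## ---- synthetic generator --------------------------------------------------

#' Synthetic semi-arid monsoonal (NCP-like) daily weather
#'
#' Seeded, reproducible generator emulating the Luancheng station climate:
#' annual precipitation drawn from a 330-600 mm envelope with about 70
#' percent falling June-September (monsoon), annual mean temperature in the
#' 11.8-13.2 degC band with a sinusoidal annual cycle peaking mid-July plus
#' AR(1) daily noise, radiation from clear-sky extraterrestrial values
#' reduced on wet (cloudy) days, higher humidity on wet days, and lognormal
#' wind.  Monthly precipitation totals are rescaled to the drawn annual
#' target, so the envelope is honoured exactly.
#'
#' @param seed integer RNG seed; same seed, same series.
#' @param n_years number of calendar years (>= 1).
#' @param start_year first calendar year (default 2001).
#' @param climate_spec optional overrides: `annual_precip_range` (mm),
#'   `annual_t_range` (degC), `monthly_precip_fraction` (12 values summing
#'   to 1), `t_amplitude` (degC), `latitude`, `altitude`.
#' @return A `weather_series`.
#' @export
synthetic_ncp_weather <- function(seed, n_years, start_year = 2001,
                                  climate_spec = list()) {
  stopifnot(n_years >= 1)
  spec <- utils::modifyList(list(
    annual_precip_range = c(330, 600),
    annual_t_range = c(11.8, 13.2),
    monthly_precip_fraction = c(0.010, 0.015, 0.030, 0.045, 0.060, 0.130,
                                0.260, 0.240, 0.090, 0.070, 0.040, 0.010),
    wet_day_prob = c(0.05, 0.05, 0.08, 0.10, 0.12, 0.22,
                     0.35, 0.33, 0.18, 0.12, 0.08, 0.05),
    t_amplitude = 14.5,
    t_half_range = 5,
    latitude = 37.89,
    altitude = 50), climate_spec)
  with_seed(seed, {
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
                 by = "day")
    n <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    yr <- as.integer(format(dates, "%Y"))
    mo <- as.integer(format(dates, "%m"))
    # temperature: per-year mean in band, sinusoid peaking around 16 July
    tbar_y <- stats::runif(n_years, spec$annual_t_range[1],
                           spec$annual_t_range[2])
    tbar <- tbar_y[yr - start_year + 1]
    noise <- stats::filter(stats::rnorm(n, 0, 1.5), 0.7, "recursive")
    t_mean <- tbar + spec$t_amplitude * sin(2 * pi * (doy - 106) / 365.25) +
      as.numeric(noise)
    # precipitation: wet-day occurrence + gamma amounts, rescaled monthly
    target_y <- stats::runif(n_years, spec$annual_precip_range[1],
                             spec$annual_precip_range[2])
    wet <- stats::runif(n) < spec$wet_day_prob[mo]
    amt <- ifelse(wet, stats::rgamma(n, shape = 0.7, scale = 12), 0)
    precip <- numeric(n)
    for (y in seq_len(n_years)) {
      for (m in 1:12) {
        idx <- which(yr == start_year + y - 1 & mo == m)
        tgt <- target_y[y] * spec$monthly_precip_fraction[m]
        tot <- sum(amt[idx])
        if (tot <= 0 && tgt > 0) {
          amt[idx[ceiling(length(idx) / 2)]] <- 1
          tot <- 1
        }
        precip[idx] <- if (tgt > 0) amt[idx] * tgt / tot else 0
      }
    }
    is_wet <- precip > 0.1
    # radiation: transmissivity lower on wet days
    ra <- solar_geometry(doy, spec$latitude)$Ra
    tau <- pmin(0.75, pmax(0.10,
      ifelse(is_wet, 0.30, 0.62) + stats::rnorm(n, 0, 0.06)))
    rad <- ra * tau / 0.0864            # MJ/m2/d -> W/m2
    rh <- pmin(98, pmax(20,
      ifelse(is_wet, 85, 55) + stats::rnorm(n, 0, 8)))
    wind <- pmin(12, stats::rlnorm(n, log(1.8), 0.4))
    validate_weather(
      data.frame(date = dates, t_mean = t_mean,
                 t_min = t_mean - spec$t_half_range,
                 t_max = t_mean + spec$t_half_range,
                 precipitation = precip, global_radiation = rad,
                 wind_speed = wind, relative_humidity = rh),
      latitude = spec$latitude, altitude = spec$altitude)
  })
}
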