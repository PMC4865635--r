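#' Goodness-of-fit statistics, hold-out splitting, sensitivity and scenarios
#'
#' The four objective measures used to judge model fit (root mean squared
#' residuals, mean deviation, Nash-Sutcliffe model efficiency, coefficient of
#' determination), the hold-out calibration/validation split, one-at-a-time
#' (mono-factor) parameter sensitivity, and the fertiliser-ladder scenario
#' analysis of post-harvest residual soil mineral N.
#'
#' @name evaluation
NULL

check_pairs <- function(obs, sim, need_var = FALSE) {
  if (length(obs) != length(sim))
    stop_domain("observed and simulated series differ in length")
  if (length(obs) < 2) stop_domain("need at least 2 paired values")
  if (need_var && stats::var(obs) == 0)
    stop_domain("observed values are all identical: statistic undefined")
  invisible(TRUE)
}

#' @rdname evaluation
#' @param obs observed values.
#' @param sim simulated values (same length, same time labels).
#' @return `rmsr()`: root mean squared residual, same units as the series.
#' @examples
#' rmsr(c(1, 2, 3), c(2, 2, 2))   # sqrt(2/3)
#' nash_sutcliffe(c(1, 2, 3), c(2, 2, 2))  # 0
#' @export
rmsr <- function(obs, sim) {
  check_pairs(obs, sim)
  sqrt(mean((sim - obs)^2))
}

#' @rdname evaluation
#' @return `dev_mean()`: mean deviation (simulated minus observed); positive
#'   values mean over-prediction.
#' @export
dev_mean <- function(obs, sim) {
  check_pairs(obs, sim)
  mean(sim - obs)
}

#' @rdname evaluation
#' @return `nash_sutcliffe()`: model efficiency ME, 1 for a perfect fit, 0
#'   when the model is no better than the observed mean, negative when worse.
#' @export
nash_sutcliffe <- function(obs, sim) {
  check_pairs(obs, sim, need_var = TRUE)
  1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)
}

#' @rdname evaluation
#' @return `r2()`: squared Pearson correlation between observed and simulated.
#' @export
r2 <- function(obs, sim) {
  check_pairs(obs, sim, need_var = TRUE)
  if (stats::var(sim) == 0)
    stop_domain("simulated values are all identical: R2 undefined")
  stats::cor(obs, sim)^2
}

#' Hold-out split of a field dataset
#'
#' Splits records into disjoint, exhaustive calibration and validation
#' subsets by an explicit assignment of period labels (the calibration
#' periods are those with the highest level of measured detail).
#'
#' @param data a data frame with a `period` column.
#' @param calibration character vector of period labels for calibration.
#' @param validation character vector of period labels for validation.
#' @return List with `calibration` and `validation` data frames and a
#'   `summary` of record counts.
#' @export
holdout_split <- function(data, calibration, validation) {
  if (length(intersect(calibration, validation)))
    stop_domain("calibration and validation periods overlap: ",
                paste(intersect(calibration, validation), collapse = ", "))
  if (!length(validation)) stop_domain("validation set is empty")
  missing <- setdiff(unique(data$period), c(calibration, validation))
  if (length(missing))
    stop_domain("periods not assigned to either subset: ",
                paste(missing, collapse = ", "))
  cal <- data[data$period %in% calibration, , drop = FALSE]
  val <- data[data$period %in% validation, , drop = FALSE]
  list(calibration = cal, validation = val,
       summary = data.frame(subset = c("calibration", "validation"),
                            n_periods = c(length(calibration),
                                          length(validation)),
                            n_records = c(nrow(cal), nrow(val))))
}

## ---- mono-factor sensitivity ---------------------------------------------

get_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}
set_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path]] <- value
    return(x)
  }
  x[[path[1]]] <- set_path(x[[path[1]]], path[-1], value)
  x
}

#' One-at-a-time (mono-factor) parameter sensitivity
#'
#' Runs the model at baseline and with a single parameter increased and
#' decreased by `delta` (default 10 percent) while every other input is held
#' constant, and reports the relative sensitivity index
#' `(dY/Y0) / (dX/X0)` per direction and output.
#'
#' @param model a function taking a config list and returning a named numeric
#'   vector of outputs (e.g. annual crop yield and nitrate leaching).
#' @param config baseline configuration (nested list).
#' @param param_path character vector addressing the parameter inside
#'   `config`, e.g. `c("crops", "maize", "Fm")`.
#' @param delta relative perturbation (default 0.1).
#' @return A `sensitivity_result`: data frame with one row per output and
#'   columns `baseline`, `up`, `down`, `rel_sens_up`, `rel_sens_down`.
#' @examples
#' m <- function(cfg) c(y = 2 * cfg$x)
#' mono_factor_sensitivity(m, list(x = 3), "x")$rel_sens_up  # 1
#' @export
mono_factor_sensitivity <- function(model, config, param_path, delta = 0.1) {
  x0 <- get_path(config, param_path)
  if (!is.numeric(x0) || length(x0) != 1 || x0 == 0)
    stop_domain("parameter at path '", paste(param_path, collapse = "$"),
                "' must be a nonzero scalar")
  run <- function(cfg, label) {
    out <- tryCatch(model(cfg), error = function(e)
      stop_domain("model failed for ", label, " run of parameter '",
                  paste(param_path, collapse = "$"), "': ",
                  conditionMessage(e)))
    if (is.null(names(out))) names(out) <- paste0("output", seq_along(out))
    out
  }
  y0 <- run(config, "baseline")
  yu <- run(set_path(config, param_path, x0 * (1 + delta)), "+delta")
  yd <- run(set_path(config, param_path, x0 * (1 - delta)), "-delta")
  if (any(y0 == 0))
    warning("zero baseline output: relative sensitivity undefined there",
            call. = FALSE)
  res <- data.frame(
    output = names(y0),
    baseline = as.numeric(y0),
    up = as.numeric(yu),
    down = as.numeric(yd),
    rel_sens_up = ((yu - y0) / y0) / delta,
    rel_sens_down = ((y0 - yd) / y0) / delta,
    row.names = NULL)
  attr(res, "parameter") <- paste(param_path, collapse = "$")
  attr(res, "delta") <- delta
  class(res) <- c("sensitivity_result", "data.frame")
  res
}

#' Linear trend of post-harvest residual soil mineral N
#'
#' Ordinary least squares slope of one value per year against year index;
#' the summary statistic of the fertiliser-ladder scenario analysis.
#'
#' @param values post-harvest soil mineral N per year, kg N/ha (0-2 m).
#' @param years year labels (default `seq_along(values)`).
#' @return Slope in kg N/ha per year.
#' @export
residual_n_trend <- function(values, years = seq_along(values)) {
  if (length(values) < 3)
    stop_domain("need at least 3 years for a trend (got ", length(values), ")")
  xd <- years - mean(years)
  sum(xd * (values - mean(values))) / sum(xd^2)
}

#' Fertiliser-ladder scenario analysis
#'
#' Runs the multi-year maize - winter wheat rotation across a ladder of annual
#' N fertiliser rates (split half to each crop) and straw managements,
#' extracts post-harvest 0-2 m soil mineral N once per crop-year, and fits an
#' OLS trend per scenario.  An increasing trend marks residual mineral N
#' accumulating in the profile.
#'
#' @param base_config a simulation config as built by [build_field_fixture()];
#'   its fertiliser events are rescaled per ladder rate.
#' @param n_rates annual N rates, kg N/ha (>= 0).
#' @param straw_options vector of incorporated straw fractions to test.
#' @param progress print one line per scenario run.
#' @return Data frame with `rate`, `straw_fraction`, `slope` (kg N/ha/y) and
#'   `mean_residual_n`.
#' @export
scenario_ladder <- function(base_config, n_rates, straw_options = c(1, 0),
                            progress = FALSE) {
  if (any(n_rates < 0)) stop_domain("n_rates must be >= 0")
  grid <- expand.grid(rate = n_rates, straw = straw_options)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rate <- grid$rate[i]
    straw <- grid$straw[i]
    cfg <- rescale_fertilisation(base_config, rate)
    cfg <- set_straw_fraction(cfg, straw)
    if (progress)
      message(sprintf("ladder: rate %g kg N/ha, straw %g", rate, straw))
    out <- run_simulation(cfg)
    resid <- post_harvest_mineral_n(out)
    if (nrow(resid) < 3)
      stop_domain("fewer than 3 post-harvest samples: run more years")
    data.frame(rate = rate, straw_fraction = straw,
               slope = residual_n_trend(resid$mineral_n,
                                        resid$year + resid$frac),
               mean_residual_n = mean(resid$mineral_n))
  })
  do.call(rbind, rows)
}
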