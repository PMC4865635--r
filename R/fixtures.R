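#' Packaged fixtures: field configurations, schedules and retention toys
#'
#' Fully offline test inputs: a maize - winter wheat rotation config for each
#' experimental field pairing the recorded management pattern (sowing,
#' harvest, split fertilisation, irrigation, tillage, straw handling) with
#' seed-pinned synthetic weather matching the station's climate envelope,
#' plus a noisy water-retention sample generator and a van Genuchten
#' least-squares fitter.
#'
#' @name fixtures
NULL

field_a_year_events <- function(year, n_rate, irr_mm) {
  # maize: sown mid June, top dressed at flowering, harvested early October;
  # wheat: sown mid October after tillage, split dressing autumn + spring,
  # harvested mid June next year; straw incorporated (80%)
  ev <- rbind(
    mgmt_event(sprintf("%d-06-15", year), "sow", crop = "maize"),
    mgmt_event(sprintf("%d-06-19", year), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-07-29", year), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-07-27", year), "fertilise",
               amount = 0.5 * n_rate, share = 0.5),
    mgmt_event(sprintf("%d-10-01", year), "harvest", straw_fraction = 0.8),
    mgmt_event(sprintf("%d-10-08", year), "till", depth = 20),
    mgmt_event(sprintf("%d-10-03", year), "fertilise",
               amount = 0.25 * n_rate, share = 0.25),
    mgmt_event(sprintf("%d-10-03", year), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-10-10", year), "sow", crop = "wheat"),
    mgmt_event(sprintf("%d-04-07", year + 1), "fertilise",
               amount = 0.25 * n_rate, share = 0.25),
    mgmt_event(sprintf("%d-04-07", year + 1), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-05-19", year + 1), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-06-14", year + 1), "harvest",
               straw_fraction = 0.8))
  ev
}

field_b_year_events <- function(year, n_rate, irr_mm) {
  # single dressings at sowing; straw removed (80% removed, 20% left)
  rbind(
    mgmt_event(sprintf("%d-06-12", year), "sow", crop = "maize"),
    mgmt_event(sprintf("%d-06-12", year), "fertilise",
               amount = 0.5 * n_rate, share = 0.5),
    mgmt_event(sprintf("%d-07-05", year), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-08-13", year), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-09-28", year), "harvest", straw_fraction = 0),
    mgmt_event(sprintf("%d-10-05", year), "till", depth = 20),
    mgmt_event(sprintf("%d-10-12", year), "sow", crop = "wheat"),
    mgmt_event(sprintf("%d-10-12", year), "fertilise",
               amount = 0.5 * n_rate, share = 0.5),
    mgmt_event(sprintf("%d-10-06", year), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-03-15", year + 1), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-04-25", year + 1), "irrigate", amount = irr_mm),
    mgmt_event(sprintf("%d-06-08", year + 1), "harvest",
               straw_fraction = 0))
}

#' Build a ready-to-run field fixture config
#'
#' Pairs the field's recorded management pattern and the packaged parameter
#' set with seed-pinned synthetic weather.  Fertiliser is split half to each
#' crop (the maize share at flowering for field A, at sowing for field B; the
#' wheat share split autumn/spring for field A).  Irrigation events receive
#' the annual amount divided evenly.
#'
#' @param field `"A"` (straw incorporated) or `"B"` (straw removed).
#' @param n_rate annual fertiliser rate, kg N/ha (default 400).
#' @param years rotation years to simulate (default 2).
#' @param warmup_years equilibration years before the reported window.
#' @param seed weather seed.
#' @param start_year first reported rotation year.
#' @param annual_irrigation mm/year split over the events (default 300).
#' @param params parameter set (default packaged NCP set).
#' @return A `sim_config`.
#' @export
build_field_fixture <- function(field = c("A", "B"), n_rate = 400, years = 2,
                                warmup_years = 0, seed = 11,
                                start_year = 2008, annual_irrigation = 300,
                                params = default_ncp_parameters()) {
  field <- match.arg(field)
  first <- start_year - warmup_years
  wx_years <- warmup_years + years + 1
  wx <- synthetic_ncp_weather(seed, wx_years, start_year = first)
  builder <- if (field == "A") field_a_year_events else field_b_year_events
  n_irr <- if (field == "A") 5 else 5
  irr_mm <- annual_irrigation / n_irr
  mg <- do.call(rbind, lapply(first:(start_year + years - 1), builder,
                              n_rate = n_rate, irr_mm = irr_mm))
  sim_config(weather = wx, params = params, field = field, management = mg,
             start = as.Date(sprintf("%d-06-01", start_year)),
             end = as.Date(sprintf("%d-06-20", start_year + years)),
             warmup_years = warmup_years, output_depth = 200,
             annual_n_rate = n_rate)
}

#' Toy water-retention samples and van Genuchten least-squares fit
#'
#' `toy_retention_dataset()` draws (pF, theta) samples from a horizon's
#' retention curve with Gaussian noise on theta; `vg_fit()` recovers
#' `(theta_res, theta_sat, alpha, n)` by bounded nonlinear least squares
#' (Levenberg-Marquardt), reporting the residual norm and convergence.
#'
#' @param horizon a soil horizon (retention parameters).
#' @param noise_sd Gaussian noise on theta (volume fraction).
#' @param seed RNG seed.
#' @param n_samples number of samples (default 20).
#' @param pf_range range of pF = log10(|h| cm) sampled (default 0 to 4.2).
#' @return Data frame `h` (cm), `theta`.
#' @export
toy_retention_dataset <- function(horizon, noise_sd = 0, seed = 1,
                                  n_samples = 20, pf_range = c(0, 4.2)) {
  with_seed(seed, {
    pf <- seq(pf_range[1], pf_range[2], length.out = n_samples)
    h <- -10^pf
    theta <- vg_theta(h, horizon) + stats::rnorm(n_samples, 0, noise_sd)
    data.frame(h = h, theta = pmin(pmax(theta, 0), 1))
  })
}

#' @rdname toy_retention_dataset
#' @param samples data frame with columns `h` (cm, negative) and `theta`.
#' @param start optional named start values.
#' @return `vg_fit()`: list with `par` (named vector `theta_res`,
#'   `theta_sat`, `alpha`, `n`), `residual_norm`, `converged`.
#' @export
vg_fit <- function(samples, start = NULL) {
  if (nrow(samples) < 6)
    stop_domain("need at least 6 retention samples (got ", nrow(samples), ")")
  pf <- log10(abs(samples$h))
  if (diff(range(pf[is.finite(pf)])) < 3)
    stop_domain("retention samples must span at least 3 pF units")
  st <- start %||% c(theta_res = 0.05,
                     theta_sat = max(samples$theta),
                     alpha = 0.01, n = 1.4)
  fit <- minpack.lm::nlsLM(
    theta ~ theta_res + (theta_sat - theta_res) *
      (1 + (alpha * abs(h))^n)^(-(1 - 1 / n)),
    data = samples, start = as.list(st),
    lower = c(theta_res = 0, theta_sat = 0.2, alpha = 1e-5, n = 1.01),
    upper = c(theta_res = 0.25, theta_sat = 0.6, alpha = 1, n = 4),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  conv <- fit$convInfo$isConv %||% TRUE
  if (!conv) warning("van Genuchten fit did not converge", call. = FALSE)
  list(par = stats::coef(fit),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       converged = conv)
}
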