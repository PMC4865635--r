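#' Field estimators: water-balance drainage and concentration-based leaching
#'
#' The classical lysimeter/neutron-probe estimators used alongside the
#' simulator: drainage past a reference depth from the interval water balance
#' `D = P + I + dSW - AET` (assuming no surface runoff and negligible upward
#' flow), and nitrate leaching as the drainage-weighted sum of measured
#' nitrate concentrations.
#'
#' @name field_estimators
NULL

#' Drainage from the interval water balance
#'
#' `D = P + I + dSW - AET`, all in mm over the interval.  `dsw` is the change
#' in soil water storage above the reference depth, entered with the sign
#' convention that storage depletion (start minus end) adds to drainage.
#' A negative result violates the no-upward-flow assumption and is returned
#' as-is, flagged by the `"warning"` attribute.
#'
#' @param p precipitation, mm (>= 0).
#' @param i irrigation, mm (>= 0).
#' @param dsw soil water storage change, mm (start minus end).
#' @param aet actual evapotranspiration, mm (>= 0).
#' @return Drainage in mm (vectorised); attribute `"warning"` is a logical
#'   vector marking negative estimates.
#' @examples
#' drainage_water_balance(p = 100, i = 0, dsw = 0, aet = 40)  # 60 mm
#' @export
drainage_water_balance <- function(p, i = 0, dsw = 0, aet = 0) {
  stopifnot(is.finite(p), is.finite(i), is.finite(dsw), is.finite(aet))
  if (any(p < 0) || any(i < 0) || any(aet < 0))
    stop_domain("p, i and aet must be non-negative")
  d <- p + i + dsw - aet
  flag <- d < 0
  if (any(flag))
    warning("negative drainage estimate: upward water movement is not ",
            "negligible over this interval", call. = FALSE)
  structure(d, warning = flag)
}

#' Nitrate leaching from drainage and measured concentrations
#'
#' Sum over sampling intervals of drainage times nitrate concentration,
#' converted to kg N/ha (1 mm x 1 mg N/L = 0.01 kg N/ha).  Intervals with
#' negative drainage contribute zero (upward flow carries no leachate under
#' the estimator's assumptions) and are flagged.
#'
#' @param drainage per-interval drainage, mm.
#' @param conc per-interval nitrate concentration, mg N/L (>= 0).
#' @return Leaching in kg N/ha, with attribute `"clamped"` marking intervals
#'   whose negative drainage was zeroed.
#' @examples
#' nitrate_leaching_estimate(c(10, 20), c(10, 5))  # 2 kg N/ha
#' @export
nitrate_leaching_estimate <- function(drainage, conc) {
  if (length(drainage) != length(conc))
    stop_domain("drainage and concentration sequences differ in length (",
                length(drainage), " vs ", length(conc), ")")
  if (any(conc < 0)) stop_domain("concentrations must be >= 0")
  clamped <- drainage < 0
  d <- pmax(drainage, 0)
  structure(sum(d * conc) * MM_MGL_TO_KG_HA, clamped = clamped)
}
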