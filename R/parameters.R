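#' Parameter containers for the NCP maize-wheat simulation
#'
#' The packaged "NCP" parameter set bundles, for each experimental field, the
#' calibrated soil hydraulic horizons, the maize and winter wheat crop
#' parameterisations, the soil organic matter turnover network, atmospheric N
#' deposition, and the ammonia volatilisation scheme.  Every scalar carries a
#' provenance tag (measured / calibrated / literature / default) preserved
#' from the config files.
#'
#' @name parameters
NULL

## ---- validators -----------------------------------------------------------

validate_soil_horizon <- function(h, where = "horizon") {
  req <- c("depth_top", "depth_bottom", "Ksat", "theta_sat", "theta_res",
           "alpha", "n", "l", "humus", "SOM_fractions", "C_per_N", "clay")
  miss <- setdiff(req, names(h))
  if (length(miss))
    stop_domain(sprintf("%s: missing mandatory field(s): %s",
                        where, paste(miss, collapse = ", ")))
  with(h, {
    if (!(theta_res >= 0 && theta_res < theta_sat && theta_sat <= 1))
      stop_domain(sprintf(
        "%s: need 0 <= theta_res < theta_sat <= 1 (got %g, %g)",
        where, theta_res, theta_sat))
    if (n <= 1) stop_domain(sprintf("%s: van Genuchten n must be > 1 (got %g)",
                                    where, n))
    if (alpha <= 0) stop_domain(sprintf("%s: alpha must be > 0 (got %g)",
                                        where, alpha))
    if (Ksat <= 0) stop_domain(sprintf("%s: Ksat must be > 0 (got %g)",
                                       where, Ksat))
    if (depth_top >= depth_bottom)
      stop_domain(sprintf("%s: depth_top must be < depth_bottom", where))
    sf <- unlist(SOM_fractions)
    if (length(sf) != 3 || any(sf < 0) || abs(sum(sf) - 1) > 1e-9)
      stop_domain(sprintf(
        "%s: SOM_fractions must be 3 non-negative values summing to 1 (got %s, sum %.10g)",
        where, paste(sf, collapse = ", "), sum(sf)))
  })
  h$SOM_fractions <- as.numeric(unlist(h$SOM_fractions))
  h
}

validate_soil_profile <- function(p, where = "soil profile") {
  if (is.null(p$horizons) || !length(p$horizons))
    stop_domain(paste(where, ": no horizons defined"))
  p$horizons <- lapply(seq_along(p$horizons), function(i)
    validate_soil_horizon(p$horizons[[i]], sprintf("%s horizon %d", where, i)))
  tops <- vapply(p$horizons, `[[`, 0, "depth_top")
  bots <- vapply(p$horizons, `[[`, 0, "depth_bottom")
  if (tops[1] != 0 || any(tops[-1] != bots[-length(bots)]))
    stop_domain(paste(where, ": horizons must tile the profile from 0 cm",
                      "without gaps or overlaps"))
  p$bulk_density <- p$bulk_density %||% 1.4
  class(p) <- "soil_profile"
  p
}

validate_crop_params <- function(cp, where = "crop") {
  req <- c("name", "EmrTSum", "DSRate1", "DSRate2", "Fm", "QEff", "SpLAI",
           "E_Leaf", "E_Stem", "E_SOrg", "r_Leaf", "r_Stem", "r_SOrg",
           "MaxPen", "MxNH4Up", "MxNO3Up", "SpRtLength",
           "pet_factor_by_DS", "LeafAIMod_by_DS", "C_per_N_slow_residue",
           "partitioning_by_DS", "temp_response_dev", "n_conc_by_DS")
  miss <- setdiff(req, names(cp))
  if (length(miss))
    stop_domain(sprintf("%s: missing mandatory field(s): %s",
                        where, paste(miss, collapse = ", ")))
  rates <- c("EmrTSum", "DSRate1", "DSRate2", "Fm", "QEff", "SpLAI",
             "r_Leaf", "r_Stem", "r_SOrg", "MaxPen", "MxNH4Up", "MxNO3Up",
             "SpRtLength")
  for (f in rates)
    if (cp[[f]] < 0) stop_domain(sprintf("%s: %s must be >= 0 (got %g)",
                                         where, f, cp[[f]]))
  for (f in c("E_Leaf", "E_Stem", "E_SOrg"))
    if (cp[[f]] < 0 || cp[[f]] > 1)
      stop_domain(sprintf("%s: conversion efficiency %s outside [0,1]",
                          where, f))
  cp$partitioning_by_DS <- do.call(rbind, lapply(cp$partitioning_by_DS,
                                                 as.numeric))
  colnames(cp$partitioning_by_DS) <- c("DS", "root", "leaf", "stem", "sorg")
  sums <- rowSums(cp$partitioning_by_DS[, -1, drop = FALSE])
  if (any(abs(sums - 1) > 1e-9))
    stop_domain(sprintf("%s: partitioning fractions must sum to 1 at every DS",
                        where))
  for (f in c("pet_factor_by_DS", "LeafAIMod_by_DS", "temp_response_dev",
              "temp_response_phot"))
    if (!is.null(cp[[f]]))
      cp[[f]] <- do.call(rbind, lapply(cp[[f]], as.numeric))
  if (any(cp$LeafAIMod_by_DS[, 2] <= 0))
    stop_domain(sprintf("%s: LeafAIMod values must be > 0", where))
  cp$n_conc_by_DS <- lapply(cp$n_conc_by_DS, function(tb)
    do.call(rbind, lapply(tb, as.numeric)))
  cp$r_Root <- cp$r_Root %||% 0.010
  cp$root_penetration_rate <- cp$root_penetration_rate %||% 2.0
  class(cp) <- "crop_params"
  cp
}

validate_turnover_params <- function(tp, where = "turnover") {
  req <- c("pools", "pool_rate_coefficients", "flows", "smb_C_per_N",
           "water_factor", "MaxRootingDepth", "annual_C_input",
           "nonroot_input_depth")
  miss <- setdiff(req, names(tp))
  if (length(miss))
    stop_domain(sprintf("%s: missing mandatory field(s): %s",
                        where, paste(miss, collapse = ", ")))
  k <- unlist(tp$pool_rate_coefficients)
  if (any(k < 0)) stop_domain(paste(where, ": rate coefficients must be >= 0"))
  effs <- vapply(tp$flows, `[[`, 0, "efficiency")
  if (any(effs <= 0 | effs > 1))
    stop_domain(paste(where, ": substrate efficiencies must be in (0, 1]"))
  tp$water_factor <- do.call(rbind, lapply(tp$water_factor, as.numeric))
  if (any(tp$water_factor[, 2] < 0))
    stop_domain(paste(where, ": water_factor values must be >= 0"))
  tp$smb_init_fraction <- tp$smb_init_fraction %||% 0.02
  tp$c_in_humus <- tp$c_in_humus %||% 0.587
  tp$denit_potential_rate <- tp$denit_potential_rate %||% 0.1
  tp$nitrification_rate <- tp$nitrification_rate %||% 0.08
  tp$n2o_fraction_nitrification <- tp$n2o_fraction_nitrification %||% 0.02
  tp$dispersivity <- tp$dispersivity %||% 5
  tp$nh4_kd <- tp$nh4_kd %||% 0.4
  tp$molecular_diffusion <- tp$molecular_diffusion %||% 0.04
  class(tp) <- "turnover_params"
  tp
}

validate_volatilisation_scheme <- function(vs, where = "volatilisation") {
  if (is.null(vs$knots)) stop_domain(paste(where, ": missing field: knots"))
  kn <- do.call(rbind, lapply(vs$knots, as.numeric))
  if (any(diff(kn[, 1]) <= 0))
    stop_domain(paste(where, ": knot amounts must be strictly increasing"))
  if (any(kn[, 2] < 0 | kn[, 2] > 1) || any(diff(kn[, 2]) < 0))
    stop_domain(paste(where, ": fractions must be in [0,1], non-decreasing"))
  vs$knots <- kn
  class(vs) <- "volatilisation_scheme"
  vs
}

validate_deposition_config <- function(dc, where = "deposition") {
  req <- c("wet_nh4", "dry_nh4", "wet_no3", "dry_no3")
  miss <- setdiff(req, names(dc))
  if (length(miss))
    stop_domain(sprintf("%s: missing mandatory field(s): %s",
                        where, paste(miss, collapse = ", ")))
  for (f in req)
    if (dc[[f]] < 0) stop_domain(sprintf("%s: %s must be >= 0", where, f))
  class(dc) <- "deposition_config"
  dc
}

## ---- readers / writers ----------------------------------------------------

read_component <- function(path, validator, where) {
  if (!file.exists(path)) stop_domain("configuration file not found: ", path)
  x <- yaml::yaml.load_file(path)
  prov <- x$provenance
  x$provenance <- NULL
  out <- validator(x, where)
  attr(out, "provenance") <- prov
  out
}

#' Load a full parameter set from a config directory
#'
#' The directory must contain `*.soil.yaml` (one per field), `*.crop.yaml`
#' (one per crop), `turnover.yaml`, `deposition.yaml` and
#' `volatilisation.yaml`, in the schema of the packaged files under
#' `system.file("extdata", "ncp", package = "cropnsim")`.  Every field is
#' validated against its type invariants; provenance tags are kept as the
#' `"provenance"` attribute of each component.
#'
#' @param path directory holding the config files.
#' @return An object of class `svat_params`: a list with elements `soils`
#'   (named by field), `crops` (named by crop), `turnover`, `deposition`,
#'   `volatilisation`.
#' @seealso [default_ncp_parameters()], [write_parameter_set()]
#' @export
load_parameter_set <- function(path) {
  if (!dir.exists(path)) stop_domain("parameter directory not found: ", path)
  soil_files <- list.files(path, "\\.soil\\.yaml$", full.names = TRUE)
  crop_files <- list.files(path, "\\.crop\\.yaml$", full.names = TRUE)
  if (!length(soil_files)) stop_domain("no *.soil.yaml files in ", path)
  if (!length(crop_files)) stop_domain("no *.crop.yaml files in ", path)
  soils <- lapply(soil_files, read_component, validate_soil_profile, "soil")
  names(soils) <- vapply(soils, function(s) as.character(s$field), "")
  crops <- lapply(crop_files, read_component, validate_crop_params, "crop")
  names(crops) <- vapply(crops, `[[`, "", "name")
  ps <- list(
    soils = soils,
    crops = crops,
    turnover = read_component(file.path(path, "turnover.yaml"),
                              validate_turnover_params, "turnover"),
    deposition = read_component(file.path(path, "deposition.yaml"),
                                validate_deposition_config, "deposition"),
    volatilisation = read_component(file.path(path, "volatilisation.yaml"),
                                    validate_volatilisation_scheme,
                                    "volatilisation"))
  class(ps) <- "svat_params"
  ps
}

strip_for_yaml <- function(x) {
  x <- unclass(x)
  rapply(x, function(v) {
    if (is.matrix(v)) return(lapply(seq_len(nrow(v)), function(i)
      as.numeric(v[i, ])))
    v
  }, classes = "ANY", how = "replace")
}

component_to_yamlable <- function(comp) {
  prov <- attr(comp, "provenance")
  attr(comp, "provenance") <- NULL
  out <- unclass(comp)
  # matrices back to row lists for YAML round-tripping
  out <- lapply(out, function(v) {
    if (is.matrix(v)) {
      dimnames(v) <- NULL
      lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
    } else if (is.list(v) && all(vapply(v, is.matrix, TRUE))) {
      lapply(v, function(m) lapply(seq_len(nrow(m)), function(i)
        as.numeric(m[i, ])))
    } else v
  })
  if (!is.null(prov)) out$provenance <- prov
  out
}

#' Write a parameter set back to a config directory
#'
#' Inverse of [load_parameter_set()]: `load_parameter_set(write_parameter_set(ps, d))`
#' reproduces every field.
#'
#' @param params an `svat_params` object.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(params$soils))
    yaml::write_yaml(component_to_yamlable(params$soils[[nm]]),
                     file.path(path, sprintf("field_%s.soil.yaml", nm)))
  for (nm in names(params$crops))
    yaml::write_yaml(component_to_yamlable(params$crops[[nm]]),
                     file.path(path, sprintf("%s.crop.yaml", nm)))
  yaml::write_yaml(component_to_yamlable(params$turnover),
                   file.path(path, "turnover.yaml"))
  yaml::write_yaml(component_to_yamlable(params$deposition),
                   file.path(path, "deposition.yaml"))
  yaml::write_yaml(component_to_yamlable(params$volatilisation),
                   file.path(path, "volatilisation.yaml"))
  invisible(path)
}

#' The packaged North China Plain parameter set
#'
#' Returns the calibrated maize - winter wheat parameter set for the Luancheng
#' fields: soil hydraulic and organic-matter horizons for fields A and B, the
#' "Pioneer maize" and "Winter wheat" crop parameterisations, the turnover
#' network, atmospheric deposition and the ammonia volatilisation scheme.
#' Identical to loading the shipped config files.
#'
#' @return An `svat_params` object (see [load_parameter_set()]).
#' @examples
#' ps <- default_ncp_parameters()
#' ps$crops$wheat$MaxPen      # 210 cm
#' ps$turnover$smb_C_per_N   # 4.8
#' @export
default_ncp_parameters <- function() {
  load_parameter_set(system.file("extdata", "ncp", package = "cropnsim",
                                 mustWork = TRUE))
}

#' Export a parameter set as JSON (for provenance records)
#'
#' @param params an `svat_params` object.
#' @param path optional file to write to.
#' @return JSON string, invisibly if `path` is given.
#' @export
parameter_set_json <- function(params, path = NULL) {
  payload <- list(
    soils = lapply(params$soils, component_to_yamlable),
    crops = lapply(params$crops, component_to_yamlable),
    turnover = component_to_yamlable(params$turnover),
    deposition = component_to_yamlable(params$deposition),
    volatilisation = component_to_yamlable(params$volatilisation))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Ammonia volatilisation fraction for a fertiliser dressing
#'
#' Fraction of an ammonium/urea dressing lost as ammonia, as a function of the
#' applied amount.  Exact at the calibrated set points (5, 10, 12, 15, 17
#' percent at 50, 100, 150, 200, 300 kg N/ha), piecewise linear between them,
#' linear from (0, 0) below the first point, and constant above the last.
#'
#' @param applied_n applied amount, kg N/ha (vectorised, must be >= 0).
#' @param scheme a `volatilisation_scheme`; defaults to the packaged NCP one.
#' @return Fraction(s) lost in `[0, 1]`.
#' @examples
#' volatilisation_fraction(150)  # 0.12
#' @export
volatilisation_fraction <- function(applied_n,
                                    scheme = default_ncp_parameters()$volatilisation) {
  if (any(applied_n < 0))
    stop_domain("applied_n must be >= 0 (got ", min(applied_n), ")")
  kn <- rbind(c(0, 0), scheme$knots)
  interp_table(applied_n, kn)
}

#' @export
print.svat_params <- function(x, ...) {
  cat("<svat_params> NCP-style parameter set\n")
  cat("  soils:", paste(names(x$soils), collapse = ", "), "\n")
  cat("  crops:", paste(names(x$crops), collapse = ", "), "\n")
  cat("  turnover pools:", paste(x$turnover$pools, collapse = ", "), "\n")
  invisible(x)
}
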