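#' @keywords internal
#' @useDynLib cropnsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Piecewise-linear interpolation through a two-column knot matrix (strictly
# increasing x), with constant extrapolation outside the knot range.  Hand
# rolled: stats::approx's ties handling is too slow for per-day calls in the
# simulation loop.
interp_table <- function(x, knots) {
  knots <- as.matrix(knots)
  kx <- knots[, 1]
  ky <- knots[, 2]
  nk <- length(kx)
  if (nk == 1) return(rep(ky, length(x)))
  xi <- pmin.int(pmax.int(x, kx[1]), kx[nk])
  i <- findInterval(xi, kx, rightmost.closed = TRUE, all.inside = TRUE)
  ky[i] + (ky[i + 1] - ky[i]) * (xi - kx[i]) / (kx[i + 1] - kx[i])
}

# Evaluate a function body under a fixed RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# kg N/ha  <->  g N/m2
KG_HA_PER_G_M2 <- 10

# mm water x mg/L  ->  kg/ha
MM_MGL_TO_KG_HA <- 0.01
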