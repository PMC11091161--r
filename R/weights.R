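#' Radial weight function
#'
#' The LoCoHD score averages Hellinger distances over radii using a weight
#' density w(r) on (0, Inf) integrating to 1; only its cumulative form W(r)
#' enters the closed-form score. Only the uniform family ships: w constant
#' on \[lower, upper\], i.e. W(r) = clamp((r - lower)/(upper - lower), 0, 1).
#' The published analyses all use uniform(3, 10) angstroms.
#'
#' @param kind weight family; only `"uniform"` is available.
#' @param lower,upper support bounds in angstroms, `0 <= lower < upper`.
#' @return a `locohd_weight` object with fields `kind`, `lower`, `upper`,
#'   `cumulative` (the function W), and `density`.
#' @examples
#' w <- uniform_weight(3, 10)
#' w$cumulative(c(0, 3, 6.5, 10, 99))  # 0 0 .5 1 1
#' @export
uniform_weight <- function(lower = 3, upper = 10, kind = "uniform") {
  if (!identical(kind, "uniform")) {
    stop_config("unknown weight kind '%s' (only 'uniform' ships)", kind)
  }
  if (!(is.finite(lower) && is.finite(upper) && lower >= 0 && upper > lower)) {
    stop_config("uniform weight needs 0 <= lower < upper (got %s, %s)",
                lower, upper)
  }
  structure(list(
    kind = "uniform", lower = lower, upper = upper,
    cumulative = function(r) pmin(pmax((r - lower) / (upper - lower), 0), 1),
    density = function(r) ifelse(r >= lower & r <= upper, 1 / (upper - lower), 0)
  ), class = "locohd_weight")
}

# W(r) with W(Inf) = 1, vectorized
weight_cdf <- function(weight, r) {
  out <- weight$cumulative(r)
  out[is.infinite(r)] <- 1
  out
}
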