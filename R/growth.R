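#' Chapman-Richards growth curve
#'
#' S-shaped stand-level carbon accumulation curve used for all forest pools.
#' Carbon density at stand age `a` is `A * (1 - exp(-k * a))^b`: zero at
#' establishment, sigmoidal when `b > 1`, saturating at the asymptote `A`.
#'
#' @param A asymptotic vegetation carbon density (tC/ha), `> 0`.
#' @param k rate parameter (1/yr), `> 0`.
#' @param b shape parameter (dimensionless), `>= 1`.
#' @return an object of class `growth_curve`.
#' @examples
#' gc <- growth_curve(A = 100, k = 0.05, b = 2)
#' stand_density(20, gc)
#' @export
growth_curve <- function(A, k, b = 2) {
  if (!is.finite(A) || A <= 0) stop_invalid("growth_curve: A must be > 0")
  if (!is.finite(k) || k <= 0) stop_invalid("growth_curve: k must be > 0")
  if (!is.finite(b) || b < 1) stop_invalid("growth_curve: b must be >= 1")
  structure(list(A = A, k = k, b = b), class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Chapman-Richards growth curve: A = %.6g tC/ha, k = %.6g /yr, b = %.6g\n",
              x$A, x$k, x$b))
  invisible(x)
}

#' Stand carbon density at a given age
#'
#' @param age stand age in years (vectorised), `>= 0`.
#' @param curve a [growth_curve()].
#' @return carbon density (tC/ha).
#' @export
stand_density <- function(age, curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(age < 0)) stop_invalid("stand_density: age must be >= 0")
  curve$A * (1 - exp(-curve$k * age))^curve$b
}

#' Rotation length of a plantation
#'
#' Returns the harvest age on a 5-year age-class grid. Under the default
#' `"CAI"` rule the rotation is the age class with the largest current annual
#' increment, i.e. the class maximising `density(a) - density(a - 5)`; under
#' `"MAI"` it is the class maximising the mean annual increment
#' `density(a) / a` (the culmination of MAI, the classical forestry rule,
#' which yields longer rotations). Ties break toward the smaller age.
#'
#' @param curve a [growth_curve()].
#' @param rule `"CAI"` (default) or `"MAI"`.
#' @param age_grid ages considered (years, 5-year steps covering at least
#'   5..150).
#' @return rotation age in years (an element of `age_grid`).
#' @examples
#' rotation_length(growth_curve(100, 0.05, 2)) # 15
#' @export
rotation_length <- function(curve, rule = c("CAI", "MAI"),
                            age_grid = seq(5, 150, by = 5)) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "growth_curve"))
  dens <- stand_density(age_grid, curve)
  if (any(diff(dens) < -1e-9 * curve$A))
    stop_invalid("rotation_length: growth curve is not non-decreasing")
  crit <- switch(rule,
    CAI = dens - stand_density(age_grid - 5, curve),
    MAI = dens / age_grid)
  ## which.max returns the first maximum: ties already resolve to smaller age
  age_grid[which.max(crit)]
}
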