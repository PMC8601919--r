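#' Bill surface area from caliper measurements
#'
#' The bill is approximated by an elliptical cone with basal semi-axes
#' `BW/2` and `BD/2` and slant length `BL`; its lateral surface is
#' `pi * BL * (BW + BD) / 4`.
#'
#' @param BW,BD,BL bill width, depth and length, mm.
#' @return surface area, mm^2.
#' @export
bill_surface_area <- function(BW, BD, BL) {
  if (any(c(BW, BD, BL) < 0)) stop("measurements must be >= 0", call. = FALSE)
  pi * BL * (BW + BD) / 4
}

#' Tarsi surface area from caliper measurements
#'
#' Each tarsus is an elliptical cylinder with semi-axes `TW/2`, `TD/2`
#' (measured at the midpoint of the tarsus) and length `TL`.  The
#' perimeter uses the standard elliptic approximation
#' `P = pi * sqrt(2 * ((TW/2)^2 + (TD/2)^2) - ((TW - TD)/2)^2 / 2)`,
#' exact for a circular cross-section; the area is `P * TL * 2` (both
#' legs).
#'
#' @param TW,TD,TL tarsus width, depth and length, mm.
#' @return combined surface area of both tarsi, mm^2.
#' @export
tarsi_surface_area <- function(TW, TD, TL) {
  if (any(c(TW, TD, TL) < 0)) stop("measurements must be >= 0", call. = FALSE)
  p <- pi * sqrt(2 * ((TW / 2)^2 + (TD / 2)^2) - 0.5 * ((TW - TD) / 2)^2)
  p * TL * 2
}

#' Whole-body surface area from body mass
#'
#' Meeh-type allometry `A = 10 * Mb^0.667` (cm^2, Mb in g), the standard
#' avian body surface scaling.
#'
#' @param Mb body mass, g.
#' @return surface area, cm^2.
#' @export
whole_body_surface_area <- function(Mb) {
  stop_if_not_positive(Mb, "Mb")
  10 * Mb^0.667
}

#' Sex-stratified relative appendage size index
#'
#' Within each sex, ordinary least squares of `log(area)` on `log(wing)`
#' (natural logarithms); the index is the residual, so it measures
#' appendage area relative to structural body size, free of the sexual
#' size dimorphism.  Within-sex indices sum to zero by construction.
#'
#' @param area appendage surface areas, mm^2.
#' @param wing wing lengths, mm (body-size proxy).
#' @param sex factor/character vector of sexes.
#' @return numeric vector of residual indices, aligned with the input.
#' @export
size_index <- function(area, wing, sex) {
  stop_if_not_positive(area, "area")
  stop_if_not_positive(wing, "wing")
  idx <- numeric(length(area))
  for (s in unique(sex)) {
    sel <- sex == s
    if (sum(sel) < 3) {
      stop(sprintf("fewer than 3 individuals of sex '%s'", s), call. = FALSE)
    }
    fit <- lm(log(area[sel]) ~ log(wing[sel]))
    idx[sel] <- residuals(fit)
  }
  idx
}

#' Mass-independent physiological values
#'
#' Residuals of `log(value)` on `log(Mb)` across all individuals (sexes
#' pooled) at a given test temperature; removes the allometric mass
#' dependence of a rate.
#'
#' @param values physiological rates (positive).
#' @param Mb body masses, g.
#' @return numeric vector of residuals (sum to zero).
#' @export
mass_independent <- function(values, Mb) {
  stop_if_not_positive(values, "values")
  stop_if_not_positive(Mb, "Mb")
  if (length(values) < 3) stop("need at least 3 individuals", call. = FALSE)
  residuals(lm(log(values) ~ log(Mb)))
}
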