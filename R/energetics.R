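#' Metabolic heat production from oxygen consumption
#'
#' Uses the energy equivalent 20 kJ per litre O2 (20 J ml^-1):
#' `MHP = VO2 * 20 / 60` watts, so 1 ml O2 min^-1 is exactly 1/3 W.
#'
#' @param VO2 oxygen consumption, ml min^-1.
#' @return metabolic heat production, W.
#' @export
mhp_from_vo2 <- function(VO2) {
  if (any(VO2 < 0)) stop("VO2 must be non-negative", call. = FALSE)
  VO2 * 20 / 60
}

#' Latent heat of vaporization of water
#'
#' Linear approximation `lambda(T) = 2501 - 2.361 * T` J g^-1, accurate
#' to well under 0.2% across the physiological range.
#'
#' @param T water/chamber temperature, degrees C, in \[0, 50\].
#' @return latent heat, J g^-1.
#' @export
latent_heat <- function(T) {
  if (any(T < 0 | T > 50)) {
    stop("temperature outside the supported range [0, 50]", call. = FALSE)
  }
  2501 - 2.361 * T
}

#' Evaporative heat loss from a water-loss rate
#'
#' `EHL = EWL (mg h^-1) * 1e-3 / 3600 * lambda(T)` watts, with the latent
#' heat evaluated at the chamber temperature.
#'
#' @param EWL evaporative water loss, mg h^-1.
#' @param T chamber temperature, degrees C.
#' @return evaporative heat loss, W.
#' @export
ehl_from_ewl <- function(EWL, T) {
  if (any(EWL < 0)) stop("EWL must be non-negative", call. = FALSE)
  EWL * 1e-3 / 3600 * latent_heat(T)
}

#' Evaporative cooling efficiency
#'
#' The ratio of evaporative heat loss to metabolic heat production;
#' values near or above 1 mean evaporation can offset all metabolic heat.
#' Computed at chamber temperatures above the upper critical temperature.
#'
#' @param EHL evaporative heat loss, W.
#' @param MHP metabolic heat production, W (> 0).
#' @return dimensionless ratio.
#' @export
cooling_efficiency <- function(EHL, MHP) {
  if (any(MHP <= 0)) stop("MHP must be positive", call. = FALSE)
  EHL / MHP
}

#' Energy budget table for a set of steady-state measurements
#'
#' @param profiles data frame with columns `id`, `Ta`, `VO2`, `EWL`.
#' @param hot_temps temperatures at which the budget is evaluated
#'   (those above the upper critical temperature).
#' @return data frame `id`, `Ta`, `MHP`, `EHL`, `ratio`.
#' @export
energy_budget <- function(profiles, hot_temps = c(35, 37, 40)) {
  sel <- profiles$Ta %in% hot_temps
  pr <- profiles[sel, ]
  mhp <- mhp_from_vo2(pr$VO2)
  ehl <- ehl_from_ewl(pr$EWL, pr$Ta)
  data.frame(id = pr$id, Ta = pr$Ta, MHP = mhp, EHL = ehl,
             ratio = cooling_efficiency(ehl, mhp),
             stringsAsFactors = FALSE)
}
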