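#' Biomass from catch and fishing mortality
#'
#' Steady-state stock size implied by the catch equation: `B = Y / F`.
#' Units follow the inputs (catch in t/yr gives biomass in t; divide by
#' lake area for densities, see [convert_landings()]).
#'
#' @param catch annual catch `Y` (t/yr).
#' @param f fishing mortality (/yr, > 0).
#' @return biomass in tonnes.
#' @export
biomass_from_catch <- function(catch, f) {
  if (any(f <= 0)) stop("fishing mortality must be positive")
  catch / f
}

#' Total mortality from its components
#'
#' Under steady state the production rate P/B of an exploited stock
#' equals total mortality `Z = M + F`.
#'
#' @param m natural mortality (/yr).
#' @param f fishing mortality (/yr).
#' @return total mortality (/yr).
#' @export
z_from_mf <- function(m, f) {
  if (any(m < 0) || any(f < 0)) stop("mortalities must be non-negative")
  m + f
}

#' Production rate from mean length (Beverton-Holt)
#'
#' The length-based total-mortality estimator
#' `Z = K (Linf - Lavg) / (Lavg - Lc)`, usable as P/B under steady state.
#'
#' @param k von Bertalanffy growth coefficient (/yr).
#' @param linf asymptotic length (cm).
#' @param lavg mean length in the catch (cm).
#' @param lc mean length at first capture (cm); must satisfy
#'   `linf > lavg > lc`.
#' @return Z = P/B (/yr).
#' @export
pb_beverton_holt <- function(k, linf, lavg, lc) {
  if (any(lavg <= lc)) stop("mean length must exceed length at first capture")
  if (any(linf <= lavg)) stop("asymptotic length must exceed mean length")
  k * (linf - lavg) / (lavg - lc)
}

#' Consumption rate from the Palomares-Pauly relation
#'
#' Empirical consumption/biomass estimator for fish:
#' `log10(Q/B) = 7.964 - 0.204 log10(Winf) - 1.965 T' + 0.083 A
#'  + 0.532 h + 0.398 d`,
#' with `T' = 1000 / (Tc + 273.1)` the inverse-Kelvin temperature term,
#' `A` the caudal-fin aspect ratio, and feeding-type dummies
#' (carnivore `h = d = 0`, herbivore `h = 1`, detritivore `d = 1`).
#' All logarithms are base 10, as in the source regression.
#'
#' @param winf asymptotic weight (g).
#' @param tc water temperature (deg C).
#' @param aspect_ratio caudal-fin aspect ratio `A = h^2 / s` (height
#'   squared over fin surface area); see [caudal_aspect_ratio()].
#' @param feeding one of `"carnivore"`, `"herbivore"`, `"detritivore"`.
#' @return Q/B (/yr).
#' @export
qb_palomares_pauly <- function(winf, tc, aspect_ratio,
                               feeding = c("carnivore", "herbivore",
                                           "detritivore")) {
  feeding <- match.arg(feeding)
  if (any(winf <= 0)) stop("asymptotic weight must be positive")
  if (any(aspect_ratio < 0)) stop("aspect ratio must be non-negative")
  h <- as.numeric(feeding == "herbivore")
  d <- as.numeric(feeding == "detritivore")
  tprime <- 1000 / (tc + 273.1)
  10^(7.964 - 0.204 * log10(winf) - 1.965 * tprime +
        0.083 * aspect_ratio + 0.532 * h + 0.398 * d)
}

#' Caudal-fin aspect ratio
#'
#' `A = h^2 / s` with `h` the fin height and `s` its surface area; a
#' proxy for sustained swimming activity and hence metabolic rate.
#'
#' @param height caudal-fin height (cm).
#' @param surface caudal-fin surface area (cm2).
#' @return dimensionless aspect ratio.
#' @export
caudal_aspect_ratio <- function(height, surface) {
  if (any(surface <= 0)) stop("fin surface area must be positive")
  height^2 / surface
}

#' Euphotic depth from Secchi depth
#'
#' `E = 2.5 * SD` (metres).
#'
#' @param secchi_m Secchi-disc depth (m).
#' @return euphotic depth (m).
#' @export
euphotic_depth <- function(secchi_m) {
  if (any(secchi_m <= 0)) stop("Secchi depth must be positive")
  2.5 * secchi_m
}

#' Detritus standing stock from primary production
#'
#' Empirical detritus-biomass relation
#' `log10(D) = 0.954 log10(PP) + 0.863 log10(E) - 2.41`, with `D` in
#' g C/m2, `PP` the primary production (g C/m2) and `E` the euphotic
#' depth (m), here derived from Secchi depth via [euphotic_depth()].
#'
#' @param pp primary production (g C/m2/yr).
#' @param secchi_m Secchi depth (m); alternatively pass `euphotic_m`.
#' @param euphotic_m euphotic depth (m), overrides `secchi_m`.
#' @return detritus biomass (g C/m2).
#' @export
detritus_biomass <- function(pp, secchi_m = NULL, euphotic_m = NULL) {
  if (is.null(euphotic_m)) {
    if (is.null(secchi_m)) stop("supply secchi_m or euphotic_m")
    euphotic_m <- euphotic_depth(secchi_m)
  }
  if (any(pp <= 0) || any(euphotic_m <= 0))
    stop("inputs must be positive")
  10^(0.954 * log10(pp) + 0.863 * log10(euphotic_m) - 2.41)
}
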