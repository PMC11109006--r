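#' Total-internal-reflection geometry checks
#'
#' Utilities to validate a TIRF dish/illumination configuration. Total
#' internal reflection at an interface requires the incidence angle to exceed
#' the critical angle `asin(n_transmitted / n_incident)`; the usable incidence
#' range is bounded above by the objective's aperture limit
#' `asin(NA / n_incident)`. All angles are returned in degrees.
#'
#' @param n_transmitted Refractive index on the sample (lower-index) side.
#' @param n_incident Refractive index on the glass (incident) side.
#' @return Angle in degrees.
#' @examples
#' critical_angle(1.34, 1.52)      # fluoropolymer layer / glass: 61.8
#' aperture_limit_angle(1.49, 1.52) # NA 1.49 oil objective: 78.6
#' @export
critical_angle <- function(n_transmitted, n_incident) {
  if (any(n_transmitted <= 0) || any(n_incident <= 0)) {
    abort("refractive indices must be positive")
  }
  if (any(n_transmitted > n_incident)) {
    abort("n_transmitted > n_incident: no total internal reflection at this interface")
  }
  asin(n_transmitted / n_incident) * 180 / pi
}

#' @rdname critical_angle
#' @param numerical_aperture Numerical aperture of the objective; must be
#'   smaller than `n_incident`.
#' @export
aperture_limit_angle <- function(numerical_aperture, n_incident) {
  if (any(numerical_aperture < 0)) abort("numerical aperture must be >= 0")
  if (any(numerical_aperture >= n_incident)) {
    abort("NA >= n_incident: aperture angle undefined")
  }
  asin(numerical_aperture / n_incident) * 180 / pi
}

#' Validate a TIRF dish configuration
#'
#' Computes the critical angles of each interface in a dish configuration and
#' the objective aperture limit, and checks that a usable incidence window
#' exists (critical angle of the well-material interface below the aperture
#' limit).
#'
#' @param n_glass Refractive index of the coverglass (default 1.52).
#' @param n_well_material Index of the microstructure material in contact with
#'   the glass (e.g. 1.34 for an amorphous fluoropolymer layer, 1.40 for
#'   PDMS).
#' @param n_sample Index of the aqueous sample (default 1.33).
#' @param numerical_aperture Objective NA (default 1.49).
#' @return A tibble with one row per quantity: `quantity`, `angle_deg`
#'   (rounded to 0.1 degree), `ok`.
#' @export
check_optics <- function(n_glass = 1.52, n_well_material = 1.34,
                         n_sample = 1.33, numerical_aperture = 1.49) {
  well_crit <- critical_angle(n_well_material, n_glass)
  sample_crit <- critical_angle(n_sample, n_glass)
  ap <- aperture_limit_angle(numerical_aperture, n_glass)
  tibble::tibble(
    quantity = c("critical_angle_well_material",
                 "critical_angle_sample",
                 "aperture_limit"),
    angle_deg = round(c(well_crit, sample_crit, ap), 1),
    ok = c(well_crit < ap, sample_crit < ap, TRUE)
  )
}
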