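#' Erythrocyte density implied by the volume-weighted mixing law
#'
#' The mixture density is the volume-weighted mean of the erythrocyte and
#' saline phases, `rho = X_e rho_e + (1 - X_e) rho_s`. Inverting at the
#' whole-blood composition gives the erythrocyte phase density.
#'
#' @param blood_density Whole-blood density (kg/m^3).
#' @param saline_density Normal-saline density (kg/m^3).
#' @param haematocrit Erythrocyte volume fraction of the whole blood, in
#'   (0, 1].
#' @return Erythrocyte density (kg/m^3). At the defaults (1056, 1000, 0.45)
#'   this is 1124.4 kg/m^3.
#' @export
#' @examples
#' erythrocyte_density(1056, 1000, 0.45)
erythrocyte_density <- function(blood_density = 1056, saline_density = 1000,
                                haematocrit = 0.45) {
  if (any(haematocrit <= 0) || any(haematocrit > 1)) {
    abort("undefined-density error: haematocrit must lie in (0, 1]",
      class = "ivoct_domain_error")
  }
  (blood_density - (1 - haematocrit) * saline_density) / haematocrit
}

#' Mixture viscosity (Einstein suspension law)
#'
#' `mu = mu_p (1 + 2.5 X_e)`: a dilute-suspension viscosity linear in the
#' haematocrit, with the plasma viscosity identified with that of normal
#' saline.
#'
#' @param haematocrit Erythrocyte volume fraction, vectorized, in \[0, 1\].
#' @param plasma_viscosity Plasma/saline viscosity (Pa s).
#' @return Mixture viscosity (Pa s).
#' @export
mixture_viscosity <- function(haematocrit, plasma_viscosity = 9.0e-4) {
  if (any(haematocrit < 0) || any(haematocrit > 1)) {
    abort("domain error: haematocrit must lie in [0, 1]", class = "ivoct_domain_error")
  }
  plasma_viscosity * (1 + 2.5 * haematocrit)
}

#' Mixture density from haematocrit
#'
#' Volume-weighted mixing of the erythrocyte and saline phases.
#'
#' @param haematocrit Erythrocyte volume fraction, vectorized.
#' @param erythrocyte_dens,saline_density Phase densities (kg/m^3).
#' @return Mixture density (kg/m^3).
#' @export
mixture_density <- function(haematocrit, erythrocyte_dens = erythrocyte_density(),
                            saline_density = 1000) {
  if (any(haematocrit < 0) || any(haematocrit > 1)) {
    abort("domain error: haematocrit must lie in [0, 1]", class = "ivoct_domain_error")
  }
  haematocrit * erythrocyte_dens + (1 - haematocrit) * saline_density
}

#' Haematocrit to erythrocyte mass fraction, and back
#'
#' `w_e = X_e rho_e / rho` with the volume-weighted mixture density; at
#' `X_e = 0.45` this gives the whole-blood erythrocyte mass fraction 0.479.
#' `haematocrit_from_mass_fraction()` is the exact algebraic inverse.
#'
#' @param haematocrit Erythrocyte volume fraction, vectorized, in \[0, 1\].
#' @param mass_fraction Erythrocyte mass fraction, vectorized, in \[0, 1\].
#' @param erythrocyte_dens,saline_density Phase densities (kg/m^3).
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' mass_fraction_from_haematocrit(0.45)
mass_fraction_from_haematocrit <- function(haematocrit,
                                           erythrocyte_dens = erythrocyte_density(),
                                           saline_density = 1000) {
  rho <- mixture_density(haematocrit, erythrocyte_dens, saline_density)
  haematocrit * erythrocyte_dens / rho
}

#' @rdname mass_fraction_from_haematocrit
#' @export
haematocrit_from_mass_fraction <- function(mass_fraction,
                                           erythrocyte_dens = erythrocyte_density(),
                                           saline_density = 1000) {
  if (any(mass_fraction < 0) || any(mass_fraction > 1)) {
    abort("domain error: mass fraction must lie in [0, 1]", class = "ivoct_domain_error")
  }
  mass_fraction * saline_density /
    ((1 - mass_fraction) * erythrocyte_dens + mass_fraction * saline_density)
}

#' Equivalent-volume diameter of a red blood cell
#'
#' Diameter of the sphere with the same volume as the (biconcave) cell:
#' `d_e = (6 V / pi)^(1/3)`.
#'
#' @param volume Cell volume in micrometre^3 (90 for an RBC).
#' @return Diameter in metres.
#' @export
rbc_equivalent_diameter <- function(volume = 90) {
  if (any(volume <= 0)) {
    abort("domain error: volume must be positive", class = "ivoct_domain_error")
  }
  (6 * volume / pi)^(1 / 3) * 1e-6
}

#' Stokes-Einstein diffusivity of erythrocytes in the mixture
#'
#' `D = k T / (3 pi d_e mu)` with the equivalent-volume RBC diameter and the
#' haematocrit-dependent mixture viscosity of [mixture_viscosity()]. With the
#' calibrated defaults (T = 310 K, plasma viscosity 0.9 mPa s) this evaluates
#' to 4.27e-14 m^2/s in whole blood and 9.08e-14 m^2/s in pure saline.
#'
#' @param haematocrit Erythrocyte volume fraction, vectorized.
#' @param temperature Absolute temperature (K).
#' @param plasma_viscosity Plasma/saline viscosity (Pa s).
#' @param rbc_volume RBC volume (micrometre^3).
#' @param boltzmann_k Boltzmann constant (J/K).
#' @return Diffusion coefficient (m^2/s).
#' @export
#' @examples
#' diffusion_coefficient(0.45)
#' diffusion_coefficient(0)
diffusion_coefficient <- function(haematocrit, temperature = 310,
                                  plasma_viscosity = 9.0e-4, rbc_volume = 90,
                                  boltzmann_k = 1.380649e-23) {
  if (any(temperature <= 0)) {
    abort("domain error: temperature must be positive", class = "ivoct_domain_error")
  }
  mu <- mixture_viscosity(haematocrit, plasma_viscosity)
  if (any(mu <= 0)) {
    abort("domain error: viscosity must be positive", class = "ivoct_domain_error")
  }
  d_e <- rbc_equivalent_diameter(rbc_volume)
  boltzmann_k * temperature / (3 * pi * d_e * mu)
}

#' Mixture properties table
#'
#' Evaluates all closed-form mixture laws on a vector of haematocrits and
#' returns them as one tibble row per value; convenient for plotting the
#' property laws and for coupling checks.
#'
#' @param haematocrit Vector of erythrocyte volume fractions.
#' @param constants A [physical_constants()] object.
#' @return A tibble with columns `haematocrit`, `mass_fraction`, `density`,
#'   `viscosity`, `diffusivity`.
#' @export
mixture_properties <- function(haematocrit, constants = physical_constants()) {
  rho_e <- erythrocyte_density(constants$whole_blood_density,
    constants$saline_density, constants$whole_blood_haematocrit)
  tibble(
    haematocrit = haematocrit,
    mass_fraction = mass_fraction_from_haematocrit(haematocrit, rho_e,
      constants$saline_density),
    density = mixture_density(haematocrit, rho_e, constants$saline_density),
    viscosity = mixture_viscosity(haematocrit, constants$plasma_viscosity),
    diffusivity = diffusion_coefficient(haematocrit,
      constants$body_temperature_T, constants$plasma_viscosity,
      constants$rbc_volume, constants$boltzmann_k)
  )
}
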