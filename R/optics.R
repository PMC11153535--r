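#' Optical coefficients of the lumen fluid
#'
#' Haematocrit-dependent coefficients of the blood/saline mixture at 1300 nm.
#' Absorption scales linearly with haematocrit from the whole-blood value;
#' scattering carries an additional `(1 - X_e)/(1 - 0.45)` shielding factor,
#' and the anisotropy is constant:
#' `phi_a = (X_e/0.45) * 0.19`,
#' `phi_s = ((1 - X_e)/0.55) * (X_e/0.45) * 45.36`, `delta = 0.9779`,
#' with the collimated-beam attenuation `phi_t = phi_a + phi_s (1 - delta)`.
#' The backscatter coefficient is `phi_b = alpha * phi_t` with `alpha = 1`.
#' At `X_e = 0.45` the attenuation is 1.1925 /mm; at `X_e = 0` the saline is
#' transparent.
#'
#' @param haematocrit Erythrocyte volume fraction, vectorized, in \[0, 1\].
#' @param alpha Backscattered fraction of the attenuated light.
#' @return A tibble with columns `phi_a`, `phi_s`, `delta`, `phi_t`, `phi_b`
#'   (all /mm except `delta`).
#' @export
#' @examples
#' fluid_coefficients(c(0, 0.225, 0.45))
fluid_coefficients <- function(haematocrit, alpha = 1) {
  if (any(haematocrit < 0) || any(haematocrit > 1)) {
    abort("domain error: haematocrit must lie in [0, 1]", class = "ivoct_domain_error")
  }
  phi_a <- haematocrit / 0.45 * 0.19
  phi_s <- (1 - haematocrit) / 0.55 * haematocrit / 0.45 * 45.36
  delta <- 0.9779
  phi_t <- phi_a + phi_s * (1 - delta)
  tibble(phi_a = phi_a, phi_s = phi_s, delta = delta,
    phi_t = phi_t, phi_b = alpha * phi_t)
}

tissue_table <- tibble::tibble(
  medium = c("intima", "media", "adventitia", "extramural"),
  phi_t = c(0.67, 0.48, 0.53, 0.50),
  phi_b = c(0.73, 0.69, 0.68, 0.50)
)

#' Optical coefficients of the solid tissues
#'
#' Tabulated 1300 nm attenuation and backscatter coefficients of the
#' vessel-wall layers (intima, media, adventitia) and extramural tissue. For
#' tissues the backscatter coefficient is tabulated directly (no
#' alpha/anisotropy decomposition).
#'
#' @param layer Character vector of layer labels.
#' @return A tibble with columns `medium`, `phi_t`, `phi_b` (/mm).
#' @export
tissue_coefficients <- function(layer = tissue_table$medium) {
  idx <- match(layer, tissue_table$medium)
  if (anyNA(idx)) {
    abort(sprintf("lookup error: unknown tissue layer '%s'",
      paste(layer[is.na(idx)], collapse = "', '")), class = "ivoct_domain_error")
  }
  tissue_table[idx, ]
}

#' Radial medium profile for one A-line
#'
#' Samples the optical media along one radial beam path: the lumen between
#' the OCT catheter wall and the vessel inner wall carries the local
#' haematocrit (and Eq.-style fluid coefficients recomputed per point); the
#' wall layers and extramural tissue carry the tabulated coefficients.
#'
#' @param geometry An [geometry_config()].
#' @param haematocrit Either a single number (uniform lumen), a function of
#'   radius `X_e(r_mm)`, or a data frame with columns `r` and `haematocrit`
#'   (linearly interpolated, constant-extrapolated).
#' @param dr Radial sampling (mm); 0.005 mm = 5 micrometres by default.
#' @return A tibble of class `ivoct_profile` with columns `r`, `medium`,
#'   `haematocrit`, `phi_t`, `phi_b`.
#' @export
medium_profile <- function(geometry, haematocrit = 0, dr = 0.005) {
  stack <- radial_media_stack(geometry)
  r <- seq(geometry$oct_catheter_radius, geometry$extramural_outer_radius,
    by = dr)
  if (abs(r[length(r)] - geometry$extramural_outer_radius) > 1e-9) {
    r <- c(r, geometry$extramural_outer_radius)
  }
  # interface samples carry the proximal (upstream) medium so that the
  # cumulative optical depth at an interface equals the exact path integral
  # up to it (e.g. M at the vessel inner wall is the lumen-only attenuation);
  # zero-thickness layers are skipped
  medium <- stack$medium[pmax(findInterval(r, stack$r_min, left.open = TRUE), 1L)]
  xe <- numeric(length(r))
  lum <- medium == "lumen"
  if (is.function(haematocrit)) {
    xe[lum] <- haematocrit(r[lum])
  } else if (is.data.frame(haematocrit)) {
    xe[lum] <- approx(haematocrit$r, haematocrit$haematocrit, xout = r[lum],
      rule = 2)$y
  } else {
    xe[lum] <- haematocrit
  }
  xe <- pmin(pmax(xe, 0), 1)
  phi_t <- numeric(length(r)); phi_b <- numeric(length(r))
  fl <- fluid_coefficients(xe[lum])
  phi_t[lum] <- fl$phi_t; phi_b[lum] <- fl$phi_b
  for (k in seq_len(nrow(tissue_table))) {
    sel <- medium == tissue_table$medium[k]
    phi_t[sel] <- tissue_table$phi_t[k]
    phi_b[sel] <- tissue_table$phi_b[k]
  }
  out <- tibble(r = r, medium = medium, haematocrit = xe,
    phi_t = phi_t, phi_b = phi_b)
  class(out) <- c("ivoct_profile", class(out))
  attr(out, "vessel_inner_radius") <- geometry$vessel_inner_radius
  out
}

#' Propagate the NIR beam through a medium profile
#'
#' Lambert-Beer attenuation of the collimated beam along the radial path with
#' cumulative trapezoidal optical depth:
#' `E(r) = E0 exp(-int phi_t dx)`, residual ratio `M(r) = E(r)/E0`, and the
#' round-trip backscatter signal `I(r) = phi_b(r) E0 exp(-2 int phi_t dx)`
#' (irradiance per mm). The grayscale channel is `G = 255 I / I_max` with
#' `I_max` the whole-blood proximal signal. `M_w` is the residual ratio at
#' the vessel inner wall.
#'
#' @param profile An [medium_profile()].
#' @param E0 Incident irradiance (W/m^2); only ratios matter, default 1.
#' @param alpha,beta Backscatter fraction and detector conversion factor.
#' @return A tibble of class `ivoct_aline` with columns `r`, `E`, `M`, `I`,
#'   `G`, and attributes `M_w` and `I_max`.
#' @export
#' @examples
#' geo <- geometry_config()
#' al <- propagate(medium_profile(geo, 0.45))
#' attr(al, "M_w") # ~ exp(-1.1925 * 1.55)
propagate <- function(profile, E0 = 1, alpha = 1, beta = 1) {
  if (E0 <= 0) abort("domain error: E0 must be positive", class = "ivoct_domain_error")
  r <- profile$r
  if (length(r) < 2 || any(diff(r) <= 0)) {
    abort("input error: radial grid must be strictly increasing",
      class = "ivoct_domain_error")
  }
  tau <- cumulative_trapezoid(r, profile$phi_t)
  E <- E0 * exp(-tau)
  M <- exp(-tau)
  I <- beta * alpha * profile$phi_b * E0 * exp(-2 * tau)
  Imax <- i_max(E0, alpha, beta)
  out <- tibble(r = r, E = E, M = M, I = I, G = grayscale(I, Imax))
  class(out) <- c("ivoct_aline", class(out))
  rw <- attr(profile, "vessel_inner_radius")
  attr(out, "M_w") <- if (!is.null(rw)) approx(r, M, xout = rw, rule = 2)$y else NA_real_
  attr(out, "I_max") <- Imax
  attr(out, "E0") <- E0
  out
}

cumulative_trapezoid <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Maximum achievable OCT signal
#'
#' The proximal signal next to the source in a whole-blood environment,
#' `I_max = alpha beta E0 phi_t(X_e = 0.45)` = 1.1925 E0 per mm at the
#' defaults; used to normalize the grayscale channel.
#'
#' @param E0 Incident irradiance (W/m^2).
#' @param alpha,beta Backscatter fraction and detector factor.
#' @return Normalization constant (irradiance per mm).
#' @export
i_max <- function(E0 = 1, alpha = 1, beta = 1) {
  if (E0 <= 0) abort("domain error: E0 must be positive", class = "ivoct_domain_error")
  alpha * beta * E0 * fluid_coefficients(0.45)$phi_t
}

#' Grayscale conversion
#'
#' `G = 255 I / I_max`, clipped to \[0, 255\] and rounded half-to-even.
#'
#' @param I Signal profile (same units as `I_max`).
#' @param I_max Normalization constant.
#' @return Integer vector in 0..255.
#' @export
grayscale <- function(I, I_max) {
  if (I_max <= 0) abort("domain error: I_max must be positive", class = "ivoct_domain_error")
  as.integer(round(pmin(pmax(255 * I / I_max, 0), 255)))
}
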