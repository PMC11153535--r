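#' Analytic haematocrit-field fixtures
#'
#' Closed-form lumen haematocrit fields `X_e(r, z, t)` that stand in for the
#' flushing solver when exercising the optics/metrics chain. Three kinds:
#'
#' * `uniform`: constant haematocrit everywhere.
#' * `axial_front`: a saline front at `z_f(t) = front_z0 + front_speed * t`;
#'   haematocrit ramps from 0 (behind the front, upstream) to `x_max` over
#'   `width` mm via a smooth logistic profile. Emulates the advancing
#'   flushing front.
#' * `cyclic_slugs`: clean saline interrupted by periodic blood slugs
#'   (period 0.8 s by default): during the first `duty` fraction of each
#'   cycle the haematocrit is `amplitude`, otherwise `baseline`. Emulates
#'   systolic inflow bringing fresh erythrocytes into the scan region.
#'
#' All fixtures are deterministic and seedless.
#'
#' @param kind One of `"uniform"`, `"axial_front"`, `"cyclic_slugs"`.
#' @param x_e Haematocrit of the `uniform` kind.
#' @param front_z0,front_speed,width,x_max `axial_front` parameters (mm,
#'   mm/s, mm, fraction).
#' @param period,amplitude,duty,baseline `cyclic_slugs` parameters (s,
#'   fraction, fraction of cycle, fraction).
#' @param horizon Optional time horizon (s) reported to the scanner.
#' @return An `ivoct_field_analytic` object usable with [haematocrit_at()],
#'   [frame_mw()] and [run_scan()].
#' @export
#' @examples
#' f <- make_fixture("uniform", x_e = 0)
#' frame_mw(f, 30, geometry_config(), t = 0) # 1: transparent lumen
make_fixture <- function(kind = c("uniform", "axial_front", "cyclic_slugs"),
                         x_e = 0.45,
                         front_z0 = 0, front_speed = 50, width = 5, x_max = 0.45,
                         period = 0.8, amplitude = 0.45, duty = 0.35,
                         baseline = 0, horizon = NULL) {
  kind <- match.arg(kind)
  check_frac <- function(x, nm) {
    if (any(x < 0) || any(x > 0.45 + 1e-12)) {
      abort(sprintf("fixture error: %s must lie in [0, 0.45]", nm),
        class = "ivoct_domain_error")
    }
  }
  fn <- switch(kind,
    uniform = {
      check_frac(x_e, "x_e")
      function(r, z, t) rep(x_e, length(r))
    },
    axial_front = {
      check_frac(x_max, "x_max")
      function(r, z, t) {
        zf <- front_z0 + front_speed * t
        rep(x_max / (1 + exp(-(z - zf) / (width / 4))), length(r))
      }
    },
    cyclic_slugs = {
      check_frac(amplitude, "amplitude")
      check_frac(baseline, "baseline")
      function(r, z, t) {
        phase <- (t %% period) / period
        rep(if (phase < duty) amplitude else baseline, length(r))
      }
    }
  )
  structure(
    list(kind = kind, haematocrit_fn = fn, horizon = horizon),
    class = "ivoct_field_analytic"
  )
}

#' @export
haematocrit_at.ivoct_field_analytic <- function(field, z, t) {
  r <- seq(0.45, 2.0, by = 0.025)
  data.frame(r = r, haematocrit = pmin(pmax(field$haematocrit_fn(r, z, t), 0), 1))
}

#' @export
field_horizon.ivoct_field_analytic <- function(field) field$horizon

#' @export
print.ivoct_field_analytic <- function(x, ...) {
  cat(sprintf("<ivoct_field_analytic: %s>\n", x$kind))
  invisible(x)
}
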