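#' Pull-back scan protocol
#'
#' Kinematics and scoring parameters of one OCT pull-back: the lens starts at
#' `lens_start_z` and retracts toward the guiding catheter (-z) at
#' `pullback_speed` for `scan_duration`, capturing one frame every
#' `frame_dt`. Defaults give a 50 mm pull-back of 251 frames spaced 0.2 mm.
#' A frame is a clear image frame (CIF) when its wall residual irradiance
#' ratio `M_w` reaches `cif_threshold`; the composite quality weights are
#' `f1` (mean clarity) and `f2` (consistency).
#'
#' @param pullback_speed Lens retraction speed (mm/s).
#' @param scan_duration Scan time (s).
#' @param frame_dt Frame interval (s).
#' @param cif_threshold CIF threshold on `M_w`, in (0, 1).
#' @param f1,f2 Quality weights; must sum to 1.
#' @param lens_start_z Lens position at scan start (mm).
#' @return An `ivoct_scan_protocol` list with derived fields
#'   `pullback_length` (mm), `n_frames`, and `frame_spacing` (mm).
#' @export
scan_protocol <- function(pullback_speed = 20, scan_duration = 2.5,
                          frame_dt = 0.01, cif_threshold = 0.75,
                          f1 = 0.7, f2 = 0.3, lens_start_z = 60) {
  if (abs(f1 + f2 - 1) > 1e-12) {
    abort("protocol invariant violated: f1 + f2 must equal 1",
      class = "ivoct_validation_error")
  }
  if (cif_threshold <= 0 || cif_threshold >= 1) {
    abort("protocol invariant violated: cif_threshold must lie in (0, 1)",
      class = "ivoct_validation_error")
  }
  if (pullback_speed < 0 || scan_duration <= 0 || frame_dt <= 0) {
    abort("protocol invariant violated: speed, duration and frame_dt must be valid",
      class = "ivoct_validation_error")
  }
  n <- scan_duration / frame_dt
  if (abs(n - round(n)) > 1e-9) {
    abort("protocol invariant violated: frame_dt must divide scan_duration",
      class = "ivoct_validation_error")
  }
  structure(
    list(
      pullback_speed = pullback_speed, scan_duration = scan_duration,
      frame_dt = frame_dt, cif_threshold = cif_threshold,
      f1 = f1, f2 = f2, lens_start_z = lens_start_z,
      pullback_length = pullback_speed * scan_duration,
      n_frames = as.integer(round(n)) + 1L,
      frame_spacing = pullback_speed * frame_dt
    ),
    class = "ivoct_scan_protocol"
  )
}

#' Haematocrit column of a field at one axial position
#'
#' Generic accessor shared by the flushing solver output and the analytic
#' fixtures: the radial haematocrit distribution of the lumen at axial
#' position `z` and time `t`.
#'
#' @param field A field object (`ivoct_flush` or `ivoct_field_analytic`).
#' @param z Axial position (mm).
#' @param t Time (s).
#' @return A data frame with columns `r` (mm) and `haematocrit`.
#' @export
haematocrit_at <- function(field, z, t) UseMethod("haematocrit_at")

#' Per-frame wall residual irradiance ratio
#'
#' Builds the radial medium profile at the lens position from the local
#' haematocrit column, propagates the beam, and returns `M_w`, the residual
#' irradiance ratio at the vessel inner wall.
#'
#' @param field A haematocrit field (see [haematocrit_at()]).
#' @param lens_z Lens axial position (mm).
#' @param geometry An [geometry_config()].
#' @param t Time (s).
#' @param dr Radial optical sampling (mm).
#' @return `M_w` in \[0, 1\].
#' @export
frame_mw <- function(field, lens_z, geometry, t, dr = 0.005) {
  col <- haematocrit_at(field, lens_z, t)
  prof <- medium_profile(geometry, col, dr = dr)
  attr(propagate(prof), "M_w")
}

#' Pull-back trigger
#'
#' First sample at which the wall clarity reaches the CIF threshold; image
#' acquisition then proceeds for the full scan duration regardless of later
#' dips.
#'
#' @param mw_series A data frame with columns `time` and `m_w`, sampled at
#'   the frame interval at the lens start position.
#' @param threshold CIF threshold.
#' @return Trigger time (s).
#' @export
pullback_trigger <- function(mw_series, threshold = 0.75) {
  hit <- which(mw_series$m_w >= threshold)
  if (!length(hit)) {
    abort(sprintf(
      "no-trigger error: M_w never reached %.3g within the horizon (max observed %.3g)",
      threshold, max(mw_series$m_w)),
      class = "ivoct_no_trigger_error")
  }
  mw_series$time[hit[1]]
}

#' Run one pull-back scan
#'
#' Moves the lens from `lens_start_z` in the -z direction at the pull-back
#' speed, captures `n` frames at the frame interval, and scores each frame's
#' `M_w` and CIF flag.
#'
#' @param field A haematocrit field (solver output or fixture).
#' @param protocol An [scan_protocol()].
#' @param geometry An [geometry_config()].
#' @param start_time Scan start (s); typically from [pullback_trigger()].
#' @param dr Radial optical sampling (mm).
#' @return A tibble of class `ivoct_scan` with columns `frame`, `time`,
#'   `lens_z`, `m_w`, `cif`; protocol stored as attribute.
#' @export
run_scan <- function(field, protocol, geometry, start_time, dr = 0.005) {
  times <- start_time + protocol$frame_dt * seq(0, protocol$n_frames - 1L)
  horizon <- field_horizon(field)
  if (!is.null(horizon) && max(times) > horizon + 1e-9) {
    abort("truncation error: flush horizon ends before the scan completes",
      class = "ivoct_domain_error")
  }
  lens_z <- protocol$lens_start_z - protocol$pullback_speed * (times - start_time)
  m_w <- vapply(seq_along(times), function(i) {
    frame_mw(field, lens_z[i], geometry, times[i], dr = dr)
  }, numeric(1))
  out <- tibble(
    frame = seq_along(times), time = times, lens_z = lens_z,
    m_w = m_w, cif = m_w >= protocol$cif_threshold
  )
  class(out) <- c("ivoct_scan", class(out))
  attr(out, "protocol") <- protocol
  out
}

field_horizon <- function(field) UseMethod("field_horizon")
#' @export
field_horizon.default <- function(field) NULL

#' Clear imaging length
#'
#' Cumulative vessel length imaged clearly: the number of CIF frames times
#' the frame spacing, counting non-contiguous clear segments, capped at the
#' pull-back length (so an all-clear scan reports the full length).
#'
#' @param scan An [run_scan()] result (or any data frame with a `cif`
#'   column).
#' @param spacing Frame spacing (mm); defaults to the scan's protocol value.
#' @param cap Maximum reported length (mm); defaults to the pull-back length.
#' @return CIL (mm).
#' @export
cil <- function(scan, spacing = NULL, cap = NULL) {
  proto <- attr(scan, "protocol")
  if (is.null(spacing)) spacing <- proto$frame_spacing
  if (is.null(cap)) cap <- if (!is.null(proto)) proto$pullback_length else Inf
  min(sum(scan$cif) * spacing, cap)
}

#' Composite scan quality
#'
#' `gamma = f1 * mean(M_w) + f2 * (1 - sigma / 0.25)` where `sigma` is the
#' population variance (divisor n) of the per-frame `M_w`. Since 0.25 is the
#' maximal variance of \[0, 1\]-valued data, `gamma` lies in \[0, 1\]
#' whenever `f1 + f2 = 1`.
#'
#' @param scan A data frame with column `m_w`.
#' @param f1,f2 Weights (must sum to 1).
#' @return A one-row tibble with `mean_mw`, `sigma`, `gamma`.
#' @export
scan_gamma <- function(scan, f1 = 0.7, f2 = 0.3) {
  if (abs(f1 + f2 - 1) > 1e-12) {
    abort("domain error: f1 + f2 must equal 1", class = "ivoct_domain_error")
  }
  m <- scan$m_w
  if (!length(m)) abort("domain error: empty M_w series", class = "ivoct_domain_error")
  mbar <- mean(m)
  sigma <- mean((m - mbar)^2)
  tibble(mean_mw = mbar, sigma = sigma, gamma = f1 * mbar + f2 * (1 - sigma / 0.25))
}

#' Scan summary
#'
#' Bundles the quality indicators of one pull-back with the saline dosage of
#' its injection schedule: mean wall clarity, its population variance, the
#' composite quality `gamma`, the clear imaging length, and the injected
#' volume `V` over the full simulation horizon.
#'
#' @param scan An [run_scan()] result.
#' @param schedule The injection [flow_waveform()] (or `NULL` for no
#'   injection).
#' @param horizon Dosage integration horizon `t_f` (s).
#' @param scheme Label for the summary row.
#' @return A one-row tibble of class `ivoct_summary`: `scheme`, `mean_mw`,
#'   `sigma`, `gamma`, `cil_mm`, `dosage_ml`, `n_frames`, `trigger_time`.
#' @export
scan_summary <- function(scan, schedule = NULL, horizon = 7.2,
                         scheme = attr(schedule, "kind") %||% "custom") {
  g <- scan_gamma(scan,
    f1 = attr(scan, "protocol")$f1 %||% 0.7,
    f2 = attr(scan, "protocol")$f2 %||% 0.3)
  v <- if (is.null(schedule)) 0 else dosage(schedule, horizon)
  out <- tibble(
    scheme = scheme,
    mean_mw = g$mean_mw, sigma = g$sigma, gamma = g$gamma,
    cil_mm = cil(scan), dosage_ml = v,
    n_frames = nrow(scan), trigger_time = scan$time[1]
  )
  class(out) <- c("ivoct_summary", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
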