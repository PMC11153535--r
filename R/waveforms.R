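#' Flow waveform
#'
#' A flow-rate time series, the common representation for the pulsatile blood
#' inflow and the saline injection schedules. Stored as a tibble of `(time,
#' flow)` samples (s, mL/s); a waveform is evaluated by linear interpolation
#' between samples, so the trapezoidal dosage quadrature is exact for
#' piecewise-linear shapes.
#'
#' @param time Strictly increasing sample times (s).
#' @param flow Flow rates (mL/s).
#' @param period Cycle period (s) for cyclic waveforms, or `NULL`.
#' @param kind Label (`"continuous"`, `"intermittent"`, `"blood"`, `"custom"`).
#' @param nonnegative If `TRUE` (injection waveforms), negative rates are an
#'   error.
#' @return A tibble of class `ivoct_waveform`.
#' @export
flow_waveform <- function(time, flow, period = NULL, kind = "custom",
                          nonnegative = FALSE) {
  if (length(time) != length(flow)) {
    abort("waveform error: time and flow must have equal length",
      class = "ivoct_domain_error")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    abort("waveform error: time must be strictly increasing",
      class = "ivoct_domain_error")
  }
  if (nonnegative && any(flow < 0)) {
    abort("domain error: injection flow rates must be non-negative",
      class = "ivoct_domain_error")
  }
  out <- tibble(time = as.numeric(time), flow = as.numeric(flow))
  class(out) <- c("ivoct_waveform", class(out))
  attr(out, "period") <- period
  attr(out, "kind") <- kind
  out
}

#' Evaluate a waveform at arbitrary times
#'
#' Linear interpolation between samples; zero outside the sampled support
#' unless the waveform is periodic, in which case time wraps modulo the
#' period.
#'
#' @param waveform An [flow_waveform()].
#' @param t Times (s).
#' @return Flow rates (mL/s).
#' @export
waveform_at <- function(waveform, t) {
  period <- attr(waveform, "period")
  tt <- if (!is.null(period)) t %% period else t
  out <- approx(waveform$time, waveform$flow, xout = tt, rule = 2)$y
  if (is.null(period)) {
    out[t < min(waveform$time) | t > max(waveform$time)] <- 0
  }
  out
}

#' Saline dosage (degree of intervention)
#'
#' Integrates the injection flow rate over the scan horizon,
#' `V = integral of Q(t) dt` from 0 to the horizon, by trapezoidal quadrature
#' on the waveform's own samples (exact for piecewise-linear waveforms).
#'
#' @param waveform An [flow_waveform()] (mL/s vs s).
#' @param horizon Upper integration limit `t_f` (s).
#' @return Injected volume (mL).
#' @export
#' @examples
#' dosage(build_continuous(), horizon = 7.2)
dosage <- function(waveform, horizon) {
  if (nrow(waveform) == 0) return(0)
  if (is.null(attr(waveform, "period")) && horizon > max(waveform$time) + 1e-9 &&
      abs(waveform$flow[nrow(waveform)]) > 0) {
    abort("extrapolation error: horizon extends beyond the waveform support",
      class = "ivoct_domain_error")
  }
  period <- attr(waveform, "period")
  if (!is.null(period)) {
    reps <- seq(0, ceiling(horizon / period)) * period
    tt <- as.vector(outer(waveform$time, reps, `+`))
  } else {
    tt <- waveform$time
  }
  tt <- sort(unique(c(tt[tt <= horizon & tt >= 0], horizon, 0)))
  qq <- waveform_at(waveform, tt)
  sum(diff(tt) * (head(qq, -1) + tail(qq, -1)) / 2)
}

#' Continuous injection schedule
#'
#' A constant-rate rectangle from `start` to `stop` with short linear on/off
#' ramps for numerical smoothness; the ramps are placed just inside/outside
#' the edges so the integral equals `peak_rate * (stop - start)` exactly.
#' Defaults give the base-case continuous scheme: 4.5 mL/s sustained over
#' 0.8--4.0 s, 14.4 mL in total.
#'
#' @param peak_rate Injection rate (mL/s).
#' @param start,stop Injection window (s); injection commences from the
#'   second cardiac cycle in the base case.
#' @param ramp Ramp duration (s).
#' @return An [flow_waveform()].
#' @export
build_continuous <- function(peak_rate = 4.5, start = 0.8, stop = 4.0,
                             ramp = 0.02) {
  if (peak_rate < 0) {
    abort("domain error: peak_rate must be non-negative", class = "ivoct_domain_error")
  }
  if (stop < start) {
    abort("domain error: stop must be >= start", class = "ivoct_domain_error")
  }
  if (stop == start || peak_rate == 0) {
    return(flow_waveform(numeric(0), numeric(0), kind = "continuous",
      nonnegative = TRUE))
  }
  # rise over [start, start+ramp], plateau to stop, fall over [stop, stop+ramp]:
  # trapezoid area = peak * (stop - start) exactly
  flow_waveform(
    time = c(start, start + ramp, stop, stop + ramp),
    flow = c(0, peak_rate, peak_rate, 0),
    kind = "continuous", nonnegative = TRUE
  )
}

#' Intermittent injection schedule
#'
#' One pulse per selected cardiac cycle: the rate rises as
#' `((t - t0) / 0.4)^a` to the peak over the first half of the cycle and
#' falls back to zero along the mirrored curve over the second half, so the
#' per-cycle volume is `peak * 0.8 / (a + 1)`. Defaults (peak 4.5 mL/s,
#' a = 0.8, cycles 2--5) give 2.0 mL per cycle and 8.0 mL in total, with the
#' same peak rate as the continuous scheme.
#'
#' @param peak_rate Peak injection rate (mL/s).
#' @param ramp_exponent Power-law exponent `a > 0` of the rise/fall.
#' @param cycles Integer cardiac-cycle indices receiving a pulse (cycle 1
#'   starts at t = 0).
#' @param cycle_period Cardiac cycle length (s).
#' @param n_samples Samples per half-cycle used to tabulate the power law.
#' @return An [flow_waveform()].
#' @export
build_intermittent <- function(peak_rate = 4.5, ramp_exponent = 0.8,
                               cycles = 2:5, cycle_period = 0.8,
                               n_samples = 200) {
  if (peak_rate < 0) {
    abort("domain error: peak_rate must be non-negative", class = "ivoct_domain_error")
  }
  if (ramp_exponent <= 0) {
    abort("domain error: ramp_exponent must be positive", class = "ivoct_domain_error")
  }
  cycles <- sort(unique(as.integer(cycles)))
  if (length(cycles) != length(unique(cycles))) {
    abort("construction error: overlapping cycles", class = "ivoct_domain_error")
  }
  half <- cycle_period / 2
  tau <- seq(0, 1, length.out = n_samples + 1)
  rise <- peak_rate * tau^ramp_exponent
  t_all <- numeric(0); q_all <- numeric(0)
  for (cy in cycles) {
    t0 <- (cy - 1) * cycle_period
    t_cycle <- c(t0 + tau * half, t0 + half + tau[-1] * half)
    q_cycle <- c(rise, rev(rise)[-1])
    t_all <- c(t_all, t_cycle)
    q_all <- c(q_all, q_cycle)
  }
  t_all <- round(t_all, 9) # snap cycle boundaries to a common time grid
  keep <- !duplicated(t_all)
  flow_waveform(t_all[keep], q_all[keep], kind = "intermittent",
    nonnegative = TRUE)
}

#' Pulsatile blood inflow waveform
#'
#' A parametric triphasic (femoral-like) template with period 0.8 s: a
#' systolic forward sine lobe, a brief early-diastolic reverse lobe, a small
#' second forward lobe, and near-zero late-diastolic flow. The default peak
#' is calibrated so the peak lumen Reynolds number in a 4 mm vessel with
#' whole-blood properties is 770. The template can be replaced by
#' user-supplied samples via [flow_waveform()].
#'
#' @param peak_rate Systolic peak flow (mL/s); `NULL` selects the calibrated
#'   default.
#' @param cycle_period Cycle length (s).
#' @param reverse_fraction,second_lobe_fraction Amplitudes of the reverse and
#'   second forward lobes relative to the systolic peak.
#' @param n_samples Samples per cycle.
#' @param constants A [physical_constants()] used for the Reynolds
#'   calibration of the default peak.
#' @param diameter_mm Vessel diameter used in the calibration (mm).
#' @return A periodic [flow_waveform()].
#' @export
blood_inflow_waveform <- function(peak_rate = NULL, cycle_period = 0.8,
                                  reverse_fraction = 0.22,
                                  second_lobe_fraction = 0.12,
                                  n_samples = 400,
                                  constants = physical_constants(),
                                  diameter_mm = 4) {
  if (is.null(peak_rate)) {
    peak_rate <- calibrated_blood_peak(constants, diameter_mm)
  }
  tau <- seq(0, 1, length.out = n_samples + 1)
  shape <- numeric(length(tau))
  sys <- tau <= 0.25
  shape[sys] <- sin(pi * tau[sys] / 0.25)
  rev_ph <- tau > 0.25 & tau <= 0.40
  shape[rev_ph] <- -reverse_fraction * sin(pi * (tau[rev_ph] - 0.25) / 0.15)
  fwd2 <- tau > 0.40 & tau <= 0.60
  shape[fwd2] <- second_lobe_fraction * sin(pi * (tau[fwd2] - 0.40) / 0.20)
  flow_waveform(tau * cycle_period, peak_rate * shape,
    period = cycle_period, kind = "blood")
}

#' Blood peak flow calibrated to a target Reynolds number
#'
#' Solves `Re = 4 rho Q / (pi d mu)` for Q with whole-blood density and
#' Einstein-law viscosity, targeting the stated maximum Reynolds number of
#' pulsatile blood flow in the lumen (770 by default).
#'
#' @param constants A [physical_constants()].
#' @param diameter_mm Vessel diameter (mm).
#' @param re_target Target Reynolds number.
#' @return Peak flow (mL/s).
#' @export
calibrated_blood_peak <- function(constants = physical_constants(),
                                  diameter_mm = 4, re_target = 770) {
  mu <- mixture_viscosity(constants$whole_blood_haematocrit,
    constants$plasma_viscosity)
  q_m3 <- re_target * pi * (diameter_mm * 1e-3) * mu /
    (4 * constants$whole_blood_density)
  q_m3 * 1e6
}

#' Duct Reynolds number
#'
#' Mean-velocity convention for a circular duct: `Re = 4 rho Q / (pi d mu)`.
#'
#' @param flow_rate Volumetric flow (mL/s).
#' @param diameter Duct diameter (mm).
#' @param density Fluid density (kg/m^3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(flow_rate, diameter, density, viscosity) {
  if (any(diameter <= 0) || any(viscosity <= 0) || any(density <= 0)) {
    abort("domain error: diameter, density and viscosity must be positive",
      class = "ivoct_domain_error")
  }
  4 * density * (flow_rate * 1e-6) / (pi * (diameter * 1e-3) * viscosity)
}

#' Peclet number
#'
#' `Pe = u L / D`: ratio of convective to diffusive mass transport. With the
#' peak lumen mean velocity, the lumen diameter, and the saline-limit
#' erythrocyte diffusivity this is of order 1e10--1e11, i.e. the flushing is
#' advection dominated.
#'
#' @param velocity Characteristic velocity (m/s).
#' @param length Characteristic length (m).
#' @param diffusivity Mass diffusivity (m^2/s).
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(velocity, length, diffusivity) {
  if (any(diffusivity <= 0)) {
    abort("domain error: diffusivity must be positive", class = "ivoct_domain_error")
  }
  velocity * length / diffusivity
}

#' Build a scheme waveform from configuration parameters
#'
#' @param scheme A parameter list as in [default_schemes()].
#' @param clock A [simulation_clock()] (supplies the cycle period).
#' @return An [flow_waveform()].
#' @export
scheme_waveform <- function(scheme, clock = simulation_clock()) {
  switch(scheme$kind,
    continuous = build_continuous(scheme$peak_rate, scheme$start, scheme$stop),
    intermittent = build_intermittent(scheme$peak_rate, scheme$ramp_exponent,
      scheme$cycles, clock$cycle_period),
    custom = flow_waveform(scheme$time, scheme$flow, kind = "custom",
      nonnegative = TRUE),
    abort(sprintf("unknown scheme kind '%s'", scheme$kind),
      class = "ivoct_domain_error")
  )
}

#' Read / write a waveform as two-column CSV
#'
#' Columns `time` (s) and `flow` (mL/s).
#'
#' @param path File path.
#' @param waveform An [flow_waveform()].
#' @param ... Passed to [flow_waveform()] on read (`period`, `kind`).
#' @return The waveform (read) or `path` invisibly (write).
#' @export
read_waveform_csv <- function(path, ...) {
  df <- read.csv(path)
  flow_waveform(df$time, df$flow, ...)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(waveform, path) {
  write.csv(as.data.frame(waveform[, c("time", "flow")]), path,
    row.names = FALSE)
  invisible(path)
}
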