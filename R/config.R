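#' Vessel--catheter geometry
#'
#' Radii and axial layout of the axisymmetric model: a straight artery with an
#' OCT catheter on the axis and a guiding catheter whose outlet sits at
#' `z = 0` (the axial origin; `z` increases downstream). All lengths are in
#' millimetres. Defaults correspond to a 4 mm lower-extremity artery
#' (inner diameter 4.0 mm, outer 4.74 mm), a 0.9 mm OCT catheter, and a
#' guiding catheter with inner/outer diameters 1.8/2.0 mm, surrounded by
#' extramural tissue out to 5 mm from the axis.
#'
#' @param vessel_inner_radius,vessel_outer_radius Vessel lumen and outer wall
#'   radii (mm).
#' @param extramural_outer_radius Outer radius of the extramural tissue shell
#'   (mm); also the radial extent of the rendered A-line.
#' @param oct_catheter_radius Outer radius of the OCT catheter (mm); the NIR
#'   source plane.
#' @param guiding_catheter_inner_radius,guiding_catheter_outer_radius Guiding
#'   catheter radii (mm); saline flows in the annulus between the OCT catheter
#'   and the guiding catheter inner wall.
#' @param guiding_catheter_outlet_z Axial position of the guiding catheter
#'   outlet (mm); fixed coordinate convention, 0.
#' @param blood_inlet_z Upstream boundary of the simulated domain (mm).
#' @param domain_z_max Downstream boundary (mm).
#' @param wall_layer_thicknesses Thicknesses (mm) of intima, media and
#'   adventitia; must sum to the vessel wall thickness.
#' @return A `ivoct_geometry` list with the validated fields.
#' @export
#' @examples
#' geo <- geometry_config()
#' radial_media_stack(geo)
geometry_config <- function(vessel_inner_radius = 2.0,
                            vessel_outer_radius = 2.37,
                            extramural_outer_radius = 5.0,
                            oct_catheter_radius = 0.45,
                            guiding_catheter_inner_radius = 0.9,
                            guiding_catheter_outer_radius = 1.0,
                            guiding_catheter_outlet_z = 0.0,
                            blood_inlet_z = -20,
                            domain_z_max = 80,
                            wall_layer_thicknesses = NULL) {
  if (is.null(wall_layer_thicknesses)) {
    wall_layer_thicknesses <- rep((vessel_outer_radius - vessel_inner_radius) / 3, 3)
  }
  geo <- structure(
    list(
      vessel_inner_radius = vessel_inner_radius,
      vessel_outer_radius = vessel_outer_radius,
      extramural_outer_radius = extramural_outer_radius,
      oct_catheter_radius = oct_catheter_radius,
      guiding_catheter_inner_radius = guiding_catheter_inner_radius,
      guiding_catheter_outer_radius = guiding_catheter_outer_radius,
      guiding_catheter_outlet_z = guiding_catheter_outlet_z,
      blood_inlet_z = blood_inlet_z,
      domain_z_max = domain_z_max,
      wall_layer_thicknesses = as.numeric(wall_layer_thicknesses)
    ),
    class = "ivoct_geometry"
  )
  validate_geometry(geo)
  geo
}

validate_geometry <- function(geo) {
  radii <- c(
    oct_catheter_radius = geo$oct_catheter_radius,
    guiding_catheter_inner_radius = geo$guiding_catheter_inner_radius,
    guiding_catheter_outer_radius = geo$guiding_catheter_outer_radius,
    vessel_inner_radius = geo$vessel_inner_radius,
    vessel_outer_radius = geo$vessel_outer_radius,
    extramural_outer_radius = geo$extramural_outer_radius
  )
  if (radii[1] <= 0 || any(diff(radii) <= 0)) {
    abort(paste0(
      "geometry invariant violated: radii must satisfy 0 < ",
      paste(names(radii), collapse = " < ")
    ), class = "ivoct_validation_error")
  }
  if (length(geo$wall_layer_thicknesses) != 3L || any(geo$wall_layer_thicknesses < 0)) {
    abort("geometry invariant violated: wall_layer_thicknesses must be 3 non-negative lengths",
      class = "ivoct_validation_error")
  }
  wall <- geo$vessel_outer_radius - geo$vessel_inner_radius
  if (abs(sum(geo$wall_layer_thicknesses) - wall) > 1e-9) {
    abort(sprintf(
      "geometry invariant violated: wall layer thicknesses sum to %.6g mm, expected %.6g mm",
      sum(geo$wall_layer_thicknesses), wall
    ), class = "ivoct_validation_error")
  }
  if (geo$blood_inlet_z >= geo$guiding_catheter_outlet_z ||
      geo$domain_z_max <= geo$guiding_catheter_outlet_z) {
    abort("geometry invariant violated: blood_inlet_z < guiding_catheter_outlet_z < domain_z_max",
      class = "ivoct_validation_error")
  }
  invisible(geo)
}

#' Physical constants of the blood/saline system
#'
#' @param boltzmann_k Boltzmann constant (J/K).
#' @param body_temperature_T Absolute temperature (K). Not printed in the
#'   source study; 310 K reproduces the reported diffusion coefficients and is
#'   a calibrated default.
#' @param saline_density Normal saline density (kg/m^3).
#' @param whole_blood_density Whole blood density (kg/m^3).
#' @param whole_blood_haematocrit Erythrocyte volume fraction of whole blood.
#' @param plasma_viscosity Plasma (= saline) viscosity (Pa s); calibrated
#'   default 0.9 mPa s, see `body_temperature_T`.
#' @param rbc_volume Red-blood-cell volume (micrometre^3).
#' @return A `ivoct_constants` list.
#' @export
physical_constants <- function(boltzmann_k = 1.380649e-23,
                               body_temperature_T = 310,
                               saline_density = 1000,
                               whole_blood_density = 1056,
                               whole_blood_haematocrit = 0.45,
                               plasma_viscosity = 9.0e-4,
                               rbc_volume = 90) {
  cst <- structure(
    list(
      boltzmann_k = boltzmann_k,
      body_temperature_T = body_temperature_T,
      saline_density = saline_density,
      whole_blood_density = whole_blood_density,
      whole_blood_haematocrit = whole_blood_haematocrit,
      plasma_viscosity = plasma_viscosity,
      rbc_volume = rbc_volume
    ),
    class = "ivoct_constants"
  )
  vals <- unlist(cst)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("constants invariant violated: all physical constants must be strictly positive",
      class = "ivoct_validation_error")
  }
  if (cst$whole_blood_haematocrit >= 1) {
    abort("constants invariant violated: whole_blood_haematocrit must lie in (0, 1)",
      class = "ivoct_validation_error")
  }
  cst
}

#' Simulation clock
#'
#' The simulated horizon is `n_cycles` cardiac cycles of `cycle_period`
#' seconds (9 x 0.8 s = 7.2 s at the defaults). `frame_dt` is the image /
#' snapshot cadence and must divide the cycle period.
#'
#' @param cycle_period Cardiac cycle length (s).
#' @param n_cycles Number of simulated cycles.
#' @param solver_dt Flow-solver macro time step (s).
#' @param frame_dt Frame/snapshot interval (s).
#' @return A `ivoct_clock` list with a derived `total_time` field.
#' @export
simulation_clock <- function(cycle_period = 0.8, n_cycles = 9,
                             solver_dt = 1e-3, frame_dt = 0.01) {
  if (cycle_period <= 0 || n_cycles < 1 || solver_dt <= 0 || frame_dt <= 0) {
    abort("clock invariant violated: periods and steps must be positive",
      class = "ivoct_validation_error")
  }
  ratio <- cycle_period / frame_dt
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("clock invariant violated: frame_dt must divide cycle_period",
      class = "ivoct_validation_error")
  }
  structure(
    list(
      cycle_period = cycle_period, n_cycles = as.integer(n_cycles),
      solver_dt = solver_dt, frame_dt = frame_dt,
      total_time = cycle_period * n_cycles
    ),
    class = "ivoct_clock"
  )
}

#' Full simulation configuration
#'
#' Bundles geometry, physical constants, clock, scan protocol and the two
#' default injection schemes. Any component can be overridden; omitted parts
#' take the package defaults (the base case of the study).
#'
#' @param geometry An [geometry_config()] object or a list of overrides.
#' @param constants A [physical_constants()] object or overrides.
#' @param clock A [simulation_clock()] object or overrides.
#' @param scan A [scan_protocol()] object or overrides.
#' @param schemes Named list of injection-scheme parameter lists (see
#'   [default_schemes()]).
#' @param solver Named list of solver controls (grid spacings `dr_mm`,
#'   `dz_mm`, macro step `dt`, fidelity).
#' @return An `ivoct_config` list.
#' @export
ivoct_config <- function(geometry = list(), constants = list(), clock = list(),
                         scan = list(), schemes = list(), solver = list()) {
  as_part <- function(x, ctor, cls) {
    if (inherits(x, cls)) return(x)
    if (!is.list(x)) abort(sprintf("configuration error: component must be a list or %s", cls),
      class = "ivoct_config_error")
    do.call(ctor, x)
  }
  sch <- modifyList(default_schemes(), schemes)
  sol <- modifyList(
    list(dr_mm = 0.05, dz_mm = 0.4, dt = 1e-3, fidelity = "laminar_eddy",
         snapshot_dt = 0.01),
    solver
  )
  structure(
    list(
      geometry = as_part(geometry, geometry_config, "ivoct_geometry"),
      constants = as_part(constants, physical_constants, "ivoct_constants"),
      clock = as_part(clock, simulation_clock, "ivoct_clock"),
      scan = as_part(scan, scan_protocol, "ivoct_scan_protocol"),
      schemes = sch,
      solver = sol
    ),
    class = "ivoct_config"
  )
}

#' Default injection-scheme parameters
#'
#' Continuous: constant 4.5 mL/s sustained over cycles 2-5 (0.8 s to 4.0 s),
#' total 14.4 mL. Intermittent: same 4.5 mL/s peak, power-law rise to the peak
#' over the first 0.4 s of each of cycles 2-5 and a mirrored fall back to
#' zero, exponent 0.8, total 8.0 mL. The two schemes share the peak rate by
#' construction.
#'
#' @return Named list with `continuous` and `intermittent` parameter lists.
#' @export
default_schemes <- function() {
  list(
    continuous = list(kind = "continuous", peak_rate = 4.5, start = 0.8, stop = 4.0),
    intermittent = list(kind = "intermittent", peak_rate = 4.5,
                        ramp_exponent = 0.8, cycles = 2:5)
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration with top-level keys `geometry`, `constants`,
#' `clock`, `scan`, `schemes` and `solver`; any omitted key falls back to the
#' package default. All type invariants are re-validated after merging.
#'
#' @param path Path to a YAML file. An empty file yields the full default
#'   configuration.
#' @return A validated `ivoct_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration error: file '%s' does not exist", path),
      class = "ivoct_config_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(
      sprintf("configuration error: could not parse '%s': %s", path, conditionMessage(e)),
      class = "ivoct_config_error")
  )
  if (is.null(raw)) raw <- list()
  known <- c("geometry", "constants", "clock", "scan", "schemes", "solver")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("configuration error: unknown key(s): %s", paste(extra, collapse = ", ")),
      class = "ivoct_config_error")
  }
  do.call(ivoct_config, raw[intersect(names(raw), known)])
}

#' Serialize a configuration to YAML
#'
#' [load_config()] of the written file reproduces the configuration
#' (round-trip identity).
#'
#' @param config An `ivoct_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ivoct_config"))
  ctors <- list(geometry = geometry_config, constants = physical_constants,
    clock = simulation_clock, scan = scan_protocol)
  plain <- lapply(setNames(names(config), names(config)), function(nm) {
    part <- lapply(unclass(config[[nm]]), function(x) {
      if (is.list(x)) unclass(x) else x
    })
    # derived fields are recomputed by the constructors on load
    if (nm %in% names(ctors)) part <- part[intersect(names(part), names(formals(ctors[[nm]])))]
    part
  })
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' Radial media stack
#'
#' Orders the optical media along an A-line: lumen (blood/saline mixture),
#' the three vessel-wall layers, and extramural tissue, as contiguous
#' half-open radial intervals `[r_min, r_max)` covering the span from the OCT
#' catheter wall to the outer extramural radius.
#'
#' @param geometry An [geometry_config()] object.
#' @return A tibble with columns `medium`, `r_min`, `r_max` (mm).
#' @export
radial_media_stack <- function(geometry) {
  validate_geometry(geometry)
  w <- geometry$wall_layer_thicknesses
  edges <- c(
    geometry$oct_catheter_radius,
    geometry$vessel_inner_radius,
    geometry$vessel_inner_radius + cumsum(w),
    geometry$extramural_outer_radius
  )
  tibble(
    medium = c("lumen", "intima", "media", "adventitia", "extramural"),
    r_min = edges[1:5],
    r_max = edges[2:6]
  )
}

#' @export
print.ivoct_config <- function(x, ...) {
  cat("<ivoct_config>\n")
  cat(sprintf("  geometry : vessel %.2f/%.2f mm, OCT catheter %.2f mm, guide %.2f/%.2f mm\n",
    x$geometry$vessel_inner_radius, x$geometry$vessel_outer_radius,
    x$geometry$oct_catheter_radius, x$geometry$guiding_catheter_inner_radius,
    x$geometry$guiding_catheter_outer_radius))
  cat(sprintf("  clock    : %d x %.2f s cycles (%.1f s), frame_dt %.3g s\n",
    x$clock$n_cycles, x$clock$cycle_period, x$clock$total_time, x$clock$frame_dt))
  cat(sprintf("  scan     : %.0f mm/s for %.2f s, CIF threshold %.2f\n",
    x$scan$pullback_speed, x$scan$scan_duration, x$scan$cif_threshold))
  cat(sprintf("  solver   : %s, dr %.3g mm, dz %.3g mm, dt %.3g s\n",
    x$solver$fidelity, x$solver$dr_mm, x$solver$dz_mm, x$solver$dt))
  invisible(x)
}
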