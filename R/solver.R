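#' Build the staggered solver grid
#'
#' Structured axisymmetric (r, z) finite-volume grid over the flow domain:
#' the annulus between the OCT catheter wall and the vessel inner wall, with
#' the guiding-catheter wall blocked out upstream of its outlet. Grid lines
#' must align with the catheter radii and the outlet plane so all walls are
#' honoured exactly.
#'
#' @param geometry An [geometry_config()].
#' @param dr_mm,dz_mm Cell sizes (mm).
#' @return A list describing the grid (SI spacings, cell centres in mm,
#'   solid mask, inlet cell classification).
#' @export
build_grid <- function(geometry, dr_mm = 0.05, dz_mm = 0.4) {
  g <- geometry
  spans <- c(
    g$guiding_catheter_inner_radius - g$oct_catheter_radius,
    g$guiding_catheter_outer_radius - g$guiding_catheter_inner_radius,
    g$vessel_inner_radius - g$guiding_catheter_outer_radius,
    g$guiding_catheter_outlet_z - g$blood_inlet_z,
    g$domain_z_max - g$guiding_catheter_outlet_z
  )
  steps <- c(dr_mm, dr_mm, dr_mm, dz_mm, dz_mm)
  bad <- abs(spans / steps - round(spans / steps)) > 1e-9
  if (any(bad)) {
    abort("grid error: dr_mm/dz_mm must divide the catheter radii spans and the axial segments",
      class = "ivoct_validation_error")
  }
  nr <- as.integer(round((g$vessel_inner_radius - g$oct_catheter_radius) / dr_mm))
  nz <- as.integer(round((g$domain_z_max - g$blood_inlet_z) / dz_mm))
  r_c <- g$oct_catheter_radius + (seq_len(nr) - 0.5) * dr_mm
  z_c <- g$blood_inlet_z + (seq_len(nz) - 0.5) * dz_mm
  solid <- matrix(0L, nr, nz)
  in_wall <- r_c > g$guiding_catheter_inner_radius &
    r_c < g$guiding_catheter_outer_radius
  upstream <- z_c < g$guiding_catheter_outlet_z
  solid[in_wall, upstream] <- 1L
  i_saline <- which(r_c < g$guiding_catheter_inner_radius)
  i_blood <- which(r_c > g$guiding_catheter_outer_radius)
  list(
    nr = nr, nz = nz,
    r0 = g$oct_catheter_radius * 1e-3, z0 = g$blood_inlet_z * 1e-3,
    dr = dr_mm * 1e-3, dz = dz_mm * 1e-3,
    r_c_mm = r_c, z_c_mm = z_c,
    r_c = r_c * 1e-3,
    solid = solid,
    i_saline = i_saline, i_blood = i_blood, i_wall = which(in_wall),
    area_saline = pi * ((g$guiding_catheter_inner_radius * 1e-3)^2 -
                        (g$oct_catheter_radius * 1e-3)^2),
    area_blood = pi * ((g$vessel_inner_radius * 1e-3)^2 -
                       (g$guiding_catheter_outer_radius * 1e-3)^2)
  )
}

# wall distance and mixing length per cell from the blocked-out geometry:
# within each radial fluid segment of a column, distance to the nearest
# no-slip radial wall and the segment half-width
grid_wall_geometry <- function(grid) {
  nr <- grid$nr; nz <- grid$nz
  y <- matrix(0, nr, nz); delta <- matrix(0, nr, nz)
  for (j in seq_len(nz)) {
    fluid <- grid$solid[, j] == 0L
    i <- 1L
    while (i <= nr) {
      if (!fluid[i]) { i <- i + 1L; next }
      a <- i
      while (i <= nr && fluid[i]) i <- i + 1L
      b <- i - 1L
      ii <- a:b
      dist_lo <- (ii - a + 0.5) * grid$dr
      dist_hi <- (b - ii + 0.5) * grid$dr
      y[ii, j] <- pmin(dist_lo, dist_hi)
      delta[ii, j] <- (b - a + 1) * grid$dr / 2
    }
  }
  list(y_wall = y, delta = delta,
    l_mix = pmin(0.41 * y, 0.09 * 2 * delta))
}

# cached sparse Cholesky factorization of the pressure Poisson operator
build_poisson <- function(grid) {
  nr <- grid$nr; nz <- grid$nz
  fluid <- grid$solid == 0L
  id <- matrix(0L, nr, nz)
  id[fluid] <- seq_len(sum(fluid))
  rf <- grid$r0 + (0:nr) * grid$dr         # face radii
  rc <- grid$r0 + ((1:nr) - 0.5) * grid$dr # cell radii
  nf <- sum(fluid)
  # radial neighbour pairs (duplicate triplets are summed by sparseMatrix)
  open_r <- fluid[-nr, , drop = FALSE] & fluid[-1, , drop = FALSE]
  pr <- id[-nr, , drop = FALSE][open_r]
  qr <- id[-1, , drop = FALSE][open_r]
  cr <- (matrix(rf[2:nr], nr - 1, nz) * grid$dz / grid$dr)[open_r]
  # axial neighbour pairs
  open_z <- fluid[, -nz, drop = FALSE] & fluid[, -1, drop = FALSE]
  pz <- id[, -nz, drop = FALSE][open_z]
  qz <- id[, -1, drop = FALSE][open_z]
  cz <- (matrix(rc, nr, nz - 1) * grid$dr / grid$dz)[open_z]
  # outlet Dirichlet (p = 0 at the last axial face)
  po <- id[fluid[, nz], nz]
  co <- rc[fluid[, nz]] * grid$dr / (grid$dz / 2)
  p_all <- c(pr, pz); q_all <- c(qr, qz); c_all <- c(cr, cz)
  A <- Matrix::sparseMatrix(
    i = c(p_all, q_all, p_all, q_all, po),
    j = c(q_all, p_all, p_all, q_all, po),
    x = c(-c_all, -c_all, c_all, c_all, co),
    dims = c(nf, nf)
  )
  list(chol = Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
    id = id, fluid = fluid, rf = rf, rc = rc)
}

#' Solve the blood-flushing problem
#'
#' Time-integrates the coupled axisymmetric incompressible flow and
#' erythrocyte transport in the vessel-catheter domain: pulsatile blood
#' enters through the outer annulus, saline is injected through the guiding
#' catheter, the outlet is held at zero pressure, and the erythrocyte mass
#' fraction is advected (dimension-split MUSCL), diffused (Stokes-Einstein
#' molecular diffusivity plus eddy diffusivity where a turbulence closure is
#' active), and coupled back through the mixture viscosity.
#'
#' Momentum uses semi-Lagrangian advection, implicit viscous diffusion and a
#' pressure projection with a constant reference density (the saline/blood
#' density contrast is 5.6%); fidelity levels select the turbulence
#' treatment: `"laminar"` (none), `"laminar_eddy"` (mixing-length eddy
#' viscosity with Van Driest near-wall damping; shipped default) or
#' `"rans_komega"` (two-equation k-omega closure).
#'
#' @param config An [ivoct_config()].
#' @param blood_waveform Blood inflow [flow_waveform()] (`NULL` for the
#'   calibrated default).
#' @param injection Saline injection [flow_waveform()] (`NULL` for no
#'   injection).
#' @param fidelity Turbulence treatment (see above).
#' @param t_end Simulation horizon (s); defaults to the clock's total time.
#' @param snapshot_dt Snapshot interval (s); defaults to the frame interval.
#' @param verbose Print progress every simulated second.
#' @return An `ivoct_flush` object: haematocrit snapshots on the grid, wall
#'   shear/normal stress profiles per snapshot, a mass-balance audit, and
#'   the final flow state. Usable directly with [haematocrit_at()],
#'   [run_scan()], [wall_stress()] and [mass_balance_report()].
#' @export
solve_flushing <- function(config = ivoct_config(),
                           blood_waveform = NULL,
                           injection = NULL,
                           fidelity = c("laminar_eddy", "laminar", "rans_komega"),
                           t_end = NULL,
                           snapshot_dt = NULL,
                           verbose = FALSE) {
  fidelity <- match.arg(fidelity)
  geo <- config$geometry
  cst <- config$constants
  if (is.null(blood_waveform)) blood_waveform <- blood_inflow_waveform(constants = cst)
  if (is.null(t_end)) t_end <- config$clock$total_time
  if (is.null(snapshot_dt)) snapshot_dt <- config$solver$snapshot_dt %||% config$clock$frame_dt

  grid <- build_grid(geo, config$solver$dr_mm, config$solver$dz_mm)
  wallgeo <- grid_wall_geometry(grid)
  pois <- build_poisson(grid)
  nr <- grid$nr; nz <- grid$nz
  dt <- config$solver$dt
  rho_ref <- mean(c(cst$saline_density, cst$whole_blood_density))
  rho_e <- erythrocyte_density(cst$whole_blood_density, cst$saline_density,
    cst$whole_blood_haematocrit)
  w_blood <- mass_fraction_from_haematocrit(cst$whole_blood_haematocrit,
    rho_e, cst$saline_density)

  fluid <- grid$solid == 0L
  ur <- matrix(0, nr + 1, nz)
  uz <- matrix(0, nr, nz + 1)
  w <- matrix(w_blood, nr, nz); w[!fluid] <- 0
  p_mat <- matrix(0, nr, nz)
  # k-omega state
  kturb <- matrix(1e-6, nr, nz); omg <- matrix(100, nr, nz)

  # face masks: radial faces open iff both neighbouring cells are fluid
  ur_open <- matrix(FALSE, nr + 1, nz)
  ur_open[2:nr, ] <- fluid[1:(nr - 1), ] & fluid[2:nr, ]
  uz_open <- matrix(FALSE, nr, nz + 1)
  uz_open[, 2:nz] <- fluid[, 1:(nz - 1)] & fluid[, 2:nz]
  uz_open[, nz + 1] <- fluid[, nz]
  w_inlet <- rep(0, nr)
  w_inlet[grid$i_blood] <- w_blood

  n_steps <- as.integer(round(t_end / dt))
  snap_every <- max(1L, as.integer(round(snapshot_dt / dt)))
  n_snap <- floor(n_steps / snap_every) + 1L
  w_snap <- array(NA_real_, c(nr, nz, n_snap))
  shear_snap <- matrix(NA_real_, nz, n_snap)
  normal_snap <- matrix(NA_real_, nz, n_snap)
  snap_times <- numeric(n_snap)
  cell_vol <- matrix(grid$r_c, nr, nz) * grid$dr * grid$dz # per unit angle
  mass_of <- function(wm) sum(wm[fluid] * cell_vol[fluid])
  audit <- matrix(0, n_steps, 4L) # time, mass, influx, outflux

  mu_of <- function(wm) {
    # property evaluation tolerates the advection limiter's small over/undershoot
    xe <- haematocrit_from_mass_fraction(pmin(pmax(wm, 0), 1),
      rho_e, cst$saline_density)
    list(xe = xe, mu = mixture_viscosity(xe, cst$plasma_viscosity))
  }
  record_snapshot <- function(k, t_now, mu_mat) {
    w_snap[, , k] <<- w
    snap_times[k] <<- t_now
    # second-order one-sided gradient at the wall through the two nearest
    # cell-centre velocities (parabolic fit with the no-slip wall value)
    u1 <- 0.5 * (uz[nr, 1:nz] + uz[nr, 2:(nz + 1)])
    u2 <- 0.5 * (uz[nr - 1, 1:nz] + uz[nr - 1, 2:(nz + 1)])
    shear_snap[, k] <<- mu_mat[nr, ] * (9 * u1 - u2) / (3 * grid$dr)
    normal_snap[, k] <<- p_mat[nr, ]
  }
  mm <- mu_of(w)
  record_snapshot(1L, 0, mm$mu)

  for (n in seq_len(n_steps)) {
    t_new <- n * dt
    qs <- if (is.null(injection)) 0 else waveform_at(injection, t_new) * 1e-6
    qb <- waveform_at(blood_waveform, t_new) * 1e-6
    u_in <- rep(0, nr)
    u_in[grid$i_saline] <- qs / grid$area_saline
    u_in[grid$i_blood] <- qb / grid$area_blood

    # --- momentum: semi-Lagrangian advection
    adv <- sl_advect_cpp(ur, uz, dt, grid$r0, grid$z0, grid$dr, grid$dz)
    ur <- adv$ur; uz <- adv$uz
    ur[!ur_open] <- 0
    uz[, 1] <- u_in
    uz[, 2:(nz + 1)][!uz_open[, 2:(nz + 1)]] <- 0

    # incremental pressure correction: apply the previous pressure force
    # before the implicit viscous solve so the stiff wall terms see it, then
    # project only the pressure increment (keeps the steady momentum balance
    # free of the splitting error at walls)
    gradr <- (p_mat[2:nr, ] - p_mat[1:(nr - 1), ]) / grid$dr
    ur[2:nr, ] <- ur[2:nr, ] - (dt / rho_ref) * gradr * ur_open[2:nr, ]
    gradz <- (p_mat[, 2:nz] - p_mat[, 1:(nz - 1)]) / grid$dz
    uz[, 2:nz] <- uz[, 2:nz] - (dt / rho_ref) * gradz * uz_open[, 2:nz]
    uz[, nz + 1] <- uz[, nz + 1] - (dt / rho_ref) *
      (0 - p_mat[, nz]) / (grid$dz / 2) * uz_open[, nz + 1]

    # --- effective viscosity
    mm <- mu_of(w)
    nu_mol <- mm$mu / rho_ref
    nu_t <- matrix(0, nr, nz)
    if (fidelity == "laminar_eddy") {
      S <- strain_rate_cpp(ur, uz, grid$r0, grid$dr, grid$dz, grid$solid)
      yplus <- wallgeo$y_wall * sqrt(pmax(S, 0) / nu_mol)
      damp <- (1 - exp(-yplus / 26))^2
      nu_t <- damp * wallgeo$l_mix^2 * S
    } else if (fidelity == "rans_komega") {
      S <- strain_rate_cpp(ur, uz, grid$r0, grid$dr, grid$dz, grid$solid)
      ko <- komega_step(kturb, omg, S, ur, uz, nu_mol, grid, wallgeo, dt)
      kturb <- ko$k; omg <- ko$omega; nu_t <- ko$nu_t
    }
    nu_eff <- nu_mol + nu_t
    nu_eff[!fluid] <- 0

    # --- implicit viscous diffusion
    vd <- visc_diffuse_cpp(ur, uz, nu_eff, dt, grid$r0, grid$dr, grid$dz,
      grid$solid)
    ur <- vd$ur; uz <- vd$uz
    ur[!ur_open] <- 0
    uz[, 1] <- u_in
    uz[, nz + 1] <- uz[, nz] * uz_open[, nz + 1]

    # --- projection of the pressure increment
    div <- (pois$rf[2:(nr + 1)] * ur[2:(nr + 1), ] -
            pois$rf[1:nr] * ur[1:nr, ]) * grid$dz +
           (uz[, 2:(nz + 1)] - uz[, 1:nz]) * pois$rc * grid$dr
    rhs <- -(rho_ref / dt) * div[pois$fluid]
    phi <- matrix(0, nr, nz)
    phi[pois$fluid] <- as.numeric(Matrix::solve(pois$chol, rhs))
    gradr <- (phi[2:nr, ] - phi[1:(nr - 1), ]) / grid$dr
    ur[2:nr, ] <- ur[2:nr, ] - (dt / rho_ref) * gradr * ur_open[2:nr, ]
    gradz <- (phi[, 2:nz] - phi[, 1:(nz - 1)]) / grid$dz
    uz[, 2:nz] <- uz[, 2:nz] - (dt / rho_ref) * gradz * uz_open[, 2:nz]
    uz[, nz + 1] <- uz[, nz + 1] - (dt / rho_ref) *
      (0 - phi[, nz]) / (grid$dz / 2) * uz_open[, nz + 1]
    p_mat <- p_mat + phi
    p_mat[!pois$fluid] <- 0

    # --- species transport
    cfl <- max(max(abs(ur)) / grid$dr, max(abs(uz)) / grid$dz) * dt
    nsub <- max(1L, as.integer(ceiling(cfl / 0.8)))
    sp <- species_advect_cpp(w, ur, uz, dt, nsub, grid$r0, grid$dr, grid$dz,
      grid$solid, w_inlet)
    w <- sp$w
    d_mol <- diffusion_coefficient(mm$xe, cst$body_temperature_T,
      cst$plasma_viscosity, cst$rbc_volume, cst$boltzmann_k)
    d_eff <- d_mol + nu_t / 0.7
    w <- scalar_adi_cpp(w, d_eff, dt, grid$r0, grid$dr, grid$dz, grid$solid)

    audit[n, ] <- c(t_new, mass_of(w), sp$influx, sp$outflux)
    if (n %% snap_every == 0L) {
      record_snapshot(n %/% snap_every + 1L, t_new, mm$mu)
    }
    if (verbose && n %% as.integer(round(1 / dt)) == 0L) {
      message(sprintf("t = %.2f s  max|u| = %.3f m/s  lumen <X_e> = %.4f",
        t_new, max(abs(uz)), mean(mm$xe[fluid])))
    }
    if (!all(is.finite(uz))) {
      abort(sprintf("solver divergence at t = %.4f s: non-finite velocity", t_new),
        class = "ivoct_solver_error")
    }
  }

  structure(
    list(
      grid = grid, geometry = geo, fidelity = fidelity,
      times = snap_times, w = w_snap,
      wall_shear = shear_snap, wall_normal = normal_snap,
      audit = tibble(
        time = audit[, 1], mass = audit[, 2],
        influx = audit[, 3], outflux = audit[, 4],
        mass0 = mass_of(w_snap[, , 1])
      ),
      rho_e = rho_e, saline_density = cst$saline_density,
      final = list(ur = ur, uz = uz, p = p_mat),
      dt = dt
    ),
    class = "ivoct_flush"
  )
}

# one k-omega update (Wilcox-style two-equation closure, semi-implicit
# destruction, omega wall condition applied as a near-wall floor)
komega_step <- function(k, omega, S, ur, uz, nu_mol, grid, wallgeo, dt,
                        beta_star = 0.09, beta = 0.075, alpha = 5 / 9,
                        sigma = 0.5) {
  solid <- grid$solid
  nu_t <- pmin(pmax(k, 0) / pmax(omega, 1e-3), 1e-3)
  k <- scalar_sl_cpp(k, ur, uz, dt, grid$r0, grid$z0, grid$dr, grid$dz, solid)
  omega <- scalar_sl_cpp(omega, ur, uz, dt, grid$r0, grid$z0, grid$dr,
    grid$dz, solid)
  k <- scalar_adi_cpp(k, nu_mol + sigma * nu_t, dt, grid$r0, grid$dr,
    grid$dz, solid)
  omega <- scalar_adi_cpp(omega, nu_mol + sigma * nu_t, dt, grid$r0,
    grid$dr, grid$dz, solid)
  pk <- nu_t * S^2
  k <- (k + dt * pk) / (1 + dt * beta_star * pmax(omega, 0))
  omega <- (omega + dt * alpha * S^2) / (1 + dt * beta * pmax(omega, 0))
  # near-wall: omega -> 6 nu / (beta y^2) as y -> 0
  om_wall <- 6 * nu_mol / (beta * pmax(wallgeo$y_wall, grid$dr / 2)^2)
  near <- wallgeo$y_wall <= grid$dr
  omega[near] <- pmax(omega[near], om_wall[near])
  k <- pmax(k, 0)
  omega <- pmax(omega, 1e-2)
  list(k = k, omega = omega, nu_t = pmin(k / omega, 1e-3))
}

#' @export
haematocrit_at.ivoct_flush <- function(field, z, t) {
  zr <- range(field$grid$z_c_mm)
  if (z < field$grid$z_c_mm[1] - field$grid$dz * 1e3 ||
      z > zr[2] + field$grid$dz * 1e3) {
    abort(sprintf("positioning error: lens z = %.1f mm outside domain [%.1f, %.1f]",
      z, zr[1], zr[2]), class = "ivoct_domain_error")
  }
  kt <- which.min(abs(field$times - t))
  zc <- field$grid$z_c_mm
  j <- findInterval(z, zc, all.inside = TRUE)
  frac <- (z - zc[j]) / (zc[j + 1] - zc[j])
  frac <- min(max(frac, 0), 1)
  wcol <- (1 - frac) * field$w[, j, kt] + frac * field$w[, j + 1, kt]
  xe <- haematocrit_from_mass_fraction(pmin(pmax(wcol, 0), 1),
    field$rho_e, field$saline_density)
  data.frame(r = field$grid$r_c_mm, haematocrit = xe)
}

#' @export
field_horizon.ivoct_flush <- function(field) max(field$times)

#' @export
print.ivoct_flush <- function(x, ...) {
  cat(sprintf("<ivoct_flush: %s, %d x %d grid, %d snapshots to %.2f s>\n",
    x$fidelity, x$grid$nr, x$grid$nz, length(x$times), max(x$times)))
  invisible(x)
}

#' Wall shear and normal stress profile
#'
#' Stress exerted by the fluid on the vessel inner wall at the snapshot
#' closest to `time`: shear from the one-sided near-wall axial velocity
#' gradient with the local effective viscosity (positive pointing
#' downstream, +z), and normal stress as the local (gauge) pressure,
#' compression positive.
#'
#' @param flush An [solve_flushing()] result.
#' @param time Requested time (s).
#' @return A tibble with columns `z` (mm), `shear` (Pa), `normal` (Pa),
#'   `time` (s; the snapshot actually used).
#' @export
wall_stress <- function(flush, time) {
  k <- which.min(abs(flush$times - time))
  tibble(
    z = flush$grid$z_c_mm,
    shear = flush$wall_shear[, k],
    normal = flush$wall_normal[, k],
    time = flush$times[k]
  )
}

#' Erythrocyte mass-balance audit
#'
#' Per solver step, the mismatch between the change of the total transported
#' erythrocyte content and the net advective boundary transport, normalized
#' by the characteristic boundary mass rate (the largest boundary flux seen
#' during the run, falling back to initial mass over total time for closed
#' boxes). The advection and diffusion schemes are conservative in exact
#' arithmetic, so this audits discrete bookkeeping and roundoff.
#'
#' @param flush An [solve_flushing()] result.
#' @return A tibble with columns `time`, `error` (relative, per step).
#' @export
mass_balance_report <- function(flush) {
  a <- flush$audit
  dm <- diff(c(a$mass0[1], a$mass))
  net <- a$influx - a$outflux
  char_rate <- max(abs(a$influx), abs(a$outflux))
  if (char_rate <= 0) char_rate <- a$mass0[1] / max(a$time)
  tibble(time = a$time, error = abs(dm - net) / char_rate)
}
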