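test_that("grid construction honours walls and inlet layout", {
  grid <- build_grid(geometry_config(), 0.05, 0.4)
  expect_equal(grid$nr, 31L)
  expect_equal(grid$nz, 250L)
  # guiding catheter wall blocked upstream of its outlet only
  expect_true(all(grid$solid[grid$i_wall, grid$z_c_mm < 0] == 1L))
  expect_true(all(grid$solid[, grid$z_c_mm > 0] == 0L))
  expect_equal(length(grid$i_saline), 9L)
  expect_equal(length(grid$i_blood), 20L)
  expect_error(build_grid(geometry_config(), 0.07, 0.4),
    class = "ivoct_validation_error")
})

test_that("quiescent equilibrium is preserved exactly", {
  cfg <- poiseuille_config()
  zero <- flow_waveform(c(0, 1), c(0, 0), kind = "blood")
  fl <- solve_flushing(cfg, blood_waveform = zero, injection = NULL,
    fidelity = "laminar", t_end = 0.05, snapshot_dt = 0.05)
  expect_equal(max(abs(fl$final$uz)), 0)
  expect_equal(max(abs(fl$final$ur)), 0)
  w0 <- mass_fraction_from_haematocrit(0.45)
  wk <- fl$w[, , dim(fl$w)[3]]
  expect_equal(max(abs(wk[fl$grid$solid == 0] - w0)), 0)
  # closed box: mass-balance drift is pure roundoff
  expect_lt(max(mass_balance_report(fl)$error), 1e-6)
  # quiescent wall stress: zero shear, reference (zero-gauge) pressure
  ws <- wall_stress(fl, 0.05)
  expect_equal(max(abs(ws$shear)), 0)
  expect_equal(max(abs(ws$normal)), 0)
})

test_that("developed annular flow matches the Poiseuille oracle", {
  fl <- cached("poiseuille_fine", steady_annular_flow(0.35, dr_mm = 0.05))
  grid <- fl$grid
  j <- which.min(abs(grid$z_c_mm - 30))
  uz_num <- 0.5 * (fl$final$uz[, j] + fl$final$uz[, j + 1])
  mu <- mixture_viscosity(0.45)
  ora <- annular_poiseuille(grid$r_c, 0.35e-6, 0.45e-3, 2.0e-3, mu)
  l2 <- sqrt(sum((uz_num - ora$u)^2) / sum(ora$u^2))
  expect_lt(l2, 0.02)
  # analytic wall shear recovered from the near-wall gradient
  ws <- wall_stress(fl, max(fl$times))
  expect_equal(abs(ws$shear[j]), ora$wall_shear, tolerance = 0.03)
})

test_that("Poiseuille error decreases under space-time refinement", {
  # radial alignment with the catheter radii fixes the admissible dr values,
  # so refinement acts jointly on the axial step and the time step (the
  # splitting error is first order in dt and dominates at the default grid)
  err_coarse <- poiseuille_l2_error(
    steady_annular_flow(0.35, dz_mm = 0.8, dt = 2e-3, t_end = 2.0))
  err_fine <- poiseuille_l2_error(
    steady_annular_flow(0.35, dz_mm = 0.4, dt = 5e-4, t_end = 2.0))
  expect_lt(err_fine, 0.75 * err_coarse)
})

test_that("species field stays bounded and is driven out by sustained injection", {
  cfg <- poiseuille_config()
  # steady low blood inflow so the flush-out is monotone once saline arrives
  blood <- flow_waveform(c(0, 2), c(0.3, 0.3), kind = "blood")
  inj <- build_continuous(4.5, 0.2, 1.4)
  fl <- solve_flushing(cfg, blood_waveform = blood, injection = inj,
    t_end = 1.4, snapshot_dt = 0.05)
  w0 <- mass_fraction_from_haematocrit(0.45)
  fluid <- fl$grid$solid == 0
  expect_gt(min(fl$w[, , dim(fl$w)[3]][fluid]), -1e-3)
  expect_lt(max(fl$w[, , dim(fl$w)[3]][fluid]), w0 + 1e-3)
  # lumen-average haematocrit decreases monotonically once saline arrives
  lumen <- fl$grid$z_c_mm > 2
  means <- vapply(seq_along(fl$times), function(k) {
    mean(fl$w[, lumen, k][fl$grid$solid[, lumen] == 0])
  }, numeric(1))
  late <- fl$times >= 0.5 & fl$times <= 1.2
  expect_true(all(diff(means[late]) < 1e-4))
  expect_lt(means[length(means)], 0.2 * w0)
  # conservation audit under strong through-flow
  expect_lt(max(mass_balance_report(fl)$error), 1e-2)
})

test_that("k-omega fidelity runs stably with admissible turbulence fields", {
  cfg <- poiseuille_config()
  blood <- blood_inflow_waveform()
  inj <- build_continuous(4.5, 0.05, 0.4)
  fl <- solve_flushing(cfg, blood_waveform = blood, injection = inj,
    fidelity = "rans_komega", t_end = 0.15, snapshot_dt = 0.05)
  expect_true(all(is.finite(fl$final$uz)))
  expect_true(all(is.finite(fl$final$ur)))
  expect_true(all(is.finite(fl$w[, , dim(fl$w)[3]])))
})
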