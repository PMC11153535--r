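geo <- geometry_config()
proto <- scan_protocol()

test_that("scan protocol arithmetic and validation", {
  expect_equal(proto$n_frames, 251L)
  expect_equal(proto$pullback_length, 50)
  expect_equal(proto$frame_spacing, 0.2)
  expect_error(scan_protocol(f1 = 0.6, f2 = 0.3),
    class = "ivoct_validation_error")
  expect_error(scan_protocol(cif_threshold = 1.2),
    class = "ivoct_validation_error")
})

test_that("frame M_w matches the closed-form lumen attenuation", {
  expect_equal(frame_mw(make_fixture("uniform", x_e = 0), 30, geo, 0), 1)
  expect_equal(frame_mw(make_fixture("uniform", x_e = 0.45), 30, geo, 0),
    exp(-fluid_coefficients(0.45)$phi_t * 1.55), tolerance = 1e-6)
  expect_equal(frame_mw(make_fixture("uniform", x_e = 0.225), 30, geo, 0),
    exp(-0.8013 * 1.55), tolerance = 1e-4)
})

test_that("pull-back trigger fires at the first threshold crossing", {
  s <- tibble::tibble(time = c(0, 0.01, 0.02, 0.03),
    m_w = c(0.1, 0.5, 0.8, 0.9))
  expect_equal(pullback_trigger(s, 0.75), 0.02)
  expect_equal(pullback_trigger(s, 0.75), 0.02) # idempotent
  s1 <- tibble::tibble(time = 0:3 * 0.01, m_w = rep(1, 4))
  expect_equal(pullback_trigger(s1, 0.75), 0)
  s0 <- tibble::tibble(time = 0:3 * 0.01, m_w = rep(0.5, 4))
  expect_error(pullback_trigger(s0, 0.75), class = "ivoct_no_trigger_error")
})

test_that("run_scan produces the documented frame kinematics", {
  f <- make_fixture("uniform", x_e = 0)
  sc <- run_scan(f, proto, geo, start_time = 1)
  expect_equal(nrow(sc), 251L)
  expect_equal(diff(sc$lens_z)[1], -0.2)
  expect_equal(sc$lens_z[1] - sc$lens_z[251], 50)
  expect_true(all(diff(sc$lens_z) < 0)) # strictly monotone pull-back
  # degenerate protocols
  still <- scan_protocol(pullback_speed = 0)
  sc0 <- run_scan(f, still, geo, start_time = 1)
  expect_true(all(sc0$lens_z == 60))
  coarse <- scan_protocol(frame_dt = 2.5)
  sc2 <- run_scan(f, coarse, geo, start_time = 1)
  expect_equal(nrow(sc2), 2L)
  expect_equal(sc2$lens_z, c(60, 10))
})

test_that("CIL counts clear frames times spacing, capped at the pull-back length", {
  f0 <- make_fixture("uniform", x_e = 0)
  sc <- run_scan(f0, proto, geo, start_time = 1)
  expect_equal(cil(sc), 50) # 251 x 0.2 capped at L
  scb <- run_scan(make_fixture("uniform", x_e = 0.45), proto, geo, 1)
  expect_equal(cil(scb), 0)
  fake <- tibble::tibble(cif = rep(c(TRUE, FALSE), length.out = 251))
  expect_equal(cil(fake, spacing = 0.2, cap = 50), 126 * 0.2) # alternating CIF
  # CIL / L equals the CIF fraction when no cap binds
  expect_equal(cil(fake, spacing = 0.2, cap = Inf) / 50.2, mean(fake$cif))
})

test_that("gamma combines mean clarity and consistency as documented", {
  const1 <- tibble::tibble(m_w = rep(1, 251))
  expect_equal(scan_gamma(const1)$gamma, 1)
  m <- 0.6
  expect_equal(scan_gamma(tibble::tibble(m_w = rep(m, 10)))$gamma,
    0.7 * m + 0.3)
  bern <- tibble::tibble(m_w = rep(c(0, 1), each = 100))
  g <- scan_gamma(bern)
  expect_equal(g$mean_mw, 0.5)
  expect_equal(g$sigma, 0.25)
  expect_equal(g$gamma, 0.35)
  expect_error(scan_gamma(tibble::tibble(m_w = numeric(0))),
    class = "ivoct_domain_error")
  expect_error(scan_gamma(const1, f1 = 0.5, f2 = 0.4),
    class = "ivoct_domain_error")
})

test_that("gamma stays in [0,1] with variance at most 0.25 on random series", {
  set.seed(123)
  for (k in seq_len(10000)) {
    n <- sample(1:40, 1)
    g <- scan_gamma(list(m_w = runif(n)))
    if (g$sigma > 0.25 || g$gamma < 0 || g$gamma > 1) {
      fail(sprintf("bounds violated: sigma=%g gamma=%g", g$sigma, g$gamma))
    }
  }
  succeed()
})

test_that("gamma is monotone under pointwise increase of a below-mean frame", {
  set.seed(99)
  for (k in 1:200) {
    m <- runif(sample(5:50, 1))
    i <- which.min(m)
    m2 <- m
    m2[i] <- min(m[i] + runif(1, 0, mean(m) - m[i]), 1)
    expect_gte(scan_gamma(list(m_w = m2))$gamma,
      scan_gamma(list(m_w = m))$gamma - 1e-12)
  }
})

test_that("scan_summary bundles quality, CIL and dosage", {
  f <- make_fixture("uniform", x_e = 0.45)
  sc <- run_scan(f, proto, geo, start_time = 1)
  summ <- scan_summary(sc, NULL, horizon = 7.2, scheme = "none")
  expect_equal(summ$dosage_ml, 0)
  expect_equal(summ$mean_mw, 0.1575, tolerance = 1e-3)
  expect_equal(summ$gamma, 0.7 * summ$mean_mw + 0.3, tolerance = 1e-6)
  summ2 <- scan_summary(sc, build_continuous(), horizon = 7.2)
  expect_equal(summ2$dosage_ml, 14.4)
})
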