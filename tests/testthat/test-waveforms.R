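test_that("continuous schedule integrates to the rectangle volume", {
  wf <- build_continuous(4.5, 0.8, 4.0)
  expect_equal(dosage(wf, 7.2), 14.4, tolerance = 1e-9)
  expect_equal(dosage(build_continuous(9.0, 0.8, 4.0), 7.2), 28.8,
    tolerance = 1e-9) # linear in amplitude
  expect_equal(nrow(build_continuous(4.5, 1, 1)), 0)
  expect_equal(dosage(build_continuous(4.5, 1, 1), 7.2), 0)
  expect_error(build_continuous(-1), class = "ivoct_domain_error")
})

test_that("intermittent schedule has the power-law per-cycle volume", {
  wf <- build_intermittent(4.5, 0.8, cycles = 2:5)
  expect_equal(dosage(wf, 7.2), 8.0, tolerance = 1e-3)
  # one cycle, triangular (a = 1)
  tri <- build_intermittent(5.0, 1, cycles = 2)
  expect_equal(dosage(tri, 7.2), 2.0, tolerance = 1e-6)
  # per-cycle volume peak*0.8/(a+1): instant rise (a -> 0) approaches the
  # rectangle volume, a sharp late spike (large a) approaches zero
  expect_gt(dosage(build_intermittent(4.5, 0.01, cycles = 2), 7.2),
    0.98 * 4.5 * 0.8)
  expect_lt(dosage(build_intermittent(4.5, 60, cycles = 2), 7.2),
    0.05 * 4.5 * 0.8)
  expect_error(build_intermittent(ramp_exponent = 0), class = "ivoct_domain_error")

  # per-cycle volume formula vs brute-force quadrature on random parameters
  set.seed(7)
  for (k in 1:50) {
    peak <- runif(1, 1, 10); a <- runif(1, 0.3, 3)
    brute <- 2 * stats::integrate(function(t) peak * (t / 0.4)^a, 0, 0.4,
      rel.tol = 1e-10)$value
    expect_equal(peak * 0.8 / (a + 1), brute, tolerance = 1e-6)
  }
})

test_that("dosage is additive over windows and errors beyond support", {
  w1 <- build_intermittent(4.5, 0.8, cycles = 2)
  w2 <- build_intermittent(4.5, 0.8, cycles = 4)
  w12 <- build_intermittent(4.5, 0.8, cycles = c(2, 4))
  expect_equal(dosage(w12, 7.2), dosage(w1, 7.2) + dosage(w2, 7.2))
  expect_equal(dosage(flow_waveform(numeric(0), numeric(0)), 7.2), 0)
  # horizon beyond a still-flowing waveform is an extrapolation error
  ramp <- flow_waveform(c(0, 1), c(0, 2))
  expect_error(dosage(ramp, 2), class = "ivoct_domain_error")
})

test_that("blood waveform is periodic, triphasic, and Reynolds-calibrated", {
  bw <- blood_inflow_waveform()
  t <- seq(0, 0.8, by = 0.001)
  expect_equal(waveform_at(bw, t), waveform_at(bw, t + 0.8), tolerance = 1e-12)
  expect_gt(mean(waveform_at(bw, t)), 0)
  expect_lt(min(bw$flow), 0) # early-diastolic reverse lobe
  expect_equal(max(abs(waveform_at(blood_inflow_waveform(peak_rate = 0), t))), 0)

  re_max <- reynolds_number(max(bw$flow), 4, 1056, mixture_viscosity(0.45))
  expect_equal(re_max, 770, tolerance = 0.02)
  re_comb <- reynolds_number(max(bw$flow) + 4.5, 4, 1000, 9e-4)
  expect_equal(re_comb, 3092, tolerance = 0.05)
  expect_equal(reynolds_number(0, 4, 1056, 1.9e-3), 0)
  expect_error(reynolds_number(1, 0, 1000, 1e-3), class = "ivoct_domain_error")
})

test_that("Peclet number shows the advection-dominated regime", {
  u_peak <- (calibrated_blood_peak() + 4.5) * 1e-6 /
    (pi * (0.002^2 - 0.00045^2))
  pe <- peclet_number(u_peak, 0.004, 9.08e-14)
  expect_gt(pe, 1e10)
  expect_lt(pe, 1e12)
  expect_equal(peclet_number(0, 0.004, 9.08e-14), 0)
  expect_equal(peclet_number(2 * u_peak, 0.004, 9.08e-14), 2 * pe)
  expect_error(peclet_number(1, 1, 0), class = "ivoct_domain_error")
})

test_that("waveforms round-trip through CSV", {
  wf <- build_intermittent()
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  back <- read_waveform_csv(path, kind = "intermittent", nonnegative = TRUE)
  expect_equal(back$time, wf$time)
  expect_equal(back$flow, wf$flow)
})
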