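geo <- geometry_config()

test_that("fluid coefficients follow the haematocrit scaling laws", {
  wb <- fluid_coefficients(0.45)
  expect_equal(wb$phi_t, 1.1925, tolerance = 1e-4)
  z <- fluid_coefficients(0)
  expect_equal(c(z$phi_a, z$phi_s, z$phi_t), c(0, 0, 0))
  half <- fluid_coefficients(0.225)
  expect_equal(half$phi_t,
    0.225 / 0.45 * 0.19 + 0.775 / 0.55 * 0.5 * 45.36 * (1 - 0.9779),
    tolerance = 1e-12)
  expect_equal(half$phi_t, 0.8013, tolerance = 1e-4)
  expect_error(fluid_coefficients(1.5), class = "ivoct_domain_error")
})

test_that("tissue coefficients come from the tabulated layer values", {
  expect_equal(tissue_coefficients("intima")[, c("phi_t", "phi_b")],
    tibble::tibble(phi_t = 0.67, phi_b = 0.73))
  expect_equal(tissue_coefficients("extramural")$phi_t, 0.5)
  expect_equal(tissue_coefficients("extramural")$phi_b, 0.5)
  expect_equal(tissue_coefficients("adventitia")$phi_b, 0.68)
  expect_equal(tissue_coefficients("media")$phi_t, 0.48)
  expect_error(tissue_coefficients("epidermis"), class = "ivoct_domain_error")
})

test_that("propagation matches the closed-form single-medium attenuation", {
  al <- propagate(medium_profile(geo, 0.45))
  phi <- fluid_coefficients(0.45)$phi_t
  expect_equal(attr(al, "M_w"), exp(-phi * 1.55), tolerance = 1e-6)
  # vacuum: all-zero coefficients
  prof <- medium_profile(geo, 0)
  prof$phi_t[] <- 0; prof$phi_b[] <- 0
  v <- propagate(prof)
  expect_true(all(v$M == 1))
  expect_true(all(v$I == 0))
  # all-saline lumen: M constant across the lumen, decreasing beyond
  sal <- propagate(medium_profile(geo, 0))
  lum <- sal$r <= 2.0
  expect_true(all(sal$M[lum] == 1))
  expect_true(all(diff(sal$M[!lum]) < 0))
})

test_that("homogeneous-segment attenuation agrees to 1e-6 with Richardson check", {
  for (dr in c(0.005, 0.0025)) {
    al <- propagate(medium_profile(geo, 0.3, dr = dr))
    phi <- fluid_coefficients(0.3)$phi_t
    lum <- al$r <= 2.0
    expect_equal(al$M[lum], exp(-phi * (al$r[lum] - 0.45)), tolerance = 1e-6)
  }
})

test_that("M is non-increasing and starts at 1; single-pass energy bookkeeping closes", {
  for (xe in c(0, 0.2, 0.45)) {
    al <- propagate(medium_profile(geo, xe))
    expect_equal(al$M[1], 1)
    expect_true(all(diff(al$M) <= 1e-15))
  }
  # int phi_t e^{-int phi_t} dr = 1 - M(end) (single-pass energy account)
  prof <- medium_profile(geo, 0.45)
  al <- propagate(prof)
  n <- nrow(prof)
  integrand <- prof$phi_t * al$M
  lhs <- sum(diff(prof$r) * (integrand[-1] + integrand[-n]) / 2)
  expect_equal(lhs, 1 - al$M[n], tolerance = 1e-4)
})

test_that("propagation is local-composition consistent under splitting", {
  prof <- medium_profile(geo, function(r) 0.45 * exp(-(r - 0.45)))
  al <- propagate(prof)
  cut <- which.min(abs(prof$r - 1.5))
  prof2 <- prof[cut:nrow(prof), ]
  attr(prof2, "vessel_inner_radius") <- 2.0
  al2 <- propagate(prof2, E0 = al$E[cut])
  expect_equal(al2$E, al$E[cut:nrow(prof)], tolerance = 1e-12)
})

test_that("normalization and grayscale follow the linear map with banker's rounding", {
  expect_equal(i_max(1), 1.1925, tolerance = 1e-4)
  expect_equal(i_max(3), 3 * i_max(1))
  expect_equal(i_max(1, alpha = 0), 0)
  im <- i_max(1)
  expect_equal(grayscale(im, im), 255L)
  expect_equal(grayscale(0, im), 0L)
  expect_equal(grayscale(im / 2, im), 128L) # round-half-to-even on 127.5
  expect_equal(grayscale(2 * im, im), 255L) # clipped
  expect_error(grayscale(1, 0), class = "ivoct_domain_error")
})
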