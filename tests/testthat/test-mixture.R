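test_that("erythrocyte density inverts the volume-weighted mixing law", {
  expect_equal(erythrocyte_density(1056, 1000, 0.45), 1124.4, tolerance = 5e-5)
  expect_equal(erythrocyte_density(1000, 1000, 0.45), 1000)
  expect_equal(erythrocyte_density(1056, 1000, 1.0), 1056)
  expect_error(erythrocyte_density(1056, 1000, 0), class = "ivoct_domain_error")
})

test_that("Einstein viscosity law and haematocrit/mass-fraction conversion", {
  expect_equal(mixture_viscosity(0, 9e-4), 9e-4)
  expect_equal(mixture_viscosity(0.45, 9e-4), 1.9125e-3)
  mu_p <- runif(5, 5e-4, 2e-3)
  expect_equal(mixture_viscosity(0.45, mu_p) / mu_p, rep(2.125, 5))
  expect_error(mixture_viscosity(-0.1), class = "ivoct_domain_error")

  expect_equal(mass_fraction_from_haematocrit(0.45), 0.479, tolerance = 1e-3)
  expect_equal(mass_fraction_from_haematocrit(0), 0)
  expect_equal(mass_fraction_from_haematocrit(1), 1)
  # algebraic inverse on a grid
  xe <- seq(0, 1, length.out = 100)
  expect_equal(
    haematocrit_from_mass_fraction(mass_fraction_from_haematocrit(xe)),
    xe, tolerance = 1e-12)
})

test_that("RBC equivalent diameter follows the cube-root law", {
  expect_equal(rbc_equivalent_diameter(90), 5.56e-6, tolerance = 2e-3)
  expect_equal(rbc_equivalent_diameter(pi / 6), 1.0e-6)
  expect_equal(rbc_equivalent_diameter(180) / rbc_equivalent_diameter(90),
    2^(1 / 3))
  expect_error(rbc_equivalent_diameter(0), class = "ivoct_domain_error")
})

test_that("Stokes-Einstein diffusivity reproduces both whole-blood and saline limits", {
  expect_equal(diffusion_coefficient(0.45, 310, 9e-4), 4.27e-14,
    tolerance = 0.01e-14 / 4.27e-14)
  expect_equal(diffusion_coefficient(0, 310, 9e-4), 9.08e-14,
    tolerance = 0.01e-14 / 9.08e-14)
  # inverse proportionality to viscosity
  expect_equal(diffusion_coefficient(0.3, 310, 4.5e-4),
    2 * diffusion_coefficient(0.3, 310, 9e-4))
  # the whole-blood/saline ratio is exactly the viscosity ratio
  expect_equal(diffusion_coefficient(0.45, 333, 1.1e-3) /
               diffusion_coefficient(0, 333, 1.1e-3), 1 / 2.125)
  expect_error(diffusion_coefficient(0.4, -1), class = "ivoct_domain_error")
})

test_that("mixture laws agree with brute-force evaluation on random draws", {
  set.seed(42)
  n <- 1000
  xe <- runif(n)
  mu_p <- runif(n, 5e-4, 2e-3)
  temp <- runif(n, 290, 320)
  # independent re-evaluation from first principles
  rho_e <- (1056 - 0.55 * 1000) / 0.45
  rho <- xe * rho_e + (1 - xe) * 1000
  w <- xe * rho_e / rho
  d_e <- (6 * 90 / pi)^(1 / 3) * 1e-6
  d_ref <- 1.380649e-23 * temp / (3 * pi * d_e * mu_p * (1 + 2.5 * xe))
  expect_equal(mixture_density(xe), rho, tolerance = 1e-12)
  expect_equal(mass_fraction_from_haematocrit(xe), w, tolerance = 1e-12)
  expect_equal(diffusion_coefficient(xe, temp, mu_p), d_ref, tolerance = 1e-12)
  # monotonicity of the mixing laws
  grid <- seq(0, 1, length.out = 200)
  expect_true(all(diff(mixture_density(grid)) > 0))
  expect_true(all(diff(mixture_viscosity(grid)) > 0))
})

test_that("mixture_properties bundles all laws as a tibble", {
  tb <- mixture_properties(c(0, 0.45))
  expect_s3_class(tb, "tbl_df")
  expect_equal(tb$mass_fraction[2], 0.479, tolerance = 1e-3)
  expect_equal(tb$diffusivity[1], 9.08e-14, tolerance = 2e-3)
})
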