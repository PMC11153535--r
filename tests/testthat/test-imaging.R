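geo <- geometry_config()

test_that("cross-section rendering rotates the A-line with exact symmetry", {
  al <- propagate(medium_profile(geo, 0))
  flat <- al
  flat$G <- rep(255L, nrow(al))
  img <- render_cross_section(flat, size = 128)
  expect_s3_class(img, "ivoct_image")
  px <- (seq_len(128) - 64.5) * (10 / 128)
  rad <- sqrt(outer(px^2, px^2, `+`))
  expect_true(all(img[rad <= 5 & rad >= 0.46] == 255L))
  expect_true(all(img[rad > 5] == 0L))
  expect_true(all(img[rad < 0.45] == 0L)) # catheter core black
  # exact 90-degree rotational symmetry of the lookup
  rot <- t(img[, rev(seq_len(ncol(img)))])
  expect_identical(unclass(img), unclass(rot)[, ])
  expect_error(render_cross_section(al, size = 1), class = "ivoct_domain_error")
})

test_that("whole-blood A-line renders a bright ring near the catheter and a dark periphery", {
  al <- propagate(medium_profile(geo, 0.45))
  img <- render_cross_section(al, size = 256)
  px <- (seq_len(256) - 128.5) * (10 / 256)
  rad <- sqrt(outer(px^2, px^2, `+`))
  near <- rad >= 0.46 & rad <= 0.6
  far <- rad > 2 & rad <= 5
  expect_gt(mean(img[near]), 200)
  expect_lt(mean(img[far]), 5)
})

test_that("longitudinal stacking mirrors frames into ordered columns", {
  al1 <- propagate(medium_profile(geo, 0))
  al2 <- propagate(medium_profile(geo, 0.45))
  img <- stack_longitudinal(list(al1, al2))
  expect_equal(ncol(img), 2L)
  expect_equal(nrow(img), 2 * nrow(al1) - 1)
  expect_equal(img[, 1], c(rev(al1$G), al1$G[-1]))
  # mirrored about the axis row
  expect_identical(img[1, ], img[nrow(img), ])
  # single frame and identical frames
  expect_equal(ncol(stack_longitudinal(list(al1))), 1L)
  same <- stack_longitudinal(list(al1, al1, al1))
  expect_true(all(same[, 1] == same[, 2]))
  bad <- al1[-1, ]
  expect_error(stack_longitudinal(list(al1, bad)), class = "ivoct_domain_error")
})

test_that("images round-trip bit-exactly through PNG and TIFF", {
  al <- propagate(medium_profile(geo, 0.3))
  img <- render_cross_section(al, size = 64)
  for (ext in c("png", "tiff")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_identical(unclass(back), unclass(img))
  }
  expect_error(write_image(img, "x.bmp"), class = "ivoct_domain_error")
  # rendering is a pure function: same A-line, byte-identical image
  expect_identical(render_cross_section(al, 64), img)
})
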