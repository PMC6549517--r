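test_that("translation map gives a uniform field and linear trajectories", {
  spec <- phantom_spec("affine", dims = c(16, 16, 16), n_frames = 8,
                       es_frame = 3, late_onset_frame = 6)
  ph <- make_affine_phantom(spec, map = affine_translation(c(100, 0, 0)))
  # field is 0.1 m/s along x everywhere, all frames
  expect_equal(max(abs(ph$field$values[, , , , 1] - 0.1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ph$field$values[, , , , 2:3])), 0, tolerance = 1e-12)
  # closed form: x0 + 100 t
  x0 <- matrix(c(10, 20, 20), 1)
  tr <- ph$trajectory(x0, c(0.25, 0.5))
  expect_equal(tr[1, , 1], c(10 + 25, 20, 20))
  expect_equal(tr[1, , 2], c(10 + 50, 20, 20))
})

test_that("rotation map yields circular closed-form trajectories", {
  rp <- rotation_phantom()
  center <- (rp$spec$dims / 2) * rp$spec$spacing_mm
  x0 <- matrix(center + c(10, 0, 0), 1)
  ts <- seq(0, 1, by = 0.1)
  tr <- rp$ph$trajectory(x0, ts)
  radii <- sqrt((tr[1, 1, ] - center[1])^2 + (tr[1, 2, ] - center[2])^2)
  expect_equal(radii, rep(10, length(ts)), tolerance = 1e-12)
  # omega = pi: half a turn after 1 s
  expect_equal(tr[1, 1:2, length(ts)], unname(center[1:2] + c(-10, 0)),
               tolerance = 1e-12)
  # the gridded field of a solid-body rotation is steady in time
  expect_equal(rp$ph$field$values[, , , 1, ], rp$ph$field$values[, , , 5, ],
               tolerance = 1e-12)
})

test_that("contraction map matches its closed form and detects singularity", {
  spec <- phantom_spec("affine", dims = c(16, 16, 16), n_frames = 8,
                       es_frame = 3, late_onset_frame = 6)
  center <- (spec$dims / 2) * spec$spacing_mm
  ph <- make_affine_phantom(
    spec, map = affine_contraction(c(-0.3, -0.3, 0.2), cycle_s = 1,
                                   center = center))
  x0 <- matrix(center + c(8, 8, 8), 1)
  tr <- ph$trajectory(x0, 0.5)
  expect_equal(tr[1, , 1],
               unname(center + c(8 * 0.85, 8 * 0.85, 8 * 1.1)),
               tolerance = 1e-12)
  # a rate of -2/cycle makes A singular mid-cycle
  expect_error(make_affine_phantom(
    spec, map = affine_contraction(c(-2, 0, 0), cycle_s = 1,
                                   center = center)),
    "singular")
})

test_that("phase-contrast encoding follows the phase model", {
  f <- uniform_field(v = c(0.6, 0, 0), dims = c(8, 8, 8), n_frames = 4)
  enc <- encoding_spec(venc_cms = 120)   # VENC = 1.2 m/s
  ph <- encode_phase_contrast(f, enc)
  # v = VENC/2 -> phi = pi/2
  expect_equal(ph$phase[1, 1, 1, 1, 1], pi / 2, tolerance = 1e-12)
  expect_equal(ph$phase[1, 1, 1, 1, 2], 0, tolerance = 1e-12)

  # constant polynomial offset appears directly in the phase of v = 0
  bg <- matrix(0, 35, 3); bg[1, 2] <- 0.7
  ph2 <- encode_phase_contrast(uniform_field(v = c(0, 0, 0), dims = c(8, 8, 8),
                                             n_frames = 4),
                               encoding_spec(venc_cms = 120, background = bg))
  expect_equal(ph2$phase[3, 4, 5, 2, 2], 0.7, tolerance = 1e-12)

  # aliasing: v = 1.5 VENC decodes to -0.5 VENC
  f3 <- uniform_field(v = c(1.8, 0, 0), dims = c(8, 8, 8), n_frames = 4)
  dec <- decode_phase_contrast(encode_phase_contrast(f3, enc))
  expect_equal(dec$values[1, 1, 1, 1, 1], -0.6, tolerance = 1e-12)
})

test_that("encode/decode round trip is exact below VENC and noise is seeded", {
  f <- uniform_field(v = c(0.83, -0.41, 0.17), dims = c(8, 8, 8), n_frames = 4)
  enc <- encoding_spec(venc_cms = 120)
  dec <- decode_phase_contrast(encode_phase_contrast(f, enc))
  expect_equal(dec$values, f$values, tolerance = 1e-12)

  encn <- encoding_spec(venc_cms = 120, noise_sd = 0.05)
  a <- encode_phase_contrast(f, encn, seed = 7)
  b <- encode_phase_contrast(f, encn, seed = 7)
  c <- encode_phase_contrast(f, encn, seed = 8)
  expect_identical(a$phase, b$phase)
  expect_false(identical(a$phase, c$phase))
  expect_error(encode_phase_contrast(f, encn), "seed")
})

test_that("acquired temporal resolution is the TR x encodings x segments product", {
  expect_identical(acquisition_temporal_resolution(5.1, 4, 2), 40.8)
  expect_identical(acquisition_temporal_resolution(7.3, 1, 1), 7.3)
  expect_equal(acquisition_temporal_resolution(2.8, 4, 2), 22.4)
  expect_error(acquisition_temporal_resolution(-5, 4, 2), "positive")
  expect_error(acquisition_temporal_resolution(5, 0, 2), "positive")
})
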