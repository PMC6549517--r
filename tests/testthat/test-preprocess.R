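test_that("static tissue is detected from temporal variation", {
  spec <- small_duct_spec()
  pf <- make_pulsatile_duct_field(spec, peak_speed_ms = 0.3, venc_cms = 120)
  sm <- detect_static_tissue(pf$field)
  # noise-free: exactly the zero-velocity shell
  expect_identical(sm$data, pf$static_shell$data)

  # all-moving field -> error
  mv <- uniform_field(v = c(0.2, 0, 0), dims = c(8, 8, 8), n_frames = 6)
  mv$values <- mv$values * array(rep(seq(0.5, 1.5, length.out = 6),
                                     each = 8^3),
                                 dim = dim(mv$values))
  expect_error(detect_static_tissue(mv), "no static voxels")

  # phase noise of 0.01 m/s in velocity units: shell recovered >= 99%
  enc <- encoding_spec(venc_cms = 120, noise_sd = 0.01 * pi / 1.2)
  meas <- decode_phase_contrast(encode_phase_contrast(pf$field, enc, seed = 11))
  smn <- detect_static_tissue(meas, sd_threshold = 0.03)
  shell <- pf$static_shell$data == 1
  sens <- sum(smn$data == 1 & shell) / sum(shell)
  expect_gte(sens, 0.99)
})

test_that("quartic background fit recovers polynomials in its model class", {
  spec <- small_duct_spec()
  pf <- make_pulsatile_duct_field(spec, peak_speed_ms = 0.3, venc_cms = 120)
  bg <- matrix(0, 35, 3)
  bg[c(2, 5, 12, 20, 35), 1] <- c(0.4, -0.25, 0.15, 0.1, -0.2)  # up to deg 4
  bg[c(1, 3), 2] <- c(0.3, 0.2)                                  # nested deg <= 1
  enc <- encoding_spec(venc_cms = 120, background = bg)
  meas <- decode_phase_contrast(encode_phase_contrast(pf$field, enc))
  sm <- detect_static_tissue(meas)
  fit <- correct_background_phase(meas, sm)
  venc_ms <- 1.2
  expect_equal(fit$model$coefficients, bg * venc_ms / pi, tolerance = 1e-9)
  # corrected static voxels are zero again
  sel <- which(sm$data == 1)
  d <- dim(fit$field$values)
  resid <- 0
  for (cmp in 1:3)
    resid <- max(resid, abs(fit$field$values[, , , 1, cmp][sel]))
  expect_lt(resid, 1e-9)

  # zero polynomial: output equals input
  id <- correct_background_phase(pf$field, sm)
  expect_equal(id$field$values, pf$field$values, tolerance = 1e-12)

  # idempotence
  twice <- correct_background_phase(fit$field, sm)
  expect_lt(max(abs(twice$field$values - fit$field$values)), 1e-12)
})

test_that("background fit errors on rank-deficient or tiny static sets", {
  f <- uniform_field(v = c(0, 0, 0), dims = c(10, 10, 10), n_frames = 4)
  plane <- array(0, c(10, 10, 10)); plane[, , 5] <- 1   # coplanar voxels
  sm <- structure(list(data = plane), class = "static_mask")
  expect_error(correct_background_phase(f, sm), "rank")
  few <- array(0, c(10, 10, 10)); few[1:3, 1, 1] <- 1
  expect_error(correct_background_phase(
    f, structure(list(data = few), class = "static_mask")), "static voxels")
})

test_that("temporal unwrap restores aliased series and is exactly minimal", {
  # single displaced frame on an otherwise smooth series
  nt <- 10
  v_true <- 0.3 * sin(2 * pi * (0:(nt - 1)) / nt)
  venc <- 0.5
  vals <- array(0, c(2, 2, 2, nt, 3))
  for (f in 1:nt) vals[, , , f, 1] <- v_true[f]
  vals[1, 1, 1, 4, 1] <- v_true[4] - 2 * venc
  fld <- velocity_field(vals, spacing = 1, venc_cms = venc * 100,
                        frame_times = (0:(nt - 1)) / nt, cycle_s = 1)
  fixed <- unwrap_temporal(fld)
  expect_equal(fixed$values[1, 1, 1, , 1], v_true, tolerance = 1e-12)
  # untouched voxels are bit-identical
  expect_identical(fixed$values[2, 2, 2, , 1], vals[2, 2, 2, , 1])

  # wrap-free smooth series pass through unchanged
  clean <- velocity_field(array(rep(v_true, each = 8), c(2, 2, 2, nt, 1))[
    , , , , c(1, 1, 1), drop = FALSE],
    spacing = 1, venc_cms = 100, frame_times = (0:(nt - 1)) / nt, cycle_s = 1)
  expect_identical(unwrap_temporal(clean)$values, clean$values)
})

test_that("unwrap matches exhaustive minimization on small series", {
  venc <- 0.4; step <- 2 * venc; K <- 1; nt <- 6
  set.seed(5)
  for (rep in 1:8) {
    v_true <- 0.9 * venc * sin(2 * pi * (0:(nt - 1)) / nt + stats::runif(1, 0, pi)) +
      stats::rnorm(nt, 0, 0.02)
    wraps <- sample(c(-1, 0, 1), nt, replace = TRUE, prob = c(.2, .6, .2))
    v_meas <- v_true + wraps * step
    vals <- array(0, c(2, 1, 1, nt, 3))
    vals[1, 1, 1, , 1] <- v_meas
    fld <- velocity_field(vals, spacing = 1, venc_cms = venc * 100,
                          frame_times = (0:(nt - 1)) / nt, cycle_s = 1)
    got <- unwrap_temporal(fld, max_wraps = K)$values[1, 1, 1, , 1]
    # exhaustive search over all offset series, lexicographic
    # (total cyclic jump, total |v|)
    grid <- as.matrix(expand.grid(rep(list((-K):K), nt)))
    best <- NULL; best_cost <- c(Inf, Inf)
    for (i in seq_len(nrow(grid))) {
      vv <- v_meas + grid[i, ] * step
      cost <- c(sum(abs(diff(c(vv, vv[1])))), sum(abs(vv)))
      if (cost[1] < best_cost[1] - 1e-12 ||
          (abs(cost[1] - best_cost[1]) <= 1e-12 && cost[2] < best_cost[2])) {
        best_cost <- cost; best <- unname(vv)
      }
    }
    jump_got <- sum(abs(diff(c(got, got[1]))))
    if (max(abs(diff(c(v_meas, v_meas[1])))) <= venc) {
      expect_identical(got, v_meas)   # guard: untouched below threshold
    } else {
      expect_equal(jump_got, best_cost[1], tolerance = 1e-9)
      expect_equal(got, best, tolerance = 1e-9)
    }
  }
})

test_that("the full correction chain inverts the encoding forward model", {
  spec <- phantom_spec("duct", dims = c(20, 18, 18), n_frames = 16,
                       es_frame = 5, late_onset_frame = 11)
  pf <- make_pulsatile_duct_field(spec, peak_speed_ms = 0.18, venc_cms = 12)
  bg <- matrix(0, 35, 3)
  bg[c(2, 6, 35), 1] <- c(0.3, -0.2, 0.12)
  bg[1, 3] <- 0.25
  enc <- encoding_spec(venc_cms = 12, background = bg)   # peak = 1.5 VENC
  meas <- decode_phase_contrast(encode_phase_contrast(pf$field, enc))
  expect_gt(max(abs(meas$values - pf$field$values)), 0.1)  # really corrupted
  pre <- preprocess_velocity(meas)
  expect_lt(max(abs(pre$field$values - pf$field$values)), 1e-6)
})
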