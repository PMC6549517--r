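test_that("seed grid fills the ED mask at the prescribed density", {
  # 28 mm cube at 2.8 mm spacing: a 10^3 lattice
  m <- box_mask(c(20, 20, 20), 3:12, 4:13, 5:14)
  s <- seed_grid(m, spacing_mm = 2.8)
  expect_equal(nrow(s), 1000)
  expect_equal(attr(s, "cell_volume_mm3"), 21.952)
  # represented volume totals the mask volume (lattice aligned to voxels)
  expect_equal(nrow(s) * attr(s, "cell_volume_mm3") / 1000, mask_volume_ml(m))
  # every seed inside the mask
  expect_true(all(mask_inside(m, as.matrix(s[, c("x", "y", "z")]))))

  empty <- box_mask(c(8, 8, 8), 1, 1, 1); empty$data[] <- 0
  expect_error(seed_grid(empty), "empty|no seeds")
  expect_error(seed_grid(m, spacing_mm = 0), "spacing")
})

test_that("velocity sampling interpolates trilinearly and linearly in time", {
  dims <- c(6, 6, 6); nt <- 4
  vals <- array(stats::rnorm(prod(dims) * nt * 3), c(dims, nt, 3))
  f <- velocity_field(vals, spacing = 2, frame_times = (0:3) / 4,
                      venc_cms = 120, cycle_s = 1)
  # voxel centre at a frame time: stored value exactly
  p <- matrix(c(2 * 2.5 + 1 - 2, 0, 0), 1)  # voxel (2,1,1) centre = (3,1,1)
  p <- matrix((c(2, 1, 1) - 1 + 0.5) * 2, 1)
  got <- sample_velocity(f, p, 0.25)
  expect_equal(got$velocity[1, ], vals[2, 1, 1, 2, ], tolerance = 1e-12)
  expect_true(got$in_domain)
  # spatial midpoint of two voxel centres: arithmetic mean
  pm <- matrix(c(2, 1, 1), 1)   # midpoint of voxel (1,1,1) and (2,1,1) centres
  gm <- sample_velocity(f, pm, 0)
  expect_equal(gm$velocity[1, ], (vals[1, 1, 1, 1, ] + vals[2, 1, 1, 1, ]) / 2,
               tolerance = 1e-12)
  # temporal midpoint between frames: (v1 + v2) / 2
  gt <- sample_velocity(f, p, 0.125)
  expect_equal(gt$velocity[1, ], (vals[2, 1, 1, 1, ] + vals[2, 1, 1, 2, ]) / 2,
               tolerance = 1e-12)
  # out-of-bounds position flagged, not an exception
  expect_false(sample_velocity(f, matrix(c(-5, 0, 0), 1), 0)$in_domain)
})

test_that("a uniform field transports seeds exactly", {
  f <- uniform_field(v = c(0.1, 0, 0), dims = c(60, 10, 10), n_frames = 10)
  m <- box_mask(c(60, 10, 10), 2:3, 4:6, 4:6)
  timing <- timing_result(0, 5, 8, 10, 1.0)   # forward branch = 0.5 s
  pl <- trace_pathlines(f, seed_grid(m), timing)
  ns <- length(pl$times)
  i_ed <- which(pl$times == 0)
  # position at ED equals the seed exactly
  expect_equal(pl$positions[, i_ed, ], as.matrix(pl$seeds[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  # 0.5 s at 0.1 m/s = 50 mm displacement
  disp <- pl$positions[, ns, 1] - pl$seeds$x
  expect_equal(disp, rep(50, nrow(pl$seeds)), tolerance = 1e-6)
  expect_true(all(pl$status$valid))
  expect_equal(nrow(pl$status), nrow(pl$seeds))
})

test_that("the tracer matches the affine closed form within a tenth voxel", {
  rp <- rotation_phantom()
  seeds <- seed_grid(rp$ph$ed_mask)
  pl <- trace_pathlines(rp$ph$field, seeds, rp$timing, step_fraction = 0.2)
  x0 <- as.matrix(seeds[, c("x", "y", "z")])
  gt <- rp$ph$trajectory(x0, pl$times)
  dev <- 0
  for (j in seq_along(pl$times)) {
    p <- pl$positions[, j, ]; dim(p) <- c(nrow(x0), 3)
    dev <- max(dev, max(abs(p - gt[, , j])))
  }
  expect_lt(dev, 0.1 * rp$spec$spacing_mm)
})

test_that("endpoint error contracts at fourth order when the step is halved", {
  rp <- rotation_phantom()
  seeds <- seed_grid(rp$ph$ed_mask)
  x0 <- as.matrix(seeds[, c("x", "y", "z")])
  endpoint_err <- function(sf) {
    pl <- trace_pathlines(rp$ph$field, seeds, rp$timing, step_fraction = sf)
    ns <- length(pl$times)
    p <- pl$positions[, ns, ]; dim(p) <- c(nrow(x0), 3)
    max(abs(p - rp$ph$trajectory(x0, pl$times[ns])[, , 1]))
  }
  e1 <- endpoint_err(1); e2 <- endpoint_err(0.5); e3 <- endpoint_err(0.25)
  expect_gt(e1 / e2, 10); expect_lt(e1 / e2, 24)
  expect_gt(e2 / e3, 10); expect_lt(e2 / e3, 24)
  # self-convergence form: halving changes the endpoint by < previous/8
  endpoint <- function(sf) {
    pl <- trace_pathlines(rp$ph$field, seeds, rp$timing, step_fraction = sf)
    ns <- length(pl$times)
    p <- pl$positions[, ns, ]; dim(p) <- c(nrow(x0), 3); p
  }
  d1 <- max(abs(endpoint(0.5) - endpoint(1)))
  d2 <- max(abs(endpoint(0.25) - endpoint(0.5)))
  expect_lt(d2, d1 / 8)
})

test_that("backward branch endpoints return to the seed when re-traced", {
  rp <- rotation_phantom()
  seeds <- seed_grid(rp$ph$ed_mask)
  pl <- trace_pathlines(rp$ph$field, seeds, rp$timing)
  # re-integrate forward from the backward endpoint over the same span
  x_es_prev <- pl$positions[, 1, ]
  dim(x_es_prev) <- c(nrow(seeds), 3)
  w <- pl$window
  nst <- 400
  hh <- (w$t_ed - w$t_es_prev) / nst
  pos <- x_es_prev
  for (i in seq_len(nst)) {
    t <- w$t_es_prev + (i - 1) * hh
    k1 <- sample_velocity(rp$ph$field, pos, t)$velocity
    k2 <- sample_velocity(rp$ph$field, pos + 500 * hh * k1, t + hh / 2)$velocity
    k3 <- sample_velocity(rp$ph$field, pos + 500 * hh * k2, t + hh / 2)$velocity
    k4 <- sample_velocity(rp$ph$field, pos + 1000 * hh * k3, t + hh)$velocity
    pos <- pos + (1000 * hh / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(max(abs(pos - as.matrix(seeds[, c("x", "y", "z")]))),
            1e-3 * rp$spec$spacing_mm)
})

test_that("domain exits freeze and flag pathlines without dropping them", {
  f <- uniform_field(v = c(0.1, 0, 0), dims = c(12, 8, 8), n_frames = 10)
  m <- box_mask(c(12, 8, 8), 8:10, 3:5, 3:5)   # 0.5 s forward run exits +x
  timing <- timing_result(0, 5, 8, 10, 1.0)
  pl <- trace_pathlines(f, seed_grid(m), timing)
  expect_equal(nrow(pl$status), nrow(pl$seeds))
  expect_true(all(pl$status$truncated))
  expect_true(all(pl$status$reason == "domain_exit"))
  # frozen at the boundary, never beyond the sampling hull
  ns <- length(pl$times)
  expect_true(all(pl$positions[, ns, 1] <= 12 * 2.8))
  # truncated pathlines are excluded from component labels
  es <- box_mask(c(12, 8, 8), 8:10, 3:5, 3:5, frame = 5)
  labs <- classify_components(pl, es)
  expect_true(all(is.na(labs$label)))
  expect_true(all(!labs$valid))
})

test_that("pathline sets tidy into long sample tables", {
  sd <- small_duct()
  pl <- sd$result$pathlines
  td <- tidy(pl)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(pl$status) * length(pl$times))
  expect_true(all(c("seed", "time", "x", "speed", "in_domain") %in% names(td)))
})
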