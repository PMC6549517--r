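## Shared fixtures: small phantoms built in code, cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

small_duct_spec <- function(fractions = c(0.30, 0.20, 0.18, 0.32), ...) {
  phantom_spec("duct", dims = c(26, 24, 24), n_frames = 20, cycle_s = 1.0,
               ed_frame = 0, es_frame = 6, late_onset_frame = 14,
               fractions = fractions, ...)
}

small_duct <- function() {
  fixture("small_duct", function() {
    ph <- make_duct_phantom(small_duct_spec())
    sp <- ph$spec
    timing <- timing_result(sp$ed_frame, sp$es_frame, sp$late_onset_frame,
                            sp$n_frames, sp$cycle_s)
    list(ph = ph, timing = timing,
         result = analyze_lv_flow(ph$field, ph$ed_mask, ph$es_mask, timing))
  })
}

rotation_phantom <- function() {
  fixture("rotation_phantom", function() {
    spec <- phantom_spec("affine", dims = c(24, 24, 24), n_frames = 20,
                         es_frame = 6, late_onset_frame = 14)
    list(spec = spec, ph = make_affine_phantom(spec),
         timing = timing_result(0, 6, 14, 20, 1.0))
  })
}

## A uniform-flow velocity field (constant v, m/s) on a small grid.
uniform_field <- function(v = c(0.1, 0, 0), dims = c(12, 10, 10),
                          n_frames = 10, cycle_s = 1, spacing = 2.8) {
  vals <- array(0, c(dims, n_frames, 3))
  for (cmp in 1:3) vals[, , , , cmp] <- v[cmp]
  velocity_field(vals, spacing = spacing,
                 frame_times = (seq_len(n_frames) - 1) * cycle_s / n_frames,
                 venc_cms = 120, cycle_s = cycle_s)
}

## Box chamber mask spanning the given 1-based voxel index ranges.
box_mask <- function(dims, xr, yr, zr, frame = 0, spacing = 2.8) {
  a <- array(0, dims)
  a[xr, yr, zr] <- 1
  chamber_mask(a, frame = frame, label = "LV", spacing = spacing)
}

## Brute-force component labelling: dense Euler stepping through the
## sampled field (the same interpolation the tracer uses, but a different,
## first-order integrator at a far smaller step), endpoints tested against
## the ES mask. Oracle for classify_components on small phantoms.
brute_force_labels <- function(field, seeds_xyz, timing, es_mask,
                               n_steps_per_frame = 200) {
  w <- lvflow:::trace_window(timing)
  dt_frame <- timing$cycle_s / timing$n_frames
  h <- dt_frame / n_steps_per_frame
  march <- function(pos, t_from, t_to) {
    nst <- round(abs(t_to - t_from) / h)
    hh <- (t_to - t_from) / nst
    for (i in seq_len(nst)) {
      t <- t_from + (i - 1) * hh
      v <- sample_velocity(field, pos, t)$velocity
      pos <- pos + 1000 * hh * v
    }
    pos
  }
  origin <- march(seeds_xyz, w$t_ed, w$t_es_prev)
  fate <- march(seeds_xyz, w$t_ed, w$t_es)
  oi <- mask_inside(es_mask, origin)
  fi <- mask_inside(es_mask, fate)
  lab <- ifelse(!oi & !fi, "Direct flow",
         ifelse(!oi & fi, "Retained inflow",
         ifelse(oi & !fi, "Delayed ejection flow", "Residual volume")))
  factor(lab, levels = component_levels())
}

## Exact two-sided signed-rank p-value by enumeration of all sign
## assignments (no ties, no zeros; n <= 12).
wilcoxon_enumerated_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}
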