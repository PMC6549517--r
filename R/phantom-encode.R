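#' Monomial exponents of the three-variable quartic polynomial basis
#'
#' The background phase model is a full three-variable polynomial of total
#' degree up to 4 (35 terms). This table fixes the canonical term order
#' shared by the encoding forward model and the background-phase
#' correction: exponents `(i, j, k)` of `u^i v^j w^k` sorted by total
#' degree, then lexicographically.
#'
#' @return integer matrix `35 x 3` of exponents.
#' @export
poly4_terms <- function() {
  ex <- expand.grid(k = 0:4, j = 0:4, i = 0:4)
  ex <- ex[ex$i + ex$j + ex$k <= 4, c("i", "j", "k")]
  ex <- ex[order(ex$i + ex$j + ex$k, ex$i, ex$j, ex$k), ]
  as.matrix(ex)
}

## Normalized grid coordinates in [-1, 1] per axis for voxel centres,
## returned as an (nvox x 3) matrix in column-major voxel order.
normalized_grid_coords <- function(dims) {
  u <- function(n) 2 * (seq_len(n) - 0.5) / n - 1
  cbind(rep(u(dims[1]), times = dims[2] * dims[3]),
        rep(rep(u(dims[2]), each = dims[1]), times = dims[3]),
        rep(u(dims[3]), each = dims[1] * dims[2]))
}

## Design matrix of the quartic basis at the given normalized coordinates.
poly4_design <- function(coords) {
  ex <- poly4_terms()
  X <- matrix(1, nrow(coords), nrow(ex))
  for (t in seq_len(nrow(ex))) {
    if (ex[t, 1] > 0) X[, t] <- X[, t] * coords[, 1]^ex[t, 1]
    if (ex[t, 2] > 0) X[, t] <- X[, t] * coords[, 2]^ex[t, 2]
    if (ex[t, 3] > 0) X[, t] <- X[, t] * coords[, 3]^ex[t, 3]
  }
  X
}

#' Phase-contrast encoding forward model
#'
#' Maps true velocities to measured phase: `phi = pi * v / VENC + P4(x) +
#' noise`, wrapped into `(-pi, pi]`. `P4` is the per-direction quartic
#' background polynomial of `enc` evaluated on normalized grid coordinates
#' (static across frames, as eddy-current offsets are), and the noise is
#' Gaussian in phase, reproducible from `seed`. Velocities beyond the VENC
#' alias: `|v| > VENC` wraps by multiples of `2 * VENC` after decoding.
#'
#' @param field a [velocity_field()] of true velocities.
#' @param enc an [encoding_spec()].
#' @param static_region optional [chamber_mask()] asserting where the true
#'   velocity is zero (checked, not used in the forward model).
#' @param seed integer seed for the phase noise (required if
#'   `enc$noise_sd > 0`).
#'
#' @return An object of class `phase_images`: the wrapped phase array
#'   `(nx, ny, nz, n_frames, 3)` plus the grid/timing metadata and `enc`.
#' @export
encode_phase_contrast <- function(field, enc, static_region = NULL,
                                  seed = NULL) {
  stopifnot(inherits(field, "velocity_field"), inherits(enc, "encoding_spec"))
  venc_ms <- enc$venc_cms / 100
  if (!is.null(static_region)) {
    check_same_geometry(field, static_region, "field and static region")
    sel <- which(static_region$data == 1)
    d <- dim(field$values)
    for (f in seq_len(d[4])) for (cmp in 1:3) {
      off <- prod(d[1:3]) * ((f - 1) + d[4] * (cmp - 1))
      if (max(abs(field$values[sel + off])) > 1e-9)
        stop("`static_region` contains voxels with non-zero true velocity",
             call. = FALSE)
    }
  }
  d <- dim(field$values)
  phi <- pi * field$values / venc_ms
  bg <- if (any(enc$background != 0))
    poly4_design(normalized_grid_coords(d[1:3])) %*% enc$background
  nxyz <- prod(d[1:3])
  for (cmp in 1:3) {
    if (all(enc$background[, cmp] == 0)) next
    for (f in seq_len(d[4])) {
      idx <- seq_len(nxyz) + nxyz * ((f - 1) + d[4] * (cmp - 1))
      phi[idx] <- phi[idx] + bg[, cmp]
    }
  }
  if (enc$noise_sd > 0) {
    if (is.null(seed))
      stop("a `seed` is required when `noise_sd > 0`", call. = FALSE)
    withr_seed <- function(code) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      code
    }
    phi <- phi + withr_seed(array(stats::rnorm(length(phi), 0, enc$noise_sd),
                                  dim = d))
  }
  wrapped <- atan2(sin(phi), cos(phi))   # (-pi, pi]
  structure(list(phase = wrapped, enc = enc, spacing = field$spacing,
                 frame_times = field$frame_times, cycle_s = field$cycle_s,
                 origin = field$origin),
            class = "phase_images")
}

#' Decode phase images to a measured velocity field
#'
#' The inverse of the linear part of the encoding: `v = phi * VENC / pi`.
#' Background offsets, aliasing and noise present in the phase carry over
#' into the decoded velocities; they are removed by the preprocessing steps
#' ([detect_static_tissue()], [correct_background_phase()],
#' [unwrap_temporal()]).
#'
#' @param phase a `phase_images` object from [encode_phase_contrast()].
#' @return A [velocity_field()] of measured (uncorrected) velocities.
#' @export
decode_phase_contrast <- function(phase) {
  stopifnot(inherits(phase, "phase_images"))
  venc_ms <- phase$enc$venc_cms / 100
  velocity_field(phase$phase * venc_ms / pi, spacing = phase$spacing,
                 frame_times = phase$frame_times,
                 venc_cms = phase$enc$venc_cms, cycle_s = phase$cycle_s,
                 origin = phase$origin)
}

#' Synthetic LV volume curve with early and late filling waves
#'
#' A smooth volume curve over one cardiac cycle: systolic ejection from ED
#' to ES, an early (E) filling wave, a diastasis plateau and a late atrial
#' (A) wave ending at the next ED. Useful for exercising the cardiac-timing
#' landmarks on a curve whose diastasis is known by construction.
#'
#' @param n_frames frames per cycle.
#' @param edv_ml,esv_ml end-diastolic / end-systolic volumes, ml.
#' @param es_frame 0-based ES frame (ED is frame 0).
#' @param e_end_frame 0-based frame at which early filling is complete.
#' @param a_start_frame 0-based frame at which the atrial wave begins;
#'   frames between `e_end_frame` and `a_start_frame` are flat diastasis.
#' @param a_fraction fraction of total filling contributed by the A wave.
#' @return numeric vector of `n_frames` volumes (ml).
#' @export
synthetic_lv_volume_curve <- function(n_frames = 40, edv_ml = 180,
                                      esv_ml = 90, es_frame = 14,
                                      e_end_frame = 24, a_start_frame = 31,
                                      a_fraction = 0.3) {
  stopifnot(es_frame < e_end_frame, e_end_frame <= a_start_frame,
            a_start_frame < n_frames)
  f <- 0:(n_frames - 1)
  vol <- numeric(n_frames)
  fill <- edv_ml - esv_ml
  ramp <- function(x) (1 - cos(pi * pmin(pmax(x, 0), 1))) / 2  # smooth 0->1
  vol[f <= es_frame] <- edv_ml - fill * ramp(f[f <= es_frame] / es_frame)
  dia <- f > es_frame
  e_amt <- fill * (1 - a_fraction)
  e_phase <- ramp((f - es_frame) / (e_end_frame - es_frame))
  a_phase <- ramp((f - a_start_frame) / (n_frames - a_start_frame))
  vol[dia] <- esv_ml + e_amt * e_phase[dia] + fill * a_fraction * a_phase[dia]
  vol
}
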