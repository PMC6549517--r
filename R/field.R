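#' Gridded time-resolved three-directional velocity data
#'
#' Container for a 4D flow velocity dataset: a `(nx, ny, nz, n_frames, 3)`
#' array of velocities in m/s on a regular grid, together with the voxel
#' spacing, the cardiac frame times, the velocity-encoding limit (VENC) and
#' the world-coordinate origin. The time axis is cyclic with period
#' `cycle_s`: frame times must lie within one cardiac cycle and sampling
#' wraps around.
#'
#' Voxel indices are 0-based; the world position of the centre of voxel
#' `i` along an axis is `origin + (i + 0.5) * spacing` (mm).
#'
#' @param values numeric array `(nx, ny, nz, n_frames, 3)`, m/s.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param frame_times numeric length `n_frames`, strictly increasing frame
#'   times in seconds, all within `[0, cycle_s)`.
#' @param venc_cms velocity-encoding limit in cm/s (> 0).
#' @param cycle_s cardiac cycle duration in seconds. Defaults to the implied
#'   uniform frame interval past the last frame.
#' @param origin numeric length-3, world coordinate of the grid corner in mm.
#'
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(values, spacing, frame_times, venc_cms,
                           cycle_s = NULL, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 5L || dim(values)[5] != 3L)
    stop("`values` must be a (nx, ny, nz, n_frames, 3) array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("velocity values must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes (mm)", call. = FALSE)
  nt <- dim(values)[4]
  if (nt < 2L) stop("a velocity field needs at least 2 time frames", call. = FALSE)
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != nt || any(diff(frame_times) <= 0))
    stop("`frame_times` must be strictly increasing, one per frame", call. = FALSE)
  if (is.null(cycle_s))
    cycle_s <- frame_times[nt] + mean(diff(frame_times))
  if (frame_times[1] < 0 || frame_times[nt] >= cycle_s)
    stop("frame times must lie within one cardiac cycle [0, cycle_s)", call. = FALSE)
  if (!is.numeric(venc_cms) || venc_cms <= 0)
    stop("`venc_cms` must be a positive VENC in cm/s", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, frame_times = frame_times,
         venc_cms = as.numeric(venc_cms), cycle_s = as.numeric(cycle_s),
         origin = as.numeric(origin)),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d frames, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  cycle %.3f s, VENC %.0f cm/s, |v| range [%.3g, %.3g] m/s\n",
              x$cycle_s, x$venc_cms, min(x$values), max(x$values)))
  invisible(x)
}

#' Binary chamber segmentation bound to a cardiac frame
#'
#' @param data logical or 0/1 numeric 3D array on the same grid geometry as
#'   the accompanying velocity field.
#' @param frame 0-based cardiac frame index the segmentation belongs to.
#' @param label chamber label, `"LV"` or `"LA"`.
#' @param spacing voxel spacing mm (length 3 or scalar).
#' @param origin world origin mm.
#'
#' @return An object of class `chamber_mask`.
#' @export
chamber_mask <- function(data, frame, label = c("LV", "LA"),
                         spacing, origin = c(0, 0, 0)) {
  label <- match.arg(label)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1)))
    stop("mask values must be binary", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  structure(
    list(data = data, frame = as.integer(frame), label = label,
         spacing = spacing, origin = as.numeric(origin)),
    class = "chamber_mask")
}

#' @export
print.chamber_mask <- function(x, ...) {
  cat(sprintf("<chamber_mask> %s at frame %d: %d voxels set (%.1f ml)\n",
              x$label, x$frame, sum(x$data), mask_volume_ml(x)))
  invisible(x)
}

#' Volume of a binary mask in ml
#'
#' Voxel count times voxel volume.
#'
#' @param mask a [chamber_mask()].
#' @return volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "chamber_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

## Check that two gridded objects share geometry (dims, spacing, origin).
check_same_geometry <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "velocity_field")) dim(a$values)[1:3] else dim(a$data)
  db <- if (inherits(b, "velocity_field")) dim(b$values)[1:3] else dim(b$data)
  if (!identical(da, db) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop(sprintf("grid geometry mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

## World mm -> continuous 0-based voxel coordinate of the surrounding cell,
## measured from the first voxel centre.
world_to_cell <- function(positions, spacing, origin) {
  sweep(sweep(positions, 2, origin, "-"), 2, spacing, "/") - 0.5
}

## Trilinear interpolation weights/indices shared by field and mask sampling.
## Returns 1-based lower-corner indices clamped to valid cells, fractional
## weights, and an in-bounds flag (inside the centre-to-centre hull).
trilinear_setup <- function(positions, dims, spacing, origin) {
  f <- world_to_cell(positions, spacing, origin)
  inside <- f[, 1] >= 0 & f[, 1] <= dims[1] - 1 &
            f[, 2] >= 0 & f[, 2] <= dims[2] - 1 &
            f[, 3] >= 0 & f[, 3] <= dims[3] - 1
  i0 <- floor(f)
  for (k in 1:3) i0[, k] <- pmin(pmax(i0[, k], 0), dims[k] - 2)
  w <- f - i0
  w <- pmin(pmax(w, 0), 1)
  list(i0 = i0 + 1, w = w, inside = inside)
}

## Temporal bracketing for cyclic frame times: indices of the two frames and
## the linear weight of the later one.
time_bracket <- function(t, frame_times, cycle_s) {
  nt <- length(frame_times)
  tau <- t %% cycle_s
  k <- findInterval(tau, frame_times)   # 0 if tau < first frame time
  if (k >= 1L && k < nt) {
    t0 <- frame_times[k]; t1 <- frame_times[k + 1]
    list(f0 = k, f1 = k + 1L, w1 = (tau - t0) / (t1 - t0))
  } else {
    # wrap interval [t_last, t_first + cycle]
    t0 <- frame_times[nt]; t1 <- frame_times[1] + cycle_s
    tt <- if (k == 0L) tau + cycle_s else tau
    list(f0 = nt, f1 = 1L, w1 = (tt - t0) / (t1 - t0))
  }
}

#' Sample a velocity field at arbitrary positions and a time
#'
#' Trilinear interpolation in space and linear, cyclic interpolation in time
#' between the two bracketing cardiac frames. Positions outside the
#' centre-to-centre hull of the grid are flagged as domain exits: their
#' returned velocity is computed from the clamped border cell but
#' `in_domain` is `FALSE` so callers can freeze the trajectory.
#'
#' @param field a [velocity_field()].
#' @param positions numeric matrix `n x 3` of world positions in mm (a
#'   length-3 vector is accepted for a single position).
#' @param time time in seconds (any real; the cardiac cycle is periodic).
#'
#' @return A list with `velocity` (`n x 3` matrix, m/s) and `in_domain`
#'   (logical length `n`).
#' @export
sample_velocity <- function(field, positions, time) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  d <- dim(field$values)
  tri <- trilinear_setup(positions, d[1:3], field$spacing, field$origin)
  tb <- time_bracket(time, field$frame_times, field$cycle_s)
  n <- nrow(positions)
  vals <- field$values
  nxyz <- d[1] * d[2] * d[3]
  # linear index of lower corner voxel (component/frame offsets added later)
  base <- tri$i0[, 1] + d[1] * (tri$i0[, 2] - 1) + d[1] * d[2] * (tri$i0[, 3] - 1)
  off <- c(0, 1, d[1], d[1] + 1, d[1] * d[2], d[1] * d[2] + 1,
           d[1] * d[2] + d[1], d[1] * d[2] + d[1] + 1)
  wx <- tri$w[, 1]; wy <- tri$w[, 2]; wz <- tri$w[, 3]
  cw <- cbind((1 - wx) * (1 - wy) * (1 - wz), wx * (1 - wy) * (1 - wz),
              (1 - wx) * wy * (1 - wz),       wx * wy * (1 - wz),
              (1 - wx) * (1 - wy) * wz,       wx * (1 - wy) * wz,
              (1 - wx) * wy * wz,             wx * wy * wz)
  out <- matrix(0, n, 3)
  for (comp in 1:3) {
    o0 <- nxyz * ((tb$f0 - 1L) + d[4] * (comp - 1L))
    o1 <- nxyz * ((tb$f1 - 1L) + d[4] * (comp - 1L))
    acc <- 0
    for (corner in 1:8) {
      idx <- base + off[corner]
      v <- (1 - tb$w1) * vals[idx + o0] + tb$w1 * vals[idx + o1]
      acc <- acc + cw[, corner] * v
    }
    out[, comp] <- acc
  }
  list(velocity = out, in_domain = tri$inside)
}

#' Interpolated inside/outside test against a chamber mask
#'
#' Trilinear interpolation of the binary mask at the query positions; a
#' point counts as inside when the interpolated occupancy is at least 0.5
#' (`method = "interpolated"`, the default, sub-voxel consistent with the
#' interpolated velocity field) or when its nearest voxel is set
#' (`method = "nearest"`). Points outside the grid hull are outside.
#'
#' @param mask a [chamber_mask()].
#' @param positions `n x 3` matrix of world positions mm.
#' @param method `"interpolated"` or `"nearest"`.
#' @return logical vector, length `n`.
#' @export
mask_inside <- function(mask, positions, method = c("interpolated", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "chamber_mask"))
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  d <- dim(mask$data)
  if (method == "nearest") {
    f <- world_to_cell(positions, mask$spacing, mask$origin)
    i <- round(f) + 1
    ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
          i[, 3] >= 1 & i[, 3] <= d[3]
    res <- rep(FALSE, nrow(positions))
    if (any(ok))
      res[ok] <- mask$data[cbind(i[ok, 1], i[ok, 2], i[ok, 3])] > 0.5
    return(res)
  }
  tri <- trilinear_setup(positions, d, mask$spacing, mask$origin)
  base <- tri$i0[, 1] + d[1] * (tri$i0[, 2] - 1) + d[1] * d[2] * (tri$i0[, 3] - 1)
  off <- c(0, 1, d[1], d[1] + 1, d[1] * d[2], d[1] * d[2] + 1,
           d[1] * d[2] + d[1], d[1] * d[2] + d[1] + 1)
  wx <- tri$w[, 1]; wy <- tri$w[, 2]; wz <- tri$w[, 3]
  cw <- cbind((1 - wx) * (1 - wy) * (1 - wz), wx * (1 - wy) * (1 - wz),
              (1 - wx) * wy * (1 - wz),       wx * wy * (1 - wz),
              (1 - wx) * (1 - wy) * wz,       wx * (1 - wy) * wz,
              (1 - wx) * wy * wz,             wx * wy * wz)
  acc <- 0
  for (corner in 1:8) acc <- acc + cw[, corner] * mask$data[base + off[corner]]
  acc >= 0.5 & tri$inside
}
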