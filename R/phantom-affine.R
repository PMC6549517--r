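#' Time-varying affine maps for the integration-accuracy phantom
#'
#' An affine motion `x(t) = A(t) x0 + b(t)` induces the velocity field
#' `v(x, t) = A'(t) A(t)^-1 (x - b(t)) + b'(t)`, which is linear in space,
#' so trilinear sampling of the gridded field is exact and any deviation of
#' a traced pathline from the closed form is attributable to the time
#' integrator. Positions in mm, velocities returned by the field in m/s.
#'
#' `affine_rotation()` is steady in time as a field (solid-body rotation),
#' making it the cleanest integrator oracle; `affine_translation()` is a
#' uniform flow; `affine_contraction()` is a time-varying diagonal
#' contraction/dilation resembling a beating chamber.
#'
#' @param velocity_mm_s translation velocity, mm/s (length 3).
#' @param omega angular velocity about the z axis, rad/s.
#' @param center rotation / contraction centre, mm.
#' @param rates fractional scaling per cycle along each axis, e.g.
#'   `c(-0.3, -0.3, 0.2)` scales x and y by `1 - 0.3 t/cycle`.
#' @param cycle_s cycle duration used to normalize `rates`.
#'
#' @return An object of class `affine_map`: a list of functions `A(t)`,
#'   `Adot(t)`, `b(t)`, `bdot(t)`.
#' @name affine_maps
NULL

affine_map <- function(A, Adot, b, bdot) {
  structure(list(A = A, Adot = Adot, b = b, bdot = bdot),
            class = "affine_map")
}

#' @rdname affine_maps
#' @export
affine_translation <- function(velocity_mm_s = c(100, 0, 0)) {
  v <- as.numeric(velocity_mm_s)
  affine_map(A = function(t) diag(3), Adot = function(t) matrix(0, 3, 3),
             b = function(t) v * t, bdot = function(t) v)
}

#' @rdname affine_maps
#' @export
affine_rotation <- function(omega = pi, center = c(0, 0, 0)) {
  c0 <- as.numeric(center)
  R <- function(th) matrix(c(cos(th), sin(th), 0,
                             -sin(th), cos(th), 0,
                             0, 0, 1), 3, 3)
  Rd <- function(th) omega * matrix(c(-sin(th), cos(th), 0,
                                      -cos(th), -sin(th), 0,
                                      0, 0, 0), 3, 3)
  affine_map(A = function(t) R(omega * t),
             Adot = function(t) Rd(omega * t),
             b = function(t) c0 - R(omega * t) %*% c0,
             bdot = function(t) -Rd(omega * t) %*% c0)
}

#' @rdname affine_maps
#' @export
affine_contraction <- function(rates = c(-0.3, -0.3, 0.2), cycle_s = 1,
                               center = c(0, 0, 0)) {
  r <- as.numeric(rates) / cycle_s
  c0 <- as.numeric(center)
  S <- function(t) diag(1 + r * t)
  Sd <- function(t) diag(r)
  affine_map(A = S, Adot = Sd,
             b = function(t) c0 - S(t) %*% c0,
             bdot = function(t) -Sd(t) %*% c0)
}

#' Affine phantom: gridded velocity field with closed-form trajectories
#'
#' Samples the velocity field of a time-varying affine motion (see
#' [affine_maps]) on the grid and cardiac frames of `spec`, and returns the
#' exact trajectory function for oracle comparison against the numeric
#' integrator. The ED segmentation is a centred sphere.
#'
#' @param spec a [phantom_spec()] with `phantom_kind = "affine"`.
#' @param map an [affine_maps] object; default solid-body rotation at
#'   `pi` rad/s about the grid centre.
#' @param mask_radius_frac ED-sphere radius as a fraction of the smallest
#'   half-extent of the grid.
#'
#' @return A list of class `affine_phantom` with `field`, `ed_mask`,
#'   `es_mask`, and `trajectory`, a `function(x0, times)` mapping seed
#'   positions (`n x 3` mm, taken at the ED time) to an `n x 3 x length(times)`
#'   array of closed-form positions.
#' @export
make_affine_phantom <- function(spec, map = NULL, mask_radius_frac = 0.3) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$phantom_kind != "affine")
    stop('`spec$phantom_kind` must be "affine"', call. = FALSE)
  dims <- spec$dims
  h <- spec$spacing_mm
  center <- (dims / 2) * h
  if (is.null(map)) map <- affine_rotation(omega = pi, center = center)
  n <- spec$n_frames
  frame_times <- (seq_len(n) - 1) * spec$cycle_s / n
  t_ed <- frame_times[spec$ed_frame + 1]

  # voxel-centre coordinates
  gx <- (seq_len(dims[1]) - 0.5) * h
  gy <- (seq_len(dims[2]) - 0.5) * h
  gz <- (seq_len(dims[3]) - 0.5) * h
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))

  vals <- array(0, c(dims, n, 3L))
  nxyz <- prod(dims)
  for (f in seq_len(n)) {
    t <- frame_times[f]
    A <- map$A(t)
    if (abs(det(A)) < 1e-12)
      stop(sprintf("affine map singular at frame %d (t = %.3f s)", f - 1, t),
           call. = FALSE)
    M <- map$Adot(t) %*% solve(A)
    b <- as.numeric(map$b(t)); bd <- as.numeric(map$bdot(t))
    v <- sweep(pts, 2, b, "-") %*% t(M)
    v <- sweep(v, 2, bd, "+") / 1000          # mm/s -> m/s
    for (comp in 1:3)
      vals[(nxyz * ((f - 1) + n * (comp - 1))) + seq_len(nxyz)] <- v[, comp]
  }
  field <- velocity_field(vals, spacing = h, frame_times = frame_times,
                          venc_cms = 120, cycle_s = spec$cycle_s)

  r <- mask_radius_frac * min(dims * h) / 2
  sph <- array(0, dims)
  d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
        (pts[, 3] - center[3])^2
  sph[d2 <= r^2] <- 1
  ed_mask <- chamber_mask(sph, frame = spec$ed_frame, label = "LV", spacing = h)
  es_mask <- chamber_mask(sph, frame = spec$es_frame, label = "LV", spacing = h)

  A_ed_inv <- solve(map$A(t_ed))
  b_ed <- as.numeric(map$b(t_ed))
  trajectory <- function(x0, times) {
    if (is.null(dim(x0))) x0 <- matrix(x0, ncol = 3)
    ref <- sweep(x0, 2, b_ed, "-") %*% t(A_ed_inv)
    out <- array(NA_real_, c(nrow(x0), 3, length(times)))
    for (j in seq_along(times)) {
      t <- times[j]
      out[, , j] <- sweep(ref %*% t(map$A(t)), 2, as.numeric(map$b(t)), "+")
    }
    out
  }
  structure(list(field = field, ed_mask = ed_mask, es_mask = es_mask,
                 trajectory = trajectory, map = map, spec = spec),
            class = "affine_phantom")
}
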