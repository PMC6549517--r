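#' Seed grid filling the end-diastolic segmentation
#'
#' Emits one seed per cell of an isotropic lattice clipped to the ED LV
#' mask. With the default spacing equal to the voxel spacing the lattice is
#' aligned to the voxel lattice (one seed at each in-mask voxel centre),
#' matching the convention that each pathline represents a blood volume
#' equal to the grid density (`spacing^3`).
#'
#' @param ed_mask a [chamber_mask()] at end-diastole.
#' @param spacing_mm isotropic seed spacing, mm; defaults to the voxel
#'   spacing (which must then be isotropic).
#'
#' @return A tibble of class `seed_grid` with columns `seed`, `x`, `y`, `z`
#'   (world mm) and attributes `spacing_mm` and `cell_volume_mm3`.
#' @export
seed_grid <- function(ed_mask, spacing_mm = NULL) {
  stopifnot(inherits(ed_mask, "chamber_mask"))
  if (is.null(spacing_mm)) {
    if (diff(range(ed_mask$spacing)) > 1e-9)
      stop("anisotropic voxels: give `spacing_mm` explicitly", call. = FALSE)
    spacing_mm <- ed_mask$spacing[1]
  }
  if (spacing_mm <= 0) stop("`spacing_mm` must be > 0", call. = FALSE)
  d <- dim(ed_mask$data)
  ext <- d * ed_mask$spacing
  nlat <- floor(ext / spacing_mm)
  # lattice cell centres in world mm
  cx <- ed_mask$origin[1] + (seq_len(nlat[1]) - 0.5) * spacing_mm
  cy <- ed_mask$origin[2] + (seq_len(nlat[2]) - 0.5) * spacing_mm
  cz <- ed_mask$origin[3] + (seq_len(nlat[3]) - 0.5) * spacing_mm
  pts <- cbind(rep(cx, times = nlat[2] * nlat[3]),
               rep(rep(cy, each = nlat[1]), times = nlat[3]),
               rep(cz, each = nlat[1] * nlat[2]))
  keep <- mask_inside(ed_mask, pts, method = "nearest")
  if (!any(keep)) stop("no seeds: ED mask is empty on the lattice", call. = FALSE)
  pts <- pts[keep, , drop = FALSE]
  out <- tibble::tibble(seed = seq_len(nrow(pts)),
                        x = pts[, 1], y = pts[, 2], z = pts[, 3])
  attr(out, "spacing_mm") <- spacing_mm
  attr(out, "cell_volume_mm3") <- spacing_mm^3
  class(out) <- c("seed_grid", class(out))
  out
}

#' Trace pathlines backward and forward from end-diastole
#'
#' Integrates each seed's trajectory with a fixed-step fourth-order
#' Runge-Kutta scheme: the backward branch runs in the reversed velocity
#' field from the ED time down to the preceding end-systole (where did the
#' blood come from?), the forward branch from ED up to end-systole (where
#' is it going?). The step is `step_fraction` of the inter-frame interval,
#' rounded so that steps tile each frame interval exactly (the field is
#' linear in time within an interval, so fourth-order convergence is
#' preserved). Positions and velocities are recorded at every frame time;
#' merging the branches covers the full traced window.
#'
#' Trajectories that leave the grid are frozen at the exit point and
#' flagged (`truncated`, reason `"domain_exit"`); non-finite velocities
#' invalidate the pathline (reason `"nonfinite"`). The number of pathlines
#' always equals the number of seeds.
#'
#' @param field a [velocity_field()].
#' @param seeds a [seed_grid()].
#' @param timing a [timing_result()].
#' @param step_fraction integration step as a fraction of the inter-frame
#'   interval (default 0.2).
#'
#' @return An object of class `pathline_set`: list with
#' * `times` — sample times (s) on the trace axis (ED time = `t_ed`),
#'   spanning `[t_es_prev, t_es]`
#' * `positions` — array `(n_seeds, n_samples, 3)` mm
#' * `velocities` — array `(n_seeds, n_samples, 3)` m/s
#' * `in_domain` — logical `(n_seeds, n_samples)`
#' * `status` — tibble: `seed`, `valid`, `truncated`, `reason`
#' * `seeds`, `timing`, `window`, `cell_volume_mm3`, `step_fraction`
#' @export
trace_pathlines <- function(field, seeds, timing, step_fraction = 0.2) {
  stopifnot(inherits(field, "velocity_field"), inherits(seeds, "seed_grid"),
            inherits(timing, "timing_result"))
  if (step_fraction <= 0 || step_fraction > 1)
    stop("`step_fraction` must be in (0, 1]", call. = FALSE)
  w <- trace_window(timing)
  n <- timing$n_frames
  s_off <- (timing$es_frame - timing$ed_frame) %% n
  # frame times along the trace axis
  fw_times <- vapply(0:s_off, function(o)
    w$t_ed + speedless_dt(timing$frame_times, timing$cycle_s,
                          timing$ed_frame, o), numeric(1))
  bw_times <- vapply(seq(n, s_off), function(o) {
    if (o == n) w$t_ed - timing$cycle_s + timing$cycle_s  # t_ed itself
    else w$t_ed - (timing$cycle_s - speedless_dt(timing$frame_times,
                                                 timing$cycle_s,
                                                 timing$ed_frame, o))
  }, numeric(1))
  n_sub <- max(1L, round(1 / step_fraction))

  pos0 <- as.matrix(seeds[, c("x", "y", "z")])
  fwd <- integrate_branch(field, pos0, fw_times, n_sub, direction = +1)
  bwd <- integrate_branch(field, pos0, bw_times, n_sub, direction = -1)

  # merge: backward samples reversed (t_es_prev .. t_ed), drop duplicate ED
  nb <- length(bw_times)
  ord <- nb:1
  times <- c(bw_times[ord], fw_times[-1])
  n_samp <- length(times)
  n_seed <- nrow(pos0)
  positions <- array(NA_real_, c(n_seed, n_samp, 3))
  velocities <- array(NA_real_, c(n_seed, n_samp, 3))
  in_domain <- matrix(NA, n_seed, n_samp)
  positions[, 1:nb, ] <- bwd$positions[, ord, , drop = FALSE]
  positions[, (nb + 1):n_samp, ] <- fwd$positions[, -1, , drop = FALSE]
  velocities[, 1:nb, ] <- bwd$velocities[, ord, , drop = FALSE]
  velocities[, (nb + 1):n_samp, ] <- fwd$velocities[, -1, , drop = FALSE]
  in_domain[, 1:nb] <- bwd$in_domain[, ord, drop = FALSE]
  in_domain[, (nb + 1):n_samp] <- fwd$in_domain[, -1, drop = FALSE]

  reason <- rep(NA_character_, n_seed)
  reason[fwd$exited | bwd$exited] <- "domain_exit"
  reason[fwd$invalid | bwd$invalid] <- "nonfinite"
  status <- tibble::tibble(
    seed = seeds$seed,
    valid = !(fwd$invalid | bwd$invalid),
    truncated = fwd$exited | bwd$exited,
    reason = reason)

  structure(list(times = times, positions = positions,
                 velocities = velocities, in_domain = in_domain,
                 status = status, seeds = seeds, timing = timing, window = w,
                 cell_volume_mm3 = attr(seeds, "cell_volume_mm3"),
                 step_fraction = step_fraction),
            class = "pathline_set")
}

## RK4 over the sample-time grid, n_sub equal substeps per interval.
## direction -1 integrates the reversed field backward in time; sample
## times are then descending.
integrate_branch <- function(field, pos0, sample_times, n_sub, direction) {
  n_seed <- nrow(pos0)
  ns <- length(sample_times)
  positions <- array(NA_real_, c(n_seed, ns, 3))
  velocities <- array(NA_real_, c(n_seed, ns, 3))
  in_dom <- matrix(TRUE, n_seed, ns)
  pos <- pos0
  active <- rep(TRUE, n_seed)
  invalid <- rep(FALSE, n_seed)
  exited <- rep(FALSE, n_seed)
  eval_v <- function(p, t) sample_velocity(field, p, t)
  sv <- eval_v(pos, sample_times[1])
  positions[, 1, ] <- pos
  velocities[, 1, ] <- sv$velocity
  in_dom[, 1] <- sv$in_domain
  if (ns == 1) return(list(positions = positions, velocities = velocities,
                           in_domain = in_dom, exited = exited,
                           invalid = invalid))
  for (k in 2:ns) {
    t0 <- sample_times[k - 1]
    t1 <- sample_times[k]
    hh <- (t1 - t0) / n_sub          # signed; direction -1 gives negative
    for (sub in seq_len(n_sub)) {
      t <- t0 + (sub - 1) * hh
      # velocities in m/s, positions mm: 1e3 scale inside the stages
      k1 <- eval_v(pos, t)
      k2 <- eval_v(pos + 500 * hh * k1$velocity, t + hh / 2)
      k3 <- eval_v(pos + 500 * hh * k2$velocity, t + hh / 2)
      k4 <- eval_v(pos + 1000 * hh * k3$velocity, t + hh)
      step <- (1000 * hh / 6) *
        (k1$velocity + 2 * k2$velocity + 2 * k3$velocity + k4$velocity)
      bad <- !is.finite(step[, 1] + step[, 2] + step[, 3])
      out <- !(k1$in_domain & k2$in_domain & k3$in_domain & k4$in_domain)
      newly_bad <- active & bad
      newly_out <- active & !bad & out
      invalid[newly_bad] <- TRUE
      exited[newly_out] <- TRUE
      active <- active & !bad & !out
      pos[active, ] <- pos[active, , drop = FALSE] + step[active, , drop = FALSE]
    }
    sv <- eval_v(pos, t1)
    positions[, k, ] <- pos
    velocities[, k, ] <- sv$velocity
    velocities[!active, k, ] <- NA_real_
    in_dom[, k] <- sv$in_domain & active
  }
  list(positions = positions, velocities = velocities, in_domain = in_dom,
       exited = exited, invalid = invalid)
}

#' @export
print.pathline_set <- function(x, ...) {
  cat(sprintf("<pathline_set> %d pathlines, %d samples over [%.3f, %.3f] s\n",
              nrow(x$status), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  valid %d, truncated %d; cell volume %.3f mm^3\n",
              sum(x$status$valid), sum(x$status$truncated),
              x$cell_volume_mm3))
  invisible(x)
}

#' Tidy a pathline set into a long tibble
#'
#' One row per pathline sample: `seed`, `time`, `x`, `y`, `z`, `vx`, `vy`,
#' `vz`, `speed`, `in_domain`.
#'
#' @param x a [trace_pathlines()] result.
#' @param ... unused.
#' @method tidy pathline_set
#' @export
tidy.pathline_set <- function(x, ...) {
  n_seed <- nrow(x$status)
  ns <- length(x$times)
  px <- as.vector(x$positions[, , 1])
  py <- as.vector(x$positions[, , 2])
  pz <- as.vector(x$positions[, , 3])
  vx <- as.vector(x$velocities[, , 1])
  vy <- as.vector(x$velocities[, , 2])
  vz <- as.vector(x$velocities[, , 3])
  dom <- as.vector(x$in_domain)
  tibble::tibble(
    seed = rep(x$status$seed, times = ns),
    time = rep(x$times, each = n_seed),
    x = px, y = py, z = pz, vx = vx, vy = vy, vz = vz,
    speed = sqrt(vx^2 + vy^2 + vz^2),
    in_domain = dom)
}

## Sample index of the ED time within a pathline set.
ed_sample_index <- function(pl) {
  which.min(abs(pl$times - pl$window$t_ed))
}
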