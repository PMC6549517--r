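#' Duct phantom: a box-shaped LV with analytically known flow components
#'
#' Builds a piecewise-steady velocity field in which a box-shaped "LV" is
#' crossed by straight axial flow lanes. Each lane (a `(y, z)` column of the
#' chamber cross-section) is assigned to one flow component, and its
#' diastolic and systolic speeds are solved so that the lane's transit over
#' the traced window realizes exactly that component:
#'
#' * *Direct flow* lanes flow during both diastole and systole; every seed
#'   enters across the inflow face during diastole and leaves across the
#'   outflow face during systole.
#' * *Retained inflow* lanes flow only during diastole: seeds enter but are
#'   not ejected.
#' * *Delayed ejection flow* lanes flow only during systole: seeds start
#'   within the chamber and are ejected.
#' * *Residual volume* lanes never move.
#'
#' Lane speeds are solved against the linearly time-interpolated speed
#' profile the tracer actually integrates (including the one-frame ramps at
#' regime switches), with zero-speed guard frames on the retained-inflow and
#' delayed-ejection regime edges so that neither branch picks up
#' displacement from the other half of the cycle. Inflow and outflow tract
#' extensions continue each lane beyond the chamber so trajectories have
#' somewhere to come from and go to; a zero-velocity tissue shell surrounds
#' the flow domain. Component fractions are realized by largest-remainder
#' apportionment of the cross-section columns, i.e. to within one column of
#' the prescription.
#'
#' The ED segmentation is the full box. The ES segmentation is the box minus
#' the direct-flow lanes' footprint: a static end-systolic mask must contain
#' the delayed-ejection blood at the previous end-systole and the retained
#' inflow at the current one, which pins its footprint to the non-direct
#' lanes (see the methods vignette for why this also fixes the phantom's
#' inflow/outflow bookkeeping).
#'
#' @param spec a [phantom_spec()] with `phantom_kind = "duct"`.
#'
#' @return A list of class `duct_phantom`:
#' * `field` — [velocity_field()]
#' * `ed_mask`, `es_mask` — [chamber_mask()] at the ED / ES frames
#' * `ground_truth` — tibble with one row per seed: `seed`, `x`, `y`, `z`
#'   (mm), `label`, `entry_time` (s, `NA` for started-inside seeds), plus a
#'   `trajectory` attribute, `function(seed, times)` giving closed-form
#'   positions
#' * `lane_speeds` — tibble of per-component per-frame axial speeds (m/s)
#' * `geometry` — internal layout (voxel index ranges, faces)
#' @export
make_duct_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$phantom_kind != "duct")
    stop('`spec$phantom_kind` must be "duct"', call. = FALSE)
  g <- duct_geometry(spec)
  n <- spec$n_frames
  h <- spec$spacing_mm
  dt <- spec$cycle_s / n
  frame_times <- (seq_len(n) - 1) * dt

  counts <- apportion_columns(spec$fractions, g$n_cols)
  if (any(counts == 0 & spec$fractions > 0)) {
    need <- ceiling(1 / min(spec$fractions[spec$fractions > 0]))
    stop(sprintf(paste0("prescribed fractions unachievable on this grid: the ",
                        "chamber cross-section has %d columns but the smallest ",
                        "positive fraction needs at least %d; increase the grid ",
                        "to at least %d^3 voxels"),
                 g$n_cols, need,
                 ceiling(3 * sqrt(need)) * 3 + 8), call. = FALSE)
  }

  speeds <- duct_lane_speeds(spec, g)   # mm/s per frame, 4 components
  if (!is.null(spec$peak_speed_ms) &&
      max(speeds) / 1000 > spec$peak_speed_ms + 1e-12)
    stop(sprintf("required lane speed %.3f m/s exceeds peak_speed_ms = %.3f",
                 max(speeds) / 1000, spec$peak_speed_ms), call. = FALSE)

  # column assignment, y-major order over the S_y x S_z cross-section;
  # ES-mask footprint = the non-direct prefix (DEF, RV, RI), DF last
  order_idx <- c(3L, 4L, 2L, 1L)        # DEF, RV, RI, DF
  col_comp <- rep.int(order_idx, counts[order_idx])
  dims <- spec$dims
  vals <- array(0, c(dims, n, 3L))
  nxyz <- prod(dims)
  cs <- expand.grid(iz = g$z_idx, iy = g$y_idx)  # y-major: y varies slowest
  # spatial linear offsets of each column's flow voxels
  col_spat <- function(cols) {
    iy <- cs$iy[cols]; iz <- cs$iz[cols]
    as.vector(outer(g$flow_x, (iy - 1) * dims[1] + (iz - 1) * dims[1] * dims[2], "+"))
  }
  for (comp in 1:4) {
    cols <- which(col_comp == comp)
    if (!length(cols)) next
    sp <- speeds[comp, ]
    if (all(sp == 0)) next
    spat <- col_spat(cols)
    for (f in which(sp != 0))
      vals[spat + nxyz * (f - 1)] <- sp[f] / 1000  # m/s
  }

  field <- velocity_field(vals, spacing = h, frame_times = frame_times,
                          venc_cms = 120, cycle_s = spec$cycle_s)

  ed <- array(0, dims)
  ed[g$box_x, g$y_idx, g$z_idx] <- 1
  es <- array(0, dims)
  es_cols <- which(col_comp != 1L)
  if (length(es_cols)) {
    iy <- cs$iy[es_cols]; iz <- cs$iz[es_cols]
    spat <- as.vector(outer(g$box_x, (iy - 1) * dims[1] + (iz - 1) * dims[1] * dims[2], "+"))
    es[spat] <- 1
  }
  ed_mask <- chamber_mask(ed, frame = spec$ed_frame, label = "LV", spacing = h)
  es_mask <- chamber_mask(es, frame = spec$es_frame, label = "LV", spacing = h)

  gt <- duct_ground_truth(spec, g, col_comp, cs, speeds, frame_times, ed_mask)

  lane_speeds <- tibble::tibble(
    component = factor(rep(component_levels(), each = n),
                       levels = component_levels()),
    frame = rep(0:(n - 1), 4),
    speed_ms = as.vector(t(speeds)) / 1000)

  structure(list(field = field, ed_mask = ed_mask, es_mask = es_mask,
                 ground_truth = gt, lane_speeds = lane_speeds,
                 geometry = g, spec = spec),
            class = "duct_phantom")
}

## Voxel-index layout of the duct phantom. All indices 1-based here.
duct_geometry <- function(spec) {
  dims <- spec$dims
  L <- (dims[1] - 8L) %/% 3L
  if (L < 3L)
    stop("grid too coarse for the duct phantom along x: need at least 17 voxels",
         call. = FALSE)
  # flow domain x voxels 3..nx-2 (0-based 2..nx-3); upstream extension L+2,
  # chamber L, downstream the rest (>= L+2)
  flow_x <- 3:(dims[1] - 2L)
  box_x <- (L + 5L):(2L * L + 4L)
  my <- dims[2] %/% 3L; mz <- dims[3] %/% 3L
  y_idx <- (my + 1L):(dims[2] - my)
  z_idx <- (mz + 1L):(dims[3] - mz)
  list(L = L, flow_x = flow_x, box_x = box_x, y_idx = y_idx, z_idx = z_idx,
       n_cols = length(y_idx) * length(z_idx),
       # world-mm faces of the chamber along x (voxel i spans [(i-1)h, ih])
       x_in_face = (box_x[1] - 1) * spec$spacing_mm,
       x_out_face = box_x[length(box_x)] * spec$spacing_mm,
       target_mm = (L + 2) * spec$spacing_mm)
}

## Largest-remainder apportionment of n_cols columns to the four fractions.
apportion_columns <- function(fractions, n_cols) {
  exact <- fractions * n_cols
  base <- floor(exact)
  rem <- n_cols - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## Per-frame axial lane speed (mm/s) for each component (rows: DF, RI, DEF,
## RV), solved so the traced displacement over the relevant branch equals
## the chamber length plus a two-voxel margin.
duct_lane_speeds <- function(spec, g) {
  n <- spec$n_frames
  dt <- spec$cycle_s / n
  s <- (spec$es_frame - spec$ed_frame) %% n      # systole length, frames
  n_d <- n - s                                    # diastole length, frames
  if (s < 4L || n_d < 4L)
    stop("duct phantom needs at least 4 frames in each of systole and diastole",
         call. = FALSE)
  D <- g$target_mm
  off <- function(f) (f - spec$ed_frame) %% n    # frame -> offset from ED
  o <- off(0:(n - 1))
  speeds <- matrix(0, 4, n)

  # Direct flow: diastolic speed v_d on offsets [s, n-1], systolic v_s on
  # [0, s-1]. Traced displacement of each branch (with the ramp between the
  # last diastolic frame and ED shared by both solves):
  #   backward: (n-1-s) dt v_d + dt (v_d + v_s)/2 = D
  #   forward:  (s-1) dt v_s + dt (v_s + v_d)/2 = D
  A <- rbind(c((n - 1 - s) + 0.5, 0.5),
             c(0.5, (s - 1) + 0.5)) * dt
  v <- solve(A, c(D, D))
  speeds[1, o >= s] <- v[1]
  speeds[1, o < s] <- v[2]

  # Retained inflow: diastole only, zero on the first diastolic frame so the
  # forward branch sees no ramp; displacement (n-s-1) dt v = D.
  v_ri <- D / ((n_d - 1) * dt)
  speeds[2, o >= s + 1] <- v_ri

  # Delayed ejection: systole only with guard frames at both ends of
  # systole; displacement (s-3) dt v = D.
  v_def <- D / ((s - 3) * dt)
  speeds[3, o >= 2 & o <= s - 2] <- v_def

  speeds
}

## Exact integral of the cyclic, linearly-interpolated per-frame speed
## profile from time a to b (a <= b, any reals). Uniform frame spacing.
speed_profile_integral <- function(speeds, dt, cycle, a, b) {
  int_0_to <- function(t) {
    full <- floor(t / cycle)
    tau <- t - full * cycle
    k <- floor(tau / dt)              # 0-based interval index
    u <- tau - k * dt
    n <- length(speeds)
    v0 <- speeds[(k %% n) + 1]
    v1 <- speeds[((k + 1) %% n) + 1]
    csum <- cumsum((speeds + speeds[c(2:n, 1)]) / 2 * dt)
    whole <- if (k >= 1) csum[k] else 0
    full * csum[n] + whole + v0 * u + (v1 - v0) * u^2 / (2 * dt)
  }
  int_0_to(b) - int_0_to(a)
}

## Time t <= t_ed at which the cumulative backward displacement from t_ed
## reaches `depth` (mm). Walks intervals backward; quadratic solve inside
## the crossing interval. Returns NA if never reached within `window` s.
backward_crossing_time <- function(speeds, dt, cycle, t_ed, depth, window) {
  if (depth <= 0) return(t_ed)
  n <- length(speeds)
  acc <- 0
  t_hi <- t_ed
  repeat {
    if (t_ed - t_hi >= window) return(NA_real_)
    # interval [t_hi - u, t_hi] lies within one frame interval
    k_hi <- ceiling(round(t_hi / dt, 9))          # frame index at/above t_hi
    t_lo <- (k_hi - 1) * dt
    if (t_lo == t_hi) t_lo <- t_hi - dt
    seg <- speed_profile_integral(speeds, dt, cycle, t_lo, t_hi)
    if (acc + seg >= depth) {
      rem <- depth - acc
      v_hi <- speed_profile_at(speeds, dt, cycle, t_hi)
      v_lo <- span <- t_hi - t_lo
      v_lo <- speed_profile_at(speeds, dt, cycle, t_lo)
      # integral over [t_hi - u, t_hi]: v_hi u + (v_lo - v_hi) u^2 / (2 span)
      a2 <- (v_lo - v_hi) / (2 * span)
      roots <- if (abs(a2) < 1e-12) {
        if (v_hi <= 0) numeric(0) else rem / v_hi
      } else {
        disc <- v_hi^2 + 4 * a2 * rem
        if (disc < 0) numeric(0)
        else c((-v_hi + sqrt(disc)) / (2 * a2), (-v_hi - sqrt(disc)) / (2 * a2))
      }
      u <- roots[roots >= -1e-9 & roots <= span + 1e-9][1]
      if (!is.na(u)) return(t_hi - min(max(u, 0), span))
    }
    acc <- acc + seg
    t_hi <- t_lo
  }
}

speed_profile_at <- function(speeds, dt, cycle, t) {
  n <- length(speeds)
  tau <- t %% cycle
  k <- floor(tau / dt)
  u <- (tau - k * dt) / dt
  v0 <- speeds[(k %% n) + 1]
  v1 <- speeds[((k + 1) %% n) + 1]
  v0 * (1 - u) + v1 * u
}

## Ground-truth table for the duct phantom: per-seed component label,
## entry time (inflow components), and a closed-form trajectory closure.
duct_ground_truth <- function(spec, g, col_comp, cs, speeds, frame_times,
                              ed_mask) {
  seeds <- seed_grid(ed_mask, spacing_mm = spec$spacing_mm)
  h <- spec$spacing_mm
  dt <- spec$cycle_s / spec$n_frames
  t_ed <- frame_times[spec$ed_frame + 1]
  s <- (spec$es_frame - spec$ed_frame) %% spec$n_frames
  window_d <- (spec$n_frames - s) * dt            # diastole duration
  # map each seed to its cross-section column (y-major order used above)
  iy <- round((seeds$y / h) - 0.5) + 1
  iz <- round((seeds$z / h) - 0.5) + 1
  col_of <- match(paste(iy, iz), paste(cs$iy, cs$iz))
  comp <- col_comp[col_of]
  labels <- factor(component_levels()[comp], levels = component_levels())

  entry <- rep(NA_real_, nrow(seeds))
  for (cmp in c(1L, 2L)) {                        # DF, RI enter during diastole
    sel <- which(comp == cmp)
    if (!length(sel)) next
    depths <- seeds$x[sel] - g$x_in_face
    for (d in unique(depths)) {
      tt <- backward_crossing_time(speeds[cmp, ], dt, spec$cycle_s,
                                   t_ed, d, window_d)
      entry[sel[depths == d]] <- tt
    }
  }

  gt <- tibble::tibble(seed = seeds$seed, x = seeds$x, y = seeds$y,
                       z = seeds$z, label = labels, entry_time = entry)
  cyc <- spec$cycle_s
  traj <- function(seed, times) {
    i <- match(seed, gt$seed)
    cmp <- comp[i]
    disp <- vapply(times, function(t)
      if (t >= t_ed) speed_profile_integral(speeds[cmp, ], dt, cyc, t_ed, t)
      else -speed_profile_integral(speeds[cmp, ], dt, cyc, t, t_ed),
      numeric(1))
    cbind(x = gt$x[i] + disp, y = rep(gt$y[i], length(times)),
          z = rep(gt$z[i], length(times)))
  }
  attr(gt, "trajectory") <- traj
  gt
}

#' Pulsatile duct field for exercising the phase-contrast corrections
#'
#' Same geometry as [make_duct_phantom()] but every chamber lane carries the
#' same smooth pulsatile axial speed `peak * sin^2(pi t / cycle)`. The
#' per-frame voxel time series is then temporally smooth, which is the
#' regime in which velocity aliasing produces large frame-to-frame jumps
#' and temporal unwrapping is well posed; the piecewise-steady component
#' phantom switches regimes too abruptly to exercise that correction.
#'
#' @param spec a [phantom_spec()] (only geometry/timing fields are used).
#' @param peak_speed_ms peak lane speed, m/s.
#' @param venc_cms VENC recorded on the returned field, cm/s.
#'
#' @return A list with `field` (a [velocity_field()]) and `static_shell`
#'   (a [chamber_mask()]-like binary mask of the zero-velocity tissue
#'   surrounding the flow domain).
#' @export
make_pulsatile_duct_field <- function(spec, peak_speed_ms = 0.18,
                                      venc_cms = 120) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- duct_geometry(spec)
  n <- spec$n_frames
  dims <- spec$dims
  frame_times <- (seq_len(n) - 1) * spec$cycle_s / n
  prof <- peak_speed_ms * sin(pi * frame_times / spec$cycle_s)^2
  vals <- array(0, c(dims, n, 3L))
  nxyz <- prod(dims)
  spat <- as.vector(outer(
    g$flow_x,
    as.vector(outer((g$y_idx - 1) * dims[1],
                    (g$z_idx - 1) * dims[1] * dims[2], "+")), "+"))
  for (f in seq_len(n))
    vals[spat + nxyz * (f - 1)] <- prof[f]
  field <- velocity_field(vals, spacing = spec$spacing_mm,
                          frame_times = frame_times, venc_cms = venc_cms,
                          cycle_s = spec$cycle_s)
  shell <- array(1, dims)
  shell[spat] <- 0
  static <- chamber_mask(shell, frame = 0L, label = "LV",
                         spacing = spec$spacing_mm)
  list(field = field, static_shell = static)
}
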