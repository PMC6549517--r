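#' Detect static tissue from temporal velocity variation
#'
#' Static tissue carries a (possibly non-zero) background velocity offset
#' that is constant over the cardiac cycle, so it is identified by a small
#' temporal standard deviation of the measured velocity in every direction.
#' An optional magnitude image excludes air/background voxels via a signal
#' floor.
#'
#' @param field a [velocity_field()] of measured velocities.
#' @param magnitude optional 3D array of signal magnitude on the same grid.
#' @param sd_threshold temporal SD threshold, m/s (default 0.03, a typical
#'   noise floor at VENC 120 cm/s).
#' @param magnitude_floor minimum magnitude, used only when `magnitude` is
#'   given.
#'
#' @return An object of class `static_mask`: binary 3D array `data` plus
#'   the thresholds used.
#' @export
detect_static_tissue <- function(field, magnitude = NULL,
                                 sd_threshold = 0.03, magnitude_floor = 0) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$values)
  nxyz <- prod(d[1:3])
  nt <- d[4]
  max_sd <- 0
  for (cmp in 1:3) {
    m <- matrix(field$values[seq_len(nxyz * nt) + nxyz * nt * (cmp - 1)],
                nxyz, nt)
    mu <- rowMeans(m)
    v <- rowSums((m - mu)^2) / (nt - 1)
    max_sd <- pmax(max_sd, v)
  }
  keep <- sqrt(max_sd) < sd_threshold
  if (!is.null(magnitude)) {
    if (!identical(dim(magnitude), d[1:3]))
      stop("`magnitude` must match the velocity grid", call. = FALSE)
    keep <- keep & as.vector(magnitude) > magnitude_floor
  }
  if (!any(keep))
    stop(paste0("no static voxels found; raise `sd_threshold` (current ",
                sd_threshold, " m/s) or check the data"), call. = FALSE)
  structure(list(data = array(as.numeric(keep), d[1:3]),
                 sd_threshold = sd_threshold,
                 magnitude_floor = if (is.null(magnitude)) NA_real_ else magnitude_floor,
                 spacing = field$spacing, origin = field$origin),
            class = "static_mask")
}

#' Background phase correction with a quartic polynomial
#'
#' Fits a full three-variable polynomial of total degree 4 (35 terms, see
#' [poly4_terms()]) per velocity direction to the temporal-mean measured
#' velocity over the static-tissue voxels, and subtracts the fitted surface
#' from every frame. Eddy-current background offsets are static over the
#' cycle, so fitting the temporal mean uses all frames' information and is
#' robust to noise; the correction is idempotent up to numerical precision.
#'
#' @param field a [velocity_field()] of measured velocities.
#' @param static_mask a `static_mask` from [detect_static_tissue()] (any
#'   object with a binary 3D `data` array works).
#'
#' @return A list with `field` (corrected [velocity_field()]) and `model`
#'   (class `background_model`: `coefficients` 35 x 3 in m/s per
#'   normalized-coordinate monomial, and per-direction `residual_rms` m/s
#'   over the static voxels).
#' @export
correct_background_phase <- function(field, static_mask) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$values)
  sel <- which(static_mask$data == 1)
  nterms <- nrow(poly4_terms())
  if (length(sel) < 2 * nterms)
    stop(sprintf("background fit needs at least %d static voxels, got %d",
                 2 * nterms, length(sel)), call. = FALSE)
  coords <- normalized_grid_coords(d[1:3])
  X <- poly4_design(coords[sel, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < nterms)
    stop(paste0("static voxels do not span a rank-sufficient degree-4 design ",
                "(coplanar or too concentrated); need wider spatial coverage"),
         call. = FALSE)
  nxyz <- prod(d[1:3])
  nt <- d[4]
  coef <- matrix(0, nterms, 3)
  rms <- numeric(3)
  corrected <- field$values
  Xfull <- NULL
  for (cmp in 1:3) {
    m <- matrix(field$values[seq_len(nxyz * nt) + nxyz * nt * (cmp - 1)],
                nxyz, nt)
    mu <- rowMeans(m)
    beta <- qr.coef(qrX, mu[sel])
    coef[, cmp] <- beta
    rms[cmp] <- sqrt(mean((mu[sel] - X %*% beta)^2))
    if (any(beta != 0)) {
      if (is.null(Xfull)) Xfull <- poly4_design(coords)
      surf <- as.vector(Xfull %*% beta)
      for (f in seq_len(nt)) {
        idx <- seq_len(nxyz) + nxyz * ((f - 1) + nt * (cmp - 1))
        corrected[idx] <- corrected[idx] - surf
      }
    }
  }
  model <- structure(list(coefficients = coef, residual_rms = rms,
                          terms = poly4_terms()),
                     class = "background_model")
  out <- field
  out$values <- corrected
  list(field = out, model = model)
}

#' Temporal phase unwrapping
#'
#' Velocities beyond the VENC alias by multiples of `2 * VENC`. Using all
#' temporal information in each voxel, this step chooses per-frame integer
#' wrap offsets `k` in `[-max_wraps, max_wraps]` that minimize the total
#' absolute frame-to-frame velocity jump around the full cyclic series
#' (ties broken toward the smallest total absolute velocity, anchoring the
#' series at the physiologic range). Only voxels whose measured cyclic
#' series contains a jump exceeding the VENC are touched; a wrap-free
#' series passes through unchanged.
#'
#' @param field a [velocity_field()] of measured velocities.
#' @param max_wraps maximum wrap count considered per frame (default 2;
#'   at VENC 120 cm/s that admits true speeds to 3.6 m/s, beyond the LV
#'   physiologic range).
#'
#' @return The unwrapped [velocity_field()].
#' @export
unwrap_temporal <- function(field, max_wraps = 2) {
  stopifnot(inherits(field, "velocity_field"))
  venc_ms <- field$venc_cms / 100
  step <- 2 * venc_ms
  d <- dim(field$values)
  nxyz <- prod(d[1:3])
  nt <- d[4]
  out <- field
  for (cmp in 1:3) {
    m <- matrix(field$values[seq_len(nxyz * nt) + nxyz * nt * (cmp - 1)],
                nxyz, nt)
    jump <- abs(m - m[, c(2:nt, 1)])
    jmax <- jump[, 1]
    for (j in 2:nt) jmax <- pmax(jmax, jump[, j])
    cand <- which(jmax > venc_ms)
    if (!length(cand)) next
    fixed <- unwrap_series_matrix(m[cand, , drop = FALSE], step, max_wraps)
    m[cand, ] <- fixed
    out$values[seq_len(nxyz * nt) + nxyz * nt * (cmp - 1)] <- m
  }
  out
}

## Exact minimization of total cyclic |jump| (+ tiny total-|v| tie-break)
## over per-frame wrap offsets, vectorized across voxels. Dynamic program
## over the (2K+1) offset states; the cyclic closure is handled by
## conditioning on the first frame's state.
unwrap_series_matrix <- function(m, step, max_wraps) {
  K <- max_wraps
  states <- (-K):K
  ns <- length(states)
  nv <- nrow(m); nt <- ncol(m)
  eps <- 1e-7 / (nt * step)   # tie-break weight, far below any jump change
  best_cost <- rep(Inf, nv)
  best_path <- matrix(0L, nv, nt)
  for (s0 in seq_len(ns)) {
    v1 <- m[, 1] + states[s0] * step
    cost <- matrix(Inf, nv, ns)
    cost[, s0] <- eps * abs(v1)
    back <- array(0L, c(nv, ns, nt))
    prev_v <- matrix(rep(m[, 1], ns), nv, ns) +
      matrix(rep(states * step, each = nv), nv, ns)
    for (f in 2:nt) {
      cur_v <- matrix(rep(m[, f], ns), nv, ns) +
        matrix(rep(states * step, each = nv), nv, ns)
      new_cost <- matrix(Inf, nv, ns)
      for (j in seq_len(ns)) {
        cj <- matrix(Inf, nv, ns)
        for (i in seq_len(ns))
          cj[, i] <- cost[, i] + abs(cur_v[, j] - prev_v[, i])
        pick <- max.col(-cj, ties.method = "first")
        new_cost[, j] <- cj[cbind(seq_len(nv), pick)] + eps * abs(cur_v[, j])
        back[, j, f] <- pick
      }
      cost <- new_cost
      prev_v <- cur_v
    }
    # close the cycle back to frame 1 at state s0
    for (j in seq_len(ns))
      cost[, j] <- cost[, j] + abs(v1 - prev_v[, j])
    pick_last <- max.col(-cost, ties.method = "first")
    total <- cost[cbind(seq_len(nv), pick_last)]
    improve <- total < best_cost - 1e-15
    if (any(improve)) {
      path <- matrix(0L, nv, nt)
      path[, nt] <- pick_last
      for (f in nt:2)
        path[, f - 1] <- back[cbind(seq_len(nv), path[, f], rep(f, nv))]
      best_path[improve, ] <- path[improve, ]
      best_cost[improve] <- total[improve]
    }
  }
  m + matrix(states[best_path], nv, nt) * step
}

#' One-call measured-data correction pipeline
#'
#' Convenience wrapper running the correction chain on decoded
#' phase-contrast velocities: static-tissue detection, background
#' polynomial subtraction, then temporal unwrapping.
#'
#' @inheritParams detect_static_tissue
#' @inheritParams unwrap_temporal
#' @param static_mask optional precomputed `static_mask`; detected when
#'   omitted.
#' @return list with `field`, `static_mask`, `background`.
#' @export
preprocess_velocity <- function(field, magnitude = NULL, static_mask = NULL,
                                sd_threshold = 0.03, max_wraps = 2) {
  if (is.null(static_mask))
    static_mask <- detect_static_tissue(field, magnitude,
                                        sd_threshold = sd_threshold)
  bg <- correct_background_phase(field, static_mask)
  list(field = unwrap_temporal(bg$field, max_wraps = max_wraps),
       static_mask = static_mask, background = bg$model)
}
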