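#' Classify pathlines into the four LV flow components
#'
#' The end-systolic segmentation decides each pathline's origin and fate:
#' the backward-branch endpoint (at the preceding end-systole) inside or
#' outside the ES mask, and the forward-branch endpoint (at end-systole)
#' inside or outside it.
#'
#' * outside -> outside: *Direct flow* (entered during diastole, ejected)
#' * outside -> inside: *Retained inflow* (entered, not ejected)
#' * inside -> outside: *Delayed ejection flow* (started within, ejected)
#' * inside -> inside: *Residual volume* (started within, remains)
#'
#' Invalid or truncated pathlines receive no label (`NA`) and are excluded
#' from component aggregates; their count feeds the quality control.
#'
#' @param pathlines a [trace_pathlines()] result.
#' @param es_mask the end-systolic [chamber_mask()].
#' @param inside_test `"interpolated"` (mask occupancy >= 0.5 at the
#'   endpoint, sub-voxel consistent with the velocity interpolation) or
#'   `"nearest"`.
#'
#' @return A tibble with one row per pathline: `seed`, `valid`,
#'   `origin_inside`, `fate_inside`, `label` (factor over
#'   [component_levels()], `NA` for excluded pathlines).
#' @export
classify_components <- function(pathlines, es_mask,
                                inside_test = c("interpolated", "nearest")) {
  stopifnot(inherits(pathlines, "pathline_set"),
            inherits(es_mask, "chamber_mask"))
  inside_test <- match.arg(inside_test)
  ns <- length(pathlines$times)
  origin <- pathlines$positions[, 1, , drop = FALSE]
  fate <- pathlines$positions[, ns, , drop = FALSE]
  dim(origin) <- dim(fate) <- c(nrow(pathlines$status), 3)
  ok <- pathlines$status$valid & !pathlines$status$truncated
  origin_inside <- mask_inside(es_mask, origin, method = inside_test)
  fate_inside <- mask_inside(es_mask, fate, method = inside_test)
  lab <- dplyr::case_when(
    !ok ~ NA_character_,
    !origin_inside & !fate_inside ~ "Direct flow",
    !origin_inside & fate_inside ~ "Retained inflow",
    origin_inside & !fate_inside ~ "Delayed ejection flow",
    TRUE ~ "Residual volume")
  tibble::tibble(seed = pathlines$status$seed,
                 valid = ok,
                 origin_inside = origin_inside,
                 fate_inside = fate_inside,
                 label = factor(lab, levels = component_levels()))
}

#' Per-component volumes and volume ratios
#'
#' Each pathline represents `cell_volume_mm3` of blood; a component's
#' volume is its pathline count times that volume, and its ratio is the
#' volume as a percentage of the summed (traced) end-diastolic volume.
#'
#' @param labels tibble from [classify_components()].
#' @param cell_volume_mm3 represented blood volume per pathline, mm^3.
#'
#' @return tibble: `component`, `n_pathlines`, `volume_ml`, `volume_pct`
#'   (percentages sum to 100 over the four components).
#' @export
component_volumes <- function(labels, cell_volume_mm3) {
  counts <- table(labels$label[labels$valid])
  n <- as.numeric(counts[component_levels()])
  n[is.na(n)] <- 0
  vol <- n * cell_volume_mm3 / 1000
  tibble::tibble(
    component = factor(component_levels(), levels = component_levels()),
    n_pathlines = as.integer(n),
    volume_ml = vol,
    volume_pct = if (sum(vol) > 0) 100 * vol / sum(vol) else rep(0, 4))
}

#' Per-component kinetic energy at end-diastole
#'
#' `KE(c) = sum over pathlines p in c of 1/2 * rho * V_p * |v_p(t_ED)|^2`,
#' with the velocity sampled at the end-diastolic time, reported in mJ,
#' plus each component's percentage of the total end-diastolic KE.
#'
#' @param pathlines a [trace_pathlines()] result.
#' @param labels tibble from [classify_components()].
#' @param rho_kg_m3 blood mass density (default 1060 kg/m^3).
#'
#' @return tibble: `component`, `ke_mj`, `ke_pct`.
#' @export
component_kinetic_energy <- function(pathlines, labels, rho_kg_m3 = 1060) {
  stopifnot(rho_kg_m3 > 0)
  i_ed <- ed_sample_index(pathlines)
  v <- pathlines$velocities[, i_ed, ]
  dim(v) <- c(nrow(pathlines$status), 3)
  sp2 <- v[, 1]^2 + v[, 2]^2 + v[, 3]^2
  vol_m3 <- pathlines$cell_volume_mm3 * 1e-9
  ke_j <- 0.5 * rho_kg_m3 * vol_m3 * sp2       # per pathline, J
  ke <- vapply(component_levels(), function(cl) {
    sel <- labels$valid & !is.na(labels$label) & labels$label == cl
    sum(ke_j[sel], na.rm = TRUE)
  }, numeric(1))
  tot <- sum(ke)
  tibble::tibble(
    component = factor(component_levels(), levels = component_levels()),
    ke_mj = unname(ke) * 1000,
    ke_pct = if (tot > 0) 100 * unname(ke) / tot else rep(0, 4))
}

#' Derived conventional volumes from the flow components
#'
#' LV inflow = direct flow + retained inflow; stroke volume = direct flow +
#' delayed ejection flow; non-ejected volume = retained inflow + residual
#' volume. The same sums apply to the end-diastolic kinetic energies.
#'
#' @param volumes tibble from [component_volumes()].
#' @param kinetic_energy tibble from [component_kinetic_energy()].
#' @return tibble: `quantity`, `volume_ml`, `ke_mj`.
#' @export
derived_flow_volumes <- function(volumes, kinetic_energy = NULL) {
  v <- stats::setNames(volumes$volume_ml, as.character(volumes$component))
  k <- if (is.null(kinetic_energy)) stats::setNames(rep(NA_real_, 4), component_levels())
       else stats::setNames(kinetic_energy$ke_mj, as.character(kinetic_energy$component))
  lv <- component_levels()
  tibble::tibble(
    quantity = c("LV inflow", "Stroke volume", "Non-ejected volume"),
    volume_ml = unname(c(v[lv[1]] + v[lv[2]], v[lv[1]] + v[lv[3]],
                         v[lv[2]] + v[lv[4]])),
    ke_mj = unname(c(k[lv[1]] + k[lv[2]], k[lv[1]] + k[lv[3]],
                     k[lv[2]] + k[lv[4]])))
}

#' Entry times and the late-diastolic share of LV inflow
#'
#' For each inflow pathline (direct flow or retained inflow) the entry time
#' is the last backward-branch crossing from outside to inside the ED LV
#' mask, located by linear interpolation of the mask occupancy between the
#' bracketing frame samples. The late-diastolic inflow fractions are the
#' volume (and end-diastolic KE) of inflow pathlines entering at or after
#' the late-diastole onset, as percentages of total inflow volume (KE).
#'
#' @param pathlines a [trace_pathlines()] result.
#' @param labels tibble from [classify_components()].
#' @param ed_mask the end-diastolic [chamber_mask()] (diastolic chamber
#'   proxy for entry detection).
#' @param rho_kg_m3 blood density for the KE weighting.
#'
#' @return list with `entry_times` (tibble: `seed`, `entry_time`),
#'   `late_volume_pct`, `late_ke_pct`, and `late_onset_time`. With zero
#'   inflow the percentages are `NaN` and `flagged = TRUE`.
#' @export
late_diastolic_split <- function(pathlines, labels, ed_mask,
                                 rho_kg_m3 = 1060) {
  stopifnot(inherits(pathlines, "pathline_set"))
  w <- pathlines$window
  t_late <- w$t_late - ifelse(w$t_late > w$t_ed, pathlines$timing$cycle_s, 0)
  i_ed <- ed_sample_index(pathlines)
  inflow_labels <- component_levels()[1:2]
  sel <- which(labels$valid & labels$label %in% inflow_labels)
  n_inflow <- length(sel)
  if (n_inflow == 0) {
    return(list(entry_times = tibble::tibble(seed = integer(), entry_time = numeric()),
                late_volume_pct = NaN, late_ke_pct = NaN,
                late_onset_time = t_late, flagged = TRUE))
  }
  # backward samples 1..i_ed (ascending time); mask occupancy per sample
  occ <- matrix(NA_real_, n_inflow, i_ed)
  for (k in seq_len(i_ed)) {
    p <- pathlines$positions[sel, k, ]
    dim(p) <- c(n_inflow, 3)
    occ[, k] <- mask_occupancy(ed_mask, p)
  }
  entry <- rep(NA_real_, n_inflow)
  tms <- pathlines$times[seq_len(i_ed)]
  inside <- occ >= 0.5
  for (i in seq_len(n_inflow)) {
    cross <- which(!inside[i, -i_ed] & inside[i, -1])
    if (!length(cross)) { entry[i] <- tms[1]; next }  # entered before window
    k <- max(cross)
    o0 <- occ[i, k]; o1 <- occ[i, k + 1]
    frac <- if (o1 > o0) (0.5 - o0) / (o1 - o0) else 0.5
    entry[i] <- tms[k] + frac * (tms[k + 1] - tms[k])
  }
  v <- pathlines$velocities[sel, i_ed, ]
  dim(v) <- c(n_inflow, 3)
  ke <- 0.5 * rho_kg_m3 * (pathlines$cell_volume_mm3 * 1e-9) *
    (v[, 1]^2 + v[, 2]^2 + v[, 3]^2)
  late <- entry >= t_late
  list(entry_times = tibble::tibble(seed = labels$seed[sel], entry_time = entry),
       late_volume_pct = 100 * mean(late),
       late_ke_pct = if (sum(ke) > 0) 100 * sum(ke[late]) / sum(ke) else NaN,
       late_onset_time = t_late, flagged = FALSE)
}

## Trilinearly interpolated mask occupancy in [0, 1] (0 outside the hull).
mask_occupancy <- function(mask, positions) {
  d <- dim(mask$data)
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
  acc * tri$inside
}
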