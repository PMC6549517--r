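#' Full LV flow-component analysis for one exam
#'
#' Runs the whole chain on corrected velocity data: seed emission on an
#' isotropic grid filling the ED segmentation, backward/forward pathline
#' tracing, component classification, volume and end-diastolic kinetic
#' energy aggregation, derived volumes, late-diastolic inflow split,
#' inflow-outflow quality control, and conventional chamber metrics.
#'
#' @param field a corrected [velocity_field()].
#' @param ed_mask,es_mask LV [chamber_mask()] at ED and ES.
#' @param timing a [timing_result()].
#' @param seed_spacing_mm seed-lattice spacing (default: voxel spacing).
#' @param step_fraction RK4 step as a fraction of the frame interval.
#' @param rho_kg_m3 blood density for KE.
#' @param inside_test endpoint inside/outside test (see
#'   [classify_components()]).
#' @param qc_threshold_pct inflow-outflow exclusion threshold, percent.
#' @param height_cm,weight_kg optional biometrics for indexed volumes.
#' @param keep_pathlines keep the full pathline set in the result (large);
#'   default `TRUE`.
#'
#' @return An object of class `lvflow_result`: list with `volumes`, `ke`,
#'   `derived`, `late`, `qc`, `chamber`, `labels`, `pathlines` (optional),
#'   `timing`. Use [tidy.lvflow_result()] / [glance.lvflow_result()] for
#'   tabular views and `autoplot()` for a component summary figure.
#' @export
analyze_lv_flow <- function(field, ed_mask, es_mask, timing,
                            seed_spacing_mm = NULL, step_fraction = 0.2,
                            rho_kg_m3 = 1060,
                            inside_test = c("interpolated", "nearest"),
                            qc_threshold_pct = 15,
                            height_cm = NULL, weight_kg = NULL,
                            keep_pathlines = TRUE) {
  inside_test <- match.arg(inside_test)
  check_same_geometry(field, ed_mask, "velocity field and ED mask")
  check_same_geometry(field, es_mask, "velocity field and ES mask")
  seeds <- seed_grid(ed_mask, spacing_mm = seed_spacing_mm)
  pl <- trace_pathlines(field, seeds, timing, step_fraction = step_fraction)
  labels <- classify_components(pl, es_mask, inside_test = inside_test)
  vols <- component_volumes(labels, pl$cell_volume_mm3)
  ke <- component_kinetic_energy(pl, labels, rho_kg_m3 = rho_kg_m3)
  derived <- derived_flow_volumes(vols, ke)
  late <- late_diastolic_split(pl, labels, ed_mask, rho_kg_m3 = rho_kg_m3)
  qc <- dplyr::bind_cols(
    inflow_outflow_discrepancy(vols, threshold_pct = qc_threshold_pct),
    aberrant_fraction(pl)[, c("n_aberrant", "aberrant_pct")])
  chamber <- lv_global_metrics(ed_mask, es_mask,
                               heart_rate_bpm = timing$heart_rate_bpm,
                               height_cm = height_cm, weight_kg = weight_kg)
  structure(list(volumes = vols, ke = ke, derived = derived, late = late,
                 qc = qc, chamber = chamber, labels = labels,
                 pathlines = if (keep_pathlines) pl else NULL,
                 timing = timing),
            class = "lvflow_result")
}

#' @export
print.lvflow_result <- function(x, ...) {
  cat("<lvflow_result>\n")
  cat(sprintf("  LVEDV %.1f ml, LVEF %.1f%%\n",
              x$chamber$lvedv_ml, x$chamber$lvef_pct))
  tab <- dplyr::left_join(x$volumes, x$ke, by = "component")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-22s %6.1f ml (%5.1f%%)  KE %7.4f mJ (%5.1f%%)\n",
                as.character(tab$component[i]), tab$volume_ml[i],
                tab$volume_pct[i], tab$ke_mj[i], tab$ke_pct[i]))
  cat(sprintf("  inflow %.1f ml, outflow %.1f ml, discrepancy %.2f%% (%s)\n",
              x$qc$inflow_ml, x$qc$outflow_ml, x$qc$discrepancy_pct,
              if (x$qc$pass) "pass" else "FAIL"))
  if (!is.na(x$late$late_volume_pct))
    cat(sprintf("  late-diastolic inflow: %.1f%% of volume, %.1f%% of KE\n",
                x$late$late_volume_pct, x$late$late_ke_pct))
  invisible(x)
}

#' Tidy an LV flow analysis into a long metric table
#'
#' One row per computed quantity (`metric`, `value`, `unit`, `group`),
#' convenient for binding across exams and feeding [cohort_compare()].
#'
#' @param x an [analyze_lv_flow()] result.
#' @param ... unused.
#' @method tidy lvflow_result
#' @export
tidy.lvflow_result <- function(x, ...) {
  comp <- dplyr::left_join(x$volumes, x$ke, by = "component")
  rows <- list(
    tibble::tibble(metric = paste0(comp$component, " volume"),
                   value = comp$volume_ml, unit = "ml", group = "component"),
    tibble::tibble(metric = paste0(comp$component, " volume ratio"),
                   value = comp$volume_pct, unit = "%", group = "component"),
    tibble::tibble(metric = paste0(comp$component, " KE"),
                   value = comp$ke_mj, unit = "mJ", group = "component"),
    tibble::tibble(metric = paste0(comp$component, " KE ratio"),
                   value = comp$ke_pct, unit = "%", group = "component"),
    tibble::tibble(metric = paste0(x$derived$quantity, " volume"),
                   value = x$derived$volume_ml, unit = "ml", group = "derived"),
    tibble::tibble(metric = paste0(x$derived$quantity, " KE"),
                   value = x$derived$ke_mj, unit = "mJ", group = "derived"),
    tibble::tibble(metric = c("Late diastolic inflow volume",
                              "Late diastolic inflow KE"),
                   value = c(x$late$late_volume_pct, x$late$late_ke_pct),
                   unit = "% of inflow", group = "late diastole"),
    tibble::tibble(metric = c("LVEDV", "LVESV", "LVEF", "Stroke volume (masks)",
                              "Cardiac output"),
                   value = c(x$chamber$lvedv_ml, x$chamber$lvesv_ml,
                             x$chamber$lvef_pct, x$chamber$sv_ml,
                             x$chamber$co_l_min),
                   unit = c("ml", "ml", "%", "ml", "l/min"),
                   group = "chamber"),
    tibble::tibble(metric = c("Inflow-outflow discrepancy", "Aberrant pathlines"),
                   value = c(x$qc$discrepancy_pct, x$qc$aberrant_pct),
                   unit = "%", group = "qc"))
  dplyr::bind_rows(rows)
}

#' One-row summary of an LV flow analysis
#'
#' @param x an [analyze_lv_flow()] result.
#' @param ... unused.
#' @method glance lvflow_result
#' @export
glance.lvflow_result <- function(x, ...) {
  v <- stats::setNames(x$volumes$volume_pct, as.character(x$volumes$component))
  k <- stats::setNames(x$ke$ke_pct, as.character(x$ke$component))
  tibble::tibble(
    lvedv_ml = x$chamber$lvedv_ml, lvef_pct = x$chamber$lvef_pct,
    direct_flow_pct = v[[1]], retained_inflow_pct = v[[2]],
    delayed_ejection_pct = v[[3]], residual_volume_pct = v[[4]],
    direct_flow_ke_pct = k[[1]], retained_inflow_ke_pct = k[[2]],
    delayed_ejection_ke_pct = k[[3]], residual_volume_ke_pct = k[[4]],
    inflow_ml = x$qc$inflow_ml, stroke_volume_ml = x$qc$outflow_ml,
    late_inflow_volume_pct = x$late$late_volume_pct,
    late_inflow_ke_pct = x$late$late_ke_pct,
    qc_discrepancy_pct = x$qc$discrepancy_pct, qc_pass = x$qc$pass,
    n_pathlines = nrow(x$labels), n_excluded = sum(!x$labels$valid))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
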