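#' Conventional global LV metrics from the ED and ES segmentations
#'
#' End-diastolic and end-systolic volumes from voxel counts, ejection
#' fraction, stroke volume, cardiac output, and (when height and weight are
#' given) body-surface-area indexed volumes.
#'
#' @param ed_mask,es_mask [chamber_mask()] objects on the same grid.
#' @param heart_rate_bpm heart rate, beats per minute.
#' @param height_cm,weight_kg optional subject biometrics for BSA indexing.
#' @param bsa_formula `"mosteller"` (default) or `"dubois"`.
#'
#' @return One-row tibble: `lvedv_ml`, `lvesv_ml`, `lvef_pct`, `sv_ml`,
#'   `co_l_min`, `bsa_m2`, `lvedvi_ml_m2`, `lvesvi_ml_m2`,
#'   `heart_rate_bpm`.
#' @export
lv_global_metrics <- function(ed_mask, es_mask, heart_rate_bpm,
                              height_cm = NULL, weight_kg = NULL,
                              bsa_formula = c("mosteller", "dubois")) {
  bsa_formula <- match.arg(bsa_formula)
  check_same_geometry(ed_mask, es_mask, "ED and ES masks")
  edv <- mask_volume_ml(ed_mask)
  esv <- mask_volume_ml(es_mask)
  if (edv <= 0) stop("empty ED segmentation (EDV = 0)", call. = FALSE)
  if (esv > edv)
    warning("ESV exceeds EDV; check the segmentations")
  sv <- edv - esv
  ef <- 100 * sv / edv
  bsa <- if (!is.null(height_cm) && !is.null(weight_kg))
    body_surface_area(height_cm, weight_kg, bsa_formula) else NA_real_
  tibble::tibble(
    lvedv_ml = edv, lvesv_ml = esv, lvef_pct = ef, sv_ml = sv,
    co_l_min = sv * heart_rate_bpm / 1000,
    bsa_m2 = bsa,
    lvedvi_ml_m2 = edv / bsa, lvesvi_ml_m2 = esv / bsa,
    heart_rate_bpm = heart_rate_bpm)
}

#' Body surface area
#'
#' Mosteller: `sqrt(height * weight / 3600)`; Du Bois:
#' `0.007184 * height^0.725 * weight^0.425`.
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @param formula `"mosteller"` or `"dubois"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  switch(formula,
         mosteller = sqrt(height_cm * weight_kg / 3600),
         dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425)
}

#' Left atrial fractional area change
#'
#' The largest and smallest LA areas are each measured twice (4-chamber
#' view planimetry) and averaged;
#' `FAC = (largest - smallest) * 100 / largest`.
#'
#' @param largest_cm2 two measurements of the largest LA area, cm^2.
#' @param smallest_cm2 two measurements of the smallest LA area, cm^2.
#' @return FAC in percent.
#' @export
la_fractional_area_change <- function(largest_cm2, smallest_cm2) {
  if (any(c(largest_cm2, smallest_cm2) < 0))
    stop("areas must be non-negative", call. = FALSE)
  lg <- mean(largest_cm2)
  sm <- mean(smallest_cm2)
  if (lg <= 0) stop("largest LA area is zero", call. = FALSE)
  if (sm > lg)
    stop("smallest LA area exceeds largest after averaging", call. = FALSE)
  (lg - sm) * 100 / lg
}
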