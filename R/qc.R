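#' Inflow-outflow consistency check
#'
#' In a conservative dataset the LV inflow traced during diastole must
#' match the volume ejected during systole. The discrepancy is
#' `|inflow - outflow| / inflow * 100`, where inflow = direct flow +
#' retained inflow and outflow is the flow-derived stroke volume (direct
#' flow + delayed ejection flow). Exams beyond the threshold (default 15%)
#' fail the gate.
#'
#' @param volumes tibble from [component_volumes()].
#' @param threshold_pct exclusion threshold in percent of inflow.
#'
#' @return One-row tibble: `inflow_ml`, `outflow_ml`, `discrepancy_pct`,
#'   `pass`.
#' @export
inflow_outflow_discrepancy <- function(volumes, threshold_pct = 15) {
  v <- stats::setNames(volumes$volume_ml, as.character(volumes$component))
  lv <- component_levels()
  inflow <- v[lv[1]] + v[lv[2]]
  outflow <- v[lv[1]] + v[lv[3]]
  if (inflow <= 0) stop("zero LV inflow: discrepancy undefined", call. = FALSE)
  disc <- abs(inflow - outflow) / inflow * 100
  tibble::tibble(inflow_ml = unname(inflow), outflow_ml = unname(outflow),
                 discrepancy_pct = unname(disc),
                 threshold_pct = threshold_pct,
                 pass = unname(disc) <= threshold_pct)
}

#' Fraction of aberrant pathlines
#'
#' A pathline is aberrant when any of its samples leaves the supplied
#' bounds (default: the velocity-grid bounding box, i.e. the tracer's
#' domain-exit flag) or when it was invalidated during tracing. Aberrant
#' traces leaving the cardiac confines indicate impaired data quality.
#'
#' @param pathlines a [trace_pathlines()] result.
#' @param bounds optional `2 x 3` matrix (min / max world mm per axis);
#'   when omitted the tracer's own domain flags are used.
#'
#' @return One-row tibble: `n_pathlines`, `n_aberrant`, `aberrant_pct`.
#' @export
aberrant_fraction <- function(pathlines, bounds = NULL) {
  stopifnot(inherits(pathlines, "pathline_set"))
  n <- nrow(pathlines$status)
  if (is.null(bounds)) {
    bad <- pathlines$status$truncated | !pathlines$status$valid
  } else {
    p <- pathlines$positions
    outside <- array(FALSE, dim(p)[1:2])
    for (ax in 1:3)
      outside <- outside | p[, , ax] < bounds[1, ax] | p[, , ax] > bounds[2, ax]
    bad <- apply(outside, 1, any) | !pathlines$status$valid
  }
  tibble::tibble(n_pathlines = n, n_aberrant = sum(bad),
                 aberrant_pct = 100 * sum(bad) / n)
}
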