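#' Write per-exam results to CSV
#'
#' Flattens an [analyze_lv_flow()] result (plus optional LA measurements)
#' into one wide CSV row per exam: chamber volumes and EF, indexed volumes,
#' cardiac output, LA fractional area change, per-component volume (ml and
#' % of LVEDV) and KE (mJ and % of total), derived inflow / stroke /
#' non-ejected volumes and KE, late-diastolic inflow percentages, and the
#' QC discrepancy and pass flag.
#'
#' @param result an [analyze_lv_flow()] result.
#' @param path output CSV path.
#' @param subject subject identifier written into the row.
#' @param la_fac_pct optional LA fractional area change, percent.
#' @param append append to an existing file instead of overwriting.
#' @return the written row as a tibble, invisibly.
#' @export
write_case_results <- function(result, path, subject = NA_character_,
                               la_fac_pct = NA_real_, append = FALSE) {
  stopifnot(inherits(result, "lvflow_result"))
  row <- case_results_row(result, subject = subject, la_fac_pct = la_fac_pct)
  readr::write_csv(row, path, append = append && file.exists(path))
  invisible(row)
}

#' @rdname write_case_results
#' @export
case_results_row <- function(result, subject = NA_character_,
                             la_fac_pct = NA_real_) {
  comp_short <- c("df", "ri", "def", "rv")
  v <- result$volumes; k <- result$ke; d <- result$derived
  row <- tibble::tibble(subject = subject)
  row <- dplyr::bind_cols(row, result$chamber)
  row$la_fac_pct <- la_fac_pct
  for (i in 1:4) {
    row[[paste0(comp_short[i], "_volume_ml")]] <- v$volume_ml[i]
    row[[paste0(comp_short[i], "_volume_pct")]] <- v$volume_pct[i]
    row[[paste0(comp_short[i], "_ke_mj")]] <- k$ke_mj[i]
    row[[paste0(comp_short[i], "_ke_pct")]] <- k$ke_pct[i]
  }
  dq <- c("inflow", "sv_flow", "non_ejected")
  for (i in 1:3) {
    row[[paste0(dq[i], "_volume_ml")]] <- d$volume_ml[i]
    row[[paste0(dq[i], "_ke_mj")]] <- d$ke_mj[i]
  }
  row$late_inflow_volume_pct <- result$late$late_volume_pct
  row$late_inflow_ke_pct <- result$late$late_ke_pct
  row$qc_discrepancy_pct <- result$qc$discrepancy_pct
  row$qc_pass <- result$qc$pass
  row$aberrant_pct <- result$qc$aberrant_pct
  row
}

#' Read a results CSV written by [write_case_results()]
#'
#' @param path CSV path.
#' @return tibble, one row per exam.
#' @export
read_case_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML of pipeline settings with defaults for anything omitted:
#' `preprocess` (`polynomial_order`, fixed at 4; `sd_threshold`;
#' `max_wraps`), `trace` (`step_fraction`), `components` (`inside_test`,
#' `rho`), `timing` (`diastasis_fraction`), `qc`
#' (`discrepancy_threshold`), plus optional per-exam entries (valve-event
#' frames, height, weight, LA areas).
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return nested list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    preprocess = list(polynomial_order = 4L, sd_threshold = 0.03,
                      max_wraps = 2L),
    trace = list(step_fraction = 0.2),
    components = list(inside_test = "interpolated", rho = 1060),
    timing = list(diastasis_fraction = 0.1),
    qc = list(discrepancy_threshold = 15),
    exam = list())
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (!is.null(user$preprocess$polynomial_order) &&
      user$preprocess$polynomial_order != 4L)
    stop("preprocess.polynomial_order is fixed at 4", call. = FALSE)
  out <- defaults
  for (sec in names(user)) {
    if (is.list(user[[sec]]))
      for (key in names(user[[sec]])) out[[sec]][[key]] <- user[[sec]][[key]]
    else out[[sec]] <- user[[sec]]
  }
  out
}
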