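#' Component summary figure for one exam
#'
#' Side-by-side bars of the four components' share of the end-diastolic
#' volume and of the end-diastolic kinetic energy.
#'
#' @param object an [analyze_lv_flow()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot lvflow_result
#' @export
autoplot.lvflow_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::transmute(object$volumes, component = .data$component,
                     what = "Volume (% of LVEDV)", pct = .data$volume_pct),
    dplyr::transmute(object$ke, component = .data$component,
                     what = "KE at ED (% of total)", pct = .data$ke_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$pct,
                                   fill = .data$component)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~what) +
    ggplot2::scale_fill_manual(values = component_palette()) +
    ggplot2::labs(x = NULL, y = "%") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

## Conventional colours: DF green, RI yellow, DEF blue, RV red.
component_palette <- function() {
  stats::setNames(c("#2E8B57", "#DAA520", "#1F6FB4", "#B22222"),
                  component_levels())
}

#' Plot an LV volume curve with its timing landmarks
#'
#' @param volume_curve per-frame LV volume, ml.
#' @param timing optional [timing_result()]; when given, ED, ES and the
#'   late-diastole onset are marked.
#' @return a ggplot object.
#' @export
plot_volume_curve <- function(volume_curve, timing = NULL) {
  df <- tibble::tibble(frame = seq_along(volume_curve) - 1,
                       volume = volume_curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$volume)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "cardiac frame", y = "LV volume (ml)") +
    ggplot2::theme_minimal()
  if (!is.null(timing)) {
    marks <- tibble::tibble(
      frame = c(timing$ed_frame, timing$es_frame, timing$late_onset_frame),
      landmark = c("ED", "ES", "late diastole onset"))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$frame,
                                              colour = .data$landmark),
                                 linetype = "dashed") +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Projected pathline plot coloured by flow component
#'
#' Draws each pathline's trajectory projected on one coordinate plane,
#' coloured by its component label (the conventional palette: direct flow
#' green, retained inflow yellow, delayed ejection blue, residual red).
#'
#' @param pathlines a [trace_pathlines()] result.
#' @param labels tibble from [classify_components()].
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param max_lines subsample at most this many pathlines (plotting all
#'   tens of thousands is rarely useful).
#' @return a ggplot object.
#' @export
plot_pathlines <- function(pathlines, labels, plane = c("xy", "xz", "yz"),
                           max_lines = 500) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
  df <- tidy(pathlines)
  df <- dplyr::left_join(df, labels[, c("seed", "label")], by = "seed")
  df <- df[!is.na(df$label), ]
  keep <- unique(df$seed)
  if (length(keep) > max_lines)
    keep <- keep[round(seq(1, length(keep), length.out = max_lines))]
  df <- df[df$seed %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   group = .data$seed,
                                   colour = .data$label)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = component_palette()) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (mm)"), y = paste0(ax[2], " (mm)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Paired cohort comparison figure
#'
#' Spaghetti-style paired points for each metric at the two timepoints.
#'
#' @param object a [cohort_compare()] result (used for the metric order),
#'   or `NULL`.
#' @param results_t1,results_t2 the per-exam tables given to
#'   [cohort_compare()].
#' @param id subject identifier column.
#' @param metrics metrics to draw; defaults to those in `object`.
#' @return a ggplot object.
#' @method autoplot cohort_comparison
#' @export
autoplot.cohort_comparison <- function(object, results_t1, results_t2,
                                       id = "subject", metrics = NULL, ...) {
  if (is.null(metrics)) metrics <- object$metric
  long <- function(df, tp) {
    df <- tibble::as_tibble(df)
    tidyr::pivot_longer(df[, c(id, intersect(metrics, names(df)))],
                        -dplyr::all_of(id), names_to = "metric") |>
      dplyr::mutate(timepoint = tp)
  }
  df <- dplyr::bind_rows(long(results_t1, "Time-1"), long(results_t2, "Time-2"))
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data$value,
                                   group = .data[[id]])) +
    ggplot2::geom_line(alpha = 0.4) + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
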