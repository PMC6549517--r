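#' Paired two-timepoint comparison of one metric
#'
#' Reproduces the cohort statistical workflow for one metric measured at
#' two timepoints in the same subjects: summaries as mean and SD at each
#' timepoint, the paired Student t test and the Wilcoxon signed-rank test
#' on the pairwise differences, and a Kolmogorov-Smirnov normality check
#' of the differences (against a normal with moment-estimated parameters).
#' Tests are two-sided; zero differences are dropped for the Wilcoxon test
#' and its exact distribution is used for up to 25 non-zero differences
#' (normal approximation above). No multiple-testing correction is
#' applied.
#'
#' @param values_t1,values_t2 equal-length paired numeric vectors.
#' @param alpha significance level (default 0.05).
#' @param metric optional metric name carried into the output.
#'
#' @return One-row tibble of class `paired_comparison`: `metric`, `n`,
#'   `mean_t1`, `sd_t1`, `mean_t2`, `sd_t2`, `mean_diff`, `p_t`,
#'   `p_wilcoxon`, `p_ks`, `normal`, `significant`, `note`.
#' @export
paired_compare <- function(values_t1, values_t2, alpha = 0.05,
                           metric = NA_character_) {
  if (length(values_t1) != length(values_t2))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- stats::complete.cases(values_t1, values_t2)
  x <- values_t1[ok]; y <- values_t2[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  note <- NA_character_
  if (all(d == 0)) {
    res <- tibble::tibble(
      metric = metric, n = n,
      mean_t1 = mean(x), sd_t1 = stats::sd(x),
      mean_t2 = mean(y), sd_t2 = stats::sd(y),
      mean_diff = 0, p_t = NA_real_, p_wilcoxon = NA_real_,
      p_ks = NA_real_, normal = NA,
      significant = FALSE, note = "all differences zero; tests undefined")
    class(res) <- c("paired_comparison", class(res))
    return(res)
  }
  p_t <- if (stats::sd(d) == 0) {
    note <- "differences identical; t test undefined"
    NA_real_
  } else stats::t.test(y, x, paired = TRUE)$p.value
  dz <- d[d != 0]
  exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
  p_w <- suppressWarnings(
    stats::wilcox.test(dz, mu = 0, exact = exact, correct = !exact)$p.value)
  p_ks <- if (stats::sd(d) > 0)
    suppressWarnings(stats::ks.test(d, "pnorm", mean(d), stats::sd(d))$p.value)
  else NA_real_
  res <- tibble::tibble(
    metric = metric, n = n,
    mean_t1 = mean(x), sd_t1 = stats::sd(x),
    mean_t2 = mean(y), sd_t2 = stats::sd(y),
    mean_diff = mean(d),
    p_t = p_t, p_wilcoxon = p_w, p_ks = p_ks,
    normal = if (!is.na(p_ks)) p_ks > alpha else NA,
    significant = !is.na(p_t) && p_t < alpha,
    note = note)
  class(res) <- c("paired_comparison", class(res))
  res
}

#' Paired comparison of every metric across a two-timepoint cohort
#'
#' Joins two per-exam results tables by subject identifier and runs
#' [paired_compare()] on every shared numeric metric column, mirroring a
#' Time-1 vs Time-2 cohort table.
#'
#' @param results_t1,results_t2 data frames with a subject identifier
#'   column and one column per metric.
#' @param id column name of the subject identifier (default `"subject"`).
#' @param metrics metric columns to compare; defaults to all shared
#'   numeric columns.
#' @param alpha significance level.
#'
#' @return A tibble with one [paired_compare()] row per metric.
#' @export
cohort_compare <- function(results_t1, results_t2, id = "subject",
                           metrics = NULL, alpha = 0.05) {
  t1 <- tibble::as_tibble(results_t1)
  t2 <- tibble::as_tibble(results_t2)
  if (!id %in% names(t1) || !id %in% names(t2))
    stop(sprintf("subject id column '%s' missing", id), call. = FALSE)
  joined <- dplyr::inner_join(t1, t2, by = id, suffix = c("_t1", "_t2"))
  if (is.null(metrics)) {
    shared <- intersect(names(t1), names(t2))
    metrics <- shared[shared != id &
                        vapply(t1[shared], is.numeric, logical(1))]
  }
  out <- purrr::map_dfr(metrics, function(mc) {
    paired_compare(joined[[paste0(mc, "_t1")]], joined[[paste0(mc, "_t2")]],
                   alpha = alpha, metric = mc)
  })
  class(out) <- c("cohort_comparison", class(out))
  out
}
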