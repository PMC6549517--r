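#' Cardiac timing landmarks for one exam
#'
#' Bundles the cardiac-frame landmarks used by the tracing and component
#' analysis: end-diastole, end-systole, onset of late diastole, the frame
#' times and the heart rate. Frames are 0-based; time is cyclic with period
#' `cycle_s`.
#'
#' @param ed_frame,es_frame,late_onset_frame 0-based frame indices.
#' @param n_frames number of frames per cycle.
#' @param cycle_s cycle duration, s (heart rate = 60 / cycle_s).
#' @param frame_times frame times, s; uniform by default.
#' @param volume_curve optional LV volume per frame, ml.
#'
#' @return An object of class `timing_result`.
#' @export
timing_result <- function(ed_frame, es_frame, late_onset_frame, n_frames,
                          cycle_s, frame_times = NULL, volume_curve = NULL) {
  if (is.null(frame_times))
    frame_times <- (seq_len(n_frames) - 1) * cycle_s / n_frames
  for (f in c(ed_frame, es_frame, late_onset_frame))
    if (f < 0 || f >= n_frames)
      stop("frame indices must lie in [0, n_frames)", call. = FALSE)
  if (length(unique(c(ed_frame, es_frame, late_onset_frame))) < 3)
    stop("ED, ES and late-onset frames must be distinct", call. = FALSE)
  # cyclic order must be ES -> late onset -> ED
  s <- (es_frame - ed_frame) %% n_frames
  l <- (late_onset_frame - ed_frame) %% n_frames
  if (!(l > s))
    stop("late-diastole onset must fall between ES and ED (cyclically)",
         call. = FALSE)
  if (!is.null(volume_curve) && any(volume_curve < 0))
    stop("volume curve must be non-negative", call. = FALSE)
  structure(list(ed_frame = as.integer(ed_frame),
                 es_frame = as.integer(es_frame),
                 late_onset_frame = as.integer(late_onset_frame),
                 n_frames = as.integer(n_frames), cycle_s = cycle_s,
                 frame_times = frame_times,
                 heart_rate_bpm = 60 / cycle_s,
                 volume_curve = volume_curve),
            class = "timing_result")
}

#' @export
print.timing_result <- function(x, ...) {
  cat(sprintf("<timing_result> %d frames / %.3f s (HR %.0f bpm): ED %d, ES %d, late diastole from %d\n",
              x$n_frames, x$cycle_s, x$heart_rate_bpm, x$ed_frame,
              x$es_frame, x$late_onset_frame))
  invisible(x)
}

## Trace-window times on a continuous axis with t = t(ED) at zero shift:
## systole covers [t_ed, t_es], diastole [t_es - cycle, t_ed].
trace_window <- function(timing) {
  ft <- timing$frame_times
  n <- timing$n_frames
  t_ed <- ft[timing$ed_frame + 1]
  frame_tau <- function(f) {
    o <- (f - timing$ed_frame) %% n
    s <- (timing$es_frame - timing$ed_frame) %% n
    if (o <= s) t_ed + speedless_dt(ft, timing$cycle_s, timing$ed_frame, o)
    else t_ed - (timing$cycle_s - speedless_dt(ft, timing$cycle_s, timing$ed_frame, o))
  }
  list(t_ed = t_ed,
       t_es = frame_tau(timing$es_frame),
       t_es_prev = frame_tau(timing$es_frame) - timing$cycle_s,
       t_late = frame_tau(timing$late_onset_frame))
}

## Elapsed time from ED to the frame `offset` frames later (cyclic).
speedless_dt <- function(frame_times, cycle_s, ed_frame, offset) {
  n <- length(frame_times)
  f <- (ed_frame + offset) %% n
  d <- frame_times[f + 1] - frame_times[ed_frame + 1]
  if (d < 0) d <- d + cycle_s
  d
}

#' LV volume curve from a mask series
#'
#' Volume per frame as voxel count times voxel volume, in ml.
#'
#' @param masks a list of [chamber_mask()] objects (one per frame, in frame
#'   order) or a numeric vector already holding per-frame volumes in ml.
#' @return numeric vector of volumes (ml).
#' @export
compute_volume_curve <- function(masks) {
  if (is.numeric(masks)) return(as.numeric(masks))
  if (!length(masks) || !all(vapply(masks, inherits, logical(1), "chamber_mask")))
    stop("`masks` must be a list of chamber_mask objects or a numeric vector",
         call. = FALSE)
  vols <- vapply(masks, mask_volume_ml, numeric(1))
  if (any(vols == 0))
    warning("empty mask in volume curve (0 ml)")
  vols
}

#' ED and ES frames from mitral valve events
#'
#' The end-diastolic frame is set one frame after mitral valve closure and
#' the end-systolic frame one frame before mitral valve opening, with
#' cyclic wraparound.
#'
#' @param mv_closure_frame,mv_opening_frame 0-based frames of mitral valve
#'   closure / opening.
#' @param n_frames frames per cycle.
#' @return list with `ed_frame` and `es_frame` (0-based).
#' @export
frames_from_valve_events <- function(mv_closure_frame, mv_opening_frame,
                                     n_frames) {
  ed <- (mv_closure_frame + 1) %% n_frames
  es <- (mv_opening_frame - 1) %% n_frames
  if (ed == es)
    stop("degenerate valve events: ED and ES coincide", call. = FALSE)
  list(ed_frame = as.integer(ed), es_frame = as.integer(es))
}

#' Onset of late diastole from the LV volume curve
#'
#' Identifies the end of the early filling phase: after the early-filling
#' peak of `dV/dt` within diastole, the first frame at which `dV/dt` falls
#' below `fraction` of that peak (diastasis, where filling is near zero).
#' If the curve never drops below the threshold before ED (early and late
#' waves abutting with no A-wave trough), the last frame below threshold
#' before ED is returned. `dV/dt` is computed by central differences on the
#' cyclic curve.
#'
#' @param volume_curve LV volume per frame, ml.
#' @param es_frame,ed_frame 0-based landmarks bounding diastole.
#' @param fraction threshold as a fraction of the early peak filling rate
#'   (default 0.1).
#' @return 0-based frame of late-diastole onset. Degenerate (monotone or
#'   flat) diastolic curves yield the midpoint of diastole with a warning.
#' @export
detect_late_diastole_onset <- function(volume_curve, es_frame, ed_frame,
                                       fraction = 0.1) {
  n <- length(volume_curve)
  v <- as.numeric(volume_curve)
  dvdt <- (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / 2
  n_d <- (ed_frame - es_frame) %% n
  if (n_d < 3) stop("diastole too short to analyse", call. = FALSE)
  dia_frames <- (es_frame + seq_len(n_d - 1)) %% n      # strictly inside
  rates <- dvdt[dia_frames + 1]
  midpoint <- dia_frames[ceiling(length(dia_frames) / 2)]
  if (max(rates) <= 0 || diff(range(rates)) < 1e-12) {
    warning("monotone or flat diastolic volume curve; using diastole midpoint")
    return(as.integer(midpoint))
  }
  peak <- which.max(rates)
  thr <- fraction * rates[peak]
  after <- seq_along(rates) > peak
  below <- which(after & rates < thr)
  if (length(below)) return(as.integer(dia_frames[below[1]]))
  # no clear diastasis: last sub-threshold frame before ED, else midpoint
  below_any <- which(rates < thr)
  if (length(below_any)) return(as.integer(dia_frames[max(below_any)]))
  warning("no diastasis found below threshold; using diastole midpoint")
  as.integer(midpoint)
}
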