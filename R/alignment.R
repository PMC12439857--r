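#' Configuration for ABGA timestamp alignment
#'
#' Parameters of the arterial-pressure-surge detector that refines each
#' recorded blood-gas timestamp to an estimated draw time: abnormal periods
#' are maximal runs of MAP samples whose z score (computed against the
#' 20-minute lookback window's own mean and SD) exceeds `z_threshold`; the
#' period nearest the recorded timestamp marks the draw, and the feature
#' trigger is set `pre_trigger_s` earlier, followed (backwards) by an optional
#' blackout and the observation window.
#'
#' @param z_threshold Positive z-score threshold (default 3).
#' @param lookback_s Lookback interval before the recorded timestamp (s),
#'   default 20 minutes.
#' @param pre_trigger_s Gap between estimated draw and trigger time (s).
#' @param blackout_s Gap between window end and trigger (s); default 0.
#' @param window_s Observation-window length (s).
#' @param min_window_samples Minimum non-missing MAP samples in the lookback
#'   needed to assess a surge.
#' @return A list of class `co2gap_alignment_config`.
#' @export
alignment_config <- function(z_threshold = 3,
                             lookback_s = 1200,
                             pre_trigger_s = 60,
                             blackout_s = 0,
                             window_s = 60,
                             min_window_samples = 10) {
  if (!is_number(z_threshold) || z_threshold <= 0) stop_config("`z_threshold` must be > 0")
  for (nm in c("lookback_s", "pre_trigger_s", "window_s")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0) stop_config("`", nm, "` must be > 0")
  }
  if (!is_number(blackout_s) || blackout_s < 0) stop_config("`blackout_s` must be >= 0")
  cfg <- list(z_threshold = z_threshold, lookback_s = lookback_s,
              pre_trigger_s = pre_trigger_s, blackout_s = blackout_s,
              window_s = window_s, min_window_samples = min_window_samples)
  class(cfg) <- "co2gap_alignment_config"
  cfg
}

#' Z scores of a MAP lookback window against its own distribution
#'
#' Each sample is standardised by the mean and sample SD of the supplied
#' window. A zero-variance window yields all-zero z scores (no sample can be
#' abnormal relative to a flat baseline).
#'
#' @param values Numeric MAP samples (missing values allowed; their z is NA).
#' @return Numeric vector of z scores, same length as `values`.
#' @export
compute_window_zscores <- function(values) {
  ok <- !is.na(values)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) {
    z <- numeric(length(values))
    z[!ok] <- NA_real_
    return(z)
  }
  (values - m) / s
}

#' Find abnormal periods in a z-score series
#'
#' Maximal runs of consecutive samples with `z > z_threshold` (strict,
#' positive side only: a blood draw transiently raises MAP). Each period is
#' reported with its start/end times and the time of its maximum z.
#'
#' @param times Sample times (s), strictly increasing.
#' @param z Z scores from [compute_window_zscores()].
#' @param z_threshold Positive threshold.
#' @return Tibble with columns `start_s`, `end_s`, `peak_s`, `peak_z`, ordered
#'   by time; zero rows when nothing exceeds the threshold.
#' @export
find_abnormal_periods <- function(times, z, z_threshold = 3) {
  stopifnot(length(times) == length(z))
  exc <- !is.na(z) & z > z_threshold
  if (!any(exc)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          peak_s = numeric(), peak_z = numeric()))
  }
  r <- rle(exc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  purrr::map_dfr(runs, function(k) {
    idx <- starts[k]:ends[k]
    peak <- idx[which.max(z[idx])]
    tibble::tibble(start_s = times[starts[k]], end_s = times[ends[k]],
                   peak_s = times[peak], peak_z = z[peak])
  })
}

#' Estimate the blood-draw time from a MAP trace
#'
#' Looks at the MAP samples in `[recorded_time_s - lookback_s,
#' recorded_time_s]` (never beyond the recorded timestamp), standardises them
#' against the window's own distribution, and selects the abnormal period
#' whose boundary lies nearest the recorded timestamp (ties broken towards the
#' later period). The returned draw-time estimate is the time of maximum z
#' within that period.
#'
#' @param map_trace Data frame with `time_s`, `value` for one case's MAP.
#' @param recorded_time_s The recorded ABGA timestamp (s).
#' @param config An [alignment_config()].
#' @return Estimated draw time (s), or `NA_real_` when no abnormal period is
#'   detectable (the event is then excluded as surge-free).
#' @export
estimate_draw_time <- function(map_trace, recorded_time_s,
                               config = alignment_config()) {
  in_win <- map_trace$time_s >= recorded_time_s - config$lookback_s &
    map_trace$time_s <= recorded_time_s
  t <- map_trace$time_s[in_win]
  v <- map_trace$value[in_win]
  if (sum(!is.na(v)) < config$min_window_samples) return(NA_real_)
  z <- compute_window_zscores(v)
  periods <- find_abnormal_periods(t, z, config$z_threshold)
  if (nrow(periods) == 0) return(NA_real_)
  dist <- pmin(abs(recorded_time_s - periods$start_s),
               abs(recorded_time_s - periods$end_s))
  # nearest period; ties -> the later one (closer to data entry)
  best <- which(dist == min(dist))
  best <- best[length(best)]
  periods$peak_s[best]
}

#' Construct an event point from an ABGA record and a draw-time estimate
#'
#' Aligned events receive `trigger_time_s = draw - pre_trigger_s` and the
#' half-open observation window `[trigger - blackout_s - window_s,
#' trigger - blackout_s)`. Events without a detectable surge, or whose window
#' would start before the case record does, are excluded.
#'
#' @param abga One-row data frame with `case_id`, `event_id`,
#'   `recorded_time_s`, `paco2`.
#' @param draw_time_s Estimated draw time or `NA`.
#' @param config An [alignment_config()].
#' @param case_start_s Earliest trace time for the case (default 0).
#' @return One-row tibble with the event-point fields and a `status` of
#'   `aligned`, `excluded_no_surge`, or `excluded_insufficient_history`.
#' @export
build_event_point <- function(abga, draw_time_s, config = alignment_config(),
                              case_start_s = 0) {
  base <- tibble::tibble(
    case_id = abga$case_id,
    event_id = abga$event_id,
    recorded_time_s = abga$recorded_time_s,
    paco2 = abga$paco2
  )
  if (is.na(draw_time_s)) {
    return(dplyr::mutate(base, estimated_draw_time_s = NA_real_,
                         trigger_time_s = NA_real_, window_start_s = NA_real_,
                         window_end_s = NA_real_, status = "excluded_no_surge"))
  }
  trigger <- draw_time_s - config$pre_trigger_s
  w_end <- trigger - config$blackout_s
  w_start <- w_end - config$window_s
  status <- if (w_start < case_start_s) "excluded_insufficient_history" else "aligned"
  dplyr::mutate(base, estimated_draw_time_s = draw_time_s,
                trigger_time_s = trigger, window_start_s = w_start,
                window_end_s = w_end, status = status)
}

#' Align all ABGA events of a cohort
#'
#' Applies [estimate_draw_time()] and [build_event_point()] to every ABGA
#' record, using each case's MAP trace. No sample later than an event's
#' recorded timestamp is ever inspected.
#'
#' @param signals Long-format signals table (`case_id`, `channel`, `time_s`,
#'   `value`).
#' @param abga ABGA table (`case_id`, `event_id`, `recorded_time_s`, `paco2`).
#' @param config An [alignment_config()].
#' @return Tibble of event points, one row per ABGA record, with alignment
#'   `status` and window bounds.
#' @export
align_events <- function(signals, abga, config = alignment_config()) {
  if (!"event_id" %in% names(abga)) {
    abga <- dplyr::mutate(abga, event_id = sprintf("ev%05d", dplyr::row_number()))
  }
  map_traces <- signals |>
    dplyr::filter(.data$channel == "MAP") |>
    dplyr::select("case_id", "time_s", "value")
  map_by_case <- split(map_traces[c("time_s", "value")], map_traces$case_id)
  missing_cases <- setdiff(unique(abga$case_id), names(map_by_case))
  if (length(missing_cases) > 0) {
    stop_schema("no MAP trace for case(s): ",
                paste(utils::head(missing_cases, 5), collapse = ", "))
  }
  purrr::map_dfr(seq_len(nrow(abga)), function(i) {
    ev <- abga[i, ]
    tr <- map_by_case[[ev$case_id]]
    draw <- estimate_draw_time(tr, ev$recorded_time_s, config)
    build_event_point(ev, draw, config, case_start_s = min(tr$time_s))
  })
}
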