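#' Interpolate an irregular series to integer seconds
#'
#' Linear interpolation at `t = 0, 1, ..., t_end`.  No extrapolation is
#' performed beyond a constant-edge hold of at most one second at either
#' end; a series whose first sample arrives after `t = 1` or whose last
#' sample precedes `t_end - 1` fails quality control instead.
#'
#' @param raw a `raw_series`.
#' @param t_end last integer second of the uniform grid.
#' @return A `uniform_series` with fields `participant_id`, `signal`,
#'   `grid_s` (`0:t_end`), `values`, `t_end`.
#' @export
interpolate_to_seconds <- function(raw, t_end = 720) {
  if (length(raw$times_s) < 2L) stop("need at least two samples")
  t0 <- min(raw$times_s); t1 <- max(raw$times_s)
  if (t0 > 1) stop(sprintf("insufficient coverage: first sample at %.2fs (> 1s gap at start)", t0))
  if (t1 < t_end - 1) stop(sprintf("insufficient coverage: last sample at %.2fs < %ds - 1", t1, t_end))
  grid <- 0:t_end
  v <- stats::approx(raw$times_s, raw$values, xout = grid, rule = 2,
                     ties = mean)$y
  structure(list(participant_id = raw$participant_id, signal = raw$signal,
                 grid_s = grid, values = v, t_end = t_end),
            class = "uniform_series")
}

#' Truncate a uniform series to the first n bouts
#'
#' With the canonical protocol (2-min bouts, 1-min rests) and
#' `n_bouts = 4` the retained window is `[0, 720]` seconds: 721 samples.
#'
#' @param series a `uniform_series`.
#' @param schedule a [generate_protocol()] schedule.
#' @param n_bouts number of leading bouts to keep.
#' @return A `uniform_series` with `t_end = n_bouts * (bout + rest)`.
#' @export
truncate_to_window <- function(series, schedule, n_bouts = 4) {
  t_end <- n_bouts * (schedule$bout_duration_s + schedule$rest_duration_s)
  if (t_end > series$t_end) {
    stop(sprintf("window [0, %g] exceeds series coverage [0, %g]",
                 t_end, series$t_end))
  }
  keep <- series$grid_s <= t_end
  structure(list(participant_id = series$participant_id,
                 signal = series$signal,
                 grid_s = series$grid_s[keep], values = series$values[keep],
                 t_end = t_end),
            class = "uniform_series")
}

#' Default physiological plausibility ranges per signal
#' @return Named list of `c(lo, hi)` bounds.
#' @export
default_qc_ranges <- function() {
  list(HR = c(25, 250), RR = c(2, 120),
       VO2 = c(0, 6000), VCO2 = c(0, 7000))
}

#' Screen a raw series for irregularities
#'
#' Flags (never errors) series with any inter-sample gap above `gap_max`,
#' values outside the physiological range for the signal, or a flatline
#' (consecutive identical values) spanning more than `flat_max` seconds.
#' These rules stand in for the informal removal of technically corrupted
#' HR / gas-exchange records.
#'
#' @param raw a `raw_series`.
#' @param gap_max maximum tolerated inter-sample gap (s).
#' @param ranges named list of `c(lo, hi)` per signal.
#' @param flat_max maximum tolerated flatline duration (s).
#' @return A `qc_report` list: `participant_id`, `signal`, `excluded`,
#'   `reasons` (character vector, possibly empty).
#' @export
qc_screen <- function(raw, gap_max = 10, ranges = default_qc_ranges(),
                      flat_max = 60) {
  reasons <- character(0)
  if (length(raw$times_s) >= 2L && max(diff(raw$times_s)) > gap_max) {
    reasons <- c(reasons, "gap")
  }
  rng <- ranges[[raw$signal]]
  if (!is.null(rng) && any(raw$values < rng[1] | raw$values > rng[2])) {
    reasons <- c(reasons, "range")
  }
  if (length(raw$values) >= 2L) {
    r <- rle(raw$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_span <- raw$times_s[ends] - raw$times_s[starts]
    if (any(r$lengths > 1L & run_span > flat_max)) {
      reasons <- c(reasons, "flatline")
    }
  }
  structure(list(participant_id = raw$participant_id, signal = raw$signal,
                 excluded = length(reasons) > 0L, reasons = reasons),
            class = "qc_report")
}

#' Preprocess a whole cohort: QC, interpolate, truncate
#'
#' A participant is excluded if any of their signals fails [qc_screen()] or
#' lacks the coverage required by [interpolate_to_seconds()].
#'
#' @param cohort list with `meta` and `series` (see [generate_cohort()]).
#' @param schedule work-rate schedule.
#' @param n_bouts leading bouts to retain (default 4: 720 s).
#' @param gap_max,flat_max,ranges QC thresholds, see [qc_screen()].
#' @return List with `uniform` (list of `uniform_series` for retained
#'   participants), `meta` (retained rows) and `qc` (per-participant
#'   data.frame of exclusions and reasons).
#' @export
preprocess_cohort <- function(cohort, schedule, n_bouts = 4,
                              gap_max = 10, flat_max = 60,
                              ranges = default_qc_ranges()) {
  t_end <- n_bouts * (schedule$bout_duration_s + schedule$rest_duration_s)
  ids <- unique(cohort$meta$participant_id)
  excl <- stats::setNames(vector("list", length(ids)), ids)
  uniform <- list()
  for (s in cohort$series) {
    rep_ <- qc_screen(s, gap_max = gap_max, ranges = ranges,
                      flat_max = flat_max)
    if (rep_$excluded) {
      excl[[s$participant_id]] <- union(excl[[s$participant_id]], rep_$reasons)
      next
    }
    u <- tryCatch(
      truncate_to_window(interpolate_to_seconds(s, schedule$total_duration_s),
                         schedule, n_bouts),
      error = function(e) e)
    if (inherits(u, "error")) {
      # a short record (early quit) is fine as long as it covers the window
      u <- tryCatch(interpolate_to_seconds(s, t_end), error = function(e) e)
    }
    if (inherits(u, "error")) {
      excl[[s$participant_id]] <- union(excl[[s$participant_id]], "coverage")
    } else {
      uniform[[length(uniform) + 1L]] <- u
    }
  }
  bad <- names(excl)[vapply(excl, length, 1L) > 0L]
  uniform <- Filter(function(u) !(u$participant_id %in% bad), uniform)
  qc <- data.frame(
    participant_id = ids,
    excluded = ids %in% bad,
    reasons = vapply(ids, function(i) paste(excl[[i]], collapse = ";"), ""),
    stringsAsFactors = FALSE)
  list(uniform = uniform,
       meta = cohort$meta[!(cohort$meta$participant_id %in% bad), ,
                          drop = FALSE],
       qc = qc)
}
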