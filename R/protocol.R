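#' Build a square-wave work-rate schedule
#'
#' An MBEB session consists of `n_bouts` constant-work-rate exercise bouts,
#' each followed by a rest period.  Bout `k` (1-based) spans
#' `[(k-1)(bout+rest), (k-1)(bout+rest) + bout)`, so the canonical protocol
#' of ten 2-min bouts with 1-min rests spans 1800 s and its first four bouts
#' span exactly 720 s.
#'
#' @param n_bouts number of bouts (>= 0).
#' @param bout_duration_s bout length in seconds (> 0).
#' @param rest_duration_s rest length in seconds (> 0).
#' @param intensity_fraction fraction of peak work rate in (0, 1], e.g. 0.4
#'   for low-intensity and 0.8 for high-intensity sessions.
#' @return An object of class `wr_schedule` with elements `bouts` (a
#'   two-column matrix of onset/offset seconds), `bout_duration_s`,
#'   `rest_duration_s`, `intensity_fraction` and `total_duration_s`.
#' @examples
#' sched <- generate_protocol(4, 120, 60, 0.8)
#' sched$total_duration_s  # 720
#' @export
generate_protocol <- function(n_bouts, bout_duration_s = 120,
                              rest_duration_s = 60,
                              intensity_fraction = 0.8) {
  if (!is.numeric(n_bouts) || length(n_bouts) != 1L || n_bouts < 0 ||
      n_bouts != round(n_bouts)) {
    stop("`n_bouts` must be a single non-negative integer")
  }
  if (bout_duration_s <= 0 || rest_duration_s <= 0) {
    stop("bout and rest durations must be positive")
  }
  if (intensity_fraction <= 0 || intensity_fraction > 1) {
    stop("`intensity_fraction` must be in (0, 1]")
  }
  n_bouts <- as.integer(n_bouts)
  period <- bout_duration_s + rest_duration_s
  onset <- (seq_len(n_bouts) - 1) * period
  bouts <- cbind(onset_s = onset, offset_s = onset + bout_duration_s)
  structure(
    list(bouts = bouts,
         bout_duration_s = bout_duration_s,
         rest_duration_s = rest_duration_s,
         intensity_fraction = intensity_fraction,
         n_bouts = n_bouts,
         total_duration_s = n_bouts * period),
    class = "wr_schedule")
}

#' @export
print.wr_schedule <- function(x, ...) {
  cat(sprintf(
    "Work-rate schedule: %d bout(s) of %gs + %gs rest (%.0f%% peak), total %gs\n",
    x$n_bouts, x$bout_duration_s, x$rest_duration_s,
    100 * x$intensity_fraction, x$total_duration_s))
  invisible(x)
}

# TRUE at times falling inside an exercise bout (right-open intervals).
in_bout <- function(schedule, t) {
  if (schedule$n_bouts == 0L) return(rep(FALSE, length(t)))
  period <- schedule$bout_duration_s + schedule$rest_duration_s
  phase <- t %% period
  t >= 0 & t < schedule$total_duration_s & phase < schedule$bout_duration_s
}
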