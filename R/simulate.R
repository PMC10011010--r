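#' Kinetics parameters for one signal in one outcome group
#'
#' Signals follow piecewise first-order kinetics over the square-wave
#' protocol: within a bout the noise-free trajectory relaxes toward
#' `baseline + amplitude` with time constant `tau_on_s`; during the rest
#' after bout `k` it relaxes toward `baseline + drift_per_bout * k` with
#' time constant `tau_off_s`.  A positive `drift_per_bout` encodes
#' incomplete recovery: the end-of-rest level creeps upward bout after
#' bout.  Observation noise is additive Gaussian with sd `noise_sd`.
#'
#' @param baseline resting level in signal units.
#' @param amplitude steady-state on-transient rise in signal units.
#' @param tau_on_s,tau_off_s positive time constants (seconds).
#' @param drift_per_bout additive end-of-rest elevation per completed bout
#'   (signal units, >= 0).
#' @param noise_sd additive Gaussian noise sd (signal units, >= 0).
#' @return A `kinetics_params` list.
#' @export
kinetics_params <- function(baseline, amplitude, tau_on_s, tau_off_s,
                            drift_per_bout = 0, noise_sd = 0) {
  if (tau_on_s <= 0 || tau_off_s <= 0) stop("time constants must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (drift_per_bout < 0) stop("`drift_per_bout` must be non-negative")
  structure(list(baseline = baseline, amplitude = amplitude,
                 tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                 drift_per_bout = drift_per_bout, noise_sd = noise_sd),
            class = "kinetics_params")
}

# Segment table for the piecewise-exponential trajectory: one row per
# bout/rest segment with start time, target level, tau, and the (noise-free)
# value at segment start, propagated analytically through the boundaries.
kinetics_segments <- function(schedule, params) {
  n <- schedule$n_bouts
  if (n == 0L) {
    return(data.frame(start = 0, end = 0, target = params$baseline,
                      tau = params$tau_on_s, y0 = params$baseline))
  }
  period <- schedule$bout_duration_s + schedule$rest_duration_s
  start <- target <- tau <- numeric(2L * n)
  for (k in seq_len(n)) {
    start[2 * k - 1] <- (k - 1) * period
    start[2 * k] <- (k - 1) * period + schedule$bout_duration_s
    target[2 * k - 1] <- params$baseline + params$amplitude
    target[2 * k] <- params$baseline + params$drift_per_bout * k
    tau[2 * k - 1] <- params$tau_on_s
    tau[2 * k] <- params$tau_off_s
  }
  end <- c(start[-1], schedule$total_duration_s)
  y0 <- numeric(2L * n)
  y0[1] <- params$baseline
  for (j in seq_len(2L * n - 1L)) {
    y0[j + 1] <- target[j] + (y0[j] - target[j]) * exp(-(end[j] - start[j]) / tau[j])
  }
  data.frame(start = start, end = end, target = target, tau = tau, y0 = y0)
}

#' Simulate one physiological signal over a work-rate schedule
#'
#' Evaluates the piecewise first-order kinetic model (see
#' [kinetics_params()]) at the requested time points and adds Gaussian
#' observation noise.  The noise-free trajectory is continuous across
#' bout/rest boundaries.
#'
#' @param schedule a [generate_protocol()] schedule.
#' @param params a [kinetics_params()] object.
#' @param grid numeric vector of times (seconds) within
#'   `[0, total_duration_s]`.
#' @param signal signal name, one of `"HR"`, `"RR"`, `"VO2"`, `"VCO2"`.
#' @param participant_id id string recorded in the output.
#' @return A `raw_series` list with `participant_id`, `signal`, `times_s`,
#'   `values` and `units`.
#' @export
simulate_signal <- function(schedule, params, grid, signal = "HR",
                            participant_id = "sim") {
  if (length(grid) == 0L) stop("`grid` must contain at least one time point")
  if (any(grid < 0 | grid > schedule$total_duration_s)) {
    stop("`grid` must lie within [0, total_duration_s]")
  }
  grid <- sort(grid)
  seg <- kinetics_segments(schedule, params)
  idx <- findInterval(grid, seg$start, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  y <- seg$target[idx] +
    (seg$y0[idx] - seg$target[idx]) * exp(-(grid - seg$start[idx]) / seg$tau[idx])
  if (params$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, params$noise_sd)
  raw_series(participant_id, signal, grid, y)
}

raw_series <- function(participant_id, signal, times_s, values) {
  units <- c(HR = "beats/min", RR = "breaths/min",
             VO2 = "mL/min", VCO2 = "mL/min")[[signal]]
  structure(list(participant_id = participant_id, signal = signal,
                 times_s = times_s, values = values, units = units),
            class = "raw_series")
}

#' Default kinetics for the four MBEB signals
#'
#' Simulation defaults (not physiological estimates) chosen so that HR is
#' the cleanest signal and RR the noisiest, with on-kinetics faster than
#' off-kinetics.  The `failure` group receives an amplitude shift (higher
#' mean response) and positive bout-to-bout drift (incomplete recovery).
#'
#' @param group `"completer"` or `"failure"`.
#' @param group_mean_shift named numeric: failure-minus-completer amplitude
#'   offset per signal.
#' @param failure_drift named numeric: drift per bout for failures.
#' @return Named list of [kinetics_params()], one per signal.
#' @export
default_kinetics <- function(group = c("completer", "failure"),
                             group_mean_shift = c(HR = 10, RR = 3,
                                                  VO2 = 150, VCO2 = 160),
                             failure_drift = c(HR = 3, RR = 0.8,
                                               VO2 = 35, VCO2 = 40)) {
  group <- match.arg(group)
  base <- list(
    HR   = kinetics_params(80, 70, 30, 45, noise_sd = 1.5),
    RR   = kinetics_params(20, 20, 25, 40, noise_sd = 4),
    VO2  = kinetics_params(300, 1200, 25, 45, noise_sd = 80),
    VCO2 = kinetics_params(300, 1200, 35, 50, noise_sd = 90))
  if (group == "failure") {
    for (s in names(base)) {
      base[[s]]$amplitude <- base[[s]]$amplitude + group_mean_shift[[s]]
      base[[s]]$drift_per_bout <- failure_drift[[s]]
    }
  }
  base
}

#' Simulation configuration for a synthetic MBEB cohort
#'
#' @param n_participants cohort size (even when `balanced`).
#' @param schedule work-rate schedule; default ten 2-min bouts with 1-min
#'   rests at 80% peak work rate.
#' @param kinetics list with elements `completer` and `failure`, each a
#'   named list of [kinetics_params()] per signal.
#' @param sampling_mean_gap_s named numeric mean inter-sample gap per signal
#'   (exponential gaps emulate breath-by-breath sampling).
#' @param between_sd fractional between-participant sd applied to baseline
#'   and amplitude.
#' @param balanced if `TRUE`, exactly half the cohort is labelled failure.
#' @param seed integer master seed; fully determines the cohort.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_participants = 78,
                              schedule = generate_protocol(10, 120, 60, 0.8),
                              kinetics = list(
                                completer = default_kinetics("completer"),
                                failure = default_kinetics("failure")),
                              sampling_mean_gap_s = c(HR = 1, RR = 2,
                                                      VO2 = 2, VCO2 = 2),
                              between_sd = 0.08,
                              balanced = TRUE,
                              seed = 1L) {
  if (balanced && n_participants %% 2L != 0L) {
    stop("`n_participants` must be even for a balanced cohort")
  }
  if (n_participants < 2L) stop("need at least two participants")
  structure(list(n_participants = as.integer(n_participants),
                 schedule = schedule, kinetics = kinetics,
                 sampling_mean_gap_s = sampling_mean_gap_s,
                 between_sd = between_sd, balanced = balanced,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic MBEB cohort
#'
#' Produces a balanced cohort of task-failure and completer participants,
#' four irregularly sampled signals each, with known group structure:
#' failures get an amplitude shift plus positive bout-to-bout drift.
#' Completers finish all bouts; failures quit uniformly after 4--9 bouts
#' (every participant completes at least four bouts, so the first 720 s are
#' always observed).  The output is a pure function of the config seed.
#'
#' @param config a [simulation_config()].
#' @return List with `meta` (one row per participant: `participant_id`,
#'   `sex`, `puberty`, `body_mass_kg`, `bouts_completed`, `label`) and
#'   `series` (a list of `raw_series`, four per participant).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  sched <- config$schedule
  signals <- c("HR", "RR", "VO2", "VCO2")
  set.seed(config$seed)
  n_fail <- if (config$balanced) n %/% 2L else stats::rbinom(1L, n, 0.5)
  label <- sample(rep(c(1L, 0L), c(n_fail, n - n_fail)))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  puberty <- sample(c("early", "late"), n, replace = TRUE)
  body_mass <- round(stats::rnorm(n, ifelse(puberty == "early", 33, 58), 8), 1)
  body_mass <- pmax(body_mass, 18)
  bouts <- ifelse(label == 1L, sample(4:9, n, replace = TRUE), sched$n_bouts)
  # one rng stream per participant, split per signal, so that adding or
  # reordering signals never perturbs another signal's draws
  part_seed <- sample.int(.Machine$integer.max - 5L, n)
  meta <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    sex = sex, puberty = puberty, body_mass_kg = body_mass,
    bouts_completed = as.integer(bouts), label = label,
    stringsAsFactors = FALSE)

  series <- vector("list", n * length(signals))
  pos <- 1L
  for (i in seq_len(n)) {
    grp <- if (label[i] == 1L) "failure" else "completer"
    # participant observes the protocol up to the end of their last rest
    t_stop <- min(bouts[i] * (sched$bout_duration_s + sched$rest_duration_s),
                  sched$total_duration_s)
    for (k in seq_along(signals)) {
      sig <- signals[k]
      set.seed((part_seed[i] + k) %% .Machine$integer.max)
      par <- config$kinetics[[grp]][[sig]]
      scl <- 1 + stats::rnorm(1, 0, config$between_sd)
      par$baseline <- par$baseline * max(scl, 0.5)
      scl <- 1 + stats::rnorm(1, 0, config$between_sd)
      par$amplitude <- par$amplitude * max(scl, 0.5)
      mg <- config$sampling_mean_gap_s[[sig]]
      # truncated-exponential breath/beat intervals: real inter-breath
      # intervals do not reach the 10-s QC gap threshold
      gaps <- pmin(stats::rexp(ceiling(2.5 * t_stop / mg), rate = 1 / mg),
                   4 * mg)
      times <- cumsum(c(stats::runif(1, 0, 0.5), gaps))
      times <- times[times < t_stop]
      times <- c(times, t_stop)  # the device logs a final sample at test end
      series[[pos]] <- simulate_signal(sched, par, times, sig,
                                       meta$participant_id[i])
      pos <- pos + 1L
    }
  }
  list(meta = meta, series = series)
}

#' Write a cohort to delimited text files
#'
#' Writes `series.csv` (`participant_id, signal, time_s, value, units`) and
#' `meta.csv` into `dir`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ser <- do.call(rbind, lapply(cohort$series, function(s) {
    data.frame(participant_id = s$participant_id, signal = s$signal,
               time_s = s$times_s, value = s$values, units = s$units,
               stringsAsFactors = FALSE)
  }))
  f1 <- file.path(dir, "series.csv")
  f2 <- file.path(dir, "meta.csv")
  utils::write.csv(ser, f1, row.names = FALSE)
  utils::write.csv(cohort$meta, f2, row.names = FALSE)
  invisible(c(series = f1, meta = f2))
}

#' Read a cohort from series.csv / meta.csv
#'
#' @param series_path,meta_path paths to the files written by
#'   [write_cohort()].
#' @return List with `meta` and `series` in the [generate_cohort()] layout.
#' @export
read_cohort <- function(series_path, meta_path) {
  ser <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (nrow(ser) == 0L) stop("empty series file: ", series_path)
  key <- interaction(ser$participant_id, ser$signal, drop = TRUE)
  series <- lapply(split(ser, key), function(d) {
    d <- d[order(d$time_s), ]
    raw_series(d$participant_id[1], d$signal[1], d$time_s, d$value)
  })
  names(series) <- NULL
  list(meta = meta, series = series)
}
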