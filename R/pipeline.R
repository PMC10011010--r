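#' Assemble a reproducible run configuration
#'
#' Everything a pipeline run needs: file paths, protocol, smoothing,
#' registration, inference and battery settings.  A run is reproducible
#' from its persisted config plus the master seed; every source of
#' randomness downstream derives from `seed`.
#'
#' @param series_path,meta_path input CSV paths (see [write_cohort()]).
#' @param out_dir output directory.
#' @param n_participants cohort size for simulation runs.
#' @param n_bouts_protocol,bout_s,rest_s,intensity protocol parameters.
#' @param n_bouts_analysis leading bouts retained for analysis (default 4,
#'   i.e. 720 s).
#' @param order,spacing_s,omega,lambda_grid smoothing parameters.  The
#'   full-resolution defaults (order 6, 1-s breakpoints) give 725 basis
#'   functions on 720 s; a coarser `spacing_s` scales the whole pipeline
#'   down for quick runs.
#' @param register run continuous registration (default `TRUE`).
#' @param n_perm,n_boot,alpha inference parameters.
#' @param k_folds CV folds.
#' @param signals signals to analyse.
#' @param specs battery specs, or `NULL` for a default GSAM-per-signal set.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(series_path = NULL, meta_path = NULL,
                       out_dir = tempfile("mbeb_run_"),
                       n_participants = 78,
                       n_bouts_protocol = 10, bout_s = 120, rest_s = 60,
                       intensity = 0.8, n_bouts_analysis = 4,
                       order = 6, spacing_s = 1, omega = 2 * pi / 180,
                       lambda_grid = mbebfda::lambda_grid(),
                       register = TRUE,
                       n_perm = 200, n_boot = 500, alpha = 0.05,
                       k_folds = 10,
                       signals = c("HR", "RR", "VO2", "VCO2"),
                       specs = NULL, seed = 1L) {
  structure(list(series_path = series_path, meta_path = meta_path,
                 out_dir = out_dir, n_participants = n_participants,
                 n_bouts_protocol = n_bouts_protocol, bout_s = bout_s,
                 rest_s = rest_s, intensity = intensity,
                 n_bouts_analysis = n_bouts_analysis,
                 order = order, spacing_s = spacing_s, omega = omega,
                 lambda_grid = lambda_grid, register = register,
                 n_perm = n_perm, n_boot = n_boot, alpha = alpha,
                 k_folds = k_folds, signals = signals, specs = specs,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_snapshot <- function(config, path) {
  snap <- config
  snap$specs <- if (is.null(config$specs)) NULL else {
    lapply(config$specs, unclass)
  }
  jsonlite::write_json(unclass(snap), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic MBEB cohort under the config's protocol and seed
#' and writes `series.csv`, `meta.csv` and a `config.json` provenance
#' snapshot into `out_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  sched <- generate_protocol(config$n_bouts_protocol, config$bout_s,
                             config$rest_s, config$intensity)
  cohort <- generate_cohort(simulation_config(
    n_participants = config$n_participants, schedule = sched,
    seed = config$seed))
  paths <- write_cohort(cohort, config$out_dir)
  config_snapshot(config, file.path(config$out_dir, "config.json"))
  invisible(c(paths, config = file.path(config$out_dir, "config.json")))
}

default_battery_specs <- function(signals) {
  lapply(signals, function(s) {
    classifier_spec("GSAM", functional_inputs = s,
                    scalar_inputs = c("sex", "puberty"))
  })
}

#' Run the full analysis pipeline
#'
#' Reads the cohort, applies QC and second-by-second interpolation,
#' truncates to the first `n_bouts_analysis` bouts, smooths each signal on
#' the shared B-spline basis with GCV-selected `lambda`, optionally
#' registers the curves, runs one bootstrap FANOVA per signal
#' (failure vs completer means) and the classifier battery under shared
#' folds, and writes a report bundle (`fanova.json`, `battery.csv`,
#' `battery.json`, `report.json`, `log.txt`) into `out_dir`.
#'
#' @param config a [run_config()] with input paths set.
#' @return Invisibly, the report list.
#' @export
cmd_analyze <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  stage <- "read"
  report <- list(seed = config$seed)
  tryCatch({
    cohort <- read_cohort(config$series_path, config$meta_path)
    sched <- generate_protocol(config$n_bouts_protocol, config$bout_s,
                               config$rest_s, config$intensity)
    stage <- "preprocess"
    pre <- preprocess_cohort(cohort, sched, n_bouts = config$n_bouts_analysis)
    if (nrow(pre$meta) < 4L || length(unique(pre$meta$label)) < 2L ||
        min(table(pre$meta$label)) < 2L) {
      stop("QC left fewer than 2 participants per class")
    }
    log_line("QC: %d of %d participants retained", nrow(pre$meta),
             nrow(cohort$meta))
    report$qc <- pre$qc

    stage <- "smooth"
    t_end <- config$n_bouts_analysis * (config$bout_s + config$rest_s)
    basis <- make_bspline_basis(t_end, config$order, config$spacing_s)
    penalty <- harmonic_penalty(basis, config$omega)
    samples <- list()
    for (sig in config$signals) {
      uni <- Filter(function(u) u$signal == sig, pre$uniform)
      s <- smooth_sample(uni, pre$meta, basis, penalty,
                         grid = config$lambda_grid)
      log_line("smooth %s: lambda = %g, df = %.1f, mean gcv = %.3g",
               sig, s$lambda[1], s$df[1], mean(s$gcv))
      samples[[sig]] <- s
    }
    report$smoothing <- lapply(samples, function(s) {
      list(lambda = s$lambda[1], df = s$df[1], mean_gcv = mean(s$gcv))
    })

    if (isTRUE(config$register)) {
      stage <- "register"
      phase <- list()
      for (sig in config$signals) {
        reg <- register_to_mean(samples[[sig]])
        samples[[sig]] <- reg$registered
        phase[[sig]] <- reg$phase_ratio
        log_line("register %s: phase ratio %.3f", sig, reg$phase_ratio)
      }
      report$phase_ratio <- phase
    }

    stage <- "fanova"
    fan <- lapply(config$signals, function(sig) {
      f <- fanova(samples[[sig]], pre$meta$label, n_boot = config$n_boot,
                  seed = config$seed + 17L)
      log_line("fanova %s: F = %.3f, p = %.4g", sig, f$statistic_obs,
               f$p_value)
      list(signal = sig, statistic = f$statistic_obs, p_value = f$p_value,
           n_boot = f$n_boot)
    })
    report$fanova <- fan
    jsonlite::write_json(fan, file.path(config$out_dir, "fanova.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "classify"
    specs <- if (is.null(config$specs)) {
      default_battery_specs(config$signals)
    } else config$specs
    tab <- run_model_battery(samples, pre$meta, specs,
                             k = min(config$k_folds, nrow(pre$meta)),
                             seed = config$seed + 31L,
                             add_full = length(config$signals) > 1L)
    utils::write.csv(tab, file.path(config$out_dir, "battery.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tab, file.path(config$out_dir, "battery.json"),
                         auto_unbox = TRUE, digits = NA)
    report$battery <- tab

    stage <- "report"
    config_snapshot(config, file.path(config$out_dir, "config.json"))
    jsonlite::write_json(
      list(seed = report$seed,
           qc_excluded = sum(report$qc$excluded),
           smoothing = report$smoothing,
           phase_ratio = report$phase_ratio,
           fanova = report$fanova,
           battery = report$battery),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
    log_line("pipeline complete")
  }, error = function(e) {
    log_line("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(report)
}

#' Command-line entry point
#'
#' A small subcommand interface: `simulate` writes a synthetic cohort,
#' `analyze` runs the full pipeline.  Flags: `--n`, `--seed`, `--out`,
#' `--series`, `--meta`, `--signals` (comma separated), `--no-register`,
#' `--n-perm`, `--n-boot`, `--k-folds`, `--spacing`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Invisibly, the subcommand result.
#' @export
mbeb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: mbeb <simulate|analyze> [--flag value ...]")
  }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  flags <- character(0)
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key == "no-register") { flags <- c(flags, key); i <- i + 1L; next }
    opts[[key]] <- args[i + 1L]; i <- i + 2L
  }
  num <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])
  chr <- function(k, d) if (is.null(opts[[k]])) d else opts[[k]]
  cfg <- run_config(
    series_path = chr("series", NULL), meta_path = chr("meta", NULL),
    out_dir = chr("out", "mbeb_out"),
    n_participants = num("n", 78), seed = as.integer(num("seed", 1)),
    spacing_s = num("spacing", 1),
    register = !("no-register" %in% flags),
    n_perm = num("n-perm", 200), n_boot = num("n-boot", 500),
    k_folds = num("k-folds", 10),
    signals = strsplit(chr("signals", "HR,RR,VO2,VCO2"), ",")[[1]])
  switch(cmd,
         simulate = cmd_simulate(cfg),
         analyze = cmd_analyze(cfg),
         stop("unknown subcommand: ", cmd))
}
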