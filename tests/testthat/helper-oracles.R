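# Independent oracles and fixture builders shared across the suite.
# These re-derive expected values through code paths deliberately different
# from the package implementation.

# Closed-form piecewise-exponential trajectory, written as a scalar
# per-time recursion over bout/rest segments (independent of the package's
# vectorized segment-table evaluation).
oracle_kinetics <- function(t, n_bouts, bout_s, rest_s, baseline, amplitude,
                            tau_on, tau_off, drift = 0) {
  vapply(t, function(tt) {
    y <- baseline
    clock <- 0
    for (k in seq_len(n_bouts)) {
      # exercise segment
      dur <- min(bout_s, max(tt - clock, 0))
      target <- baseline + amplitude
      y <- target + (y - target) * exp(-dur / tau_on)
      clock <- clock + bout_s
      if (tt <= clock) return(y)
      # rest segment
      dur <- min(rest_s, max(tt - clock, 0))
      target <- baseline + drift * k
      y <- target + (y - target) * exp(-dur / tau_off)
      clock <- clock + rest_s
      if (tt <= clock) return(y)
    }
    y
  }, numeric(1))
}

# Generic ridge oracle for the penalized smoother: QR on the augmented
# system rbind(Phi, sqrt(lambda) * R^(1/2)), with R^(1/2) from an eigen
# decomposition (handles the rank-deficient penalty).
oracle_ridge <- function(Phi, y, R, lambda) {
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  sqR <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  A <- rbind(Phi, sqrt(lambda) * sqR)
  b <- c(y, rep(0, nrow(sqR)))
  qr.coef(qr(A), b)
}

# Third-derivative roughness penalty by an independent composite-Simpson
# quadrature over pairwise products (loop form, small bases only).
oracle_d3_penalty <- function(basis, step = 0.01) {
  a <- basis$domain[1]; b <- basis$domain[2]
  nn <- ceiling((b - a) / step); if (nn %% 2 == 1) nn <- nn + 1
  x <- seq(a, b, length.out = nn + 1)
  w <- rep(c(2, 4), length.out = nn + 1); w[1] <- w[nn + 1] <- 1
  w <- w * (b - a) / nn / 3
  D3 <- eval_basis(basis, x, deriv = 3)
  K <- basis$n_basis
  out <- matrix(0, K, K)
  for (j in seq_len(K)) for (k in j:K) {
    v <- sum(w * D3[, j] * D3[, k])
    out[j, k] <- v; out[k, j] <- v
  }
  out
}

# Least-squares projection of values onto the given basis (tiny ridge for
# rank safety); returns the coefficient vector/matrix.
project_onto_basis <- function(basis, tg, Y) {
  Phi <- eval_basis(basis, tg)
  qr.solve(crossprod(Phi) + 1e-10 * diag(basis$n_basis), crossprod(Phi, Y))
}

# A small fd_sample of noisy bump curves with an optional group mean shift
# on label-1 curves.  Returns the sample plus the labels.
make_toy_sample <- function(n = 12, t_end = 120, spacing = 10, order = 4,
                            shift = 0, noise = 1, seed = 1,
                            signal = "HR") {
  set.seed(seed)
  basis <- make_bspline_basis(t_end, order, spacing)
  tg <- 0:t_end
  labels <- rep(c(0L, 1L), length.out = n)
  Y <- sapply(seq_len(n), function(i) {
    base <- 60 + 25 * sin(pi * tg / t_end)^2 + rnorm(1, 0, 2)
    base + shift * labels[i] + rnorm(length(tg), 0, noise)
  })
  coefs <- project_onto_basis(basis, tg, Y)
  meta <- data.frame(participant_id = sprintf("T%02d", seq_len(n)),
                     sex = rep(c("F", "M"), length.out = n),
                     puberty = rep(c("early", "late"), length.out = n),
                     body_mass_kg = 40 + seq_len(n),
                     bouts_completed = ifelse(labels == 1L, 5L, 10L),
                     label = labels, stringsAsFactors = FALSE)
  list(sample = fd_sample(basis, coefs, meta, signal), labels = labels,
       grid = tg)
}

# Small synthetic cohort smoothed end to end on a coarse basis; used by
# classification and pipeline tests.  `shift_sd` is the failure amplitude
# shift in units of the between-participant amplitude SD.
make_smoothed_cohort <- function(n = 78, seed = 1, shift_sd = 2,
                                 signal = "VO2", spacing = 20,
                                 drift = NULL, between_sd = 0.08) {
  base_amp <- 1200
  shift <- shift_sd * between_sd * base_amp
  drift_vec <- c(HR = 0, RR = 0, VO2 = 0, VCO2 = 0)
  if (is.null(drift)) drift <- 35
  drift_vec[signal] <- drift
  shift_vec <- c(HR = 0, RR = 0, VO2 = 0, VCO2 = 0)
  shift_vec[signal] <- shift
  sched <- generate_protocol(4, 120, 60, 0.8)
  cfg <- simulation_config(
    n_participants = n, schedule = sched,
    kinetics = list(completer = default_kinetics("completer"),
                    failure = default_kinetics("failure",
                                               group_mean_shift = shift_vec,
                                               failure_drift = drift_vec)),
    between_sd = between_sd, seed = seed)
  cohort <- generate_cohort(cfg)
  pre <- preprocess_cohort(cohort, sched, n_bouts = 4)
  basis <- make_bspline_basis(720, 6, spacing)
  pen <- harmonic_penalty(basis)
  uni <- Filter(function(u) u$signal == signal, pre$uniform)
  smp <- smooth_sample(uni, pre$meta, basis, pen,
                       grid = lambda_grid(9, 1e-1, 1e3))
  list(sample = smp, meta = smp$meta, schedule = sched)
}
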