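test_that("basis counts follow interior + order, including the 725 case", {
  b <- make_bspline_basis(720, 6, 1)
  expect_length(b$breakpoints, 721L)
  expect_equal(b$n_basis, 725L)                  # 719 interior + 6

  b2 <- make_bspline_basis(10, 4, 5)
  expect_equal(b2$n_basis, 5L)                   # 1 interior + 4
  # cross-check against the de Boor recursion: evaluation matrix has that
  # many columns and full column rank on a dense grid
  B <- eval_basis(b2, seq(0, 10, by = 0.1))
  expect_equal(ncol(B), 5L)
  expect_equal(qr(B)$rank, 5L)

  expect_error(make_bspline_basis(10, 4, 3), "divide")
})

test_that("the basis is a nonnegative partition of unity with local support", {
  b <- make_bspline_basis(60, 6, 5)
  tt <- seq(0, 60, by = 0.25)
  B <- eval_basis(b, tt)
  expect_true(all(B >= -1e-12))
  expect_equal(rowSums(B), rep(1, length(tt)), tolerance = 1e-10)
  # support of each function spans at most `order` inter-breakpoint spans
  for (j in seq_len(b$n_basis)) {
    nz <- range(tt[B[, j] > 1e-10])
    expect_lte(diff(nz), 6 * 5 + 1e-9)
  }
})

test_that("harmonic penalty annihilates its null space but not sin(2wt)", {
  omega <- 2 * pi / 30
  b <- make_bspline_basis(60, 6, 2)
  pen <- harmonic_penalty(b, omega, quadrature_step_s = 0.05)
  tg <- seq(0, 60, by = 0.1)
  ref_coef <- project_onto_basis(b, tg, sin(2 * omega * tg))
  ref_form <- drop(t(ref_coef) %*% pen$matrix %*% ref_coef)
  expect_gt(ref_form, 0)
  for (f in list(function(t) rep(1, length(t)),
                 function(t) sin(omega * t),
                 function(t) cos(omega * t))) {
    cf <- project_onto_basis(b, tg, f(tg))
    expect_lt(drop(t(cf) %*% pen$matrix %*% cf) / ref_form, 1e-6)
  }
  # the constant is annihilated exactly (partition of unity)
  cn <- rep(1, b$n_basis)
  expect_lt(abs(drop(cn %*% pen$matrix %*% cn)) / ref_form, 1e-10)
})

test_that("omega = 0 reduces to the D3 roughness penalty (oracle match)", {
  b <- make_bspline_basis(10, 5, 2)
  pen <- harmonic_penalty(b, omega = 0, quadrature_step_s = 0.005)
  want <- oracle_d3_penalty(b, step = 0.005)
  expect_lt(max(abs(pen$matrix - want)) / max(abs(want)), 1e-8)
  expect_error(harmonic_penalty(make_bspline_basis(10, 3, 2), 0.1),
               "order")
})

test_that("penalized_smooth solves the penalized normal equations", {
  # exact reproduction of penalty-null-space data at any lambda (the basis
  # must be fine enough to represent sin/cos to well below the tolerance)
  omega <- 2 * pi / 40
  b <- make_bspline_basis(80, 6, 1)
  pen <- harmonic_penalty(b, omega, quadrature_step_s = 0.1)
  tg <- 0:80
  y <- list(grid_s = tg, values = 3 + 2 * sin(omega * tg) -
              1.5 * cos(omega * tg))
  # (sin/cos sit in the spline span only to O(h^6), so beyond lambda ~ 1e8
  # the product lambda * approximation-error leaves double precision and
  # the analytic null space no longer matches the discrete one)
  for (lam in c(1e-2, 1e2, 1e6, 1e8)) {
    fit <- penalized_smooth(y, b, pen, lam)
    expect_equal(fit$fitted, y$values, tolerance = 1e-6)
  }

  # lambda -> very large approaches the regression onto {1, sin, cos}
  set.seed(1)
  y2 <- list(grid_s = tg, values = 50 + 10 * sin(omega * tg) + rnorm(81, 0, 3))
  big <- penalized_smooth(y2, b, pen, 1e10)
  X <- cbind(1, sin(omega * tg), cos(omega * tg))
  proj <- drop(X %*% qr.solve(X, y2$values))
  expect_lt(max(abs(big$fitted - proj)) / diff(range(y2$values)), 1e-4)

  # sse is minimal at lambda = 0 when the system is well posed
  b3 <- make_bspline_basis(40, 4, 8)
  pen3 <- harmonic_penalty(b3, omega, quadrature_step_s = 0.02)
  y3 <- list(grid_s = 0:40, values = rnorm(41, 10, 2))
  sses <- vapply(c(0, 1, 100, 1e4), function(l) {
    penalized_smooth(y3, b3, pen3, l)$sse
  }, 0)
  expect_true(all(diff(sses) >= -1e-10))

  # lambda = 0 with fewer points than basis functions: informative error
  b4 <- make_bspline_basis(40, 6, 1)
  pen4 <- harmonic_penalty(b4, omega)
  expect_error(penalized_smooth(list(grid_s = 0:40, values = rnorm(41)),
                                b4, pen4, 0), "positive")
})

test_that("smoother matches a generic ridge solve on random small problems", {
  set.seed(11)
  for (rep in 1:10) {
    t_end <- sample(c(12, 20, 40), 1)
    order <- sample(4:6, 1)
    spacing <- t_end / sample(2:4, 1)
    b <- make_bspline_basis(t_end, order, spacing)
    pen <- harmonic_penalty(b, 2 * pi / t_end, quadrature_step_s = 0.02)
    n <- sample(15:40, 1)
    tg <- sort(runif(n, 0, t_end))
    y <- list(grid_s = tg, values = rnorm(n, 10, 3))
    lam <- 10^runif(1, -2, 3)
    fit <- penalized_smooth(y, b, pen, lam)
    Phi <- eval_basis(b, tg)
    want <- oracle_ridge(Phi, y$values, pen$matrix, lam)
    expect_equal(fit$coefficients, unname(want), tolerance = 1e-8)
  }
})

test_that("df and gcv behave as the hat-matrix theory requires", {
  omega <- 2 * pi / 40
  b <- make_bspline_basis(40, 4, 5)
  pen <- harmonic_penalty(b, omega, quadrature_step_s = 0.02)
  set.seed(3)
  y <- list(grid_s = 0:40, values = 20 + 5 * sin(omega * (0:40)) + rnorm(41))
  # df(lambda = 0, full rank) equals n_basis
  f0 <- penalized_smooth(y, b, pen, 0)
  expect_equal(f0$df, b$n_basis, tolerance = 1e-8)
  # df equals the eigenvalue sum of the smoothing map
  lam <- 37
  fit <- penalized_smooth(y, b, pen, lam)
  Phi <- eval_basis(b, y$grid_s)
  H <- Phi %*% solve(crossprod(Phi) + lam * pen$matrix, t(Phi))
  expect_equal(fit$df, sum(eigen(H, only.values = TRUE)$values),
               tolerance = 1e-8)
  # gcv two ways: trace form vs per-residual leave-structure form
  n <- length(y$values)
  resid <- y$values - fit$fitted
  gcv2 <- mean((resid / (1 - fit$df / n))^2)
  expect_equal(fit$gcv, gcv2, tolerance = 1e-10)
  # evaluation of the fit at observation points equals Phi c
  expect_equal(fit$fitted, drop(Phi %*% fit$coefficients), tolerance = 1e-12)
})

test_that("select_lambda returns the gcv trace and ties to largest lambda", {
  omega <- 2 * pi / 40
  b <- make_bspline_basis(40, 6, 4)
  pen <- harmonic_penalty(b, omega, quadrature_step_s = 0.02)
  grid <- lambda_grid(9, 1e-2, 1e4)

  # noise-free null-space signal: everything ties, largest lambda wins
  y0 <- list(grid_s = 0:40, values = 2 + sin(omega * (0:40)))
  sel0 <- select_lambda(y0, b, pen, grid)
  expect_equal(sel0$curve$lambda, max(grid))

  # df is non-increasing in lambda across the trace
  set.seed(8)
  y <- list(grid_s = 0:40, values = rnorm(41, 50, 5))
  sel <- select_lambda(y, b, pen, grid)
  expect_true(all(diff(sel$trace$df) <= 1e-8))
  expect_equal(nrow(sel$trace), length(grid))
  expect_equal(sel$curve$gcv, min(sel$trace$gcv))
})

test_that("gcv-selected smoothing beats both grid extremes against truth", {
  omega <- 2 * pi / 60
  b <- make_bspline_basis(60, 6, 3)
  pen <- harmonic_penalty(b, omega, quadrature_step_s = 0.05)
  grid <- lambda_grid(11, 1e-4, 1e6)
  tg <- 0:60
  truth <- 30 + 10 * sin(2 * pi * tg / 30) + 4 * cos(2 * pi * tg / 17)
  set.seed(21)
  wins <- 0L
  for (r in 1:10) {
    y <- list(grid_s = tg, values = truth + rnorm(61, 0, 2))
    sel <- select_lambda(y, b, pen, grid)
    rmse <- function(lam) {
      sqrt(mean((penalized_smooth(y, b, pen, lam)$fitted - truth)^2))
    }
    if (sqrt(mean((sel$curve$fitted - truth)^2)) <=
        min(rmse(min(grid)), rmse(max(grid))) + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("smooth_sample shares one lambda per signal and is deterministic", {
  toy <- make_toy_sample(n = 6, seed = 13)
  sched <- generate_protocol(2, 40, 20, 0.8)
  uni <- lapply(seq_len(6), function(i) {
    structure(list(participant_id = toy$sample$meta$participant_id[i],
                   signal = "HR", grid_s = toy$grid,
                   values = eval_sample(toy$sample, toy$grid)[, i] +
                     rnorm(length(toy$grid), 0, 0.5),
                   t_end = 120),
              class = "uniform_series")
  })
  b <- make_bspline_basis(120, 5, 10)
  pen <- harmonic_penalty(b, 2 * pi / 60)
  s1 <- smooth_sample(uni, toy$sample$meta, b, pen, grid = lambda_grid(7, 1, 1e4))
  expect_equal(length(unique(s1$lambda)), 1L)
  expect_equal(n_curves(s1), 6L)
  s2 <- smooth_sample(uni, toy$sample$meta, b, pen, grid = lambda_grid(7, 1, 1e4))
  expect_identical(s1$coefs, s2$coefs)

  # single-curve sample agrees with select_lambda
  s3 <- smooth_sample(uni[1], toy$sample$meta[1, , drop = FALSE], b, pen,
                      grid = lambda_grid(7, 1, 1e4))
  sel <- select_lambda(uni[[1]], b, pen, lambda_grid(7, 1, 1e4))
  expect_equal(drop(s3$coefs), sel$curve$coefficients, tolerance = 1e-10)
  expect_equal(s3$lambda[1], sel$curve$lambda)
})
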