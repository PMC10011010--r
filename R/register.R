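#' Monotone warping functions for continuous registration
#'
#' Warps are parameterized as exponentiated B-spline integrals,
#' `h(t) = T * int_0^t exp(W(s)) ds / int_0^T exp(W(s)) ds`, with `W` a
#' spline with coefficients `w`.  This guarantees `h(0) = 0`, `h(T) = T`
#' and a strictly positive derivative; `w = 0` gives the identity warp.
#'
#' @param basis the warp coefficient basis (a small `bspline_basis`).
#' @param w coefficient vector.
#' @return A `warp_fn` list.
#' @keywords internal
warp_fn <- function(basis, w) {
  structure(list(basis = basis, w = w), class = "warp_fn")
}

#' Evaluate a warping function (or its derivative)
#'
#' Uses cumulative trapezoid integration of `exp(W)` on a fine internal
#' grid.
#'
#' @param warp a `warp_fn`.
#' @param t evaluation times.
#' @param n_fine internal integration grid size.
#' @param deriv 0 for `h(t)`, 1 for `h'(t)`.
#' @return Numeric vector.
#' @export
eval_warp <- function(warp, t, n_fine = 401L, deriv = 0) {
  dom <- warp$basis$domain
  tf <- seq(dom[1], dom[2], length.out = n_fine)
  # clamp the log-slope so optimizer excursions cannot overflow exp()
  eW <- exp(pmin(pmax(eval_coefs(warp$basis, warp$w, tf), -20), 20))
  dt <- diff(tf)
  cum <- c(0, cumsum((eW[-1] + eW[-n_fine]) / 2 * dt))
  total <- cum[n_fine]
  h <- dom[1] + (dom[2] - dom[1]) * cum / total
  if (deriv == 0) {
    stats::approx(tf, h, xout = t, rule = 2)$y
  } else {
    dh <- (dom[2] - dom[1]) * eW / total
    stats::approx(tf, dh, xout = t, rule = 2)$y
  }
}

#' Apply a time warp to a smoothed curve
#'
#' Computes `x(h(t))` on a fine grid and re-projects it onto the curve's
#' own basis by penalized least squares (a tiny ridge on the identity keeps
#' the projection well-posed when the basis outnumbers the grid).
#'
#' @param curve a `smoothed_curve`.
#' @param warp a `warp_fn` on the same domain.
#' @return A `smoothed_curve` representing the warped curve.
#' @export
apply_warp <- function(curve, warp) {
  dom <- curve$basis$domain
  if (any(abs(warp$basis$domain - dom) > 1e-8)) {
    stop("warp domain does not match curve domain")
  }
  nf <- max(4L * curve$basis$n_basis, 401L)
  tf <- seq(dom[1], dom[2], length.out = nf)
  ht <- pmin(pmax(eval_warp(warp, tf), dom[1]), dom[2])
  yv <- eval_curve(curve, ht)
  Phi <- eval_basis(curve$basis, tf)
  M <- crossprod(Phi) + 1e-10 * diag(curve$basis$n_basis)
  coefs <- solve(M, crossprod(Phi, yv))
  out <- curve
  out$coefficients <- drop(coefs)
  out
}

#' Continuous registration of a functional sample to its mean
#'
#' Iteratively (i) computes the cross-sectional mean, (ii) finds, for each
#' curve, the monotone warp minimizing penalized least-squares misalignment
#' to the mean, and (iii) updates the mean, until the mean changes by less
#' than `tol` (relative) or `max_iter` is reached.  The phase/amplitude
#' decomposition follows the Kneip--Ramsay construction:
#' `MSE_total = MSE_phase + MSE_amp` with
#' `MSE_amp = C * mean_i int (y_i - ybar)^2`,
#' `MSE_phase = C * int ybar^2 - int xbar^2`, and
#' `C = mean_i int x_i^2 / mean_i int y_i^2` (registered curves `y_i`,
#' unregistered `x_i`); with this `C` the additivity identity is exact.
#'
#' @param sample an `fd_sample` with at least two curves.
#' @param warp_basis_size number of coefficients of the warp spline.
#' @param max_iter outer iterations.
#' @param tol relative change in the mean at which to stop.
#' @param warp_penalty roughness weight on the warp coefficients.
#' @param n_grid working grid size.
#' @return A `registration_result`: `registered` (an `fd_sample`), `warps`
#'   (list of `warp_fn`), `mse_total`, `mse_phase`, `mse_amp`,
#'   `phase_ratio`, `iterations`.
#' @export
register_to_mean <- function(sample, warp_basis_size = 5, max_iter = 3,
                             tol = 1e-4, warp_penalty = 1e-2,
                             n_grid = 241L) {
  n <- n_curves(sample)
  if (n < 2L) stop("registration needs at least two curves")
  dom <- sample$basis$domain
  if (warp_basis_size < 4L) stop("`warp_basis_size` must be >= 4")
  # order-4 warp spline with interior breakpoints chosen so that
  # n_basis == warp_basis_size
  wbasis <- make_bspline_basis(dom[2] - dom[1], order = 4,
                               breakpoint_spacing_s =
                                 (dom[2] - dom[1]) / (warp_basis_size - 3))
  tg <- seq(dom[1], dom[2], length.out = n_grid)
  X <- eval_sample(sample, tg)                    # unregistered evaluations
  # cubic interpolators make repeated warped evaluation cheap inside optim
  interps <- lapply(seq_len(n), function(i) {
    stats::splinefun(tg, X[, i], method = "natural")
  })
  W <- matrix(0, wbasis$n_basis, n)
  Y <- X
  for (iter in seq_len(max_iter)) {
    mu <- rowMeans(Y)
    Y_old <- Y
    for (i in seq_len(n)) {
      obj <- function(w) {
        ht <- eval_warp(warp_fn(wbasis, w), tg)
        ht <- pmin(pmax(ht, dom[1]), dom[2])
        mean((interps[[i]](ht) - mu)^2) + warp_penalty * mean(w^2)
      }
      fit <- stats::optim(W[, i], obj, method = "BFGS",
                          control = list(maxit = 50, reltol = 1e-8))
      W[, i] <- fit$par
      ht <- pmin(pmax(eval_warp(warp_fn(wbasis, W[, i]), tg), dom[1]), dom[2])
      Y[, i] <- interps[[i]](ht)
    }
    delta <- sqrt(mean((rowMeans(Y) - mu)^2)) /
      max(sqrt(mean(mu^2)), .Machine$double.eps)
    if (delta < tol && iter > 1L) break
  }
  warps <- lapply(seq_len(n), function(i) warp_fn(wbasis, W[, i]))

  # quadrature on the working grid (trapezoid)
  wq <- rep(diff(tg)[1], n_grid); wq[c(1, n_grid)] <- wq[1] / 2
  int <- function(v) sum(wq * v)
  xbar <- rowMeans(X); ybar <- rowMeans(Y)
  int_x2 <- mean(apply(X, 2, function(v) int(v^2)))
  int_y2 <- mean(apply(Y, 2, function(v) int(v^2)))
  C <- if (int_y2 > 0) int_x2 / int_y2 else 1
  mse_total <- int_x2 - int(xbar^2)
  mse_amp <- C * (int_y2 - int(ybar^2))
  mse_phase <- C * int(ybar^2) - int(xbar^2)
  phase_ratio <- if (mse_total > 0) min(max(mse_phase / mse_total, 0), 1) else 0

  # re-project registered evaluations onto the shared basis
  Phi <- eval_basis(sample$basis, tg)
  M <- crossprod(Phi) + 1e-10 * diag(sample$basis$n_basis)
  reg_coefs <- solve(M, crossprod(Phi, Y))
  registered <- sample
  registered$coefs <- reg_coefs
  structure(list(registered = registered, warps = warps,
                 mse_total = mse_total, mse_phase = mse_phase,
                 mse_amp = mse_amp, phase_ratio = phase_ratio,
                 iterations = iter),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "Registration: %d curves, MSE total %.4g = phase %.4g + amplitude %.4g (phase ratio %.1f%%)\n",
    n_curves(x$registered), x$mse_total, x$mse_phase, x$mse_amp,
    100 * x$phase_ratio))
  invisible(x)
}
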