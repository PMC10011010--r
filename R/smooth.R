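#' Penalized least-squares smoothing of a uniform series
#'
#' Solves `(Phi' Phi + lambda R) c = Phi' y` for the basis coefficients,
#' where `Phi` is the basis evaluated at the observation grid and `R` the
#' roughness penalty.  Effective degrees of freedom are the trace of the
#' hat matrix, `df = tr(Phi (Phi'Phi + lambda R)^{-1} Phi')`, and
#' `GCV = n * SSE / (n - df)^2` (Craven--Wahba).
#'
#' @param y a `uniform_series` (or list with `grid_s` and `values`).
#' @param basis a `bspline_basis`.
#' @param penalty a [harmonic_penalty()] object.
#' @param lambda smoothing parameter (>= 0).
#' @return A `smoothed_curve`: `basis`, `coefficients`, `lambda`, `df`,
#'   `sse`, `gcv`, `fitted`.
#' @export
penalized_smooth <- function(y, basis, penalty, lambda) {
  if (lambda < 0) stop("`lambda` must be non-negative")
  Phi <- eval_basis(basis, y$grid_s)
  fit <- smooth_engine(Phi, matrix(y$values, ncol = 1), penalty$matrix, lambda)
  structure(list(basis = basis, coefficients = drop(fit$coefs),
                 lambda = lambda, df = fit$df, sse = fit$sse[1],
                 gcv = fit$gcv[1], fitted = drop(fit$fitted)),
            class = "smoothed_curve")
}

# Shared solver: one Phi/penalty factorization smoothing many curves
# (columns of Y) at once.  df depends only on (Phi, R, lambda).
# Moderate lambdas take the Cholesky normal-equations route; extreme
# lambdas (where lambda*R swamps Phi'Phi and the normal equations lose
# half the significant digits) fall back to QR on the augmented system
# rbind(Phi, sqrt(lambda) R^{1/2}), which is stable in the limit.
smooth_engine <- function(Phi, Y, R, lambda) {
  n <- nrow(Phi)
  PtP <- crossprod(Phi)
  scale_ratio <- if (lambda > 0) {
    lambda * norm(R, "F") / max(norm(PtP, "F"), .Machine$double.eps)
  } else 0
  if (scale_ratio > 1e6) {
    eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
    sqR <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
    qrA <- qr(rbind(Phi, sqrt(lambda) * sqR))
    coefs <- qr.coef(qrA, rbind(Y, matrix(0, nrow(sqR), ncol(Y))))
    Rq <- qr.R(qrA)
    # df = tr(Phi M^-1 Phi') = ||Phi Rq^-1||_F^2  (M = Rq'Rq up to pivot)
    piv <- qrA$pivot
    X <- t(backsolve(Rq, t(Phi[, piv, drop = FALSE]), transpose = TRUE))
    df <- sum(X^2)
  } else {
    ch <- tryCatch(chol(PtP + lambda * R), error = function(e) NULL)
    if (is.null(ch)) {
      if (lambda == 0 && n < ncol(Phi)) {
        stop("singular system: fewer observations than basis functions; ",
             "use a positive `lambda`")
      }
      stop("penalized normal equations are numerically singular")
    }
    coefs <- backsolve(ch, forwardsolve(t(ch), crossprod(Phi, Y)))
    # tr(M^-1 Phi'Phi) without forming the n x n hat matrix
    df <- sum(diag(backsolve(ch, forwardsolve(t(ch), PtP))))
  }
  fitted <- Phi %*% coefs
  sse <- colSums((Y - fitted)^2)
  df <- min(df, n - 1e-8)  # guard the GCV denominator
  gcv <- n * sse / (n - df)^2
  list(coefs = coefs, fitted = fitted, sse = sse, df = df, gcv = gcv)
}

#' Evaluate a smoothed curve
#' @param curve a `smoothed_curve`.
#' @param t times within the basis domain.
#' @param deriv derivative order.
#' @return Numeric vector of curve values.
#' @export
eval_curve <- function(curve, t, deriv = 0) {
  eval_coefs(curve$basis, curve$coefficients, t, deriv)
}

#' Select the smoothing parameter by generalized cross-validation
#'
#' Fits the penalized smooth over a grid of `lambda` values and returns the
#' fit minimizing GCV, together with the full `(lambda, df, gcv)` trace for
#' inspection (the classic GCV-vs-DoF search plot).  Ties are broken toward
#' the largest `lambda` (the smoother fit).
#'
#' @inheritParams penalized_smooth
#' @param grid positive `lambda` values to try; default 41 points
#'   log-spaced between 1e-2 and 1e6.
#' @return List with `curve` (the selected `smoothed_curve`) and `trace`
#'   (data.frame `lambda`, `df`, `gcv`).
#' @export
select_lambda <- function(y, basis, penalty, grid = lambda_grid()) {
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("`grid` must be a nonempty vector of positive lambdas")
  }
  grid <- sort(grid)
  fits <- lapply(grid, function(l) {
    tryCatch(penalized_smooth(y, basis, penalty, l), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, TRUE, what = "error")
  if (!any(ok)) stop("smoothing failed at every lambda in the grid")
  tr <- data.frame(lambda = grid[ok],
                   df = vapply(fits[ok], `[[`, 0, "df"),
                   gcv = vapply(fits[ok], `[[`, 0, "gcv"))
  # ties (within a tiny absolute + relative band, e.g. noise-free
  # null-space signals where every gcv is numerically zero) go to the
  # largest lambda, i.e. the smoothest fit
  best <- max(which(tr$gcv <= min(tr$gcv) * (1 + 1e-10) + 1e-10))
  list(curve = fits[ok][[best]], trace = tr)
}

#' Default lambda search grid
#' @param n number of grid points.
#' @param lo,hi grid range.
#' @return Log-spaced lambda values.
#' @export
lambda_grid <- function(n = 41, lo = 1e-2, hi = 1e6) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Smooth a cohort of uniform series into a functional sample
#'
#' All curves of one signal share a single `lambda`, chosen to minimize the
#' sum of per-curve GCV over the grid (per-curve selection is available via
#' `per_curve = TRUE`).
#'
#' @param uniform list of `uniform_series`, all same signal and grid.
#' @param meta metadata data.frame aligned by `participant_id`.
#' @param basis,penalty basis and penalty shared by all curves.
#' @param grid lambda search grid.
#' @param per_curve if `TRUE`, select lambda independently per curve.
#' @return An `fd_sample`: `basis`, `coefs` (`n_basis x n` matrix), `meta`
#'   (aligned rows), `signal`, `lambda`, `df`, `gcv` and `sse` per curve,
#'   and the observation grid `grid_s`.
#' @export
smooth_sample <- function(uniform, meta, basis, penalty,
                          grid = lambda_grid(), per_curve = FALSE) {
  if (length(uniform) == 0L) stop("no series to smooth")
  sig <- unique(vapply(uniform, `[[`, "", "signal"))
  if (length(sig) != 1L) stop("all series must share one signal")
  g0 <- uniform[[1]]$grid_s
  if (!all(vapply(uniform, function(u) identical(u$grid_s, g0), TRUE))) {
    stop("all series must share one grid")
  }
  ids <- vapply(uniform, `[[`, "", "participant_id")
  meta <- meta[match(ids, meta$participant_id), , drop = FALSE]
  Y <- vapply(uniform, `[[`, numeric(length(g0)), "values")
  Phi <- eval_basis(basis, g0)
  R <- penalty$matrix

  if (per_curve) {
    sel <- lapply(seq_along(uniform), function(i) {
      select_lambda(uniform[[i]], basis, penalty, grid)$curve
    })
    coefs <- vapply(sel, `[[`, numeric(basis$n_basis), "coefficients")
    lam <- vapply(sel, `[[`, 0, "lambda")
    dfs <- vapply(sel, `[[`, 0, "df")
    gcvs <- vapply(sel, `[[`, 0, "gcv")
    sses <- vapply(sel, `[[`, 0, "sse")
  } else {
    grid <- sort(grid)
    tot <- rep(Inf, length(grid))
    fits <- vector("list", length(grid))
    for (j in seq_along(grid)) {
      f <- tryCatch(smooth_engine(Phi, Y, R, grid[j]), error = function(e) NULL)
      if (!is.null(f)) { fits[[j]] <- f; tot[j] <- sum(f$gcv) }
    }
    if (!any(is.finite(tot))) stop("smoothing failed at every lambda")
    best <- max(which(tot <= min(tot) * (1 + 1e-10) + 1e-10))
    f <- fits[[best]]
    coefs <- f$coefs
    lam <- rep(grid[best], ncol(Y))
    dfs <- rep(f$df, ncol(Y))
    gcvs <- f$gcv
    sses <- f$sse
  }
  fd_sample(basis, coefs, meta, sig, lambda = lam, df = dfs, gcv = gcvs,
            sse = sses, grid_s = g0)
}

#' Construct a functional sample (a cohort of curves on one shared basis)
#'
#' @param basis shared `bspline_basis`.
#' @param coefs `n_basis x n_curves` coefficient matrix.
#' @param meta metadata data.frame with one row per curve (may be `NULL`).
#' @param signal signal name.
#' @param ... further per-curve fields (`lambda`, `df`, `gcv`, `sse`,
#'   `grid_s`).
#' @return An `fd_sample`.
#' @export
fd_sample <- function(basis, coefs, meta = NULL, signal = "HR", ...) {
  coefs <- as.matrix(coefs)
  if (nrow(coefs) != basis$n_basis) {
    stop("coefficient rows must equal the basis size")
  }
  if (!is.null(meta) && nrow(meta) != ncol(coefs)) {
    stop("meta rows must align 1:1 with curves")
  }
  structure(c(list(basis = basis, coefs = coefs, meta = meta,
                   signal = signal), list(...)),
            class = "fd_sample")
}

#' Number of curves in a functional sample
#' @param sample an `fd_sample`.
#' @return Integer count.
#' @export
n_curves <- function(sample) ncol(sample$coefs)

#' Evaluate all curves of a functional sample on a grid
#' @param sample an `fd_sample`.
#' @param t times; defaults to integer seconds over the domain.
#' @param deriv derivative order.
#' @return Matrix `length(t) x n_curves`.
#' @export
eval_sample <- function(sample, t = NULL, deriv = 0) {
  if (is.null(t)) t <- seq(sample$basis$domain[1], sample$basis$domain[2])
  eval_coefs(sample$basis, sample$coefs, t, deriv)
}

#' Subset a functional sample by curve index
#' @param sample an `fd_sample`.
#' @param idx integer or logical index over curves.
#' @return An `fd_sample` with the selected curves (and meta rows).
#' @export
subset_sample <- function(sample, idx) {
  out <- sample
  out$coefs <- sample$coefs[, idx, drop = FALSE]
  if (!is.null(sample$meta)) out$meta <- sample$meta[idx, , drop = FALSE]
  for (f in c("lambda", "df", "gcv", "sse")) {
    if (!is.null(sample[[f]]) && length(sample[[f]]) == ncol(sample$coefs)) {
      out[[f]] <- sample[[f]][idx]
    }
  }
  out
}

#' @export
print.fd_sample <- function(x, ...) {
  cat(sprintf("Functional sample: %d %s curve(s), %d basis fns on [%g, %g]\n",
              n_curves(x), x$signal, x$basis$n_basis,
              x$basis$domain[1], x$basis$domain[2]))
  invisible(x)
}
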