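#' Functional principal component analysis of a functional sample
#'
#' Eigen-decomposes the sample covariance operator in coefficient space
#' using the basis Gram matrix `G`: with centered coefficients `C` (curves
#' in rows) and `G = U'U` (Cholesky), the eigenproblem of the operator is
#' the symmetric eigenproblem of `U (C'C/(n-1)) U'`.  Eigenfunctions are
#' orthonormal in L2; scores are the L2 inner products of centered curves
#' with the eigenfunctions.
#'
#' @param sample an `fd_sample` with >= 2 curves.
#' @param n_components fixed number of components, or `NULL` to use
#'   `var_threshold`.
#' @param var_threshold keep the smallest K reaching this cumulative
#'   variance proportion (default 0.95), capped at `max_components`.
#' @param max_components cap on K (default 10).
#' @return An `fpca_basis`: `mean_coefs`, `eigen_coefs`
#'   (`n_basis x K`, eigenfunction coefficients), `eigenvalues` (all),
#'   `scores` (`n x K`), `varprop` (cumulative), `n_components`, `basis`,
#'   `gram`.
#' @export
fpca <- function(sample, n_components = NULL, var_threshold = 0.95,
                 max_components = 10) {
  n <- n_curves(sample)
  if (n < 2L) stop("FPCA needs at least two curves")
  if (!is.null(n_components) && n_components > n - 1L) {
    stop("`n_components` may not exceed n - 1")
  }
  G <- basis_gram(sample$basis)
  mean_coefs <- rowMeans(sample$coefs)
  Cc <- t(sample$coefs - mean_coefs)          # n x n_basis, centered
  U <- chol(G)
  S <- U %*% (crossprod(Cc) / (n - 1)) %*% t(U)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  nkeep <- min(n - 1L, sample$basis$n_basis)
  cumv <- cumsum(vals) / max(sum(vals), .Machine$double.eps)
  K <- if (!is.null(n_components)) as.integer(n_components) else {
    min(max(which(cumv[seq_len(nkeep)] >= var_threshold)[1], 1L, na.rm = TRUE),
        max_components, nkeep)
  }
  if (is.na(K) || K < 1L) K <- 1L
  # eigenfunction coefficients: u = U^{-1} v, so that u'Gu = 1
  Uc <- backsolve(U, eg$vectors[, seq_len(K), drop = FALSE])
  scores <- Cc %*% G %*% Uc
  structure(list(mean_coefs = mean_coefs, eigen_coefs = Uc,
                 eigenvalues = vals, scores = scores,
                 varprop = cumv, n_components = K,
                 basis = sample$basis, gram = G),
            class = "fpca_basis")
}

#' Project new curves onto a fitted FPCA basis
#'
#' Used inside cross-validation: test-fold curves are scored against the
#' training fold's mean and eigenfunctions (no leakage).
#'
#' @param fp an `fpca_basis`.
#' @param sample an `fd_sample` on the same basis.
#' @return Score matrix `n x K`.
#' @export
fpca_project <- function(fp, sample) {
  Cc <- t(sample$coefs - fp$mean_coefs)
  Cc %*% fp$gram %*% fp$eigen_coefs
}

#' @export
print.fpca_basis <- function(x, ...) {
  cat(sprintf("FPCA: %d component(s), %.1f%% of variance\n",
              x$n_components, 100 * x$varprop[x$n_components]))
  invisible(x)
}
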