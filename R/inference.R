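#' Pointwise Welch t-statistic between two functional samples
#'
#' Evaluates both groups' curves on a grid and computes, at each time, the
#' two-sample t-statistic with unpooled (Welch) variances.
#'
#' @param groupA,groupB `fd_sample`s on a shared basis, each with >= 2
#'   curves.
#' @param grid_s evaluation times; default integer seconds over the domain.
#' @return Numeric vector of t values on `grid_s`.
#' @export
pointwise_tstat <- function(groupA, groupB, grid_s = NULL) {
  if (is.null(grid_s)) {
    grid_s <- seq(groupA$basis$domain[1], groupA$basis$domain[2])
  }
  welch_t(eval_sample(groupA, grid_s), eval_sample(groupB, grid_s))
}

# Welch t at every row of two evaluation matrices (rows = times).
welch_t <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2L || nB < 2L) stop("each group needs at least two curves")
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se <- sqrt(vA / nA + vB / nB)
  se[se == 0] <- .Machine$double.eps
  (mA - mB) / se
}

#' Functional permutation t-test between two groups
#'
#' Permutes group labels `n_perm` times and records the null distribution
#' of the pointwise |t| and of its maximum over the grid.  The familywise
#' decision uses the max-statistic criterion: times where the observed |t|
#' exceeds the permutation `1 - alpha` quantile of `max_t |t|` form the
#' rejection regions; pointwise quantiles are returned for plotting.
#'
#' @inheritParams pointwise_tstat
#' @param n_perm number of label permutations (>= 100).
#' @param alpha familywise level.
#' @param seed integer seed (mandatory: results are resampling-based).
#' @return A `perm_test_result`: `grid_s`, `t_obs`, `pointwise_crit`,
#'   `max_crit`, `alpha`, `n_perm`, `reject_regions` (two-column matrix of
#'   interval endpoints), `reject` (any region found).
#' @export
permutation_ttest <- function(groupA, groupB, n_perm = 200, alpha = 0.05,
                              seed, grid_s = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: permutation results must be reproducible")
  }
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (is.null(grid_s)) {
    grid_s <- seq(groupA$basis$domain[1], groupA$basis$domain[2])
  }
  A <- eval_sample(groupA, grid_s)
  B <- eval_sample(groupB, grid_s)
  res <- perm_ttest_matrix(A, B, n_perm, alpha, seed)
  res$grid_s <- grid_s
  res$reject_regions <- runs_to_intervals(grid_s,
                                          abs(res$t_obs) > res$max_crit)
  res$reject <- nrow(res$reject_regions) > 0L
  class(res) <- "perm_test_result"
  res
}

# Matrix core shared with calibration studies: columns are curves.
perm_ttest_matrix <- function(A, B, n_perm, alpha, seed) {
  nA <- ncol(A); nB <- ncol(B)
  X <- cbind(A, B)
  t_obs <- welch_t(A, B)
  set.seed(seed)
  null_abs <- matrix(0, nrow(X), n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(nA + nB)
    null_abs[, p] <- abs(welch_t(X[, idx[seq_len(nA)], drop = FALSE],
                                 X[, idx[-seq_len(nA)], drop = FALSE]))
  }
  # 'type 1'-style upper quantile keeps the test level conservative for
  # finite n_perm
  qidx <- ceiling((1 - alpha) * n_perm)
  max_null <- sort(apply(null_abs, 2, max))
  pointwise_crit <- apply(null_abs, 1, function(v) sort(v)[qidx])
  list(t_obs = t_obs, pointwise_crit = pointwise_crit,
       max_crit = max_null[qidx], alpha = alpha, n_perm = n_perm)
}

# Convert a logical vector over a grid into closed intervals.
runs_to_intervals <- function(grid_s, flag) {
  if (!any(flag)) {
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("from_s", "to_s"))))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(from_s = grid_s[starts[keep]], to_s = grid_s[ends[keep]])
}

#' Group mean curves and the grand mean
#'
#' Means are taken in coefficient space, which is exact on a shared basis.
#'
#' @param sample an `fd_sample`.
#' @param labels vector (one per curve) defining the groups.
#' @return List with `groups` (named list of coefficient vectors), `grand`
#'   (grand-mean coefficients) and `basis`.
#' @export
group_mean_curves <- function(sample, labels) {
  if (length(labels) != n_curves(sample)) {
    stop("`labels` must align with curves")
  }
  lev <- sort(unique(labels))
  groups <- lapply(lev, function(g) {
    rowMeans(sample$coefs[, labels == g, drop = FALSE])
  })
  names(groups) <- as.character(lev)
  list(groups = groups, grand = rowMeans(sample$coefs),
       basis = sample$basis)
}

#' One-way functional ANOVA with a bootstrap null
#'
#' The observed statistic is a functional F ratio: integrated
#' between-group sum of squares of the group mean curves over integrated
#' within-group variability, each with its usual degrees of freedom.  The
#' null distribution is built by resampling group-centered curves
#' (residuals from the group means, pooled) with replacement while keeping
#' the labels fixed, which preserves the within-group covariance structure
#' under the null of equal means.  The p-value uses the add-one rule
#' `(1 + #{F* >= F_obs}) / (1 + n_boot)`.
#'
#' @param sample an `fd_sample`.
#' @param labels binary (two-level) label vector, one per curve; each group
#'   needs >= 2 curves.
#' @param n_boot bootstrap replications (default 500).
#' @param seed integer seed (mandatory).
#' @param grid_s evaluation grid; default integer seconds.
#' @return A `fanova_result`: `statistic_obs`, `p_value`, `n_boot`,
#'   `group_means` (from [group_mean_curves()]), `grid_s`.
#' @export
fanova <- function(sample, labels, n_boot = 500, seed, grid_s = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: bootstrap results must be reproducible")
  }
  if (length(unique(labels)) < 2L) stop("need at least two groups")
  if (min(table(labels)) < 2L) stop("each group needs >= 2 curves")
  if (is.null(grid_s)) {
    grid_s <- seq(sample$basis$domain[1], sample$basis$domain[2])
  }
  X <- eval_sample(sample, grid_s)
  res <- fanova_matrix(X, labels, n_boot, seed)
  res$group_means <- group_mean_curves(sample, labels)
  res$grid_s <- grid_s
  class(res) <- "fanova_result"
  res
}

# Matrix core: columns are curves evaluated on a common grid.
fanova_matrix <- function(X, labels, n_boot, seed) {
  lev <- sort(unique(labels))
  idx <- lapply(lev, function(g) which(labels == g))
  n <- ncol(X); G <- length(lev)
  fstat <- function(M) {
    grand <- rowMeans(M)
    between <- 0; within <- 0
    for (j in seq_len(G)) {
      Mg <- M[, idx[[j]], drop = FALSE]
      mg <- rowMeans(Mg)
      between <- between + length(idx[[j]]) * sum((mg - grand)^2)
      within <- within + sum((Mg - mg)^2)
    }
    (between / (G - 1)) / (within / (n - G))
  }
  obs <- fstat(X)
  # pooled group-centered residual curves
  Rm <- X
  for (j in seq_len(G)) {
    Rm[, idx[[j]]] <- X[, idx[[j]], drop = FALSE] -
      rowMeans(X[, idx[[j]], drop = FALSE])
  }
  set.seed(seed)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    boot[b] <- fstat(Rm[, sample.int(n, replace = TRUE), drop = FALSE])
  }
  list(statistic_obs = obs,
       p_value = (1 + sum(boot >= obs)) / (1 + n_boot),
       n_boot = n_boot)
}

#' @export
print.fanova_result <- function(x, ...) {
  cat(sprintf("Functional ANOVA: F = %.3f, bootstrap p = %.4g (n_boot = %d)\n",
              x$statistic_obs, x$p_value, x$n_boot))
  invisible(x)
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "Permutation t-test: max |t| = %.3f, max-stat critical value %.3f (alpha %.2f, %d perms)\n",
    max(abs(x$t_obs)), x$max_crit, x$alpha, x$n_perm))
  if (x$reject) {
    cat(sprintf("  %d rejection region(s) totalling %g s\n",
                nrow(x$reject_regions),
                sum(x$reject_regions[, 2] - x$reject_regions[, 1])))
  } else cat("  no rejection regions\n")
  invisible(x)
}
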