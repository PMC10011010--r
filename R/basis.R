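#' Construct a B-spline basis with equally spaced breakpoints
#'
#' Order-`order` B-splines (degree `order - 1`) on `[0, t_end]` with
#' breakpoints every `breakpoint_spacing_s` seconds.  The basis size is
#' `n_interior + order`; with `t_end = 720`, `order = 6` and 1-s spacing
#' this yields 719 interior breakpoints and 725 basis functions.
#'
#' @param t_end domain right endpoint (seconds).
#' @param order spline order (>= 1); 6 gives quintic pieces.
#' @param breakpoint_spacing_s breakpoint spacing; must divide `t_end`.
#' @return A `bspline_basis` with `domain`, `breakpoints`, `order`,
#'   `n_basis` and the full `knots` vector (boundary knots repeated
#'   `order` times).
#' @export
make_bspline_basis <- function(t_end, order = 6, breakpoint_spacing_s = 1) {
  if (order < 1) stop("`order` must be >= 1")
  k <- t_end / breakpoint_spacing_s
  if (abs(k - round(k)) > 1e-8) {
    stop("`breakpoint_spacing_s` must divide `t_end`")
  }
  breakpoints <- seq(0, t_end, by = breakpoint_spacing_s)
  n_interior <- length(breakpoints) - 2L
  knots <- c(rep(0, order), breakpoints[-c(1L, length(breakpoints))],
             rep(t_end, order))
  structure(list(domain = c(0, t_end), breakpoints = breakpoints,
                 order = as.integer(order),
                 n_basis = n_interior + as.integer(order),
                 knots = knots),
            class = "bspline_basis")
}

#' Evaluate the basis (or a derivative) at given times
#'
#' @param basis a `bspline_basis`.
#' @param t evaluation times within the domain.
#' @param deriv derivative order (0 = function values).
#' @return Matrix `length(t) x n_basis`.
#' @export
eval_basis <- function(basis, t, deriv = 0) {
  if (any(t < basis$domain[1] - 1e-10 | t > basis$domain[2] + 1e-10)) {
    stop("evaluation times outside basis domain")
  }
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
  # splineDesign treats the right endpoint as outside the last half-open
  # interval; nudging it in keeps the evaluation defined there.
  eps <- 1e-9 * diff(basis$domain)
  t[t >= basis$domain[2]] <- basis$domain[2] - eps
  splines::splineDesign(basis$knots, t, ord = basis$order,
                        derivs = rep(deriv, length(t)))
}

#' Evaluate a coefficient vector/matrix as curves
#'
#' @param basis a `bspline_basis`.
#' @param coefs coefficient vector (one curve) or matrix
#'   (`n_basis x n_curves`).
#' @param t times.
#' @param deriv derivative order.
#' @return Vector or matrix of curve values (`length(t) x n_curves`).
#' @export
eval_coefs <- function(basis, coefs, t, deriv = 0) {
  B <- eval_basis(basis, t, deriv)
  out <- B %*% coefs
  if (is.null(dim(coefs))) drop(out) else out
}

# Composite-Simpson nodes and weights on [a, b] with approximately the
# requested step (interval count rounded up to an even number).
simpson_rule <- function(a, b, step) {
  n <- max(2L, ceiling((b - a) / step))
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  h <- (b - a) / n
  w <- rep(c(2, 4), length.out = n + 1L)
  w[1] <- w[n + 1L] <- 1
  list(x = x, w = w * h / 3)
}

#' Harmonic-acceleration roughness penalty matrix
#'
#' Penalty for the differential operator `L = omega^2 D + D^3`, whose null
#' space `{1, sin(omega t), cos(omega t)}` is left unpenalized:
#' `R[j, k] = integral (L phi_j)(t) (L phi_k)(t) dt`, computed by composite
#' Simpson quadrature.  With `omega = 0` this reduces to the plain
#' third-derivative roughness penalty.
#'
#' @param basis a `bspline_basis` of order >= 4.
#' @param omega harmonic frequency in rad/s.  The default used downstream
#'   is `2*pi/180`: one cycle per 180-s bout+rest period, so oscillation at
#'   the protocol's driving frequency is not penalized.
#' @param quadrature_step_s quadrature step; default a quarter of the
#'   breakpoint spacing.
#' @return A `penalty_matrix`: `matrix` (symmetric `n_basis x n_basis`)
#'   and `omega`.
#' @export
harmonic_penalty <- function(basis, omega = 2 * pi / 180,
                             quadrature_step_s = NULL) {
  if (basis$order < 4) stop("basis order must be >= 4 for a D^3 penalty")
  if (is.null(quadrature_step_s)) {
    quadrature_step_s <- diff(basis$breakpoints[1:2]) / 4
  }
  q <- simpson_rule(basis$domain[1], basis$domain[2], quadrature_step_s)
  L <- omega^2 * eval_basis(basis, q$x, deriv = 1) +
    eval_basis(basis, q$x, deriv = 3)
  R <- crossprod(L * sqrt(q$w))
  R <- (R + t(R)) / 2
  structure(list(matrix = R, omega = omega), class = "penalty_matrix")
}

# Gram matrix of the basis (integral of phi_j phi_k), used by FPCA and
# curve inner products.  Simpson on a fine grid is plenty accurate for the
# smooth integrands involved.
basis_gram <- function(basis, quadrature_step_s = NULL) {
  if (is.null(quadrature_step_s)) {
    quadrature_step_s <- diff(basis$breakpoints[1:2]) / 4
  }
  q <- simpson_rule(basis$domain[1], basis$domain[2], quadrature_step_s)
  B <- eval_basis(basis, q$x)
  G <- crossprod(B * sqrt(q$w))
  (G + t(G)) / 2
}
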