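#' Factorization objective, gradients and optimality residual
#'
#' The factorization minimizes `F(W, H) = 0.5 * ||A - WH||_F^2` over
#' nonnegative `W` (n x r) and `H` (r x m). These helpers expose the
#' objective, its matrix gradients, the matrix inner product used by the
#' conjugate-gradient solver, and the projected-gradient KKT residual used
#' as the outer stopping measure.
#'
#' @param A nonnegative data matrix, n x m.
#' @param W basis matrix, n x r.
#' @param H coordinate matrix, r x m.
#' @return `nmf_objective()`: a nonnegative scalar.
#' @name objective
NULL

check_shapes <- function(A, W, H) {
  if (nrow(W) != nrow(A) || ncol(H) != ncol(A) || ncol(W) != nrow(H)) {
    stop(sprintf(
      "incompatible shapes: A %dx%d, W %dx%d, H %dx%d",
      nrow(A), ncol(A), nrow(W), ncol(W), nrow(H), ncol(H)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname objective
#' @export
nmf_objective <- function(A, W, H) {
  check_shapes(A, W, H)
  0.5 * sum((A - W %*% H)^2)
}

#' Gradient of the objective with respect to W
#'
#' `-A t(H) + W H t(H)`. When the Gram matrix `H t(H)` and the product
#' `A t(H)` are already available (the inner solver caches them per sweep)
#' they can be passed to avoid recomputation; the result is identical.
#'
#' @inheritParams objective
#' @param HHt optional cached `H %*% t(H)` (r x r).
#' @param AHt optional cached `A %*% t(H)` (n x r).
#' @return n x r gradient matrix.
#' @export
nmf_grad_w <- function(A, W, H, HHt = NULL, AHt = NULL) {
  check_shapes(A, W, H)
  if (is.null(HHt)) HHt <- tcrossprod(H)
  if (is.null(AHt)) AHt <- tcrossprod(A, H)
  W %*% HHt - AHt
}

#' Gradient of the objective with respect to H
#'
#' `-t(W) A + t(W) W H`.
#'
#' @inheritParams objective
#' @param WtW optional cached `t(W) %*% W` (r x r).
#' @param WtA optional cached `t(W) %*% A` (r x m).
#' @return r x m gradient matrix.
#' @export
nmf_grad_h <- function(A, W, H, WtW = NULL, WtA = NULL) {
  check_shapes(A, W, H)
  if (is.null(WtW)) WtW <- crossprod(W)
  if (is.null(WtA)) WtA <- crossprod(W, A)
  WtW %*% H - WtA
}

#' Matrix inner product
#'
#' `<S, T> = sum_ij S[i, j] * T[i, j]`, the Frobenius inner product; the
#' conjugate-gradient recursions are written entirely in terms of it.
#'
#' @param s,t numeric matrices of identical shape.
#' @return A scalar.
#' @export
mat_inner <- function(s, t) {
  if (!identical(dim(s), dim(t))) {
    stop("inner product needs matrices of identical shape", call. = FALSE)
  }
  sum(s * t)
}

#' Projected-gradient KKT residual
#'
#' First-order optimality measure for the nonnegativity-constrained
#' problem: for each factor entry, the residual is the gradient where the
#' entry is strictly positive and `min(0, gradient)` where the entry is
#' zero (a positive gradient at an active bound is no violation). The
#' returned scalar is the Frobenius norm of the stacked residuals over both
#' factors; it is zero exactly at a KKT point. The outer loop stops when
#' this residual has fallen below a fixed fraction of its value at the
#' random start.
#'
#' @inheritParams objective
#' @return Nonnegative scalar.
#' @export
kkt_residual <- function(A, W, H) {
  check_shapes(A, W, H)
  if (any(W < 0) || any(H < 0)) {
    stop("kkt_residual requires elementwise nonnegative W and H", call. = FALSE)
  }
  gw <- nmf_grad_w(A, W, H)
  gh <- nmf_grad_h(A, W, H)
  pw <- ifelse(W > 0, gw, pmin(gw, 0))
  ph <- ifelse(H > 0, gh, pmin(gh, 0))
  sqrt(sum(pw^2) + sum(ph^2))
}
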