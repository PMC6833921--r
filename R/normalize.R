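#' Per-gene min-max normalization
#'
#' Rescales every gene row of the expression matrix to \[0, 1\]: with
#' `b_i = max_k A[i, k]` and `a_i = min_k A[i, k]`, row `i` becomes
#' `(A[i, ] - a_i) / (b_i - a_i)`. A constant row (`b_i == a_i`) has no
#' class signal and would divide by zero; it is mapped to all zeros and
#' counted in `n_constant_rows`.
#'
#' The row minima and maxima are retained on the result (`row_min`,
#' `row_max`) so that reports can refer back to the raw scale.
#'
#' @param x an [expr_matrix()] with `normalized = FALSE`, or a nonnegative
#'   numeric matrix.
#' @return An `expr_matrix` with `normalized = TRUE`.
#' @export
normalize_rows <- function(x) {
  x <- as_expr_matrix(x)
  if (isTRUE(x$normalized)) {
    stop("expression matrix is already normalized", call. = FALSE)
  }
  v <- x$values
  b <- apply(v, 1L, max)
  a <- apply(v, 1L, min)
  rng <- b - a
  const <- rng == 0
  rng[const] <- 1 # avoid 0/0; constant rows are zeroed below
  out <- (v - a) / rng
  if (any(const)) out[const, ] <- 0
  res <- expr_matrix(out, gene_ids = x$gene_ids, sample_ids = x$sample_ids,
                     groups = x$groups, normalized = TRUE)
  res$row_min <- stats::setNames(a, x$gene_ids)
  res$row_max <- stats::setNames(b, x$gene_ids)
  res$n_constant_rows <- sum(const)
  res
}
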