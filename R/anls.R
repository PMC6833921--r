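# run code with a temporary RNG state derived from `seed`, restoring the
# caller's state afterwards so library calls never disturb user RNG flow
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random nonnegative initialization
#'
#' Draws `W0` (n x r) and `H0` (r x m) with i.i.d. uniform \[0, 1) entries.
#' The same seed always reproduces the same pair; the caller's RNG state is
#' left untouched.
#'
#' @param n,m,r matrix dimensions (genes, samples, classes).
#' @param seed integer seed.
#' @return List with matrices `W0` and `H0`.
#' @export
random_init <- function(n, m, r, seed = 1L) {
  stopifnot(n >= 1, m >= 1, r >= 1)
  if (r > n * m) {
    warning("rank r exceeds the number of data entries; the factorization is over-parameterized")
  }
  with_seed(seed, {
    W0 <- matrix(stats::runif(n * r), n, r)
    H0 <- matrix(stats::runif(r * m), r, m)
    list(W0 = W0, H0 = H0)
  })
}

#' Projection onto the nonnegative orthant
#'
#' Elementwise `max(x, 0)`: negative entries produced by the unconstrained
#' subproblem solve are clipped to zero. Idempotent.
#'
#' @param x numeric matrix.
#' @return Matrix of the same shape with no negative entries.
#' @export
project_nonnegative <- function(x) {
  stopifnot(all(is.finite(x)))
  pmax(x, 0)
}

# replace all-zero columns (W) or rows (H) by small uniform noise; a dead
# class would make every membership denominator it touches degenerate
reseed_dead <- function(mat, margin, seed, scale = 1e-4) {
  sums <- if (margin == 2L) colSums(mat) else rowSums(mat)
  dead <- which(sums == 0)
  if (!length(dead)) return(list(mat = mat, n_reseeded = 0L))
  k <- if (margin == 2L) nrow(mat) else ncol(mat)
  noise <- with_seed(seed, matrix(stats::runif(length(dead) * k) * scale,
                                  nrow = if (margin == 2L) k else length(dead)))
  if (margin == 2L) mat[, dead] <- noise else mat[dead, ] <- noise
  list(mat = mat, n_reseeded = length(dead))
}

#' Nonnegative matrix factorization by alternating subproblem solves
#'
#' Factorizes a nonnegative gene x sample matrix `A` as `A ~ W H` with
#' `W >= 0` (n x r basis, one column per class) and `H >= 0` (r x m
#' coordinates, one column per sample). Starting from a random nonnegative
#' pair, each outer sweep solves the W-subproblem by the spectral conjugate
#' gradient method (warm-started from the previous factor), projects onto
#' the nonnegative orthant, then does the same for H. The loop stops when
#' the projected-gradient KKT residual has fallen to
#' `outer_epsilon * kkt_residual(W0, H0)` — a relative test, chosen because
#' iterates can stagnate in a curved valley where an absolute test never
#' fires — or when `max_outer_iter` sweeps have run.
#'
#' Classes that die during the alternation (an all-zero basis column or
#' coordinate row) are re-seeded with small uniform noise and counted in
#' `n_reseeded`.
#'
#' @param A an [expr_matrix()] or nonnegative numeric matrix.
#' @param r number of classes (factorization rank), `1 <= r`. Values above
#'   the sample count are allowed with a warning.
#' @param control an [scg_control()]; `control$seed` fixes the random
#'   initialization.
#' @return An object of class `nmf_fit`: list with `W`, `H`, `r`,
#'   `objective_trace` (objective after each full sweep, position 1 = at
#'   initialization), `kkt_ratio_trace`, `converged`, `outer_iters`,
#'   `inner_iters` (per-sweep inner iteration counts), `restarts`,
#'   `n_reseeded`, `seed`, `control`, and the gene/sample ids when `A` was
#'   an `expr_matrix`.
#' @export
nmf_factorize <- function(A, r, control = scg_control()) {
  x <- as_expr_matrix(A)
  V <- x$values
  n <- nrow(V); m <- ncol(V)
  r <- as.integer(r)
  stopifnot(r >= 1)
  if (r > m) {
    warning(sprintf("rank r = %d exceeds the sample count m = %d; classes cannot all be occupied", r, m))
  }
  init <- random_init(n, m, r, control$seed)
  W <- init$W0; H <- init$H0
  kkt0 <- kkt_residual(V, W, H)
  if (kkt0 == 0) {
    stop("degenerate start: KKT residual is zero at the random initialization; choose another seed",
         call. = FALSE)
  }
  obj_trace <- nmf_objective(V, W, H)
  kkt_trace <- 1
  inner_iters <- integer(0)
  restarts <- 0L
  n_reseeded <- 0L
  converged <- FALSE
  outer <- 0L
  for (k in seq_len(control$max_outer_iter)) {
    resW <- solve_subproblem(V, H, W, which = "W", control = control)
    W <- project_nonnegative(resW$X)
    rs <- reseed_dead(W, 2L, control$seed + k)
    W <- rs$mat; n_reseeded <- n_reseeded + rs$n_reseeded
    resH <- solve_subproblem(V, W, H, which = "H", control = control)
    H <- project_nonnegative(resH$X)
    rs <- reseed_dead(H, 1L, control$seed + k + control$max_outer_iter)
    H <- rs$mat; n_reseeded <- n_reseeded + rs$n_reseeded
    restarts <- restarts + resW$restarts + resH$restarts
    inner_iters <- c(inner_iters, resW$iterations + resH$iterations)
    obj_trace <- c(obj_trace, nmf_objective(V, W, H))
    ratio <- kkt_residual(V, W, H) / kkt0
    kkt_trace <- c(kkt_trace, ratio)
    outer <- k
    if (ratio <= control$outer_epsilon) { converged <- TRUE; break }
  }
  dimnames(W) <- list(x$gene_ids, paste0("class_", seq_len(r)))
  dimnames(H) <- list(paste0("class_", seq_len(r)), x$sample_ids)
  structure(
    list(W = W, H = H, r = r, objective_trace = obj_trace,
         kkt_ratio_trace = kkt_trace, converged = converged,
         outer_iters = outer, inner_iters = inner_iters,
         restarts = restarts, n_reseeded = n_reseeded,
         seed = control$seed, control = control,
         gene_ids = x$gene_ids, sample_ids = x$sample_ids),
    class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> %d genes x %d samples, r = %d classes\n",
              nrow(x$W), ncol(x$H), x$r))
  cat(sprintf("  seed %d, %d outer sweeps, %s\n", x$seed, x$outer_iters,
              if (x$converged) "converged (relative KKT)" else "outer cap reached"))
  cat(sprintf("  objective %.6g -> %.6g, final KKT ratio %.3g\n",
              x$objective_trace[1L], utils::tail(x$objective_trace, 1L),
              utils::tail(x$kkt_ratio_trace, 1L)))
  invisible(x)
}

#' Relative reconstruction residual of a fit
#'
#' `||A - WH||_F / ||A||_F`.
#'
#' @param model an `nmf_fit`.
#' @param A the matrix that was factorized.
#' @return Scalar in \[0, Inf).
#' @export
relative_residual <- function(model, A) {
  V <- expr_values(A)
  sqrt(sum((V - model$W %*% model$H)^2)) / sqrt(sum(V^2))
}
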