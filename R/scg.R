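#' Solver configuration
#'
#' Collects every algorithmic constant of the spectral conjugate gradient
#' subproblem solver and the outer alternating loop. Defaults are the
#' published working values: `delta1 = 0.4`, `delta2 = 0.001`,
#' `eta = 0.001`, `rho = 0.65`, `epsilon = 1e-7`. The backtracking
#' contraction `rho` can be varied in \[0.05, 0.75\] without changing
#' classification results on well-separated data.
#'
#' @param delta1 sufficient-decrease coefficient in (0, 1) for the
#'   Armijo-type line search.
#' @param delta2 positive curvature-penalty coefficient of the line search
#'   (the extra `-delta2 * alpha^2 * ||D||^2` term).
#' @param eta branch threshold in (0, 1) for the spectral/conjugate
#'   parameter formulas.
#' @param rho backtracking contraction factor in (0, 1); trial steps are
#'   the powers `rho^l`.
#' @param epsilon gradient tolerance for the inner solver; also the default
#'   for both `inner_epsilon` and `outer_epsilon`.
#' @param inner_epsilon stopping tolerance on the gradient Frobenius norm
#'   inside one subproblem.
#' @param outer_epsilon relative KKT tolerance of the alternating loop:
#'   stop once `kkt_residual(W, H) <= outer_epsilon * kkt_residual(W0, H0)`.
#' @param max_inner_iter iteration cap per subproblem.
#' @param max_backtracks cap on line-search halvings (`rho^60 ~ 6e-12`).
#' @param max_outer_iter cap on outer alternation sweeps.
#' @param seed integer seed for the random initialization.
#' @return An object of class `scg_control`.
#' @export
scg_control <- function(delta1 = 0.4, delta2 = 0.001, eta = 0.001,
                        rho = 0.65, epsilon = 1e-7,
                        inner_epsilon = epsilon, outer_epsilon = epsilon,
                        max_inner_iter = 1000L, max_backtracks = 60L,
                        max_outer_iter = 200L, seed = 1L) {
  stopifnot(delta1 > 0, delta1 < 1, delta2 > 0, eta > 0, eta < 1,
            rho > 0, rho < 1, epsilon > 0, inner_epsilon > 0,
            outer_epsilon > 0, max_inner_iter >= 1, max_backtracks >= 1,
            max_outer_iter >= 1)
  structure(list(delta1 = delta1, delta2 = delta2, eta = eta, rho = rho,
                 epsilon = epsilon, inner_epsilon = inner_epsilon,
                 outer_epsilon = outer_epsilon,
                 max_inner_iter = as.integer(max_inner_iter),
                 max_backtracks = as.integer(max_backtracks),
                 max_outer_iter = as.integer(max_outer_iter),
                 seed = as.integer(seed)),
            class = "scg_control")
}

#' @export
print.scg_control <- function(x, ...) {
  cat("<scg_control>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}

# denominators smaller than this trigger a steepest-descent restart
.denom_guard <- 1e-300

#' Initial search direction
#'
#' The first direction is steepest descent, `-g`.
#'
#' @param g gradient matrix.
#' @return Matrix of the same shape.
#' @export
initial_direction <- function(g) -g

#' Iterate and gradient differences with projected gradient difference
#'
#' Forms `s = x_cur - x_prev`, `y = g_cur - g_prev`, and the component of
#' `y` orthogonal to the current gradient,
#' `y_bar = y - g_cur * <g_cur, y> / ||g_cur||^2`, so that
#' `<g_cur, y_bar> = 0` by construction.
#'
#' @param x_cur,x_prev current and previous iterates.
#' @param g_cur,g_prev current and previous gradients; `g_cur` must be
#'   nonzero (a zero gradient means the solver already converged).
#' @return List with elements `s`, `y`, `y_bar`.
#' @export
curvature_quantities <- function(x_cur, x_prev, g_cur, g_prev) {
  gn2 <- sum(g_cur^2)
  if (gn2 == 0) {
    stop("zero current gradient: iterate is already stationary", call. = FALSE)
  }
  s <- x_cur - x_prev
  y <- g_cur - g_prev
  y_bar <- y - g_cur * (mat_inner(g_cur, y) / gn2)
  list(s = s, y = y, y_bar = y_bar)
}

#' Spectral and conjugate parameters
#'
#' Two-branch formulas for the spectral scaling `theta` and the conjugacy
#' coefficient `beta` of the search direction
#' `D = -theta * g + beta * d_prev`. The well-conditioned branch applies
#' when `<d_prev, y_bar> > eta * ||g_prev||^2`; otherwise a fallback based
#' on `<-d_prev, g_prev>` and `||g_prev||^2` is used. If the active
#' branch's denominator is numerically zero the caller must restart with
#' steepest descent; that condition is signalled by returning
#' `degenerate = TRUE`.
#'
#' @param d_prev previous search direction.
#' @param g_cur,g_prev current and previous gradients.
#' @param s,y,y_bar differences from [curvature_quantities()].
#' @param eta branch threshold (see [scg_control()]).
#' @return List `theta`, `beta`, `branch` (1 or 2), `degenerate`.
#' @export
spectral_params <- function(d_prev, g_cur, g_prev, s, y, y_bar, eta) {
  gn2 <- sum(g_cur^2)
  gp2 <- sum(g_prev^2)
  if (gn2 == 0 || gp2 == 0) {
    return(list(theta = NA_real_, beta = NA_real_, branch = NA_integer_,
                degenerate = TRUE))
  }
  dy <- mat_inner(d_prev, y)
  dg <- mat_inner(d_prev, g_cur)
  dybar <- mat_inner(d_prev, y_bar)
  if (dybar > eta * gp2) {
    if (abs(dybar) < .denom_guard) {
      return(list(theta = NA_real_, beta = NA_real_, branch = 1L,
                  degenerate = TRUE))
    }
    gs <- mat_inner(g_cur, s)
    theta <- (dy - dg * gs / gn2) / dybar
    beta <- (mat_inner(g_cur, y) - gs) / dybar
    list(theta = theta, beta = beta, branch = 1L, degenerate = FALSE)
  } else {
    denom <- mat_inner(-d_prev, g_prev)
    if (abs(denom) < .denom_guard || abs(gp2) < .denom_guard) {
      return(list(theta = NA_real_, beta = NA_real_, branch = 2L,
                  degenerate = TRUE))
    }
    ggp <- mat_inner(g_cur, g_prev)
    theta <- (dy - dg * ggp / gn2) / denom
    beta <- mat_inner(g_cur, y) / gp2
    list(theta = theta, beta = beta, branch = 2L, degenerate = FALSE)
  }
}

#' Assemble the search direction
#'
#' `D = -g` at the first iteration, otherwise
#' `D = -theta * g + beta * d_prev`. The published recursion assumes the
#' result is a descent direction; in floating point (or with degenerate
#' curvature) it can fail the test `<g, D> < 0`, in which case the
#' direction is replaced by steepest descent so the line-search
#' precondition always holds.
#'
#' @param theta,beta scalars from [spectral_params()].
#' @param g_cur current gradient.
#' @param d_prev previous direction.
#' @param k iteration counter (0-based).
#' @return List `d` (the direction) and `restarted` (logical; `TRUE` when
#'   the safeguard replaced the recursion by `-g_cur`).
#' @export
search_direction <- function(theta, beta, g_cur, d_prev, k) {
  if (k == 0L) {
    return(list(d = -g_cur, restarted = FALSE))
  }
  d <- -theta * g_cur + beta * d_prev
  if (!all(is.finite(d)) || mat_inner(g_cur, d) >= 0) {
    return(list(d = -g_cur, restarted = TRUE))
  }
  list(d = d, restarted = FALSE)
}

#' Armijo-type backtracking line search
#'
#' Finds the largest step `alpha = rho^l`, `l = 0, 1, 2, ...`, satisfying
#' the sufficient-decrease inequality
#' `F(x + alpha d) <= F(x) + delta1 * alpha * <g, d>
#'  - delta2 * alpha^2 * ||d||^2`.
#' Because `<g, d> < 0` and `delta2 > 0`, any accepted step strictly
#' decreases `F` by at least `delta2 * alpha^2 * ||d||^2`.
#'
#' @param f_eval function of `alpha` returning `F(x + alpha * d)`.
#' @param f0 objective value at `alpha = 0`.
#' @param gd directional derivative `<g, d>`; must be negative.
#' @param dnorm2 squared Frobenius norm `||d||^2`; must be positive.
#' @param control an [scg_control()].
#' @return List `alpha`, `f_new`, `l` (number of contractions).
#' @export
backtracking_step <- function(f_eval, f0, gd, dnorm2, control = scg_control()) {
  if (!(gd < 0)) stop("line search needs a descent direction (<g, d> < 0)",
                      call. = FALSE)
  if (!(dnorm2 > 0)) stop("line search needs a nonzero direction", call. = FALSE)
  alpha <- 1
  for (l in 0:control$max_backtracks) {
    f_new <- f_eval(alpha)
    if (f_new <= f0 + control$delta1 * alpha * gd -
        control$delta2 * alpha^2 * dnorm2) {
      return(list(alpha = alpha, f_new = f_new, l = l))
    }
    alpha <- alpha * control$rho
  }
  stop(sprintf(
    "line search failed: no step within %d backtracks (|<g,d>| = %.3g, ||d||^2 = %.3g)",
    control$max_backtracks, abs(gd), dnorm2), call. = FALSE)
}

# Core solver in canonical form: minimize 0.5 * ||A - X B||_F^2 over X
# (n x r), B (r x m) fixed. The subproblem is an exact quadratic in X, so
# the objective along a direction is a quadratic in alpha evaluated from
# cached Gram products; the gradient updates as G <- G + alpha * (D %*% BBt).
# Two interchangeable engines: the compiled loop (default) and this pure-R
# reference, which composes the exported building blocks and is what the
# compiled loop is tested against.
scg_core <- function(A, B, X0, control, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- .scg_core_cpp(A, B, X0, control$delta1, control$delta2,
                         control$eta, control$rho, control$inner_epsilon,
                         control$max_inner_iter, control$max_backtracks)
    res$final_gnorm <- utils::tail(res$gnorm_trace, 1L)
    return(res)
  }
  scg_core_r(A, B, X0, control)
}

scg_core_r <- function(A, B, X0, control) {
  BBt <- tcrossprod(B)
  ABt <- tcrossprod(A, B)
  cA <- 0.5 * sum(A^2)
  X <- X0
  fval <- cA - mat_inner(X, ABt) + 0.5 * mat_inner(X, X %*% BBt)
  G <- X %*% BBt - ABt
  D <- NULL; Xp <- NULL; Gp <- NULL
  f_trace <- fval
  gnorm_trace <- numeric(0)
  restarts <- 0L
  n_iter <- 0L
  converged <- FALSE
  for (k in seq_len(control$max_inner_iter) - 1L) {
    gnorm <- sqrt(sum(G^2))
    gnorm_trace <- c(gnorm_trace, gnorm)
    if (!is.finite(gnorm)) stop("numerical failure: non-finite gradient",
                                call. = FALSE)
    if (gnorm <= control$inner_epsilon) { converged <- TRUE; break }
    if (k == 0L) {
      D <- initial_direction(G)
    } else {
      cq <- curvature_quantities(X, Xp, G, Gp)
      sp <- spectral_params(D, G, Gp, cq$s, cq$y, cq$y_bar, control$eta)
      if (sp$degenerate) {
        D <- -G
        restarts <- restarts + 1L
      } else {
        sd <- search_direction(sp$theta, sp$beta, G, D, k)
        D <- sd$d
        if (sd$restarted) restarts <- restarts + 1L
      }
    }
    ls <- NULL
    for (attempt in 1:2) {
      gd <- mat_inner(G, D)
      dn2 <- sum(D^2)
      DBBt <- D %*% BBt
      dBd <- mat_inner(D, DBBt)
      ls <- tryCatch(
        backtracking_step(
          function(alpha) fval + alpha * gd + 0.5 * alpha^2 * dBd,
          fval, gd, dn2, control),
        error = function(e) e)
      if (!inherits(ls, "error")) break
      # extreme-norm conjugate direction: retry once from steepest descent
      if (attempt == 1L && any(D != -G)) {
        D <- -G
        restarts <- restarts + 1L
      } else {
        stop(ls)
      }
    }
    Xp <- X; Gp <- G
    X <- X + ls$alpha * D
    G <- G + ls$alpha * DBBt
    fval <- ls$f_new
    f_trace <- c(f_trace, fval)
    n_iter <- k + 1L
    if (!all(is.finite(X))) stop("numerical failure: non-finite iterate",
                                 call. = FALSE)
  }
  list(X = X, converged = converged, iterations = n_iter,
       f_trace = f_trace, gnorm_trace = gnorm_trace,
       final_gnorm = utils::tail(gnorm_trace, 1L), restarts = restarts)
}

#' Solve one alternating least-squares subproblem
#'
#' Minimizes `F(W, H) = 0.5 * ||A - WH||_F^2` over the free factor with
#' the other held fixed, using the modified spectral conjugate gradient
#' method: spectral/conjugate direction recursion with a descent safeguard,
#' Armijo-type backtracking, stopping when the gradient Frobenius norm
#' falls below `control$inner_epsilon`. The subproblem is solved as an
#' unconstrained (sign-free) quadratic; projection onto the nonnegative
#' orthant is the outer driver's job, not this function's.
#'
#' @param A data matrix n x m.
#' @param fixed the held factor: `H` (r x m) when `which = "W"`, `W`
#'   (n x r) when `which = "H"`.
#' @param x0 starting iterate for the free factor.
#' @param which which factor is free.
#' @param control an [scg_control()].
#' @param engine `"cpp"` (compiled inner loop, default) or `"r"` (pure-R
#'   reference built from the exported direction/line-search functions;
#'   the two produce the same iterates up to floating-point accumulation
#'   order).
#' @return List with `X` (final iterate), `converged`, `iterations`,
#'   `f_trace` (strictly decreasing after every accepted step),
#'   `gnorm_trace`, `final_gnorm`, `restarts`.
#' @export
solve_subproblem <- function(A, fixed, x0, which = c("W", "H"),
                             control = scg_control(),
                             engine = c("cpp", "r")) {
  which <- match.arg(which)
  engine <- match.arg(engine)
  if (which == "W") {
    stopifnot(ncol(A) == ncol(fixed), nrow(x0) == nrow(A),
              ncol(x0) == nrow(fixed))
    scg_core(A, fixed, x0, control, engine)
  } else {
    # 0.5||A - W H||^2 = 0.5||t(A) - t(H) t(W)||^2: canonical form in t(H)
    stopifnot(nrow(A) == nrow(fixed), ncol(x0) == ncol(A),
              nrow(x0) == ncol(fixed))
    res <- scg_core(t(A), t(fixed), t(x0), control, engine)
    res$X <- t(res$X)
    res
  }
}
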