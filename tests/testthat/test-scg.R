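test_that("initial direction is steepest descent, including the worked 1x1 case", {
  expect_equal(initial_direction(rbind(c(1, -2))), rbind(c(-1, 2)))
  expect_equal(initial_direction(matrix(0, 2, 2)), matrix(0, 2, 2))
  # A = [[2]], W0 = H0 = [[1]]: D0 = A H' - W H H' = 2 - 1 = 1
  g <- nmf_grad_w(matrix(2), matrix(1), matrix(1))
  expect_equal(initial_direction(g), matrix(1))
})

test_that("curvature quantities orthogonalize y against the current gradient", {
  g <- rbind(c(1, 2), c(0, 1))
  # y parallel to g -> fully projected out
  cq <- curvature_quantities(g, g * 0, g, g - 3 * g)
  expect_equal(cq$y_bar, matrix(0, 2, 2), tolerance = 1e-14)
  # y orthogonal to g -> unchanged
  y <- rbind(c(2, -1), c(0, 0))    # <g, y> = 0
  cq <- curvature_quantities(g, g, g, g - y)
  expect_equal(cq$y_bar, y)
  set.seed(21)
  for (i in 1:20) {
    xc <- matrix(runif(4), 2); xp <- matrix(runif(4), 2)
    gc_ <- matrix(rnorm(4), 2); gp <- matrix(rnorm(4), 2)
    cq <- curvature_quantities(xc, xp, gc_, gp)
    expect_lt(abs(mat_inner(gc_, cq$y_bar)), 1e-12 * max(1, sum(gc_^2)))
    expect_equal(cq$s, xc - xp)
    expect_equal(cq$y, gc_ - gp)
  }
  expect_error(curvature_quantities(xc, xp, matrix(0, 2, 2), gp), "stationary")
})

test_that("spectral parameters follow the two-branch formulas (scalar oracle)", {
  # scalar instance evaluated by hand arithmetic in-line
  d <- matrix(-1); gp <- matrix(1); g <- matrix(0.5)
  s <- matrix(0.5); y <- matrix(-0.5)
  eta <- 0.001
  gn2 <- 0.25
  ybar <- y - g * (sum(g * y) / gn2)      # = -0.5 - 0.5*(-0.25/0.25) = 0
  expect_equal(ybar, matrix(0))
  sp <- spectral_params(d, g, gp, s, y, ybar, eta)
  # <d, ybar> = 0 is not > eta * ||gp||^2 -> fallback branch
  expect_identical(sp$branch, 2L)
  theta_hand <- (sum(d * y) - sum(d * g) * sum(g * gp) / gn2) / sum(-d * gp)
  beta_hand <- sum(g * y) / sum(gp^2)
  expect_equal(sp$theta, theta_hand)   # (0.5 + 0.5*0.5/0.25)/1 = 1.5
  expect_equal(sp$theta, 1.5)
  expect_equal(sp$beta, beta_hand)     # -0.25
  expect_equal(sp$beta, -0.25)

  # y_bar = 0 with d = -gp: fallback beta = <g, y>/||gp||^2
  sp2 <- spectral_params(-gp, g, gp, s, y, matrix(0), eta)
  expect_equal(sp2$beta, sum(g * y) / sum(gp^2))

  # main branch, checked against direct transcription of the formulas
  set.seed(22)
  for (i in 1:20) {
    d <- matrix(rnorm(4), 2); g <- matrix(rnorm(4), 2); gp <- matrix(rnorm(4), 2)
    s <- matrix(rnorm(4), 2); y <- matrix(rnorm(4), 2)
    ybar <- y - g * (sum(g * y) / sum(g^2))
    sp <- spectral_params(d, g, gp, s, y, ybar, eta)
    if (sum(d * ybar) > eta * sum(gp^2)) {
      expect_identical(sp$branch, 1L)
      th <- (sum(d * y) - sum(d * g) * sum(g * s) / sum(g^2)) / sum(d * ybar)
      be <- (sum(g * y) - sum(g * s)) / sum(d * ybar)
      expect_equal(sp$theta, th)
      expect_equal(sp$beta, be)
    } else {
      expect_identical(sp$branch, 2L)
    }
  }
})

test_that("search direction mixes -theta*g + beta*d and safeguards ascent", {
  g <- rbind(c(1, -1))
  expect_equal(search_direction(NA, NA, g, NULL, 0L)$d, -g)
  d <- rbind(c(-2, 1))
  res <- search_direction(1, 0, g, d, 3L)
  expect_equal(res$d, -g)
  expect_false(res$restarted)
  res <- search_direction(-1, 0, g, d, 3L)  # ascent: +g fails <g, D> < 0
  expect_equal(res$d, -g)
  expect_true(res$restarted)
  res <- search_direction(2, 0.5, g, d, 1L)
  expect_equal(res$d, -2 * g + 0.5 * d)
})

test_that("backtracking accepts the worked quadratic step and guarantees decrease", {
  ctrl <- scg_control()
  # f(x) = x^2/2 at x = 1, d = -1: alpha = 1 accepted at l = 0 because
  # 0 <= 0.5 - 0.4 - 0.001
  ls <- backtracking_step(function(a) 0.5 * (1 - a)^2, f0 = 0.5, gd = -1,
                          dnorm2 = 1, control = ctrl)
  expect_equal(ls$alpha, 1)
  expect_equal(ls$l, 0L)
  expect_equal(ls$f_new, 0)
  expect_error(backtracking_step(function(a) a, 0, gd = 1, 1, ctrl), "descent")

  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:4, 1); r <- sample(1:3, 1); m <- sample(2:4, 1)
    A <- matrix(runif(n * m), n, m); B <- matrix(runif(r * m), r, m)
    X <- matrix(rnorm(n * r, sd = 2), n, r)
    G <- X %*% tcrossprod(B) - tcrossprod(A, B)
    if (sum(G^2) == 0) next
    D <- -G
    f0 <- 0.5 * sum((A - X %*% B)^2)
    ls <- backtracking_step(function(a) 0.5 * sum((A - (X + a * D) %*% B)^2),
                            f0, sum(G * D), sum(D^2), ctrl)
    # alpha is an integer power of rho in (0, 1]
    expect_lte(ls$alpha, 1)
    expect_gt(ls$alpha, 0)
    expect_equal(ls$alpha, ctrl$rho^ls$l, tolerance = 1e-14)
    # strict decrease by at least the curvature-penalty margin
    expect_lte(ls$f_new,
               f0 + ctrl$delta1 * ls$alpha * sum(G * D) -
                 ctrl$delta2 * ls$alpha^2 * sum(D^2))
    expect_lt(ls$f_new, f0)
  }
})

test_that("subproblem solver reaches the gradient tolerance with decreasing objective", {
  # fixed factor = identity: unconstrained least squares, exact solution A
  set.seed(24)
  A <- matrix(runif(12), 4, 3)
  res <- solve_subproblem(A, diag(3), matrix(0, 4, 3), "W")
  expect_true(res$converged)
  expect_lte(res$final_gnorm, 1e-7)
  expect_lt(max(abs(res$X - A)), 1e-6)

  # already-optimal start exits with zero iterations
  H <- matrix(runif(6), 2, 3)
  Wstar <- t(qr.solve(tcrossprod(H), tcrossprod(H, A)))
  res0 <- solve_subproblem(A, H, Wstar, "W")
  expect_equal(res0$iterations, 0L)

  # random instances: tolerance reached, f_trace strictly decreasing
  for (i in 1:10) {
    A <- matrix(runif(15), 5, 3)
    H <- matrix(runif(6), 2, 3)
    res <- solve_subproblem(A, H, matrix(runif(10), 5, 2), "W",
                            scg_control(max_inner_iter = 2000))
    expect_true(res$converged)
    expect_lte(res$final_gnorm, 1e-7)
    # strict descent per accepted step, up to double rounding at the tail
    expect_true(all(diff(res$f_trace) <= 0))
    expect_true(any(diff(res$f_trace) < 0))
    gw <- nmf_grad_w(A, res$X, H)          # independent gradient check
    expect_lte(sqrt(sum(gw^2)), 1e-6)
  }
})

test_that("W- and H-subproblems are symmetric and engines agree", {
  set.seed(25)
  A <- matrix(runif(20), 5, 4)
  W <- matrix(runif(10), 5, 2)
  h0 <- matrix(runif(8), 2, 4)
  resH <- solve_subproblem(A, W, h0, "H")
  expect_lte(sqrt(sum(nmf_grad_h(A, W, resH$X)^2)), 1e-6)
  # the pure-R reference and the compiled loop produce the same solve
  rc <- solve_subproblem(A, W, h0, "H", engine = "cpp")
  rr <- solve_subproblem(A, W, h0, "H", engine = "r")
  expect_equal(rc$iterations, rr$iterations)
  expect_lt(max(abs(rc$X - rr$X)), 1e-8)
  expect_equal(rc$f_trace, rr$f_trace, tolerance = 1e-10)
})

test_that("on a separable quadratic the solver terminates within a small iteration budget", {
  set.seed(26)
  for (i in 1:20) {
    n <- sample(3:6, 1); r <- sample(2:3, 1)
    B <- qr.Q(qr(matrix(rnorm(16), 4, 4)))[seq_len(r), , drop = FALSE]  # orthonormal rows
    A <- matrix(runif(n * 4), n, 4)
    res <- solve_subproblem(A, B, matrix(runif(n * r), n, r), "W")
    expect_true(res$converged)
    expect_lte(res$iterations, 10 * n * r)
  }
})
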