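test_that("membership columns are gene-averaged class shares summing to 1", {
  # identity-like W with column [2,1]: per-gene shares (1,0) and (0,1)
  W <- rbind(c(1, 0), c(0, 1))
  H <- matrix(c(2, 1), 2, 1)
  memb <- membership_matrix(W, H)
  expect_equal(unname(memb$R[, 1]), c(0.5, 0.5))
  expect_equal(memb$included_gene_count, 2L)

  # r = 1: every gene's share ratio is 1
  memb1 <- membership_matrix(matrix(runif(5), 5, 1), matrix(runif(3), 1, 3))
  expect_equal(unname(memb1$R), matrix(1, 1, 3))

  set.seed(51)
  for (i in 1:10) {
    W <- matrix(runif(20), 5, 4) * rbinom(20, 1, 0.7)
    H <- matrix(runif(12), 4, 3)
    memb <- membership_matrix(W, H)
    expect_true(all(abs(colSums(memb$R) - 1) <= 1e-8))
    expect_true(all(memb$R >= 0 & memb$R <= 1))
  }
  expect_error(membership_matrix(matrix(0, 3, 2), matrix(1, 2, 2)),
               "undefined for sample")
  expect_error(membership_matrix(-W, H), "nonnegative")
})

test_that("samples are assigned to the dominant class as in the published membership table", {
  # membership columns of the trained 8-sample group at r = 6
  bsbl2 <- c(0, 0.3713, 0, 0, 0, 0.6287)
  tcl2 <- c(0, 0.1597, 0, 0, 0.8403, 0)
  R <- cbind(BSBL2 = bsbl2, TCL2 = tcl2)
  asg <- assign_classes(R, source = "R")
  expect_equal(unname(asg$assignment["BSBL2"]), 6L)
  expect_equal(unname(asg$assignment["TCL2"]), 5L)
  expect_equal(unname(asg$ratio_gap["BSBL2"]), 0.6287 / 0.3713)

  # exact tie breaks toward the lowest class index
  tie <- assign_classes(matrix(c(0.5, 0.5), 2, 1))
  expect_equal(unname(tie$assignment), 1L)
  # second-largest zero gives an infinite clarity gap
  clean <- assign_classes(matrix(c(0, 3), 2, 1))
  expect_equal(unname(clean$ratio_gap), Inf)
  expect_error(assign_classes(matrix(0, 2, 1)), "all-zero")
})

test_that("classification by H and by R agrees when W rows are balanced", {
  sim <- planted_matrix(n = 200, m = 6, r = 3, signal_genes_per_class = 30,
                        noise_sigma = 0, seed = 52)
  fit <- nmf_factorize(sim$data, 3, scg_control(seed = 53))
  # rescale to balance: unit-max W columns (H rows absorb the scale)
  scale <- apply(fit$W, 2, max)
  Wb <- sweep(fit$W, 2, scale, "/")
  Hb <- sweep(fit$H, 1, scale, "*")
  asgH <- assign_classes(Hb, source = "H")
  asgR <- assign_classes(membership_matrix(Wb, Hb))
  expect_true(same_partition(asgH, asgR))
  expect_true(same_partition(asgR$assignment, sim$truth$labels))
})

test_that("trial-rank selection recovers a planted 3-class structure", {
  sim <- planted_matrix(n = 500, m = 9, r = 3, signal_genes_per_class = 40,
                        noise_sigma = 0.02, seed = 54)
  sel <- select_rank(sim$data, 2:5, scg_control(seed = 55), n_starts = 2L)
  expect_equal(sel$r_star, 3L)
  expect_true(sel$all_separated)
  expect_true(all(c("r", "seed", "n_clear") %in% names(sel$diagnostics)))
  # different seed set, same selection
  sel2 <- select_rank(sim$data, 2:5, scg_control(seed = 155), n_starts = 2L)
  expect_equal(sel2$r_star, 3L)
  expect_error(select_rank(sim$data, integer(0)), "empty")
})

test_that("structureless data yields the no-structure warning flag", {
  set.seed(56)
  u <- runif(120, 0.5, 1.5); v <- runif(5, 0.8, 1.2)
  A <- outer(u, v) + matrix(rnorm(600, 0, 0.01), 120, 5)  # one block only
  sel <- select_rank(pmax(A, 0), 2:3, scg_control(seed = 57), n_starts = 2L)
  expect_true(sel$no_structure)
  expect_equal(sel$r_star, 2L)  # smallest candidate, flagged for override
  expect_true(all(sel$gains < sel$min_gain))
})

test_that("sample correlation matches the direct formula and flags degenerate columns", {
  set.seed(58)
  A <- matrix(runif(40), 10, 4)
  cm <- sample_correlation(A)
  expect_equal(dim(cm), c(4L, 4L))
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_equal(cm, t(cm))
  direct <- cov(A[, 1], A[, 2]) / (sd(A[, 1]) * sd(A[, 2]))
  expect_equal(cm[1, 2], direct)
  # duplicated column and mirrored column
  B <- cbind(A[, 1], A[, 1], max(A[, 1]) + min(A[, 1]) - A[, 1])
  cmB <- sample_correlation(B)
  expect_equal(cmB[1, 2], 1)
  expect_equal(cmB[1, 3], -1)
  expect_warning(cmC <- sample_correlation(cbind(A[, 1:2], rep(2, 10))),
                 "zero-variance")
  expect_true(all(is.na(cmC[3, ])))
  # spearman route
  expect_equal(diag(sample_correlation(A, method = "spearman")), rep(1, 4),
               ignore_attr = TRUE)
})

test_that("top genes rank by scaled basis weight with index tie-breaks", {
  W <- cbind(c(0.1, 0.9, 0.5), c(0.2, 1.8, 1.0))
  lists <- top_genes(W, gene_ids = c("a", "b", "c"), k = 2)
  expect_equal(lists[[1]], c("b", "c"))
  # proportional columns rank identically (scale invariance)
  expect_identical(lists[[1]], lists[[2]])
  all3 <- top_genes(W, gene_ids = c("a", "b", "c"), k = 3)
  expect_setequal(all3[[1]], c("a", "b", "c"))
  # ties break by gene index
  Wt <- cbind(c(0.5, 0.9, 0.5))
  expect_equal(top_genes(Wt, gene_ids = c("a", "b", "c"), k = 3)[[1]],
               c("b", "a", "c"))
})

test_that("shared genes are set intersections, monotone in the class set", {
  lists <- list(c("a", "b", "c"), c("b", "c", "d"), c("c", "e"))
  expect_equal(shared_genes(lists, c(1, 2))$genes, c("b", "c"))
  sg <- shared_genes(lists, 1:3)
  expect_equal(sg$count, 1L)
  expect_equal(sg$genes, "c")
  expect_equal(shared_genes(list(c("x"), c("y")), 1:2)$count, 0L)
  expect_equal(shared_genes(list(letters[1:4], letters[1:4]), 1:2)$count, 4L)
  # monotone non-increasing as more classes are intersected
  expect_gte(shared_genes(lists, 1:2)$count, shared_genes(lists, 1:3)$count)
  expect_error(shared_genes(lists, 5), "out of range")
  expect_error(shared_genes(lists, integer(0)), "no classes")
})
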