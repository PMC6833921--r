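#' Membership matrix of a factorization
#'
#' Converts a factorization `A ~ WH` into soft class memberships. For
#' sample `j` and class `i`, each gene `g` contributes the share
#' `W[g, i] * H[i, j] / sum_k W[g, k] * H[k, j]` of its reconstructed
#' expression that class `i` explains; the membership `R[i, j]` is the
#' average of these shares over the genes whose denominator is positive
#' (their count is reported per sample). Columns therefore sum to exactly
#' 1, and entries lie in \[0, 1\].
#'
#' @param W nonnegative basis matrix n x r, or an `nmf_fit` (then `H` is
#'   taken from the fit).
#' @param H nonnegative coordinate matrix r x m.
#' @return An object of class `membership_matrix`: list with `R` (r x m),
#'   `included_gene_count` (per sample).
#' @export
membership_matrix <- function(W, H = NULL) {
  if (inherits(W, "nmf_fit")) { H <- W$H; W <- W$W }
  stopifnot(is.matrix(W), is.matrix(H), ncol(W) == nrow(H))
  if (any(W < 0) || any(H < 0)) {
    stop("membership_matrix requires nonnegative factors", call. = FALSE)
  }
  r <- ncol(W); m <- ncol(H)
  R <- matrix(0, r, m)
  included <- integer(m)
  for (j in seq_len(m)) {
    contrib <- sweep(W, 2L, H[, j], `*`)   # n x r, gene-by-class shares
    denom <- rowSums(contrib)
    ok <- denom > 0
    if (!any(ok)) {
      nm <- colnames(H)[j]
      stop(sprintf("membership undefined for sample %s: WH is zero for every gene",
                   if (is.null(nm)) as.character(j) else nm), call. = FALSE)
    }
    R[, j] <- colSums(contrib[ok, , drop = FALSE] / denom[ok]) / sum(ok)
    included[j] <- sum(ok)
  }
  dimnames(R) <- list(rownames(H), colnames(H))
  structure(list(R = R, included_gene_count = included),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("<membership_matrix> %d classes x %d samples (columns sum to 1)\n",
              nrow(x$R), ncol(x$R)))
  print(round(x$R, 4), ...)
  invisible(x)
}

#' Assign samples to classes
#'
#' Each sample is assigned to the class with the largest entry in its
#' column of the score matrix — either the membership matrix `R` or the
#' coordinate matrix `H`; the two agree whenever the rows of `W` share an
#' order of magnitude, and can disagree otherwise. Exact ties go to the
#' lowest class index. The per-sample `ratio_gap` (largest over
#' second-largest column entry, `Inf` when the second-largest is 0)
#' measures how clearly the sample is classified.
#'
#' @param scores a `membership_matrix`, an `nmf_fit` (its `H` is used), or
#'   a numeric matrix with classes in rows and samples in columns.
#' @param source label recorded on the result (`"H"` or `"R"`); inferred
#'   when `scores` is a classed object.
#' @return An object of class `class_assignment`: list with `assignment`
#'   (named integer vector), `ratio_gap` (named numeric), `partition`
#'   (list of sample-name vectors, one per occupied class), `source`, `r`.
#' @export
assign_classes <- function(scores, source = NULL) {
  if (inherits(scores, "membership_matrix")) {
    if (is.null(source)) source <- "R"
    scores <- scores$R
  } else if (inherits(scores, "nmf_fit")) {
    if (is.null(source)) source <- "H"
    scores <- scores$H
  } else {
    if (is.null(source)) source <- "H"
    scores <- as.matrix(scores)
  }
  source <- match.arg(source, c("H", "R"))
  r <- nrow(scores); m <- ncol(scores)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("sample_", seq_len(m))
  assignment <- integer(m)
  gap <- numeric(m)
  for (j in seq_len(m)) {
    col <- scores[, j]
    if (all(col == 0)) {
      stop(sprintf("sample %s has an all-zero score column and cannot be assigned",
                   colnames(scores)[j]), call. = FALSE)
    }
    assignment[j] <- which.max(col)  # ties -> lowest index
    srt <- sort(col, decreasing = TRUE)
    gap[j] <- if (r == 1L || srt[2L] == 0) Inf else srt[1L] / srt[2L]
  }
  names(assignment) <- colnames(scores)
  names(gap) <- colnames(scores)
  partition <- split(colnames(scores), assignment)
  structure(list(assignment = assignment, ratio_gap = gap,
                 partition = unname(partition), source = source, r = r),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("<class_assignment> from %s, %d classes\n", x$source, x$r))
  for (grp in x$partition) {
    cls <- x$assignment[grp[1L]]
    cat(sprintf("  class %d: %s\n", cls, paste(grp, collapse = ", ")))
  }
  invisible(x)
}

#' Do two assignments induce the same sample partition?
#'
#' Class labels of a factorization are arbitrary (the factorization is
#' unique at most up to permutation and scaling), so assignments are
#' compared as partitions of the sample set, not by label values.
#'
#' @param a,b `class_assignment` objects, or integer label vectors over
#'   the same samples.
#' @return Logical.
#' @export
same_partition <- function(a, b) {
  la <- if (inherits(a, "class_assignment")) a$assignment else a
  lb <- if (inherits(b, "class_assignment")) b$assignment else b
  stopifnot(length(la) == length(lb))
  # canonical form: relabel classes by order of first appearance
  canon <- function(l) match(l, unique(l))
  identical(canon(la), canon(lb))
}

#' Trial-rank selection
#'
#' Factorizes `A` at every candidate rank (each from `n_starts` seeded
#' initializations, keeping the best fit per rank) and selects the number
#' of classes at the elbow of the objective curve: `r_star` is the largest
#' rank whose best objective improves on the rank below it by at least the
#' fraction `min_gain` — one more class must explain a substantial share
#' of the still-unexplained signal, not just absorb noise. The rank below
#' the scanned range (down to 1) is fitted once as the baseline. Gains are
#' not credited once the objective is already negligible (below `1e-8` of
#' `0.5 * ||A||_F^2`), so an essentially exact fit is not refined further.
#'
#' Per-rank clarity diagnostics are reported alongside: a sample is
#' "clearly classified" when the ratio of the largest to second-largest
#' entry of its coordinate column is at least `tau` (second-largest 0
#' counts as infinitely clear). `all_separated` records whether any rank
#' clearly separates every sample; when no rank passes the gain test the
#' smallest candidate is returned with `no_structure = TRUE` and the
#' diagnostics let the user override.
#'
#' @param A an [expr_matrix()] or nonnegative matrix.
#' @param r_range consecutive integer ranks to scan, e.g. `2:7`.
#' @param control an [scg_control()]; seeds used are
#'   `control$seed + 0:(n_starts-1)`.
#' @param tau clear-classification threshold on the ratio gap (> 1).
#' @param min_gain minimal fractional objective improvement per added
#'   class, in (0, 1).
#' @param n_starts random initializations per rank.
#' @return An object of class `rank_selection`: list with `r_star`,
#'   `diagnostics` (data frame: r, seed, n_clear, median_gap, objective,
#'   converged), `gains` (named vector of per-rank fractional
#'   improvements), `all_separated`, `no_structure`, `tau`, `min_gain`.
#' @export
select_rank <- function(A, r_range, control = scg_control(), tau = 5,
                        min_gain = 0.5, n_starts = 3L) {
  r_range <- sort(unique(as.integer(r_range)))
  if (!length(r_range)) stop("empty rank range", call. = FALSE)
  if (length(r_range) > 1L && any(diff(r_range) != 1L)) {
    stop("rank range must be consecutive integers", call. = FALSE)
  }
  stopifnot(tau > 1, min_gain > 0, min_gain < 1, n_starts >= 1)
  x <- as_expr_matrix(A)
  m <- ncol(x$values)
  total <- 0.5 * sum(x$values^2)
  seeds <- control$seed + seq_len(n_starts) - 1L
  fit_best <- function(r) {
    best <- Inf
    for (s in seeds) {
      ctrl <- control; ctrl$seed <- s
      fit <- suppressWarnings(nmf_factorize(x, r, ctrl))
      best <- min(best, utils::tail(fit$objective_trace, 1L))
    }
    best
  }
  rows <- list()
  best_obj <- rep(NA_real_, length(r_range))
  best_count <- rep(-1L, length(r_range))
  for (i in seq_along(r_range)) {
    r <- r_range[i]
    for (s in seeds) {
      ctrl <- control; ctrl$seed <- s
      fit <- suppressWarnings(nmf_factorize(x, r, ctrl))
      asg <- assign_classes(fit)
      n_clear <- sum(asg$ratio_gap >= tau)
      obj <- utils::tail(fit$objective_trace, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        r = r, seed = s, n_clear = n_clear,
        median_gap = stats::median(asg$ratio_gap),
        objective = obj, converged = fit$converged)
      best_count[i] <- max(best_count[i], n_clear)
      best_obj[i] <- min(best_obj[i], obj, na.rm = TRUE)
    }
  }
  baseline <- if (r_range[1L] > 1L) fit_best(r_range[1L] - 1L) else total
  prev <- c(baseline, best_obj[-length(best_obj)])
  gains <- ifelse(prev > 1e-8 * total, 1 - best_obj / prev, 0)
  names(gains) <- r_range
  passing <- which(gains >= min_gain)
  no_structure <- length(passing) == 0L
  r_star <- if (no_structure) r_range[1L] else r_range[max(passing)]
  structure(list(r_star = r_star,
                 diagnostics = do.call(rbind, rows),
                 gains = gains,
                 all_separated = max(best_count) == m,
                 no_structure = no_structure,
                 tau = tau, min_gain = min_gain),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("<rank_selection> r_star = %d (min_gain = %g, tau = %g)%s\n",
              x$r_star, x$min_gain, x$tau,
              if (x$no_structure)
                " [warning: no rank clears the gain threshold]" else ""))
  agg <- merge(stats::aggregate(n_clear ~ r, data = x$diagnostics, FUN = max),
               stats::aggregate(objective ~ r, data = x$diagnostics, FUN = min))
  agg$gain <- x$gains[as.character(agg$r)]
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Sample-sample correlation matrix
#'
#' Pearson (default) or Spearman correlation between sample columns of the
#' expression matrix, used to diagnose replicate samples with large
#' detection error: a replicate that correlates less with its siblings
#' than with other fish explains its misclassification. Zero-variance
#' columns get `NA` in their row/column, with a warning naming them.
#'
#' @param A an [expr_matrix()] or numeric matrix (genes x samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return m x m symmetric matrix with unit diagonal (NA rows/columns for
#'   degenerate samples).
#' @export
sample_correlation <- function(A, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  V <- expr_values(A)
  if (ncol(V) < 2L) stop("need at least two samples", call. = FALSE)
  sds <- apply(V, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    warning("zero-variance sample column(s): ",
            paste(if (is.null(colnames(V))) flat else colnames(V)[flat],
                  collapse = ", "),
            "; correlations set to NA")
  }
  cm <- suppressWarnings(stats::cor(V, method = method))
  cm[flat, ] <- NA_real_   # cor() leaves a unit diagonal even when degenerate
  cm[, flat] <- NA_real_
  cm
}

#' Highly expressed genes per class
#'
#' Ranks genes within each class by their weight in the corresponding
#' basis-matrix column. Each column is first scaled to unit maximum so
#' that ranking is invariant to the scale ambiguity of the factorization;
#' ties break by gene index (file order).
#'
#' @param W basis matrix n x r or an `nmf_fit`.
#' @param gene_ids gene identifiers; taken from `W`'s rownames when absent.
#' @param k number of genes per class (`k <= n`).
#' @return Named list, one character vector of `k` gene ids per class,
#'   in decreasing weight order.
#' @export
top_genes <- function(W, gene_ids = NULL, k = 200L) {
  if (inherits(W, "nmf_fit")) W <- W$W
  n <- nrow(W)
  if (is.null(gene_ids)) gene_ids <- rownames(W)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  stopifnot(k >= 1, k <= n, length(gene_ids) == n)
  out <- vector("list", ncol(W))
  for (i in seq_len(ncol(W))) {
    col <- W[, i]
    mx <- max(col)
    if (mx > 0) col <- col / mx
    ord <- order(col, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    out[[i]] <- gene_ids[ord[seq_len(k)]]
  }
  names(out) <- colnames(W)
  if (is.null(names(out))) names(out) <- paste0("class_", seq_len(ncol(W)))
  out
}

#' Shared highly expressed genes across classes
#'
#' Intersects the top-gene lists of the selected classes; larger
#' intersections between two classes indicate stronger genetic similarity
#' between them.
#'
#' @param lists per-class gene lists from [top_genes()].
#' @param classes indices (or names) of the classes to intersect; defaults
#'   to all.
#' @return List with `count` and `genes` (character vector).
#' @export
shared_genes <- function(lists, classes = seq_along(lists)) {
  if (!length(classes)) stop("no classes selected", call. = FALSE)
  if (is.character(classes)) {
    missing <- setdiff(classes, names(lists))
    if (length(missing)) stop("unknown class name(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
  } else if (any(classes < 1 | classes > length(lists))) {
    stop("class index out of range", call. = FALSE)
  }
  genes <- Reduce(intersect, lists[classes])
  list(count = length(genes), genes = genes)
}
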