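#' Expression matrix container
#'
#' Wraps a nonnegative gene x sample matrix together with gene identifiers,
#' sample identifiers, optional replicate-group tags and a normalization
#' flag. All downstream functions ([normalize_rows()], [nmf_factorize()],
#' [sample_correlation()], ...) accept this container; most also accept a
#' bare numeric matrix, which is coerced via [as_expr_matrix()].
#'
#' @param values numeric matrix, genes in rows, samples in columns. All
#'   entries must be finite and nonnegative.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)` or `gene_1 ... gene_n`.
#' @param sample_ids character vector of unique sample names, one per
#'   column. Defaults to `colnames(values)` or `sample_1 ... sample_m`.
#' @param groups optional named character vector mapping sample name to a
#'   replicate-group label.
#' @param normalized logical; `TRUE` once per-gene min-max normalization has
#'   been applied (entries then lie in \[0, 1\]).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix, with dimnames set), `gene_ids`, `sample_ids`, `groups`,
#'   `normalized`, and after normalization `row_min`, `row_max`,
#'   `n_constant_rows`.
#' @seealso [read_expression_table()], [normalize_rows()]
#' @export
expr_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                        groups = NULL, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  m <- ncol(values)
  if (n < 1L) stop("expression matrix needs at least one gene row", call. = FALSE)
  if (m < 2L) stop("expression matrix needs at least two sample columns", call. = FALSE)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(m))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != n) stop("length(gene_ids) != nrow(values)", call. = FALSE)
  if (length(sample_ids) != m) stop("length(sample_ids) != ncol(values)", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[rc[1L]], sample_ids[rc[2L]]), call. = FALSE)
  }
  neg <- which(values < 0)
  if (length(neg)) {
    rc <- arrayInd(neg[1L], dim(values))
    stop(sprintf("negative expression value (%g) at gene '%s', sample '%s'",
                 values[neg[1L]], gene_ids[rc[1L]], sample_ids[rc[2L]]),
         call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- as.character(groups)[match(sample_ids, names(groups))]
    names(groups) <- sample_ids
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         groups = groups, normalized = isTRUE(normalized)),
    class = "expr_matrix"
  )
}

#' Coerce to an expression matrix
#'
#' @param x an `expr_matrix` or a numeric matrix.
#' @param ... passed to [expr_matrix()] when coercing a bare matrix.
#' @return An `expr_matrix`.
#' @export
as_expr_matrix <- function(x, ...) {
  if (inherits(x, "expr_matrix")) return(x)
  expr_matrix(x, ...)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) ", min-max normalized" else ""))
  if (!is.null(x$groups)) {
    cat("  groups:", paste(unique(x$groups), collapse = ", "), "\n")
  }
  k <- min(5L, nrow(x$values))
  j <- min(6L, ncol(x$values))
  print(x$values[seq_len(k), seq_len(j), drop = FALSE], ...)
  if (nrow(x$values) > k) cat("  ...", nrow(x$values) - k, "more genes\n")
  invisible(x)
}

# internal: extract the numeric matrix from either representation
expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
}
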