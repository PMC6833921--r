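#' Read a gene x sample expression table
#'
#' Reads a delimited text file (CSV or TSV) or a spreadsheet (XLSX, first
#' worksheet only) laid out with gene identifiers in the first column and
#' sample names in the header row. Every data cell must parse as a finite,
#' nonnegative number; row/column identifiers must be unique. Gene and
#' sample order is preserved exactly as in the file.
#'
#' @param path path to the input file.
#' @param format one of `"auto"` (default; inferred from the file
#'   extension), `"csv"`, `"tsv"`, `"xlsx"`.
#' @return An [expr_matrix()] with `normalized = FALSE`.
#' @export
read_expression_table <- function(path, format = c("auto", "csv", "tsv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv", tsv = "tsv", tab = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly", call. = FALSE))
  }
  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the 'readxl' package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = 1L,
                                           col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", stringsAsFactors = FALSE)
  }
  if (ncol(df) < 3L) {
    stop("expression table needs a gene-ID column plus at least two samples",
         call. = FALSE)
  }
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      stop(sprintf(
        "malformed cell at gene '%s', sample '%s': '%s' is not numeric",
        gene_ids[bad[1L]], sample_ids[j], col[bad[1L]]), call. = FALSE)
    }
    vals[, j] <- num
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf(
      "malformed cell at gene '%s', sample '%s': negative value %g",
      gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]],
      vals[neg[1L, 1L], neg[1L, 2L]]), call. = FALSE)
  }
  expr_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids,
              normalized = FALSE)
}

#' Write an expression matrix as CSV
#'
#' Inverse of [read_expression_table()]: first column `gene_id`, one column
#' per sample. Values are written at full double precision so that a
#' write/read round trip reproduces the matrix.
#'
#' @param x an [expr_matrix()] or numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  x <- as_expr_matrix(x)
  df <- data.frame(gene_id = x$gene_ids,
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", x$sample_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: matrix -> CSV with a leading ID column, full precision
write_matrix_csv <- function(mat, path, id_name) {
  df <- data.frame(rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(mat))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write factorization outputs to a directory
#'
#' Persists the basis matrix `W` (gene x class), the coordinate matrix `H`
#' (class x sample) and the membership matrix `R` (class x sample) as CSV
#' files `W.csv`, `H.csv`, `R.csv`, plus a plain-text `report.txt` holding
#' the solver configuration, seed, convergence status, objective trace and
#' KKT-ratio trace.
#'
#' @param model an `nmf_fit` from [nmf_factorize()].
#' @param r_matrix a `membership_matrix` from [membership_matrix()], or
#'   `NULL` to compute it from the model.
#' @param dir output directory; created if absent.
#' @return Character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(model, r_matrix = NULL, dir) {
  stopifnot(inherits(model, "nmf_fit"))
  if (is.null(r_matrix)) r_matrix <- membership_matrix(model$W, model$H)
  if (nrow(r_matrix$R) != model$r || ncol(r_matrix$R) != ncol(model$H)) {
    stop("membership matrix shape inconsistent with the model", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  classes <- paste0("class_", seq_len(model$r))
  W <- model$W; colnames(W) <- classes
  H <- model$H; rownames(H) <- classes
  R <- r_matrix$R; rownames(R) <- classes
  paths <- file.path(dir, c("W.csv", "H.csv", "R.csv", "report.txt"))
  write_matrix_csv(W, paths[1L], "gene_id")
  write_matrix_csv(H, paths[2L], "class")
  write_matrix_csv(R, paths[3L], "class")
  cfg <- model$control
  lines <- c(
    "scgnmf factorization report",
    sprintf("rank r: %d", model$r),
    sprintf("seed: %d", cfg$seed),
    sprintf("converged: %s (%s)", model$converged,
            if (model$converged) "relative KKT tolerance reached"
            else "outer iteration cap reached"),
    sprintf("outer sweeps: %d", model$outer_iters),
    sprintf("final objective: %.10g", utils::tail(model$objective_trace, 1L)),
    sprintf("final KKT ratio: %.10g", utils::tail(model$kkt_ratio_trace, 1L)),
    "",
    "solver configuration:",
    sprintf("  %s = %g", names(unclass(cfg)), unlist(unclass(cfg))),
    "",
    "objective trace (per outer sweep):",
    paste0("  ", format(model$objective_trace, digits = 10)),
    "",
    "KKT ratio trace (per outer sweep):",
    paste0("  ", format(model$kkt_ratio_trace, digits = 10))
  )
  writeLines(lines, paths[4L])
  invisible(paths)
}

#' Read back a matrix written by [write_outputs()]
#'
#' @param path a `W.csv`, `H.csv` or `R.csv` file.
#' @return Numeric matrix with dimnames.
#' @export
read_output_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}
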