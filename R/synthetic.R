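#' Synthetic expression matrix with planted class structure
#'
#' Builds a nonnegative gene x sample matrix `A = max(0, W* H* + noise)`
#' whose factorization structure is known. The planted basis `W*` gives
#' each class a dedicated block of `signal_genes_per_class` high-weight
#' genes over a low uniform background, so class signatures have disjoint
#' support; the planted coordinates `H*` are near-one-hot (dominant class
#' weight 1, off-class weight `off_weight`, so the dominant class carries
#' at least 80% of the column mass at the default). Sample labels are the
#' argmax of the `H*` columns; samples are dealt to classes cyclically, so
#' all `r` classes are occupied whenever `m >= r`. Noise is Gaussian
#' truncated at zero — the pipeline consumes min-max-normalized values in
#' \[0, 1\], so a count model would add nothing the code paths exercise.
#'
#' Defaults (500 genes, 8 samples, 6 classes) are a down-scaled version of
#' the motivating study design: 8 fish samples, 6 transcriptome classes,
#' ~20000 genes. Set `n = 20093L` for a full-scale matrix.
#'
#' @param n,m number of genes and samples.
#' @param r number of planted classes, `r <= m`.
#' @param signal_genes_per_class genes in each class's high-weight block;
#'   `r * signal_genes_per_class <= n`.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param background upper bound of the uniform background weight in `W*`.
#' @param signal_range range of the uniform high-weight block entries.
#' @param off_weight off-class entry of each `H*` column.
#' @return List with `data` (an [expr_matrix()]) and `truth` (class
#'   `synthetic_truth`: `W_true`, `H_true`, `labels`, `noise_sigma`,
#'   `seed`).
#' @export
planted_matrix <- function(n = 500L, m = 8L, r = 6L,
                           signal_genes_per_class = 30L,
                           noise_sigma = 0, seed = 1L,
                           background = 0.05,
                           signal_range = c(0.8, 1.2),
                           off_weight = 0.02) {
  n <- as.integer(n); m <- as.integer(m); r <- as.integer(r)
  stopifnot(noise_sigma >= 0)
  if (r > m) stop("planted class count r must not exceed the sample count m",
                  call. = FALSE)
  if (r * signal_genes_per_class > n) {
    stop("infeasible block sizes: r * signal_genes_per_class > n", call. = FALSE)
  }
  with_seed(seed, {
    W <- matrix(stats::runif(n * r, 0, background), n, r)
    for (i in seq_len(r)) {
      block <- ((i - 1L) * signal_genes_per_class + 1L):(i * signal_genes_per_class)
      W[block, i] <- stats::runif(signal_genes_per_class,
                                  signal_range[1L], signal_range[2L])
    }
    labels <- rep(seq_len(r), length.out = m)
    H <- matrix(off_weight, r, m)
    H[cbind(labels, seq_len(m))] <- 1
    A <- W %*% H
    if (noise_sigma > 0) {
      A <- A + matrix(stats::rnorm(n * m, 0, noise_sigma), n, m)
      A <- pmax(A, 0)
    }
    gene_ids <- sprintf("gene_%04d", seq_len(n))
    sample_ids <- paste0("S", seq_len(m))
    names(labels) <- sample_ids
    data <- expr_matrix(A, gene_ids = gene_ids, sample_ids = sample_ids)
    truth <- structure(
      list(W_true = W, H_true = H, labels = labels,
           noise_sigma = noise_sigma, seed = seed),
      class = "synthetic_truth")
    list(data = data, truth = truth)
  })
}

#' Replicated sampling groups from a planted truth
#'
#' Emulates repeated sampling periods of the same fish panel: for each of
#' `groups` periods every base sample is re-emitted with coordinate column
#' `replicate_corr * H*[, j] + (1 - replicate_corr) * u`, `u` uniform
#' noise, so the expected correlation between replicates of one fish rises
#' monotonically with `replicate_corr` (at `replicate_corr = 1` and zero
#' noise, replicates are identical). Samples named in `outlier_samples`
#' (emitted names, e.g. `"S1L2"`) instead get an independent random
#' near-one-hot column — simulating a sample with large detection error
#' that will correlate poorly with its siblings and may be misclassified.
#'
#' Emitted names follow the `<base>L<group>` convention (sample `S1` in
#' period 2 becomes `S1L2`); the result's `groups` field maps each emitted
#' sample to its period label.
#'
#' @param truth a `synthetic_truth` from [planted_matrix()].
#' @param groups number of sampling periods.
#' @param replicate_corr replicate fidelity in (0, 1\].
#' @param outlier_samples character vector of emitted sample names to
#'   corrupt.
#' @param noise_sigma additive noise sd; defaults to the truth's value.
#' @param seed integer seed.
#' @return An [expr_matrix()] with `groups * m` columns and period tags.
#' @export
replicate_groups <- function(truth, groups = 3L, replicate_corr = 0.9,
                             outlier_samples = character(),
                             noise_sigma = truth$noise_sigma, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            replicate_corr > 0, replicate_corr <= 1, groups >= 1)
  W <- truth$W_true
  H0 <- truth$H_true
  r <- nrow(H0); m <- ncol(H0); n <- nrow(W)
  base_names <- names(truth$labels)
  with_seed(seed, {
    cols <- list(); tags <- character(0)
    for (g in seq_len(groups)) {
      for (j in seq_len(m)) {
        nm <- paste0(base_names[j], "L", g)
        if (nm %in% outlier_samples) {
          h <- rep(0.02, r)
          h[sample.int(r, 1L)] <- 1
          h <- h * stats::runif(1L, 0.5, 1.5)
        } else {
          u <- stats::runif(r)
          h <- replicate_corr * H0[, j] + (1 - replicate_corr) * u
        }
        cols[[nm]] <- h
        tags[nm] <- paste0("L", g)
      }
    }
    Hrep <- do.call(cbind, cols)
    A <- W %*% Hrep
    if (noise_sigma > 0) {
      A <- pmax(A + matrix(stats::rnorm(length(A), 0, noise_sigma),
                           nrow(A), ncol(A)), 0)
    }
    expr_matrix(A, gene_ids = sprintf("gene_%04d", seq_len(n)),
                sample_ids = colnames(Hrep), groups = tags)
  })
}

#' Planted labels of replicated samples
#'
#' Maps emitted replicate names (`S1L2`, ...) back to the planted class of
#' their base sample. Outlier samples keep their base label here; whether
#' the pipeline misassigns them is what experiments measure.
#'
#' @param truth a `synthetic_truth`.
#' @param sample_ids emitted sample names from [replicate_groups()].
#' @return Named integer vector of planted class labels.
#' @export
replicate_labels <- function(truth, sample_ids) {
  base <- sub("L[0-9]+$", "", sample_ids)
  lab <- truth$labels[base]
  names(lab) <- sample_ids
  lab
}
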