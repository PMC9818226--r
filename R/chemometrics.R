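#' Z-score a peak-area matrix by compound
#'
#' Standardises each compound (row) across all samples to mean 0 and unit
#' sample standard deviation (n - 1), the usual preprocessing before
#' heat-map clustering and multivariate modelling of metabolite panels.
#' A compound with constant signal carries no contrast and maps to a row of
#' zeros rather than NaN.
#'
#' @param x A [peak_table()] or a numeric matrix (rows = compounds).
#' @return A numeric matrix of the same shape, with a logical attribute
#'   `constant` flagging degenerate rows.
#' @export
#' @examples
#' zscore(matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE))
zscore <- function(x) {
  m <- if (inherits(x, "peak_table")) x$areas else as.matrix(x)
  if (ncol(m) < 2) {
    abort("Z-scoring needs at least 2 samples (SD undefined for 1).",
          class = "aromascreen_validation_error")
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  constant <- s == 0
  s[constant] <- 1
  z <- (m - mu) / s
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}

#' Deterministic leaf order from agglomerative clustering
#'
#' Orders the rows (compounds) or columns (samples) of a z-scored matrix by
#' the leaf sequence of an average-linkage (UPGMA) agglomerative clustering
#' on Euclidean distances, as used to arrange metabolite heat maps. The
#' order is the standard recursive dendrogram traversal of
#' [stats::hclust()], which is deterministic for a given input; an axis
#' with a single item returns the identity permutation.
#'
#' @param z Numeric matrix (typically from [zscore()]).
#' @param axis `"rows"` or `"columns"`.
#' @return Integer permutation of the axis indices.
#' @export
hcluster_order <- function(z, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "rows") z else t(z)
  if (nrow(m) < 2) return(seq_len(nrow(m)))
  stats::hclust(dist(m, method = "euclidean"), method = "average")$order
}

#' Principal component analysis of a z-scored compound matrix
#'
#' Singular-value decomposition of the column-centred samples x variables
#' matrix (variables are the z-scored compounds), the standard unsupervised
#' overview of a two-group volatile profile. Explained-variance fractions
#' are squared singular values over total variance, in percent.
#'
#' @param z Matrix, compounds x samples (as returned by [zscore()]), or
#'   samples x variables when `samples_in_rows = TRUE`.
#' @param k Number of components to keep; at most
#'   `min(n_samples - 1, n_vars)`.
#' @param samples_in_rows Set TRUE if `z` is already samples x variables.
#' @return A `pca_model`: list with `scores` (samples x k), `loadings`
#'   (vars x k, orthonormal columns), `explained_pct` (length k),
#'   `center`.
#' @export
fit_pca <- function(z, k = 2, samples_in_rows = FALSE) {
  X <- if (samples_in_rows) as.matrix(z) else t(as.matrix(z))
  n <- nrow(X)
  p <- ncol(X)
  kmax <- min(n - 1, p)
  if (k > kmax) {
    abort(sprintf("k = %d exceeds the maximum %d for %d samples x %d variables.",
                  k, kmax, n, p),
          class = "aromascreen_argument_error")
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  ev <- sv$d^2
  explained <- 100 * ev / sum(ev)
  structure(
    list(
      scores = sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], nrow = k),
      loadings = sv$v[, seq_len(k), drop = FALSE],
      explained_pct = explained[seq_len(k)],
      center = center
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components: %s\n", ncol(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_along(x$explained_pct),
                            x$explained_pct), collapse = ", ")))
  invisible(x)
}

#' Two-sample t-test with degenerate-input conventions
#'
#' Two-sided independent-samples t-test, pooled-variance by default (the
#' "equal variances assumed" reading of the classical test, df =
#' n_a + n_b - 2); `variant = "welch"` uses the Satterthwaite
#' approximation. When both groups have zero variance the t distribution
#' degenerates: equal means return `t = 0, p = 1`; unequal means return the
#' `p = 0` limit with a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return A list with elements `t`, `p`, `df`.
#' @export
ttest_groups <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 observations.",
          class = "aromascreen_validation_error")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    warn("Zero variance in both groups with unequal means; p = 0 limit.")
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  fit <- t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Per-compound t-tests between the two groups of a peak table
#'
#' Runs [ttest_groups()] on the raw peak areas of every compound, contrasting
#' the two sample groups. A Benjamini-Hochberg adjusted column is included
#' for convenience; the classical VIP/p screen uses the raw p-values.
#'
#' @param x A [peak_table()] with exactly two groups.
#' @param variant Passed to [ttest_groups()].
#' @return Tibble `id, name, t, p, p_adj`, in compound order.
#' @export
ttest_peaks <- function(x, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  gl <- require_two_groups(x)
  ca <- group_samples(x, gl[1])
  cb <- group_samples(x, gl[2])
  res <- lapply(seq_len(n_compounds(x)), function(i) {
    ttest_groups(x$areas[i, ca], x$areas[i, cb], variant)
  })
  tibble(
    id = x$compounds$id, name = x$compounds$name,
    t = vapply(res, `[[`, numeric(1), "t"),
    p = vapply(res, `[[`, numeric(1), "p"),
    p_adj = p.adjust(vapply(res, `[[`, numeric(1), "p"), method = "BH")
  )
}
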