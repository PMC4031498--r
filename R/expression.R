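#' Coefficient of variation of one expression profile
#'
#' The variability measure used throughout the package: the ratio of the
#' sample standard deviation (n-1 denominator) to the mean.
#'
#' @param values Numeric vector of expression values (>= 2 finite values,
#'   positive mean).
#' @param gene_id Optional id used in error messages.
#' @return A one-row tibble `mu`, `sigma`, `cv`.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 3))  # cv = sqrt(2)/2
coefficient_of_variation <- function(values, gene_id = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort(sprintf("need at least 2 finite values%s",
                  if (is.null(gene_id)) "" else paste0(" for gene ", gene_id)))
  }
  mu <- mean(values)
  if (mu <= 0) {
    abort(sprintf("mean expression must be positive%s (got %g)",
                  if (is.null(gene_id)) "" else paste0(" for gene ", gene_id),
                  mu))
  }
  sigma <- sd(values)
  tibble(mu = mu, sigma = sigma, cv = sigma / mu)
}

#' Per-gene expression variability across samples
#'
#' Computes mean, standard deviation and coefficient of variation for every
#' gene of a genes-by-samples table. Expression is used on the scale
#' provided; set `log2_transform = TRUE` to work on log2 intensities
#' instead (useful when the input panel is on a linear scale but the
#' variability of log-intensities is wanted).
#'
#' @param expression Tibble from [read_expression()] (first column
#'   `gene_id`) or a numeric matrix with gene rownames.
#' @param log2_transform Take `log2` of the values first (requires all
#'   values positive).
#' @return A tibble `gene_id`, `mu`, `sigma`, `cv`. Genes with
#'   non-positive mean are dropped with a warning reporting the count.
#' @export
expression_cv <- function(expression, log2_transform = FALSE) {
  if (is.data.frame(expression)) {
    genes <- expression[[1]]
    mat <- as.matrix(expression[, -1, drop = FALSE])
  } else {
    mat <- expression
    genes <- rownames(mat)
  }
  if (ncol(mat) < 2) abort("need at least 2 samples per gene")
  if (log2_transform) {
    if (any(mat <= 0)) abort("log2 transform requires positive values")
    mat <- log2(mat)
  }
  mu <- rowMeans(mat)
  keep <- mu > 0
  if (any(!keep)) {
    warn(sprintf("%d gene(s) with non-positive mean expression dropped",
                 sum(!keep)))
  }
  mat <- mat[keep, , drop = FALSE]
  mu <- mu[keep]
  sigma <- apply(mat, 1, sd)
  tibble(gene_id = genes[keep], mu = unname(mu), sigma = unname(sigma),
         cv = unname(sigma / mu))
}

#' Compare expression variability between two gene groups
#'
#' Two-sided two-sample Kolmogorov-Smirnov comparison of the coefficient of
#' variation between the low-count (Q1) and high-count (Q4) gene groups.
#' Genes without an expression-derived CV are dropped with a notice.
#'
#' @param cv Tibble from [expression_cv()].
#' @param q1_set,q4_set Character vectors of gene ids, or pass a
#'   `gene_strata` object as `q1_set` to use its two tails.
#' @return A one-row tibble `ks_D`, `p_value`, `mean_q1`, `mean_q4`,
#'   `n_q1`, `n_q4`.
#' @export
cv_group_comparison <- function(cv, q1_set, q4_set = NULL) {
  if (inherits(q1_set, "gene_strata")) {
    q4_set <- q1_set$q4_set
    q1_set <- q1_set$q1_set
  }
  cv1 <- cv$cv[cv$gene_id %in% q1_set]
  cv4 <- cv$cv[cv$gene_id %in% q4_set]
  miss <- (length(q1_set) - length(cv1)) + (length(q4_set) - length(cv4))
  if (miss > 0) {
    inform(sprintf("cv_group_comparison: %d group gene(s) lack expression",
                   miss))
  }
  if (length(cv1) < 5 || length(cv4) < 5) {
    abort("both groups need at least 5 genes with CV values")
  }
  ks <- ks_two_sample(cv1, cv4)
  tibble(ks_D = ks$statistic, p_value = ks$p_value,
         mean_q1 = mean(cv1), mean_q4 = mean(cv4),
         n_q1 = length(cv1), n_q4 = length(cv4))
}
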