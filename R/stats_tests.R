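# Statistical tests used by the site-distribution analyses. Each wrapper
# returns a light "mir_test" object so results can be tidied uniformly.

new_mir_test <- function(statistic, p_value, method, alternative, n,
                         degenerate = FALSE) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         alternative = alternative, n = n, degenerate = degenerate),
    class = "mir_test"
  )
}

#' @export
print.mir_test <- function(x, ...) {
  cat(sprintf("<mir_test> %s (%s): statistic = %g, p = %g\n",
              x$method, x$alternative, x$statistic, x$p_value))
  invisible(x)
}

#' @method tidy mir_test
#' @export
tidy.mir_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method,
         alternative = x$alternative)
}

#' @method glance mir_test
#' @export
glance.mir_test <- function(x, ...) tidy(x)

#' Hypergeometric enrichment / depletion test
#'
#' Tail probabilities of the hypergeometric distribution for the overlap
#' between a gene set of size `set_k` and a drawn group of size `draw_n`
#' inside a universe of `universe_n` genes: `tail = "greater"` gives the
#' enrichment p-value `P(X >= overlap_x)`, `tail = "less"` the depletion
#' p-value `P(X <= overlap_x)`. Computation goes through
#' [stats::phyper()], which works in log space internally, so very small
#' p-values are returned accurately.
#'
#' @param universe_n Universe size (must be stated explicitly; results are
#'   meaningless without a defensible universe).
#' @param set_k Number of universe genes in the annotated set (e.g. TFs).
#' @param draw_n Number of genes drawn (e.g. the Q4 group).
#' @param overlap_x Observed overlap.
#' @param tail `"greater"` (enrichment) or `"less"` (depletion).
#' @return A `mir_test`.
#' @export
hypergeometric_enrichment <- function(universe_n, set_k, draw_n, overlap_x,
                                      tail = c("greater", "less")) {
  tail <- match.arg(tail)
  ok <- overlap_x >= 0 && set_k >= 0 && draw_n >= 0 &&
    set_k <= universe_n && draw_n <= universe_n &&
    overlap_x <= min(set_k, draw_n) &&
    overlap_x >= max(0, set_k + draw_n - universe_n)
  if (!ok) abort("inconsistent hypergeometric counts")
  p <- if (tail == "greater") {
    phyper(overlap_x - 1, set_k, universe_n - set_k, draw_n,
           lower.tail = FALSE)
  } else {
    phyper(overlap_x, set_k, universe_n - set_k, draw_n, lower.tail = TRUE)
  }
  new_mir_test(statistic = overlap_x, p_value = p,
               method = "hypergeometric",
               alternative = tail,
               n = c(universe_n = universe_n, set_k = set_k, draw_n = draw_n))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties. For pooled sizes `n + m <= 16`
#' the p-value is exact, from full enumeration of the
#' `choose(n + m, n)` rank assignments (ties handled by enumerating
#' midrank sums, which [stats::wilcox.test()] does not offer); larger
#' samples use the normal approximation with tie correction and continuity
#' correction. The reported statistic is the rank sum of `x`.
#'
#' @param x,y Numeric samples.
#' @param tail `"two_sided"`, `"greater"` or `"less"` (for `x` tending
#'   larger / smaller than `y`).
#' @param exact_max_n Pooled-size cutoff for exact enumeration.
#' @return A `mir_test`.
#' @export
wilcoxon_rank_sum <- function(x, y, tail = c("two_sided", "greater", "less"),
                              exact_max_n = 16) {
  tail <- match.arg(tail)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) abort("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n)])
  eps <- 1e-9
  sizes <- c(n_x = n, n_y = m)
  if (n + m <= exact_max_n) {
    sums <- combn(r, n, FUN = sum)
    p_ge <- mean(sums >= w - eps)
    p_le <- mean(sums <= w + eps)
    p <- switch(tail,
                two_sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    return(new_mir_test(w, p, "Wilcoxon rank-sum (exact)", tail, sizes))
  }
  mu <- n * (n + m + 1) / 2
  ties <- table(pooled)
  N <- n + m
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all pooled values identical
    return(new_mir_test(w, 1, "Wilcoxon rank-sum (degenerate)", tail, sizes,
                        degenerate = TRUE))
  }
  sigma <- sqrt(sigma2)
  z_upper <- (w - mu - 0.5) / sigma
  z_lower <- (w - mu + 0.5) / sigma
  p_ge <- stats::pnorm(z_upper, lower.tail = FALSE)
  p_le <- stats::pnorm(z_lower, lower.tail = TRUE)
  p <- switch(tail,
              two_sided = min(1, 2 * min(p_ge, p_le)),
              greater = p_ge,
              less = p_le)
  new_mir_test(w, p, "Wilcoxon rank-sum (normal approximation)", tail, sizes)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions evaluated at the pooled sample points; the two-sided p-value
#' uses the asymptotic Kolmogorov distribution with effective size
#' `n m / (n + m)`.
#'
#' @param x,y Numeric samples.
#' @return A `mir_test`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) abort("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  f1 <- vapply(pts, function(t) mean(x <= t), 0)
  f2 <- vapply(pts, function(t) mean(y <= t), 0)
  D <- max(abs(f1 - f2))
  t <- sqrt(n * m / (n + m)) * D
  p <- kolmogorov_sf(t)
  new_mir_test(D, p, "two-sample Kolmogorov-Smirnov (asymptotic)",
               "two_sided", c(n_x = n, n_y = m))
}

# asymptotic survival function of the Kolmogorov distribution,
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2); for small t the
# alternating series converges slowly, so the Jacobi-theta transform
# 1 - sqrt(2*pi)/t * sum exp(-(2k-1)^2 pi^2 / (8 t^2)) is used instead
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  if (t < 1) {
    k <- seq_len(20)
    p <- 1 - sqrt(2 * pi) / t * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
  } else {
    k <- seq_len(101)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  }
  min(1, max(0, p))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Returns `NA` (with a notice) when
#' either vector is constant, where rank correlation is undefined.
#'
#' @param x,y Numeric vectors (>= 3 complete pairs).
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    inform("spearman_cor: constant input, correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

#' Spearman correlation test
#'
#' Wrapper around [stats::cor.test()] (asymptotic, midranks for ties) used
#' to ask whether a monotone association is detectably present.
#'
#' @param x,y Numeric vectors.
#' @return A `mir_test`; statistic is rho, `p_value` is two-sided
#'   (`NA` rho for constant input gives p 1).
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(new_mir_test(NA_real_, 1, "Spearman (degenerate)", "two_sided",
                        length(x), degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  new_mir_test(unname(ct$estimate), ct$p.value, "Spearman", "two_sided",
               length(x))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()]. The package's analyses report raw
#' p-values by default (no multiplicity correction is applied anywhere
#' automatically); this helper exists for users who want FDR control.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
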