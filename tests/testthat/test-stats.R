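# enumeration oracles: independent of the implementations under test
hyper_oracle <- function(N, K, n, x, tail) {
  universe <- c(rep(1, K), rep(0, N - K))
  draws <- combn(N, n)
  overlaps <- apply(draws, 2, function(idx) sum(universe[idx]))
  if (tail == "greater") mean(overlaps >= x) else mean(overlaps <= x)
}

ranksum_oracle <- function(x, y, tail = "two_sided") {
  n <- length(x)
  pooled <- c(x, y)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">")) +
    0.5 * sum(outer(xi, yi, "=="))
  u_obs <- u_of(x, y)
  us <- apply(combn(length(pooled), n), 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  p_ge <- mean(us >= u_obs - 1e-9)
  p_le <- mean(us <= u_obs + 1e-9)
  switch(tail, two_sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge, less = p_le)
}

ks_oracle <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
}

test_that("hypergeometric tails match full draw enumeration", {
  expect_equal(hypergeometric_enrichment(10, 5, 4, 4, "greater")$p_value,
               5 / 210, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:30) {
    N <- sample(4:12, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    lo <- max(0, K + n - N); hi <- min(K, n)
    x <- sample_between(lo, hi)
    for (tail in c("greater", "less")) {
      expect_equal(hypergeometric_enrichment(N, K, n, x, tail)$p_value,
                   hyper_oracle(N, K, n, x, tail), tolerance = 1e-9)
    }
  }
})

test_that("hypergeometric edge cases and the tail identity", {
  expect_equal(hypergeometric_enrichment(10, 0, 4, 0, "less")$p_value, 1)
  expect_equal(hypergeometric_enrichment(10, 10, 4, 4, "greater")$p_value, 1)
  expect_error(hypergeometric_enrichment(10, 5, 4, 6, "greater"),
               "inconsistent")
  set.seed(42)
  for (i in 1:30) {
    N <- sample(2:12, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    lo <- max(0, K + n - N); hi <- min(K, n)
    x <- sample_between(lo, hi)
    if (x == lo) next  # P(X <= lo - 1) undefined below the support
    p_ge <- hypergeometric_enrichment(N, K, n, x, "greater")$p_value
    p_le <- hypergeometric_enrichment(N, K, n, x - 1, "less")$p_value
    expect_equal(p_ge + p_le, 1, tolerance = 1e-12)
  }
})

test_that("rank-sum exact p matches permutation enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)

  same <- wilcoxon_rank_sum(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$p_value, 1)

  set.seed(43)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    vals <- sample.int(6, n + m, replace = TRUE)  # forces ties
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    for (tail in c("two_sided", "greater", "less")) {
      expect_equal(wilcoxon_rank_sum(x, y, tail)$p_value,
                   ranksum_oracle(x, y, tail), tolerance = 1e-9)
    }
  }
})

test_that("rank-sum normal approximation tracks the exact enumeration", {
  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8) + runif(1, 0, 2)
    exact <- wilcoxon_rank_sum(x, y)$p_value
    approx <- wilcoxon_rank_sum(x, y, exact_max_n = 0)$p_value
    # the tie-corrected normal approximation with continuity correction
    # sits within ~0.011 of the exact enumeration at n = m = 8
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("rank-sum approximation agrees with stats::wilcox.test", {
  set.seed(45)
  x <- rnorm(30); y <- rnorm(25, 0.3)
  ours <- wilcoxon_rank_sum(x, y)$p_value
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_equal(wilcoxon_rank_sum(rep(1, 20), rep(1, 20))$p_value, 1)
})

test_that("KS distance comes from the pooled ECDF", {
  ident <- ks_two_sample(1:5, 1:5)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  r <- ks_two_sample(c(1, 2, 3), c(2.5, 3.5))
  expect_equal(r$statistic, ks_oracle(c(1, 2, 3), c(2.5, 3.5)),
               tolerance = 1e-12)
  set.seed(46)
  for (i in 1:15) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.5)
    expect_equal(ks_two_sample(x, y)$statistic, ks_oracle(x, y),
                 tolerance = 1e-12)
    ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
    # ks.test truncates the Kolmogorov series at an absolute tolerance of
    # 1e-6; compare at the accuracy that truncation supports
    expect_equal(ks_two_sample(x, y)$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("Spearman correlation uses midranks and flags constants", {
  expect_equal(spearman_cor(1:10, (1:10)^3), 1)
  expect_equal(spearman_cor(1:10, -(1:10)), -1)
  x <- c(1, 2, 2, 3, 5); y <- c(2, 2, 4, 4, 7)
  expect_equal(spearman_cor(x, y),
               cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(spearman_cor(x, y),
               suppressWarnings(cor.test(x, y, method = "spearman",
                                         exact = FALSE)$estimate[[1]]),
               tolerance = 1e-12)
  expect_message(r <- spearman_cor(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
})
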