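test_that("percentile filter keeps the strongest sites, ties included", {
  s <- make_sites("g1", c("a", "b", "c", "d"),
                  context_score = c(-0.9, -0.5, -0.3, -0.1))
  kept <- filter_sites_by_percentile(s, pct_conserved = 50)
  expect_setequal(kept$context_score, c(-0.9, -0.5))

  tied <- make_sites("g1", c("a", "b", "c", "d"), context_score = -0.2)
  expect_equal(nrow(filter_sites_by_percentile(tied, pct_conserved = 50)), 4)

  empty <- make_sites(character(), character())
  expect_message(out <- filter_sites_by_percentile(empty), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("retained fraction tracks (100 - pct)/100 per category", {
  set.seed(1)
  s <- random_sites(400)
  s$context_score <- -runif(400)  # distinct scores: the 1/n bound assumes no ties
  for (pct in c(0, 25, 50, 75, 90)) {
    kept <- suppressMessages(
      filter_sites_by_percentile(s, pct_conserved = pct,
                                 pct_nonconserved = pct))
    for (cat in c("conserved", "nonconserved")) {
      n <- sum(s$category == cat)
      frac <- sum(kept$category == cat) / n
      expect_lte(abs(frac - (100 - pct) / 100), 1 / n + 1e-12)
    }
  }
})

test_that("percentile filter is monotone: lower pct retains a superset", {
  set.seed(2)
  s <- random_sites(300)
  grid <- c(0, 20, 40, 60, 80, 95)
  kept <- lapply(grid, function(p) {
    k <- filter_sites_by_percentile(s, pct_conserved = p,
                                    pct_nonconserved = p)
    paste(k$gene_id, k$mirna_id, k$context_score)
  })
  for (i in seq_along(grid)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("matrix construction collapses duplicate sites per miRNA", {
  s <- make_sites(rep("g1", 4), c("miR-1", "miR-1", "miR-1", "miR-2"))
  m <- build_interaction_matrix(s)
  expect_equal(site_counts(m)$n_mirnas, 2L)

  # one 3'UTR position shared by two distinct miRNAs counts twice
  shared <- make_sites("g1", c("miR-1", "miR-2"),
                       utr_start = 10L, utr_end = 17L)
  expect_equal(site_counts(build_interaction_matrix(shared))$n_mirnas, 2L)

  # universe genes without records keep an all-zero row
  m2 <- build_interaction_matrix(s, gene_universe = c("g1", "g5"))
  cnt <- site_counts(m2)
  expect_equal(cnt$n_mirnas[cnt$gene_id == "g5"], 0L)
  expect_true(all(m2$incidence %in% c(0L, 1L)))
})

test_that("matrix construction is idempotent over its own pair expansion", {
  set.seed(3)
  s <- random_sites(500, n_genes = 50, n_mirnas = 20)
  m1 <- build_interaction_matrix(s)
  m2 <- build_interaction_matrix(tidy(m1))
  expect_identical(m1$incidence, m2$incidence)
})

test_that("counts equal a brute-force distinct-miRNA oracle", {
  set.seed(4)
  for (i in 1:200) {
    s <- random_sites(sample.int(300, 1),
                      n_genes = sample.int(200, 1),
                      n_mirnas = sample.int(50, 1))
    m <- build_interaction_matrix(s)
    oracle <- vapply(
      split(s$mirna_id, s$gene_id),
      function(v) length(unique(v)), 0L)
    cnt <- site_counts(m)
    expect_identical(cnt$n_mirnas, unname(oracle[cnt$gene_id]))
  }
})

test_that("quartile thresholds follow the nearest-rank convention", {
  counts <- tibble::tibble(gene_id = sprintf("g%d", 1:8), n_mirnas = 1:8)
  st <- assign_quartile_groups(counts)
  expect_equal(st$q25_threshold, 2L)
  expect_equal(st$q75_threshold, 6L)
  expect_equal(st$q1_set, "g1")
  expect_setequal(st$q4_set, c("g7", "g8"))

  const <- tibble::tibble(gene_id = sprintf("g%d", 1:10), n_mirnas = 10L)
  expect_warning(st2 <- assign_quartile_groups(const), "degenerate")
  expect_length(st2$q1_set, 0)
  expect_length(st2$q4_set, 0)

  skewed <- tibble::tibble(gene_id = sprintf("g%d", 1:8),
                           n_mirnas = c(rep(0L, 7), 100L))
  st3 <- assign_quartile_groups(skewed)
  expect_equal(st3$q4_set, "g8")
  expect_length(st3$q1_set, 0)
})

test_that("quartile tails never overlap on random counts", {
  set.seed(5)
  for (i in 1:20) {
    counts <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                             n_mirnas = rpois(100, 20))
    st <- assign_quartile_groups(counts)
    expect_length(intersect(st$q1_set, st$q4_set), 0)
  }
})

test_that("vigintile bins are balanced, deterministic and partition genes", {
  counts40 <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                             n_mirnas = sample(1000L, 40))
  v40 <- assign_vigintiles(counts40)
  expect_true(all(table(v40$bin) == 2))

  counts41 <- tibble::tibble(gene_id = sprintf("g%02d", 1:41),
                             n_mirnas = sample(1000L, 41))
  v41 <- assign_vigintiles(counts41)
  expect_equal(sort(as.integer(table(v41$bin))), c(rep(2L, 19), 3L))

  # ties at a bin boundary resolved by gene_id, identically across runs
  tied <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                         n_mirnas = rep(c(1L, 2L), each = 20))
  expect_identical(assign_vigintiles(tied), assign_vigintiles(tied))

  set.seed(6)
  counts <- tibble::tibble(gene_id = sprintf("g%03d", 1:137),
                           n_mirnas = rpois(137, 10))
  v <- assign_vigintiles(counts)
  expect_setequal(v$gene_id, counts$gene_id)
  expect_true(max(table(v$bin)) - min(table(v$bin)) <= 1)
  expect_error(assign_vigintiles(counts[1:10, ]), "at least")
})

test_that("binned means are arithmetic and ordered by bin", {
  set.seed(7)
  counts <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                           n_mirnas = sample(200L, 40))
  v <- assign_vigintiles(counts)
  feats <- tibble::tibble(gene_id = counts$gene_id, val = 3.0)
  bm <- binned_means(v, feats, x = "val")
  expect_equal(bm$mean_x, rep(3.0, 20))
  expect_equal(bm$bin, 1:20)
  # sorted binning forces non-decreasing count means
  expect_true(all(diff(bm$mean_y) >= 0))

  two <- tibble::tibble(gene_id = v$gene_id[order(v$bin)],
                        val = rep(c(1, 3), 20))
  bm2 <- binned_means(v, two, x = "val")
  expect_equal(bm2$mean_x, rep(2, 20))

  feats$val[1:2] <- NA
  expect_message(bm3 <- binned_means(v, feats, x = "val"), "excluded")
  expect_true(all(bm3$n <= 2))
})
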