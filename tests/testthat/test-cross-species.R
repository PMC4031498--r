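counts_tbl <- function(n) {
  tibble::tibble(gene_id = sprintf("g%02d", seq_along(n)),
                 n_mirnas = as.integer(n))
}

mat_from_counts <- function(n, species = "s00") {
  # one distinct miRNA column per needed slot
  recs <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", seq_along(n)), n),
    mirna_id = unlist(lapply(n, function(k) sprintf("m%03d", seq_len(k)))),
    species_id = species, category = "conserved", context_score = -0.5,
    utr_start = NA_integer_, utr_end = NA_integer_)
  build_interaction_matrix(recs, species_id = species,
                           gene_universe = sprintf("g%02d", seq_along(n)))
}

test_that("normalized counts divide by the species mean", {
  nc <- normalized_counts(counts_tbl(c(2, 4, 6)))
  expect_equal(nc$norm_count, c(0.5, 1.0, 1.5))
  expect_equal(normalized_counts(counts_tbl(7))$norm_count, 1.0)
  expect_equal(normalized_counts(counts_tbl(c(0, 10)))$norm_count, c(0, 2))
  expect_error(normalized_counts(counts_tbl(c(0, 0))), "all-zero")
})

test_that("normalized counts average to one in every species", {
  set.seed(51)
  for (i in 1:20) {
    n <- rpois(sample(10:200, 1), runif(1, 1, 40))
    if (sum(n) == 0) n[1] <- 1L
    nc <- normalized_counts(counts_tbl(n))
    expect_equal(mean(nc$norm_count), 1, tolerance = 1e-12)
  }
})

test_that("species panel validates ranks and matrix coverage", {
  mats <- list(s00 = mat_from_counts(c(1, 2), "s00"),
               s01 = mat_from_counts(c(2, 1), "s01"))
  sp <- tibble::tibble(species_id = c("s00", "s01"), distance_rank = 0:1)
  expect_s3_class(species_panel(mats, sp), "species_panel")
  expect_error(species_panel(mats[1], sp), "no matrix")
  sp_bad <- tibble::tibble(species_id = c("s00", "s01"),
                           distance_rank = c(1L, 2L))
  expect_error(species_panel(mats, sp_bad), "rank 0")
})

test_that("group trajectories average normalized counts per species", {
  mats <- list(s00 = mat_from_counts(c(2, 4, 6), "s00"),
               s01 = mat_from_counts(c(4, 4, 4), "s01"),
               s02 = mat_from_counts(c(6, 4, 2), "s02"))
  sp <- tibble::tibble(species_id = c("s00", "s01", "s02"),
                       distance_rank = 0:2)
  panel <- species_panel(mats, sp)

  # a group containing every gene is pinned at 1 by the normalization
  all_t <- group_trajectory(panel, sprintf("g%02d", 1:3))
  expect_equal(all_t$trajectory$mean_norm_count, rep(1, 3))
  expect_true(is.na(all_t$trend))  # constant trajectory

  one <- group_trajectory(panel, "g01")
  expect_equal(one$trajectory$mean_norm_count, c(0.5, 1.0, 1.5))
  expect_equal(one$trend, 1)

  dec <- group_trajectory(panel, "g03")
  expect_equal(dec$trend, -1)

  # member missing from one species: mean over the remaining members
  map <- tibble::tibble(ref_gene_id = c("g01", "g02", "g01", "g02"),
                        species_id = c("s01", "s01", "s02", "s02"),
                        gene_id = c("g01", "g02", "g01", "g02"))
  map <- map[-1, ]  # g01 has no ortholog in s01
  two <- suppressMessages(
    group_trajectory(panel, c("g01", "g02"), ortholog_map = map))
  expect_equal(two$trajectory$n_genes, c(2L, 1L, 2L))
})

test_that("trend statistic equals the rank-correlation formula", {
  traj <- tibble::tibble(distance_rank = 0:4,
                         mean_norm_count = c(0.5, 0.8, 0.9, 1.4, 2.0))
  expect_equal(trend_statistic(traj), 1)
  traj$mean_norm_count <- rev(traj$mean_norm_count)
  expect_equal(trend_statistic(traj), -1)
  set.seed(52)
  for (i in 1:10) {
    tr <- tibble::tibble(distance_rank = 0:7,
                         mean_norm_count = rnorm(8))
    d <- rank(tr$distance_rank) - rank(tr$mean_norm_count)
    expect_equal(trend_statistic(tr), 1 - 6 * sum(d^2) / (8 * 63),
                 tolerance = 1e-12)
  }
  expect_error(trend_statistic(
    tibble::tibble(distance_rank = 0:1, mean_norm_count = c(1, 2))),
    "at least 3")
})

test_that("planted turnover yields opposite Q1/Q4 trends", {
  cfg <- synthetic_config(seed = 53, n_genes = 400, n_mirnas = 80,
                          n_species = 6)
  labels <- generate_gene_labels(cfg)
  sites <- generate_sites(cfg, labels)
  mats <- lapply(names(sites$tables), function(sp) {
    build_interaction_matrix(sites$tables[[sp]], species_id = sp,
                             gene_universe = labels$gene_id)
  })
  names(mats) <- names(sites$tables)
  panel <- species_panel(mats, sites$species)
  strata <- assign_quartile_groups(site_counts(mats$s00))
  q1 <- group_trajectory(panel, strata$q1_set, sites$ortholog_map, "Q1")
  q4 <- group_trajectory(panel, strata$q4_set, sites$ortholog_map, "Q4")
  expect_gt(q1$trend, 0)
  expect_lt(q4$trend, 0)
})
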