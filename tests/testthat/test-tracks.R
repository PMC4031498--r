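track_tbl <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(chrom = "chr1", start = as.integer(m[, 1]),
                 end = as.integer(m[, 2]), score = m[, 3])
}

test_that("mean conservation is length-weighted over covered bases", {
  iv1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 40L)
  expect_equal(mean_conservation(track_tbl(0, 40, 0.5), iv1), 0.5)
  expect_equal(mean_conservation(track_tbl(0, 10, 1, 10, 40, 0), iv1), 0.25)
  # half-covered interval: only covered bases enter the denominator
  expect_equal(mean_conservation(track_tbl(0, 20, 0.8), iv1), 0.8)
  # no coverage at all
  expect_true(is.na(mean_conservation(track_tbl(100, 120, 0.9), iv1)))
})

test_that("mean conservation equals a per-base brute-force average", {
  set.seed(31)
  for (i in 1:25) {
    n_seg <- sample(3:15, 1)
    bounds <- sort(sample.int(1000, n_seg + 1))
    keep <- sample(c(TRUE, FALSE), n_seg, replace = TRUE, prob = c(.7, .3))
    tr <- tibble::tibble(chrom = "chr1", start = bounds[-(n_seg + 1)],
                         end = bounds[-1],
                         score = round(runif(n_seg), 3))[keep, ]
    ivs <- tibble::tibble(chrom = "chr1",
                          start = sample.int(500, 3),
                          end = 0L)
    ivs$end <- ivs$start + sample.int(300, 3)
    got <- mean_conservation(tr, ivs)
    base_score <- rep(NA_real_, 1200)
    for (j in seq_len(nrow(tr))) {
      base_score[(tr$start[j] + 1):tr$end[j]] <- tr$score[j]
    }
    covered <- unique(unlist(lapply(seq_len(3), function(j) {
      (ivs$start[j] + 1):ivs$end[j]
    })))
    vals <- base_score[covered]
    want <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    if (is.na(want)) expect_true(is.na(got)) else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("repeat overlap uses half-open intervals and the class filter", {
  ann <- make_annotation("gA", tss = 100L, span_start = 100L,
                         span_end = 200L, utr3 = list(iv(100, 200)),
                         cds = list(iv()))
  reps <- tibble::tibble(chrom = "chr1",
                         start = c(150L, 200L, 150L),
                         end = c(160L, 250L, 160L),
                         repeat_class = c("LTR", "SINE", "LINE"))
  f1 <- flag_repeat_overlap(ann, reps[1, ])
  expect_true(f1$has_repeat); expect_equal(f1$overlap_bp, 10L)
  expect_false(flag_repeat_overlap(ann, reps[2, ])$has_repeat)  # abutting
  expect_false(flag_repeat_overlap(ann, reps[3, ])$has_repeat)  # LINE
})

test_that("repeat-stratified medians and rank-sum comparison", {
  counts <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                           n_mirnas = c(2L, 4L, 6L, 1L, 3L))
  flags <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                          has_repeat = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                          overlap_bp = c(10L, 10L, 10L, 0L, 0L))
  res <- stratified_count_medians(counts, flags)
  expect_equal(res$median_with, 4)
  expect_equal(res$median_without, 2)

  # identical strata give p = 1 under the exact method
  counts2 <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                            n_mirnas = rep(c(1L, 2L, 3L), 2))
  flags2 <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                           has_repeat = rep(c(TRUE, FALSE), each = 3),
                           overlap_bp = rep(c(5L, 0L), each = 3))
  expect_equal(stratified_count_medians(counts2, flags2)$p_value, 1)

  expect_error(
    stratified_count_medians(counts, flags, within = c("g4", "g5")),
    "empty")
})

test_that("3'UTR length analysis reports a Spearman association", {
  set.seed(32)
  lens <- sample(seq(100L, 4000L, by = 100L), 30)
  ann <- make_annotation(sprintf("g%02d", 1:30), tss = 0L,
                         span_start = 0L, span_end = lens + 10L,
                         utr3 = lapply(lens, function(l) iv(0, l)),
                         cds = replicate(30, iv(), simplify = FALSE))
  counts <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                           n_mirnas = as.integer(lens / 100))
  ul <- utr_length_vs_counts(ann, counts)
  expect_equal(glance(ul)$spearman, 1)

  const <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), n_mirnas = 5L)
  expect_message(ul2 <- utr_length_vs_counts(ann, const), "constant")
  expect_true(is.na(glance(ul2)$spearman))

  # permuted counts agree with the textbook rank formula (no ties)
  perm <- counts
  perm$n_mirnas <- sample(perm$n_mirnas)
  ul3 <- utr_length_vs_counts(ann, perm)
  d <- rank(tidy(ul3)$utr3_len) - rank(tidy(ul3)$n_mirnas)
  n <- nrow(tidy(ul3))
  expect_equal(glance(ul3)$spearman, 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
               tolerance = 1e-12)
})

test_that("co-localization window arithmetic and boundary rule", {
  ann <- make_annotation("gA", tss = 100000L, span_start = 100000L,
                         span_end = 150000L,
                         utr3 = list(iv(140000, 150000)),
                         cds = list(iv(100000, 110000)))
  loci <- tibble::tibble(
    mirna_id = c("in_intron", "at_20kb", "far"),
    chrom = "chr1",
    start = c(120000L, 80000L, 175000L),
    end = c(120080L, 80080L, 175080L),
    strand = "+")
  cl <- colocalize_mirnas(loci, ann)
  expect_setequal(tidy(cl)$mirna_id, c("in_intron", "at_20kb"))
  expect_equal(glance(cl)$n_mirnas, 2)
  expect_equal(glance(cl)$n_genes, 1)
})

test_that("co-localization grows monotonically with the window", {
  set.seed(33)
  sim <- simulate_study(small_config(seed = 33))
  pairs_at <- function(w) {
    cl <- colocalize_mirnas(sim$mirna_loci, sim$annotations, window = w)
    paste(cl$pairs$mirna_id, cl$pairs$gene_id)
  }
  p0 <- pairs_at(0); p20 <- pairs_at(20000); p50 <- pairs_at(50000)
  expect_true(all(p0 %in% p20))
  expect_true(all(p20 %in% p50))
  cl <- colocalize_mirnas(sim$mirna_loci, sim$annotations)
  expect_equal(cl$n_mirnas, length(unique(cl$pairs$mirna_id)))
  expect_equal(cl$n_genes, length(unique(cl$pairs$gene_id)))
})

test_that("conservation summary recovers the planted class contrast", {
  sim <- simulate_study(small_config(seed = 34))
  cons <- conservation_summary(sim$track, sim$annotations)
  reg <- sim$labels$regulatory[match(cons$gene_id, sim$labels$gene_id)]
  expect_gt(mean(cons$utr3_mean[reg]), mean(cons$utr3_mean[!reg]))
  expect_lt(mean(cons$cds_mean[reg]), mean(cons$cds_mean[!reg]))
  expect_true(all(cons$utr3_mean >= 0 & cons$utr3_mean <= 1))
  expect_equal(cons$utr3_len,
               vapply(sim$annotations$utr3, function(d) sum(d$end - d$start),
                      0L))
})
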