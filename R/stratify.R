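#' Split genes into lower/upper quartile groups by distinct-miRNA count
#'
#' Thresholds are the nearest-rank 25th and 75th percentiles of the count
#' distribution; the Q1 set holds genes strictly below the lower threshold
#' and the Q4 set genes strictly above the upper one (strict inequalities,
#' so genes sitting exactly on a threshold belong to neither tail).
#'
#' @param counts An `interaction_matrix` or a tibble with `gene_id`,
#'   `n_mirnas` (at least 8 genes).
#' @param lower_pct,upper_pct Percentiles defining the tails.
#' @return An object of class `gene_strata`: list with `q25_threshold`,
#'   `q75_threshold`, `q1_set`, `q4_set` and an `assignments` tibble
#'   (`gene_id`, `n_mirnas`, `group` in Q1/mid/Q4).
#' @export
assign_quartile_groups <- function(counts, lower_pct = 25, upper_pct = 75) {
  counts <- site_counts(counts)
  if (nrow(counts) < 8) abort("need at least 8 genes to form quartile groups")
  q25 <- nearest_rank(counts$n_mirnas, lower_pct)
  q75 <- nearest_rank(counts$n_mirnas, upper_pct)
  group <- dplyr::case_when(
    counts$n_mirnas < q25 ~ "Q1",
    counts$n_mirnas > q75 ~ "Q4",
    TRUE ~ "mid"
  )
  if (!any(group == "Q1") && !any(group == "Q4")) {
    warn("count distribution is degenerate; both quartile sets are empty")
  }
  structure(
    list(
      q25_threshold = q25,
      q75_threshold = q75,
      q1_set = counts$gene_id[group == "Q1"],
      q4_set = counts$gene_id[group == "Q4"],
      assignments = tibble(gene_id = counts$gene_id,
                           n_mirnas = counts$n_mirnas,
                           group = factor(group, levels = c("Q1", "mid", "Q4")))
    ),
    class = "gene_strata"
  )
}

#' @export
print.gene_strata <- function(x, ...) {
  cat(sprintf(
    "<gene_strata> thresholds %s/%s: Q1 %d genes (< %s), Q4 %d genes (> %s)\n",
    x$q25_threshold, x$q75_threshold, length(x$q1_set), x$q25_threshold,
    length(x$q4_set), x$q75_threshold))
  invisible(x)
}

#' @method tidy gene_strata
#' @export
tidy.gene_strata <- function(x, ...) x$assignments

#' @method glance gene_strata
#' @export
glance.gene_strata <- function(x, ...) {
  tibble(q25_threshold = x$q25_threshold, q75_threshold = x$q75_threshold,
         n_q1 = length(x$q1_set), n_q4 = length(x$q4_set),
         n_genes = nrow(x$assignments))
}

#' Assign genes to vigintiles (or another number of rank bins)
#'
#' Genes are ranked ascending by distinct-miRNA count (ties broken by
#' lexicographic `gene_id`, so the assignment is deterministic) and split
#' into `n_bins` contiguous bins whose sizes differ by at most one. Bin 1
#' holds the fewest-site genes, bin `n_bins` the most-targeted ones.
#'
#' @param counts An `interaction_matrix` or tibble `gene_id`, `n_mirnas`.
#' @param n_bins Number of rank bins (default 20, i.e. vigintiles).
#' @return A tibble `gene_id`, `n_mirnas`, `bin`.
#' @export
assign_vigintiles <- function(counts, n_bins = 20) {
  counts <- site_counts(counts)
  n <- nrow(counts)
  if (n < n_bins) {
    abort(sprintf("need at least %d genes for %d bins, got %d",
                  n_bins, n_bins, n))
  }
  ord <- order(counts$n_mirnas, counts$gene_id)
  bin <- integer(n)
  bin[ord] <- as.integer(ceiling(n_bins * seq_len(n) / n))
  tibble(gene_id = counts$gene_id, n_mirnas = counts$n_mirnas, bin = bin)
}

#' Per-bin means of two gene-level variables
#'
#' Joins per-gene values onto a vigintile assignment and returns one row per
#' bin with the arithmetic means of `x` and `y`. Genes missing a value are
#' excluded from that bin's mean (a notice reports how many were dropped);
#' a bin with no usable genes gets `NA` means.
#'
#' @param vigintiles Tibble from [assign_vigintiles()].
#' @param features Tibble with `gene_id` and the value columns.
#' @param x,y Column names (strings) in `features` (or `"n_mirnas"` for the
#'   counts carried by `vigintiles`).
#' @return A tibble `bin`, `mean_x`, `mean_y`, `n` ordered by bin;
#'   `n` counts genes contributing to both means.
#' @export
binned_means <- function(vigintiles, features, x, y = "n_mirnas") {
  d <- left_join(vigintiles, features, by = "gene_id")
  if (!x %in% names(d)) abort(sprintf("column '%s' not found", x))
  if (!y %in% names(d)) abort(sprintf("column '%s' not found", y))
  xv <- d[[x]]; yv <- d[[y]]
  n_drop <- sum(is.na(xv) | is.na(yv))
  if (n_drop > 0) {
    inform(sprintf("binned_means: %d gene(s) missing a value were excluded",
                   n_drop))
  }
  safe_mean <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  tibble(bin = d$bin, .x = xv, .y = yv) |>
    group_by(.data$bin) |>
    summarise(mean_x = safe_mean(.data$.x),
              mean_y = safe_mean(.data$.y),
              n = sum(!is.na(.data$.x) & !is.na(.data$.y)),
              .groups = "drop") |>
    arrange(.data$bin)
}
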