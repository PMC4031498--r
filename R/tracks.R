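# Conservation aggregation, repeat overlap, 3'UTR length and miRNA-gene
# co-localization. Interval arithmetic is delegated to IRanges; all
# coordinates are 0-based half-open.

# long (chrom, start, end [, gene_id]) overlap table between two interval
# sets; returns query index, subject index and overlap width
overlap_table <- function(a, b) {
  out <- vector("list", 0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    ra <- as_iranges0(a$start[ia], a$end[ia])
    rb <- as_iranges0(b$start[ib], b$end[ib])
    h <- IRanges::findOverlaps(ra, rb)
    if (length(h) == 0) next
    qi <- ia[S4Vectors::queryHits(h)]
    si <- ib[S4Vectors::subjectHits(h)]
    w <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
    out[[length(out) + 1]] <- tibble(query = qi, subject = si, width = w)
  }
  if (length(out) == 0) {
    return(tibble(query = integer(), subject = integer(), width = integer()))
  }
  dplyr::bind_rows(out)
}

# flatten the utr3 or cds list-column into a long interval table
gene_intervals <- function(annotations, which = c("utr3", "cds")) {
  which <- match.arg(which)
  iv <- annotations[[which]]
  n <- vapply(iv, nrow, 0L)
  tibble(
    gene_id = rep(annotations$gene_id, n),
    chrom = rep(annotations$chrom, n),
    start = unlist(lapply(iv, function(d) d$start), use.names = FALSE) %n% integer(),
    end = unlist(lapply(iv, function(d) d$end), use.names = FALSE) %n% integer()
  )
}

#' Length-weighted mean track score over a set of intervals
#'
#' The mean is taken over the intersection of the (union-normalized)
#' intervals with the track's covered bases; bases the track does not cover
#' are excluded from the denominator, since conservation tables only score
#' aligned positions. Returns `NA` when no base is covered.
#'
#' @param track Score track tibble (see [read_track()]).
#' @param intervals Tibble `chrom`, `start`, `end`.
#' @return A single number in the track's score scale, or `NA`.
#' @export
mean_conservation <- function(track, intervals) {
  if (nrow(intervals) == 0) return(NA_real_)
  iv <- intervals |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) normalize_intervals(d)) |>
    ungroup()
  h <- overlap_table(iv, track)
  if (nrow(h) == 0) return(NA_real_)
  sum(h$width * track$score[h$subject]) / sum(h$width)
}

#' Per-gene conservation over 3'UTR and CDS regions
#'
#' Gene-level, length-weighted averaging of track scores over each gene's
#' 3'UTR and CDS intervals, with the annotated (not covered) lengths
#' reported alongside.
#'
#' @param track Score track tibble.
#' @param annotations Annotation tibble.
#' @return A tibble `gene_id`, `utr3_mean`, `cds_mean`, `utr3_len`,
#'   `cds_len`; means are `NA` where the track covers no base.
#' @export
conservation_summary <- function(track, annotations) {
  region_mean <- function(which) {
    iv <- gene_intervals(annotations, which)
    if (nrow(iv) == 0) {
      return(tibble(gene_id = character(), m = numeric()))
    }
    h <- overlap_table(iv, track)
    tibble(gene_id = iv$gene_id[h$query],
           w = h$width, s = track$score[h$subject]) |>
      group_by(.data$gene_id) |>
      summarise(m = sum(.data$w * .data$s) / sum(.data$w), .groups = "drop")
  }
  u <- region_mean("utr3"); cd <- region_mean("cds")
  tibble(
    gene_id = annotations$gene_id,
    utr3_mean = u$m[match(annotations$gene_id, u$gene_id)],
    cds_mean = cd$m[match(annotations$gene_id, cd$gene_id)],
    utr3_len = vapply(annotations$utr3, interval_total_width, 0L),
    cds_len = vapply(annotations$cds, interval_total_width, 0L)
  )
}

#' Flag genes whose 3'UTR overlaps repeat elements
#'
#' A gene is flagged when at least one base of a repeat of the requested
#' classes intersects any of its 3'UTR intervals (half-open intervals, so
#' abutting features do not count).
#'
#' @param annotations Annotation tibble.
#' @param repeats Repeat tibble (see [read_repeats()]).
#' @param classes Repeat classes to consider (default LTR and SINE).
#' @return A tibble `gene_id`, `has_repeat`, `overlap_bp`.
#' @export
flag_repeat_overlap <- function(annotations, repeats,
                                classes = c("LTR", "SINE")) {
  rep_sel <- repeats[repeats$repeat_class %in% classes, , drop = FALSE]
  iv <- gene_intervals(annotations, "utr3")
  ob <- rep(0L, nrow(annotations))
  if (nrow(iv) > 0 && nrow(rep_sel) > 0) {
    h <- overlap_table(iv, rep_sel)
    if (nrow(h) > 0) {
      per_gene <- tibble(gene_id = iv$gene_id[h$query], w = h$width) |>
        group_by(.data$gene_id) |>
        summarise(bp = sum(.data$w), .groups = "drop")
      ob <- per_gene$bp[match(annotations$gene_id, per_gene$gene_id)]
      ob[is.na(ob)] <- 0L
    }
  }
  tibble(gene_id = annotations$gene_id,
         has_repeat = ob >= 1,
         overlap_bp = as.integer(ob))
}

#' Median distinct-miRNA counts by repeat status
#'
#' Compares the per-gene distinct-miRNA counts of repeat-containing versus
#' repeat-free genes (optionally restricted to a gene subset such as the
#' upper quartile group) with a two-sided Wilcoxon rank-sum test.
#'
#' @param counts An `interaction_matrix` or tibble `gene_id`, `n_mirnas`.
#' @param flags Tibble from [flag_repeat_overlap()].
#' @param within Optional character vector restricting the comparison.
#' @return A one-row tibble `median_with`, `median_without`, `n_with`,
#'   `n_without`, `statistic`, `p_value`.
#' @export
stratified_count_medians <- function(counts, flags, within = NULL) {
  d <- inner_join(site_counts(counts), flags, by = "gene_id")
  if (!is.null(within)) d <- d[d$gene_id %in% within, , drop = FALSE]
  with_r <- d$n_mirnas[d$has_repeat]
  without_r <- d$n_mirnas[!d$has_repeat]
  if (length(with_r) == 0 || length(without_r) == 0) {
    abort("one of the repeat strata is empty")
  }
  wt <- wilcoxon_rank_sum(with_r, without_r, tail = "two_sided")
  tibble(median_with = median(with_r), median_without = median(without_r),
         n_with = length(with_r), n_without = length(without_r),
         statistic = wt$statistic, p_value = wt$p_value)
}

#' 3'UTR length versus distinct-miRNA count
#'
#' Pairs each gene's summed 3'UTR length with its distinct-miRNA count and
#' quantifies the monotone association with a Spearman correlation. Genes
#' without a 3'UTR annotation are dropped with a notice.
#'
#' @param annotations Annotation tibble.
#' @param counts An `interaction_matrix` or tibble `gene_id`, `n_mirnas`.
#' @return An object of class `utr_length_analysis` with the per-gene table
#'   (`tidy()`) and the correlation summary (`glance()`).
#' @export
utr_length_vs_counts <- function(annotations, counts) {
  counts <- site_counts(counts)
  len <- tibble(gene_id = annotations$gene_id,
                utr3_len = vapply(annotations$utr3, interval_total_width, 0L))
  len <- len[len$utr3_len > 0, , drop = FALSE]
  d <- inner_join(counts, len, by = "gene_id")
  n_drop <- nrow(counts) - nrow(d)
  if (n_drop > 0) {
    inform(sprintf("utr_length_vs_counts: %d gene(s) without 3'UTR dropped",
                   n_drop))
  }
  rho <- spearman_cor(d$utr3_len, d$n_mirnas)
  structure(list(data = d, spearman = rho, n_dropped = n_drop),
            class = "utr_length_analysis")
}

#' @export
print.utr_length_analysis <- function(x, ...) {
  cat(sprintf("<utr_length_analysis> %d genes, Spearman rho = %s\n",
              nrow(x$data), format(x$spearman, digits = 3)))
  invisible(x)
}

#' @method tidy utr_length_analysis
#' @export
tidy.utr_length_analysis <- function(x, ...) x$data

#' @method glance utr_length_analysis
#' @export
glance.utr_length_analysis <- function(x, ...) {
  tibble(spearman = x$spearman, n_genes = nrow(x$data),
         n_dropped = x$n_dropped)
}

#' Co-localization of miRNA loci with genes
#'
#' A miRNA locus is co-localized with a gene when it intersects the gene's
#' full genomic span (introns included) extended by `window` bases on both
#' sides, on the same chromosome. With the half-open convention a locus
#' starting exactly `window` bases upstream of the span is included.
#'
#' @param mirna_loci Loci tibble (see [read_mirna_loci()]).
#' @param annotations Annotation tibble (uses `span_start`, `span_end`).
#' @param window Flank in bp added to each side of the gene span
#'   (default 20000, i.e. -/+20 kb).
#' @return An object of class `colocalization`: `pairs` tibble
#'   (`mirna_id`, `gene_id`) plus distinct `n_mirnas` and `n_genes`.
#' @export
colocalize_mirnas <- function(mirna_loci, annotations, window = 20000) {
  if (window < 0) abort("window must be >= 0")
  spans <- tibble(chrom = annotations$chrom,
                  start = pmax(0, annotations$span_start - window),
                  end = annotations$span_end + window)
  h <- overlap_table(mirna_loci, spans)
  pairs <- tibble(mirna_id = mirna_loci$mirna_id[h$query],
                  gene_id = annotations$gene_id[h$subject]) |>
    distinct() |>
    arrange(.data$mirna_id, .data$gene_id)
  structure(
    list(pairs = pairs, window = window,
         n_mirnas = length(unique(pairs$mirna_id)),
         n_genes = length(unique(pairs$gene_id))),
    class = "colocalization"
  )
}

#' @export
print.colocalization <- function(x, ...) {
  cat(sprintf(
    "<colocalization> %d miRNAs within -/+%g bp of %d genes (%d pairs)\n",
    x$n_mirnas, x$window, x$n_genes, nrow(x$pairs)))
  invisible(x)
}

#' @method tidy colocalization
#' @export
tidy.colocalization <- function(x, ...) x$pairs

#' @method glance colocalization
#' @export
glance.colocalization <- function(x, ...) {
  tibble(n_mirnas = x$n_mirnas, n_genes = x$n_genes,
         n_pairs = nrow(x$pairs), window = x$window)
}
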