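#' Filter predicted sites by score percentile within category
#'
#' Weak sites are removed independently within the conserved and
#' nonconserved categories: a site is retained iff its score strength lies
#' above the category's percentile threshold. Score strength defaults to the
#' negated context+ score (more negative score = stronger predicted
#' repression), so `pct_conserved = 50` keeps roughly the strongest half of
#' the conserved sites and `pct_nonconserved = 75` the strongest quarter of
#' the nonconserved ones. Thresholds use the nearest-rank convention and
#' ties at the threshold are all kept, so the retained fraction per category
#' is within `1/n` of `(100 - pct)/100`.
#'
#' @param sites Site tibble (see [read_site_table()]).
#' @param pct_conserved,pct_nonconserved Percentile cutoffs in `[0, 100]`.
#' @param direction `"strength"` ranks by negated context score (keep the
#'   most repressive sites); `"raw"` ranks by the score as given.
#' @return The filtered site tibble (row order preserved).
#' @export
#' @examples
#' sites <- tibble::tibble(
#'   gene_id = "g1", mirna_id = letters[1:4], species_id = "mmu",
#'   category = "conserved", context_score = c(-0.9, -0.5, -0.3, -0.1))
#' filter_sites_by_percentile(sites, pct_conserved = 50)
filter_sites_by_percentile <- function(sites, pct_conserved = 50,
                                       pct_nonconserved = 75,
                                       direction = c("strength", "raw")) {
  direction <- match.arg(direction)
  stopifnot(pct_conserved >= 0, pct_conserved <= 100,
            pct_nonconserved >= 0, pct_nonconserved <= 100)
  strength <- if (direction == "strength") -sites$context_score else
    sites$context_score
  keep <- rep(TRUE, nrow(sites))
  for (cat in c("conserved", "nonconserved")) {
    pct <- if (cat == "conserved") pct_conserved else pct_nonconserved
    idx <- which(sites$category == cat)
    if (length(idx) == 0) {
      inform(sprintf("no %s sites; percentile filter skipped for category",
                     cat))
      next
    }
    thr <- percentile_cutoff(strength[idx], pct)
    keep[idx] <- strength[idx] >= thr
  }
  sites[keep, , drop = FALSE]
}

#' Build a binary gene-by-miRNA interaction matrix
#'
#' Collapses site records into a binary incidence matrix: an entry is 1 iff
#' at least one (filtered) site exists for that gene/miRNA pair, so several
#' sites of the same miRNA in one 3'UTR count once, while one site shared by
#' two distinct miRNAs counts for both. The per-gene row sums are the
#' distinct-miRNA counts used throughout the downstream analyses.
#'
#' @param sites Site tibble; all records must belong to one species.
#' @param species_id Species the matrix belongs to; defaults to the single
#'   species present in `sites`.
#' @param gene_universe,mirna_universe Optional ids to include even without
#'   records (rows/columns of zeros), e.g. all annotated genes.
#' @return An object of class `interaction_matrix` with elements
#'   `species_id`, `gene_ids`, `mirna_ids`, `incidence` (0/1 integer
#'   matrix) and `counts` (tibble `gene_id`, `n_mirnas`).
#' @seealso [site_counts()], [tidy.interaction_matrix()]
#' @export
build_interaction_matrix <- function(sites, species_id = NULL,
                                     gene_universe = NULL,
                                     mirna_universe = NULL) {
  sp <- unique(sites$species_id)
  if (is.null(species_id)) {
    if (length(sp) > 1) {
      abort("records span several species; pass species_id explicitly")
    }
    species_id <- if (length(sp) == 1) sp else "unknown"
  } else if (length(sp) > 0 && !all(sp == species_id)) {
    abort(sprintf("records for species %s do not match species_id '%s'",
                  paste(setdiff(sp, species_id), collapse = ", "), species_id))
  }
  genes <- sort(unique(c(gene_universe, sites$gene_id)))
  mirnas <- sort(unique(c(mirna_universe, sites$mirna_id)))
  if (length(genes) == 0 || length(mirnas) == 0) {
    abort("cannot build an interaction matrix without genes and miRNAs")
  }
  inc <- matrix(0L, nrow = length(genes), ncol = length(mirnas),
                dimnames = list(genes, mirnas))
  if (nrow(sites) > 0) {
    pairs <- dplyr::distinct(sites, .data$gene_id, .data$mirna_id)
    inc[cbind(match(pairs$gene_id, genes), match(pairs$mirna_id, mirnas))] <- 1L
  }
  new_interaction_matrix(species_id, inc)
}

new_interaction_matrix <- function(species_id, incidence) {
  structure(
    list(
      species_id = species_id,
      gene_ids = rownames(incidence),
      mirna_ids = colnames(incidence),
      incidence = incidence,
      counts = tibble(gene_id = rownames(incidence),
                      n_mirnas = as.integer(rowSums(incidence)))
    ),
    class = "interaction_matrix"
  )
}

#' Per-gene distinct-miRNA counts
#'
#' @param x An `interaction_matrix`, or a tibble already holding columns
#'   `gene_id` and `n_mirnas` (returned unchanged).
#' @return A tibble `gene_id`, `n_mirnas`.
#' @export
site_counts <- function(x) {
  if (inherits(x, "interaction_matrix")) return(x$counts)
  if (is.data.frame(x)) {
    check_columns(x, c("gene_id", "n_mirnas"), "count table")
    return(as_tibble(x[, c("gene_id", "n_mirnas")]))
  }
  abort("expected an interaction_matrix or a gene_id/n_mirnas data frame")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "<interaction_matrix> %s: %d genes x %d miRNAs, %d interactions\n",
    x$species_id, length(x$gene_ids), length(x$mirna_ids), sum(x$incidence)))
  invisible(x)
}

#' @export
dim.interaction_matrix <- function(x) dim(x$incidence)

#' Tidy an interaction matrix into its gene/miRNA pairs
#'
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return A tibble `gene_id`, `mirna_id`, `species_id`, one row per
#'   interaction (incidence entry equal to 1).
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  idx <- which(x$incidence == 1L, arr.ind = TRUE)
  tibble(gene_id = x$gene_ids[idx[, 1]],
         mirna_id = x$mirna_ids[idx[, 2]],
         species_id = x$species_id) |>
    arrange(.data$gene_id, .data$mirna_id)
}

#' One-row summary of an interaction matrix
#'
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return A tibble with `species_id`, `n_genes`, `n_mirnas`,
#'   `n_interactions`, `density`.
#' @method glance interaction_matrix
#' @export
glance.interaction_matrix <- function(x, ...) {
  n_int <- sum(x$incidence)
  tibble(species_id = x$species_id,
         n_genes = length(x$gene_ids),
         n_mirnas = length(x$mirna_ids),
         n_interactions = n_int,
         density = n_int / length(x$incidence))
}
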