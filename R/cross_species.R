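# Cross-species normalized site counts and distance-ordered trajectories.
# Species enter only through their distance rank to the reference; no branch
# lengths are used.

#' Normalize per-gene counts to the species average
#'
#' Divides each gene's distinct-miRNA count by the mean count over all
#' genes present in that species' matrix, so species with different numbers
#' of annotated miRNAs become comparable; the normalized counts average to
#' 1 in every species by construction.
#'
#' @param x An `interaction_matrix` or tibble `gene_id`, `n_mirnas`.
#' @param nonzero_only Use only genes with at least one site in the
#'   normalization mean (default FALSE: every gene in the matrix counts).
#' @return A tibble `gene_id`, `n_mirnas`, `norm_count`.
#' @export
normalized_counts <- function(x, nonzero_only = FALSE) {
  counts <- site_counts(x)
  if (nrow(counts) == 0) abort("empty matrix")
  denom <- if (nonzero_only) {
    mean(counts$n_mirnas[counts$n_mirnas > 0])
  } else {
    mean(counts$n_mirnas)
  }
  if (!is.finite(denom) || denom <= 0) {
    abort("all-zero matrix: species mean count is not positive")
  }
  mutate(counts, norm_count = .data$n_mirnas / denom)
}

#' Bundle per-species interaction matrices with their distance order
#'
#' @param matrices Named list of `interaction_matrix` objects, one per
#'   species (names = species ids); each matrix should be restricted to the
#'   genes with an orthologous 3'UTR in that species.
#' @param species Tibble `species_id`, `distance_rank`; exactly one species
#'   (the reference) must have rank 0 and ranks must be unique.
#' @return An object of class `species_panel`.
#' @export
species_panel <- function(matrices, species) {
  check_columns(species, c("species_id", "distance_rank"), "species table")
  if (anyDuplicated(species$distance_rank)) {
    abort("distance ranks must be unique")
  }
  if (sum(species$distance_rank == 0) != 1) {
    abort("exactly one species (the reference) must have distance rank 0")
  }
  missing <- setdiff(species$species_id, names(matrices))
  if (length(missing) > 0) {
    abort(sprintf("no matrix for species: %s", paste(missing, collapse = ", ")))
  }
  species <- arrange(species, .data$distance_rank)
  structure(
    list(species = species,
         matrices = matrices[species$species_id],
         reference_species = species$species_id[species$distance_rank == 0]),
    class = "species_panel"
  )
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf("<species_panel> %d species, reference '%s'\n",
              nrow(x$species), x$reference_species))
  invisible(x)
}

#' Mean normalized site count of a gene group across species
#'
#' For each species, averages the normalized distinct-miRNA counts over the
#' group members present in that species (after translating reference gene
#' ids through the ortholog map, when given). Members absent from a species
#' are excluded from that species' mean with a notice; a species with no
#' members yields an `NA` point.
#'
#' @param panel A `species_panel`.
#' @param gene_group Character vector of reference-species gene ids (e.g. a
#'   quartile set).
#' @param ortholog_map Optional tibble `ref_gene_id`, `species_id`,
#'   `gene_id`; identity mapping is assumed when absent.
#' @param group_name Label carried into the result.
#' @param nonzero_only Passed to [normalized_counts()].
#' @return An object of class `gene_trajectory`: trajectory tibble
#'   (`species_id`, `distance_rank`, `mean_norm_count`, `n_genes`) ordered
#'   by distance, plus the Spearman trend statistic.
#' @export
group_trajectory <- function(panel, gene_group, ortholog_map = NULL,
                             group_name = "group", nonzero_only = FALSE) {
  stopifnot(inherits(panel, "species_panel"))
  n_missing_total <- 0L
  rows <- purrr::pmap(
    list(panel$species$species_id, panel$species$distance_rank),
    function(sp, rank) {
      ids <- if (is.null(ortholog_map)) {
        gene_group
      } else if (sp == panel$reference_species) {
        gene_group
      } else {
        ortholog_map$gene_id[ortholog_map$species_id == sp &
                               ortholog_map$ref_gene_id %in% gene_group]
      }
      nc <- normalized_counts(panel$matrices[[sp]], nonzero_only)
      vals <- nc$norm_count[nc$gene_id %in% ids]
      n_missing_total <<- n_missing_total + (length(gene_group) - length(vals))
      tibble(species_id = sp, distance_rank = rank,
             mean_norm_count = if (length(vals) > 0) mean(vals) else NA_real_,
             n_genes = length(vals))
    }
  )
  traj <- dplyr::bind_rows(rows) |> arrange(.data$distance_rank)
  if (n_missing_total > 0) {
    inform(sprintf(
      "group_trajectory(%s): %d group membership(s) absent across species",
      group_name, n_missing_total))
  }
  trend <- trend_statistic(traj)
  structure(list(group_name = group_name, trajectory = traj, trend = trend),
            class = "gene_trajectory")
}

#' Monotone trend of a trajectory with evolutionary distance
#'
#' Spearman correlation between distance rank and the group's mean
#' normalized count: +1 means the group's relative site load increases
#' monotonically with distance from the reference. `NA` (with a notice) for
#' a constant trajectory.
#'
#' @param trajectory A `gene_trajectory` or its trajectory tibble
#'   (`distance_rank`, `mean_norm_count`).
#' @return A single correlation in `[-1, 1]` or `NA`.
#' @export
trend_statistic <- function(trajectory) {
  if (inherits(trajectory, "gene_trajectory")) {
    trajectory <- trajectory$trajectory
  }
  check_columns(trajectory, c("distance_rank", "mean_norm_count"),
                "trajectory")
  ok <- is.finite(trajectory$mean_norm_count)
  if (sum(ok) < 3) abort("need at least 3 non-missing trajectory points")
  spearman_cor(trajectory$distance_rank[ok], trajectory$mean_norm_count[ok])
}

#' @export
print.gene_trajectory <- function(x, ...) {
  cat(sprintf("<gene_trajectory> %s over %d species, trend = %s\n",
              x$group_name, nrow(x$trajectory),
              format(x$trend, digits = 3)))
  invisible(x)
}

#' @method tidy gene_trajectory
#' @export
tidy.gene_trajectory <- function(x, ...) {
  mutate(x$trajectory, group = x$group_name, .before = 1)
}

#' @method glance gene_trajectory
#' @export
glance.gene_trajectory <- function(x, ...) {
  tibble(group = x$group_name, trend = x$trend,
         n_species = nrow(x$trajectory),
         n_missing = sum(!is.finite(x$trajectory$mean_norm_count)))
}
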