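# Writers paired with the readers in read.R. Writing a parsed table and
# re-parsing it yields identical records (round-trip tested).

#' Write a site table (generic dialect)
#'
#' @param sites Site tibble as returned by [read_site_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

#' Write gene annotations as BED12
#'
#' Exons are reconstructed as the union of the CDS and 3'UTR intervals; the
#' thick range is the CDS extent. Genes whose annotation carries exonic
#' structure beyond CDS + 3'UTR do not round-trip exactly (the extra exons
#' are not represented here).
#'
#' @param annotations Annotation tibble from [read_annotation()].
#' @param path Output BED12 path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path) {
  lines <- purrr::pmap_chr(
    list(annotations$gene_id, annotations$chrom, annotations$strand,
         annotations$span_start, annotations$span_end,
         annotations$utr3, annotations$cds),
    function(g, ch, st, ss, se, utr3, cds) {
      exons <- normalize_intervals(dplyr::bind_rows(utr3, cds))
      if (nrow(exons) == 0) exons <- tibble(start = ss, end = se)
      thick_s <- if (nrow(cds) > 0) min(cds$start) else ss
      thick_e <- if (nrow(cds) > 0) max(cds$end) else ss
      paste(ch, ss, se, g, 0L, st, thick_s, thick_e, "0",
            nrow(exons),
            paste0(paste(exons$end - exons$start, collapse = ","), ","),
            paste0(paste(exons$start - ss, collapse = ","), ","),
            sep = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write an expression table
#' @param expression Expression tibble (first column `gene_id`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Write a score track as bedGraph
#' @param track Track tibble (`chrom`, `start`, `end`, `score`).
#' @param path Output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  readr::write_tsv(track, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write repeat annotations
#' @param repeats Repeat tibble (`chrom`, `start`, `end`, `repeat_class`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(repeats, path) {
  readr::write_tsv(repeats, path, progress = FALSE)
  invisible(path)
}

#' Write a gene set, one id per line
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  readr::write_lines(unique(genes), path)
  invisible(path)
}

#' Write miRNA loci as BED
#' @param loci Loci tibble (`mirna_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_mirna_loci <- function(loci, path) {
  out <- tibble(loci$chrom, loci$start, loci$end, loci$mirna_id, 0L,
                loci$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a species ladder
#' @param species Tibble with `species_id`, `distance_rank`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(species, path) {
  readr::write_tsv(species, path, progress = FALSE)
  invisible(path)
}

#' Write an ortholog map
#' @param map Tibble with `ref_gene_id`, `species_id`, `gene_id`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Write an interaction matrix
#'
#' The matrix is written as TSV with `gene_id` in the first column and one
#' 0/1 column per miRNA; per-gene distinct-miRNA counts go to a two-column
#' sidecar when `counts_path` is given.
#'
#' @param x An `interaction_matrix`.
#' @param path Output TSV path.
#' @param counts_path Optional path for the `gene_id`/`n_mirnas` sidecar.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(x, path, counts_path = NULL) {
  stopifnot(inherits(x, "interaction_matrix"))
  wide <- as_tibble(x$incidence, .name_repair = "minimal")
  names(wide) <- x$mirna_ids
  wide <- dplyr::bind_cols(tibble(gene_id = x$gene_ids), wide)
  readr::write_tsv(wide, path, progress = FALSE)
  if (!is.null(counts_path)) {
    readr::write_tsv(x$counts, counts_path, progress = FALSE)
  }
  invisible(path)
}
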