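#' Promoter windows around transcription start sites
#'
#' Returns the `[tss - flank, tss + flank)` window for every gene, clipped
#' to the chromosome bounds, the region whose sequence composition serves
#' as a proxy for nucleosome occupancy and intrinsic transcriptional noise.
#'
#' @param annotations Annotation tibble (see [read_annotation()]).
#' @param flank Half-width of the window in bp (default 1000, i.e. +/-1 kb).
#' @param chrom_sizes Named vector or tibble (`chrom`, `size`) of
#'   chromosome lengths used for clipping.
#' @return A tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
promoter_windows <- function(annotations, flank = 1000, chrom_sizes) {
  if (flank <= 0) abort("flank must be a positive number of bases")
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  }
  size <- unname(chrom_sizes[annotations$chrom])
  if (any(is.na(size))) {
    abort(sprintf("no chromosome length for '%s'",
                  annotations$chrom[is.na(size)][1]))
  }
  bad <- annotations$tss < 0 | annotations$tss >= size
  if (any(bad)) {
    abort(sprintf("TSS of gene %s lies outside its chromosome",
                  annotations$gene_id[bad][1]))
  }
  tibble(
    gene_id = annotations$gene_id,
    chrom = annotations$chrom,
    start = pmax(0L, as.integer(annotations$tss - flank)),
    end = pmin(as.integer(size), as.integer(annotations$tss + flank))
  )
}

as_dna <- function(x) {
  if (inherits(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
}

#' GC fraction of sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from numerator and
#' denominator. An all-`N` (or empty) sequence yields `NA`.
#'
#' @param x Character vector or [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
#' @examples
#' gc_content(c("GGCC", "ACGT", "ANGT"))
gc_content <- function(x) {
  x <- as_dna(x)
  lf <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  acgt <- rowSums(lf)
  out <- ifelse(acgt == 0, NA_real_, (lf[, "C"] + lf[, "G"]) / acgt)
  unname(out)
}

#' Nucleosome favoring/disfavoring dinucleotide counts and ratio
#'
#' Counts overlapping (step 1) dinucleotides: favoring = GC, CG, GG;
#' disfavoring = AA, CA, AC. Windows containing `N` are skipped. The ratio
#' favoring/disfavoring is `NA` when no disfavoring dinucleotide occurs;
#' such genes are excluded (not imputed) from downstream bin averages.
#'
#' @param x Character vector or [Biostrings::DNAStringSet] (length >= 2 each).
#' @return A tibble `fav_count`, `disfav_count`, `dinuc_ratio` (one row per
#'   sequence, named rows following `names(x)` when present).
#' @export
#' @examples
#' dinucleotide_counts("GCAA")  # fav 1 (GC), disfav 2 (CA, AA), ratio 0.5
dinucleotide_counts <- function(x) {
  x <- as_dna(x)
  if (any(Biostrings::width(x) < 2)) {
    abort("sequences must have length >= 2 to count dinucleotides")
  }
  dn <- Biostrings::oligonucleotideFrequency(x, width = 2, step = 1)
  fav <- as.integer(dn[, "GC"] + dn[, "CG"] + dn[, "GG"])
  disfav <- as.integer(dn[, "AA"] + dn[, "CA"] + dn[, "AC"])
  tibble(
    fav_count = fav,
    disfav_count = disfav,
    dinuc_ratio = ifelse(disfav > 0, fav / disfav, NA_real_)
  )
}

#' Promoter sequence features: GC content and dinucleotide ratio
#'
#' Computes the two promoter-composition noise proxies for each gene. By
#' default sequences are interpreted on the gene's annotated strand
#' (`strand_mode = "sense"`): when `annotations` are supplied, minus-strand
#' promoters are reverse-complemented before counting. Pass
#' `strand_mode = "plus"` to count sequences exactly as given.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet]
#'   keyed by gene id (e.g. from [read_promoter_fasta()]).
#' @param annotations Optional annotation tibble supplying strands.
#' @param strand_mode `"sense"` or `"plus"`.
#' @return A tibble `gene_id`, `gc_fraction`, `fav_count`, `disfav_count`,
#'   `dinuc_ratio`.
#' @export
promoter_features <- function(sequences, annotations = NULL,
                              strand_mode = c("sense", "plus")) {
  strand_mode <- match.arg(strand_mode)
  sequences <- as_dna(sequences)
  if (is.null(names(sequences))) {
    abort("promoter sequences must be named by gene id")
  }
  if (strand_mode == "sense" && !is.null(annotations)) {
    strand <- setNames(annotations$strand, annotations$gene_id)
    flip <- which(strand[names(sequences)] == "-")
    if (length(flip) > 0) {
      sequences[flip] <- Biostrings::reverseComplement(sequences[flip])
    }
  }
  bind_cols(
    tibble(gene_id = names(sequences), gc_fraction = gc_content(sequences)),
    dinucleotide_counts(sequences)
  )
}
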