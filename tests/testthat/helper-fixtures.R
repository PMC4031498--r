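# Shared fixture builders. Everything is generated in code; tests set their
# own seeds so each block is reproducible in isolation.

make_sites <- function(gene_id, mirna_id, species_id = "s00",
                       category = "conserved", context_score = -0.5,
                       utr_start = NA_integer_, utr_end = NA_integer_) {
  tibble::tibble(gene_id = gene_id, mirna_id = mirna_id,
                 species_id = species_id, category = category,
                 context_score = context_score,
                 utr_start = as.integer(utr_start),
                 utr_end = as.integer(utr_end))
}

random_sites <- function(n_records, n_genes = 20, n_mirnas = 10,
                         species_id = "s00") {
  make_sites(
    gene_id = sprintf("g%03d", sample.int(n_genes, n_records, replace = TRUE)),
    mirna_id = sprintf("m%02d", sample.int(n_mirnas, n_records, replace = TRUE)),
    species_id = species_id,
    category = sample(c("conserved", "nonconserved"), n_records,
                      replace = TRUE),
    context_score = -round(runif(n_records, 0.01, 1), 3)
  )
}

write_tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# minimal annotation row with explicit interval lists
make_annotation <- function(gene_id, chrom = "chr1", strand = "+",
                            tss, span_start, span_end, utr3, cds) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = tss, span_start = span_start, span_end = span_end,
                 utr3 = utr3, cds = cds)
}

iv <- function(...) {
  if (...length() == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_genes = 100, n_mirnas = 40,
                   n_samples = 20, n_species = 4, ...)
}

# sample one integer uniformly from [lo, hi], safe when lo == hi
sample_between <- function(lo, hi) {
  if (lo >= hi) return(lo)
  sample(seq(lo, hi), 1)
}
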