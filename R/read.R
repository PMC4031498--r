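#' Read a miRNA target-site table
#'
#' Parses tab-delimited site predictions into a tidy site table with one row
#' per predicted site. Three dialects are supported:
#'
#' * `"generic"`: columns `gene_id`, `mirna_id`, `species_id`, `category`,
#'   `context_score` and optionally `utr_start`, `utr_end` (0-based
#'   half-open positions within the 3'UTR).
#' * `"targetscan"`: the "site context+ score" layout with columns
#'   `Gene Symbol`, `miRNA`, `Species ID`, `Site type`, `context+ score` and
#'   optionally `UTR_start`, `UTR_end` (1-based inclusive, converted).
#' * `"miranda"`: mirSVR-scored predictions with columns `gene_symbol`,
#'   `mirna_name`, `species_id`, `category`, `mirsvr_score`; rows with a
#'   mirSVR score above `mirsvr_cutoff` (i.e. weaker than the cutoff, scores
#'   being negative) are dropped. The published analyses only say that
#'   "good" mirSVR scores were kept, so the cutoff is a user setting.
#'
#' Duplicate records (same gene, miRNA and position) are retained: collapsing
#' them is the job of [build_interaction_matrix()].
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect One of `"generic"`, `"targetscan"`, `"miranda"`.
#' @param mirsvr_cutoff Keep miranda rows with score `<=` this value
#'   (default -0.1; more negative = stronger predicted repression).
#' @return A tibble with columns `gene_id`, `mirna_id`, `species_id`,
#'   `category` (`"conserved"` or `"nonconserved"`), `context_score`,
#'   `utr_start`, `utr_end`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tmirna_id\tspecies_id\tcategory\tcontext_score",
#'              "g1\tmiR-a\tmmu\tconserved\t-0.31"), f)
#' read_site_table(f)
read_site_table <- function(path,
                            dialect = c("generic", "targetscan", "miranda"),
                            mirsvr_cutoff = -0.1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  map <- switch(dialect,
    generic = c(gene_id = "gene_id", mirna_id = "mirna_id",
                species_id = "species_id", category = "category",
                context_score = "context_score",
                utr_start = "utr_start", utr_end = "utr_end"),
    targetscan = c(gene_id = "Gene Symbol", mirna_id = "miRNA",
                   species_id = "Species ID", category = "Site type",
                   context_score = "context+ score",
                   utr_start = "UTR_start", utr_end = "UTR_end"),
    miranda = c(gene_id = "gene_symbol", mirna_id = "mirna_name",
                species_id = "species_id", category = "category",
                context_score = "mirsvr_score",
                utr_start = "utr_start", utr_end = "utr_end")
  )
  mandatory <- map[c("gene_id", "mirna_id", "species_id", "category",
                     "context_score")]
  check_columns(raw, unname(mandatory), sprintf("site table (%s)", dialect))
  out <- tibble(
    gene_id = raw[[map[["gene_id"]]]],
    mirna_id = raw[[map[["mirna_id"]]]],
    species_id = raw[[map[["species_id"]]]],
    category = tolower(gsub("[ _-]", "", raw[[map[["category"]]]])),
    context_score = parse_numeric_column(raw[[map[["context_score"]]]],
                                         map[["context_score"]], "site table")
  )
  has_pos <- all(map[c("utr_start", "utr_end")] %in% names(raw))
  if (has_pos) {
    # positions are optional per record; absent entries stay NA
    out$utr_start <- suppressWarnings(as.numeric(raw[[map[["utr_start"]]]]))
    out$utr_end <- suppressWarnings(as.numeric(raw[[map[["utr_end"]]]]))
    if (dialect == "targetscan") {
      # 1-based inclusive -> 0-based half-open
      out$utr_start <- out$utr_start - 1
    }
    out$utr_start <- as.integer(out$utr_start)
    out$utr_end <- as.integer(out$utr_end)
    bad <- which(out$utr_start >= out$utr_end)
    if (length(bad) > 0) {
      format_error(sprintf("site table: utr_start >= utr_end at line %d",
                           bad[1] + 1L))
    }
  } else {
    out$utr_start <- NA_integer_
    out$utr_end <- NA_integer_
  }
  out$category <- ifelse(out$category %in% c("conserved", "c"), "conserved",
                         ifelse(out$category %in% c("nonconserved", "nc"),
                                "nonconserved", out$category))
  bad <- which(!out$category %in% c("conserved", "nonconserved"))
  if (length(bad) > 0) {
    format_error(sprintf(
      "site table: unknown site category '%s' at line %d",
      out$category[bad[1]], bad[1] + 1L))
  }
  if (any(!nzchar(out$gene_id)) || any(!nzchar(out$mirna_id))) {
    format_error("site table: empty gene_id or mirna_id")
  }
  if (dialect == "miranda") {
    out <- out[out$context_score <= mirsvr_cutoff, , drop = FALSE]
  }
  out
}

#' Read gene annotations
#'
#' Parses gene models into one row per gene with the transcription start
#' site, the full genomic span and normalized (union-merged) 3'UTR and CDS
#' interval lists. All output coordinates are 0-based half-open; the TSS of
#' a minus-strand gene is its rightmost transcript coordinate.
#'
#' * `format = "bed12"`: headerless BED12; blocks are exons, the thick range
#'   is the CDS extent, the 3'UTR is the exonic part 3' of the thick range
#'   on the annotated strand.
#' * `format = "gtf"`: GTF-like 9-column rows (1-based inclusive, converted)
#'   using features `transcript`/`exon` (span), `CDS` and
#'   `three_prime_utr`; `gene_id` is taken from the attributes column.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `span_start`, `span_end` and list-columns `utr3`, `cds` of
#'   `(start, end)` tibbles.
#' @export
read_annotation <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  if (format == "bed12") parse_bed12(path) else parse_gtf(path)
}

parse_bed12 <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 12) format_error("bed12 annotation needs 12 columns")
  chrom <- raw[[1]]
  start <- as.integer(raw[[2]]); end <- as.integer(raw[[3]])
  gene_id <- raw[[4]]
  strand <- raw[[6]]
  thick_s <- as.integer(raw[[7]]); thick_e <- as.integer(raw[[8]])
  sizes <- strsplit(gsub(",$", "", raw[[11]]), ",")
  offs <- strsplit(gsub(",$", "", raw[[12]]), ",")
  if (any(!strand %in% c("+", "-"))) {
    format_error("bed12 annotation: strand must be '+' or '-'")
  }
  rows <- purrr::pmap(
    list(chrom, start, end, gene_id, strand, thick_s, thick_e, sizes, offs),
    function(ch, s, e, g, st, ts, te, sz, of) {
      sz <- as.integer(sz); of <- as.integer(of)
      ex_s <- s + of
      ex_e <- ex_s + sz
      if (any(ex_s >= ex_e) || s >= e) {
        format_error(sprintf("bed12 annotation: empty interval for gene %s", g))
      }
      exons <- tibble(start = ex_s, end = ex_e)
      cds <- clip_intervals(exons, ts, te)
      utr3 <- if (st == "+") clip_intervals(exons, te, e) else
        clip_intervals(exons, s, ts)
      tibble(
        gene_id = g, chrom = ch, strand = st,
        tss = if (st == "+") s else e - 1L,
        span_start = s, span_end = e,
        utr3 = list(normalize_intervals(utr3)),
        cds = list(normalize_intervals(cds))
      )
    }
  )
  dplyr::bind_rows(rows)
}

# intersect exon intervals with a [lo, hi) window
clip_intervals <- function(iv, lo, hi) {
  if (is.na(lo) || is.na(hi) || lo >= hi) {
    return(tibble(start = integer(), end = integer()))
  }
  s <- pmax(iv$start, lo); e <- pmin(iv$end, hi)
  keep <- s < e
  tibble(start = s[keep], end = e[keep])
}

parse_gtf <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 9) format_error("gtf annotation needs 9 columns")
  gene_id <- sub(".*gene_id[ =\"]+([^\";]+).*", "\\1", raw[[9]])
  # 1-based inclusive -> 0-based half-open
  start <- as.integer(raw[[4]]) - 1L
  end <- as.integer(raw[[5]])
  if (any(start >= end)) {
    format_error("gtf annotation: start >= end after coordinate conversion")
  }
  feat <- tolower(raw[[3]])
  d <- tibble(gene_id = gene_id, chrom = raw[[1]], strand = raw[[7]],
              feature = feat, start = start, end = end)
  if (any(!d$strand %in% c("+", "-"))) {
    format_error("gtf annotation: strand must be '+' or '-'")
  }
  d |>
    group_by(.data$gene_id) |>
    group_modify(function(g, key) {
      span_s <- min(g$start); span_e <- max(g$end)
      st <- g$strand[1]
      utr3 <- g[g$feature %in% c("three_prime_utr", "3utr", "utr3"),
                c("start", "end")]
      cds <- g[g$feature == "cds", c("start", "end")]
      tibble(
        chrom = g$chrom[1], strand = st,
        tss = if (st == "+") span_s else span_e - 1L,
        span_start = span_s, span_end = span_e,
        utr3 = list(normalize_intervals(utr3)),
        cds = list(normalize_intervals(cds))
      )
    }) |>
    ungroup()
}

#' Read a genes-by-samples expression table
#'
#' @param path TSV with a header; first column `gene_id`, remaining columns
#'   numeric sample intensities on a linear scale.
#' @return A tibble (genes in rows, one column per sample).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) format_error("expression table needs >= 2 columns")
  names(raw)[1] <- "gene_id"
  if (anyDuplicated(raw$gene_id)) {
    format_error(sprintf("expression table: duplicate gene_id '%s'",
                         raw$gene_id[duplicated(raw$gene_id)][1]))
  }
  for (cn in names(raw)[-1]) {
    raw[[cn]] <- parse_numeric_column(raw[[cn]], cn, "expression table")
  }
  raw
}

#' Read a per-base score track (bedGraph)
#'
#' Intervals are 0-based half-open. Unsorted input is sorted with a notice;
#' overlapping intervals on one chromosome are a format error.
#'
#' @param path bedGraph file (`chrom start end score`), no header required;
#'   `track`/`#` lines are skipped.
#' @return A tibble `chrom`, `start`, `end`, `score`, sorted by position.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  raw <- readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "score"),
                         col_types = "ciid", progress = FALSE,
                         show_col_types = FALSE)
  if (any(is.na(raw$start)) || any(is.na(raw$score))) {
    format_error("track: malformed bedGraph line")
  }
  if (any(raw$start >= raw$end)) format_error("track: start >= end")
  resorted <- raw |> arrange(.data$chrom, .data$start)
  if (!identical(resorted$start, raw$start) ||
      !identical(resorted$chrom, raw$chrom)) {
    inform("track was not position-sorted; sorted internally")
  }
  overlap <- resorted |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start < dplyr::lag(.data$end, default = -1L)),
              .groups = "drop")
  if (any(overlap$bad)) format_error("track: overlapping intervals")
  resorted
}

#' Read repeat annotations
#'
#' Accepts a headered TSV with columns `chrom`, `start`, `end`,
#' `repeat_class`, or the RepeatMasker rmsk column names
#' (`genoName`, `genoStart`, `genoEnd`, `repClass`).
#'
#' @param path TSV file of repeat intervals (0-based half-open).
#' @return A tibble `chrom`, `start`, `end`, `repeat_class`.
#' @export
read_repeats <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  rmsk <- c(chrom = "genoName", start = "genoStart", end = "genoEnd",
            repeat_class = "repClass")
  if (all(rmsk %in% names(raw))) {
    raw <- raw |> rename(!!!rmsk)
  }
  check_columns(raw, c("chrom", "start", "end", "repeat_class"), "repeat table")
  out <- tibble(
    chrom = raw$chrom,
    start = as.integer(parse_numeric_column(raw$start, "start", "repeat table")),
    end = as.integer(parse_numeric_column(raw$end, "end", "repeat table")),
    repeat_class = raw$repeat_class
  )
  if (any(out$start >= out$end)) format_error("repeat table: start >= end")
  out
}

#' Read a gene set (one id per line)
#'
#' @param path Text file, one gene id per line; duplicates are collapsed.
#' @param name Optional set name stored as an attribute.
#' @return Character vector of unique gene ids.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- unique(ids[nzchar(ids)])
  attr(ids, "set_name") <- name %n% basename(path)
  ids
}

#' Read miRNA genomic loci (BED)
#'
#' @param path BED file with at least 4 columns
#'   (`chrom start end name [score strand]`), 0-based half-open.
#' @return A tibble `mirna_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_mirna_loci <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 4) format_error("miRNA loci BED needs >= 4 columns")
  out <- tibble(
    mirna_id = raw[[4]],
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = if (ncol(raw) >= 6) raw[[6]] else "+"
  )
  if (any(out$start >= out$end)) format_error("miRNA loci: start >= end")
  out
}

#' Read a species ladder
#'
#' @param path TSV with header columns `species_id`, `distance_rank`
#'   (rank 0 = reference species).
#' @return A tibble ordered by `distance_rank`.
#' @export
read_species_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ci", progress = FALSE,
                         show_col_types = FALSE)
  check_columns(raw, c("species_id", "distance_rank"), "species table")
  arrange(raw, .data$distance_rank)
}

#' Read an ortholog map
#'
#' @param path TSV with header columns `ref_gene_id`, `species_id`, `gene_id`
#'   mapping reference genes to their orthologs in each species.
#' @return A tibble with those three columns.
#' @export
read_ortholog_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE,
                         show_col_types = FALSE)
  check_columns(raw, c("ref_gene_id", "species_id", "gene_id"), "ortholog map")
  raw
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file keyed by gene id.
#' @return A [Biostrings::DNAStringSet] named by gene id.
#' @export
read_promoter_fasta <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  Biostrings::readDNAStringSet(path)
}
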