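# End-to-end orchestration: load inputs, build matrices, stratify, overlay
# features and write a machine-readable report. Stages with missing inputs
# are recorded as SKIPPED, never dropped silently.

#' Analysis parameters for the full pipeline
#'
#' @param pct_conserved,pct_nonconserved Score-percentile cutoffs for the
#'   site filter (see [filter_sites_by_percentile()]).
#' @param filter_direction `"strength"` or `"raw"`.
#' @param flank Promoter half-width in bp.
#' @param coloc_window Co-localization window in bp.
#' @param log2_expression Compute CV on log2 intensities.
#' @param n_bins Number of rank bins for the binned scatters.
#' @param strand_mode Promoter strand handling (see [promoter_features()]).
#' @param mirsvr_cutoff Cutoff for miranda-dialect site tables.
#' @param site_dialect Dialect of the site tables on disk.
#' @return A named list of validated parameters.
#' @export
pipeline_params <- function(pct_conserved = 50, pct_nonconserved = 75,
                            filter_direction = "strength",
                            flank = 1000, coloc_window = 20000,
                            log2_expression = FALSE, n_bins = 20,
                            strand_mode = "sense", mirsvr_cutoff = -0.1,
                            site_dialect = "generic") {
  params <- as.list(environment())
  stopifnot(pct_conserved >= 0, pct_conserved <= 100,
            pct_nonconserved >= 0, pct_nonconserved <= 100,
            flank > 0, coloc_window >= 0, n_bins >= 2)
  params
}

load_inputs <- function(inputs, params) {
  if (inherits(inputs, "mir_simulation")) {
    return(list(
      sites = inputs$sites, species = inputs$species,
      orthologs = inputs$ortholog_map, expression = inputs$expression,
      promoters = inputs$promoters, annotations = inputs$annotations,
      track = inputs$track, repeats = inputs$repeats,
      mirna_loci = inputs$mirna_loci, tf_genes = inputs$tf_set,
      chrom_sizes = inputs$chrom_sizes
    ))
  }
  rd <- function(x, f) if (is.null(x)) NULL else f(x)
  site_paths <- inputs$sites
  if (is.character(site_paths)) site_paths <- as.list(site_paths)
  sites <- lapply(site_paths, read_site_table, dialect = params$site_dialect,
                  mirsvr_cutoff = params$mirsvr_cutoff)
  cs <- rd(inputs$chrom_sizes, function(p) {
    d <- readr::read_tsv(p, col_types = "ci", progress = FALSE,
                         show_col_types = FALSE)
    setNames(d$size, d$chrom)
  })
  list(
    sites = sites,
    species = rd(inputs$species, read_species_table),
    orthologs = rd(inputs$orthologs, read_ortholog_map),
    expression = rd(inputs$expression, read_expression),
    promoters = rd(inputs$promoters, read_promoter_fasta),
    annotations = rd(inputs$annotations, read_annotation),
    track = rd(inputs$track, read_track),
    repeats = rd(inputs$repeats, read_repeats),
    mirna_loci = rd(inputs$mirna_loci, read_mirna_loci),
    tf_genes = rd(inputs$tf_genes, read_gene_set),
    chrom_sizes = cs
  )
}

#' Run the full site-distribution analysis
#'
#' Executes the stages in dependency order: site filtering and matrix
#' construction, quartile/vigintile stratification, promoter features,
#' expression variability, gene-set enrichment, conservation, repeats,
#' 3'UTR length, co-localization and the cross-species trend analysis.
#' Stages whose inputs are absent are reported as `"skipped"`. Re-running
#' on identical inputs reproduces identical report values.
#'
#' @param inputs A `mir_simulation` or a named list of file paths as
#'   produced by [bundle_inputs()] (`sites` must be a named list/vector of
#'   per-species site tables; other entries are optional).
#' @param params Parameters from [pipeline_params()].
#' @return An object of class `mir_report`: list with a `summary` (nested
#'   list of per-stage statistics), `tables` (tibbles backing every
#'   number) and the parameters used.
#' @export
run_pipeline <- function(inputs, params = pipeline_params()) {
  x <- load_inputs(inputs, params)
  if (length(x$sites) == 0) abort("no site tables supplied")
  summary <- list(schema_version = "1.0", params = params[order(names(params))])
  tables <- list()

  # reference species id: rank 0 if a ladder is given, else first table
  ref_id <- if (!is.null(x$species)) {
    x$species$species_id[x$species$distance_rank == 0]
  } else {
    names(x$sites)[1]
  }
  gene_universe <- if (!is.null(x$annotations)) x$annotations$gene_id else NULL

  filtered <- lapply(x$sites, filter_sites_by_percentile,
                     pct_conserved = params$pct_conserved,
                     pct_nonconserved = params$pct_nonconserved,
                     direction = params$filter_direction)
  matrices <- lapply(names(filtered), function(sp) {
    build_interaction_matrix(filtered[[sp]], species_id = sp,
                             gene_universe = gene_universe)
  })
  names(matrices) <- names(filtered)
  ref_matrix <- matrices[[ref_id]]
  summary$matrix <- c(
    list(status = "ok", reference_species = ref_id,
         n_records_in = sum(vapply(x$sites, nrow, 0L)),
         n_records_filtered = sum(vapply(filtered, nrow, 0L))),
    as.list(glance(ref_matrix))
  )
  counts <- site_counts(ref_matrix)
  tables$counts <- counts

  strata <- assign_quartile_groups(counts)
  vig <- assign_vigintiles(counts, n_bins = params$n_bins)
  summary$stratify <- c(list(status = "ok"), as.list(glance(strata)))
  tables$strata <- tidy(strata)
  tables$vigintiles <- vig

  run_stage <- function(name, needed, fn) {
    if (any(vapply(needed, is.null, TRUE))) {
      summary[[name]] <<- list(status = "skipped",
                               reason = "missing input")
      return(invisible(NULL))
    }
    res <- fn()
    summary[[name]] <<- c(list(status = "ok"), res)
  }

  bin_spearman <- function(features, col) {
    bm <- suppressMessages(binned_means(vig, features, x = col))
    list(spearman = spearman_cor(bm$mean_y, bm$mean_x),
         p_value = spearman_test(bm$mean_y, bm$mean_x)$p_value,
         table = bm)
  }

  run_stage("promoter", list(x$promoters), function() {
    feats <- promoter_features(x$promoters, x$annotations,
                               strand_mode = params$strand_mode)
    tables$promoter_features <<- feats
    gc <- bin_spearman(feats, "gc_fraction")
    dn <- bin_spearman(feats, "dinuc_ratio")
    tables$vigintile_gc <<- gc$table
    tables$vigintile_dinuc <<- dn$table
    list(n_genes = nrow(feats),
         n_ratio_undefined = sum(is.na(feats$dinuc_ratio)),
         gc_spearman = gc$spearman, gc_spearman_p = gc$p_value,
         dinuc_spearman = dn$spearman, dinuc_spearman_p = dn$p_value)
  })

  run_stage("expression", list(x$expression), function() {
    cv <- expression_cv(x$expression,
                        log2_transform = params$log2_expression)
    tables$cv <<- cv
    comp <- suppressMessages(cv_group_comparison(cv, strata))
    tables$cv_comparison <<- comp
    sp <- bin_spearman(cv, "cv")
    tables$vigintile_cv <<- sp$table
    c(as.list(comp),
      list(cv_spearman = sp$spearman, cv_spearman_p = sp$p_value))
  })

  run_stage("gene_set_enrichment", list(x$tf_genes), function() {
    universe <- counts$gene_id
    tf <- intersect(x$tf_genes, universe)
    enr <- hypergeometric_enrichment(
      length(universe), length(tf), length(strata$q4_set),
      length(intersect(tf, strata$q4_set)), tail = "greater")
    dep <- hypergeometric_enrichment(
      length(universe), length(tf), length(strata$q1_set),
      length(intersect(tf, strata$q1_set)), tail = "less")
    wt <- wilcoxon_rank_sum(counts$n_mirnas[counts$gene_id %in% tf],
                            counts$n_mirnas[!counts$gene_id %in% tf])
    list(n_set = length(tf),
         q4_overlap = enr$statistic, q4_enrichment_p = enr$p_value,
         q1_overlap = dep$statistic, q1_depletion_p = dep$p_value,
         set_vs_rest_wilcoxon_p = wt$p_value)
  })

  run_stage("conservation", list(x$track, x$annotations), function() {
    cons <- conservation_summary(x$track, x$annotations)
    tables$conservation <<- cons
    ut <- bin_spearman(cons, "utr3_mean")
    cd <- bin_spearman(cons, "cds_mean")
    tables$vigintile_utr_cons <<- ut$table
    tables$vigintile_cds_cons <<- cd$table
    list(utr3_spearman = ut$spearman, utr3_spearman_p = ut$p_value,
         cds_spearman = cd$spearman, cds_spearman_p = cd$p_value)
  })

  run_stage("repeats", list(x$repeats, x$annotations), function() {
    flags <- flag_repeat_overlap(x$annotations, x$repeats)
    tables$repeat_flags <<- flags
    frac <- function(set) {
      f <- flags$has_repeat[flags$gene_id %in% set]
      if (length(f) == 0) NA_real_ else mean(f)
    }
    med <- tryCatch(
      stratified_count_medians(counts, flags, within = strata$q4_set),
      error = function(e) NULL)
    c(list(frac_q4 = frac(strata$q4_set), frac_q1 = frac(strata$q1_set)),
      if (is.null(med)) list(q4_within_p = NA_real_) else
        list(q4_median_with = med$median_with,
             q4_median_without = med$median_without,
             q4_within_p = med$p_value))
  })

  run_stage("utr_length", list(x$annotations), function() {
    ul <- suppressMessages(utr_length_vs_counts(x$annotations, counts))
    tables$utr_length <<- tidy(ul)
    as.list(glance(ul))
  })

  run_stage("colocalization", list(x$mirna_loci, x$annotations), function() {
    cl <- colocalize_mirnas(x$mirna_loci, x$annotations,
                            window = params$coloc_window)
    tables$colocalization <<- tidy(cl)
    as.list(glance(cl))
  })

  run_stage("cross_species",
            list(x$species, if (length(matrices) > 1) matrices else NULL),
            function() {
    panel <- species_panel(matrices, x$species)
    t1 <- suppressMessages(group_trajectory(panel, strata$q1_set,
                                            x$orthologs, "Q1"))
    t4 <- suppressMessages(group_trajectory(panel, strata$q4_set,
                                            x$orthologs, "Q4"))
    tables$trajectories <<- dplyr::bind_rows(tidy(t1), tidy(t4))
    list(q1_trend = t1$trend, q4_trend = t4$trend)
  })

  structure(list(summary = summary, tables = tables, params = params),
            class = "mir_report")
}

#' @export
print.mir_report <- function(x, ...) {
  stages <- setdiff(names(x$summary), c("schema_version", "params"))
  status <- vapply(stages, function(s) x$summary[[s]]$status, "")
  cat("<mir_report>\n")
  for (s in stages) cat(sprintf("  %-22s %s\n", s, status[s]))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (every per-stage statistic, at fixed numeric
#' precision so identical analyses produce identical bytes) and one TSV
#' per backing table.
#'
#' @param report A `mir_report`.
#' @param dir Output directory (created if needed).
#' @return The path of the JSON report, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mir_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null", na = "null")
  for (nm in names(report$tables)) {
    readr::write_tsv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  invisible(json_path)
}
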