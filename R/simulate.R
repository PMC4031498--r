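# Seeded synthetic-data generator. One shared latent noise level per gene
# drives promoter GC content, expression variability and (through the
# per-gene site rate) the distinct-miRNA count, so the planted correlations
# mirror the relationships the pipeline is meant to detect without asserting
# any causal mechanism. Species evolution follows a star topology rooted at
# a shared ancestor: the reference genome is the endpoint of site loss in
# non-regulatory genes and site gain in regulatory genes, so a species at
# distance rank d still carries Poisson(loss_rate * d) ancestral miRNAs per
# non-regulatory gene that the reference has lost, and retains each
# regulatory-gene site of the reference with probability exp(-gain_rate * d).

#' Configuration for the synthetic study generator
#'
#' All downstream generators are deterministic functions of this object:
#' the same configuration yields byte-identical outputs.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_genes,n_mirnas,n_samples,n_species Problem dimensions
#'   (>= 40 genes so quartiles and vigintiles are well defined).
#' @param frac_regulatory Fraction of genes planted as regulatory
#'   (`round(frac * n_genes)` labels, deterministic).
#' @param site_rate_reg,site_rate_nonreg Mean distinct miRNAs per gene for
#'   the two classes in the reference species.
#' @param site_noise_slope Log-linear coupling of the per-gene site rate to
#'   the gene's latent noise level (0 = class-only rates).
#' @param noise_mean_reg,noise_mean_nonreg,noise_sd Latent noise level per
#'   gene: truncated normal on `[0, 1]` with a class-specific mean.
#' @param gc_base,noise_gc_slope Per-base promoter GC probability is
#'   `gc_base + noise_gc_slope * noise`.
#' @param cv_base,cv_slope Planted lognormal sigma per gene is
#'   `cv_base + cv_slope * noise` (for small sigma this is close to the
#'   coefficient of variation it induces).
#' @param cons_utr_reg,cons_utr_nonreg,cons_cds_reg,cons_cds_nonreg Mean
#'   conservation scores planted in 3'UTR and CDS bins by class; defaults
#'   make regulatory 3'UTRs better and regulatory CDS worse conserved.
#' @param gain_rate,loss_rate Per-distance-rank site turnover along the
#'   reference lineage (see the generator description above).
#' @param repeat_prob_reg,repeat_prob_nonreg Probability that a gene's
#'   3'UTR carries an LTR/SINE element.
#' @param coloc_prob_reg Probability that a regulatory gene hosts a miRNA
#'   locus within its span.
#' @param dup_site_prob Probability that a reference site record is
#'   duplicated at a second 3'UTR position (exercises the collapsing rule).
#' @param frac_conserved Fraction of site records labelled conserved.
#' @param flank Promoter half-width in bp.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 2000, n_mirnas = 300,
                             n_samples = 100, n_species = 10,
                             frac_regulatory = 0.25,
                             site_rate_reg = 60, site_rate_nonreg = 12,
                             site_noise_slope = 1.5,
                             noise_mean_reg = 0.7, noise_mean_nonreg = 0.3,
                             noise_sd = 0.12,
                             gc_base = 0.4, noise_gc_slope = 0.3,
                             cv_base = 0.1, cv_slope = 0.8,
                             cons_utr_reg = 0.75, cons_utr_nonreg = 0.35,
                             cons_cds_reg = 0.5, cons_cds_nonreg = 0.8,
                             gain_rate = 0.06, loss_rate = 0.8,
                             repeat_prob_reg = 0.6, repeat_prob_nonreg = 0.17,
                             coloc_prob_reg = 0.2,
                             dup_site_prob = 0.3, frac_conserved = 0.5,
                             flank = 1000) {
  cfg <- as.list(environment())
  probs <- c(frac_regulatory, frac_conserved, repeat_prob_reg,
             repeat_prob_nonreg, coloc_prob_reg, dup_site_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_genes < 40) abort("need n_genes >= 40 for quartiles and vigintiles")
  if (gain_rate < 0 || loss_rate < 0) abort("turnover rates must be >= 0")
  if (site_rate_reg <= 0 || site_rate_nonreg <= 0) {
    abort("site rates must be > 0")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

#' Null configuration with all couplings removed
#'
#' Same dimensions as [synthetic_config()] but no planted structure: equal
#' site rates for both classes, no noise coupling to GC, CV or site rate,
#' no cross-species turnover and class-independent conservation, repeat
#' and co-localization probabilities. Used to verify that the pipeline does
#' not manufacture signals on its own.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
null_config <- function(seed = 1, ...) {
  synthetic_config(
    seed = seed,
    site_rate_reg = 24, site_rate_nonreg = 24,
    site_noise_slope = 0, noise_gc_slope = 0, cv_slope = 0,
    gain_rate = 0, loss_rate = 0,
    cons_utr_reg = 0.5, cons_utr_nonreg = 0.5,
    cons_cds_reg = 0.5, cons_cds_nonreg = 0.5,
    repeat_prob_reg = 0.3, repeat_prob_nonreg = 0.3,
    ...
  )
}

# per-generator RNG streams derived from the config seed
with_config_seed <- function(config, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed * 64L + offset)
  force(code)
}

#' Planted gene labels and latent noise levels
#'
#' @param config A `synthetic_config`.
#' @return A tibble `gene_id`, `regulatory` (logical), `noise` in `[0, 1]`.
#' @export
generate_gene_labels <- function(config) {
  with_config_seed(config, 1L, {
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    regulatory <- logical(n)
    n_reg <- round(config$frac_regulatory * n)
    regulatory[sample.int(n, n_reg)] <- TRUE
    noise <- clip01(rnorm(
      n,
      mean = ifelse(regulatory, config$noise_mean_reg,
                    config$noise_mean_nonreg),
      sd = config$noise_sd
    ))
    tibble(gene_id = gene_id, regulatory = regulatory, noise = noise)
  })
}

#' Synthetic genome: gene models, promoter sequences, chromosome sizes
#'
#' Genes are laid out without overlap on one synthetic chromosome, each
#' with a random strand, one CDS interval and one 3'UTR interval (drawn
#' longer on average for regulatory genes). Promoters are `2 * flank` bp of
#' sequence on the gene's sense strand with per-base GC probability
#' `gc_base + noise_gc_slope * noise`.
#'
#' @param config A `synthetic_config`.
#' @param labels Tibble from [generate_gene_labels()].
#' @return A list with `annotations` (see [read_annotation()] for the
#'   layout), `promoters` (named [Biostrings::DNAStringSet]) and
#'   `chrom_sizes` (named vector).
#' @export
generate_genome_and_annotations <- function(config, labels) {
  with_config_seed(config, 2L, {
    n <- config$n_genes
    utr_len <- as.integer(
      50 + round(rgamma(n, shape = 2,
                        scale = ifelse(labels$regulatory, 450, 225))))
    cds_len <- as.integer(round(runif(n, 300, 1500)))
    gap <- as.integer(sample(2000:8000, n, replace = TRUE))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    body <- utr_len + cds_len
    start <- cumsum(c(3000L, head(body + gap, -1)))
    end <- start + body
    utr3 <- vector("list", n); cds <- vector("list", n)
    for (i in seq_len(n)) {
      s_i <- start[i]; e_i <- end[i]
      if (strand[i] == "+") {
        mid <- s_i + cds_len[i]
        cds[[i]] <- tibble(start = s_i, end = mid)
        utr3[[i]] <- tibble(start = mid, end = e_i)
      } else {
        mid <- s_i + utr_len[i]
        utr3[[i]] <- tibble(start = s_i, end = mid)
        cds[[i]] <- tibble(start = mid, end = e_i)
      }
    }
    annotations <- tibble(
      gene_id = labels$gene_id, chrom = "chrS1", strand = strand,
      tss = ifelse(strand == "+", start, end - 1L),
      span_start = start, span_end = end,
      utr3 = utr3, cds = cds
    )
    chrom_sizes <- c(chrS1 = max(end) + 10000L)

    L <- 2L * config$flank
    p_gc <- config$gc_base + config$noise_gc_slope * labels$noise
    if (any(p_gc < 0 | p_gc > 1)) abort("promoter GC probability outside [0,1]")
    is_gc <- matrix(runif(n * L), nrow = L) < rep(p_gc, each = L)
    pick <- matrix(runif(n * L), nrow = L) < 0.5
    base <- matrix("T", nrow = L, ncol = n)
    base[is_gc & pick] <- "G"
    base[is_gc & !pick] <- "C"
    base[!is_gc & pick] <- "A"
    seqs <- apply(base, 2, paste, collapse = "")
    promoters <- Biostrings::DNAStringSet(setNames(seqs, labels$gene_id))
    list(annotations = annotations, promoters = promoters,
         chrom_sizes = chrom_sizes)
  })
}

#' Synthetic site tables for the reference species and its relatives
#'
#' The reference gene g receives `Poisson(lambda_g)` distinct miRNAs with
#' `lambda_g = rate_class * exp(site_noise_slope * (noise_g - class mean))`,
#' plus duplicate records at second 3'UTR positions with probability
#' `dup_site_prob` (the matrix builder must collapse these). A species at
#' distance rank d diverged before part of the reference lineage's
#' turnover, so each regulatory-gene site is retained with probability
#' `exp(-gain_rate * d)` while every non-regulatory gene carries
#' `Poisson(loss_rate * d)` additional ancestral miRNAs.
#'
#' @param config A `synthetic_config`.
#' @param labels Tibble from [generate_gene_labels()].
#' @return A list: `tables` (named list of site tibbles, reference first),
#'   `species` (tibble `species_id`, `distance_rank`), `ortholog_map`
#'   (identity map for every non-reference species) and `mirna_pool`.
#' @export
generate_sites <- function(config, labels) {
  with_config_seed(config, 3L, {
    n <- config$n_genes
    pool <- sprintf("miR-%03d", seq_len(config$n_mirnas))
    class_rate <- ifelse(labels$regulatory, config$site_rate_reg,
                         config$site_rate_nonreg)
    class_mean <- ifelse(labels$regulatory, config$noise_mean_reg,
                         config$noise_mean_nonreg)
    lambda <- class_rate *
      exp(config$site_noise_slope * (labels$noise - class_mean))
    k <- pmin(rpois(n, lambda), config$n_mirnas)
    if (sum(k) == 0) abort("site rates produced an empty reference matrix")
    mirna_idx <- unlist(lapply(k, function(ki) {
      if (ki == 0) integer() else sample.int(config$n_mirnas, ki)
    }), use.names = FALSE)
    ref_pairs <- tibble(
      gene_id = rep(labels$gene_id, k),
      mirna_id = pool[mirna_idx],
      regulatory = rep(labels$regulatory, k)
    )
    species_ids <- sprintf("s%02d", seq_len(config$n_species) - 1L)
    ranks <- seq_len(config$n_species) - 1L

    finish_table <- function(pairs, sp, dup_prob) {
      m <- nrow(pairs)
      rec <- tibble(
        gene_id = pairs$gene_id, mirna_id = pairs$mirna_id, species_id = sp,
        category = ifelse(runif(m) < config$frac_conserved,
                          "conserved", "nonconserved"),
        context_score = -round(runif(m, 0.01, 1), 4),
        utr_start = as.integer(floor(runif(m, 0, 393))),
        utr_end = NA_integer_
      )
      rec$utr_end <- rec$utr_start + 7L
      if (dup_prob > 0 && m > 0) {
        dup <- rec[runif(m) < dup_prob, , drop = FALSE]
        if (nrow(dup) > 0) {
          dup$utr_start <- dup$utr_start + 8L
          dup$utr_end <- dup$utr_end + 8L
          dup$context_score <- -round(runif(nrow(dup), 0.01, 1), 4)
          rec <- dplyr::bind_rows(rec, dup)
        }
      }
      arrange(rec, .data$gene_id, .data$mirna_id, .data$utr_start)
    }

    tables <- vector("list", config$n_species)
    names(tables) <- species_ids
    tables[[1]] <- finish_table(ref_pairs, species_ids[1],
                                config$dup_site_prob)
    nonreg_genes <- labels$gene_id[!labels$regulatory]
    for (i in seq_len(config$n_species - 1L)) {
      d <- ranks[i + 1]
      keep <- ifelse(ref_pairs$regulatory,
                     runif(nrow(ref_pairs)) < exp(-config$gain_rate * d),
                     TRUE)
      pairs_d <- ref_pairs[keep, c("gene_id", "mirna_id")]
      extra_k <- rpois(length(nonreg_genes), config$loss_rate * d)
      if (sum(extra_k) > 0) {
        extra <- tibble(
          gene_id = rep(nonreg_genes, extra_k),
          mirna_id = pool[unlist(lapply(extra_k, function(ki) {
            if (ki == 0) integer() else sample.int(config$n_mirnas, ki)
          }), use.names = FALSE)]
        )
        pairs_d <- distinct(dplyr::bind_rows(pairs_d, extra),
                            .data$gene_id, .data$mirna_id)
      }
      tables[[i + 1]] <- finish_table(pairs_d, species_ids[i + 1], 0)
    }

    species <- tibble(species_id = species_ids, distance_rank = ranks)
    ortholog_map <- tidyr::expand_grid(
      ref_gene_id = labels$gene_id,
      species_id = species_ids[-1]
    ) |>
      mutate(gene_id = .data$ref_gene_id) |>
      select("ref_gene_id", "species_id", "gene_id")
    list(tables = tables, species = species, ortholog_map = ortholog_map,
         mirna_pool = pool)
  })
}

#' Synthetic expression matrix with planted per-gene variability
#'
#' Values are lognormal with per-gene `sdlog = cv_base + cv_slope * noise`,
#' sharing the latent noise with the promoter generator so GC content,
#' expression variability and site counts are mutually correlated.
#'
#' @param config A `synthetic_config`.
#' @param labels Tibble from [generate_gene_labels()].
#' @return An expression tibble (first column `gene_id`).
#' @export
generate_expression <- function(config, labels) {
  with_config_seed(config, 4L, {
    n <- config$n_genes; s <- config$n_samples
    if (s < 10) abort("need n_samples >= 10")
    sdlog <- config$cv_base + config$cv_slope * labels$noise
    if (any(sdlog < 0)) abort("planted sigma must be >= 0")
    meanlog <- rnorm(n, log(500), 0.6)
    vals <- matrix(rlnorm(n * s, meanlog, sdlog), nrow = n)
    out <- as_tibble(vals, .name_repair = "minimal")
    names(out) <- sprintf("s%03d", seq_len(s))
    dplyr::bind_cols(tibble(gene_id = labels$gene_id), out)
  })
}

#' Synthetic conservation track, repeat annotations and miRNA loci
#'
#' Conservation is planted in 25-bp bins over each gene's 3'UTR and CDS
#' around the class-specific means (clipped to `[0, 1]`); bases outside
#' genes stay uncovered. LTR/SINE repeats are dropped into 3'UTRs with
#' class-dependent probability (plus occasional LINE decoys that the class
#' filter must ignore), and miRNA loci are placed inside regulatory gene
#' spans with probability `coloc_prob_reg`, plus a few background loci.
#'
#' @param config A `synthetic_config`.
#' @param annotations Annotations from [generate_genome_and_annotations()].
#' @param labels Tibble from [generate_gene_labels()].
#' @return A list `track`, `repeats`, `mirna_loci`.
#' @export
generate_tracks_and_repeats <- function(config, annotations, labels) {
  with_config_seed(config, 5L, {
    reg <- setNames(labels$regulatory, labels$gene_id)
    tile_region <- function(which, mean_reg, mean_nonreg) {
      iv <- gene_intervals(annotations, which)
      bins <- purrr::pmap(list(iv$gene_id, iv$start, iv$end),
        function(g, s, e) {
          b <- seq(s, e, by = 25L)
          if (b[length(b)] < e) b <- c(b, e)
          tibble(gene_id = g, start = head(b, -1), end = b[-1])
        })
      bins <- dplyr::bind_rows(bins)
      mu <- ifelse(reg[bins$gene_id], mean_reg, mean_nonreg)
      tibble(chrom = "chrS1", start = as.integer(bins$start),
             end = as.integer(bins$end),
             score = round(clip01(rnorm(nrow(bins), mu, 0.08)), 4))
    }
    track <- dplyr::bind_rows(
      tile_region("utr3", config$cons_utr_reg, config$cons_utr_nonreg),
      tile_region("cds", config$cons_cds_reg, config$cons_cds_nonreg)
    ) |> arrange(.data$chrom, .data$start)

    utr_iv <- gene_intervals(annotations, "utr3")
    utr_iv <- utr_iv[(utr_iv$end - utr_iv$start) >= 250, , drop = FALSE]
    p_rep <- ifelse(reg[utr_iv$gene_id], config$repeat_prob_reg,
                    config$repeat_prob_nonreg)
    hit <- runif(nrow(utr_iv)) < p_rep
    rep_iv <- utr_iv[hit, , drop = FALSE]
    rep_start <- rep_iv$start + as.integer(
      floor(runif(nrow(rep_iv), 0, rep_iv$end - rep_iv$start - 150)))
    repeats <- tibble(
      chrom = "chrS1", start = rep_start, end = rep_start + 150L,
      repeat_class = sample(c("LTR", "SINE"), nrow(rep_iv), replace = TRUE)
    )
    decoy <- utr_iv[runif(nrow(utr_iv)) < 0.1, , drop = FALSE]
    if (nrow(decoy) > 0) {
      ds <- decoy$start + as.integer(
        floor(runif(nrow(decoy), 0, decoy$end - decoy$start - 100)))
      repeats <- dplyr::bind_rows(
        repeats,
        tibble(chrom = "chrS1", start = ds, end = ds + 100L,
               repeat_class = "LINE"))
    }
    repeats <- arrange(repeats, .data$start)

    host <- annotations[labels$regulatory &
                          runif(config$n_genes) < config$coloc_prob_reg, ,
                        drop = FALSE]
    loci <- tibble(
      mirna_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )
    if (nrow(host) > 0) {
      off <- as.integer(floor(runif(
        nrow(host), 0, pmax(1, host$span_end - host$span_start - 80))))
      loci <- tibble(
        mirna_id = sprintf("miR-%03d",
                           sample.int(config$n_mirnas, nrow(host),
                                      replace = TRUE)),
        chrom = host$chrom, start = host$span_start + off,
        end = host$span_start + off + 80L,
        strand = sample(c("+", "-"), nrow(host), replace = TRUE)
      )
    }
    n_bg <- max(1L, round(0.05 * config$n_genes))
    chrom_len <- max(annotations$span_end) + 10000L
    bg_start <- as.integer(floor(runif(n_bg, 0, chrom_len - 80)))
    loci <- dplyr::bind_rows(
      loci,
      tibble(mirna_id = sprintf("miR-%03d",
                                sample.int(config$n_mirnas, n_bg,
                                           replace = TRUE)),
             chrom = "chrS1", start = bg_start, end = bg_start + 80L,
             strand = sample(c("+", "-"), n_bg, replace = TRUE))
    ) |> arrange(.data$start)
    list(track = track, repeats = repeats, mirna_loci = loci)
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator in a fixed order and bundles their outputs; with
#' the same configuration the result is bit-identical across calls.
#'
#' @param config A `synthetic_config`.
#' @return An object of class `mir_simulation`: list with `labels`,
#'   `annotations`, `promoters`, `chrom_sizes`, `sites` (per-species
#'   tables), `species`, `ortholog_map`, `expression`, `track`, `repeats`,
#'   `mirna_loci`, `tf_set` (the planted regulatory gene ids) and `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- generate_gene_labels(config)
  geno <- generate_genome_and_annotations(config, labels)
  sites <- generate_sites(config, labels)
  expression <- generate_expression(config, labels)
  tracks <- generate_tracks_and_repeats(config, geno$annotations, labels)
  structure(
    list(labels = labels,
         annotations = geno$annotations,
         promoters = geno$promoters,
         chrom_sizes = geno$chrom_sizes,
         sites = sites$tables,
         species = sites$species,
         ortholog_map = sites$ortholog_map,
         expression = expression,
         track = tracks$track,
         repeats = tracks$repeats,
         mirna_loci = tracks$mirna_loci,
         tf_set = labels$gene_id[labels$regulatory],
         config = config),
    class = "mir_simulation"
  )
}

#' @export
print.mir_simulation <- function(x, ...) {
  cat(sprintf(
    "<mir_simulation> %d genes, %d miRNAs, %d samples, %d species (seed %d)\n",
    x$config$n_genes, x$config$n_mirnas, x$config$n_samples,
    x$config$n_species, x$config$seed))
  invisible(x)
}

#' Write a simulated study to disk as a pipeline input bundle
#'
#' Writes every input type in the plain-text formats the readers consume:
#' per-species site tables, expression TSV, promoter FASTA, BED12
#' annotations, bedGraph conservation, repeat TSV, miRNA loci BED, gene
#' sets, species ladder, ortholog map, chromosome sizes and the generator
#' configuration (YAML).
#'
#' @param sim A `mir_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "mir_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paths <- list()
  for (sp in names(sim$sites)) {
    paths[[paste0("sites_", sp)]] <-
      write_site_table(sim$sites[[sp]], p(sprintf("sites_%s.tsv", sp)))
  }
  paths$expression <- write_expression(sim$expression, p("expression.tsv"))
  Biostrings::writeXStringSet(sim$promoters, p("promoters.fa"))
  paths$promoters <- p("promoters.fa")
  paths$annotations <- write_annotation(sim$annotations, p("annotations.bed"))
  paths$track <- write_track(sim$track, p("conservation.bedGraph"))
  paths$repeats <- write_repeats(sim$repeats, p("repeats.tsv"))
  paths$mirna_loci <- write_mirna_loci(sim$mirna_loci, p("mirna_loci.bed"))
  paths$tf_genes <- write_gene_set(sim$tf_set, p("tf_genes.txt"))
  paths$species <- write_species_table(sim$species, p("species.tsv"))
  paths$orthologs <- write_ortholog_map(sim$ortholog_map, p("orthologs.tsv"))
  readr::write_tsv(tibble(chrom = names(sim$chrom_sizes),
                          size = unname(sim$chrom_sizes)),
                   p("chrom_sizes.tsv"), progress = FALSE)
  paths$chrom_sizes <- p("chrom_sizes.tsv")
  yaml::write_yaml(unclass(sim$config), p("config.yml"))
  paths$config <- p("config.yml")
  invisible(paths)
}

#' Locate the files of a simulation bundle
#'
#' @param dir Directory written by [write_simulation_bundle()].
#' @return Named list of input paths suitable for [run_pipeline()].
#' @export
bundle_inputs <- function(dir) {
  site_files <- sort(list.files(dir, pattern = "^sites_.*\\.tsv$",
                                full.names = TRUE))
  names(site_files) <- sub("^sites_(.*)\\.tsv$", "\\1", basename(site_files))
  maybe <- function(f) {
    path <- file.path(dir, f)
    if (file.exists(path)) path else NULL
  }
  list(
    sites = as.list(site_files),
    expression = maybe("expression.tsv"),
    promoters = maybe("promoters.fa"),
    annotations = maybe("annotations.bed"),
    track = maybe("conservation.bedGraph"),
    repeats = maybe("repeats.tsv"),
    mirna_loci = maybe("mirna_loci.bed"),
    tf_genes = maybe("tf_genes.txt"),
    species = maybe("species.tsv"),
    orthologs = maybe("orthologs.tsv"),
    chrom_sizes = maybe("chrom_sizes.tsv")
  )
}
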