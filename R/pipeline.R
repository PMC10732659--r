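# End-to-end orchestration: simulate -> count -> filter/diff ->
# annotate -> assoc, from one flat configuration, with a run report
# whose counts satisfy each stage's conservation arithmetic.

#' Default pipeline configuration
#'
#' Returns the flat key-value configuration driving
#' \code{\link{run_rrhp}}, mirroring the study design: two groups of 5
#' samples, fast-group library sizes about three times the slow-group
#' ones, a minority of CCGG sites with |log2FC| >= 1, negative-binomial
#' noise, and full-sib genotypes with no true group differentiation.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param ... overrides of any default field.
#' @return named list.
#' @export
rrhp_config <- function(seed = 42, ...) {
  cfg <- list(
    seed = seed,
    n_chroms = 2L, chrom_length = 50000L, ccgg_spacing_mean = 100,
    n_genes = 20L, exons_per_gene = 3L,
    frac_differential = 0.1, effect_log2 = 2, hyper_share = 0.84,
    n_per_group = 5L, lib_fast = 60000, lib_slow = 20000, nb_dispersion = 0.2,
    k_zero = NULL, k_below = NULL, span = 0.5,
    lfc = 1, q_threshold = 0.05,
    promoter_window = c(-1000L, 100L), tts_window = c(-100L, 1000L),
    n_loci = 2000L, parent_maf = 0.3, missing_rate = 0.05,
    p_highlight = 0.01, assoc_q = 0.05,
    out_dir = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

# small deterministic config fingerprint (polynomial rolling hash);
# output paths do not affect the analysis and are excluded
config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full RRHP analysis pipeline
#'
#' Executes the stages in dependency order on synthetic data: genome and
#' ground-truth simulation, tag-stream replay through site extraction
#' and count-matrix construction, the two-stage filter and differential
#' model, feature annotation and enrichment of the DhmC calls, and the
#' full-sib SNP association scan. When \code{out_dir} is set, all
#' intermediate tables are written as plain-text TSV/JSON with fixed
#' column orders, so identical configurations produce byte-identical
#' outputs.
#'
#' @param config list from \code{\link{rrhp_config}}.
#' @return list of class \code{rrhp_run}: the stage objects
#'   (\code{genome}, \code{counts}, \code{fit}, \code{annotation},
#'   \code{enrichment}, \code{assoc}, \code{venn}) and \code{report},
#'   the per-stage record counts with the configuration hash.
#' @export
run_rrhp <- function(config = rrhp_config()) {
  cfg <- config
  stage <- "simulate"
  res <- tryCatch({
    g <- sim_genome(n_chroms = cfg$n_chroms, chrom_length = cfg$chrom_length,
                    ccgg_spacing_mean = cfg$ccgg_spacing_mean,
                    n_genes = cfg$n_genes, exons_per_gene = cfg$exons_per_gene,
                    seed = cfg$seed)
    truth <- sim_hmc_truth(g$ccgg, frac_differential = cfg$frac_differential,
                           effect_log2 = cfg$effect_log2,
                           hyper_share = cfg$hyper_share, seed = cfg$seed + 1L)
    sim <- sim_tag_counts(truth, n_per_group = cfg$n_per_group,
                          lib_sizes = c(cfg$lib_fast, cfg$lib_slow),
                          nb_dispersion = cfg$nb_dispersion,
                          seed = cfg$seed + 2L)

    stage <- "count"
    tags <- counts_to_tags(sim)
    tagrec <- data.frame(sample_id = tags$sample_id, chrom = tags$chrom,
                         start = tags$pos, end = tags$pos + 3L,
                         strand = tags$strand, lead4 = "CCGG")
    obs <- extract_sites(tagrec, g$genome)
    counts <- build_count_matrix(obs, sim$samples)
    venn <- presence_venn(counts)

    stage <- "diff"
    fit <- dhmc_fit(counts, lfc = cfg$lfc, q_threshold = cfg$q_threshold,
                    k_zero = cfg$k_zero, k_below = cfg$k_below, span = cfg$span)

    stage <- "annotate"
    dhmc_sites <- fit$table[fit$table$class != "ns", c("chrom", "pos")]
    ann <- classify_features(fit$table[, c("chrom", "pos")], g$genes,
                             promoter_window = cfg$promoter_window,
                             tts_window = cfg$tts_window)
    nt <- nearest_tss(fit$table[, c("chrom", "pos")], g$genes)
    ann$nearest_gene <- nt$gene_id
    ann$nearest_d_tss <- nt$d_tss
    enr <- feature_enrichment(
      list(background = g$ccgg,
           raw = counts$sites,
           filtered = fit$table[, c("chrom", "pos")],
           dhmc = dhmc_sites),
      g$genes,
      promoter_window = cfg$promoter_window, tts_window = cfg$tts_window)

    stage <- "assoc"
    gt <- sim_fullsib_genotypes(n_loci = cfg$n_loci,
                                n_offspring_per_group = cfg$n_per_group,
                                parent_maf = cfg$parent_maf,
                                missing_rate = cfg$missing_rate,
                                seed = cfg$seed + 3L)
    assoc <- assoc_scan(gt$geno, gt$samples$group, gt$loci,
                        p_highlight = cfg$p_highlight,
                        q_threshold = cfg$assoc_q)
    list(genome = g, truth = truth, tags = tags, counts = counts, venn = venn,
         fit = fit, annotation = ann, enrichment = enr, genotypes = gt,
         assoc = assoc)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  cls <- table(res$fit$table$class)
  report <- list(
    config_hash = config_hash(cfg),
    version = as.character(utils::packageVersion("rrhp")),
    n_ccgg_catalog = nrow(res$genome$ccgg),
    n_tags = nrow(res$tags),
    n_tags_accepted = sum(res$counts$counts),
    sites_raw = nrow(res$counts$counts),
    sites_removed_stage1 = res$fit$filter$n_removed_stage1,
    sites_removed_stage2 = res$fit$filter$n_removed_stage2,
    sites_filtered = res$fit$filter$n_retained,
    filter_median = res$fit$filter$median,
    dhmc_hyper = unname(cls[["hyper"]]),
    dhmc_hypo = unname(cls[["hypo"]]),
    dhmc_total = unname(cls[["hyper"]] + cls[["hypo"]]),
    loci_input = res$assoc$filter$n_input,
    loci_tested = res$assoc$n_tested,
    snps_p_below = res$assoc$n_p_below,
    snps_q_below = res$assoc$n_q_below)

  out <- structure(c(res, list(report = report, config = cfg)),
                   class = "rrhp_run")
  if (!is.null(cfg$out_dir)) write_run_outputs(out, cfg$out_dir)
  out
}

#' @export
print.rrhp_run <- function(x, ...) {
  r <- x$report
  cat("RRHP pipeline run (config ", r$config_hash, ")\n", sep = "")
  cat(sprintf("  catalog %d CCGG sites; %d tags accepted; %d sites observed\n",
              r$n_ccgg_catalog, r$n_tags_accepted, r$sites_raw))
  cat(sprintf("  filter: -%d (zeros) -%d (median %g) -> %d tested\n",
              r$sites_removed_stage1, r$sites_removed_stage2,
              r$filter_median, r$sites_filtered))
  cat(sprintf("  DhmCs: %d hyper + %d hypo = %d\n",
              r$dhmc_hyper, r$dhmc_hypo, r$dhmc_total))
  cat(sprintf("  SNPs: %d tested, %d at p < %g, %d at q < %g\n",
              r$loci_tested, r$snps_p_below, x$config$p_highlight,
              r$snps_q_below, x$config$assoc_q))
  invisible(x)
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_genome_fasta(run$genome$genome, fp("genome.fa"))
  write_gene_models_gff3(run$genome$genes, fp("genes.gff3"))
  utils::write.table(run$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tags_tsv(run$tags, fp("tags.tsv"))
  write_counts_tsv(run$counts, fp("counts.tsv"))
  utils::write.table(run$counts$samples, fp("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$venn, fp("venn.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(run$fit$filter), fp("filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(run$fit$table, fp("diff_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$annotation, fp("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  enr <- data.frame(class = rownames(run$enrichment$fractions),
                    run$enrichment$fractions,
                    delta_pp = run$enrichment$delta_pp[, "dhmc"])
  utils::write.table(enr, fp("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_genotypes_tsv(run$genotypes, fp("genotypes.tsv"))
  utils::write.table(run$assoc$results, fp("assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
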