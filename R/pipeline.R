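# End-to-end orchestration with a single config, per-stage seeds and a
# reproducibility manifest of output hashes.

#' Default pipeline configuration
#'
#' Thresholds follow the analysis design: aLIS alpha 0.05, DE p 0.05, mQTL
#' distance 200 bp, flank half-width 250 bp, 10,000 permutation
#' replicates. Per-stage seeds are derived from one master seed so stages
#' can be re-run in isolation; all are recorded in the run log.
#'
#' @param seed master integer seed
#' @param out_dir run directory
#' @param ... overrides for any top-level config entry
#' @return nested config list
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("stressmeth_run_"),
                            ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    seeds = lapply(setNames(nm = c("simulate", "preprocess", "dml", "enrich",
                                   "expression", "integrate", "motif")),
                   function(st) derive_seed(seed, st)),
    alpha = 0.05, de_p = 0.05, mqtl_distance = 200, halfwidth = 250,
    reps = 10000, hmm_restarts = 3,
    max_failed_samples = 0, detection_threshold = 0.01,
    kmer = list(k_min = 4, k_max = 8, e_cutoff = 1e-3,
                background = "dinucleotide"),
    simulate = list(n_chromosomes = 4, genes_per_chromosome = 50,
                    n_probes = 2000, n_samples = 22,
                    motif = "TACGTA"),
    strict_tail = FALSE, chromosome_mode = "familywise")
  user <- list(...)
  cfg[names(user)] <- user
  cfg
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file; entries override [pipeline_config()] defaults
#' @return config list
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(pipeline_config, user)
}

run_log <- function(path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  cat(msg, "\n", file = path, append = TRUE)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> dml -> enrich -> expression -> integrate ->
#' motif, writing every stage's result tables into the run directory and a
#' manifest of output file hashes; a re-run with an identical config
#' reproduces byte-identical tables. Any stage error halts the run with
#' the stage name; outputs of completed stages are preserved.
#'
#' @param config list from [pipeline_config()] / [read_pipeline_config()]
#' @return invisibly, a list with the in-memory results of every stage and
#'   `manifest` (file md5 hashes)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  stage <- "simulate"
  res <- list()
  tryCatch({
    run_log(logf, "seeds: %s",
            paste(sprintf("%s=%d", names(config$seeds),
                          unlist(config$seeds)), collapse = " "))
    run_log(logf, "stage simulate")
    sim <- config$simulate
    study <- simulate_study(n_chromosomes = sim$n_chromosomes,
                            genes_per_chromosome = sim$genes_per_chromosome,
                            n_probes = sim$n_probes,
                            n_samples = sim$n_samples,
                            motif = sim$motif,
                            seed = config$seeds$simulate)
    write_study(study, file.path(config$out_dir, "input"))
    res$study <- study

    stage <- "preprocess"
    run_log(logf, "stage preprocess")
    samples <- read_sample_sheet(file.path(config$out_dir, "input",
                                           "samples.csv"))
    filt <- filter_probes(study$beta, study$detection_p, study$probes,
                          max_failed_samples = config$max_failed_samples,
                          detection_threshold = config$detection_threshold)
    write_tsv(filt$report, file.path(config$out_dir, "filter_report.tsv"))
    res$filter <- filt

    stage <- "dml"
    run_log(logf, "stage dml")
    dml <- call_dmls(filt$beta, filt$detection_p, filt$manifest, samples,
                     snps = study$snps, alpha = config$alpha,
                     mqtl_distance = config$mqtl_distance,
                     hmm_restarts = config$hmm_restarts,
                     seed = config$seeds$dml, filter = FALSE)
    write_tsv(dml$stats[, c("id", "chrom", "pos", "coef", "se", "df",
                            "raw_t", "moderated_t", "p", "z")],
              file.path(config$out_dir, "locus_stats.tsv"))
    write_tsv(dml$calls, file.path(config$out_dir, "dml_calls.tsv"))
    run_log(logf, "called %d DMLs at aLIS < %g", sum(dml$calls$called),
            config$alpha)
    res$dml <- dml

    stage <- "enrich"
    run_log(logf, "stage enrich")
    enr <- run_enrichment_suite(dml$calls, filt$manifest,
                                reps = config$reps,
                                seed = config$seeds$enrich,
                                strict = config$strict_tail,
                                chromosome_mode = config$chromosome_mode)
    write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
    res$enrichment <- enr

    stage <- "expression"
    run_log(logf, "stage expression")
    expr <- run_expression_de(study$expression$gene_counts,
                              study$expression$isoform_counts,
                              study$expression$isoform_map, samples,
                              threshold = config$de_p)
    write_tsv(rbind(expr$gene, expr$isoform),
              file.path(config$out_dir, "de_results.tsv"))
    writeLines(expr$de_genes, file.path(config$out_dir, "de_genes.txt"))
    res$expression <- expr

    stage <- "integrate"
    run_log(logf, "stage integrate")
    called <- dml$calls[dml$calls$called, , drop = FALSE]
    assign <- map_nearest_gene(called, study$genome)
    assign$direction <- called$direction
    gsets <- aggregate_genes(assign)
    universe <- study$genome$genes$gene_id
    mq <- attr(dml$calls, "summary")
    report <- integrate_report(gsets, expr$de_genes, study$gene_list,
                               universe, mqtl_summary = mq)
    write_tsv(data.frame(metric = names(report$counts),
                         value = unname(report$counts)),
              file.path(config$out_dir, "integration_counts.tsv"))
    write_tsv(report$overlap_genes,
              file.path(config$out_dir, "overlap_genes.tsv"))
    res$integration <- report

    stage <- "motif"
    run_log(logf, "stage motif")
    fg <- extract_flanks(called$probe_id, study$probes,
                         halfwidth = config$halfwidth)
    motif_res <- NULL
    if (length(fg) > 0) {
      bg <- shuffle_background(fg, mode = config$kmer$background,
                               seed = config$seeds$motif)
      write_fasta(fg, file.path(config$out_dir, "flanks_foreground.fasta"))
      write_fasta(bg, file.path(config$out_dir, "flanks_background.fasta"))
      motif_res <- kmer_enrichment(fg, bg, k_min = config$kmer$k_min,
                                   k_max = config$kmer$k_max,
                                   e_cutoff = config$kmer$e_cutoff)
      write_tsv(motif_res, file.path(config$out_dir, "kmer_enrichment.tsv"))
    }
    res$motif <- motif_res

    files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("run\\.log$|manifest\\.tsv$", files)]
    manifest <- data.frame(
      file = sub(paste0("^", config$out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
    res$manifest <- manifest
    run_log(logf, "pipeline complete")
    invisible(res)
  }, stressmeth_error = function(e) {
    run_log(logf, "pipeline halted at stage '%s': %s", stage,
            conditionMessage(e))
    stop_pipeline("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}
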