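#' Run-configuration validation
#'
#' Configurations are flat JSON files (or equivalent R lists): a `stage`
#' plus per-stage parameter blocks. Unknown keys are rejected so typos
#' cannot silently fall back to defaults, and the resolved configuration
#' (defaults filled in) is echoed into the output directory for
#' provenance.
#'
#' @param config an R list or path to a JSON config file.
#' @return The validated, default-filled config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(config_error("config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- c("simulate", "detect-integration", "enrich-test", "smallrna",
              "qpcr", "closed-loop")
  if (is.null(config$stage) || !config$stage %in% stages)
    stop(config_error("config$stage must be one of: ",
                      paste(stages, collapse = ", ")))
  known <- list(
    common = c("stage", "seed", "outdir"),
    `simulate` = c("n_contigs", "contig_length", "gc", "virus_length",
                   "n_events"),
    `detect-integration` = c("fastq", "host_fasta", "virus_fasta", "k",
                             "max_mismatch_rate", "min_span",
                             "min_subread"),
    `enrich-test` = c("exposed_fastq", "control_fastq", "virus_fasta",
                      "n_resamples"),
    `smallrna` = c("fastq", "control_fastq", "target_fasta", "adapter",
                   "required_length", "required_first_base",
                   "min_retained_length", "antisense_only", "pseudocount"),
    `qpcr` = c("ct_tsv", "target_gene", "reference_genes",
               "calibrator_group", "control_groups", "efficiency"),
    `closed-loop` = c("n_events", "n_reads", "read_len", "error_rate",
                      "junction_reads_per_site", "contig_length",
                      "virus_length", "min_subread"))
  ok <- c(known$common, known[[config$stage]])
  bad <- setdiff(names(config), ok)
  if (length(bad))
    stop(config_error("unknown config key(s) for stage ", config$stage,
                      ": ", paste(bad, collapse = ", ")))
  config$seed <- config$seed %||% 1L
  config
}

config_error <- function(...) {
  structure(class = c("ln_config_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run a pipeline stage from a configuration
#'
#' Single entry point behind the command-line interface. Executes the
#' requested stage, writes result tables, a plain-text log and a
#' machine-readable `summary.json` into the output directory, and echoes
#' the resolved configuration as `config.json`.
#'
#' Stages: `simulate` (genome + provirus + truth), `detect-integration`,
#' `enrich-test`, `smallrna` (one or two libraries; with a control
#' library the fold change is reported), `qpcr`, and `closed-loop`
#' (simulate, then detect, then score against the truth set).
#'
#' @param config list or JSON path; see [validate_config()].
#' @param outdir output directory (created; overrides `config$outdir`).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_config(config)
  outdir <- outdir %||% config$outdir %||% stop(config_error(
    "no output directory given"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config$outdir <- outdir
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_con <- file(file.path(outdir, "log.txt"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "stage: ", config$stage)
  summary <- switch(config$stage,
    "simulate" = .stage_simulate(config, outdir, log_con),
    "detect-integration" = .stage_detect(config, outdir, log_con),
    "enrich-test" = .stage_enrich(config, outdir, log_con),
    "smallrna" = .stage_smallrna(config, outdir, log_con),
    "qpcr" = .stage_qpcr(config, outdir, log_con),
    "closed-loop" = .stage_closed_loop(config, outdir, log_con))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(log_con, "done")
  invisible(summary)
}

.require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(config_error("missing ", what, " file: ",
                      if (is.null(path)) "<unset>" else path))
  path
}

.stage_simulate <- function(cfg, outdir, log) {
  host <- simulate_genome(cfg$n_contigs %||% 1L,
                          cfg$contig_length %||% 1e5,
                          cfg$gc %||% 0.4, seed = cfg$seed)
  virus <- simulate_virus(cfg$virus_length %||% 8000L,
                          seed = cfg$seed + 1L)
  inj <- inject_provirus(host, virus, cfg$n_events %||% 2L,
                         seed = cfg$seed + 2L)
  write_fasta(seq_set(names(host), unname(host)),
              file.path(outdir, "host.fasta"))
  write_fasta(seq_set(names(virus), unname(virus)),
              file.path(outdir, "virus.fasta"))
  write_fasta(seq_set(names(inj$genome), unname(inj$genome)),
              file.path(outdir, "genome_with_provirus.fasta"))
  write_table_tsv(inj$truth, file.path(outdir, "truth_junctions.tsv"))
  .log_line(log, nrow(inj$truth), " truth junctions written")
  list(stage = "simulate", n_contigs = length(host),
       n_truth_junctions = nrow(inj$truth))
}

.stage_detect <- function(cfg, outdir, log) {
  reads <- read_fastq(.require_file(cfg$fastq, "fastq"))
  host <- read_fasta(.require_file(cfg$host_fasta, "host fasta"))
  virus <- read_fasta(.require_file(cfg$virus_fasta, "virus fasta"))
  ap <- aligner_params(k = cfg$k %||% 10L,
                       max_mismatch_rate = cfg$max_mismatch_rate %||% 0.05,
                       min_span = cfg$min_span %||% 15L)
  params <- integration_params(ap, cfg$min_subread %||% 15L)
  calls <- detect_integrations(reads,
                               reference_set(host = host, virus = virus),
                               params)
  write_junctions_tsv(calls, file.path(outdir, "junctions.tsv"))
  .log_line(log, nrow(calls$events), " split-read events")
  list(stage = "detect-integration", n_events = nrow(calls$events),
       total_reads_screened = calls$total_reads_screened,
       rate_per_million = calls$rate_per_million)
}

.stage_enrich <- function(cfg, outdir, log) {
  exposed <- read_fastq(.require_file(cfg$exposed_fastq, "exposed fastq"))
  control <- read_fastq(.require_file(cfg$control_fastq, "control fastq"))
  virus <- read_fasta(.require_file(cfg$virus_fasta, "virus fasta"))
  vidx <- build_index(virus)
  res <- viral_read_enrichment_test(exposed, control, vidx,
                                    cfg$n_resamples %||% 100L,
                                    seed = cfg$seed)
  write_table_tsv(data.frame(resample = seq_along(res$downsampled_counts),
                             viral_count = res$downsampled_counts),
                  file.path(outdir, "downsampled_counts.tsv"))
  .log_line(log, "empirical p = ", format(res$empirical_p))
  list(stage = "enrich-test", control_viral_count = res$control_viral_count,
       exposed_viral_count = res$exposed_viral_count,
       n_resamples = res$n_resamples, empirical_p = res$empirical_p)
}

.stage_smallrna <- function(cfg, outdir, log) {
  target <- read_fasta(.require_file(cfg$target_fasta, "target fasta"))
  if (is.null(cfg$adapter))
    stop(config_error("smallrna stage requires an adapter sequence"))
  params <- classifier_params(
    required_length = cfg$required_length %||% 23L,
    required_first_base = cfg$required_first_base %||% "G",
    min_retained_length = cfg$min_retained_length %||% 15L,
    antisense_only = cfg$antisense_only %||% FALSE)
  tidx <- build_index(target)
  treat <- process_smallrna_library(
    read_fastq(.require_file(cfg$fastq, "fastq")), tidx, cfg$adapter,
    params, library_id = "treatment")
  counts <- list(treat)
  out <- list(stage = "smallrna", treatment_rpm = treat$rpm,
              treatment_count = treat$target_22g_count,
              treatment_total = treat$total_reads)
  if (!is.null(cfg$control_fastq)) {
    ctl <- process_smallrna_library(
      read_fastq(.require_file(cfg$control_fastq, "control fastq")),
      tidx, cfg$adapter, params, library_id = "control")
    counts <- c(counts, list(ctl))
    out$control_rpm <- ctl$rpm
    out$fold_change <- fold_change(treat, ctl,
                                   cfg$pseudocount %||% 0)
  }
  write_smallrna_tsv(counts, file.path(outdir, "smallrna_counts.tsv"))
  .log_line(log, "rpm(treatment) = ", format(treat$rpm))
  out
}

.stage_qpcr <- function(cfg, outdir, log) {
  ct <- read_table_tsv(.require_file(cfg$ct_tsv, "Ct table"))
  res <- relative_expression(ct, cfg$target_gene,
                             cfg$reference_genes,
                             cfg$calibrator_group,
                             efficiency = cfg$efficiency %||% 2)
  grp <- summarize_group(res)
  write_table_tsv(res, file.path(outdir, "per_sample_results.tsv"))
  write_table_tsv(grp, file.path(outdir, "group_summary.tsv"))
  ctrl <- cfg$control_groups %||% cfg$calibrator_group
  stats_json <- NULL
  enough <- all(table(res$group) >= 2) && length(unique(res$group)) >= 2
  if (enough) {
    cmp <- compare_groups(res$log2_fc, res$group, ctrl)
    stats_json <- list(H = cmp$H, p = cmp$p, p_method = cmp$p_method,
                       pairwise = cmp$pairwise)
    jsonlite::write_json(stats_json, file.path(outdir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .log_line(log, nrow(grp), " group summaries written")
  list(stage = "qpcr",
       groups = setNames(as.list(grp$mean_log2), grp$group),
       percent_knockdown = setNames(as.list(grp$percent_knockdown),
                                    grp$group),
       kruskal_wallis = if (enough) list(H = stats_json$H,
                                         p = stats_json$p) else NULL)
}

.stage_closed_loop <- function(cfg, outdir, log) {
  host <- simulate_genome(1L, cfg$contig_length %||% 1e5, seed = cfg$seed)
  virus <- simulate_virus(cfg$virus_length %||% 8000L,
                          seed = cfg$seed + 1L)
  inj <- inject_provirus(host, virus, cfg$n_events %||% 2L,
                         seed = cfg$seed + 2L)
  sim <- simulate_wgs_reads(inj$genome, cfg$n_reads %||% 5000L,
                            cfg$read_len %||% 150L,
                            cfg$error_rate %||% 0, truth = inj$truth,
                            junction_reads_per_site =
                              cfg$junction_reads_per_site %||% 10L,
                            junction_min_flank = 20L,
                            seed = cfg$seed + 3L)
  params <- integration_params(min_subread = cfg$min_subread %||% 15L)
  calls <- detect_integrations(sim$reads,
                               reference_set(host = host, virus = virus),
                               params)
  write_junctions_tsv(calls, file.path(outdir, "junctions.tsv"))
  truth_pos <- unique(inj$truth[, c("contig", "host_pos")])
  found <- unique(calls$events[, c("host_contig", "junction_host_pos")])
  recovered <- if (nrow(truth_pos) == 0L) 0L else
    sum(vapply(seq_len(nrow(truth_pos)), function(i)
      any(found$host_contig == truth_pos$contig[i] &
          found$junction_host_pos == truth_pos$host_pos[i]), logical(1)))
  recall <- if (nrow(truth_pos)) recovered / nrow(truth_pos) else NA_real_
  .log_line(log, "junction recall = ", format(recall))
  list(stage = "closed-loop", n_truth_junction_sites = nrow(truth_pos),
       n_events = nrow(calls$events),
       rate_per_million = calls$rate_per_million,
       junction_site_recall = recall)
}
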