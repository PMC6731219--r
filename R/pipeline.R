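#' Pipeline configuration
#'
#' One flat configuration object driving [run_pipeline()]. The shipped
#' defaults are the thresholds of the published analysis (three-read
#' cluster minima, 200 bp somatic and merge windows, MAPQ cut 37, 1000 bp
#' source proximity); any override sits alongside the recorded default in
#' the run manifest.
#'
#' @param synthetic A [synthetic_config()] (the pipeline's input source),
#'   or `NULL` when `inputs` provides pre-built tables.
#' @param inputs Optional named list of pre-built tables (same elements as
#'   a `simulated_cohort`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "call", "transduce", "annotate", "stats",
#'   "clinical")`.
#' @param outdir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param seed Master seed.
#' @param n_perm Permutations for the expression rank test.
#' @param thresholds Named list of threshold overrides (`min_reads`,
#'   `min_reads_normal`, `join_distance`, `pairing_window`,
#'   `somatic_window`, `sv_min_support`, `sv_min_mapq`, `sv_merge_window`,
#'   `sv_min_length`, `source_proximity`, `dedupe_window`,
#'   `tail_window`, `log_offset`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            inputs = NULL,
                            stages = c("simulate", "call", "transduce",
                                       "annotate", "stats", "clinical"),
                            outdir = NULL, seed = 1L, n_perm = 10000L,
                            thresholds = list()) {
  defaults <- list(min_reads = 3L, min_reads_normal = 3L,
                   join_distance = 500L, pairing_window = 500L,
                   somatic_window = 200L, sv_min_support = 3L,
                   sv_min_mapq = 37, sv_merge_window = 200L,
                   sv_min_length = 1000L, source_proximity = 1000L,
                   dedupe_window = 200L, tail_window = 200,
                   log_offset = 1)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  thr <- utils::modifyList(defaults, thresholds)
  cfg <- list(synthetic = synthetic, inputs = inputs, stages = stages,
              outdir = outdir, seed = as.integer(seed),
              n_perm = as.integer(n_perm), thresholds = thr,
              threshold_defaults = defaults)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read or write a synthetic-cohort configuration as flat YAML
#'
#' The file holds one key per configuration field; `genome` and
#' `family_mix` are named maps. Unknown keys are rejected by the
#' constructor's validation.
#'
#' @param path YAML file path.
#' @return For the reader, a validated [synthetic_config()].
#' @export
read_synthetic_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$genome <- unlist(vals$genome)
  if (!is.null(vals$family_mix)) vals$family_mix <- unlist(vals$family_mix)
  vals$decoy_contig <- NULL
  do.call(synthetic_config, vals)
}

#' @rdname read_synthetic_config_yaml
#' @param config A [synthetic_config()] to serialize.
#' @export
write_synthetic_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x), path, precision = 15)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in their fixed order — cohort simulation
#' (or pre-built inputs), cluster-based insertion calling, SV-based
#' transduction calling, annotation, recurrence/association statistics,
#' and clinical models — writing TSV artifacts when an output directory is
#' configured and returning all results with a run manifest of per-stage
#' content hashes and wall-clock times.
#'
#' @param config A [pipeline_config()].
#' @return list with the stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  stages <- config$stages
  res <- list()
  manifest <- list(config_hash = content_hash(
    config[setdiff(names(config), "outdir")]), stages = list())

  need <- function(stage, what, ok) {
    if (!ok) stop("stage '", stage, "' enabled but required input '",
                  what, "' is missing", call. = FALSE)
  }
  record <- function(name, value, t0) {
    manifest$stages[[name]] <<- list(
      hash = content_hash(value),
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }

  cohort <- config$inputs
  if ("simulate" %in% stages) {
    need("simulate", "synthetic config", !is.null(config$synthetic))
    t0 <- as.numeric(Sys.time())
    cohort <- simulate_cohort(config$synthetic)
    record("simulate", cohort$truth, t0)
  }
  need("call", "discordant-pair tables",
       !("call" %in% stages) || !is.null(cohort$tumor_pairs))

  if ("call" %in% stages) {
    t0 <- as.numeric(Sys.time())
    res$calls <- call_insertions(
      cohort$tumor_pairs, cohort$normal_pairs, cohort$panel_calls,
      decoy_contigs = cohort$annotation$decoy_contig,
      min_reads = thr$min_reads,
      min_reads_normal = thr$min_reads_normal,
      join_distance = thr$join_distance,
      pairing_window = thr$pairing_window,
      somatic_window = thr$somatic_window)
    record("call", res$calls, t0)
  }

  if ("transduce" %in% stages) {
    need("transduce", "SV tables", !is.null(cohort$tumor_svs))
    t0 <- as.numeric(Sys.time())
    sex <- setNames(cohort$clinical$sex, cohort$clinical$sample_id)
    res$transductions <- call_transductions(
      cohort$tumor_svs, cohort$normal_svs, cohort$annotation$sources,
      sex, min_support = thr$sv_min_support,
      min_mapq = thr$sv_min_mapq, merge_window = thr$sv_merge_window,
      min_length = thr$sv_min_length, proximity = thr$source_proximity)
    record("transduce", res$transductions, t0)
  }

  if ("annotate" %in% stages) {
    need("annotate", "called insertions", !is.null(res$calls))
    t0 <- as.numeric(Sys.time())
    unified <- merge_dedupe_calls(
      if (!is.null(res$transductions)) res$transductions else
        data.frame(sample_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   source_id = character(), cytoband = character(),
                   class = character(), support = integer(),
                   stringsAsFactors = FALSE),
      res$calls, window = thr$dedupe_window)
    res$insertions <- annotate_insertions(
      unified, cohort$annotation, cohort$split_reads,
      tail_window = thr$tail_window)
    res$density_replication <- compute_insertion_density(
      res$insertions, cohort$annotation$replication, "bin")
    res$density_chromatin <- compute_insertion_density(
      res$insertions, cohort$annotation$open_closed, "state")
    record("annotate", res$insertions, t0)
  }

  if ("stats" %in% stages) {
    need("stats", "annotated insertions", !is.null(res$insertions))
    t0 <- as.numeric(Sys.time())
    res$gene_summary <- tally_recurrent_genes(res$insertions)
    res$source_summary <- summarize_source_activity(
      res$insertions[!is.na(res$insertions$source_id), , drop = FALSE])
    res$fragile_sites <- fragile_site_fractions(
      res$insertions, cohort$ai_events, cohort$annotation$fragile_sites)
    carrier <- res$insertions[!is.na(res$insertions$nearest_gene), ,
                              drop = FALSE]
    res$expression_test <- rank_uniformity_expression_test(
      cohort$tpm,
      data.frame(sample_id = carrier$sample_id,
                 gene_id = carrier$nearest_gene,
                 stringsAsFactors = FALSE),
      n_perm = config$n_perm,
      seed = derive_seed(config$seed, "expression"))
    res$ai_colocalization <- colocalize_with_ai_breakpoints(
      res$insertions, cohort$ai_events)
    record("stats", res[c("gene_summary", "source_summary",
                          "fragile_sites")], t0)
  }

  if ("clinical" %in% stages) {
    need("clinical", "clinical table", !is.null(cohort$clinical))
    t0 <- as.numeric(Sys.time())
    res$cimp <- score_cimp(cohort$methylation,
                           cohort$methylation_normals)
    res$regression <- fit_log_count_regression(cohort$clinical,
                                               offset = thr$log_offset)
    res$cox <- fit_disease_specific_cox(cohort$clinical)
    record("clinical", list(res$regression$table, res$cox$table), t0)
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name, schema) {
      write_mei_table(df, file.path(config$outdir,
                                    paste0(name, ".tsv")), schema)
    }
    if (!is.null(res$calls)) {
      wr(res$calls, "candidate_insertions", "candidate_insertions")
      write_insertions_bed(res$calls,
                           file.path(config$outdir, "insertions.bed"))
    }
    if (!is.null(res$transductions) && nrow(res$transductions) > 0L) {
      wr(res$transductions, "transductions", "transduction_calls")
    }
    if (!is.null(cohort$clinical)) wr(cohort$clinical, "clinical",
                                      "clinical")
    jsonlite::write_json(
      manifest, file.path(config$outdir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res$cohort <- cohort
  res
}
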