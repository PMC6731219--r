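#' Configuration for the synthetic tumor-cohort generator
#'
#' Bundles every tunable of the simulator with defaults matching the
#' colorectal whole-genome cohort the package models: 202 tumors with a mean
#' of 25 somatic insertions each (median 17, negative-binomial dispersion
#' `size = 1`), a 99/0.26/0.39/0.30 percent LINE-1/Alu/SVA/ERV family mix,
#' about 7% of insertions arising as 3' transductions with 46% of those from
#' a single dominant source element, insertion density enriched ~4.2-fold in
#' late-replicating and ~1.9-fold in closed-chromatin regions, a CIMP-high
#' effect of 0.607 and an allelic-imbalance effect of 0.0826 per 10% on log
#' insertion counts, and a disease-specific log-hazard of 0.108 per 10
#' insertions.
#'
#' @param n_tumors Number of tumor/normal pairs.
#' @param genome Named numeric vector of chromosome lengths in bp
#'   (decoy contig excluded; see `decoy_contig`).
#' @param n_genes Number of protein-coding gene models to place.
#' @param mean_insertions_per_tumor Marginal mean somatic insertion count.
#' @param dispersion Negative-binomial `size`; `size = 1` reproduces a
#'   median of 17 at mean 25.
#' @param transduction_fraction Proportion of LINE-1 insertions that are 3'
#'   transductions.
#' @param dominant_source_share Share of transductions assigned to the
#'   single most active source element.
#' @param family_mix Named proportions over `LINE-1`, `Alu`, `SVA`, `ERV`;
#'   must sum to 1.
#' @param late_replication_enrichment Planted density ratio, latest vs
#'   earliest replication-timing bin.
#' @param closed_chromatin_enrichment Planted density ratio, closed vs open
#'   chromatin.
#' @param germline_panel_size Number of unmatched normals in the
#'   panel-of-normals.
#' @param germline_per_sample Mean germline insertions planted per sample.
#' @param subthreshold_fraction Proportion of somatic truths emitted with
#'   only two supporting pairs (below the three-read cluster minimum).
#' @param cimp_log_effect Additive CIMP-high effect on log insertion count.
#' @param ai_log_effect_per_10pct Additive effect on log count per 10% of
#'   the genome under allelic imbalance.
#' @param log_hazard_per_10_insertions Survival log-hazard per 10
#'   insertions.
#' @param censoring_rate Target proportion of censored survival records.
#' @param n_sources Size of the full-length reference L1HS source catalog.
#' @param n_active_sources Number of catalog elements allowed to seed
#'   transductions.
#' @param noise_sv_rate Noise SVs emitted per signal SV.
#' @param read_length Read length in bp used for anchor spans.
#' @param cimp_prevalence Probability a tumor is CIMP-high.
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_tumors = 202L,
                             genome = c(chr1 = 12e6, chr2 = 8e6),
                             n_genes = 120L,
                             mean_insertions_per_tumor = 25,
                             dispersion = 1.0,
                             transduction_fraction = 346 / 5072,
                             dominant_source_share = 0.46,
                             family_mix = c("LINE-1" = 5024, Alu = 13,
                                            SVA = 20, ERV = 15) / 5072,
                             late_replication_enrichment = 3.06 / 0.73,
                             closed_chromatin_enrichment = 1.78 / 0.96,
                             germline_panel_size = 234L,
                             germline_per_sample = 5,
                             subthreshold_fraction = 0.05,
                             cimp_log_effect = 0.607,
                             ai_log_effect_per_10pct = 0.0826,
                             log_hazard_per_10_insertions = 0.108,
                             censoring_rate = 0.7,
                             n_sources = 60L,
                             n_active_sources = 20L,
                             noise_sv_rate = 0.2,
                             read_length = 100L,
                             cimp_prevalence = 0.25,
                             seed = 1L) {
  cfg <- list(
    n_tumors = as.integer(n_tumors), genome = genome,
    n_genes = as.integer(n_genes),
    mean_insertions_per_tumor = mean_insertions_per_tumor,
    dispersion = dispersion,
    transduction_fraction = transduction_fraction,
    dominant_source_share = dominant_source_share,
    family_mix = family_mix,
    late_replication_enrichment = late_replication_enrichment,
    closed_chromatin_enrichment = closed_chromatin_enrichment,
    germline_panel_size = as.integer(germline_panel_size),
    germline_per_sample = germline_per_sample,
    subthreshold_fraction = subthreshold_fraction,
    cimp_log_effect = cimp_log_effect,
    ai_log_effect_per_10pct = ai_log_effect_per_10pct,
    log_hazard_per_10_insertions = log_hazard_per_10_insertions,
    censoring_rate = censoring_rate,
    n_sources = as.integer(n_sources),
    n_active_sources = as.integer(n_active_sources),
    noise_sv_rate = noise_sv_rate,
    read_length = as.integer(read_length),
    cimp_prevalence = cimp_prevalence,
    decoy_contig = "hs37d5",
    seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(length(cfg$genome) >= 1L, all(cfg$genome > 0),
            !is.null(names(cfg$genome)))
  props <- c(cfg$transduction_fraction, cfg$dominant_source_share,
             cfg$censoring_rate, cfg$subthreshold_fraction,
             cfg$cimp_prevalence)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$family_mix) - 1) > 1e-8) {
    stop("family_mix must sum to 1", call. = FALSE)
  }
  if (any(cfg$family_mix < 0)) stop("family_mix must be non-negative",
                                    call. = FALSE)
  if (cfg$mean_insertions_per_tumor < 0 || cfg$dispersion <= 0 ||
      cfg$late_replication_enrichment <= 0 ||
      cfg$closed_chromatin_enrichment <= 0) {
    stop("rates and enrichments must be positive", call. = FALSE)
  }
  if (cfg$n_tumors < 1L) stop("n_tumors must be >= 1", call. = FALSE)
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  tumors: %d | genome: %s (%.1f Mbp)\n", x$n_tumors,
              paste(names(x$genome), collapse = ","),
              sum(x$genome) / 1e6))
  cat(sprintf("  insertions/tumor: mean %.1f (NB size %.2f), %d genes\n",
              x$mean_insertions_per_tumor, x$dispersion, x$n_genes))
  cat(sprintf("  transductions: %.1f%% of LINE-1, dominant source %.0f%%\n",
              100 * x$transduction_fraction,
              100 * x$dominant_source_share))
  invisible(x)
}
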