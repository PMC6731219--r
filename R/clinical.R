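#' CIMP scoring from MS-MLPA probe methylation ratios
#'
#' A probe is methylated when its tumor ratio exceeds a threshold derived
#' from normal-tissue probes (per-probe mean + `threshold_sd` SDs by
#' default). A gene is methylated when at least `probe_frac` of its probes
#' are; a tumor with `gene_cut` or more of the eight panel genes
#' methylated is CIMP-high, otherwise CIMP-low.
#'
#' @param tumor_probes data.frame `probe_id`, `gene`, `sample_id`,
#'   `ratio`.
#' @param normal_probes data.frame `probe_id`, `gene`, `normal_id`,
#'   `ratio`.
#' @param probe_frac Fraction of probes needed to call a gene (default
#'   0.25).
#' @param gene_cut Methylated genes needed for CIMP-high (default 5).
#' @param threshold_sd SD multiplier on the normal mean (default 3).
#' @return list with `samples` (per-sample class) and `genes` (per
#'   sample x gene methylation calls).
#' @export
score_cimp <- function(tumor_probes, normal_probes, probe_frac = 0.25,
                       gene_cut = 5L, threshold_sd = 3) {
  panel <- c("CACNA1G", "CDKN2A", "CRABP1", "IGF2", "MLH1", "NEUROG1",
             "RUNX3", "SOCS1")
  missing <- setdiff(panel, unique(tumor_probes$gene))
  if (length(missing) > 0L) {
    stop("panel gene(s) missing from probe table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  thr <- tapply(normal_probes$ratio, normal_probes$probe_id,
                function(r) mean(r) + threshold_sd * sd(r))
  tp <- tumor_probes
  tp$threshold <- thr[tp$probe_id]
  if (any(is.na(tp$threshold))) {
    stop("tumor probe(s) without normal-derived threshold",
         call. = FALSE)
  }
  tp$methylated <- tp$ratio > tp$threshold
  gene_calls <- stats::aggregate(methylated ~ sample_id + gene, data = tp,
                                 FUN = function(m) mean(m) >= probe_frac)
  n_meth <- tapply(gene_calls$methylated, gene_calls$sample_id, sum)
  samples <- data.frame(sample_id = names(n_meth),
                        n_methylated_genes = as.integer(n_meth),
                        cimp = ifelse(n_meth >= gene_cut, "CIMP-H",
                                      "CIMP-L"),
                        stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  list(samples = samples, genes = gene_calls)
}

#' Driver-mutation status from a filtered variant table
#'
#' Variants failing the coverage (>= 4 reads), allelic-fraction (>= 10%)
#' or quality (>= 20) filters are dropped. KRAS is positive on any
#' non-synonymous change at codons 12, 13, 61, 117 or 146 in any
#' transcript; BRAF only on the V600E hotspot; TP53 on any non-synonymous
#' change.
#'
#' @param variants data.frame with `sample_id`, `gene`, `codon`,
#'   `consequence` (`"non_synonymous"` counts), `protein_change`,
#'   `coverage`, `allelic_fraction` (percent), `quality`.
#' @param min_coverage,min_af,min_quality Filter cutoffs (4, 10, 20).
#' @return data.frame per sample with logical `tp53`, `kras_hotspot`,
#'   `braf_v600e` flags.
#' @export
classify_driver_mutations <- function(variants, min_coverage = 4,
                                      min_af = 10, min_quality = 20) {
  v <- variants[variants$coverage >= min_coverage &
                variants$allelic_fraction >= min_af &
                variants$quality >= min_quality, , drop = FALSE]
  samples <- unique(variants$sample_id)
  ns <- v$consequence == "non_synonymous"
  kras_codons <- c(12, 13, 61, 117, 146)
  flag <- function(cond) {
    vapply(samples, function(s) any(cond & v$sample_id == s), logical(1))
  }
  data.frame(
    sample_id = samples,
    tp53 = flag(v$gene == "TP53" & ns),
    kras_hotspot = flag(v$gene == "KRAS" & ns & v$codon %in% kras_codons),
    braf_v600e = flag(v$gene == "BRAF" & v$protein_change == "V600E"),
    stringsAsFactors = FALSE, row.names = NULL)
}

# shared model-frame construction for the two clinical models
clinical_model_frame <- function(records) {
  data.frame(
    sample_id = records$sample_id,
    count = records$insertion_count,
    cimp_h = as.integer(records$cimp == "CIMP-H"),
    ai10 = records$ai_fraction * 10,       # per 10% of the genome
    tp53 = as.integer(records$tp53),
    msi = as.integer(records$msi == "MSI"),
    braf = as.integer(records$braf_v600e),
    coverage10 = records$mean_coverage / 10,
    age10 = records$age / 10,
    age_cat = cut(records$age, c(-Inf, 55, 75, Inf),
                  labels = c("<55", "[55,75)", ">=75"), right = FALSE),
    male = as.integer(records$sex == "male"),
    dukes = factor(records$dukes_stage, levels = c("A", "B", "C", "D")),
    proximal = as.integer(records$location == "proximal"),
    location = records$location,
    time = records$followup_days,
    event = records$event,
    stringsAsFactors = FALSE)
}

#' Multiple linear regression for log insertion counts
#'
#' Ordinary least squares for `log(count + offset)` on CIMP-high, allelic
#' imbalance per 10% of the genome, TP53, MSI, mean coverage per 10 reads,
#' age per 10 years, sex, Dukes stage and proximal location, on complete
#' cases only. Reports per-term coefficient, SE, z and normal p-value, a
#' Pearson chi-square goodness-of-fit (sum of squared standardized
#' residuals against chi-square on n - p df) and variance inflation
#' factors as a collinearity screen.
#'
#' @param records Clinical table (see [emit_clinical_tables()] for the
#'   column dictionary).
#' @param offset Added inside the log (default 1; must be positive when
#'   zero counts are present).
#' @return A `mei_model_fit` list with `table`, `gof`, `vif`, `n`, `fit`.
#' @export
fit_log_count_regression <- function(records, offset = 1) {
  mf <- clinical_model_frame(records)
  vars <- c("count", "cimp_h", "ai10", "tp53", "msi", "coverage10",
            "age10", "male", "dukes", "proximal")
  mf <- mf[complete.cases(mf[, vars]), , drop = FALSE]
  if (any(mf$count == 0) && offset <= 0) {
    stop("zero counts require a positive log offset", call. = FALSE)
  }
  mf$y <- log(mf$count + offset)
  fit <- lm(y ~ cimp_h + ai10 + tp53 + msi + coverage10 + age10 + male +
              dukes + proximal, data = mf)
  al <- alias(fit)
  if (!is.null(al$Complete)) {
    stop("perfect collinearity among terms: ",
         paste(rownames(al$Complete), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, 1],
                    se = sm$coefficients[, 2],
                    stringsAsFactors = FALSE)
  tab$z <- tab$coef / tab$se
  tab$p <- 2 * pnorm(-abs(tab$z))
  rownames(tab) <- NULL
  rs <- stats::rstandard(fit)
  gof_stat <- sum(rs ^ 2)
  gof_df <- fit$df.residual
  gof <- list(statistic = gof_stat, df = gof_df,
              p_value = pchisq(gof_stat, gof_df, lower.tail = FALSE))
  vifs <- car::vif(fit)
  out <- list(table = tab, gof = gof, vif = vifs, n = nrow(mf),
              fit = fit)
  class(out) <- "mei_model_fit"
  out
}

#' Disease-specific Cox proportional-hazards model
#'
#' Partial-likelihood fit of disease-specific survival on insertion count
#' per 10 insertions, MSI, CIMP-high, BRAF V600E, age categories [55,75)
#' and >= 75 (reference < 55), sex, Dukes stage and allelic imbalance per
#' 10%, with the baseline hazard stratified by tumor location. Deaths from
#' causes other than the disease are censoring events in the input coding.
#' Reports hazard ratios with 95% CIs, the Grambsch-Therneau
#' proportional-hazards test per term (scaled Schoenfeld residuals) and a
#' dfbeta influence summary.
#'
#' @param records Clinical table; complete cases are used.
#' @return A `mei_model_fit` list with `table` (incl. `hr`, `hr_lo`,
#'   `hr_hi`), `ph_test`, `max_abs_dfbeta`, `n`, `n_events`, `fit`.
#' @export
fit_disease_specific_cox <- function(records) {
  mf <- clinical_model_frame(records)
  vars <- c("count", "msi", "cimp_h", "braf", "age_cat", "male", "dukes",
            "ai10", "location", "time", "event")
  mf <- mf[complete.cases(mf[, vars]), , drop = FALSE]
  if (sum(mf$event) == 0L) stop("no events in the data", call. = FALSE)
  ev_by_stratum <- tapply(mf$event, mf$location, sum)
  if (any(ev_by_stratum == 0)) {
    warning("stratum without events: ",
            paste(names(ev_by_stratum)[ev_by_stratum == 0],
                  collapse = ", "), call. = FALSE)
  }
  mf$count10 <- mf$count / 10
  fit <- survival::coxph(
    survival::Surv(time, event) ~ count10 + msi + cimp_h + braf +
      age_cat + male + dukes + ai10 + survival::strata(location),
    data = mf)
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    se = sm$coefficients[, "se(coef)"],
                    stringsAsFactors = FALSE)
  tab$z <- tab$coef / tab$se
  tab$p <- 2 * pnorm(-abs(tab$z))
  hr <- t(vapply(seq_len(nrow(tab)), function(i) {
    if (is.finite(tab$se[i]) && tab$se[i] > 0 && is.finite(tab$coef[i]))
      unlist(hazard_ratio_from_coefficient(tab$coef[i], tab$se[i]))
    else c(NA_real_, NA_real_, NA_real_)
  }, numeric(3)))
  tab$hr <- hr[, 1]; tab$hr_lo <- hr[, 2]; tab$hr_hi <- hr[, 3]
  rownames(tab) <- NULL
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  dfb <- stats::residuals(fit, type = "dfbeta")
  out <- list(table = tab,
              ph_test = if (!is.null(zph)) zph$table else NULL,
              max_abs_dfbeta = apply(abs(dfb), 2, max),
              n = nrow(mf), n_events = sum(mf$event), fit = fit)
  class(out) <- "mei_model_fit"
  out
}

#' @export
print.mei_model_fit <- function(x, ...) {
  cat(sprintf("Model fit on n = %d%s\n", x$n,
              if (!is.null(x$n_events))
                sprintf(" (%d events)", x$n_events) else ""))
  print(format(x$table, digits = 3), row.names = FALSE)
  if (!is.null(x$gof)) {
    cat(sprintf("Pearson GOF: X2 = %.2f on %d df, p = %.3g\n",
                x$gof$statistic, x$gof$df, x$gof$p_value))
  }
  invisible(x)
}

#' Hazard ratio and confidence interval from a Cox coefficient
#'
#' @param coefficient Log-hazard coefficient.
#' @param se Its standard error (must be positive).
#' @param level Confidence level (default 0.95).
#' @return list with `hr`, `lower`, `upper`.
#' @export
hazard_ratio_from_coefficient <- function(coefficient, se, level = 0.95) {
  if (!is.numeric(se) || se <= 0) stop("se must be positive",
                                       call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  list(hr = exp(coefficient),
       lower = exp(coefficient - z * se),
       upper = exp(coefficient + z * se))
}

#' False-positive rate with exact binomial confidence interval
#'
#' From visual-inspection validation labels: the false-positive rate is
#' the share of reviewed calls judged not to be true somatic insertions,
#' with a Clopper-Pearson (default) or Wilson 95% interval.
#'
#' @param labels Logical vector, `TRUE` for calls validated as true
#'   somatic insertions.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @return list with `n`, `n_true`, `n_false`, `rate`, `ci` (length 2).
#' @export
estimate_false_positive_rate <- function(labels, conf_level = 0.95,
                                         method = c("clopper-pearson",
                                                    "wilson")) {
  method <- match.arg(method)
  n <- length(labels)
  if (n == 0L) stop("no validation labels", call. = FALSE)
  n_false <- sum(!labels)
  rate <- n_false / n
  ci <- if (method == "clopper-pearson") {
    as.numeric(binom.test(n_false, n,
                          conf.level = conf_level)$conf.int)
  } else {
    as.numeric(stats::prop.test(n_false, n, conf.level = conf_level,
                                correct = FALSE)$conf.int)
  }
  list(n = n, n_true = n - n_false, n_false = n_false, rate = rate,
       ci = ci)
}
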