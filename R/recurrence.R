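#' Per-gene insertion recurrence tallies
#'
#' Counts cohort-wide insertions per gene (an insertion overlapping
#' several genes counts once in each), flags genes with two or more
#' insertions as recurrent, and annotates cancer-census roles when a
#' census list is supplied.
#'
#' @param insertions Annotated insertion table with a `gene_id` column
#'   (comma-joined when several genes overlap).
#' @param census Optional data.frame with `gene_id` and `role`.
#' @return data.frame `gene_id`, `count`, `recurrent`, `census_role`.
#' @export
tally_recurrent_genes <- function(insertions, census = NULL) {
  gids <- insertions$gene_id[!is.na(insertions$gene_id)]
  gids <- unlist(strsplit(gids, ",", fixed = TRUE))
  if (length(gids) == 0L) {
    return(data.frame(gene_id = character(), count = integer(),
                      recurrent = logical(), census_role = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(gids)
  out <- data.frame(gene_id = names(tab), count = as.integer(tab),
                    recurrent = as.integer(tab) >= 2L,
                    census_role = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(census)) {
    out$census_role <- census$role[match(out$gene_id, census$gene_id)]
  }
  out <- out[order(-out$count, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Fragile-site insertion and allelic-imbalance fractions
#'
#' For each fragile site: the insertion fraction is the number of cohort
#' insertions whose breakpoint midpoint falls in the site divided by the
#' total number of insertions; the AI fraction counts only focal AI events
#' with both breakpoints inside the site, over all AI events. The
#' ratio insertion/AI classifies the site: in (0,1) AI-high, above 1
#' retrotransposon-high, undefined when the AI fraction is zero.
#'
#' @param insertions Insertion table (`chrom`, `start`, `end`).
#' @param ai_events AI segment table (`chrom`, `bp1`, `bp2` breakpoint
#'   coordinates).
#' @param fragile_sites data.frame `site_id`, `chrom`, `start`, `end`.
#' @return data.frame per site with fractions, ratio and category.
#' @export
fragile_site_fractions <- function(insertions, ai_events, fragile_sites) {
  n_ins <- nrow(insertions)
  n_ai <- nrow(ai_events)
  if (n_ins == 0L) stop("no insertions; fractions undefined",
                        call. = FALSE)
  mid <- (insertions$start + insertions$end) %/% 2
  rows <- lapply(seq_len(nrow(fragile_sites)), function(i) {
    fs <- fragile_sites[i, ]
    ins_in <- sum(insertions$chrom == fs$chrom & mid >= fs$start &
                    mid < fs$end)
    ai_in <- if (n_ai > 0L) {
      sum(ai_events$chrom == fs$chrom &
            ai_events$bp1 >= fs$start & ai_events$bp1 < fs$end &
            ai_events$bp2 >= fs$start & ai_events$bp2 < fs$end)
    } else 0L
    ins_frac <- ins_in / n_ins
    ai_frac <- if (n_ai > 0L) ai_in / n_ai else 0
    ratio <- if (ai_frac > 0) ins_frac / ai_frac else NA_real_
    category <- if (is.na(ratio) || ratio == 0) "undefined"
      else if (ratio > 1) "retrotransposon-high" else "AI-high"
    data.frame(site_id = fs$site_id, insertion_count = ins_in,
               ai_count = ai_in, insertion_fraction = ins_frac,
               ai_fraction = ai_frac, ratio = ratio,
               category = category, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-sample Fisher-Pitman permutation test
#'
#' Tests equality of distribution between two groups using the sum of
#' group-one values as statistic. All assignments are enumerated exactly
#' when the number of combinations is at most `exact_limit`; otherwise
#' `reps` Monte Carlo draws are used (with add-one correction). The
#' two-sided p-value is the tail probability of the statistic centered at
#' its permutation mean.
#'
#' @param x,y Numeric vectors for the two groups (both non-empty).
#' @param reps Monte Carlo permutations (default 10000).
#' @param seed Optional seed for the Monte Carlo path.
#' @param exact_limit Maximum combinations enumerated exactly.
#' @return list with `statistic`, `p_value`, `method` (`exact`/`mc`).
#' @export
fisher_pitman_test <- function(x, y, reps = 10000L, seed = NULL,
                               exact_limit = 1e5) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pool <- c(x, y)
  n1 <- length(x)
  obs <- sum(x)
  center <- n1 * mean(pool)
  n_comb <- choose(length(pool), n1)
  if (n_comb <= exact_limit) {
    sums <- utils::combn(pool, n1, sum)
    p <- mean(abs(sums - center) >= abs(obs - center) - 1e-12)
    method <- "exact"
  } else {
    if (!is.null(seed)) set.seed(seed)
    sums <- vapply(seq_len(reps), function(i)
      sum(sample(pool, n1)), numeric(1))
    p <- (sum(abs(sums - center) >= abs(obs - center) - 1e-12) + 1) /
      (reps + 1)
    method <- "mc"
  }
  list(statistic = obs, p_value = min(1, p), method = method)
}

#' Rank-uniformity test for insertion effects on expression
#'
#' For every (gene, insertion-carrying sample) pair, the carrier's rank of
#' TPM among all samples (ascending, ties broken randomly under the run
#' seed) is recorded. Under no insertion effect the ranks are uniform on
#' 1..S; the statistic is the chi-square sum-of-squared-error of the rank
#' frequency table (one bin per rank), and the p-value is the proportion
#' of permutations with uniformly redrawn ranks whose statistic is at
#' least the observed one, with add-one correction.
#'
#' @param tpm Gene x sample numeric matrix with dimnames.
#' @param insertion_genes data.frame with `sample_id` and `gene_id`
#'   columns (the nearest/overlapping gene of each insertion).
#' @param n_perm Number of permutations (default 100000).
#' @param seed Seed for tie-breaking and permutation draws.
#' @return list with `statistic`, `p_value`, `ranks`, `n_obs`, `n_perm`.
#' @export
rank_uniformity_expression_test <- function(tpm, insertion_genes,
                                            n_perm = 100000L, seed = 1L) {
  if (ncol(tpm) < 2L) stop("need at least two samples", call. = FALSE)
  set.seed(seed)
  S <- ncol(tpm)
  # one rank per (gene, carrier sample) pair: several insertions from one
  # sample near the same gene contribute a single observation
  insertion_genes <- unique(insertion_genes[, c("sample_id", "gene_id")])
  missing <- setdiff(unique(insertion_genes$gene_id), rownames(tpm))
  if (length(missing) > 0L) {
    warning("genes absent from the expression matrix skipped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...", call. = FALSE)
  }
  obs_ranks <- integer(0)
  for (i in seq_len(nrow(insertion_genes))) {
    g <- insertion_genes$gene_id[i]
    s <- insertion_genes$sample_id[i]
    if (!g %in% rownames(tpm) || !s %in% colnames(tpm)) next
    r <- rank(tpm[g, ], ties.method = "random")
    obs_ranks <- c(obs_ranks, as.integer(r[s]))
  }
  n_obs <- length(obs_ranks)
  if (n_obs == 0L) stop("no usable (gene, sample) observations",
                        call. = FALSE)
  chisq_stat <- function(counts, expected) {
    sum((counts - expected) ^ 2 / expected)
  }
  expected <- n_obs / S
  obs_stat <- chisq_stat(tabulate(obs_ranks, nbins = S), expected)
  # permutation null: N ranks uniform on 1..S <=> multinomial table
  perm_tabs <- rmultinom(n_perm, n_obs, rep(1 / S, S))
  perm_stats <- colSums((perm_tabs - expected) ^ 2 / expected)
  p <- (sum(perm_stats >= obs_stat - 1e-12) + 1) / (n_perm + 1)
  list(statistic = obs_stat, p_value = p, ranks = obs_ranks,
       n_obs = n_obs, n_perm = n_perm)
}

#' Colocalization of insertions with allelic-imbalance breakpoints
#'
#' An insertion colocalizes when its breakpoint midpoint lies within
#' `window` bp of any AI breakpoint of the same sample; each insertion is
#' counted at most once however many breakpoints it matches.
#'
#' @param insertions Insertion table with `sample_id`, `chrom`, `start`,
#'   `end`.
#' @param ai_events AI table with `sample_id`, `chrom`, `bp1`, `bp2`.
#' @param window Half-width in bp (default 5000).
#' @return The colocalizing subset of `insertions`.
#' @export
colocalize_with_ai_breakpoints <- function(insertions, ai_events,
                                           window = 5000L) {
  if (nrow(insertions) == 0L || nrow(ai_events) == 0L) {
    return(insertions[0L, , drop = FALSE])
  }
  mid <- (insertions$start + insertions$end) %/% 2
  hit <- vapply(seq_len(nrow(insertions)), function(i) {
    ai <- ai_events[ai_events$sample_id == insertions$sample_id[i] &
                    ai_events$chrom == insertions$chrom[i], ,
                    drop = FALSE]
    if (nrow(ai) == 0L) return(FALSE)
    any(abs(ai$bp1 - mid[i]) <= window | abs(ai$bp2 - mid[i]) <= window)
  }, logical(1))
  out <- insertions[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
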