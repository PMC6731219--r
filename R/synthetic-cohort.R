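#' Plant ground-truth insertions for a synthetic cohort
#'
#' Draws per-sample clinical covariates, then per-tumor somatic insertion
#' counts from a lognormal moment-matched to a negative binomial with the
#' configured mean and dispersion, with the CIMP and allelic-imbalance
#' effects entering the log mean. Insertions are placed with probability
#' proportional to the configured late-replication and closed-chromatin
#' enrichments; LINE-1 insertions become 3' transductions at the configured
#' fraction, with the dominant source element taking its configured share.
#' A shared pool of germline insertion loci is planted per sample and used
#' as the panel-of-normals.
#'
#' @param config A [synthetic_config()].
#' @param annotation A `cohort_annotation` from [build_annotation()].
#' @return data.frame of ground-truth insertions (`sample_id`, `chrom`,
#'   `position`, `family`, `somatic`, `transduction`, `source_id`,
#'   `gene_id`, `poly_tail`, `strand`, `subthreshold`) with the covariate
#'   table attached as attribute `covariates` and the germline locus pool
#'   as attribute `germline_pool`.
#' @export
simulate_cohort_truth <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(annotation, "cohort_annotation"))
  set.seed(derive_seed(config$seed, "truth"))
  cov <- simulate_covariates(config)

  # log(count + 1) is linear in the covariates with Gaussian noise whose
  # variance moment-matches NB(mean, size = dispersion) overdispersion
  # (CV^2 ~ 1/size + (1 + 1/size)/mu). The +1 convention matches the
  # analysis model, so regression recovers the effects without offset
  # bias; at dispersion 1 and mean 25 the marginal median is 17.
  lp <- config$cimp_log_effect * (cov$cimp == "CIMP-H") +
    config$ai_log_effect_per_10pct * (cov$ai_fraction * 10)
  counts <- if (config$mean_insertions_per_tumor == 0) {
    rep(0L, config$n_tumors)
  } else {
    M <- config$mean_insertions_per_tumor
    s <- config$dispersion
    sigma2 <- log(1 + 1 / s + (1 + 1 / s) / M)
    b0 <- log(M + 1) - sigma2 / 2 - log(mean(exp(lp)))
    y <- b0 + lp + sqrt(sigma2) * rnorm(config$n_tumors)
    as.integer(pmax(0, round(exp(y) - 1)))
  }

  # germline locus pool, shared across samples; doubles as the panel
  # joint placement-weight segments are computed once per cohort
  attr(annotation, "placement_segments") <-
    placement_segments(config, annotation)
  pool <- place_positions(40L, config, annotation,
                          min_separation = 1500L)
  pool$family <- sample(names(config$family_mix), nrow(pool),
                        replace = TRUE, prob = config$family_mix)
  pool$locus_id <- sprintf("GL%03d", seq_len(nrow(pool)))

  active <- annotation$sources$element_id[annotation$sources$cancer_active]
  dominant <- if (length(active) > 0L) sort(active)[1L] else NA_character_

  # keep planted insertions outside the germline pool's filter window and
  # outside the source-attribution radius of catalog 3' ends, where truth
  # attribution would be genuinely ambiguous
  avoid_loci <- rbind(
    pool[, c("chrom", "position")],
    data.frame(chrom = annotation$sources$chrom,
               position = annotation$sources$three_prime,
               stringsAsFactors = FALSE))

  rows <- vector("list", config$n_tumors)
  for (i in seq_len(config$n_tumors)) {
    n <- counts[i]
    som <- if (n > 0L) {
      pos <- place_positions(n, config, annotation, avoid = avoid_loci,
                             avoid_window = 1500L,
                             min_separation = 1500L)
      fam <- sample(names(config$family_mix), n, replace = TRUE,
                    prob = config$family_mix)
      td <- fam == "LINE-1" &
        runif(n) < config$transduction_fraction & length(active) > 0L
      src <- rep(NA_character_, n)
      if (any(td)) {
        take_dom <- runif(sum(td)) < config$dominant_source_share
        others <- setdiff(active, dominant)
        src[td] <- ifelse(take_dom, dominant,
                          if (length(others) > 0L)
                            sample(others, sum(td), replace = TRUE)
                          else dominant)
      }
      strand <- sample(c("forward", "reverse"), n, replace = TRUE)
      tail <- ifelse(strand == "reverse", "A", "T")
      tail[runif(n) < 0.15] <- "none"
      data.frame(sample_id = cov$sample_id[i], chrom = pos$chrom,
                 position = pos$position, family = fam, somatic = TRUE,
                 transduction = td, source_id = src,
                 gene_id = NA_character_, poly_tail = tail,
                 strand = strand,
                 subthreshold = runif(n) < config$subthreshold_fraction,
                 stringsAsFactors = FALSE)
    } else NULL
    gl_take <- runif(nrow(pool)) <
      config$germline_per_sample / max(1L, nrow(pool))
    glm_df <- if (any(gl_take)) {
      data.frame(sample_id = cov$sample_id[i],
                 chrom = pool$chrom[gl_take],
                 position = pool$position[gl_take],
                 family = pool$family[gl_take], somatic = FALSE,
                 transduction = FALSE, source_id = NA_character_,
                 gene_id = NA_character_, poly_tail = "none",
                 strand = "forward", subthreshold = FALSE,
                 stringsAsFactors = FALSE)
    } else NULL
    rows[[i]] <- rbind(som, glm_df)
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    truth <- data.frame(sample_id = character(), chrom = character(),
                        position = integer(), family = character(),
                        somatic = logical(), transduction = logical(),
                        source_id = character(), gene_id = character(),
                        poly_tail = character(), strand = character(),
                        subthreshold = logical(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL

  # planted gene context
  if (nrow(truth) > 0L && nrow(annotation$genes) > 0L) {
    g <- annotation$genes
    for (j in seq_len(nrow(truth))) {
      hit <- g$gene_id[g$chrom == truth$chrom[j] &
                       g$start <= truth$position[j] &
                       truth$position[j] < g$end]
      if (length(hit) > 0L) truth$gene_id[j] <- hit[1L]
    }
  }

  cov$insertion_count <- counts
  attr(truth, "covariates") <- cov
  attr(truth, "germline_pool") <- pool
  truth
}

# placement weighted by replication-bin and chromatin-state enrichment;
# resampled away from an avoid set of loci and, so that read clusters of
# distinct events can never chain together, kept mutually separated
place_positions <- function(n, config, annotation, avoid = NULL,
                            avoid_window = 500L, min_separation = 0L) {
  if (n == 0L) {
    return(data.frame(chrom = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  seg <- placement_segments(config, annotation)
  draw <- function(k) {
    idx <- sample.int(nrow(seg), k, replace = TRUE, prob = seg$w)
    pos <- seg$start[idx] +
      floor(runif(k) * (seg$end[idx] - seg$start[idx]))
    data.frame(chrom = seg$chrom[idx], position = as.integer(pos),
               stringsAsFactors = FALSE)
  }
  out <- draw(n)
  too_close <- function(df) {
    bad <- rep(FALSE, nrow(df))
    if (!is.null(avoid) && nrow(avoid) > 0L) {
      bad <- vapply(seq_len(nrow(df)), function(j) {
        any(avoid$chrom == df$chrom[j] &
              abs(avoid$position - df$position[j]) <= avoid_window)
      }, logical(1))
    }
    if (min_separation > 0L) {
      o <- order(df$chrom, df$position)
      ds <- diff(df$position[o])
      same <- df$chrom[o][-1] == df$chrom[o][-nrow(df)]
      clash <- which(same & ds <= min_separation)
      # resample the later of each clashing pair
      bad[o[clash + 1L]] <- TRUE
    }
    bad
  }
  for (it in 1:50) {
    bad <- too_close(out)
    if (!any(bad)) break
    out[bad, ] <- draw(sum(bad))
  }
  out
}

# joint replication x chromatin segment table with per-bp weights, cached
# on the annotation bundle's environment-free structure via attribute
placement_segments <- function(config, annotation) {
  seg <- attr(annotation, "placement_segments")
  if (!is.null(seg)) return(seg)
  rep_gr <- intervals_to_granges(annotation$replication)
  oc_gr <- intervals_to_granges(annotation$open_closed)
  ov <- GenomicRanges::findOverlaps(rep_gr, oc_gr)
  pieces <- GenomicRanges::pintersect(
    rep_gr[S4Vectors::queryHits(ov)], oc_gr[S4Vectors::subjectHits(ov)])
  seg <- granges_to_intervals(pieces)
  seg$bin <- annotation$replication$bin[S4Vectors::queryHits(ov)]
  seg$state <- annotation$open_closed$state[S4Vectors::subjectHits(ov)]
  seg <- seg[seg$end > seg$start, c("chrom", "start", "end", "bin",
                                    "state")]
  w_bin <- config$late_replication_enrichment ^ (seg$bin / 4)
  w_chr <- ifelse(seg$state == "closed",
                  config$closed_chromatin_enrichment, 1)
  seg$w <- w_bin * w_chr * (seg$end - seg$start)
  rownames(seg) <- NULL
  seg
}

simulate_covariates <- function(config) {
  n <- config$n_tumors
  data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    cimp = ifelse(runif(n) < config$cimp_prevalence, "CIMP-H", "CIMP-L"),
    ai_fraction = rbeta(n, 2, 6),
    msi = ifelse(runif(n) < 12 / 202, "MSI", "MSS"),
    tp53 = runif(n) < 0.5,
    braf_v600e = runif(n) < 0.1,
    kras_hotspot = runif(n) < 0.4,
    dukes_stage = sample(c("A", "B", "C", "D"), n, replace = TRUE,
                         prob = c(0.15, 0.35, 0.30, 0.20)),
    age = round(runif(n, 40, 90)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    location = sample(c("proximal", "distal"), n, replace = TRUE,
                      prob = c(0.4, 0.6)),
    mean_coverage = round(rnorm(n, 45, 5), 1),
    stringsAsFactors = FALSE)
}

#' Emit discordant-pair and split-read evidence tables
#'
#' Every above-threshold somatic truth yields a positive-strand anchor
#' cluster ending at the insertion position and a negative-strand cluster
#' starting just beyond it (a small target-site duplication), each with at
#' least three pairs; sub-threshold truths get exactly two pairs per
#' strand. Truths with a planted poly tail yield at least two qualifying
#' split reads. Germline truths produce the same evidence in the tumor and
#' its matched normal; the shared germline pool is returned as the
#' panel-of-normals call set.
#'
#' @param truths Output of [simulate_cohort_truth()].
#' @param annotation The `cohort_annotation` bundle.
#' @param config The [synthetic_config()].
#' @return list with `tumor_pairs`, `normal_pairs`, `split_reads`,
#'   `panel_calls` data.frames.
#' @export
emit_read_evidence <- function(truths, annotation, config) {
  set.seed(derive_seed(config$seed, "reads"))
  rl <- config$read_length
  pair_rows <- list(); split_rows <- list(); k <- 0L
  for (j in seq_len(nrow(truths))) {
    tr <- truths[j, ]
    pos <- tr$position
    tsd <- sample(5:15, 1L)
    n_pairs <- if (tr$subthreshold) 2L else 3L + rpois(1L, 2)
    offs_p <- c(0L, sample.int(150L, n_pairs - 1L, replace = TRUE))
    offs_n <- c(0L, sample.int(150L, n_pairs - 1L, replace = TRUE))
    mk <- function(tissue) {
      data.frame(
        sample_id = tr$sample_id, tissue = tissue,
        chrom = tr$chrom,
        anchor_start = c(pos - offs_p - rl, pos + tsd + offs_n),
        anchor_end = c(pos - offs_p, pos + tsd + offs_n + rl),
        strand = rep(c("+", "-"), each = n_pairs),
        anchor_mapq = sample(40:60, 2L * n_pairs, replace = TRUE),
        mate_mapq = sample(0:60, 2L * n_pairs, replace = TRUE),
        mate_family = tr$family, mate_in_repeat = TRUE,
        stringsAsFactors = FALSE)
    }
    k <- k + 1L
    pair_rows[[k]] <- cbind(mk("tumor"), germline = !tr$somatic)
    if (!tr$somatic) {
      k <- k + 1L
      pair_rows[[k]] <- cbind(mk("normal"), germline = TRUE)
    }
    if (tr$somatic && tr$poly_tail != "none" && !tr$subthreshold) {
      n_sr <- 2L + rpois(1L, 1)
      run <- strrep(tr$poly_tail, sample(8:30, n_sr, replace = TRUE))
      body <- vapply(seq_len(n_sr), function(z)
        paste(sample(setdiff(c("A", "C", "G", "T"), tr$poly_tail),
                     20, replace = TRUE), collapse = ""), character(1))
      split_rows[[length(split_rows) + 1L]] <- data.frame(
        sample_id = tr$sample_id, chrom = tr$chrom,
        pos = pos + sample(-20:20, n_sr, replace = TRUE),
        strand = if (tr$poly_tail == "A") "+" else "-",
        seq = if (tr$poly_tail == "A") paste0(run, body)
              else paste0(body, run),
        ref_seq = strrep("ACGT", 10),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs)) {
    pairs <- data.frame(sample_id = character(), tissue = character(),
                        chrom = character(), anchor_start = integer(),
                        anchor_end = integer(), strand = character(),
                        anchor_mapq = integer(), mate_mapq = integer(),
                        mate_family = character(), mate_in_repeat = logical(),
                        germline = logical(), stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  splits <- do.call(rbind, split_rows)
  if (is.null(splits)) {
    splits <- data.frame(sample_id = character(), chrom = character(),
                         pos = integer(), strand = character(),
                         seq = character(), ref_seq = character(),
                         stringsAsFactors = FALSE)
  }
  pool <- attr(truths, "germline_pool")
  panel <- if (!is.null(pool) && nrow(pool) > 0L) {
    data.frame(chrom = pool$chrom, position = pool$position,
               family = pool$family,
               n_samples = pmin(config$germline_panel_size,
                                1L + rpois(nrow(pool), 5)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), position = integer(),
               family = character(), n_samples = integer(),
               stringsAsFactors = FALSE)
  }
  list(tumor_pairs = pairs[pairs$tissue == "tumor",
                           names(pairs) != "germline"],
       normal_pairs = pairs[pairs$tissue == "normal",
                            names(pairs) != "germline"],
       split_reads = splits, panel_calls = panel)
}

#' Emit structural-variant call tables for transductions
#'
#' Each planted transduction yields one SV whose A end lies within a small
#' jitter of its source element's 3' end and whose B end is the insertion
#' site, with supporting-read counts and mapping qualities drawn around
#' high means. Noise SVs with random ends (and a spread of support/MAPQ
#' values, many failing the downstream filters) are added at the configured
#' rate, and a handful of shared germline SVs appear identically in tumor
#' and matched-normal tables.
#'
#' @inheritParams emit_read_evidence
#' @return list with `tumor_svs` and `normal_svs` data.frames.
#' @export
emit_sv_calls <- function(truths, annotation, config) {
  set.seed(derive_seed(config$seed, "svs"))
  src <- annotation$sources
  td <- truths[truths$transduction & !is.na(truths$source_id), ,
               drop = FALSE]
  sv_proto <- data.frame(sample_id = character(), sv_id = character(),
                         type = character(), chromA = character(),
                         posA = integer(), chromB = character(),
                         posB = integer(), support = integer(),
                         mapq = integer(), length = numeric(),
                         stringsAsFactors = FALSE)
  rows <- list()
  if (nrow(td) > 0L) {
    si <- match(td$source_id, src$element_id)
    posA <- src$three_prime[si] + sample(-300:300, nrow(td),
                                         replace = TRUE)
    len <- ifelse(src$chrom[si] == td$chrom,
                  abs(posA - td$position), 1e6)
    rows[[1]] <- data.frame(
      sample_id = td$sample_id,
      sv_id = sprintf("SV_sig_%04d", seq_len(nrow(td))),
      type = "TRA", chromA = src$chrom[si], posA = posA,
      chromB = td$chrom, posB = td$position,
      support = 3L + rpois(nrow(td), 5),
      mapq = sample(50:60, nrow(td), replace = TRUE),
      length = pmax(len, 1500), stringsAsFactors = FALSE)
  }
  n_noise <- round(config$noise_sv_rate * max(nrow(td), 1L))
  if (n_noise > 0L && nrow(truths) > 0L) {
    g <- config$genome
    ch <- function(k) sample(names(g), k, replace = TRUE, prob = g)
    ca <- ch(n_noise); cb <- ch(n_noise)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample(unique(truths$sample_id), n_noise,
                         replace = TRUE),
      sv_id = sprintf("SV_noise_%04d", seq_len(n_noise)),
      type = sample(c("TRA", "DEL", "DUP"), n_noise, replace = TRUE),
      chromA = ca, posA = sapply(g[ca], function(l) sample.int(l, 1L)),
      chromB = cb, posB = sapply(g[cb], function(l) sample.int(l, 1L)),
      support = sample(1:10, n_noise, replace = TRUE),
      mapq = sample(c(10, 20, 30, 37, 45, 60), n_noise, replace = TRUE),
      length = round(runif(n_noise, 200, 2e6)),
      stringsAsFactors = FALSE)
  }
  tumor <- if (length(rows) > 0L) do.call(rbind, rows) else sv_proto
  # shared germline SVs, present in both tumor and matched normal
  normal <- sv_proto
  if (nrow(truths) > 0L) {
    g <- config$genome
    n_gl <- 5L
    ch <- sample(names(g), n_gl, replace = TRUE, prob = g)
    p1 <- sapply(g[ch], function(l) sample.int(l - 2e5, 1L))
    gl <- data.frame(sample_id = NA_character_,
                     sv_id = sprintf("SV_gl_%02d", seq_len(n_gl)),
                     type = "DEL", chromA = ch, posA = p1, chromB = ch,
                     posB = p1 + round(runif(n_gl, 5e3, 2e5)),
                     support = 3L + rpois(n_gl, 5), mapq = 60,
                     length = NA_real_, stringsAsFactors = FALSE)
    gl$length <- gl$posB - gl$posA
    per_sample <- lapply(unique(truths$sample_id), function(s) {
      take <- runif(n_gl) < 0.5
      if (!any(take)) return(NULL)
      out <- gl[take, ]
      out$sample_id <- s
      out
    })
    gl_all <- do.call(rbind, per_sample)
    if (!is.null(gl_all)) {
      tumor <- rbind(tumor, gl_all)
      normal <- rbind(normal, gl_all)
    }
  }
  rownames(tumor) <- rownames(normal) <- NULL
  list(tumor_svs = tumor, normal_svs = normal)
}

#' Emit clinical, methylation and expression tables
#'
#' Survival times are exponential with log-hazard equal to the configured
#' effect per 10 insertions plus Dukes-stage effects, with a distinct
#' baseline per tumor location (the Cox model's stratification variable);
#' censoring is an independent exponential race calibrated to the
#' configured censoring rate. MS-MLPA probe ratios are planted so that the
#' 25%-of-probes gene rule and the 5-of-8 gene rule reproduce each sample's
#' assigned CIMP class against a mean + 3 SD threshold from normal-tissue
#' probes. The TPM matrix has, by default, no dependence on insertion
#' status.
#'
#' @param truths Output of [simulate_cohort_truth()].
#' @param config The [synthetic_config()].
#' @param annotation Optional `cohort_annotation`; supplies gene ids for
#'   the TPM matrix.
#' @return list with `clinical`, `methylation` (tumor probe table),
#'   `methylation_normals`, `tpm` (gene x sample matrix) and `ai_events`
#'   (per-sample allelic-imbalance segments with breakpoint coordinates)
#'   elements.
#' @export
emit_clinical_tables <- function(truths, config, annotation = NULL) {
  set.seed(derive_seed(config$seed, "clinical"))
  cov <- attr(truths, "covariates")
  if (is.null(cov)) stop("truths must carry the covariates attribute",
                         call. = FALSE)
  counts <- vapply(cov$sample_id, function(s)
    sum(truths$sample_id == s & truths$somatic), integer(1))
  cov$insertion_count <- as.integer(counts)

  stage_eff <- c(A = 0, B = 0.452, C = 1.77, D = 2.78)
  loc_base <- c(distal = 1 / 3000, proximal = 1 / 2000)  # per day
  lp <- config$log_hazard_per_10_insertions * counts / 10 +
    stage_eff[cov$dukes_stage]
  haz <- loc_base[cov$location] * exp(lp)
  time_event <- rexp(nrow(cov), rate = haz)
  cr <- config$censoring_rate
  if (cr >= 1) {
    cov$followup_days <- round(rexp(nrow(cov), rate = mean(haz))) + 1
    cov$event <- 0L
  } else if (cr <= 0) {
    cov$followup_days <- round(time_event) + 1
    cov$event <- 1L
  } else {
    cens <- rexp(nrow(cov), rate = haz * cr / (1 - cr))
    cov$followup_days <- round(pmin(time_event, cens)) + 1
    cov$event <- as.integer(time_event <= cens)
  }

  meth <- plant_methylation(cov)
  genes <- if (!is.null(annotation) && nrow(annotation$genes) > 0L) {
    annotation$genes$gene_id
  } else {
    unique(na.omit(truths$gene_id))
  }
  tpm <- if (length(genes) > 0L) {
    base <- 2 ^ rnorm(length(genes), 3, 1.5)
    m <- matrix(base, nrow = length(genes), ncol = nrow(cov)) *
      2 ^ matrix(rnorm(length(genes) * nrow(cov), 0, 0.5),
                 nrow = length(genes))
    dimnames(m) <- list(genes, cov$sample_id)
    round(m, 3)
  } else {
    matrix(numeric(0), 0, nrow(cov),
           dimnames = list(NULL, cov$sample_id))
  }
  # allelic-imbalance segments, ~24 focal events per tumor
  g <- config$genome
  ai_rows <- lapply(seq_len(nrow(cov)), function(i) {
    k <- rpois(1L, 24)
    if (k == 0L) return(NULL)
    ch <- sample(names(g), k, replace = TRUE, prob = g)
    st <- vapply(g[ch], function(l)
      sample.int(max(1L, l - 1100000L), 1L), integer(1))
    data.frame(sample_id = cov$sample_id[i], chrom = ch, bp1 = st,
               bp2 = st + round(runif(k, 1e4, 1e6)),
               stringsAsFactors = FALSE)
  })
  ai_events <- do.call(rbind, ai_rows)
  if (is.null(ai_events)) {
    ai_events <- data.frame(sample_id = character(), chrom = character(),
                            bp1 = integer(), bp2 = integer(),
                            stringsAsFactors = FALSE)
  }
  rownames(ai_events) <- NULL
  list(clinical = cov, methylation = meth$tumor,
       methylation_normals = meth$normals, tpm = tpm,
       ai_events = ai_events)
}

# MS-MLPA probe ratios: 8 genes x 4 probes; elevated probes >= 0.5, clean
# probes <= 0.2, normal-tissue probes Beta(2, 18) so the mean + 3 SD
# threshold always falls between the two.
plant_methylation <- function(cov) {
  genes <- c("CACNA1G", "CDKN2A", "CRABP1", "IGF2", "MLH1", "NEUROG1",
             "RUNX3", "SOCS1")
  n_probes <- 4L
  probe_id <- paste0(rep(genes, each = n_probes), "_p",
                     rep(seq_len(n_probes), length(genes)))
  gene_of <- rep(genes, each = n_probes)
  n_norm <- 50L
  normals <- data.frame(
    probe_id = rep(probe_id, n_norm),
    gene = rep(gene_of, n_norm),
    normal_id = rep(sprintf("N%03d", seq_len(n_norm)),
                    each = length(probe_id)),
    ratio = round(rbeta(length(probe_id) * n_norm, 2, 18), 4),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cov))) {
    n_meth <- if (cov$cimp[i] == "CIMP-H") sample(5:8, 1L)
              else sample(0:4, 1L)
    meth_genes <- if (n_meth > 0L) sample(genes, n_meth) else character(0)
    ratio <- pmin(round(rbeta(length(probe_id), 2, 18), 4), 0.2)
    for (g in meth_genes) {
      idx <- which(gene_of == g)
      n_el <- sample(ceiling(0.25 * n_probes):n_probes, 1L)
      el <- sample(idx, n_el)
      ratio[el] <- round(runif(n_el, 0.5, 0.9), 4)
    }
    rows[[i]] <- data.frame(probe_id = probe_id, gene = gene_of,
                            sample_id = cov$sample_id[i], ratio = ratio,
                            stringsAsFactors = FALSE)
  }
  list(tumor = do.call(rbind, rows), normals = normals)
}

#' Simulate a complete synthetic cohort
#'
#' Runs annotation building, truth planting, read-evidence, SV and
#' clinical-table emission in one deterministic pass.
#'
#' @param config A [synthetic_config()].
#' @return A `simulated_cohort` list bundling the annotation, all evidence
#'   tables, clinical/methylation/expression tables and the ground truth.
#' @export
simulate_cohort <- function(config) {
  annotation <- build_annotation(config)
  truth <- simulate_cohort_truth(config, annotation)
  ev <- emit_read_evidence(truth, annotation, config)
  sv <- emit_sv_calls(truth, annotation, config)
  cl <- emit_clinical_tables(truth, config, annotation)
  cohort <- c(list(config = config, annotation = annotation,
                   truth = truth), ev, sv, cl)
  class(cohort) <- "simulated_cohort"
  cohort
}
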