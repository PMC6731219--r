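test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(transduction_fraction = 1.5),
               "proportions")
  expect_error(synthetic_config(family_mix = c("LINE-1" = 0.5,
                                               Alu = 0.2, SVA = 0.2,
                                               ERV = 0.2)), "sum to 1")
  expect_error(synthetic_config(dispersion = 0), "positive")
  expect_error(
    build_annotation(synthetic_config(genome = c(chr1 = 15000))),
    "callable margin")
})

test_that("annotation bundle partitions the callable genome", {
  cfg <- synthetic_config(n_tumors = 3L, seed = 11L,
                          genome = c(chr1 = 3e6, chr2 = 2e6),
                          n_genes = 20L)
  ann <- build_annotation(cfg)
  callable_bp <- sum(ann$callable$end - ann$callable$start)
  # replication bins tile the callable genome exactly
  expect_equal(sum(ann$replication$end - ann$replication$start),
               callable_bp)
  # each of the 5 bins holds ~1/5 of the callable bp
  by_bin <- tapply(ann$replication$end - ann$replication$start,
                   ann$replication$bin, sum)
  expect_length(by_bin, 5L)
  expect_true(all(abs(by_bin / callable_bp - 0.2) < 0.01))
  # open + closed partition the callable genome
  expect_equal(sum(ann$open_closed$end - ann$open_closed$start),
               callable_bp)
  # zero genes still yields a full track set
  ann0 <- build_annotation(synthetic_config(n_tumors = 3L, n_genes = 0L,
                                            seed = 11L))
  expect_equal(nrow(ann0$genes), 0L)
  expect_gt(nrow(ann0$replication), 0L)
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- synthetic_config(n_tumors = 4L, seed = 99L,
                          genome = c(chr1 = 2e6), n_genes = 10L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (el in c("truth", "tumor_pairs", "split_reads", "tumor_svs",
               "clinical", "tpm")) {
    expect_identical(content_hash(a[[el]]), content_hash(b[[el]]),
                     info = el)
  }
  c2 <- simulate_cohort(synthetic_config(n_tumors = 4L, seed = 100L,
                                         genome = c(chr1 = 2e6),
                                         n_genes = 10L))
  expect_false(identical(content_hash(a$truth), content_hash(c2$truth)))
})

test_that("zero insertion rate yields zero somatic truths", {
  cfg <- synthetic_config(n_tumors = 5L, mean_insertions_per_tumor = 0,
                          seed = 5L, genome = c(chr1 = 2e6),
                          n_genes = 5L)
  truth <- simulate_cohort_truth(cfg, build_annotation(cfg))
  expect_equal(sum(truth$somatic), 0L)
})

test_that("placement enrichment reproduces the configured ratios", {
  # late/early = 4 exactly on ~equal bins; check at n ~ 10,000 within
  # 3 binomial SEs
  cfg <- synthetic_config(n_tumors = 34L, seed = 21L,
                          mean_insertions_per_tumor = 300,
                          late_replication_enrichment = 4,
                          closed_chromatin_enrichment = 1,
                          transduction_fraction = 0,
                          subthreshold_fraction = 0,
                          genome = c(chr1 = 60e6), n_genes = 10L)
  ann <- build_annotation(cfg)
  truth <- simulate_cohort_truth(cfg, ann)
  som <- truth[truth$somatic, ]
  ins <- data.frame(chrom = som$chrom, start = som$position,
                    end = som$position)
  dens <- compute_insertion_density(ins, ann$replication, "bin")
  n_le <- dens$count[dens$label == 4] + dens$count[dens$label == 0]
  p_hat <- dens$count[dens$label == 4] / n_le
  # expected share of "late" among late+early at equal bp: 4/5
  se <- sqrt(0.8 * 0.2 / n_le)
  expect_lt(abs(p_hat - 0.8), 3 * se)
  # conservation: per-bin counts sum to total planted count
  expect_equal(sum(dens$count), nrow(som))
})

test_that("dominant source takes its configured transduction share", {
  cfg <- synthetic_config(n_tumors = 40L, seed = 33L,
                          mean_insertions_per_tumor = 60,
                          transduction_fraction = 0.5,
                          dominant_source_share = 0.46,
                          genome = c(chr1 = 8e6), n_genes = 10L)
  truth <- simulate_cohort_truth(cfg, build_annotation(cfg))
  td <- truth[truth$transduction, ]
  expect_gt(nrow(td), 200)
  share <- max(table(td$source_id)) / nrow(td)
  se <- sqrt(0.46 * 0.54 / nrow(td))
  expect_lt(abs(share - 0.46), 3 * se)
})

test_that("read evidence is sound: somatic has no normal support, germline has both", {
  co <- tiny_cohort()
  truth <- co$truth
  som <- truth[truth$somatic, ]
  glm_t <- truth[!truth$somatic, ]
  expect_gt(nrow(glm_t), 0L)
  near <- function(pairs, tr, win = 400) {
    any(pairs$sample_id == tr$sample_id & pairs$chrom == tr$chrom &
          abs(pairs$anchor_start - tr$position) <= win)
  }
  for (i in sample(nrow(som), min(25, nrow(som)))) {
    expect_false(near(co$normal_pairs, som[i, ]))
  }
  for (i in seq_len(min(10, nrow(glm_t)))) {
    expect_true(near(co$normal_pairs, glm_t[i, ]))
    expect_true(near(co$tumor_pairs, glm_t[i, ]))
  }
  # above-threshold somatic truths have >= 3 pairs per strand
  tr <- som[!som$subthreshold, ][1, ]
  sub <- co$tumor_pairs[co$tumor_pairs$sample_id == tr$sample_id &
                        co$tumor_pairs$chrom == tr$chrom &
                        abs(co$tumor_pairs$anchor_start - tr$position)
                        <= 400, ]
  expect_gte(sum(sub$strand == "+"), 3L)
  expect_gte(sum(sub$strand == "-"), 3L)
})

test_that("planted poly tails appear in split reads as specified", {
  co <- tiny_cohort()
  som <- co$truth[co$truth$somatic & !co$truth$subthreshold &
                  co$truth$poly_tail == "A", ]
  tr <- som[1, ]
  sr <- co$split_reads[co$split_reads$sample_id == tr$sample_id &
                       abs(co$split_reads$pos - tr$position) <= 50, ]
  expect_gte(sum(sr$strand == "+" & grepl("^AAA", sr$seq)), 2L)
})

test_that("sub-threshold truths emit exactly two pairs per strand", {
  cfg <- synthetic_config(n_tumors = 10L, seed = 13L,
                          subthreshold_fraction = 0.5,
                          genome = c(chr1 = 5e6), n_genes = 10L)
  ann <- build_annotation(cfg)
  truth <- simulate_cohort_truth(cfg, ann)
  ev <- emit_read_evidence(truth, ann, cfg)
  sub <- truth[truth$somatic & truth$subthreshold, ][1, ]
  pairs <- ev$tumor_pairs[ev$tumor_pairs$sample_id == sub$sample_id &
                          ev$tumor_pairs$chrom == sub$chrom &
                          abs(ev$tumor_pairs$anchor_start -
                                sub$position) <= 400, ]
  expect_equal(sum(pairs$strand == "+"), 2L)
  expect_equal(sum(pairs$strand == "-"), 2L)
})

test_that("sv emission: no transductions means only noise and germline svs", {
  cfg <- synthetic_config(n_tumors = 6L, seed = 17L,
                          transduction_fraction = 0,
                          genome = c(chr1 = 5e6), n_genes = 5L)
  ann <- build_annotation(cfg)
  truth <- simulate_cohort_truth(cfg, ann)
  sv <- emit_sv_calls(truth, ann, cfg)
  expect_false(any(grepl("^SV_sig", sv$tumor_svs$sv_id)))
})

test_that("full censoring yields a no-events error downstream", {
  cfg <- synthetic_config(n_tumors = 25L, seed = 19L, censoring_rate = 1,
                          genome = c(chr1 = 4e6), n_genes = 10L)
  ann <- build_annotation(cfg)
  truth <- simulate_cohort_truth(cfg, ann)
  cl <- emit_clinical_tables(truth, cfg, ann)
  expect_true(all(cl$clinical$event == 0L))
  expect_error(fit_disease_specific_cox(cl$clinical), "no events")
})
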