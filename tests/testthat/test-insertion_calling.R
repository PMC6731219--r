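mk_pairs <- function(starts, strand = "+", sample_id = "S1",
                     chrom = "chr1", mapq = 30, mate_mapq = 20,
                     family = "LINE-1", rl = 100L) {
  data.frame(sample_id = sample_id, chrom = chrom,
             anchor_start = as.integer(starts),
             anchor_end = as.integer(starts) + rl, strand = strand,
             anchor_mapq = mapq, mate_mapq = mate_mapq,
             mate_family = family, stringsAsFactors = FALSE)
}

test_that("anchor selection applies the equal-quality and repeat rules", {
  p <- rbind(mk_pairs(100, mapq = 30, mate_mapq = 30),   # equal, >0: keep
             mk_pairs(200, mapq = 0, mate_mapq = 0),     # equal, 0: drop
             mk_pairs(300, mapq = 30, mate_mapq = 20),   # keep
             mk_pairs(400, family = "none"),             # no repeat mate
             mk_pairs(500, mapq = 0, mate_mapq = 20))    # anchor unmapped
  out <- select_anchor_reads(p)
  expect_equal(out$anchor_start, c(100L, 300L))
})

test_that("clustering enforces the three-read minimum and strand inner rule", {
  # 3 plus anchors within 100 bp: one cluster at the threshold
  cl <- cluster_discordant_pairs(mk_pairs(c(1000, 1050, 1100)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 3L)
  expect_equal(cl$inner, 1200L)  # rightmost anchor end for +
  # 2 anchors: below the minimum
  expect_equal(nrow(cluster_discordant_pairs(mk_pairs(c(1, 50)))), 0L)
  # minus-cluster inner is the leftmost anchor start
  cl2 <- cluster_discordant_pairs(mk_pairs(c(2000, 2040, 2080),
                                           strand = "-"))
  expect_equal(cl2$inner, 2000L)
})

test_that("cluster joins match a brute-force single-linkage oracle", {
  set.seed(7)
  for (rep in 1:10) {
    starts <- sort(sample.int(20000, 40))
    jd <- sample(c(200L, 500L, 1000L), 1L)
    got <- cluster_discordant_pairs(mk_pairs(starts), min_reads = 1L,
                                    join_distance = jd)
    memb <- oracle_single_linkage(starts, jd)
    expect_equal(nrow(got), length(unique(memb)))
    sizes <- sort(as.integer(table(memb)))
    expect_equal(sort(got$n), sizes)
  }
})

test_that("reciprocal pairing takes nearest minus cluster, ties to leftmost", {
  cl <- rbind(
    cluster_discordant_pairs(mk_pairs(c(900, 950, 1000) - 100)),
    cluster_discordant_pairs(mk_pairs(c(1050, 1090, 1130), "-")))
  cand <- pair_reciprocal_clusters(cl)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 1000L)   # + inner (anchor end 900+100)
  expect_equal(cand$end, 1050L)     # - inner
  # different families never pair
  cl2 <- cl
  cl2$family[cl2$strand == "-"] <- "Alu"
  expect_equal(nrow(pair_reciprocal_clusters(cl2)), 0L)
  # competition: nearest + cluster wins, distance tie to leftmost
  clusters <- data.frame(
    sample_id = "S1", chrom = "chr1",
    strand = c("+", "+", "-"), n = c(3L, 3L, 3L),
    start = c(500L, 900L, 1100L), end = c(900L, 1050L, 1500L),
    inner = c(900L, 1100L, 1000L), family = "LINE-1",
    stringsAsFactors = FALSE)
  got <- pair_reciprocal_clusters(clusters)
  expect_equal(nrow(got), 1L)
  expect_equal(sort(c(got$start, got$end)), c(900L, 1000L))
})

test_that("pairing is consistent with exhaustive assignment on small sets", {
  set.seed(11)
  for (rep in 1:8) {
    np <- sample(2:5, 1); nm <- sample(2:5, 1)
    inner_p <- sort(sample.int(5000, np))
    inner_m <- sort(sample.int(5000, nm))
    clusters <- data.frame(
      sample_id = "S1", chrom = "chr1",
      strand = rep(c("+", "-"), c(np, nm)),
      n = 3L, start = c(inner_p, inner_m) - 10L,
      end = c(inner_p, inner_m) + 10L,
      inner = c(inner_p, inner_m), family = "LINE-1",
      stringsAsFactors = FALSE)
    got <- pair_reciprocal_clusters(clusters, pairing_window = 1000L)
    # oracle: sequential global argmin by (distance, + inner)
    d <- abs(outer(inner_p, inner_m, "-"))
    d[d > 1000] <- NA
    pairs <- list()
    while (any(!is.na(d))) {
      dmin <- min(d, na.rm = TRUE)
      hits <- which(d == dmin, arr.ind = TRUE)
      hits <- hits[order(inner_p[hits[, 1]]), , drop = FALSE]
      i <- hits[1, 1]; j <- hits[1, 2]
      pairs[[length(pairs) + 1L]] <- sort(c(inner_p[i], inner_m[j]))
      d[i, ] <- NA; d[, j] <- NA
    }
    want <- do.call(rbind, pairs)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want) > 0) {
      got_m <- as.matrix(got[order(got$start), c("start", "end")])
      dimnames(got_m) <- NULL
      expect_equal(got_m, want[order(want[, 1]), , drop = FALSE])
    }
  }
})

test_that("somatic panel filter matches the quadratic oracle", {
  # the printed-window examples
  cand <- data.frame(sample_id = "S1", chrom = "chr1",
                     start = c(1000L, 5000L), end = c(1010L, 5020L),
                     family = "LINE-1", pos_support = 3L,
                     neg_support = 3L, stringsAsFactors = FALSE)
  panel <- data.frame(chrom = "chr1", position = c(1160L, 5270L))
  out <- filter_somatic_against_panel(cand, panel)
  expect_equal(out$start, 5000L)  # 150 bp away removed, 250 bp kept
  # random instances vs oracle
  set.seed(23)
  for (rep in 1:6) {
    n <- 120; m <- 80
    cand <- data.frame(sample_id = "S1",
                       chrom = sample(c("chr1", "chr2"), n, TRUE),
                       start = sample.int(50000, n),
                       family = "LINE-1", pos_support = 3L,
                       neg_support = 3L, stringsAsFactors = FALSE)
    cand$end <- cand$start + sample.int(50, n, replace = TRUE)
    panel <- data.frame(chrom = sample(c("chr1", "chr2"), m, TRUE),
                        position = sample.int(50000, m))
    got <- filter_somatic_against_panel(cand, panel)
    want <- oracle_panel_filter(cand, panel, 200)
    expect_equal(got$start, want$start)
    expect_equal(got$chrom, want$chrom)
  }
})

test_that("decoy filtering removes decoy contigs and warns on unknowns", {
  cand <- data.frame(sample_id = "S1",
                     chrom = c("chr1", "hs37d5", "weird"),
                     start = c(1L, 2L, 3L), end = c(2L, 3L, 4L),
                     family = "LINE-1", pos_support = 3L,
                     neg_support = 3L, stringsAsFactors = FALSE)
  expect_warning(out <- filter_decoy_regions(cand, "hs37d5",
                                             known_contigs = "chr1"),
                 "weird")
  expect_equal(out$chrom, c("chr1", "weird"))
  expect_identical(filter_decoy_regions(cand, character(0)), cand)
})

test_that("calling is invariant to input row order", {
  co <- tiny_cohort()
  base <- call_insertions(co$tumor_pairs, co$normal_pairs,
                          co$panel_calls)
  set.seed(1)
  shuf <- co$tumor_pairs[sample.int(nrow(co$tumor_pairs)), ]
  again <- call_insertions(shuf, co$normal_pairs, co$panel_calls)
  expect_equal(base, again)
})

test_that("tumor evidence identical to normal yields zero somatic calls", {
  co <- tiny_cohort()
  calls <- call_insertions(co$tumor_pairs,
                           normal_pairs = co$tumor_pairs,
                           panel_calls = NULL)
  expect_equal(nrow(calls), 0L)
})

test_that("caller recovers every above-threshold planted somatic truth", {
  co <- tiny_cohort()
  calls <- call_insertions(co$tumor_pairs, co$normal_pairs,
                           co$panel_calls)
  above <- co$truth[co$truth$somatic & !co$truth$subthreshold, ]
  hit <- vapply(seq_len(nrow(above)), function(i) {
    any(calls$sample_id == above$sample_id[i] &
          calls$chrom == above$chrom[i] &
          abs((calls$start + calls$end) / 2 - above$position[i]) <= 500)
  }, logical(1))
  expect_equal(mean(hit), 1)
  # and no call sits on a germline locus
  pool <- attr(co$truth, "germline_pool")
  for (i in seq_len(nrow(calls))) {
    same <- pool[pool$chrom == calls$chrom[i], ]
    if (nrow(same) > 0) {
      expect_true(all(interval_gap(calls$start[i], calls$end[i],
                                   same$position, same$position) > 200))
    }
  }
})
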