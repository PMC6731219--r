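mk_sv <- function(posA, posB, sample_id = "S1", type = "TRA",
                  chromA = "chr1", chromB = "chr2", support = 5L,
                  mapq = 60, length = 1e6, id = NULL) {
  data.frame(sample_id = sample_id,
             sv_id = if (is.null(id)) sprintf("sv%03d", seq_along(posA))
                     else id,
             type = type, chromA = chromA, posA = as.integer(posA),
             chromB = chromB, posB = as.integer(posB),
             support = support, mapq = mapq, length = length,
             stringsAsFactors = FALSE)
}

test_that("support and MAPQ filters are strict where specified", {
  svs <- rbind(mk_sv(100, 100, support = 2L),          # low support
               mk_sv(200, 200, support = 3L, mapq = 37),  # boundary mapq
               mk_sv(300, 300, support = 3L, mapq = 38))
  out <- filter_sv_calls(svs)
  expect_equal(out$posA, 300L)
  # random tables match a row-wise filter
  set.seed(3)
  tab <- mk_sv(sample.int(1e5, 50), sample.int(1e5, 50),
               support = sample(0:8, 50, TRUE),
               mapq = sample(30:45, 50, TRUE))
  got <- filter_sv_calls(tab)
  want <- tab[tab$support >= 3 & tab$mapq > 37, ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("sv merging is transitive and matches a components oracle", {
  # two same-type calls 150 bp apart merge; 250 bp apart do not
  expect_equal(nrow(merge_sv_calls(mk_sv(c(1000, 1150), c(5000, 5100)))),
               1L)
  expect_equal(nrow(merge_sv_calls(mk_sv(c(1000, 1250), c(5000, 5100)))),
               2L)
  # chain A-B 150, B-C 150: one merged call
  chain <- merge_sv_calls(mk_sv(c(1000, 1150, 1300), c(5000, 5050, 5100)))
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$n_merged, 3L)
  expect_equal(chain$support, 15L)
  # random instances vs BFS oracle
  set.seed(9)
  for (rep in 1:6) {
    n <- 18
    svs <- mk_sv(sample.int(4000, n, TRUE), sample.int(4000, n, TRUE),
                 id = sprintf("r%02d", 1:n))
    got <- merge_sv_calls(svs)
    adj <- function(i, j) {
      abs(svs$posA[i] - svs$posA[j]) <= 200 &&
        abs(svs$posB[i] - svs$posB[j]) <= 200
    }
    memb <- oracle_components(n, adj)
    expect_equal(nrow(got), length(unique(memb)))
    expect_equal(sort(got$n_merged), sort(as.integer(table(memb))))
  }
})

test_that("germline subtraction removes short and normal-matched svs", {
  tum <- merge_sv_calls(mk_sv(c(1000, 3000, 9000), c(500, 700, 900),
                              length = c(900, 5000, 5000)))
  nor <- merge_sv_calls(mk_sv(3100, 650))
  out <- subtract_germline_svs(tum, nor)
  expect_equal(out$posA, 9000L)  # 900 bp fails length; 3000 matches normal
  # disjoint sets: identity on length-passing calls
  out2 <- subtract_germline_svs(tum, merge_sv_calls(mk_sv(99000, 99000)))
  expect_equal(out2$posA, c(3000L, 9000L))
})

test_that("source attachment picks nearest 3' end, ties to lowest id", {
  catalog <- data.frame(
    element_id = c("L1HS_001", "L1HS_002", "L1HS_003"),
    cytoband = c("1q21.1", "1q22.1", "2q11.1"),
    chrom = c("chr1", "chr1", "chr2"), strand = "+",
    three_prime = c(10000L, 20000L, 10000L),
    stringsAsFactors = FALSE)
  svs <- merge_sv_calls(mk_sv(10800, 5e5, chromB = "chr2"))
  out <- attach_source_elements(svs, catalog)
  expect_equal(out$source_id, "L1HS_001")   # 800 bp away
  expect_equal(out$chrom, "chr2")           # other end is the site
  # 1500 bp away: not attributed
  expect_equal(nrow(attach_source_elements(
    merge_sv_calls(mk_sv(11500, 5e5, chromB = "chr2")), catalog)), 0L)
  # exact tie at 15000 (5000 bp from both) is out of range; make a tie
  # within range: 1000 bp from each of two elements
  tie <- merge_sv_calls(mk_sv(15000, 5e5, chromB = "chr2"))
  out_tie <- attach_source_elements(tie, catalog, proximity = 5000L)
  expect_equal(out_tie$source_id, "L1HS_001")
  expect_true(out_tie$ambiguous)
  # random instances vs exhaustive nearest-neighbor oracle (A ends only;
  # positions spaced so no 200 bp merging interferes)
  cat1 <- catalog[catalog$chrom == "chr1", ]
  set.seed(31)
  for (rep in 1:5) {
    posA <- sample(seq(500L, 30000L, by = 500L), 20)
    posB <- 5e5 + seq_len(20) * 1000L
    svs <- merge_sv_calls(mk_sv(posA, posB, chromB = "chr2"))
    got <- attach_source_elements(svs, cat1, proximity = 1000L)
    for (i in seq_len(nrow(svs))) {
      dA <- abs(cat1$three_prime - svs$posA[i])
      in_got <- any(got$start == svs$posB[i])
      expect_equal(in_got, min(dA) <= 1000)
      if (in_got) {
        expect_equal(got$source_id[got$start == svs$posB[i]],
                     cat1$element_id[which.min(dA)])
      }
    }
  }
})

test_that("sex filter removes female Y-source calls and panel neighbors", {
  catalog <- data.frame(element_id = c("L1HS_Y", "L1HS_A"),
                        cytoband = c("Yp11.2", "1q21.1"),
                        chrom = c("chrY", "chr1"), strand = "+",
                        three_prime = c(1000L, 1000L),
                        stringsAsFactors = FALSE)
  calls <- data.frame(
    sample_id = c("F1", "M1", "F1"), chrom = "chr3",
    start = c(100L, 100L, 9000L), end = c(120L, 120L, 9020L),
    source_id = c("L1HS_Y", "L1HS_Y", "L1HS_A"),
    cytoband = c("Yp11.2", "Yp11.2", "1q21.1"), class = "3prime",
    support = 5L, ambiguous = FALSE, stringsAsFactors = FALSE)
  sex <- c(F1 = "female", M1 = "male")
  out <- somatic_and_sex_filter(calls, NULL, sex, catalog)
  expect_equal(paste(out$sample_id, out$source_id),
               c("M1 L1HS_Y", "F1 L1HS_A"))
  # panel neighbor at 100 bp removes the call
  panel <- data.frame(chrom = "chr3", position = 9120L)
  out2 <- somatic_and_sex_filter(calls, panel, sex, catalog)
  expect_equal(paste(out2$sample_id, out2$source_id), "M1 L1HS_Y")
  expect_error(somatic_and_sex_filter(calls, NULL, c(F1 = "female"),
                                      catalog), "missing sex")
})

test_that("dedupe collapses same-sample same-family calls within 200 bp", {
  td <- data.frame(sample_id = c("S1", "S1", "S2"), chrom = "chr1",
                   start = c(1000L, 1150L, 1000L),
                   end = c(1010L, 1160L, 1010L),
                   source_id = "L1HS_001", cytoband = "1q21.1",
                   class = "3prime", support = 4L, ambiguous = FALSE,
                   stringsAsFactors = FALSE)
  cc <- data.frame(sample_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   family = character(), pos_support = integer(),
                   neg_support = integer(), stringsAsFactors = FALSE)
  out <- merge_dedupe_calls(td, cc)
  expect_equal(nrow(out), 2L)  # S1 pair collapses; S2 separate
  # transduction near a cluster call becomes one dual-evidence record
  cc2 <- data.frame(sample_id = "S1", chrom = "chr1", start = 1100L,
                    end = 1120L, family = "LINE-1", pos_support = 3L,
                    neg_support = 4L, stringsAsFactors = FALSE)
  out2 <- merge_dedupe_calls(td[1, ], cc2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$method, "both")
  expect_equal(out2$class, "3prime")
  # transduction with no cluster support is an orphan
  lone <- merge_dedupe_calls(td[3, ], cc)
  expect_equal(lone$class, "orphan")
})

test_that("source activity summary reproduces printed fractions", {
  calls <- data.frame(
    source_id = c(rep("L1HS_22q12.1", 160),
                  sprintf("L1HS_other%03d", seq_len(186))),
    stringsAsFactors = FALSE)
  s <- summarize_source_activity(calls)
  expect_equal(sum(s$fraction), 1)
  expect_equal(round(100 * s$fraction[1]), 46)
  expect_true(s$recurrent[1])
  one <- summarize_source_activity(data.frame(source_id = "X"))
  expect_equal(one$fraction, 1)
  expect_false(one$recurrent)
  expect_equal(nrow(summarize_source_activity(
    data.frame(source_id = character()))), 0L)
})

test_that("planted low-MAPQ svs never survive the pipeline", {
  co <- tiny_cohort()
  svs <- co$tumor_svs
  svs$mapq <- 10
  sex <- setNames(co$clinical$sex, co$clinical$sample_id)
  out <- call_transductions(svs, co$normal_svs, co$annotation$sources,
                            sex)
  expect_equal(nrow(out), 0L)
})

test_that("transduction pipeline attributes every clean planted event", {
  co <- tiny_cohort()
  sex <- setNames(co$clinical$sex, co$clinical$sample_id)
  out <- call_transductions(co$tumor_svs, co$normal_svs,
                            co$annotation$sources, sex)
  td_truth <- co$truth[co$truth$transduction, ]
  for (i in seq_len(nrow(td_truth))) {
    m <- out[out$sample_id == td_truth$sample_id[i] &
             out$chrom == td_truth$chrom[i] &
             interval_gap(out$start, out$end, td_truth$position[i],
                          td_truth$position[i]) <= 300, , drop = FALSE]
    expect_gte(nrow(m), 1L)
    expect_true(td_truth$source_id[i] %in% m$source_id)
  }
})
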