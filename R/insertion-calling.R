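#' Select anchor reads from discordant pairs
#'
#' A discordant pair is usable when its mate maps into a retrotransposon
#' family; the anchor is the end mapping to non-repetitive sequence (laid
#' out as the first end in the table's `anchor_*` columns). When both ends
#' have equal mapping quality the pair is kept only if that quality is
#' above zero, with the first end as anchor; pairs whose anchor has MAPQ 0
#' are excluded.
#'
#' @param pairs data.frame with columns `sample_id`, `chrom`,
#'   `anchor_start`, `anchor_end`, `strand`, `anchor_mapq`, `mate_mapq`,
#'   `mate_family` (`"none"` when the mate is non-repetitive).
#' @return The retained, anchor-oriented subset.
#' @export
select_anchor_reads <- function(pairs) {
  keep <- !is.na(pairs$mate_family) & pairs$mate_family != "none"
  equal_q <- pairs$anchor_mapq == pairs$mate_mapq
  keep <- keep & ifelse(equal_q, pairs$anchor_mapq > 0,
                        pairs$anchor_mapq > 0)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering of anchored discordant pairs
#'
#' Same-sample, same-chromosome, same-strand anchors whose consecutive
#' starts are at most `join_distance` apart form one cluster; clusters with
#' fewer than `min_reads` members are discarded. The inner coordinate is
#' the rightmost anchor end for plus clusters and the leftmost anchor start
#' for minus clusters; the cluster family is the majority vote of mate
#' families (alphabetical tie-break).
#'
#' @param pairs Anchored pairs from [select_anchor_reads()].
#' @param min_reads Minimum cluster size (default 3, the tumor-cluster
#'   threshold; use the same value for matched-normal germline clusters).
#' @param join_distance Maximum gap between consecutive anchor starts.
#' @return data.frame of read clusters (`sample_id`, `chrom`, `strand`,
#'   `n`, `start`, `end`, `inner`, `family`).
#' @export
cluster_discordant_pairs <- function(pairs, min_reads = 3L,
                                     join_distance = 500L) {
  proto <- data.frame(sample_id = character(), chrom = character(),
                      strand = character(), n = integer(),
                      start = integer(), end = integer(),
                      inner = integer(), family = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(proto)
  out <- list()
  grp <- split(pairs, list(pairs$sample_id, pairs$chrom, pairs$strand),
               drop = TRUE)
  for (g in grp) {
    g <- g[order(g$anchor_start), , drop = FALSE]
    brk <- c(TRUE, diff(g$anchor_start) > join_distance)
    cid <- cumsum(brk)
    for (cl in split(g, cid)) {
      if (nrow(cl) < min_reads) next
      fam <- names(sort(table(cl$mate_family), decreasing = TRUE))
      fam <- sort(fam[table(cl$mate_family)[fam] ==
                        max(table(cl$mate_family))])[1L]
      inner <- if (cl$strand[1L] == "+") max(cl$anchor_end)
               else min(cl$anchor_start)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = cl$sample_id[1L], chrom = cl$chrom[1L],
        strand = cl$strand[1L], n = nrow(cl),
        start = min(cl$anchor_start), end = max(cl$anchor_end),
        inner = as.integer(inner), family = fam,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(proto)
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Pair reciprocal read clusters into candidate insertions
#'
#' Each plus cluster is matched to the nearest unused minus cluster of the
#' same sample, chromosome and family whose inner coordinate lies within
#' `pairing_window` bp. Matching is globally greedy by distance, with ties
#' broken towards the leftmost plus cluster, so each cluster is used at
#' most once. The candidate's breakpoint window spans the two inner
#' coordinates.
#'
#' @param clusters Output of [cluster_discordant_pairs()].
#' @param pairing_window Maximum inner-coordinate separation in bp.
#' @return data.frame of candidate insertions (`sample_id`, `chrom`,
#'   `start`, `end`, `family`, `pos_support`, `neg_support`).
#' @export
pair_reciprocal_clusters <- function(clusters, pairing_window = 500L) {
  proto <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      family = character(), pos_support = integer(),
                      neg_support = integer(), stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L) return(proto)
  out <- list()
  grp <- split(clusters,
               list(clusters$sample_id, clusters$chrom, clusters$family),
               drop = TRUE)
  for (g in grp) {
    p <- g[g$strand == "+", , drop = FALSE]
    m <- g[g$strand == "-", , drop = FALSE]
    if (nrow(p) == 0L || nrow(m) == 0L) next
    cand <- expand.grid(i = seq_len(nrow(p)), j = seq_len(nrow(m)))
    cand$dist <- abs(p$inner[cand$i] - m$inner[cand$j])
    cand <- cand[cand$dist <= pairing_window, , drop = FALSE]
    cand <- cand[order(cand$dist, p$inner[cand$i]), , drop = FALSE]
    used_p <- logical(nrow(p)); used_m <- logical(nrow(m))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_p[i] || used_m[j]) next
      used_p[i] <- used_m[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        sample_id = p$sample_id[i], chrom = p$chrom[i],
        start = min(p$inner[i], m$inner[j]),
        end = max(p$inner[i], m$inner[j]),
        family = p$family[i], pos_support = p$n[i],
        neg_support = m$n[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(proto)
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Filter candidates against germline calls
#'
#' A candidate is removed when any panel-of-normals or matched-normal
#' germline call (of any family, by default) lies within `window` bp of its
#' breakpoint window, measured between closest interval edges (zero when
#' overlapping). Survivors are flagged somatic.
#'
#' @param candidates Candidate insertions.
#' @param panel_calls data.frame with `chrom` and `position` (or
#'   `start`/`end`) columns; may be `NULL`.
#' @param matched_normal_calls Same layout, from the matched normal.
#' @param window Filter window in bp (default 200).
#' @param same_family_only If `TRUE`, only germline calls of the same
#'   family mask a candidate.
#' @return The surviving candidates with a `somatic = TRUE` column.
#' @export
filter_somatic_against_panel <- function(candidates, panel_calls = NULL,
                                         matched_normal_calls = NULL,
                                         window = 200L,
                                         same_family_only = FALSE) {
  panel <- normalize_calls(panel_calls)
  matched <- normalize_calls(matched_normal_calls)
  hit <- function(cand_row, g, match_sample) {
    if (nrow(g) == 0L) return(FALSE)
    g <- g[g$chrom == cand_row$chrom, , drop = FALSE]
    if (match_sample && "sample_id" %in% names(g)) {
      g <- g[g$sample_id == cand_row$sample_id, , drop = FALSE]
    }
    if (same_family_only && "family" %in% names(g)) {
      g <- g[g$family == cand_row$family, , drop = FALSE]
    }
    if (nrow(g) == 0L) return(FALSE)
    any(interval_gap(cand_row$start, cand_row$end, g$start, g$end) <=
          window)
  }
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (hit(candidates[i, ], panel, match_sample = FALSE) ||
        hit(candidates[i, ], matched, match_sample = TRUE)) {
      keep[i] <- FALSE
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out$somatic <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

normalize_calls <- function(d) {
  if (is.null(d) || nrow(d) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  if (!"start" %in% names(d)) {
    d$start <- d$position
    d$end <- d$position
  }
  cols <- intersect(c("sample_id", "chrom", "start", "end", "family"),
                    names(d))
  d[, cols, drop = FALSE]
}

#' Remove candidates on decoy contigs
#'
#' @param candidates Candidate insertions.
#' @param decoy_contigs Character vector of decoy contig names (e.g.
#'   `"hs37d5"`).
#' @param known_contigs Optional vector of recognized contig names;
#'   candidates on contigs in neither list trigger a warning but are kept.
#' @return Candidates off the decoy contigs.
#' @export
filter_decoy_regions <- function(candidates, decoy_contigs,
                                 known_contigs = NULL) {
  if (length(decoy_contigs) == 0L) return(candidates)
  if (!is.null(known_contigs)) {
    unknown <- setdiff(unique(candidates$chrom),
                       c(known_contigs, decoy_contigs))
    if (length(unknown) > 0L) {
      warning("candidates on unrecognized contig(s) kept: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out <- candidates[!candidates$chrom %in% decoy_contigs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call somatic insertions from discordant-pair evidence
#'
#' End-to-end cluster caller: anchor selection, reciprocal clustering with
#' the three-read tumor minimum, germline calling on the matched normal
#' with the three-read normal minimum, somatic filtering against the panel
#' of normals and matched-normal calls with a 200 bp window, and decoy
#' removal.
#'
#' @param tumor_pairs,normal_pairs Discordant-pair tables.
#' @param panel_calls Panel-of-normals germline call table.
#' @param decoy_contigs Decoy contig names.
#' @param min_reads Tumor cluster minimum (default 3).
#' @param min_reads_normal Normal cluster minimum (default 3).
#' @param join_distance,pairing_window Clustering distances in bp.
#' @param somatic_window Germline filter window in bp (default 200).
#' @return data.frame of somatic candidate insertions.
#' @export
call_insertions <- function(tumor_pairs, normal_pairs = NULL,
                            panel_calls = NULL,
                            decoy_contigs = "hs37d5",
                            min_reads = 3L, min_reads_normal = 3L,
                            join_distance = 500L, pairing_window = 500L,
                            somatic_window = 200L) {
  anchors <- select_anchor_reads(tumor_pairs)
  clusters <- cluster_discordant_pairs(anchors, min_reads = min_reads,
                                       join_distance = join_distance)
  cands <- pair_reciprocal_clusters(clusters,
                                    pairing_window = pairing_window)
  normal_cands <- NULL
  if (!is.null(normal_pairs) && nrow(normal_pairs) > 0L) {
    na <- select_anchor_reads(normal_pairs)
    ncl <- cluster_discordant_pairs(na, min_reads = min_reads_normal,
                                    join_distance = join_distance)
    normal_cands <- pair_reciprocal_clusters(
      ncl, pairing_window = pairing_window)
  }
  som <- filter_somatic_against_panel(cands, panel_calls, normal_cands,
                                      window = somatic_window)
  filter_decoy_regions(som, decoy_contigs)
}
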