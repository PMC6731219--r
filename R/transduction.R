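#' Filter SV calls on support and mapping quality
#'
#' Retains calls with at least `min_support` supporting discordant reads
#' and mapping quality strictly greater than `min_mapq` (a call at exactly
#' the MAPQ cut fails).
#'
#' @param svs SV call data.frame (`sample_id`, `sv_id`, `type`, `chromA`,
#'   `posA`, `chromB`, `posB`, `support`, `mapq`, `length`).
#' @param min_support Minimum supporting reads (default 3).
#' @param min_mapq Exclusive MAPQ lower bound (default 37).
#' @return The surviving rows.
#' @export
filter_sv_calls <- function(svs, min_support = 3L, min_mapq = 37) {
  out <- svs[svs$support >= min_support & svs$mapq > min_mapq, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby same-type SV calls
#'
#' Same-sample, same-type calls whose A ends and B ends are each within
#' `window` bp merge transitively (connected components), summing support
#' and taking the union of end spans.
#'
#' @param svs SV call data.frame.
#' @param window Merge window in bp (default 200).
#' @return Merged SV calls; end positions become `posA`/`posA2` and
#'   `posB`/`posB2` spans with `n_merged` members.
#' @export
merge_sv_calls <- function(svs, window = 200L) {
  proto <- data.frame(sample_id = character(), sv_id = character(),
                      type = character(), chromA = character(),
                      posA = integer(), posA2 = integer(),
                      chromB = character(), posB = integer(),
                      posB2 = integer(), support = integer(),
                      mapq = numeric(), length = numeric(),
                      n_merged = integer(), stringsAsFactors = FALSE)
  if (nrow(svs) == 0L) return(proto)
  out <- list()
  for (g in split(svs, list(svs$sample_id, svs$type), drop = TRUE)) {
    n <- nrow(g)
    pair_idx <- if (n > 1L) utils::combn(n, 2L) else matrix(0L, 2, 0)
    close <- function(i, j) {
      g$chromA[i] == g$chromA[j] && g$chromB[i] == g$chromB[j] &&
        abs(g$posA[i] - g$posA[j]) <= window &&
        abs(g$posB[i] - g$posB[j]) <= window
    }
    edges <- which(apply(pair_idx, 2L, function(p) close(p[1], p[2])))
    memb <- components_from_edges(n, pair_idx[1L, edges],
                                  pair_idx[2L, edges])
    for (cmp in split(seq_len(n), memb)) {
      cl <- g[cmp, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = cl$sample_id[1L],
        sv_id = paste(cl$sv_id, collapse = ";"), type = cl$type[1L],
        chromA = cl$chromA[1L], posA = min(cl$posA),
        posA2 = max(cl$posA), chromB = cl$chromB[1L],
        posB = min(cl$posB), posB2 = max(cl$posB),
        support = sum(cl$support), mapq = max(cl$mapq),
        length = max(cl$length), n_merged = nrow(cl),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chromA, res$posA), ]
  rownames(res) <- NULL
  res
}

#' Subtract germline SVs from tumor SVs
#'
#' Tumor merged SVs longer than `min_length` bp are retained only if no
#' merged normal SV of the same type matches both ends within the filter
#' window.
#'
#' @param tumor_svs,normal_svs Merged SV tables from [merge_sv_calls()].
#' @param min_length Exclusive SV length cut in bp (default 1000).
#' @param window Matching window in bp (default 200).
#' @return Somatic tumor SVs.
#' @export
subtract_germline_svs <- function(tumor_svs, normal_svs,
                                  min_length = 1000L, window = 200L) {
  out <- tumor_svs[tumor_svs$length > min_length, , drop = FALSE]
  if (nrow(out) == 0L || nrow(normal_svs) == 0L) {
    rownames(out) <- NULL
    return(out)
  }
  keep <- vapply(seq_len(nrow(out)), function(i) {
    nm <- normal_svs[normal_svs$type == out$type[i] &
                     normal_svs$chromA == out$chromA[i] &
                     normal_svs$chromB == out$chromB[i], , drop = FALSE]
    if (nrow(nm) == 0L) return(TRUE)
    dA <- interval_gap(out$posA[i], out$posA2[i], nm$posA, nm$posA2)
    dB <- interval_gap(out$posB[i], out$posB2[i], nm$posB, nm$posB2)
    !any(dA <= window & dB <= window)
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute somatic SVs to reference L1HS source elements
#'
#' An SV is kept when either end lies within `proximity` bp of a catalog
#' element's 3'-end coordinate; that end becomes the source link and the
#' other end the insertion site. The nearest element wins; an exact
#' distance tie goes to the lexicographically lowest element id and is
#' flagged ambiguous.
#'
#' @param svs Somatic merged SVs.
#' @param catalog Source-element data.frame (`element_id`, `cytoband`,
#'   `chrom`, `strand`, `three_prime`, activity flags).
#' @param proximity Maximum distance from the 3' end in bp (default 1000).
#' @return Provisional transduction calls (`sample_id`, `chrom`, `start`,
#'   `end`, `source_id`, `cytoband`, `class`, `support`, `ambiguous`).
#' @export
attach_source_elements <- function(svs, catalog, proximity = 1000L) {
  stopifnot(nrow(catalog) > 0L)
  proto <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      source_id = character(), cytoband = character(),
                      class = character(), support = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (nrow(svs) == 0L) return(proto)
  out <- list()
  for (i in seq_len(nrow(svs))) {
    best <- NULL
    for (endlab in c("A", "B")) {
      ch <- svs[[paste0("chrom", endlab)]][i]
      lo <- svs[[paste0("pos", endlab)]][i]
      hi <- svs[[paste0("pos", endlab, "2")]][i]
      cat_ch <- catalog[catalog$chrom == ch, , drop = FALSE]
      if (nrow(cat_ch) == 0L) next
      d <- interval_gap(lo, hi, cat_ch$three_prime, cat_ch$three_prime)
      ok <- which(d <= proximity)
      if (length(ok) == 0L) next
      dmin <- min(d[ok])
      nearest <- cat_ch$element_id[ok][d[ok] == dmin]
      cand <- list(dist = dmin,
                   source_id = sort(nearest)[1L],
                   ambiguous = length(nearest) > 1L,
                   site_end = if (endlab == "A") "B" else "A")
      if (is.null(best) || cand$dist < best$dist) best <- cand
    }
    if (is.null(best)) next
    site_ch <- svs[[paste0("chrom", best$site_end)]][i]
    site_lo <- svs[[paste0("pos", best$site_end)]][i]
    site_hi <- svs[[paste0("pos", best$site_end, "2")]][i]
    src <- catalog[catalog$element_id == best$source_id, ]
    out[[length(out) + 1L]] <- data.frame(
      sample_id = svs$sample_id[i], chrom = site_ch,
      start = site_lo, end = site_hi, source_id = best$source_id,
      cytoband = src$cytoband[1L], class = "3prime",
      support = svs$support[i], ambiguous = best$ambiguous,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(proto)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Panel and sex filtering of transduction calls
#'
#' The insertion-site end is filtered against panel transduction calls
#' with a 200 bp window, and calls whose source element lies on chromosome
#' Y are removed for female samples.
#'
#' @param calls Transduction calls from [attach_source_elements()].
#' @param panel_calls Panel call table with `chrom` and `position` (or
#'   `start`/`end`); may be `NULL`.
#' @param sample_sex Named character vector mapping sample id to
#'   `"male"`/`"female"`; an unmapped sample is an error.
#' @param catalog Source catalog (for source chromosomes).
#' @param window Panel window in bp (default 200).
#' @return Filtered calls.
#' @export
somatic_and_sex_filter <- function(calls, panel_calls = NULL, sample_sex,
                                   catalog, window = 200L) {
  if (nrow(calls) == 0L) return(calls)
  sex <- sample_sex[calls$sample_id]
  if (any(is.na(sex))) {
    stop("missing sex for sample(s): ",
         paste(unique(calls$sample_id[is.na(sex)]), collapse = ", "),
         call. = FALSE)
  }
  src_chrom <- catalog$chrom[match(calls$source_id, catalog$element_id)]
  keep <- !(sex == "female" & src_chrom %in% c("Y", "chrY"))
  panel <- normalize_calls(panel_calls)
  if (nrow(panel) > 0L) {
    for (i in which(keep)) {
      g <- panel[panel$chrom == calls$chrom[i], , drop = FALSE]
      if (nrow(g) == 0L) next
      if (any(interval_gap(calls$start[i], calls$end[i], g$start,
                           g$end) <= window)) {
        keep[i] <- FALSE
      }
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge transduction and cluster-caller insertions into a unified list
#'
#' Within a sample, calls of the same retrotransposon family within
#' `window` bp are regarded as the same insertion and collapsed to one
#' record (transitively); records detected by both the SV route and the
#' cluster route are flagged dual-evidence and counted once.
#'
#' @param transduction_calls Calls from the SV route (family LINE-1).
#' @param cluster_calls Somatic candidates from [call_insertions()].
#' @param window Deduplication window in bp (default 200).
#' @return Unified insertion data.frame with `method`
#'   (`cluster`/`transduction`/`both`) and transduction annotations where
#'   available.
#' @export
merge_dedupe_calls <- function(transduction_calls, cluster_calls,
                               window = 200L) {
  td <- transduction_calls
  cc <- cluster_calls
  recs <- rbind(
    if (nrow(cc) > 0L) data.frame(
      sample_id = cc$sample_id, chrom = cc$chrom, start = cc$start,
      end = cc$end, family = cc$family, method = "cluster",
      source_id = NA_character_, cytoband = NA_character_,
      class = NA_character_,
      support = cc$pos_support + cc$neg_support,
      stringsAsFactors = FALSE) else NULL,
    if (nrow(td) > 0L) data.frame(
      sample_id = td$sample_id, chrom = td$chrom, start = td$start,
      end = td$end, family = "LINE-1", method = "transduction",
      source_id = td$source_id, cytoband = td$cytoband,
      class = td$class, support = td$support,
      stringsAsFactors = FALSE) else NULL)
  if (is.null(recs) || nrow(recs) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      family = character(), method = character(),
                      source_id = character(), cytoband = character(),
                      class = character(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (g in split(recs, list(recs$sample_id, recs$chrom, recs$family),
                  drop = TRUE)) {
    n <- nrow(g)
    pair_idx <- if (n > 1L) utils::combn(n, 2L) else matrix(0L, 2, 0)
    edges <- which(apply(pair_idx, 2L, function(p) {
      interval_gap(g$start[p[1]], g$end[p[1]],
                   g$start[p[2]], g$end[p[2]]) <= window
    }))
    memb <- components_from_edges(n, pair_idx[1L, edges],
                                  pair_idx[2L, edges])
    for (cmp in split(seq_len(n), memb)) {
      cl <- g[cmp, , drop = FALSE]
      methods <- unique(cl$method)
      both <- length(methods) > 1L
      src <- na.omit(cl$source_id)
      is_td <- "transduction" %in% methods
      # a transduced site also carrying cluster-caller LINE-1 evidence is
      # a 3' transduction; transduced flank alone is an orphan
      cls <- if (!is_td) NA_character_ else if (both) "3prime"
             else "orphan"
      out[[length(out) + 1L]] <- data.frame(
        sample_id = cl$sample_id[1L], chrom = cl$chrom[1L],
        start = min(cl$start), end = max(cl$end),
        family = cl$family[1L],
        method = if (both) "both" else methods,
        source_id = if (length(src) > 0L) src[1L] else NA_character_,
        cytoband = if (any(!is.na(cl$cytoband)))
          cl$cytoband[!is.na(cl$cytoband)][1L] else NA_character_,
        class = cls,
        support = max(cl$support), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Per-source transduction activity summary
#'
#' @param calls Attributed transduction calls.
#' @return data.frame with per-element `count`, `fraction` (summing to 1)
#'   and `recurrent` flag (count >= 2), sorted by descending count.
#' @export
summarize_source_activity <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(source_id = character(), count = integer(),
                      fraction = numeric(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(calls$source_id)
  out <- data.frame(source_id = names(tab),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    recurrent = as.integer(tab) >= 2L,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$source_id), ]
  rownames(out) <- NULL
  out
}

#' Call LINE-1 transductions from SV tables
#'
#' Applies the fixed filter chain: support/MAPQ filter, same-type 200 bp
#' merge, germline subtraction of merged normal SVs (length > 1000 bp),
#' source-element attachment within 1000 bp of a catalog 3' end, then the
#' panel and female-chromosome-Y filters.
#'
#' @param tumor_svs,normal_svs Raw SV call tables.
#' @param catalog Source-element catalog.
#' @param sample_sex Named sex vector.
#' @param panel_calls Optional panel transduction calls.
#' @param min_support,min_mapq,merge_window,min_length,proximity,panel_window
#'   Stage thresholds (defaults: 3, 37, 200, 1000, 1000, 200).
#' @return Transduction call data.frame.
#' @export
call_transductions <- function(tumor_svs, normal_svs, catalog, sample_sex,
                               panel_calls = NULL, min_support = 3L,
                               min_mapq = 37, merge_window = 200L,
                               min_length = 1000L, proximity = 1000L,
                               panel_window = 200L) {
  t1 <- filter_sv_calls(tumor_svs, min_support, min_mapq)
  n1 <- filter_sv_calls(normal_svs, min_support, min_mapq)
  t2 <- merge_sv_calls(t1, merge_window)
  n2 <- merge_sv_calls(n1, merge_window)
  som <- subtract_germline_svs(t2, n2, min_length, merge_window)
  prov <- attach_source_elements(som, catalog, proximity)
  somatic_and_sex_filter(prov, panel_calls, sample_sex, catalog,
                         panel_window)
}
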