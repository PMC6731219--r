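#' Breakpoint window from reciprocal-cluster inner coordinates
#'
#' The insertion breakpoint is bracketed by the inner coordinates of the
#' positive- and negative-strand read clusters (the rightmost anchor end of
#' the + cluster and the leftmost anchor start of the - cluster). The window
#' is their min/max span regardless of which side is larger; the midpoint is
#' the floor of their mean.
#'
#' @param pos_inner,neg_inner Inner coordinates (either may be `NA` when a
#'   cluster is missing, flagging a partial call).
#' @return A list with `start`, `end`, `midpoint`, `partial`.
#' @export
define_breakpoint_window <- function(pos_inner, neg_inner) {
  if (is.na(pos_inner) && is.na(neg_inner)) {
    stop("both inner coordinates missing", call. = FALSE)
  }
  if (is.na(pos_inner) || is.na(neg_inner)) {
    x <- if (is.na(pos_inner)) neg_inner else pos_inner
    return(list(start = x, end = x, midpoint = x, partial = TRUE))
  }
  lo <- min(pos_inner, neg_inner)
  hi <- max(pos_inner, neg_inner)
  list(start = lo, end = hi, midpoint = (lo + hi) %/% 2, partial = FALSE)
}

#' Call a poly-A/T tail from split reads around a breakpoint
#'
#' Poly-A is called when at least two forward-strand split reads within the
#' window around the breakpoint midpoint begin with three or more
#' consecutive A bases; poly-T symmetrically from reverse-strand reads
#' ending in three or more consecutive T bases. A call is vetoed when any
#' overlapping read shows the same homopolymer run in its reference-aligned
#' portion (the run is then genomic, not a tail). If both A and T qualify
#' the call is returned as `none` and flagged conflicting.
#'
#' @param split_reads data.frame with columns `chrom`, `pos`, `strand`
#'   (`+`/`-`), `seq` (read sequence), `ref_seq` (reference-aligned portion,
#'   `NA` if unavailable).
#' @param chrom,midpoint Breakpoint location.
#' @param window Total window width in bp centered on the midpoint.
#' @param min_reads Minimum qualifying reads (default 2).
#' @param min_run Minimum homopolymer run length (default 3).
#' @return A list with `tail` (`"A"`, `"T"` or `"none"`) and `conflicting`.
#' @export
call_poly_tail <- function(split_reads, chrom, midpoint, window = 200,
                           min_reads = 2L, min_run = 3L) {
  half <- window / 2
  sel <- split_reads[split_reads$chrom == chrom &
                     abs(split_reads$pos - midpoint) <= half, , drop = FALSE]
  if (nrow(sel) == 0L) return(list(tail = "none", conflicting = FALSE))

  run_a <- paste0("^A{", min_run, ",}")
  run_t <- paste0("T{", min_run, ",}$")
  a_reads <- sum(sel$strand == "+" & grepl(run_a, sel$seq))
  t_reads <- sum(sel$strand == "-" & grepl(run_t, sel$seq))

  ref <- sel$ref_seq[!is.na(sel$ref_seq)]
  ref_run <- function(base) {
    any(grepl(paste0(base, "{", min_run, ",}"), ref))
  }
  a_ok <- a_reads >= min_reads && !ref_run("A")
  t_ok <- t_reads >= min_reads && !ref_run("T")

  if (a_ok && t_ok) return(list(tail = "none", conflicting = TRUE))
  if (a_ok) return(list(tail = "A", conflicting = FALSE))
  if (t_ok) return(list(tail = "T", conflicting = FALSE))
  list(tail = "none", conflicting = FALSE)
}

#' Insertion strand and orientation from poly tail and gene strand
#'
#' A poly-A tail implies the insertion is on the reverse strand with
#' respect to the reference; a poly-T tail implies forward. An insertion is
#' sense when reverse in a plus-strand gene or forward in a minus-strand
#' gene, antisense in the two remaining combinations; without a tail call
#' or a gene strand both are unknown.
#'
#' @param tail `"A"`, `"T"` or `"none"`.
#' @param gene_strand `"+"`, `"-"` or `NA` (intergenic / no single strand).
#' @return list with `insertion_strand` and `orientation`.
#' @export
assign_orientation <- function(tail, gene_strand = NA_character_) {
  ins <- switch(tail, A = "reverse", T = "forward", "unknown")
  if (ins == "unknown" || is.na(gene_strand)) {
    return(list(insertion_strand = ins, orientation = "unknown"))
  }
  sense <- (ins == "reverse" && gene_strand == "+") ||
           (ins == "forward" && gene_strand == "-")
  list(insertion_strand = ins,
       orientation = if (sense) "sense" else "antisense")
}

#' Gene context of insertion breakpoint windows
#'
#' Classifies each insertion as exon (window overlaps any protein-coding
#' exon), intron (within a protein-coding gene body but no exon overlap) or
#' intergenic; reports all overlapping gene ids, plus the nearest gene for
#' intergenic insertions (used by the expression association test).
#'
#' @param insertions data.frame with `chrom`, `start`, `end`.
#' @param genes,exons Gene-model tables from the annotation bundle.
#' @return `insertions` with `region`, `gene_id` (comma-joined when
#'   several), `gene_strand` (`NA` unless exactly one gene strand applies)
#'   and `nearest_gene` columns appended.
#' @export
annotate_gene_context <- function(insertions, genes, exons) {
  n <- nrow(insertions)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  gene_strand <- rep(NA_character_, n)
  nearest <- rep(NA_character_, n)
  if (n == 0L) {
    return(cbind(insertions, region = character(0), gene_id = character(0),
                 gene_strand = character(0), nearest_gene = character(0)))
  }
  ins_gr <- intervals_to_granges(insertions[, c("chrom", "start", "end")])
  if (nrow(genes) > 0L) {
    pc <- genes[genes$protein_coding, , drop = FALSE]
    gene_gr <- intervals_to_granges(pc[, c("chrom", "start", "end")])
    hit_g <- GenomicRanges::findOverlaps(ins_gr, gene_gr)
    by_ins <- split(S4Vectors::subjectHits(hit_g),
                    S4Vectors::queryHits(hit_g))
    for (q in names(by_ins)) {
      i <- as.integer(q)
      gids <- pc$gene_id[by_ins[[q]]]
      strands <- unique(pc$strand[by_ins[[q]]])
      region[i] <- "intron"
      gene_id[i] <- paste(gids, collapse = ",")
      gene_strand[i] <- if (length(strands) == 1L) strands else NA_character_
      nearest[i] <- gids[1L]
    }
    pc_ex <- exons[exons$gene_id %in% pc$gene_id, , drop = FALSE]
    if (nrow(pc_ex) > 0L) {
      ex_gr <- intervals_to_granges(pc_ex[, c("chrom", "start", "end")])
      hit_e <- GenomicRanges::findOverlaps(ins_gr, ex_gr)
      region[unique(S4Vectors::queryHits(hit_e))] <- "exon"
    }
    miss <- which(region == "intergenic")
    if (length(miss) > 0L && nrow(pc) > 0L) {
      nn <- GenomicRanges::distanceToNearest(ins_gr[miss], gene_gr)
      nearest[miss[S4Vectors::queryHits(nn)]] <-
        pc$gene_id[S4Vectors::subjectHits(nn)]
    }
  }
  out <- insertions
  out$region <- region
  out$gene_id <- gene_id
  out$gene_strand <- gene_strand
  out$nearest_gene <- nearest
  out
}

#' Insertion density per track label
#'
#' Number of insertion midpoints falling in each label of a genome
#' partition track, divided by the label's span in Mbp. The bp-weighted
#' mean of label densities equals the genome-wide density exactly.
#'
#' @param insertions data.frame with `chrom`, `start`, `end` (midpoint is
#'   used for bin membership).
#' @param track data.frame with `chrom`, `start`, `end` and a label column.
#' @param label_col Name of the label column (e.g. `"bin"` or `"state"`).
#' @return data.frame with `label`, `bp`, `count`, `density_per_mbp`
#'   (`NA` for zero-bp labels).
#' @export
compute_insertion_density <- function(insertions, track,
                                      label_col = "bin") {
  labels <- sort(unique(track[[label_col]]))
  bp <- vapply(labels, function(l) {
    sub <- track[track[[label_col]] == l, ]
    sum(sub$end - sub$start)
  }, numeric(1))
  mid <- (insertions$start + insertions$end) %/% 2
  count <- vapply(labels, function(l) {
    sub <- track[track[[label_col]] == l, ]
    hits <- 0L
    for (ch in unique(sub$chrom)) {
      m <- mid[insertions$chrom == ch]
      s <- sub[sub$chrom == ch, ]
      if (length(m) == 0L || nrow(s) == 0L) next
      hits <- hits + sum(vapply(m, function(x)
        any(x >= s$start & x < s$end), logical(1)))
    }
    as.numeric(hits)
  }, numeric(1))
  data.frame(label = labels, bp = bp, count = count,
             density_per_mbp = ifelse(bp > 0, count / (bp / 1e6), NA_real_),
             stringsAsFactors = FALSE)
}

#' Open/closed chromatin partition from DNase consensus
#'
#' Open chromatin is every base covered by DNase intervals in at least two
#' of the four cell-line sets, intersected with the callable regions;
#' closed chromatin is the callable remainder. The two states partition the
#' callable genome exactly.
#'
#' @param dnase_sets List of interval data.frames (`chrom`,`start`,`end`).
#' @param callable Callable-region data.frame.
#' @param min_sets Minimum number of supporting sets (default 2).
#' @return data.frame `chrom`, `start`, `end`, `state` (`open`/`closed`).
#' @export
derive_open_chromatin <- function(dnase_sets, callable, min_sets = 2L) {
  callable_gr <- intervals_to_granges(callable)
  # collapse within-set overlaps first: a base counts once per cell line
  all_gr <- do.call(c, lapply(dnase_sets, function(d)
    GenomicRanges::reduce(
      intervals_to_granges(d[, c("chrom", "start", "end")]))))
  GenomeInfoDb::seqlevels(all_gr) <-
    union(GenomeInfoDb::seqlevels(all_gr),
          GenomeInfoDb::seqlevels(callable_gr))
  cov <- GenomicRanges::coverage(all_gr)
  open_gr <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_sets,
                                                   rangesOnly = TRUE))
  open_gr <- GenomicRanges::intersect(
    open_gr, callable_gr, ignore.strand = TRUE)
  closed_gr <- GenomicRanges::setdiff(callable_gr, open_gr,
                                      ignore.strand = TRUE)
  open_df <- granges_to_intervals(open_gr)
  closed_df <- granges_to_intervals(closed_gr)
  open_df$state <- if (nrow(open_df)) "open" else character(0)
  closed_df$state <- if (nrow(closed_df)) "closed" else character(0)
  out <- rbind(open_df, closed_df)
  out <- out[out$end > out$start, ]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Annotate a unified insertion table
#'
#' Applies gene context, poly-tail calling, orientation assignment,
#' replication-bin and chromatin-state membership to every insertion.
#'
#' @param insertions Unified insertion data.frame (`sample_id`, `chrom`,
#'   `start`, `end`, `family`).
#' @param annotation A `cohort_annotation` bundle.
#' @param split_reads Split-read table for poly-tail calls (may be empty).
#' @param tail_window Poly-tail search window width in bp.
#' @return The insertion table with annotation columns appended.
#' @export
annotate_insertions <- function(insertions, annotation, split_reads = NULL,
                                tail_window = 200) {
  out <- annotate_gene_context(insertions, annotation$genes,
                               annotation$exons)
  n <- nrow(out)
  out$midpoint <- (out$start + out$end) %/% 2
  out$poly_tail <- rep("none", n)
  out$insertion_strand <- rep("unknown", n)
  out$orientation <- rep("unknown", n)
  for (i in seq_len(n)) {
    if (!is.null(split_reads)) {
      sr <- split_reads[split_reads$sample_id == out$sample_id[i], ,
                        drop = FALSE]
      tail <- call_poly_tail(sr, out$chrom[i], out$midpoint[i],
                             window = tail_window)$tail
    } else tail <- "none"
    ori <- assign_orientation(tail, out$gene_strand[i])
    out$poly_tail[i] <- tail
    out$insertion_strand[i] <- ori$insertion_strand
    out$orientation[i] <- ori$orientation
  }
  out$replication_bin <- label_by_track(out, annotation$replication, "bin")
  out$chromatin <- label_by_track(out, annotation$open_closed, "state")
  out$chromatin[is.na(out$chromatin)] <- "uncallable"
  out
}

# midpoint membership lookup in a partition track
label_by_track <- function(insertions, track, label_col) {
  mid <- (insertions$start + insertions$end) %/% 2
  res <- rep(NA, nrow(insertions))
  for (i in seq_len(nrow(insertions))) {
    s <- track[track$chrom == insertions$chrom[i] &
               track$start <= mid[i] & mid[i] < track$end, ]
    if (nrow(s) > 0L) res[i] <- s[[label_col]][1L]
  }
  res
}
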