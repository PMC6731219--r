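#' Gap between two closed genomic intervals
#'
#' Distance between the closest edges of two intervals on the same
#' chromosome; zero when the intervals overlap or touch.
#'
#' @param start1,end1,start2,end2 Numeric vectors of interval edges
#'   (0-based positions, `end >= start`). Recycled to a common length.
#' @return Numeric vector of gaps in bp.
#' @export
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Each pipeline stage draws from its own stream so toggling one stage does
#' not perturb another's randomness. The result stays below 2^31.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629)
}

#' Content hash of an R object
#'
#' MD5 of the serialized object, used for run-manifest determinism checks.
#'
#' @param x Any serializable R object.
#' @return A length-one character MD5 digest.
#' @export
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Connected components over an edge list on nodes 1..n; returns integer
# membership vector. Uses igraph so transitive merge rules ("within 200 bp")
# chain correctly.
components_from_edges <- function(n, from, to) {
  if (n == 0L) return(integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  igraph::components(g)$membership
}

# Empty data.frame with given column names/prototypes
empty_df <- function(proto) {
  proto[0L, , drop = FALSE]
}

#' Convert between 0-based half-open interval tables and GRanges
#'
#' Internal coordinates are 0-based half-open (BED convention); `GRanges`
#' is 1-based closed. Extra columns travel as metadata columns.
#'
#' @param df data.frame with `chrom`, `start`, `end` columns.
#' @return A [GenomicRanges::GRanges] object.
#' @export
intervals_to_granges <- function(df) {
  meta <- df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  if (ncol(meta) > 0L) S4Vectors::mcols(gr) <- meta
  gr
}

#' @rdname intervals_to_granges
#' @param gr A `GRanges` object.
#' @export
granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(meta) > 0L) df <- cbind(df, meta)
  rownames(df) <- NULL
  df
}
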