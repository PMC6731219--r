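# Declared artifact schemas: column name -> readr-style type letter
# (c = character, i = integer, d = double, l = logical)
mei_schemas <- function() {
  list(
    discordant_pairs = c(sample_id = "c", tissue = "c", chrom = "c",
                         anchor_start = "i", anchor_end = "i",
                         strand = "c", anchor_mapq = "i",
                         mate_mapq = "i", mate_family = "c",
                         mate_in_repeat = "l"),
    split_reads = c(sample_id = "c", chrom = "c", pos = "i",
                    strand = "c", seq = "c", ref_seq = "c"),
    panel_calls = c(chrom = "c", position = "i", family = "c",
                    n_samples = "i"),
    sv_calls = c(sample_id = "c", sv_id = "c", type = "c", chromA = "c",
                 posA = "i", chromB = "c", posB = "i", support = "i",
                 mapq = "d", length = "d"),
    candidate_insertions = c(sample_id = "c", chrom = "c", start = "i",
                             end = "i", family = "c", pos_support = "i",
                             neg_support = "i", somatic = "l"),
    transduction_calls = c(sample_id = "c", chrom = "c", start = "i",
                           end = "i", source_id = "c", cytoband = "c",
                           class = "c", support = "i", ambiguous = "l"),
    ai_events = c(sample_id = "c", chrom = "c", bp1 = "i", bp2 = "i"),
    clinical = c(sample_id = "c", cimp = "c", ai_fraction = "d",
                 msi = "c", tp53 = "l", braf_v600e = "l",
                 kras_hotspot = "l", dukes_stage = "c", age = "d",
                 sex = "c", location = "c", mean_coverage = "d",
                 insertion_count = "i", followup_days = "d",
                 event = "i"),
    methylation = c(probe_id = "c", gene = "c", sample_id = "c",
                    ratio = "d"),
    truth = c(sample_id = "c", chrom = "c", position = "i",
              family = "c", somatic = "l", transduction = "l",
              source_id = "c", gene_id = "c", poly_tail = "c",
              strand = "c", subthreshold = "l"))
}

#' Write an artifact table with a declared schema
#'
#' Tab-separated, with the schema's columns in declared order; the inverse
#' of [read_mei_table()], giving identity round-trips.
#'
#' @param df data.frame containing at least the schema columns.
#' @param path Output file path.
#' @param schema Schema id; one of `names(mei_schemas())`.
#' @return `path`, invisibly.
#' @export
write_mei_table <- function(df, path, schema) {
  sc <- mei_schema_get(schema)
  miss <- setdiff(names(sc), names(df))
  if (length(miss) > 0L) {
    stop("schema '", schema, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  write.table(df[, names(sc), drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an artifact table, validating its schema
#'
#' @param path Input file path.
#' @param schema Schema id; one of `names(mei_schemas())`.
#' @return data.frame with columns typed per the schema.
#' @export
read_mei_table <- function(path, schema) {
  sc <- mei_schema_get(schema)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, names(sc))) {
    stop("schema '", schema, "' violation at line 1 of ", path,
         ": expected columns ", paste(names(sc), collapse = ", "),
         call. = FALSE)
  }
  classes <- setNames(c(c = "character", i = "integer", d = "numeric",
                        l = "logical")[sc], names(sc))
  read.table(path, sep = "\t", header = TRUE, colClasses = classes,
             na.strings = "NA", quote = "", comment.char = "",
             stringsAsFactors = FALSE)
}

mei_schema_get <- function(schema) {
  schemas <- mei_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema '", schema, "'", call. = FALSE)
  }
  schemas[[schema]]
}

#' Export insertion calls as BED
#'
#' Breakpoint windows become the BED intervals (0-based half-open), with
#' the family in the name column and total support in the score column.
#' Uses rtracklayer when available so the written file follows the BED
#' convention exactly.
#'
#' @param insertions Insertion table with `chrom`, `start`, `end`,
#'   `family` and a support column.
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_insertions_bed <- function(insertions, path) {
  support <- if ("support" %in% names(insertions)) insertions$support
    else insertions$pos_support + insertions$neg_support
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- intervals_to_granges(
      insertions[, c("chrom", "start", "end"), drop = FALSE])
    # zero-width breakpoint windows still need one representable base
    IRanges::width(gr) <- pmax(IRanges::width(gr), 1L)
    gr$name <- insertions$family
    gr$score <- pmin(1000, as.numeric(support))
    rtracklayer::export(gr, path, format = "BED")
  } else {
    bed <- data.frame(insertions$chrom, insertions$start,
                      pmax(insertions$end, insertions$start + 1L),
                      insertions$family, pmin(1000, support), ".")
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read insertion intervals back from a BED file
#'
#' @param path A `.bed` path written by [write_insertions_bed()].
#' @return data.frame with 0-based half-open `chrom`, `start`, `end`,
#'   `family`, `support`.
#' @export
read_insertions_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    df <- granges_to_intervals(gr)
    names(df)[names(df) == "name"] <- "family"
    names(df)[names(df) == "score"] <- "support"
    df[, c("chrom", "start", "end", "family", "support")]
  } else {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    setNames(df[, 1:5], c("chrom", "start", "end", "family", "support"))
  }
}
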