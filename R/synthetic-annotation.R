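#' Build the synthetic annotation bundle
#'
#' Lays down, deterministically from the config seed, everything the
#' downstream stages need: non-overlapping protein-coding gene models with
#' exons and strands, callable regions (chromosomes minus 10 kb telomeric
#' margins), a replication-timing track partitioning the callable genome
#' into five equal-width bins (0 = earliest), DNase hypersensitivity
#' interval sets for four pseudo cell lines together with the derived
#' open/closed chromatin partition, a fragile-site gene subset, a catalog
#' of full-length reference L1HS source elements with 3'-end coordinates,
#' and a decoy contig.
#'
#' @param config A [synthetic_config()].
#' @return A `cohort_annotation` list with elements `genes`, `exons`,
#'   `callable`, `replication`, `dnase`, `open_closed`, `fragile_sites`,
#'   `sources`, `decoy_contig`, `genome`. All interval tables are 0-based
#'   half-open.
#' @export
build_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  genome <- config$genome
  margin <- 10000L

  if (any(genome <= 2 * margin)) {
    stop("chromosome shorter than twice the callable margin; ",
         "increase chromosome lengths", call. = FALSE)
  }

  callable <- data.frame(chrom = names(genome),
                         start = margin,
                         end = as.integer(genome) - margin,
                         stringsAsFactors = FALSE)

  genes <- make_gene_models(genome, config$n_genes, margin)

  replication <- make_replication_track(callable, n_bins = 5L,
                                        segments_per_bin = 5L)
  dnase <- make_dnase_sets(callable, n_sets = 4L)
  open_closed <- derive_open_chromatin(dnase, callable)

  n_frag <- max(1L, round(0.1 * nrow(genes$genes)))
  fragile_sites <- if (nrow(genes$genes) == 0L) {
    empty_df(data.frame(site_id = character(), chrom = character(),
                        start = integer(), end = integer()))
  } else {
    fs <- genes$genes[seq_len(n_frag), c("gene_id", "chrom", "start", "end")]
    names(fs)[1] <- "site_id"
    rownames(fs) <- NULL
    fs
  }

  sources <- make_source_catalog(callable, config$n_sources,
                                 config$n_active_sources)

  ann <- list(genes = genes$genes, exons = genes$exons,
              callable = callable, replication = replication,
              dnase = dnase, open_closed = open_closed,
              fragile_sites = fragile_sites, sources = sources,
              decoy_contig = config$decoy_contig, genome = genome)
  class(ann) <- "cohort_annotation"
  ann
}

# Non-overlapping genes placed in equal slots along each chromosome; one
# transcript with 2-8 non-overlapping exons per gene.
make_gene_models <- function(genome, n_genes, margin) {
  gene_proto <- data.frame(gene_id = character(), name = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           protein_coding = logical(),
                           stringsAsFactors = FALSE)
  exon_proto <- data.frame(gene_id = character(), transcript_id = character(),
                           chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  if (n_genes == 0L) return(list(genes = gene_proto, exons = exon_proto))

  per_chrom <- table(factor(
    sample(names(genome), n_genes, replace = TRUE, prob = genome),
    levels = names(genome)))
  genes <- list(); exons <- list(); gi <- 0L
  for (chrom in names(genome)) {
    k <- per_chrom[[chrom]]
    if (k == 0L) next
    usable <- genome[[chrom]] - 2 * margin
    slot <- floor(usable / k)
    if (slot < 5000) {
      stop("chromosome ", chrom, " too short for ", k, " gene slots",
           call. = FALSE)
    }
    for (j in seq_len(k)) {
      gi <- gi + 1L
      slot_start <- margin + (j - 1L) * slot
      glen <- round(runif(1, 0.2, 0.6) * slot)
      gstart <- slot_start + sample.int(slot - glen, 1L)
      gid <- sprintf("GENE%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      genes[[gi]] <- data.frame(gene_id = gid,
                                name = sprintf("SYN%04d", gi),
                                chrom = chrom, start = gstart,
                                end = gstart + glen, strand = strand,
                                protein_coding = TRUE,
                                stringsAsFactors = FALSE)
      n_ex <- sample(2:8, 1L)
      # short exons (~5% of the gene body) spread across its span
      slots <- round(seq(gstart, gstart + glen, length.out = n_ex + 1L))
      ex_start <- slots[-(n_ex + 1L)]
      ex_end <- pmin(ex_start +
                       pmax(150L, round(0.05 * glen / n_ex)),
                     slots[-1L])
      exons[[gi]] <- data.frame(gene_id = gid,
                                transcript_id = paste0(gid, ".t1"),
                                chrom = chrom, start = ex_start,
                                end = ex_end, stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

# Five-bin replication-timing partition of the callable genome; each bin's
# total bp is (up to integer rounding) one fifth of the callable bp.
make_replication_track <- function(callable, n_bins = 5L,
                                   segments_per_bin = 5L) {
  out <- list()
  for (i in seq_len(nrow(callable))) {
    n_seg <- n_bins * segments_per_bin
    cuts <- round(seq(callable$start[i], callable$end[i],
                      length.out = n_seg + 1L))
    out[[i]] <- data.frame(chrom = callable$chrom[i],
                           start = cuts[-(n_seg + 1L)],
                           end = cuts[-1L],
                           bin = rep(seq_len(n_seg) %% n_bins),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[res$end > res$start, ]
  rownames(res) <- NULL
  res
}

# Random DNase interval sets; each set covers ~35% of the callable genome so
# that the >=2-of-4 consensus yields a plausible open fraction.
make_dnase_sets <- function(callable, n_sets = 4L) {
  lapply(seq_len(n_sets), function(s) {
    rows <- list()
    for (i in seq_len(nrow(callable))) {
      len <- callable$end[i] - callable$start[i]
      n_iv <- max(1L, round(len / 50000))
      centers <- sort(callable$start[i] + sample.int(len, n_iv))
      widths <- pmax(500L, round(rexp(n_iv, 1 / 17500)))
      st <- pmax(callable$start[i], centers - widths %/% 2L)
      en <- pmin(callable$end[i], centers + widths %/% 2L)
      rows[[i]] <- data.frame(chrom = callable$chrom[i], start = st,
                              end = en, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    # collapse overlaps within a set
    granges_to_intervals(GenomicRanges::reduce(intervals_to_granges(df)))
  })
}

# Full-length L1HS catalog: 6 kb elements, random strand; the 3' end is the
# right edge on + and the left edge on -. Element ids sort lexicographically
# so deterministic tie-breaks are reproducible.
make_source_catalog <- function(callable, n_sources, n_active) {
  el_len <- 6000L
  chroms <- sample(callable$chrom, n_sources, replace = TRUE,
                   prob = callable$end - callable$start)
  idx <- match(chroms, callable$chrom)
  start <- callable$start[idx] +
    vapply(callable$end[idx] - callable$start[idx] - el_len,
           function(m) sample.int(m, 1L), integer(1))
  strand <- sample(c("+", "-"), n_sources, replace = TRUE)
  df <- data.frame(
    element_id = sprintf("L1HS_%03d", seq_len(n_sources)),
    cytoband = sprintf("%sq%02d.%d", sub("chr", "", chroms),
                       sample(11:44, n_sources, replace = TRUE),
                       sample(1:3, n_sources, replace = TRUE)),
    chrom = chroms, start = start, end = start + el_len, strand = strand,
    three_prime = ifelse(strand == "+", start + el_len, start),
    germline_active = FALSE, cancer_active = FALSE,
    stringsAsFactors = FALSE)
  active <- sample.int(n_sources, min(n_active, n_sources))
  df$cancer_active[active] <- TRUE
  df$germline_active[sample(active, ceiling(length(active) / 2))] <- TRUE
  rownames(df) <- NULL
  df
}
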