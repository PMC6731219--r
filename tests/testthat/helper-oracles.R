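# Independent brute-force oracles used to cross-check the interval and
# clustering machinery. Deliberately quadratic / per-base; none of them
# shares code with the package implementations.

# all-pairs single-linkage clustering of positions: i~j iff |xi-xj| <= d,
# components by repeated sweep (no igraph)
oracle_single_linkage <- function(x, d) {
  n <- length(x)
  memb <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(x[i] - x[j]) <= d && memb[j] != memb[i]) {
        memb[memb == memb[j]] <- memb[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(memb, unique(memb))
}

# closed-interval gap by scanning integer positions (tiny ranges only)
oracle_gap <- function(s1, e1, s2, e2) {
  if (max(s1, s2) <= min(e1, e2)) return(0)
  min(abs(outer(c(s1, e1), c(s2, e2), "-")))
}

# quadratic somatic filter: drop candidate i if any germline call within w
oracle_panel_filter <- function(cand, germ, w) {
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(germ))) {
      if (cand$chrom[i] != germ$chrom[j]) next
      if (oracle_gap(cand$start[i], cand$end[i],
                     germ$position[j], germ$position[j]) <= w) {
        keep[i] <- FALSE
      }
    }
  }
  cand[keep, , drop = FALSE]
}

# connected components by hand-rolled BFS over an adjacency predicate
oracle_components <- function(n, adjacent) {
  memb <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(memb[s])) next
    comp <- comp + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(memb[v])) next
      memb[v] <- comp
      for (u in seq_len(n)) {
        if (is.na(memb[u]) && adjacent(v, u)) queue <- c(queue, u)
      }
    }
  }
  memb
}

# per-base bitmap open/closed partition on a small genome
oracle_open_closed <- function(dnase_sets, callable, min_sets = 2L) {
  stopifnot(nrow(callable) == 1L)
  L <- callable$end
  cover <- matrix(0L, nrow = length(dnase_sets), ncol = L)
  for (k in seq_along(dnase_sets)) {
    d <- dnase_sets[[k]]
    for (i in seq_len(nrow(d))) {
      lo <- max(0L, d$start[i]); hi <- min(L, d$end[i])
      if (hi > lo) cover[k, (lo + 1L):hi] <- 1L
    }
  }
  open <- colSums(cover) >= min_sets
  open[seq_len(L) <= callable$start] <- NA  # outside callable
  open
}

# tiny shared synthetic cohort, built once per test run
tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$cohort)) {
    cfg <- synthetic_config(n_tumors = 15L, seed = 42L,
                            genome = c(chr1 = 6e6, chr2 = 4e6),
                            n_genes = 60L)
    tiny_cohort_env$cohort <- simulate_cohort(cfg)
  }
  tiny_cohort_env$cohort
}
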