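# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use naive O(n^2) / exhaustive-scan logic so they
# share no code path with the production implementations they check.

library(data.table)

# Build a pooled CtssProfile directly from a signal table
# (chrom, pos, strand, score[, sample_id]); score is taken as pooled TPM of
# a single sample unless sample_id is present.
pooled_from_table <- function(dt) {
  dt <- as.data.table(dt)
  if (!"sample_id" %in% names(dt)) dt[, sample_id := "s1"]
  pooled <- dt[, .(score = sum(score)), by = .(chrom, pos, strand)]
  data.table::setorder(pooled, chrom, strand, pos)
  libs <- setNames(rep(1e6, uniqueN(dt$sample_id)), unique(dt$sample_id))
  structure(list(ctss = dt[, .(chrom, pos, strand, sample_id, score)],
                 units = "tpm", lib_sizes = libs, pooled = pooled),
            class = "CtssProfile")
}

# Connected components of the "within max_gap" graph over positions;
# returns a list of sorted position vectors.
oracle_components <- function(pos, max_gap) {
  n <- length(pos)
  if (n == 0L) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  lapply(split(pos, comp), sort)
}

# Exhaustive-scan enhancer caller: computes the balance score at every base
# of the scanned range with explicit subset sums, thresholds, merges by gap
# and reports (start, end, mid, balance) per region.
oracle_call_bidirectional <- function(signal, window = 201L,
                                      threshold = 0.95, max_gap = 20L) {
  signal <- as.data.table(signal)
  h <- (window - 1L) %/% 2L
  out <- list()
  for (chr in sort(unique(signal$chrom))) {
    x <- signal[chrom == chr]
    lo <- max(0L, min(x$pos) - h)
    hi <- max(x$pos) + h
    mids <- integer(0)
    bs <- numeric(0)
    for (m in lo:hi) {
      D <- sum(x[strand == "-" & pos >= m - h & pos <= m - 1L]$score)
      U <- sum(x[strand == "+" & pos >= m + 1L & pos <= m + h]$score)
      Tt <- sum(x[pos >= m - h & pos <= m + h]$score)
      B <- if (Tt > 0) sqrt(0.5 * D / Tt) + sqrt(0.5 * U / Tt) else 0
      if (B >= threshold && D > 0 && U > 0) {
        mids <- c(mids, m)
        bs <- c(bs, B)
      }
    }
    if (length(mids) == 0L) next
    grp <- cumsum(c(1L, diff(mids) > max_gap))
    for (g in unique(grp)) {
      mm <- mids[grp == g]
      bb <- bs[grp == g]
      out[[length(out) + 1L]] <- data.table(
        chrom = chr, start = min(mm), end = max(mm) + 1L,
        mid = mm[which.max(bb)], balance = max(bb))
    }
  }
  if (length(out) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), mid = integer(), balance = numeric()))
  }
  res <- rbindlist(out)
  data.table::setorder(res, chrom, start)
  res
}

# Random pooled signal instance for clustering / calling property tests.
random_signal <- function(n, span = 1500L, chroms = "chr1") {
  data.table(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    score = round(stats::runif(n, 0.5, 20), 3)
  )[, .(score = sum(score)), by = .(chrom, pos, strand)]
}

# A small, quick fixture world shared by binding/network tests.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 11L, n_chrom = 2L, chrom_len = 150000L,
                           n_genes = 20L, n_enhancers = 12L, n_tfs = 4L,
                           targets_per_driver = 3L)
      cache <<- list(spec = spec, world = make_genome(spec))
    }
    cache
  }
})
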