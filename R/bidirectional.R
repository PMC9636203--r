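# Enhancer calling from balanced divergent (bidirectional) transcription,
# plus region annotation against genes and peak sets.
#
# The balance score over a window of odd width w centred on midpoint m uses
#   D = minus-strand pooled TPM in the upstream arm  [m-(w-1)/2, m)
#   U = plus-strand pooled TPM in the downstream arm (m, m+(w-1)/2]
#   T = total pooled TPM, both strands, whole window [m-(w-1)/2, m+(w-1)/2]
#   B = sqrt(0.5 * D/T) + sqrt(0.5 * U/T),  B = 0 when T = 0.
# This is the Bhattacharyya coefficient between the observed divergent-arm
# signal fractions and the ideal (0.5, 0.5) pattern: B = 1 for perfectly
# balanced divergent initiation, B = sqrt(0.5) ~ 0.707 for fully
# unidirectional signal, so a 0.95 threshold rejects plain TSS clusters.
# Signal on the "wrong" arms (plus upstream, minus downstream) and at the
# midpoint base itself counts toward T only, penalizing embedded TSSs.

.strand_signal <- function(pooled, chrom_name, strand_name) {
  x <- pooled$pooled[chrom == chrom_name & strand == strand_name]
  setorder(x, pos)
  list(pos = x$pos, val = x$score)
}

.balance_at <- function(minus, plus, mids, h) {
  D <- sparse_interval_sum(minus$pos, minus$val, mids - h, mids - 1L)
  U <- sparse_interval_sum(plus$pos, plus$val, mids + 1L, mids + h)
  Tt <- sparse_interval_sum(minus$pos, minus$val, mids - h, mids + h) +
    sparse_interval_sum(plus$pos, plus$val, mids - h, mids + h)
  B <- numeric(length(mids))
  nz <- Tt > 0
  B[nz] <- sqrt(0.5 * D[nz] / Tt[nz]) + sqrt(0.5 * U[nz] / Tt[nz])
  list(B = B, D = D, U = U, T = Tt)
}

#' Balance score of divergent transcription at a midpoint
#'
#' @param pooled a pooled `CtssProfile` (see [pool_profiles()]).
#' @param chrom chromosome name.
#' @param midpoint midpoint position(s), 0-based (vectorized).
#' @param window odd window width in bp (default 201 = 100 + 1 + 100).
#' @return numeric vector of balance scores in `[0, 1]`.
#' @export
balance_score <- function(pooled, chrom, midpoint, window = 201L) {
  stopifnot(is(pooled, "CtssProfile"), !is.null(pooled$pooled))
  if (window %% 2L == 0L) stop("window width must be odd", call. = FALSE)
  if (any(midpoint < 0)) stop("midpoint outside chromosome", call. = FALSE)
  h <- (window - 1L) %/% 2L
  minus <- .strand_signal(pooled, chrom, "-")
  plus <- .strand_signal(pooled, chrom, "+")
  .balance_at(minus, plus, as.integer(midpoint), h)$B
}

#' Call bidirectional (enhancer candidate) regions
#'
#' Scans every candidate midpoint (positions whose window can contain
#' minus-strand signal upstream and plus-strand signal downstream), keeps
#' midpoints with balance `>= balance_threshold`, and merges qualifying
#' midpoints `<= max_gap` bp apart into one region.  The region midpoint is
#' the qualifying midpoint with maximal balance (leftmost on ties).  The
#' region interval `[start, end)` is the run of qualifying midpoints;
#' `win_start`/`win_end` extend it by one arm on each side, and pooled TPM
#' (both strands) is computed over that signal window.
#'
#' @param pooled a pooled `CtssProfile`.
#' @param window odd window width (default 201).
#' @param balance_threshold minimum balance score (default 0.95).
#' @param max_gap merge distance between qualifying midpoints (default 20).
#' @return a `data.table`: `region_id`, `chrom`, `start`, `end`, `mid`,
#'   `balance`, `tpm`, `support`, `win_start`, `win_end`.
#' @export
call_bidirectional <- function(pooled, window = 201L, balance_threshold = 0.95,
                               max_gap = 20L) {
  stopifnot(is(pooled, "CtssProfile"), !is.null(pooled$pooled))
  if (window %% 2L == 0L) stop("window width must be odd", call. = FALSE)
  h <- (window - 1L) %/% 2L
  out <- list()
  for (chr in unique(pooled$pooled$chrom)) {
    minus <- .strand_signal(pooled, chr, "-")
    plus <- .strand_signal(pooled, chr, "+")
    if (length(minus$pos) == 0L || length(plus$pos) == 0L) next
    # candidate midpoints: D > 0 possible and U > 0 possible
    up <- IRanges::reduce(IRanges::IRanges(minus$pos + 1L, minus$pos + h))
    dn <- IRanges::reduce(IRanges::IRanges(plus$pos - h, plus$pos - 1L))
    cand_r <- IRanges::intersect(up, dn)
    if (length(cand_r) == 0L) next
    mids <- unlist(lapply(seq_along(cand_r), function(i) {
      seq.int(IRanges::start(cand_r)[i], IRanges::end(cand_r)[i])
    }))
    mids <- mids[mids >= 0L]
    b <- .balance_at(minus, plus, mids, h)
    keep <- b$B >= balance_threshold & b$D > 0 & b$U > 0
    if (!any(keep)) next
    mids <- mids[keep]
    bb <- b$B[keep]
    grp <- cumsum(c(1L, diff(mids) > max_gap))
    dt <- data.table(mid0 = mids, B = bb, grp = grp)
    reg <- dt[, {
      i <- which.max(B)
      .(start = min(mid0), end = max(mid0) + 1L, mid = mid0[i],
        balance = B[i])
    }, by = grp]
    reg[, grp := NULL]
    reg[, chrom := chr]
    out[[chr]] <- reg
  }
  if (length(out) == 0L) {
    return(data.table(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), mid = integer(),
                      balance = numeric(), tpm = numeric(),
                      support = integer(), win_start = integer(),
                      win_end = integer()))
  }
  reg <- rbindlist(out)
  reg[, `:=`(win_start = start - h, win_end = end + h)]
  setorder(reg, chrom, start)
  reg[, region_id := sprintf("BR%05d", .I)]
  reg[, tpm := {
    v <- numeric(.N)
    for (chr in unique(chrom)) {
      i <- which(chrom == chr)
      minus <- .strand_signal(pooled, chr, "-")
      plus <- .strand_signal(pooled, chr, "+")
      v[i] <- sparse_interval_sum(minus$pos, minus$val, win_start[i],
                                  win_end[i] - 1L) +
        sparse_interval_sum(plus$pos, plus$val, win_start[i], win_end[i] - 1L)
    }
    v
  }]
  reg[, support := count_support(pooled, chrom, win_start, win_end)]
  setcolorder(reg, c("region_id", "chrom", "start", "end", "mid", "balance",
                     "tpm", "support", "win_start", "win_end"))
  reg[]
}

#' Filter bidirectional regions by per-sample support
#'
#' Keeps regions with at least one tag (either strand, within the region's
#' signal window) in `>= min_support` samples.
#'
#' @param regions region table from [call_bidirectional()].
#' @param profile a `CtssProfile` carrying per-sample records (the pooled
#'   profile retains them).
#' @param min_support minimum number of supporting samples (default 2).
#' @export
filter_bidirectional <- function(regions, profile, min_support = 2L) {
  dt <- as.data.table(regions)
  if (nrow(dt) == 0L) return(dt)
  sup <- count_support(profile, dt$chrom, dt$win_start, dt$win_end)
  dt[, support := sup]
  dt[support >= min_support]
}

#' Normalize region widths to a fixed window centred on the midpoint
#'
#' The normalized interval is `[mid - width/2, mid + width/2)`, clipped at
#' chromosome edges with a warning.
#'
#' @param regions region table.
#' @param width normalized width in bp (default 200).
#' @param chrom_lengths named vector of chromosome lengths; required to clip
#'   at the right edge (regions beyond known chromosomes are left unclipped).
#' @export
normalize_width <- function(regions, width = 200L, chrom_lengths = NULL) {
  dt <- as.data.table(regions)
  half <- width %/% 2L
  dt[, `:=`(norm_start = mid - half, norm_end = mid + (width - half))]
  clipped <- dt$norm_start < 0L
  dt[clipped, norm_start := 0L]
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[dt$chrom]
    over <- !is.na(len) & dt$norm_end > len
    dt[over, norm_end := as.integer(len[over])]
    clipped <- clipped | over
  }
  if (any(clipped)) {
    warning(sprintf("%d region(s) clipped at chromosome edges", sum(clipped)),
            call. = FALSE)
  }
  dt[]
}

#' Annotate regions with their nearest gene TSS
#'
#' Distance is signed (`mid - tss`) to the nearest TSS by absolute value
#' (ties broken by gene id), binned in 5-kb increments of |distance|.
#' Regions farther than `max_distance` from every TSS are dropped and
#' counted as unassociated.
#'
#' @param regions region table.
#' @param annotation gene table from [read_annotation()].
#' @param max_distance association horizon in bp (default 1e6).
#' @param bin_width distance bin width in bp (default 5000).
#' @return a list with `annotation` (region_id, gene_id, distance, bin) and
#'   `n_unassociated`.
#' @export
annotate_nearest_gene <- function(regions, annotation, max_distance = 1e6,
                                  bin_width = 5000L) {
  dt <- as.data.table(regions)
  ann <- as.data.table(annotation)
  if (nrow(ann) == 0L) stop("empty annotation", call. = FALSE)
  res <- rbindlist(lapply(seq_len(nrow(dt)), function(i) {
    g <- ann[chrom == dt$chrom[i]]
    if (nrow(g) == 0L) return(NULL)
    d <- dt$mid[i] - g$tss
    o <- order(abs(d), g$gene_id)
    data.table(region_id = dt$region_id[i], gene_id = g$gene_id[o[1]],
               distance = d[o[1]])
  }))
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.table(region_id = character(), gene_id = character(),
                      distance = numeric())
  }
  assoc <- res[abs(distance) <= max_distance]
  assoc[, bin := sprintf("[%d,%d)kb", floor(abs(distance) / bin_width) *
                           (bin_width %/% 1000L),
                         (floor(abs(distance) / bin_width) + 1L) *
                           (bin_width %/% 1000L))]
  list(annotation = assoc[],
       n_unassociated = nrow(dt) - nrow(assoc))
}

#' Categorize regions by genomic context
#'
#' Precedence: promoter (|distance to nearest TSS| `<= promoter_window`) >
#' proximal (`<= proximal_window`) > gene body (midpoint inside a gene span)
#' > distal/intergenic.  Category counts partition the input.
#'
#' @param regions region table.
#' @param annotation gene table.
#' @param promoter_window promoter radius in bp (default 1000).
#' @param proximal_window proximal radius in bp (default 5000).
#' @return a list with `categories` (region_id, category) and `counts`.
#' @export
categorize_regions <- function(regions, annotation, promoter_window = 1000L,
                               proximal_window = 5000L) {
  dt <- as.data.table(regions)
  ann <- as.data.table(annotation)
  near <- annotate_nearest_gene(dt, ann, max_distance = Inf)$annotation
  dt2 <- merge(dt[, .(region_id, chrom, mid)], near, by = "region_id",
               all.x = TRUE)
  gene_gr <- bed_to_granges(ann$chrom, ann$start, ann$end)
  mid_gr <- bed_to_granges(dt2$chrom, dt2$mid, dt2$mid + 1L)
  in_gene <- IRanges::overlapsAny(mid_gr, gene_gr, ignore.strand = TRUE)
  cat <- ifelse(!is.na(dt2$distance) & abs(dt2$distance) <= promoter_window,
                "promoter",
         ifelse(!is.na(dt2$distance) & abs(dt2$distance) <= proximal_window,
                "proximal",
         ifelse(in_gene, "gene_body", "distal")))
  res <- data.table(region_id = dt2$region_id, category = cat)
  counts <- res[, .N, by = category]
  lvls <- c("promoter", "proximal", "gene_body", "distal")
  counts <- merge(data.table(category = lvls), counts, by = "category",
                  all.x = TRUE, sort = FALSE)
  counts[is.na(N), N := 0L]
  list(categories = res[], counts = counts[])
}

#' Intersection (upset-style) counts of regions against peak sets
#'
#' For every subset of the peak tracks, counts the regions overlapping
#' (>= 1 bp) exactly that subset of tracks.  Counts sum to the number of
#' regions.
#'
#' @param regions region table; normalized intervals are used when present.
#' @param peak_sets named list of [GenomicRanges::GRanges] peak sets.
#' @return a `data.table` with one row per observed membership combination:
#'   `combination` (e.g. `"H3K27ac+H3K4me1"`, `"none"`) and `N`.
#' @export
overlap_upset <- function(regions, peak_sets) {
  dt <- as.data.table(regions)
  use_norm <- all(c("norm_start", "norm_end") %in% names(dt))
  gr <- bed_to_granges(dt$chrom,
                       if (use_norm) dt$norm_start else dt$start,
                       if (use_norm) dt$norm_end else dt$end)
  if (length(peak_sets) == 0L) {
    return(data.table(combination = "none", N = nrow(dt)))
  }
  memb <- vapply(peak_sets, function(p) {
    IRanges::overlapsAny(gr, p, ignore.strand = TRUE)
  }, logical(nrow(dt)))
  memb <- matrix(memb, nrow = nrow(dt),
                 dimnames = list(NULL, names(peak_sets)))
  combo <- apply(memb, 1L, function(r) {
    if (!any(r)) "none" else paste(names(peak_sets)[r], collapse = "+")
  })
  out <- data.table(combination = combo)[, .N, by = combination]
  setorder(out, -N)
  out[]
}
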