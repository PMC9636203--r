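# CTSS normalization, pooling, unidirectional tag clustering and per-gene
# expression quantification.
#
# A CtssProfile is a list:
#   $ctss      data.table(chrom, pos, strand, sample_id, score)
#   $units     "count" or "tpm"
#   $lib_sizes named numeric, total tags per sample (from the raw counts)
#   $pooled    (pooled profiles only) data.table(chrom, pos, strand, score)
#              with score = sum of per-sample TPM at that position

#' Assemble a CTSS profile from one or more record tables
#'
#' @param records a `data.table` as returned by [read_ctss()], or a list of
#'   them (one per sample).
#' @return a `CtssProfile` holding raw counts.
#' @export
ctss_profile <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  dt <- rbindlist(records)
  if (nrow(dt) && anyDuplicated(dt, by = c("chrom", "pos", "strand",
                                           "sample_id"))) {
    stop("duplicate (chrom, position, strand, sample) records", call. = FALSE)
  }
  libs <- if (nrow(dt)) dt[, .(n = sum(count)), by = sample_id] else
    data.table(sample_id = character(), n = numeric())
  structure(
    list(ctss = dt[, .(chrom, pos, strand, sample_id, score = count)],
         units = "count",
         lib_sizes = setNames(libs$n, libs$sample_id)),
    class = "CtssProfile"
  )
}

#' @export
print.CtssProfile <- function(x, ...) {
  cat(sprintf("CtssProfile (%s): %d positions, %d sample(s)%s\n", x$units,
              nrow(x$ctss), length(x$lib_sizes),
              if (!is.null(x$pooled)) ", pooled" else ""))
  invisible(x)
}

#' TPM-normalize a CTSS profile
#'
#' Each sample's counts are scaled by `1e6 / library size` so per-sample
#' values sum to one million.
#'
#' @param profile a raw-count `CtssProfile`.
#' @return a TPM `CtssProfile`.
#' @export
tpm_normalize <- function(profile) {
  stopifnot(is(profile, "CtssProfile"))
  if (profile$units == "tpm") return(profile)
  if (any(profile$lib_sizes == 0)) {
    stop("zero library size; cannot TPM-normalize", call. = FALSE)
  }
  dt <- copy(profile$ctss)
  dt[, score := score / profile$lib_sizes[sample_id] * 1e6]
  profile$ctss <- dt
  profile$units <- "tpm"
  profile
}

#' Pool TPM-normalized profiles and pre-filter weak positions
#'
#' The pooled signal at a position is the sum of per-sample TPM.  Pooled
#' positions below `position_floor` TPM are dropped (both from the pooled
#' view and the per-sample records), mirroring default CTSS pre-filtering.
#' Per-sample records are retained for support counting downstream.
#'
#' @param profiles a TPM `CtssProfile` or list of them.
#' @param position_floor minimum pooled TPM for a position to survive
#'   (default 0.1; set 0 to disable).
#' @return a pooled `CtssProfile` with a `$pooled` table.
#' @export
pool_profiles <- function(profiles, position_floor = 0.1) {
  if (is(profiles, "CtssProfile")) profiles <- list(profiles)
  for (p in profiles) {
    stopifnot(is(p, "CtssProfile"))
    if (p$units != "tpm") stop("pool_profiles() requires TPM-normalized input",
                               call. = FALSE)
  }
  ctss <- rbindlist(lapply(profiles, `[[`, "ctss"))
  libs <- do.call(c, lapply(profiles, `[[`, "lib_sizes"))
  if (anyDuplicated(names(libs))) {
    stop("duplicate sample ids across pooled profiles", call. = FALSE)
  }
  pooled <- ctss[, .(score = sum(score)), by = .(chrom, pos, strand)]
  if (position_floor > 0) {
    pooled <- pooled[score >= position_floor]
    ctss <- ctss[pooled, on = c("chrom", "pos", "strand"), nomatch = NULL,
                 .(chrom, pos, strand, sample_id, score = x.score)]
  }
  setorder(pooled, chrom, strand, pos)
  structure(list(ctss = ctss, units = "tpm", lib_sizes = libs,
                 pooled = pooled),
            class = "CtssProfile")
}

#' Cluster same-strand CTSSs into unidirectional tag clusters
#'
#' Slice-reduce clustering: on each (chromosome, strand), maximal runs of
#' CTSS positions with inter-position gap `<= max_gap` form one tag cluster.
#' The summit is the position of maximal pooled TPM (leftmost on ties).
#'
#' @param pooled a pooled `CtssProfile` (see [pool_profiles()]).
#' @param max_gap maximum gap (bp) between consecutive member CTSSs
#'   (default 20, i.e. positions 100 and 120 merge, 100 and 121 do not).
#' @return a `data.table` of tag clusters: `tc_id`, `chrom`, `strand`,
#'   `start`, `end` (half-open), `summit`, `tpm` (pooled sum), `support`
#'   (number of samples with >= 1 tag inside the cluster).
#' @export
slice_unidirectional <- function(pooled, max_gap = 20L) {
  stopifnot(is(pooled, "CtssProfile"), !is.null(pooled$pooled))
  dt <- copy(pooled$pooled)
  if (nrow(dt) == 0L) {
    return(data.table(tc_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), summit = integer(), tpm = numeric(),
                      support = integer()))
  }
  setorder(dt, chrom, strand, pos)
  dt[, grp := cumsum(c(1L, diff(pos) > max_gap)), by = .(chrom, strand)]
  tcs <- dt[, .(start = min(pos), end = max(pos) + 1L,
                summit = pos[which.max(score)], tpm = sum(score)),
            by = .(chrom, strand, grp)]
  tcs[, grp := NULL]
  setorder(tcs, chrom, start, strand)
  tcs[, tc_id := sprintf("TC%05d", .I)]
  tcs[, support := count_support(pooled, chrom, start, end, strand = strand)]
  setcolorder(tcs, c("tc_id", "chrom", "strand", "start", "end", "summit",
                     "tpm", "support"))
  tcs[]
}

#' Number of samples with at least one tag inside each interval
#'
#' @param profile a `CtssProfile` with per-sample records.
#' @param chrom,start,end interval vectors (0-based half-open).
#' @param strand optional strand vector; if omitted, both strands count.
#' @return integer vector of per-sample support counts.
#' @export
count_support <- function(profile, chrom, start, end, strand = NULL) {
  q <- data.table(chrom = chrom, qstart = start, qend = end,
                  idx = seq_along(start))
  tags <- profile$ctss[, .(chrom, strand, pos, sample_id)]
  if (!is.null(strand)) q[, strand := strand]
  out <- integer(nrow(q))
  if (nrow(tags) == 0L || nrow(q) == 0L) return(out)
  by_cols <- if (is.null(strand)) "chrom" else c("chrom", "strand")
  tags[, `:=`(tstart = pos, tend = pos + 1L)]
  setkeyv(tags, c(by_cols, "tstart", "tend"))
  qk <- copy(q)
  setnames(qk, c("qstart", "qend"), c("tstart", "tend"))
  ov <- foverlaps(qk, tags, by.x = c(by_cols, "tstart", "tend"),
                  type = "any", nomatch = NULL)
  if (nrow(ov)) {
    cnt <- ov[, .(n = uniqueN(sample_id)), by = idx]
    out[cnt$idx] <- cnt$n
  }
  out
}

#' Filter tag clusters on sample support and pooled expression
#'
#' Keeps clusters expressed in at least `min_support` samples with pooled
#' TPM strictly greater than `min_pooled_tpm` (a cluster at exactly the
#' threshold is dropped).  Idempotent.
#'
#' @param clusters tag cluster table from [slice_unidirectional()].
#' @param min_support minimum number of supporting samples (default 2).
#' @param min_pooled_tpm strict lower bound on pooled TPM (default 1.0).
#' @export
filter_tcs <- function(clusters, min_support = 2L, min_pooled_tpm = 1.0) {
  dt <- as.data.table(clusters)
  dt[support >= min_support & tpm > min_pooled_tpm]
}

#' Quantify gene expression by summing tag clusters per gene
#'
#' A tag cluster is assigned to a same-strand gene whose span, extended
#' upstream by `assignment_window` bp, contains the cluster summit.  When
#' several genes qualify, the gene with the nearest TSS wins (smallest
#' |summit - TSS|, ties broken by gene id).  Unassigned clusters are
#' reported as intergenic.  Every annotated gene appears in the output
#' (zero TPM when no cluster is assigned).
#'
#' @param clusters tag cluster table (typically after [filter_tcs()]).
#' @param annotation gene table from [read_annotation()].
#' @param profile optional pooled `CtssProfile`; when given, per-sample gene
#'   TPMs are also computed.
#' @param assignment_window upstream extension in bp (default 500).
#' @return a list with `genes` (gene_id, tpm), `per_sample` (gene_id,
#'   sample_id, tpm; only when `profile` given), `assignments`
#'   (tc_id, gene_id) and `intergenic` (tc ids).
#' @export
quantify_genes <- function(clusters, annotation, profile = NULL,
                           assignment_window = 500L) {
  ann <- as.data.table(annotation)
  if (nrow(ann) == 0L) stop("empty annotation", call. = FALSE)
  tcs <- as.data.table(clusters)
  ext <- ann[, .(gene_id, chrom, strand, tss,
                 xstart = ifelse(strand == "+", start - assignment_window,
                                 start),
                 xend = ifelse(strand == "+", end, end + assignment_window))]
  assign <- data.table(tc_id = character(), gene_id = character())
  if (nrow(tcs)) {
    q <- tcs[, .(tc_id, chrom, strand, xstart = summit,
                 xend = summit + 1L, tpm)]
    setkey(ext, chrom, strand, xstart, xend)
    ov <- foverlaps(q, ext, by.x = c("chrom", "strand", "xstart", "xend"),
                    type = "any", nomatch = NULL)
    if (nrow(ov)) {
      ov[, d := abs(i.xstart - tss)]
      setorder(ov, tc_id, d, gene_id)
      assign <- ov[, .SD[1L], by = tc_id][, .(tc_id, gene_id)]
    }
  }
  assigned <- tcs[assign, on = "tc_id"]
  genes <- assigned[, .(tpm = sum(tpm)), by = gene_id]
  genes <- merge(ann[, .(gene_id)], genes, by = "gene_id", all.x = TRUE)
  genes[is.na(tpm), tpm := 0]
  setorder(genes, gene_id)
  per_sample <- NULL
  if (!is.null(profile)) {
    tc_assigned <- tcs[assign, on = "tc_id"]
    tags <- copy(profile$ctss)
    tags[, `:=`(tstart = pos, tend = pos + 1L)]
    setkey(tags, chrom, strand, tstart, tend)
    qk <- tc_assigned[, .(tc_id, gene_id, chrom, strand, tstart = start,
                          tend = end)]
    ov <- foverlaps(qk, tags, by.x = c("chrom", "strand", "tstart", "tend"),
                    type = "any", nomatch = NULL)
    per_sample <- ov[, .(tpm = sum(score)), by = .(gene_id, sample_id)]
    full <- CJ(gene_id = ann$gene_id, sample_id = names(profile$lib_sizes))
    per_sample <- merge(full, per_sample, by = c("gene_id", "sample_id"),
                        all.x = TRUE)
    per_sample[is.na(tpm), tpm := 0]
  }
  list(genes = genes[], per_sample = per_sample,
       assignments = assign[],
       intergenic = setdiff(tcs$tc_id, assign$tc_id))
}
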