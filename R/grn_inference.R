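# TF -> gene interaction scores and network construction.
#
# An edge's interaction score is the mean of four components, each
# rank-scaled to [0, 1] across all candidate (TF, gene) pairs:
#   * TF expression (log1p pooled gene TPM of the TF's gene)
#   * target expression (log1p pooled gene TPM)
#   * distance-weighted binding: sum over enhancers near the target's TSS
#     of p(TF binds enhancer) * w(distance)
#   * genome-wide motif activity of the TF
# Pairs with zero weighted binding are excluded; self-edges are kept and
# flagged.

#' Distance weight of an enhancer relative to a TSS
#'
#' Full weight within `full_radius`, exponential decay with constant
#' `decay` beyond it, and zero past `max_radius`:
#' `w = exp(-(|d| - full_radius) / decay)` for
#' `full_radius < |d| <= max_radius`.
#'
#' @param d signed or absolute distance(s) in bp.
#' @param full_radius radius of full weight (default 5 kb).
#' @param max_radius association horizon (default 100 kb).
#' @param decay decay constant in bp (default 25 kb).
#' @return weights in `[0, 1]`, non-increasing in |d|.
#' @export
distance_weight <- function(d, full_radius = 5000, max_radius = 1e5,
                            decay = 25000) {
  a <- abs(d)
  w <- exp(-(a - full_radius) / decay)
  w[a <= full_radius] <- 1
  w[a > max_radius] <- 0
  w
}

#' Distance-weighted binding of one TF at one gene
#'
#' @param probs binding probabilities of the TF at enhancers near the gene.
#' @param distances enhancer-midpoint-to-TSS distances (bp), aligned with
#'   `probs`.
#' @inheritParams distance_weight
#' @return scalar: `sum(p * w(d))`; 0 when no enhancer is in range.
#' @export
weighted_binding <- function(probs, distances, full_radius = 5000,
                             max_radius = 1e5, decay = 25000) {
  if (length(probs) == 0L) return(0)
  sum(probs * distance_weight(distances, full_radius, max_radius, decay))
}

#' Distance-weighted binding for all (TF, gene) pairs
#'
#' @param binding table with `tf`, `region_id`, `prob`.
#' @param regions region table with `region_id`, `chrom`, `mid`.
#' @param annotation gene table with `gene_id`, `chrom`, `tss`.
#' @inheritParams distance_weight
#' @return a `data.table` `tf`, `gene`, `wb` (pairs with `wb > 0` only).
#' @export
binding_by_gene <- function(binding, regions, annotation, full_radius = 5000,
                            max_radius = 1e5, decay = 25000) {
  bind <- as.data.table(binding)
  reg <- as.data.table(regions)[, .(region_id, chrom, mid)]
  ann <- as.data.table(annotation)[, .(gene_id, chrom, tss)]
  # enhancer-gene pairs within the horizon
  reg[, `:=`(xstart = mid - as.integer(max_radius),
             xend = mid + as.integer(max_radius))]
  ann[, `:=`(xstart = tss, xend = tss + 1L)]
  setkey(ann, chrom, xstart, xend)
  pairs <- foverlaps(reg, ann, by.x = c("chrom", "xstart", "xend"),
                     type = "any", nomatch = NULL)
  if (nrow(pairs) == 0L) {
    return(data.table(tf = character(), gene = character(), wb = numeric()))
  }
  pairs <- pairs[, .(region_id, gene_id, d = mid - tss)]
  pairs[, w := distance_weight(d, full_radius, max_radius, decay)]
  pairs <- pairs[w > 0]
  merged <- bind[pairs, on = "region_id", allow.cartesian = TRUE,
                 nomatch = NULL]
  out <- merged[, .(wb = sum(prob * w)), by = .(tf, gene = gene_id)]
  out[wb > 0]
}

#' Genome-wide motif activity per TF
#'
#' Ridge regression of log1p enhancer intensities on the motif z-score
#' matrix; a TF's activity is the coefficient of its motif with the largest
#' absolute coefficient.
#'
#' @param intensity enhancer intensity vector (TPM).
#' @param zscores motif z-score matrix (enhancers x motifs) with motif ids
#'   as column names.
#' @param motif2tf mapping table (`motif`, `tf`).
#' @param penalty ridge penalty (default 1).
#' @return a `data.table` `tf`, `activity`.
#' @export
motif_activity <- function(intensity, zscores, motif2tf, penalty = 1) {
  X <- as.matrix(zscores)
  if (nrow(X) < 2L) {
    stop("motif activity is underdetermined with fewer than 2 enhancers",
         call. = FALSE)
  }
  stopifnot(length(intensity) == nrow(X))
  y <- log1p(intensity)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  coef <- drop(solve(crossprod(Xc) + penalty * diag(ncol(Xc)),
                     crossprod(Xc, yc)))
  names(coef) <- colnames(X)
  map <- as.data.table(motif2tf)[motif %in% colnames(X)]
  map[, activity := coef[motif]]
  out <- map[, .(activity = activity[which.max(abs(activity))]), by = tf]
  setorder(out, tf)
  out[]
}

#' TF -> gene interaction scores
#'
#' @param expression gene expression table (`gene_id`, `tpm`) from
#'   [quantify_genes()]; must contain the TF genes.
#' @param binding weighted-binding table from [binding_by_gene()].
#' @param activity motif activity table from [motif_activity()].
#' @param tf2gene optional named character vector mapping TF name to its
#'   gene id (default: TF name is the gene id).
#' @return a `data.table` of edges: `tf`, `gene`, `interaction_score`, the
#'   four scaled components and a `self_edge` flag.
#' @export
interaction_scores <- function(expression, binding, activity,
                               tf2gene = NULL) {
  expr <- as.data.table(expression)
  bind <- as.data.table(binding)[wb > 0]
  act <- as.data.table(activity)
  tfs <- unique(bind$tf)
  tf_gene <- if (is.null(tf2gene)) setNames(tfs, tfs) else tf2gene
  expr_of <- setNames(expr$tpm, expr$gene_id)
  tf_expr <- expr_of[tf_gene[tfs]]
  bad <- tfs[is.na(tf_expr)]
  if (length(bad)) {
    # a TF absent from the quantified expression table cannot regulate in
    # this framework; zero TPM is allowed (component rank-scales to 0)
    bind <- bind[!tf %in% bad]
  }
  if (nrow(bind) == 0L) {
    return(data.table(tf = character(), gene = character(),
                      interaction_score = numeric(), c_tf_expr = numeric(),
                      c_target_expr = numeric(), c_binding = numeric(),
                      c_activity = numeric(), self_edge = logical()))
  }
  edges <- copy(bind)
  edges[, tf_expr_raw := log1p(expr_of[tf_gene[tf]])]
  tgt <- expr_of[edges$gene]
  tgt[is.na(tgt)] <- 0
  edges[, target_expr_raw := log1p(tgt)]
  act_of <- setNames(act$activity, act$tf)
  edges[, activity_raw := act_of[tf]]
  if (any(is.na(edges$activity_raw))) {
    stop("missing motif activity for TF(s): ",
         paste(unique(edges$tf[is.na(edges$activity_raw)]), collapse = ", "),
         call. = FALSE)
  }
  edges[, `:=`(c_tf_expr = rank_scale(tf_expr_raw),
               c_target_expr = rank_scale(target_expr_raw),
               c_binding = rank_scale(wb),
               c_activity = rank_scale(activity_raw))]
  edges[, interaction_score :=
          (c_tf_expr + c_target_expr + c_binding + c_activity) / 4]
  edges[, self_edge := gene == tf_gene[tf]]
  out <- edges[, .(tf, gene, interaction_score, c_tf_expr, c_target_expr,
                   c_binding, c_activity, self_edge)]
  setorder(out, -interaction_score, tf, gene)
  out[]
}

#' Keep the strongest edges of a network
#'
#' @param edges edge table with `tf`, `gene`, `interaction_score`.
#' @param top_n number of edges to retain (default 500000).  Ties at the
#'   cutoff are broken by (tf, gene) lexical order; ordering is stable
#'   across runs.
#' @export
build_grn <- function(edges, top_n = 500000L) {
  dt <- as.data.table(edges)
  setorder(dt, -interaction_score, tf, gene)
  head(dt, top_n)
}
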