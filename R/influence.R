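# Differential-network influence scoring between two cell states, and
# time-course clustering of influence profiles.
#
# The influence of a TF for a source -> target transition sums, over genes
# reachable in the differential network within `max_depth` steps, a
# depth-discounted best-path score times the gene's positive log2 fold
# change.  Only positive fold changes contribute: the framework models
# activation.  Final scores are scaled so the best TF has influence 1.

#' Differential GRN between a source and a target network
#'
#' Per (TF, gene) pair, `diff = max(0, target - source)` with missing edges
#' scored 0; zero-diff edges are dropped and the strongest `top_n` edges
#' kept (ties broken lexically).
#'
#' @param source_grn,target_grn edge tables with `tf`, `gene`,
#'   `interaction_score`.
#' @param top_n number of edges kept (default 500000).
#' @return a `data.table` `tf`, `gene`, `diff_score`.
#' @export
differential_grn <- function(source_grn, target_grn, top_n = 500000L) {
  s <- as.data.table(source_grn)[, .(tf, gene, s_score = interaction_score)]
  t <- as.data.table(target_grn)[, .(tf, gene, t_score = interaction_score)]
  m <- merge(s, t, by = c("tf", "gene"), all = TRUE)
  m[is.na(s_score), s_score := 0]
  m[is.na(t_score), t_score := 0]
  m[, diff_score := pmax(0, t_score - s_score)]
  m <- m[diff_score > 0, .(tf, gene, diff_score)]
  setorder(m, -diff_score, tf, gene)
  head(m, top_n)
}

#' Influence scores of TFs over a differential network
#'
#' For each TF, genes are reached by following differential edges to depth
#' `<= max_depth` (an intermediate node must itself be a TF in the edge
#' list).  A gene g reached along a path of length l with edge scores
#' `s_1..s_l` contributes
#' `max over paths of prod(s_i) / 2^(l-1) * max(0, log2FC_g)`.
#' The TF's own gene is excluded from its targets.  Raw sums are scaled by
#' the maximum across TFs, so the top TF scores 1 (all scores are 0 when no
#' TF reaches an upregulated gene).
#'
#' @param diff_grn differential edge table from [differential_grn()].
#' @param de_table table with `gene`, `log2fc` (genes absent are treated as
#'   log2FC 0; an empty table yields all-zero scores with a warning).
#' @param max_depth maximum path length (default 2).
#' @return an `InfluenceResult`: `data.table` with `tf`, `influence`,
#'   `raw`, `out_degree` (distinct reachable targets within the horizon).
#' @export
influence_scores <- function(diff_grn, de_table, max_depth = 2L) {
  edges <- as.data.table(diff_grn)
  if (nrow(edges) == 0L) stop("empty differential network", call. = FALSE)
  de <- as.data.table(de_table)
  if (nrow(de) == 0L) {
    warning("empty differential-expression table; all influence scores 0",
            call. = FALSE)
  }
  lfc <- setNames(rep(0, 0), character(0))
  if (nrow(de)) lfc <- setNames(de$log2fc, de$gene)
  lfc_of <- function(g) {
    v <- lfc[g]
    v[is.na(v)] <- 0
    pmax(0, v)
  }
  tfs <- sort(unique(edges$tf))
  res <- rbindlist(lapply(tfs, function(f) {
    # frontier holds, per gene, the best depth-discounted score among paths
    # of the current length; extending by one edge halves the discount again
    frontier <- edges[tf == f, .(gene, path = diff_score)]
    best <- copy(frontier)
    if (max_depth >= 2L) {
      for (depth in 2:max_depth) {
        nxt <- merge(frontier[, .(tf = gene, path)], edges, by = "tf",
                     allow.cartesian = TRUE)
        if (nrow(nxt) == 0L) break
        frontier <- nxt[, .(path = max(path * diff_score / 2)), by = gene]
        best <- rbind(best, frontier)[, .(path = max(path)), by = gene]
      }
    }
    best <- best[gene != f]
    data.table(tf = f,
               raw = sum(best$path * lfc_of(best$gene)),
               out_degree = nrow(best))
  }))
  mx <- max(res$raw)
  res[, influence := if (mx > 0) raw / mx else 0]
  setorder(res, -influence, tf)
  setcolorder(res, c("tf", "influence", "raw", "out_degree"))
  structure(res[], class = c("InfluenceResult", class(res)))
}

#' Ranked TF table for influence scatterplots
#'
#' Per TF: influence, the TF's own log2 fold change, and out-degree.
#' Zero-influence TFs are unranked (dropped).  This is the data surface of
#' the influence-vs-log2FC scatterplots.
#'
#' @param result an `InfluenceResult`.
#' @param de_table table with `gene`, `log2fc`.
#' @param tf2gene optional named map TF -> gene id (default identity).
#' @return a `data.table`: `rank_`, `tf`, `influence`, `log2fc`,
#'   `out_degree`, sorted by influence descending.
#' @export
rank_and_plot_data <- function(result, de_table, tf2gene = NULL) {
  dt <- as.data.table(result)[influence > 0]
  de <- as.data.table(de_table)
  lfc <- setNames(de$log2fc, de$gene)
  gene_of <- if (is.null(tf2gene)) setNames(dt$tf, dt$tf) else tf2gene
  dt[, log2fc := lfc[gene_of[tf]]]
  dt[is.na(log2fc), log2fc := 0]
  setorder(dt, -influence, tf)
  dt[, rank_ := .I]
  dt[, .(rank_, tf, influence, log2fc, out_degree)]
}

#' Simple log2 fold change fallback
#'
#' `log2((target + pc) / (source + pc))` per gene on pooled TPM; a stand-in
#' when no external differential-expression table is supplied.
#'
#' @param expr_source,expr_target named numeric vectors (gene -> TPM) or
#'   tables with `gene_id`, `tpm`.
#' @param pseudocount pseudocount (default 1).
#' @return a `data.table` `gene`, `log2fc` over the union of genes.
#' @export
simple_log2fc <- function(expr_source, expr_target, pseudocount = 1) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$tpm, x$gene_id) else x
  }
  s <- as_vec(expr_source)
  t <- as_vec(expr_target)
  genes <- sort(union(names(s), names(t)))
  sv <- s[genes]
  tv <- t[genes]
  sv[is.na(sv)] <- 0
  tv[is.na(tv)] <- 0
  data.table(gene = genes,
             log2fc = log2((tv + pseudocount) / (sv + pseudocount)))
}

#' K-means clustering of TF influence time courses
#'
#' Runs seeded k-means (Euclidean, on raw influence values, 25 restarts)
#' for each k and picks the elbow as the k with the largest second
#' difference of the within-cluster sum of squares curve.
#'
#' @param influence_matrix numeric matrix, TFs x timepoints, with TF row
#'   names.
#' @param k_range candidate k values (default 1:8).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 25).
#' @return a `TemporalClusters` list: `k` (elbow choice), `assignment`
#'   (named vector), `centers` (cluster x timepoint mean-influence matrix),
#'   `elbow` (`data.table` k, wss), `fits` (kmeans objects per k).
#' @export
timecourse_cluster <- function(influence_matrix, k_range = 1:8, seed = 1L,
                               nstart = 25L) {
  m <- as.matrix(influence_matrix)
  k_range <- sort(unique(as.integer(k_range)))
  n_distinct <- nrow(unique(m))
  k_range <- k_range[k_range >= 1L & k_range <= n_distinct]
  if (length(k_range) == 0L) stop("no feasible k in k_range", call. = FALSE)
  fits <- list()
  wss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[as.character(k)]] <- with_seed(seed, {
      kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
    })
    wss[i] <- fits[[as.character(k)]]$tot.withinss
  }
  elbow_k <- if (length(k_range) >= 3L) {
    d2 <- diff(diff(wss))                  # wss[i-1] - 2 wss[i] + wss[i+1]
    k_range[which.max(d2) + 1L]
  } else {
    k_range[which.min(wss)]
  }
  fit <- fits[[as.character(elbow_k)]]
  assignment <- setNames(fit$cluster, rownames(m))
  structure(
    list(k = elbow_k, assignment = assignment, centers = fit$centers,
         elbow = data.table(k = k_range, wss = wss), fits = fits),
    class = "TemporalClusters"
  )
}

#' @export
print.TemporalClusters <- function(x, ...) {
  cat(sprintf("TemporalClusters: elbow k = %d over %d TFs x %d timepoints\n",
              x$k, length(x$assignment), ncol(x$centers)))
  invisible(x)
}
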