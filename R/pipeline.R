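# High-level orchestration: CTSS records -> tag clusters / expression,
# pooled signal -> enhancer regions, and one cell state -> a GRN.

#' Process CTSS records into pooled signal, tag clusters and expression
#'
#' Runs TPM normalization, pooling with position pre-filtering,
#' unidirectional slice clustering, support/expression filtering and
#' (optionally) per-gene quantification.
#'
#' @param records_list list of CTSS record tables (one per sample), as from
#'   [read_ctss()] or [make_ctss()].
#' @param annotation optional gene table; when given, gene expression is
#'   quantified from the filtered tag clusters.
#' @param position_floor pooled-TPM floor for positions (default 0.1).
#' @param max_gap clustering gap (default 20).
#' @param min_support,min_pooled_tpm tag cluster filters (defaults 2 and 1).
#' @param assignment_window upstream extension for TC-to-gene assignment.
#' @return a list: `pooled` (a pooled `CtssProfile`), `tcs` (filtered tag
#'   clusters), `tcs_all` (unfiltered), `expression` (see
#'   [quantify_genes()]; `NULL` without annotation).
#' @export
process_ctss <- function(records_list, annotation = NULL,
                         position_floor = 0.1, max_gap = 20L,
                         min_support = 2L, min_pooled_tpm = 1.0,
                         assignment_window = 500L) {
  profiles <- lapply(records_list, function(r) tpm_normalize(ctss_profile(r)))
  pooled <- pool_profiles(profiles, position_floor = position_floor)
  tcs_all <- slice_unidirectional(pooled, max_gap = max_gap)
  tcs <- filter_tcs(tcs_all, min_support = min_support,
                    min_pooled_tpm = min_pooled_tpm)
  expression <- NULL
  if (!is.null(annotation)) {
    expression <- quantify_genes(tcs, annotation, profile = pooled,
                                 assignment_window = assignment_window)
  }
  list(pooled = pooled, tcs = tcs, tcs_all = tcs_all,
       expression = expression)
}

#' Call, filter and width-normalize enhancer regions
#'
#' @param pooled a pooled `CtssProfile`.
#' @param window,balance_threshold,max_gap see [call_bidirectional()].
#' @param min_support per-sample support filter (default 2).
#' @param width normalized width (default 200).
#' @param chrom_lengths named lengths for edge clipping.
#' @return the filtered, normalized region table.
#' @export
find_enhancers <- function(pooled, window = 201L, balance_threshold = 0.95,
                           max_gap = 20L, min_support = 2L, width = 200L,
                           chrom_lengths = NULL) {
  regions <- call_bidirectional(pooled, window = window,
                                balance_threshold = balance_threshold,
                                max_gap = max_gap)
  regions <- filter_bidirectional(regions, pooled,
                                  min_support = min_support)
  normalize_width(regions, width = width, chrom_lengths = chrom_lengths)
}

#' Build the GRN of one cell state
#'
#' Computes motif z-scores and the feature table at the state's enhancers,
#' predicts binding with the supplied model for every TF, aggregates
#' distance-weighted binding per gene, estimates genome-wide motif
#' activity, and combines everything into interaction-scored edges.
#'
#' @param regions normalized region table of the state.
#' @param expression gene expression table (`gene_id`, `tpm`).
#' @param genome a `GenomeIndex`.
#' @param motifs,motif2tf motif collection and TF mapping.
#' @param coverage a `CoverageTrack` or `NULL`.
#' @param model a `BindingModel` (per-TF models may be supplied as a named
#'   list; TFs without a model fall back to the `"general"` entry).
#' @param tfs TFs to include (default: all mapped TFs).
#' @param quantile_ref optional `QuantileReference` for the intensity
#'   feature.
#' @param n_background,seed motif z-score null parameters.
#' @param top_n edge count retained (default 500000).
#' @param full_radius,max_radius,decay distance weighting parameters.
#' @return edge table from [build_grn()].
#' @export
network_from_state <- function(regions, expression, genome, motifs,
                               motif2tf, coverage, model, tfs = NULL,
                               quantile_ref = NULL, n_background = 1000L,
                               seed = 1L, top_n = 500000L,
                               full_radius = 5000, max_radius = 1e5,
                               decay = 25000, annotation) {
  dt <- as.data.table(regions)
  map <- as.data.table(motif2tf)
  tfs <- tfs %||% sort(unique(map$tf))
  seqs <- vapply(seq_len(nrow(dt)), function(i) {
    get_sequence(genome, dt$chrom[i], dt$norm_start[i], dt$norm_end[i])
  }, character(1))
  zmat <- motif_zscore_matrix(seqs, motifs, n_background = n_background,
                              seed = seed)
  S <- rbindlist(lapply(tfs, function(f) {
    mot <- intersect(map[tf == f]$motif, colnames(zmat))
    if (length(mot) == 0L) stop(sprintf("no motifs mapped for TF %s", f),
                                call. = FALSE)
    data.table(tf = f, region_id = dt$region_id,
               S = apply(zmat[, mot, drop = FALSE], 1L, max))
  }))
  e_cage <- normalize_cage_feature(dt$tpm, quantile_ref)
  e_chip <- if (is.null(coverage)) {
    warning("no coverage track; E_ChIP imputed as 0", call. = FALSE)
    numeric(nrow(dt))
  } else {
    log1p(mean_coverage(coverage, dt$chrom, dt$norm_start, dt$norm_end))
  }
  feat <- data.table(region_id = dt$region_id, E_CAGE = e_cage,
                     E_ChIP = e_chip)
  features <- S[feat, on = "region_id"]
  model_for <- function(f) {
    if (is(model, "BindingModel")) return(model)
    model[[f]] %||% model[["general"]] %||%
      stop(sprintf("no model for TF %s and no general model", f),
           call. = FALSE)
  }
  binding <- rbindlist(lapply(tfs, function(f) {
    rows <- features[tf == f]
    data.table(tf = f, region_id = rows$region_id,
               prob = predict_binding(model_for(f), rows))
  }))
  wb <- binding_by_gene(binding, dt, annotation, full_radius = full_radius,
                        max_radius = max_radius, decay = decay)
  act <- motif_activity(dt$tpm, zmat, map)
  edges <- interaction_scores(expression, wb, act)
  build_grn(edges, top_n = top_n)
}
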