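# Logistic TF-binding models at enhancers.
#
# The binding probability of TF f at enhancer l follows
#   log(p / (1 - p)) = b1 * S + b2 * E_CAGE + b3 * E_ChIP + intercept
# where S is the TF's best motif z-score in the enhancer, E_CAGE the
# log-transformed, quantile-normalized bidirectional TPM, and E_ChIP the
# log1p of the averaged curated ChIP coverage over the normalized 200-bp
# region.  Fits are L2-regularized (penalty 1.0 on the summed
# log-likelihood, negligible shrinkage at training sizes) on standardized
# features; coefficients are reported on the standardized scale.

FEATURE_NAMES <- c("S", "E_CAGE", "E_ChIP")

# ---------------------------------------------------------------------------
# Quantile normalization of the CAGE intensity feature

#' Build a quantile reference from training intensity vectors
#'
#' Values are log1p-transformed; when all vectors share a length the
#' reference is the classic column-wise mean of sorted values, otherwise a
#' dense quantile grid is averaged.
#'
#' @param x_list list of numeric TPM vectors (one per training cell type).
#' @param n_grid grid size for the unequal-length fallback.
#' @return an object of class `QuantileReference`.
#' @export
quantile_reference <- function(x_list, n_grid = 1000L) {
  if (is.numeric(x_list)) x_list <- list(x_list)
  lx <- lapply(x_list, log1p)
  lens <- lengths(lx)
  if (length(unique(lens)) == 1L && lens[1] > 1L) {
    vals <- rowMeans(vapply(lx, sort, numeric(lens[1])))
    probs <- seq(0, 1, length.out = lens[1])
  } else {
    probs <- seq(0, 1, length.out = n_grid)
    vals <- rowMeans(vapply(lx, quantile, numeric(n_grid), probs = probs,
                            names = FALSE, type = 7))
  }
  structure(list(probs = probs, values = vals), class = "QuantileReference")
}

#' Log-transform and quantile-normalize enhancer TPMs
#'
#' Maps `log1p(tpm)` onto the reference distribution by rank: a value of
#' rank r (average ranks for ties) among n maps to the reference quantile at
#' `(r - 1) / (n - 1)`.  Monotone, so within-sample rank order is preserved.
#'
#' @param tpm numeric vector of bidirectional TPMs.
#' @param reference a `QuantileReference`; defaults to the vector's own
#'   distribution (pure log transform up to ties).
#' @return numeric vector of normalized intensities (`E_CAGE`).
#' @export
normalize_cage_feature <- function(tpm, reference = NULL) {
  reference <- reference %||% quantile_reference(list(tpm))
  stopifnot(is(reference, "QuantileReference"))
  n <- length(tpm)
  if (n == 0L) return(numeric(0))
  r <- data.table::frank(tpm, ties.method = "average")
  p <- if (n == 1L) 0.5 else (r - 1) / (n - 1)
  approx(reference$probs, reference$values, xout = p, rule = 2)$y
}

# ---------------------------------------------------------------------------
# Features and labels

#' Assemble the per-(TF, enhancer) feature table
#'
#' @param regions region table with normalized intervals (see
#'   [normalize_width()]).
#' @param genome a `GenomeIndex`.
#' @param motifs,motif2tf motif collection and mapping.
#' @param coverage a `CoverageTrack` (averaged curated ChIP coverage), or
#'   `NULL` to impute `E_ChIP = 0` with a warning.
#' @param tfs TFs to score.
#' @param quantile_ref a `QuantileReference` for the intensity feature
#'   (default: built from these regions).
#' @param n_background,seed passed to [motif_zscore()].
#' @return a `data.table` with `tf`, `region_id`, `chrom`, `S`, `E_CAGE`,
#'   `E_ChIP`.
#' @export
enhancer_features <- function(regions, genome, motifs, motif2tf, coverage,
                              tfs = NULL, quantile_ref = NULL,
                              n_background = 1000L, seed = 1L) {
  dt <- as.data.table(regions)
  stopifnot(all(c("norm_start", "norm_end") %in% names(dt)))
  seqs <- vapply(seq_len(nrow(dt)), function(i) {
    get_sequence(genome, dt$chrom[i], dt$norm_start[i], dt$norm_end[i])
  }, character(1))
  S <- motif_zscore(seqs, motifs, motif2tf, tfs = tfs,
                    n_background = n_background, seed = seed)
  e_cage <- normalize_cage_feature(dt$tpm, quantile_ref)
  if (is.null(coverage)) {
    warning("no coverage track; E_ChIP imputed as 0", call. = FALSE)
    e_chip <- numeric(nrow(dt))
  } else {
    e_chip <- log1p(mean_coverage(coverage, dt$chrom, dt$norm_start,
                                  dt$norm_end))
  }
  feat <- data.table(seq_index = seq_len(nrow(dt)), region_id = dt$region_id,
                     chrom = dt$chrom, E_CAGE = e_cage, E_ChIP = e_chip)
  out <- S[feat, on = "seq_index"]
  out[, seq_index := NULL]
  setcolorder(out, c("tf", "region_id", "chrom", "S", "E_CAGE", "E_ChIP"))
  out[]
}

#' Label enhancers by ChIP peak overlap
#'
#' Label 1 iff the normalized 200-bp region overlaps (>= 1 bp, half-open
#' semantics) any peak of that TF.
#'
#' @param regions region table with normalized intervals.
#' @param chip_peaks named list of peak `GRanges`, one entry per TF.
#' @param tfs TFs to label (default: all entries of `chip_peaks`).  A
#'   requested TF without a peak set is an error; route such TFs to the
#'   general model instead.
#' @return a `data.table` with `tf`, `region_id`, `label`.
#' @export
label_enhancers <- function(regions, chip_peaks, tfs = NULL) {
  dt <- as.data.table(regions)
  tfs <- tfs %||% names(chip_peaks)
  missing_tf <- setdiff(tfs, names(chip_peaks))
  if (length(missing_tf)) {
    stop(sprintf("no ChIP peaks for TF(s): %s (use the general model)",
                 paste(missing_tf, collapse = ", ")), call. = FALSE)
  }
  gr <- bed_to_granges(dt$chrom, dt$norm_start, dt$norm_end)
  rbindlist(lapply(tfs, function(f) {
    data.table(tf = f, region_id = dt$region_id,
               label = as.integer(IRanges::overlapsAny(gr, chip_peaks[[f]],
                                                       ignore.strand = TRUE)))
  }))
}

# ---------------------------------------------------------------------------
# Ridge logistic regression (IRLS with an L2 penalty on the slopes)

.fit_logistic_ridge <- function(X, y, lambda = 1, max_iter = 100L,
                                tol = 1e-10) {
  stop_if_not_finite(X, "features")
  if (length(unique(y)) < 2L) {
    stop("labels are single-class; cannot fit a binding model",
         call. = FALSE)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  n <- nrow(Xs)
  Xd <- cbind(`(Intercept)` = 1, Xs)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)))    # intercept unpenalized
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    beta_new <- solve(XtW %*% Xd + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  list(intercept = beta[1], beta = setNames(beta[-1], colnames(X)),
       center = setNames(ctr, colnames(X)), scale = setNames(scl, colnames(X)),
       lambda = lambda)
}

#' Train a per-TF binding model
#'
#' @param features feature table from [enhancer_features()] (rows for one
#'   TF, or any table with the selected feature columns).
#' @param labels 0/1 vector aligned with `features` rows.
#' @param feature_subset which of `S`, `E_CAGE`, `E_ChIP` (plus optional
#'   extra columns such as `H3K27ac`) to use (default all three).
#' @param tf TF name recorded on the model (default taken from the table).
#' @param lambda L2 penalty (default 1).
#' @return an object of class `BindingModel` with standardized-scale
#'   coefficients `beta`, `intercept` and the feature scaling state.
#' @export
train_tf_model <- function(features, labels,
                           feature_subset = FEATURE_NAMES, tf = NULL,
                           lambda = 1) {
  dt <- as.data.table(features)
  missing_col <- setdiff(feature_subset, names(dt))
  if (length(missing_col)) {
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_col, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(dt[, feature_subset, with = FALSE])
  fit <- .fit_logistic_ridge(X, as.numeric(labels), lambda = lambda)
  structure(c(list(tf = tf %||% (if ("tf" %in% names(dt) &&
                                     uniqueN(dt$tf) == 1L) dt$tf[1]
                                 else "general"),
                   features = feature_subset), fit),
            class = "BindingModel")
}

#' Train the general (pooled) binding model
#'
#' One model fit on pooled (TF, enhancer) rows across all trained TFs; used
#' whenever a TF lacks its own model.
#'
#' @inheritParams train_tf_model
#' @export
train_general_model <- function(features, labels,
                                feature_subset = FEATURE_NAMES, lambda = 1) {
  train_tf_model(features, labels, feature_subset = feature_subset,
                 tf = "general", lambda = lambda)
}

#' @export
print.BindingModel <- function(x, ...) {
  cat(sprintf("BindingModel [%s]: logit(p) = %.4g + %s\n", x$tf, x$intercept,
              paste(sprintf("%.4g*%s", x$beta, names(x$beta)),
                    collapse = " + ")))
  invisible(x)
}

#' Predict binding probabilities
#'
#' @param model a `BindingModel`.
#' @param features table (or matrix) with the model's feature columns, on
#'   the raw scale; the model applies its stored standardization.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_binding <- function(model, features) {
  stopifnot(is(model, "BindingModel"))
  dt <- as.data.table(features)
  X <- as.matrix(dt[, model$features, with = FALSE])
  Xs <- scale(X, center = model$center[model$features],
              scale = model$scale[model$features])
  plogis(drop(Xs %*% model$beta[model$features]) + model$intercept)
}

#' Serialize / restore a binding model as JSON
#' @param model a `BindingModel`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(is(model, "BindingModel"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$features <- as.character(x$features)
  for (f in c("beta", "center", "scale")) {
    x[[f]] <- setNames(as.numeric(unlist(x[[f]])), x$features)
  }
  structure(x, class = "BindingModel")
}

# ---------------------------------------------------------------------------
# Precision-recall AUC and cross-validation

#' Area under the precision-recall curve
#'
#' Average precision with tied scores handled as one group, so a constant
#' predictor scores exactly the positive prevalence and a perfect separator
#' scores 1.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels)
  if (P == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- cumsum(rle(s)$lengths)        # last index of each tie group
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Cross-validated PR AUC of binding models
#'
#' Two schemes mirror the training design: `"chromosome"` fits one model
#' per TF and evaluates on held-out chromosomes; `"cell_type"` fits a
#' pooled (general) model on training cell types and evaluates per TF on
#' the held-out cell type.  The random baseline per fold is the positive
#' prevalence of the evaluation set.  Folds whose evaluation set lacks a
#' class, or whose training set is single-class, are skipped.
#'
#' @param features feature table with `tf`, `label`, the feature columns
#'   and a `chrom` (scheme `"chromosome"`) or `cell_type` (scheme
#'   `"cell_type"`) column.
#' @param scheme `"chromosome"` or `"cell_type"`.
#' @param feature_subset feature columns for the fitted models.
#' @param lambda L2 penalty.
#' @return a `data.table`: `tf`, `fold`, `n`, `n_pos`, `baseline`,
#'   `pr_auc`.
#' @export
crossval_pr_auc <- function(features, scheme = c("chromosome", "cell_type"),
                            feature_subset = FEATURE_NAMES, lambda = 1) {
  scheme <- match.arg(scheme)
  dt <- as.data.table(features)
  fold_col <- if (scheme == "chromosome") "chrom" else "cell_type"
  stopifnot(all(c("tf", "label", fold_col, feature_subset) %in% names(dt)))
  folds <- sort(unique(dt[[fold_col]]))
  res <- list()
  for (fd in folds) {
    train <- dt[dt[[fold_col]] != fd]
    test <- dt[dt[[fold_col]] == fd]
    if (scheme == "chromosome") {
      for (f in sort(unique(dt$tf))) {
        tr <- train[tf == f]
        te <- test[tf == f]
        if (uniqueN(tr$label) < 2L || uniqueN(te$label) < 2L) next
        m <- train_tf_model(tr, tr$label, feature_subset, tf = f,
                            lambda = lambda)
        res[[length(res) + 1L]] <- data.table(
          tf = f, fold = as.character(fd), n = nrow(te),
          n_pos = sum(te$label), baseline = mean(te$label),
          pr_auc = pr_auc(predict_binding(m, te), te$label))
      }
    } else {
      if (uniqueN(train$label) < 2L) next
      m <- train_general_model(train, train$label, feature_subset,
                               lambda = lambda)
      for (f in sort(unique(test$tf))) {
        te <- test[tf == f]
        if (uniqueN(te$label) < 2L) next
        res[[length(res) + 1L]] <- data.table(
          tf = f, fold = as.character(fd), n = nrow(te),
          n_pos = sum(te$label), baseline = mean(te$label),
          pr_auc = pr_auc(predict_binding(m, te), te$label))
      }
    }
  }
  if (length(res) == 0L) {
    return(data.table(tf = character(), fold = character(), n = integer(),
                      n_pos = integer(), baseline = numeric(),
                      pr_auc = numeric()))
  }
  rbindlist(res)
}

#' Paired Wilcoxon signed-rank test of PR AUC against the random baseline
#'
#' @param cv_table output of [crossval_pr_auc()].
#' @return the `htest` object of a two-sided paired test on per-(TF, fold)
#'   PR AUC vs prevalence baseline.
#' @export
prauc_wilcoxon <- function(cv_table) {
  dt <- as.data.table(cv_table)
  wilcox.test(dt$pr_auc, dt$baseline, paired = TRUE, exact = FALSE)
}
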