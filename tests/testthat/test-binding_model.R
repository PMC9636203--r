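# Motif z-scores, quantile normalization, labels, logistic fits, PR AUC
# and cross-validation.

toy_motifs <- function() {
  consensus <- "TGACGTCATTGA"                     # 12-bp planted motif
  pfm <- matrix(2, 4L, nchar(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(consensus, "")[[1]]
  for (j in seq_along(b)) pfm[b[j], j] <- 90
  list(consensus = consensus,
       motifs = list(M1 = list(id = "M1", name = "TFA", pfm = pfm)),
       map = data.table(motif = "M1", tf = "TFA"))
}

random_dna <- function(n, len, seed) {
  cagegrn:::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

test_that("motif z-scores separate planted consensus from background", {
  tm <- toy_motifs()
  seqs <- random_dna(40, 200, seed = 21)
  planted <- seqs
  substr(planted, 80, 79 + nchar(tm$consensus)) <- tm$consensus
  z_pl <- motif_zscore(planted, tm$motifs, tm$map, n_background = 300,
                       seed = 2)
  expect_true(all(z_pl$S > 3))
  z_bg <- motif_zscore(seqs, tm$motifs, tm$map, n_background = 300, seed = 2)
  expect_true(mean(abs(z_bg$S) < 3) >= 0.99)
  # errors: unmapped TF; motif wider than region
  expect_error(motif_zscore(seqs, tm$motifs, tm$map, tfs = "TFZ"),
               "no motifs mapped")
  expect_error(motif_zscore(substr(seqs, 1, 8), tm$motifs, tm$map),
               "wider")
})

test_that("quantile normalization maps ranks onto the reference", {
  ref <- quantile_reference(list(c(1, 2, 3), c(4, 5, 6)))
  out1 <- normalize_cage_feature(c(1, 2, 3), ref)
  out2 <- normalize_cage_feature(c(4, 5, 6), ref)
  want <- rowMeans(cbind(sort(log1p(c(1, 2, 3))), sort(log1p(c(4, 5, 6)))))
  expect_equal(out1, want)
  expect_equal(out2, want)
  # identical inputs -> identical outputs; monotone rank preservation
  x <- c(9, 1, 5, 5, 22)
  expect_equal(normalize_cage_feature(x, ref), normalize_cage_feature(x, ref))
  expect_equal(order(normalize_cage_feature(x, ref)[c(2, 3, 1, 5)]),
               order(x[c(2, 3, 1, 5)]))
})

test_that("label_enhancers uses >= 1 bp overlap with half-open intervals", {
  reg <- data.table(region_id = "r1", chrom = "chr1", norm_start = 900L,
                    norm_end = 1100L)
  peak_in <- list(TFA = cagegrn:::bed_to_granges("chr1", 1099L, 1200L))
  peak_out <- list(TFA = cagegrn:::bed_to_granges("chr1", 1100L, 1200L))
  expect_equal(label_enhancers(reg, peak_in)$label, 1L)
  expect_equal(label_enhancers(reg, peak_out)$label, 0L)
  expect_error(label_enhancers(reg, peak_in, tfs = c("TFA", "TFB")),
               "general model")
})

test_that("predict_binding reproduces logistic closed forms", {
  mk_model <- function(beta) {
    structure(list(tf = "t", features = cagegrn:::FEATURE_NAMES,
                   intercept = 0, beta = setNames(beta,
                                                  cagegrn:::FEATURE_NAMES),
                   center = setNames(rep(0, 3), cagegrn:::FEATURE_NAMES),
                   scale = setNames(rep(1, 3), cagegrn:::FEATURE_NAMES),
                   lambda = 1),
              class = "BindingModel")
  }
  X <- data.table(S = c(0, log(3)), E_CAGE = c(0, 0), E_ChIP = c(0, 0))
  expect_equal(predict_binding(mk_model(c(0, 0, 0)), X), c(0.5, 0.5))
  expect_equal(predict_binding(mk_model(c(1, 1, 1)), X)[1], 0.5)
  expect_equal(predict_binding(mk_model(c(1, 0, 0)), X)[2], 0.75)
})

test_that("training recovers generative coefficients and rejects bad input", {
  d <- make_eq1_data(4000, beta = c(1.5, 0.8, 2.0), intercept = -1,
                     seed = 8)
  m <- train_tf_model(d$features, d$labels)
  expect_equal(unname(m$beta), c(1.5, 0.8, 2.0), tolerance = 0.15 / 1.5)
  expect_true(all(abs(unname(m$beta) - c(1.5, 0.8, 2.0)) < 0.15))
  # null labels: no signal, PR AUC ~ prevalence
  null <- cagegrn:::with_seed(9, rbinom(4000, 1, 0.25))
  m0 <- train_tf_model(d$features, null)
  expect_true(all(abs(m0$beta) < 0.1))
  expect_equal(pr_auc(predict_binding(m0, d$features), null), 0.25,
               tolerance = 0.12)
  expect_error(train_tf_model(d$features, rep(1, 4000)), "single-class")
  bad <- copy(d$features)[1, S := NaN]
  expect_error(train_tf_model(bad, d$labels), "non-finite")
})

test_that("duplicating every training row barely moves the fit", {
  d <- make_eq1_data(1500, seed = 4)
  m1 <- train_tf_model(d$features, d$labels)
  m2 <- train_tf_model(rbind(d$features, d$features),
                       c(d$labels, d$labels))
  expect_equal(unname(m2$beta), unname(m1$beta), tolerance = 0.01)
})

test_that("models serialize and reload with identical predictions", {
  d <- make_eq1_data(500, seed = 6)
  m <- train_tf_model(d$features, d$labels)
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict_binding(m2, d$features),
               predict_binding(m, d$features))
})

test_that("enhancer_features assembles one finite row per (TF, region)", {
  sw <- small_world()
  recs <- make_ctss(sw$spec, sw$world, "A")
  res <- process_ctss(recs)
  regions <- find_enhancers(res$pooled,
                            chrom_lengths = sw$world$genome$lengths)
  truth <- make_binding_truth(sw$spec, sw$world, regions)
  trk_file <- tempfile(fileext = ".bedGraph")
  write_coverage_track(truth$coverage, trk_file)
  feats <- enhancer_features(regions, sw$world$genome, sw$world$motifs,
                             sw$world$motif2tf,
                             read_coverage_track(trk_file),
                             n_background = 200, seed = 4)
  expect_equal(nrow(feats), nrow(regions) * sw$spec$n_tfs)
  expect_true(all(is.finite(feats$S)))
  expect_true(all(is.finite(feats$E_CAGE)))
  expect_true(all(is.finite(feats$E_ChIP)))
  # planted (enhancer, TF) pairs carry clearly elevated motif scores
  planted <- merge(sw$world$planted,
                   sw$world$enhancers[state == "both"], by = "enh_id")
  hit <- merge(feats, regions[, .(region_id, mid)], by = "region_id")
  hit <- merge(hit, planted[, .(tf, chrom, emid = mid)],
               by = c("tf", "chrom"))
  hit <- hit[abs(mid - emid) <= 50]
  expect_true(nrow(hit) > 0)
  expect_true(median(hit$S) > 3)
  # deterministic given the same background seed
  feats2 <- enhancer_features(regions, sw$world$genome, sw$world$motifs,
                              sw$world$motif2tf,
                              read_coverage_track(trk_file),
                              n_background = 200, seed = 4)
  expect_equal(feats2, feats)
  # absent coverage imputes E_ChIP = 0 with a warning
  expect_warning(f0 <- enhancer_features(regions, sw$world$genome,
                                         sw$world$motifs, sw$world$motif2tf,
                                         NULL, n_background = 50, seed = 4),
                 "imputed")
  expect_true(all(f0$E_ChIP == 0))
})

test_that("pr_auc behaves at its closed-form anchors", {
  y <- c(rep(1, 5), rep(0, 15))
  expect_equal(pr_auc(seq(20, 1), y), 1.0)       # perfect separation
  expect_equal(pr_auc(rep(1, 20), y), 0.25)      # constant -> prevalence
  # uniform random scores, prevalence 0.2, n = 2000
  s <- cagegrn:::with_seed(12, runif(2000))
  yy <- cagegrn:::with_seed(13, rbinom(2000, 1, 0.2))
  expect_equal(pr_auc(s, yy), mean(yy), tolerance = 0.03 / 0.2)
})

test_that("cross-validation reports per-fold PR AUC against prevalence", {
  d <- make_eq1_data(1200, seed = 14)
  feats <- copy(d$features)
  feats[, `:=`(tf = "TFA", label = d$labels,
               chrom = rep(c("chr1", "chr2", "chr3"), length.out = .N),
               cell_type = rep(c("K562", "GM12878"), length.out = .N))]
  cv <- crossval_pr_auc(feats, scheme = "chromosome")
  expect_equal(nrow(cv), 3L)
  expect_true(all(cv$pr_auc > cv$baseline))
  cv2 <- crossval_pr_auc(feats, scheme = "cell_type")
  expect_equal(sort(cv2$fold), c("GM12878", "K562"))
  expect_true(all(cv2$pr_auc > cv2$baseline))
  # a perfect feature gives PR AUC 1 on every fold
  perfect <- copy(feats)[, S := label * 10 + S * 1e-3]
  cvp <- crossval_pr_auc(perfect, scheme = "chromosome",
                         feature_subset = "S")
  expect_equal(cvp$pr_auc, rep(1, 3))
  wt <- prauc_wilcoxon(cv)
  expect_s3_class(wt, "htest")
})

test_that("fitted models beat the constant predictor across seeds", {
  wins <- vapply(1:20, function(s) {
    d <- make_eq1_data(400, beta = c(1, 0.5, 1), seed = 100 + s)
    if (length(unique(d$labels)) < 2) return(NA)
    m <- train_tf_model(d$features, d$labels)
    pr_auc(predict_binding(m, d$features), d$labels) - mean(d$labels)
  }, numeric(1))
  expect_true(mean(wins, na.rm = TRUE) > 0)
  expect_true(mean(wins > 0, na.rm = TRUE) > 0.9)
})

test_that("pooling a single TF reproduces that TF's model", {
  d <- make_eq1_data(800, seed = 19)
  feats <- copy(d$features)[, tf := "TFA"]
  m1 <- train_tf_model(feats, d$labels, tf = "TFA")
  m2 <- train_general_model(feats, d$labels)
  expect_equal(unname(m2$beta), unname(m1$beta), tolerance = 1e-8)
  expect_equal(m2$tf, "general")
})
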