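# PFM scanning and empirical motif z-scores.
#
# Log-odds scores use a uniform background with a +0.25 pseudocount per
# PFM cell; GC composition is accounted for empirically, by scoring a
# seeded null of sequences generated from the input set's dinucleotide
# (first-order Markov) composition.

.encode_seqs <- function(seqs) {
  # integer matrix nseq x L; A=1 C=2 G=3 T=4, anything else 5 (scores 0)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must share one length", call. = FALSE)
  m <- matrix(match(unlist(strsplit(toupper(seqs), "")),
                    c("A", "C", "G", "T")),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  m[is.na(m)] <- 5L
  m
}

.pfm_logodds <- function(pfm, pseudocount = 0.25) {
  p <- sweep(pfm + pseudocount, 2L, colSums(pfm + pseudocount), "/")
  lod <- log2(p / 0.25)
  rbind(lod, N = 0)                        # 5th row: unknown base scores 0
}

.revcomp_lod <- function(lod) {
  lod[c(4L, 3L, 2L, 1L, 5L), ncol(lod):1L, drop = FALSE]
}

# best log-odds score over all offsets for a batch of encoded sequences
.scan_best_one_strand <- function(enc, lod) {
  L <- ncol(enc)
  w <- ncol(lod)
  best <- rep(-Inf, nrow(enc))
  for (o in seq_len(L - w + 1L)) {
    sc <- numeric(nrow(enc))
    for (j in seq_len(w)) {
      sc <- sc + lod[enc[, o + j - 1L] + (j - 1L) * 5L]
    }
    best <- pmax(best, sc)
  }
  best
}

.scan_best <- function(enc, pfm) {
  lod <- .pfm_logodds(pfm)
  pmax(.scan_best_one_strand(enc, lod),
       .scan_best_one_strand(enc, .revcomp_lod(lod)))
}

#' Generate background sequences matching input composition
#'
#' First-order Markov (dinucleotide-aware, hence GC-matched) sequences of a
#' fixed length, estimated from the input set.
#'
#' @param seqs character vector of input sequences.
#' @param n number of background sequences.
#' @param length_out sequence length (default: length of the inputs).
#' @param seed RNG seed.
#' @return character vector of `n` sequences.
#' @export
background_sequences <- function(seqs, n, length_out = NULL, seed = 1L) {
  length_out <- length_out %||% nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  cat_enc <- unlist(lapply(seqs, function(s) {
    match(strsplit(toupper(s), "")[[1]], bases)
  }))
  cat_enc <- cat_enc[!is.na(cat_enc)]
  if (length(cat_enc) < 2L) stop("not enough sequence to model background",
                                 call. = FALSE)
  trans <- matrix(1, 4L, 4L)               # +1 smoothing
  from <- cat_enc[-length(cat_enc)]
  to <- cat_enc[-1L]
  for (k in seq_along(from)) trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
  trans <- trans / rowSums(trans)
  p0 <- tabulate(cat_enc, 4L) / length(cat_enc)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      out <- integer(length_out)
      out[1] <- sample.int(4L, 1L, prob = p0)
      for (j in 2:length_out) {
        out[j] <- sample.int(4L, 1L, prob = trans[out[j - 1L], ])
      }
      paste(bases[out], collapse = "")
    }, character(1))
  })
}

#' Motif z-score matrix (sequences x motifs)
#'
#' Best-hit log-odds scores standardized against a seeded
#' composition-matched background (see [motif_zscore()]).
#'
#' @param seqs character vector of sequences (equal length).
#' @param motifs motif list from [read_motifs()].
#' @param n_background number of background sequences.
#' @param seed RNG seed.
#' @return numeric matrix, `length(seqs)` rows by `length(motifs)` columns.
#' @export
motif_zscore_matrix <- function(seqs, motifs, n_background = 1000L,
                                seed = 1L) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must share one length", call. = FALSE)
  widths <- vapply(motifs, function(m) ncol(m$pfm), integer(1))
  if (any(widths > L)) {
    stop(sprintf("motif(s) wider than the %d-bp regions: %s", L,
                 paste(names(motifs)[widths > L], collapse = ", ")),
         call. = FALSE)
  }
  enc <- .encode_seqs(seqs)
  bg <- background_sequences(seqs, n_background, length_out = L, seed = seed)
  enc_bg <- .encode_seqs(bg)
  z <- matrix(NA_real_, nrow = length(seqs), ncol = length(motifs),
              dimnames = list(NULL, names(motifs)))
  for (m in names(motifs)) {
    obs <- .scan_best(enc, motifs[[m]]$pfm)
    null <- .scan_best(enc_bg, motifs[[m]]$pfm)
    s <- sd(null)
    if (s == 0) s <- 1e-9
    z[, m] <- (obs - mean(null)) / s
  }
  z
}

#' Motif z-scores per (TF, sequence)
#'
#' For each motif, the best log-odds score over both strands and all offsets
#' is computed for every input sequence and for a seeded composition-matched
#' background; the z-score standardizes the observed best score against the
#' background distribution.  A TF's score `S` is the maximum z over its
#' motifs.
#'
#' @param seqs character vector of enhancer sequences (equal length).
#' @param motifs motif list from [read_motifs()].
#' @param motif2tf mapping table (`motif`, `tf`) from [read_motif2tf()].
#' @param tfs TFs to score (default: all TFs in the mapping).  A requested
#'   TF with no mapped motif is an error.
#' @param n_background number of background sequences (default 1000).
#' @param seed RNG seed for the background generator.
#' @return a `data.table` with `tf`, `seq_index`, `S`.
#' @export
motif_zscore <- function(seqs, motifs, motif2tf, tfs = NULL,
                         n_background = 1000L, seed = 1L) {
  map <- as.data.table(motif2tf)
  tfs <- tfs %||% sort(unique(map$tf))
  missing_tf <- setdiff(tfs, map$tf)
  if (length(missing_tf)) {
    stop(sprintf("no motifs mapped for TF(s): %s",
                 paste(missing_tf, collapse = ", ")), call. = FALSE)
  }
  need <- unique(map[tf %in% tfs]$motif)
  absent <- setdiff(need, names(motifs))
  if (length(absent)) {
    stop(sprintf("motif(s) in mapping but not in collection: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  z <- motif_zscore_matrix(seqs, motifs[need], n_background = n_background,
                           seed = seed)
  out <- rbindlist(lapply(tfs, function(f) {
    mot <- intersect(map[tf == f]$motif, colnames(z))
    data.table(tf = f, seq_index = seq_along(seqs),
               S = apply(z[, mot, drop = FALSE], 1L, max))
  }))
  out[]
}
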