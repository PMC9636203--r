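# Deterministic synthetic-data generator: a miniature genome with planted
# TSS clusters, enhancers, motifs, binding labels and a two-cell-state
# design, so every pipeline stage has an exact ground truth.
#
# Layout: each chromosome is divided into equal blocks, one gene per block
# (span at a fixed offset), with one baseline enhancer placed in the
# intergenic part of the block.  Driver TF motifs are never planted in
# baseline enhancers; state B adds one motif-bearing enhancer upstream of
# each planted target.  Driver TF genes are silent in state A, so state-A
# networks carry no driver edges by construction.

#' Specification of a synthetic fixture world
#'
#' Defaults describe a small but complete world: 2 chromosomes x 500 kb,
#' 60 genes, 40 baseline enhancers, 8 TFs, 3 replicates; enhancers emit
#' divergent tags at +/- 60 bp from the midpoint with a balanced (0.5)
#' strand split; tag clusters spread geometrically within 20 bp; binding
#' labels follow the logistic model with beta = (1.5, 0.8, 2.0).
#'
#' @param seed master RNG seed; identical spec + seed give identical worlds.
#' @param n_chrom,chrom_len,gc genome geometry and GC content.
#' @param n_genes,gene_length gene count and span length.
#' @param n_enhancers baseline enhancer count (split across chromosomes).
#' @param n_tfs number of TFs (each with one motif and one gene).
#' @param n_replicates CAGE replicates per state.
#' @param motif_width planted motif width (bp).
#' @param arm_offset divergent arm distance from the enhancer midpoint (bp).
#' @param gene_tags,enhancer_tags expected tag counts per replicate.
#' @param balance_fraction fraction of enhancer tags on the plus (downstream)
#'   arm; 0.5 is perfectly balanced, 1.0 one-armed.
#' @param planted_motif_prob probability a non-driver TF's motif is planted
#'   in a baseline enhancer.
#' @param beta,intercept logistic coefficients generating binding labels.
#' @param n_drivers,targets_per_driver,driver_effect two-state design: how
#'   many driver TFs, targets each, and the state-B fold effect on target
#'   and driver-gene expression.
#' @param a_high_genes,a_high_effect optionally upregulate this many genes
#'   in state A instead (default 0: state A is pure baseline, so the
#'   reverse B -> A comparison has no upregulated genes and planted drivers
#'   provably score zero influence in that direction).
#' @param noise use Poisson tag counts and geometric positional spread
#'   (`FALSE` gives exact expected counts at exact positions).
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chrom = 2L, chrom_len = 500000L,
                         gc = 0.41, n_genes = 60L, gene_length = 2000L,
                         n_enhancers = 40L, n_tfs = 8L, n_replicates = 3L,
                         motif_width = 10L, arm_offset = 60L,
                         gene_tags = 200, enhancer_tags = 50,
                         balance_fraction = 0.5, planted_motif_prob = 0.3,
                         beta = c(1.5, 0.8, 2.0), intercept = -1,
                         n_drivers = 2L, targets_per_driver = 6L,
                         driver_effect = 6, a_high_genes = 0L,
                         a_high_effect = 4, noise = TRUE) {
  stopifnot(n_genes %% n_chrom == 0L, n_enhancers %% n_chrom == 0L,
            n_tfs + n_drivers * targets_per_driver + a_high_genes <= n_genes,
            n_drivers <= n_tfs)
  structure(as.list(environment()), class = "FixtureSpec")
}

#' @export
print.FixtureSpec <- function(x, ...) {
  cat(sprintf(
    "FixtureSpec: seed %d; %d x %d bp, %d genes, %d enhancers, %d TFs\n",
    x$seed, x$n_chrom, x$chrom_len, x$n_genes, x$n_enhancers, x$n_tfs))
  invisible(x)
}

.random_consensus <- function(n, width) {
  # distinct, composition-mixed consensi
  out <- character(0)
  while (length(out) < n) {
    s <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
               collapse = "")
    if (!s %in% out && !grepl("(A{5}|C{5}|G{5}|T{5})", s)) out <- c(out, s)
  }
  out
}

.consensus_pfm <- function(consensus, dominant = 85, other = 5) {
  b <- strsplit(consensus, "")[[1]]
  pfm <- matrix(other, 4L, length(b), dimnames = list(c("A", "C", "G", "T"),
                                                      NULL))
  for (j in seq_along(b)) pfm[b[j], j] <- dominant
  pfm
}

#' Generate the fixture genome, annotation, motifs and planted truth
#'
#' @param spec a `FixtureSpec`.
#' @return a "fixture world" list: `spec`, `genome` (`GenomeIndex`),
#'   `annotation`, `motifs`, `motif2tf`, `enhancers` (with `state` =
#'   `"both"` or `"B"`), `planted` (enh_id, tf), `expr` (per-gene expected
#'   tag rates per state), `tf_genes`, `drivers`, `targets`, `a_high`.
#' @export
make_genome <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    genes_per_chrom <- spec$n_genes %/% spec$n_chrom
    enh_per_chrom <- spec$n_enhancers %/% spec$n_chrom
    block <- spec$chrom_len %/% genes_per_chrom
    chroms <- sprintf("chr%d", seq_len(spec$n_chrom))
    # raw sequences
    base_prob <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
                   (1 - spec$gc) / 2)
    seqs <- lapply(chroms, function(ch) {
      sample(c("A", "C", "G", "T"), spec$chrom_len, replace = TRUE,
             prob = base_prob)
    })
    names(seqs) <- chroms
    # genes: one per block
    ann <- rbindlist(lapply(seq_along(chroms), function(ci) {
      data.table(chrom = chroms[ci], blk = seq_len(genes_per_chrom),
                 start = (seq_len(genes_per_chrom) - 1L) * block + 2000L,
                 strand = sample(c("+", "-"), genes_per_chrom,
                                 replace = TRUE))
    }))
    ann[, end := start + spec$gene_length]
    tf_names <- sprintf("TF%d", seq_len(spec$n_tfs))
    gene_ids <- c(tf_names,
                  sprintf("G%03d", seq_len(spec$n_genes - spec$n_tfs)))
    # spread TF genes across the genome rather than clustering them
    ord <- sample(nrow(ann))
    ann <- ann[ord]
    ann[, gene_id := gene_ids]
    ann[, tss := ifelse(strand == "+", start, end - 1L)]
    # motifs: one sharp PFM per TF
    consensi <- .random_consensus(spec$n_tfs, spec$motif_width)
    motifs <- lapply(seq_len(spec$n_tfs), function(k) {
      id <- sprintf("M%03d", k)
      list(id = id, name = tf_names[k], pfm = .consensus_pfm(consensi[k]))
    })
    names(motifs) <- vapply(motifs, `[[`, character(1), "id")
    motif2tf <- data.table(motif = names(motifs), tf = tf_names)
    drivers <- tf_names[seq_len(spec$n_drivers)]
    non_tf_genes <- setdiff(ann$gene_id, tf_names)
    targets <- data.table(
      driver = rep(drivers, each = spec$targets_per_driver),
      gene = sample(non_tf_genes,
                    spec$n_drivers * spec$targets_per_driver))
    a_high <- sample(setdiff(non_tf_genes, targets$gene), spec$a_high_genes)
    # baseline enhancers: intergenic part of each of the first blocks
    enh <- rbindlist(lapply(seq_along(chroms), function(ci) {
      data.table(chrom = chroms[ci],
                 mid = (seq_len(enh_per_chrom) - 1L) * block + 11000L)
    }))
    enh[, `:=`(state = "both", enh_id = sprintf("E%03d", seq_len(nrow(enh))))]
    # planted motifs in baseline enhancers: non-driver TFs only
    non_driver <- setdiff(tf_names, drivers)
    planted <- rbindlist(lapply(enh$enh_id, function(e) {
      hit <- non_driver[runif(length(non_driver)) < spec$planted_motif_prob]
      if (length(hit) == 0L) return(NULL)
      data.table(enh_id = e, tf = hit)
    }))
    # state-B enhancers: one upstream of each target, carrying its driver's
    # motif
    tss_of <- setNames(ann$tss, ann$gene_id)
    chrom_of <- setNames(ann$chrom, ann$gene_id)
    enh_b <- targets[, .(chrom = chrom_of[gene],
                         mid = as.integer(ifelse(tss_of[gene] >= 3200L,
                                                 tss_of[gene] - 3000L,
                                                 tss_of[gene] + 3000L)))]
    enh_b[, `:=`(state = "B",
                 enh_id = sprintf("E%03d", nrow(enh) + seq_len(nrow(enh_b))))]
    planted_b <- data.table(enh_id = enh_b$enh_id, tf = targets$driver)
    enh <- rbind(enh, enh_b)
    planted <- rbind(planted, planted_b)
    # write planted motifs into the sequence, stacked at per-TF slots so
    # several motifs fit in one 200-bp window
    slot_of <- setNames(seq_len(spec$n_tfs), tf_names)
    for (i in seq_len(nrow(planted))) {
      e <- enh[enh_id == planted$enh_id[i]]
      at <- e$mid - 80L + (slot_of[planted$tf[i]] - 1L) * 13L
      seqs[[e$chrom]][at:(at + spec$motif_width - 1L)] <-
        strsplit(consensi[slot_of[planted$tf[i]]], "")[[1]]
    }
    # expression rates
    expr <- ann[, .(gene_id)]
    expr[, base := exp(rnorm(.N, log(spec$gene_tags), 0.5))]
    expr[, `:=`(rate_A = base, rate_B = base)]
    expr[gene_id %in% drivers, rate_A := 0]
    expr[gene_id %in% drivers, rate_B := base * spec$driver_effect]
    expr[gene_id %in% targets$gene, rate_B := base * spec$driver_effect]
    expr[gene_id %in% a_high, rate_A := base * spec$a_high_effect]
    enh[, `:=`(rate_A = ifelse(state == "both", spec$enhancer_tags, 0),
               rate_B = spec$enhancer_tags)]
    dna <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                           collapse = ""))
    names(dna) <- chroms
    ann_out <- ann[, .(gene_id, chrom, strand, start, end, tss)]
    setorder(ann_out, chrom, start)
    list(spec = spec, genome = genome_index(dna), annotation = ann_out,
         motifs = motifs, motif2tf = motif2tf, enhancers = enh[],
         planted = planted[], expr = expr[], tf_genes = tf_names,
         drivers = drivers, targets = targets[], a_high = a_high)
  })
}

#' Simulate CTSS records for one state
#'
#' TSS clusters emit same-strand tags spread geometrically (capped at
#' 20 bp) downstream of the gene TSS; enhancers emit divergent tags at
#' `-arm_offset` (minus strand) and `+arm_offset` (plus strand) from the
#' midpoint, split by `balance_fraction`.  With `noise = TRUE`, counts are
#' Poisson per replicate and positions jittered; otherwise expected counts
#' land at exact positions.
#'
#' @param spec a `FixtureSpec`.
#' @param world fixture world from [make_genome()].
#' @param state `"A"` or `"B"`.
#' @return a list of CTSS record tables (one per replicate), suitable for
#'   [ctss_profile()] / [write_ctss()].
#' @export
make_ctss <- function(spec, world, state = c("A", "B")) {
  state <- match.arg(state)
  rate_col <- if (state == "A") "rate_A" else "rate_B"
  ann <- world$annotation
  enh <- world$enhancers
  lapply(seq_len(spec$n_replicates), function(r) {
    with_seed(spec$seed * 10000L + r * 10L + (state == "B"), {
      recs <- list()
      for (i in seq_len(nrow(ann))) {
        rate <- world$expr[gene_id == ann$gene_id[i]][[rate_col]]
        n <- if (spec$noise) rpois(1L, rate) else round(rate)
        if (n == 0L) next
        off <- if (spec$noise) pmin(rgeom(n, 0.25), 20L) else rep(0L, n)
        pos <- if (ann$strand[i] == "+") ann$tss[i] + off else
          ann$tss[i] - off
        recs[[length(recs) + 1L]] <- data.table(
          chrom = ann$chrom[i], pos = pos, strand = ann$strand[i])
      }
      for (i in seq_len(nrow(enh))) {
        rate <- enh[[rate_col]][i]
        n <- if (spec$noise) rpois(1L, rate) else round(rate)
        if (n == 0L) next
        n_plus <- if (spec$noise) rbinom(1L, n, spec$balance_fraction) else
          round(n * spec$balance_fraction)
        n_minus <- n - n_plus
        jit <- function(k) if (spec$noise) pmin(rgeom(k, 0.3), 15L) else
          rep(0L, k)
        if (n_minus > 0L) {
          recs[[length(recs) + 1L]] <- data.table(
            chrom = enh$chrom[i],
            pos = enh$mid[i] - spec$arm_offset - jit(n_minus), strand = "-")
        }
        if (n_plus > 0L) {
          recs[[length(recs) + 1L]] <- data.table(
            chrom = enh$chrom[i],
            pos = enh$mid[i] + spec$arm_offset + jit(n_plus), strand = "+")
        }
      }
      dt <- rbindlist(recs)
      out <- dt[, .(count = as.numeric(.N)), by = .(chrom, pos, strand)]
      out[, sample_id := sprintf("%s_rep%d", state, r)]
      setorder(out, chrom, pos, strand)
      setcolorder(out, c("chrom", "pos", "strand", "count", "sample_id"))
      out[]
    })
  })
}

#' Binding labels and a correlated coverage track for called regions
#'
#' True features follow the generative logistic model: the motif feature is
#' high (`N(6, 1)`) where the region matches a planted (enhancer, TF) pair
#' and null (`N(0, 1)`) otherwise; the intensity feature is the
#' standardized log1p region TPM; a latent standard-normal per-region
#' signal `z` drives both the ChIP feature and the emitted coverage track
#' (`value = exp(z + 3)` over the normalized window, so that
#' `log1p(mean coverage)` recovers `z + 3` up to a small softplus
#' distortion).  Labels are Bernoulli draws from
#' `plogis(b1 S + b2 E_CAGE + b3 z + intercept)`.
#'
#' @param spec a `FixtureSpec`.
#' @param world fixture world.
#' @param regions called region table with normalized intervals and `tpm`.
#' @param match_tol max distance (bp) between a region midpoint and a
#'   planted enhancer midpoint to inherit its planted motifs (default 150).
#' @return a list: `labels` (tf, region_id, label, p_true), `coverage`
#'   (bedGraph-ready table), `features_true`.
#' @export
make_binding_truth <- function(spec, world, regions, match_tol = 150L) {
  dt <- as.data.table(regions)
  stopifnot(all(c("region_id", "chrom", "mid", "tpm", "norm_start",
                  "norm_end") %in% names(dt)))
  with_seed(spec$seed + 777L, {
    # region -> nearest planted enhancer
    enh_of <- vapply(seq_len(nrow(dt)), function(i) {
      e <- world$enhancers[chrom == dt$chrom[i]]
      if (nrow(e) == 0L) return(NA_character_)
      j <- which.min(abs(e$mid - dt$mid[i]))
      if (abs(e$mid[j] - dt$mid[i]) <= match_tol) e$enh_id[j] else
        NA_character_
    }, character(1))
    e_cage <- as.numeric(scale(log1p(dt$tpm)))
    if (any(is.na(e_cage))) e_cage <- numeric(nrow(dt))
    z <- rnorm(nrow(dt))
    feats <- rbindlist(lapply(world$tf_genes, function(f) {
      planted_here <- !is.na(enh_of) &
        paste(enh_of, f) %in% world$planted[, paste(enh_id, tf)]
      S <- rnorm(nrow(dt))
      S[planted_here] <- rnorm(sum(planted_here), 6, 1)
      data.table(tf = f, region_id = dt$region_id, S = S,
                 E_CAGE = e_cage, E_ChIP = z)
    }))
    feats[, p_true := plogis(spec$beta[1] * S + spec$beta[2] * E_CAGE +
                               spec$beta[3] * E_ChIP + spec$intercept)]
    feats[, label := rbinom(.N, 1L, p_true)]
    coverage <- dt[, .(chrom, start = norm_start, end = norm_end,
                       value = exp(z + 3))]
    setorder(coverage, chrom, start)
    list(labels = feats[, .(tf, region_id, label, p_true)],
         coverage = coverage[],
         features_true = feats[, .(tf, region_id, S, E_CAGE, E_ChIP)])
  })
}

#' Draw (feature, label) data straight from the logistic generative model
#'
#' Features are independent standard normals, so recovered standardized
#' coefficients estimate `beta` directly.
#'
#' @param n number of rows.
#' @param beta length-3 coefficient vector for (S, E_CAGE, E_ChIP).
#' @param intercept intercept.
#' @param seed RNG seed.
#' @return list with `features` (data.table S, E_CAGE, E_ChIP), `labels`,
#'   `prob`.
#' @export
make_eq1_data <- function(n, beta = c(1.5, 0.8, 2.0), intercept = -1,
                          seed = 1L) {
  with_seed(seed, {
    X <- matrix(rnorm(n * 3L), ncol = 3L,
                dimnames = list(NULL, FEATURE_NAMES))
    p <- plogis(drop(X %*% beta) + intercept)
    y <- rbinom(n, 1L, p)
    list(features = as.data.table(X), labels = y, prob = p)
  })
}

#' Build the full two-state fixture
#'
#' State A is the source: driver TF genes are silent and state-B-specific
#' enhancers emit no tags.  State B upregulates driver genes and their
#' targets (`driver_effect`-fold) and switches on the motif-bearing
#' enhancers near the targets.  The emitted DE truth is the exact
#' `log2((rate_B + 1) / (rate_A + 1))` of the expected tag rates.
#'
#' @param spec a `FixtureSpec`.
#' @return a list: `world`, `ctss_a`, `ctss_b` (record-table lists),
#'   `de` (gene, log2fc for A -> B; negate for B -> A), `truth`
#'   (drivers, targets, a_high).
#' @export
make_two_state <- function(spec) {
  world <- make_genome(spec)
  de <- world$expr[, .(gene = gene_id,
                       log2fc = log2((rate_B + 1) / (rate_A + 1)))]
  list(world = world,
       ctss_a = make_ctss(spec, world, "A"),
       ctss_b = make_ctss(spec, world, "B"),
       de = de[],
       truth = list(drivers = world$drivers, targets = world$targets,
                    a_high = world$a_high))
}
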