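# Balance score, bidirectional calling, support filtering, width
# normalization and region annotation.

ideal_enhancer <- function(mid, tags = 50, chrom = "chr1", arm = 60L) {
  data.table(chrom = chrom, pos = c(mid - arm, mid + arm),
             strand = c("-", "+"), score = as.numeric(tags))
}

tss_cluster <- function(at, tags = 50, chrom = "chr1", strand = "+") {
  data.table(chrom = chrom, pos = as.integer(at + 0:4), strand = strand,
             score = as.numeric(tags))
}

test_that("balance score hits its closed forms", {
  # perfectly balanced divergent signal
  b <- balance_score(pooled_from_table(ideal_enhancer(1000L)), "chr1", 1000L)
  expect_equal(b, 1.0)
  # fully unidirectional: B = sqrt(0.5), below the 0.95 threshold
  uni <- pooled_from_table(data.table(chrom = "chr1", pos = 1060L,
                                      strand = "+", score = 50))
  expect_equal(balance_score(uni, "chr1", 1000L), sqrt(0.5))
  # no signal in the window
  expect_equal(balance_score(uni, "chr1", 5000L), 0)
  expect_error(balance_score(uni, "chr1", 1000L, window = 200L), "odd")
  expect_error(balance_score(uni, "chr1", -5L), "outside")
})

test_that("balance is scale-invariant and mirror-symmetric", {
  set.seed(99)
  for (i in 1:20) {
    sig <- random_signal(40)
    mids <- sample(200:1300, 5)
    b1 <- balance_score(pooled_from_table(sig), "chr1", mids)
    scaled <- copy(sig)[, score := score * 37.5]
    expect_equal(balance_score(pooled_from_table(scaled), "chr1", mids), b1)
    # mirror: reflect coordinates and swap strands
    span <- 2000L
    mir <- copy(sig)[, `:=`(pos = span - pos,
                            strand = ifelse(strand == "+", "-", "+"))]
    b2 <- balance_score(pooled_from_table(mir), "chr1", span - mids)
    expect_equal(b2, b1, tolerance = 1e-12)
  }
})

test_that("call_bidirectional finds planted enhancers, not TSS clusters", {
  # one ideal enhancer
  pooled <- pooled_from_table(ideal_enhancer(1000L))
  reg <- call_bidirectional(pooled)
  expect_equal(nrow(reg), 1L)
  expect_true(reg$start <= 1000L && reg$end > 1000L)
  expect_equal(reg$balance, 1.0)
  expect_equal(reg$tpm, 100)

  # a pure unidirectional cluster yields nothing
  expect_equal(nrow(call_bidirectional(pooled_from_table(tss_cluster(500L)))),
               0L)

  # two ideal enhancers 1 kb apart -> two non-overlapping regions
  two <- pooled_from_table(rbind(ideal_enhancer(1000L),
                                 ideal_enhancer(2000L)))
  reg2 <- call_bidirectional(two)
  expect_equal(nrow(reg2), 2L)
  expect_true(all(reg2$end[-nrow(reg2)] <= reg2$start[-1]))
})

test_that("call_bidirectional agrees exactly with the exhaustive oracle", {
  set.seed(31)
  for (i in 1:25) {
    sig <- rbind(random_signal(sample(10:60, 1)),
                 ideal_enhancer(sample(300:1200, 1)))
    sig <- sig[, .(score = sum(score)), by = .(chrom, pos, strand)]
    got <- call_bidirectional(pooled_from_table(sig))
    want <- oracle_call_bidirectional(sig)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$mid, want$mid)
      expect_equal(got$balance, want$balance, tolerance = 1e-12)
    }
  }
})

test_that("filter_bidirectional counts supporting samples per region", {
  mk <- function(samples) {
    recs <- rbindlist(lapply(samples, function(s) {
      data.table(chrom = "chr1", pos = c(940L, 1060L), strand = c("-", "+"),
                 score = 10, sample_id = s)
    }))
    recs
  }
  # region support comes from the per-sample records of the pooled profile
  tab <- rbind(mk(c("s1", "s2")),
               data.table(chrom = "chr1", pos = 5000L, strand = "+",
                          score = 1, sample_id = "s3"))
  pooled <- pooled_from_table(tab)
  reg <- call_bidirectional(pooled)
  expect_equal(nrow(reg), 1L)
  expect_equal(nrow(filter_bidirectional(reg, pooled, min_support = 2L)), 1L)
  expect_equal(nrow(filter_bidirectional(reg, pooled, min_support = 3L)), 0L)
  expect_equal(nrow(filter_bidirectional(reg, pooled, min_support = 1L)), 1L)
})

test_that("normalize_width centres 200-bp windows and clips at edges", {
  reg <- data.table(region_id = "r1", chrom = "chr1", start = 995L,
                    end = 1006L, mid = 1000L, balance = 1, tpm = 10,
                    support = 3L)
  norm <- normalize_width(reg)
  expect_equal(norm$norm_start, 900L)
  expect_equal(norm$norm_end, 1100L)
  edge <- copy(reg)[, mid := 50L]
  expect_warning(norm2 <- normalize_width(edge), "clipped")
  expect_equal(norm2$norm_start, 0L)
  expect_equal(norm2$norm_end, 150L)
  far <- copy(reg)[, mid := 990L]
  expect_warning(norm3 <- normalize_width(far, chrom_lengths = c(chr1 = 1000L)),
                 "clipped")
  expect_equal(norm3$norm_end, 1000L)
})

test_that("nearest-gene annotation bins distances and drops orphans", {
  ann <- data.table(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                    strand = "+", start = c(1000L, 9000L, 50000L),
                    end = c(2000L, 10000L, 51000L),
                    tss = c(1000L, 9000L, 50000L))
  reg <- data.table(region_id = sprintf("r%d", 1:3), chrom = "chr1",
                    start = 0L, end = 1L,
                    mid = c(1000L, 16300L, 900000L), balance = 1, tpm = 1,
                    support = 3L)
  res <- annotate_nearest_gene(reg, ann, max_distance = 100000)
  expect_equal(res$n_unassociated, 1L)
  a <- res$annotation
  expect_equal(a[region_id == "r1", distance], 0)
  expect_equal(a[region_id == "r1", bin], "[0,5)kb")
  expect_equal(a[region_id == "r2", gene_id], "gB")   # 7300 bp beats 33700
  expect_equal(a[region_id == "r2", bin], "[5,10)kb")
})

test_that("nearest-gene distances equal the all-pairs minimum", {
  set.seed(5)
  for (i in 1:10) {
    ann <- data.table(gene_id = sprintf("g%d", 1:3), chrom = "chr1",
                      strand = "+", start = sort(sample.int(80000L, 3)))
    ann[, `:=`(end = start + 1000L, tss = start)]
    reg <- data.table(region_id = sprintf("r%d", 1:5), chrom = "chr1",
                      start = 0L, end = 1L, mid = sample.int(90000L, 5),
                      balance = 1, tpm = 1, support = 3L)
    a <- annotate_nearest_gene(reg, ann)$annotation
    for (j in seq_len(nrow(reg))) {
      expect_equal(abs(a[region_id == reg$region_id[j], distance]),
                   min(abs(reg$mid[j] - ann$tss)))
    }
  }
})

test_that("region categories follow the stated precedence and partition", {
  ann <- data.table(gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
                    start = c(1000L, 10000L), end = c(2000L, 40000L),
                    tss = c(1000L, 10000L))
  reg <- data.table(region_id = sprintf("r%d", 1:4), chrom = "chr1",
                    start = 0L, end = 1L,
                    mid = c(10200L,   # 200 bp from gB TSS (inside gB)
                            4000L,    # 3 kb from gA TSS
                            30000L,   # inside gB body, 20 kb from its TSS
                            500000L), # far from everything
                    balance = 1, tpm = 1, support = 3L)
  res <- categorize_regions(reg, ann)
  got <- setNames(res$categories$category, res$categories$region_id)
  expect_equal(unname(got[c("r1", "r2", "r3", "r4")]),
               c("promoter", "proximal", "gene_body", "distal"))
  expect_equal(sum(res$counts$N), nrow(reg))
})

test_that("overlap_upset partitions regions by exact track membership", {
  reg <- data.table(region_id = sprintf("r%d", 1:3), chrom = "chr1",
                    start = c(100L, 500L, 900L), end = c(300L, 700L, 1100L),
                    mid = c(200L, 600L, 1000L), balance = 1, tpm = 1,
                    support = 3L)
  peaks <- list(
    H3K27ac = cagegrn:::bed_to_granges("chr1", c(150L, 950L), c(250L, 1050L)),
    H3K4me1 = cagegrn:::bed_to_granges("chr1", 140L, 260L)
  )
  res <- overlap_upset(reg, peaks)
  expect_equal(sum(res$N), 3L)
  expect_equal(res[combination == "H3K27ac+H3K4me1", N], 1L)
  expect_equal(res[combination == "H3K27ac", N], 1L)
  expect_equal(res[combination == "none", N], 1L)
  # no peak sets at all
  expect_equal(overlap_upset(reg, list())$combination, "none")
})

test_that("overlap_upset equals brute-force membership enumeration", {
  set.seed(17)
  for (i in 1:10) {
    reg <- data.table(region_id = sprintf("r%d", 1:12), chrom = "chr1",
                      start = sample.int(5000L, 12))
    reg[, `:=`(end = start + 100L, mid = start + 50L, balance = 1, tpm = 1,
               support = 3L)]
    tracks <- lapply(1:3, function(k) {
      s <- sample.int(5000L, 6)
      cagegrn:::bed_to_granges("chr1", s, s + 150L)
    })
    names(tracks) <- c("t1", "t2", "t3")
    res <- overlap_upset(reg, tracks)
    # brute force: per region, test every track by interval arithmetic
    combos <- vapply(seq_len(nrow(reg)), function(j) {
      memb <- vapply(tracks, function(tr) {
        any(reg$start[j] < GenomicRanges::end(tr) &
              reg$end[j] > GenomicRanges::start(tr) - 1L)
      }, logical(1))
      if (!any(memb)) "none" else paste(names(tracks)[memb], collapse = "+")
    }, character(1))
    want <- as.data.table(table(combos))
    for (j in seq_len(nrow(want))) {
      expect_equal(res[combination == want$combos[j], N],
                   as.integer(want$N[j]))
    }
  }
})
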