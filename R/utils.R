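# Internal helpers shared across modules.
#
# Coordinate convention: all intervals are 0-based half-open (BED-native).
# GRanges objects are 1-based closed; conversion happens only inside
# `bed_to_granges()` / `granges_to_bed()`.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not
#' perturb the global random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Sum of sparse per-position values over closed intervals [lo, hi]
#'
#' @param pos sorted integer positions.
#' @param val values aligned with `pos`.
#' @param lo,hi interval bounds (inclusive), vectorized.
#' @keywords internal
#' @noRd
sparse_interval_sum <- function(pos, val, lo, hi) {
  if (length(pos) == 0L) return(numeric(length(lo)))
  cs <- c(0, cumsum(val))
  i_hi <- findInterval(hi, pos)
  i_lo <- findInterval(lo - 1L, pos)
  cs[i_hi + 1L] - cs[i_lo + 1L]
}

#' Convert a BED-style table to GRanges (0-based half-open -> 1-based closed)
#' @keywords internal
#' @noRd
bed_to_granges <- function(chrom, start, end, strand = NULL) {
  strand <- strand %||% rep("*", length(chrom))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

#' @keywords internal
#' @noRd
granges_to_bed <- function(gr) {
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Rank-scale a numeric vector to [0, 1]
#'
#' Average ranks are mapped linearly so the (unique) maximum becomes 1 and
#' the minimum 0; constant vectors map to 0.5.  Invariant under strictly
#' monotone transforms of the input.
#' @keywords internal
#' @noRd
rank_scale <- function(x) {
  if (length(x) == 1L) return(1)
  r <- data.table::frank(x, ties.method = "average")
  rng <- range(r)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (r - rng[1]) / (rng[2] - rng[1])
}

#' @keywords internal
#' @noRd
stop_if_not_finite <- function(x, what) {
  if (any(!is.finite(x))) {
    stop(sprintf("%s contains non-finite values (NA/NaN/Inf)", what),
         call. = FALSE)
  }
  invisible(x)
}
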