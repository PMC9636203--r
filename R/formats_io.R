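# Readers and writers for every external format the pipeline touches.
#
# Everything here validates on the way in and reports malformed lines by
# number.  Interval arithmetic is 0-based half-open throughout; CTSS
# "position" is the BED start field.

# ---------------------------------------------------------------------------
# Genome

#' Build a genome index from a FASTA file or DNAStringSet
#'
#' Provides chromosome names/lengths and a strand-aware sequence accessor on
#' 0-based half-open intervals.
#'
#' @param fasta path to an (uncompressed) FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @return an object of class `GenomeIndex`.
#' @export
genome_index <- function(fasta) {
  seqs <- if (is(fasta, "DNAStringSet")) fasta else {
    Biostrings::readDNAStringSet(fasta)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(
    list(seqs = seqs, lengths = setNames(Biostrings::width(seqs), names(seqs))),
    class = "GenomeIndex"
  )
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$seqs), "sequences,",
      sum(as.numeric(x$lengths)), "bp total\n")
  invisible(x)
}

#' Extract a sequence from a genome index
#'
#' @param gi a `GenomeIndex`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return a character string of length `end - start`.
#' @export
get_sequence <- function(gi, chrom, start, end, strand = "+") {
  stopifnot(is(gi, "GenomeIndex"))
  if (!chrom %in% names(gi$lengths)) {
    stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  }
  len <- gi$lengths[[chrom]]
  if (start < 0L || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) outside %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  }
  s <- Biostrings::subseq(gi$seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# ---------------------------------------------------------------------------
# CTSS

#' Read a CTSS BED file
#'
#' CTSS files are BED6-like with one line per 5' tag position:
#' `chrom start end name count strand` where `end == start + 1` and `count`
#' is a non-negative integer tag count.
#'
#' @param path file path.
#' @param sample_id sample identifier attached to every record.
#' @return a `data.table` with columns `chrom`, `pos`, `strand`, `count`,
#'   `sample_id`.
#' @export
read_ctss <- function(path, sample_id) {
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), count = numeric(),
                      sample_id = character())
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (ncol(dt) < 6L) {
    stop(sprintf("%s: expected >= 6 tab-separated columns, got %d",
                 path, ncol(dt)), call. = FALSE)
  }
  setnames(dt, 1:6, c("chrom", "start", "end", "name", "count", "strand"))
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("%s line %d: %s", path, i[1], msg), call. = FALSE)
    }
  }
  bad(!is.finite(dt$start) | !is.finite(dt$end), "non-numeric coordinates")
  bad(dt$end != dt$start + 1L, "CTSS width must be exactly 1 (end = start+1)")
  bad(!dt$strand %in% c("+", "-"), "strand must be '+' or '-'")
  cnt <- suppressWarnings(as.numeric(dt$count))
  bad(!is.finite(cnt) | cnt != round(cnt) | cnt < 0,
      "count must be a non-negative integer")
  out <- data.table(chrom = dt$chrom, pos = as.integer(dt$start),
                    strand = dt$strand, count = cnt,
                    sample_id = sample_id)
  if (anyDuplicated(out, by = c("chrom", "pos", "strand"))) {
    stop(sprintf("%s: duplicate (chrom, position, strand) records", path),
         call. = FALSE)
  }
  out[]
}

#' Write CTSS records as a CTSS BED file
#'
#' @param records a `data.table` with `chrom`, `pos`, `strand`, `count`.
#' @param path output path.
#' @export
write_ctss <- function(records, path) {
  dt <- as.data.table(records)
  out <- dt[, .(chrom, start = pos, end = pos + 1L, name = ".",
                count = count, strand)]
  setorder(out, chrom, start, strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Generic BED intervals (ChIP peaks, histone marks)

#' Read a BED3+ file as a GRanges
#'
#' Intervals are kept as-is (no merging).  Input is 0-based half-open; the
#' returned `GRanges` uses the usual 1-based closed convention.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges], sorted within chromosome.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L) return(GenomicRanges::GRanges())
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path),
                          call. = FALSE)
  setnames(dt, 1:3, c("chrom", "start", "end"))
  i <- which(dt$start >= dt$end)
  if (length(i)) {
    stop(sprintf("%s line %d: start >= end", path, i[1]), call. = FALSE)
  }
  strand <- if (ncol(dt) >= 6L && all(dt[[6]] %in% c("+", "-", "."))) {
    ifelse(dt[[6]] == ".", "*", dt[[6]])
  } else NULL
  gr <- bed_to_granges(dt$chrom, dt$start, dt$end, strand)
  sort(gr, ignore.strand = TRUE)
}

# ---------------------------------------------------------------------------
# Coverage track (bedGraph)

#' Read a bedGraph coverage track
#'
#' Gaps read as coverage 0.  Intervals on one chromosome must not overlap.
#'
#' @param path bedGraph file: `chrom start end value`.
#' @return an object of class `CoverageTrack`.
#' @export
read_coverage_track <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L) {
    return(structure(list(chroms = list()), class = "CoverageTrack"))
  }
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  if (ncol(dt) < 4L) stop(sprintf("%s: bedGraph needs 4 columns", path),
                          call. = FALSE)
  setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  i <- which(dt$start >= dt$end | !is.finite(dt$value))
  if (length(i)) {
    stop(sprintf("%s line %d: invalid bedGraph record", path, i[1]),
         call. = FALSE)
  }
  setorder(dt, chrom, start)
  chroms <- split(dt, by = "chrom", keep.by = FALSE)
  for (nm in names(chroms)) {
    x <- chroms[[nm]]
    if (any(x$start[-1] < x$end[-nrow(x)])) {
      stop(sprintf("%s: overlapping bedGraph intervals on %s", path, nm),
           call. = FALSE)
    }
  }
  structure(list(chroms = chroms), class = "CoverageTrack")
}

#' Mean coverage over a 0-based half-open interval
#'
#' Positions not covered by any bedGraph record contribute 0.  Chromosomes
#' absent from the track are treated as uncovered, with a warning.
#'
#' @param track a `CoverageTrack`.
#' @param chrom chromosome name (vectorized with `start`/`end`).
#' @param start,end interval bounds, 0-based half-open.
#' @return numeric vector of mean coverages.
#' @export
mean_coverage <- function(track, chrom, start, end) {
  stopifnot(is(track, "CoverageTrack"))
  if (any(start >= end)) stop("zero- or negative-length interval",
                              call. = FALSE)
  n <- length(start)
  chrom <- rep_len(chrom, n)
  out <- numeric(n)
  missing_chrom <- setdiff(unique(chrom), names(track$chroms))
  if (length(missing_chrom) && length(track$chroms)) {
    warning(sprintf("chromosome(s) %s absent from coverage track; coverage 0",
                    paste(missing_chrom, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(n)) {
    x <- track$chroms[[chrom[i]]]
    if (is.null(x)) next
    ov_len <- pmax(0, pmin(x$end, end[i]) - pmax(x$start, start[i]))
    out[i] <- sum(ov_len * x$value) / (end[i] - start[i])
  }
  out
}

#' Write a bedGraph coverage track
#' @param dt a table with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_coverage_track <- function(dt, path) {
  dt <- as.data.table(dt)[, .(chrom, start, end, value)]
  setorder(dt, chrom, start)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene annotation

#' Read a gene annotation (BED6, BED12 or GTF)
#'
#' Retains one canonical record per gene id (the first seen; duplicates are
#' dropped with a warning).  The TSS is the 5' end of the gene span: the
#' `start` field on "+" genes, `end - 1` on "-" genes.
#'
#' @param path annotation file.  `.gtf`/`.gff` files are parsed for `gene`
#'   features (falling back to `transcript`) using the `gene_id`/`gene_name`
#'   attribute; anything else is treated as BED with the gene id in column 4.
#' @return a `data.table` with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss` (all coordinates 0-based half-open).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    ann <- .read_annotation_gtf(path)
  } else {
    ann <- .read_annotation_bed(path)
  }
  if (nrow(ann) == 0L) stop(sprintf("%s: no gene records found", path),
                            call. = FALSE)
  dup <- duplicated(ann$gene_id)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicated gene id(s); keeping first occurrence",
                    path, sum(dup)), call. = FALSE)
    ann <- ann[!dup]
  }
  ann[, tss := ifelse(strand == "+", start, end - 1L)]
  setorder(ann, chrom, start)
  ann[]
}

.read_annotation_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (ncol(dt) < 6L) stop(sprintf("%s: annotation BED needs >= 6 columns", path),
                          call. = FALSE)
  i <- which(dt$V2 >= dt$V3 | !dt$V6 %in% c("+", "-"))
  if (length(i)) stop(sprintf("%s line %d: invalid gene record", path, i[1]),
                      call. = FALSE)
  data.table(gene_id = as.character(dt$V4), chrom = dt$V1, strand = dt$V6,
             start = as.integer(dt$V2), end = as.integer(dt$V3))
}

.read_annotation_gtf <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE, quote = "",
              colClasses = list(character = 1))
  if (ncol(dt) < 9L) stop(sprintf("%s: malformed GTF", path), call. = FALSE)
  feat <- dt[dt$V3 == "gene"]
  if (nrow(feat) == 0L) feat <- dt[dt$V3 == "transcript"]
  attr_get <- function(attrs, key) {
    pat <- sprintf('%s[ =]+"?([^";]+)"?', key)
    m <- regexpr(pat, attrs, perl = TRUE)
    out <- rep(NA_character_, length(attrs))
    hit <- m > 0L
    out[hit] <- sub(pat, "\\1", regmatches(attrs, m), perl = TRUE)
    out
  }
  ids <- attr_get(feat$V9, "gene_id")
  nm <- attr_get(feat$V9, "gene_name")
  ids[!is.na(nm)] <- nm[!is.na(nm)]
  data.table(gene_id = ids, chrom = feat$V1, strand = feat$V7,
             start = as.integer(feat$V4) - 1L, end = as.integer(feat$V5))
}

# ---------------------------------------------------------------------------
# Motifs

#' Read a JASPAR-style PFM collection
#'
#' Accepts the standard JASPAR text layout: a `>id name` header followed by
#' four rows (A, C, G, T) of counts, with or without the letter prefix and
#' square brackets.
#'
#' @param path motif file.
#' @return a named list of motifs; each motif is a list with `id`, `name`
#'   and `pfm` (a 4 x width matrix with rows A, C, G, T).
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop(sprintf("%s: no '>' motif headers", path),
                              call. = FALSE)
  motifs <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L) {
      stop(sprintf("%s: motif block %d must have 4 rows (A,C,G,T)", path, k),
           call. = FALSE)
    }
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) {
      stop(sprintf("%s: ragged PFM in motif block %d", path, k), call. = FALSE)
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0) || any(colSums(pfm) <= 0)) {
      stop(sprintf("%s: motif block %d has invalid PFM counts", path, k),
           call. = FALSE)
    }
    h <- strsplit(sub("^>", "", lines[bounds[k]]), "\\s+")[[1]]
    id <- h[1]
    motifs[[id]] <- list(id = id, name = if (length(h) > 1L) h[2] else id,
                         pfm = pfm)
  }
  motifs
}

#' Write motifs in JASPAR text layout
#' @param motifs list as returned by [read_motifs()].
#' @param path output path.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$pfm[b, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a motif-to-TF mapping table
#'
#' @param path two-column TSV (`motif`, `tf`); a header line is detected and
#'   skipped.
#' @return a `data.table` with columns `motif`, `tf`.
#' @export
read_motif2tf <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop(sprintf("%s: motif2tf needs 2 columns", path),
                          call. = FALSE)
  setnames(dt, 1:2, c("motif", "tf"))
  if (tolower(dt$motif[1]) %in% c("motif", "motif_id")) dt <- dt[-1]
  unique(dt[, .(motif = as.character(motif), tf = as.character(tf))])
}

# ---------------------------------------------------------------------------
# GRN edges and enhancer regions

#' Write a GRN edge table
#'
#' TSV with header `tf<TAB>gene<TAB>interaction_score`, sorted by score
#' descending (ties broken by TF then gene).
#'
#' @param edges table with columns `tf`, `gene`, `interaction_score`.
#' @param path output path.
#' @export
write_grn <- function(edges, path) {
  dt <- as.data.table(edges)
  stopifnot(all(c("tf", "gene", "interaction_score") %in% names(dt)))
  stop_if_not_finite(dt$interaction_score, "interaction_score")
  out <- dt[, .(tf, gene, interaction_score)]
  setorder(out, -interaction_score, tf, gene)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a GRN edge table written by [write_grn()]
#' @param path file path.
#' @export
read_grn <- function(path) {
  dt <- fread(path, sep = "\t")
  stopifnot(all(c("tf", "gene", "interaction_score") %in% names(dt)))
  dt
}

#' Write bidirectional regions as BED6
#'
#' The score column carries the balance score scaled to 0-1000 by
#' `floor(1000 * B)` (capped at 1000).  The written interval is the
#' normalized window when present, otherwise the called extent.
#'
#' @param regions region table (see [call_bidirectional()]).
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  dt <- as.data.table(regions)
  stop_if_not_finite(dt$balance, "balance")
  use_norm <- all(c("norm_start", "norm_end") %in% names(dt))
  out <- data.table(
    chrom = dt$chrom,
    start = if (use_norm) dt$norm_start else dt$start,
    end = if (use_norm) dt$norm_end else dt$end,
    name = dt$region_id %||% sprintf("region_%05d", seq_len(nrow(dt))),
    score = pmin(1000L, as.integer(floor(1000 * dt$balance))),
    strand = "."
  )
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read regions written by [write_regions()]
#' @param path file path.
#' @export
read_regions <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  setnames(dt, 1:6, c("chrom", "start", "end", "region_id", "score", "strand"))
  dt[, balance := score / 1000]
  dt[, .(chrom, start, end, region_id, balance)]
}
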