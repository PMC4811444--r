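# Internal coordinates are 0-based half-open everywhere. VCF (1-based) and
# BED (0-based half-open) are converted at the I/O boundary only.

#' Construct a table of genomic intervals
#'
#' Intervals use the package-internal convention: 0-based start (inclusive),
#' 0-based end (exclusive). Strand is ignored throughout.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, 0-based exclusive; must satisfy `start < end`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chrT", 10, 50)
#' @export
genomic_interval <- function(chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (anyNA(start) || anyNA(end) || anyNA(chrom)) {
    stop("interval coordinates must be non-missing integers")
  }
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed), with an explicit
# seqlevel universe so cross-object comparisons never drop chromosomes.
gi_to_gr <- function(x, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(x$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_gi <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Construct an amplicon panel
#'
#' @param amplicons `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open insert coordinates) and optionally `pool`
#'   (small positive integer multiplex-pool id; defaults to 1).
#' @param n_pools Number of multiplex PCR pools; defaults to `max(pool)`.
#' @return An object of class `amplicon_panel`.
#' @export
amplicon_panel <- function(amplicons, n_pools = NULL) {
  stopifnot(is.data.frame(amplicons),
            all(c("chrom", "start", "end") %in% names(amplicons)))
  if (nrow(amplicons) == 0L) stop("panel must contain at least one amplicon")
  if (is.null(amplicons$pool)) amplicons$pool <- 1L
  amplicons$pool <- as.integer(amplicons$pool)
  invisible(genomic_interval(amplicons$chrom, amplicons$start, amplicons$end))
  if (is.null(n_pools)) n_pools <- max(amplicons$pool)
  if (any(amplicons$pool < 1L | amplicons$pool > n_pools)) {
    stop("pool ids must lie in [1, n_pools]")
  }
  structure(list(amplicons = amplicons[, c("chrom", "start", "end", "pool")],
                 n_pools = as.integer(n_pools)),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("amplicon_panel: %d amplicons in %d pool(s) on %d sequence(s)\n",
              nrow(x$amplicons), x$n_pools, length(unique(x$amplicons$chrom))))
  invisible(x)
}

#' Read an amplicon panel from a BED file
#'
#' BED is 0-based half-open; the optional 4th column is taken as the
#' multiplex pool id (non-numeric names default to pool 1).
#'
#' @param path Path to a BED file.
#' @param n_pools Optional pool count (defaults to the maximum pool id seen).
#' @return An `amplicon_panel`.
#' @export
read_panel_bed <- function(path, n_pools = NULL) {
  if (!file.exists(path)) stop("panel BED not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop("BED needs at least chrom, start, end")
  amp <- data.frame(chrom = as.character(bed[[1L]]),
                    start = as.integer(bed[[2L]]),
                    end = as.integer(bed[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) {
    pool <- suppressWarnings(as.integer(bed[[4L]]))
    amp$pool <- ifelse(is.na(pool), 1L, pool)
  }
  amplicon_panel(amp, n_pools = n_pools)
}

#' Write intervals as BED
#'
#' @param x `data.frame` with `chrom`, `start`, `end` and optional extra
#'   columns (written as BED columns 4+).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merged covered regions of a panel
#'
#' Union of all amplicon inserts, merged into disjoint sorted intervals.
#' Idempotent: merging the merged output changes nothing.
#'
#' @param panel An `amplicon_panel` (or a bare interval `data.frame`).
#' @return `data.frame` of disjoint sorted intervals (`chrom`, `start`, `end`).
#' @export
covered_regions <- function(panel) {
  amp <- if (inherits(panel, "amplicon_panel")) panel$amplicons else panel
  if (nrow(amp) == 0L) stop("panel must contain at least one amplicon")
  gr <- GenomicRanges::reduce(gi_to_gr(amp, seqlevels = sort(unique(amp$chrom))))
  gr <- GenomicRanges::sort(gr)
  gr_to_gi(gr)
}

#' Read a transcript/exon model
#'
#' Tab-separated with a header; required columns `gene`, `transcript_id`,
#' `start`, `end` (0-based half-open coding exon coordinates) and an optional
#' `chrom` column (defaults to the gene symbol, the layout used by the
#' synthetic reference where each gene occupies its own contig).
#'
#' @param path Path to the exon TSV.
#' @return `data.frame` of exons, sorted within transcript, validated to be
#'   non-overlapping.
#' @export
read_exon_table <- function(path) {
  if (!file.exists(path)) stop("exon table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "transcript_id", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$chrom)) tab$chrom <- tab$gene
  validate_exons(tab)
}

validate_exons <- function(exons) {
  invisible(genomic_interval(exons$chrom, exons$start, exons$end))
  exons <- exons[order(exons$gene, exons$start), , drop = FALSE]
  for (tr in split(exons, exons$transcript_id)) {
    if (nrow(tr) > 1L && any(tr$start[-1L] < tr$end[-nrow(tr)])) {
      stop("overlapping exons in transcript ", tr$transcript_id[1L])
    }
  }
  rownames(exons) <- NULL
  exons
}

#' Write a transcript/exon model TSV
#' @param exons Exon `data.frame` as returned by [read_exon_table()].
#' @param path Output path.
#' @export
write_exon_table <- function(exons, path) {
  utils::write.table(
    exons[, intersect(c("gene", "transcript_id", "chrom", "start", "end"),
                      names(exons))],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coding length per gene
#'
#' Sum of coding-exon lengths, the "coding region (bp)" of the panel report.
#'
#' @param exons Exon `data.frame` (columns `gene`, `start`, `end`).
#' @return Named integer vector of coding bp per gene.
#' @export
coding_length <- function(exons) {
  len <- tapply(exons$end - exons$start, exons$gene, sum)
  out <- as.integer(len)
  names(out) <- names(len)
  out
}
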