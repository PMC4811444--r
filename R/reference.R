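#' Read a reference FASTA
#'
#' Sequences are upper-cased and validated to contain IUPAC nucleotide codes
#' only (enforced by the DNA alphabet of [Biostrings::readDNAStringSet()]).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty FASTA record in ", path)
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a reference FASTA
#' @param reference Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_reference <- function(reference, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(reference)) {
    writeLines(paste0(">", nm), con)
    s <- reference[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Find maximal homopolymer runs in one sequence
#'
#' Homopolymer stretches are the dominant indel-error context of
#' flow/semiconductor sequencing chemistry. Only A/C/G/T form runs; any other
#' character (e.g. N) terminates a run.
#'
#' @param sequence A single nucleotide string.
#' @param min_len Minimum run length to report (>= 2).
#' @return `data.frame` with 0-based half-open `start`, `end`, plus `base`
#'   and `length`, sorted by start. Runs are maximal and non-overlapping.
#' @examples
#' find_homopolymers("TTTTTCGGGGA", min_len = 4)
#' @export
find_homopolymers <- function(sequence, min_len = 4L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 2L) stop("min_len must be >= 2")
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(bases) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      base = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(bases)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  data.frame(start = as.integer(start[keep]), end = as.integer(end[keep]),
             base = r$values[keep], length = as.integer(r$lengths[keep]),
             stringsAsFactors = FALSE)
}

#' Homopolymer runs across a whole reference
#'
#' @param reference Named character vector of sequences.
#' @param min_len Minimum run length (>= 2).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `base`,
#'   `length`.
#' @export
homopolymer_runs <- function(reference, min_len = 4L) {
  out <- lapply(names(reference), function(nm) {
    runs <- find_homopolymers(reference[[nm]], min_len)
    if (nrow(runs)) cbind(chrom = nm, runs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), base = character(),
                      length = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Sequence-context configuration
#'
#' Thresholds that operationalize "homopolymer" and "artefact-prone" context:
#' `min_homopolymer_len` (H) is the shortest run treated as a homopolymer
#' stretch; `proximity_window` (D) the distance, in intervening bases, within
#' which a locus counts as near a run; `amplicon_end_margin` (E) the distance
#' from an amplicon insert boundary inside which base calling is considered
#' artefact-prone; `max_hp_indel_len` caps the indel size subject to the
#' homopolymer-indel uncallability rule (single/double base events).
#'
#' @param min_homopolymer_len bp, default 4.
#' @param proximity_window bp, default 3.
#' @param amplicon_end_margin bp, default 5.
#' @param max_hp_indel_len bp, default 2.
#' @return List of class `context_config`.
#' @export
context_config <- function(min_homopolymer_len = 4L, proximity_window = 3L,
                           amplicon_end_margin = 5L, max_hp_indel_len = 2L) {
  cfg <- list(min_homopolymer_len = as.integer(min_homopolymer_len),
              proximity_window = as.integer(proximity_window),
              amplicon_end_margin = as.integer(amplicon_end_margin),
              max_hp_indel_len = as.integer(max_hp_indel_len))
  if (any(vapply(cfg, function(x) is.na(x) || x < 1L, logical(1L)))) {
    stop("all context_config values must be positive integers")
  }
  structure(cfg, class = "context_config")
}

#' Annotate loci with callability-relevant sequence context
#'
#' For each locus the flags are: `uncovered` (not fully inside the union of
#' amplicon inserts), `in_homopolymer` (overlaps a run), `near_homopolymer`
#' (at most `proximity_window` intervening bases from the nearest run;
#' overlap counts as distance 0, so `in_homopolymer` implies
#' `near_homopolymer`), and `near_amplicon_end` (the locus is within
#' `amplicon_end_margin` bp of the boundary of every single insert that fully
#' contains it; a covered locus contained in no single insert — i.e. one that
#' straddles two inserts — is flagged as well).
#'
#' @param loci Interval `data.frame` (`chrom`, `start`, `end`), 0-based
#'   half-open; one row per locus.
#' @param panel An `amplicon_panel`.
#' @param runs Homopolymer run table from [homopolymer_runs()], computed with
#'   `min_len = config$min_homopolymer_len` on the same reference.
#' @param config A [context_config()].
#' @param reference Optional named reference vector; when given, loci on
#'   sequences absent from it are an error (otherwise the panel's sequence
#'   names are used for the check).
#' @return `data.frame` of logical flags `uncovered`, `in_homopolymer`,
#'   `near_homopolymer`, `near_amplicon_end`, one row per locus.
#' @export
annotate_context <- function(loci, panel, runs, config = context_config(),
                             reference = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"))
  amp <- panel$amplicons
  known <- if (!is.null(reference)) names(reference) else unique(amp$chrom)
  bad <- setdiff(unique(loci$chrom), known)
  if (length(bad)) {
    stop("locus sequence name(s) absent from the panel's reference: ",
         paste(bad, collapse = ", "))
  }
  lv <- sort(unique(c(loci$chrom, amp$chrom, runs$chrom)))
  lg <- gi_to_gr(loci, seqlevels = lv)
  ag <- gi_to_gr(amp, seqlevels = lv)
  n <- length(lg)

  covered <- IRanges::overlapsAny(lg, GenomicRanges::reduce(ag),
                                  type = "within")

  hits <- GenomicRanges::findOverlaps(lg, ag, type = "within")
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  margin <- pmin(loci$start[qi] - amp$start[si], amp$end[si] - loci$end[qi])
  # a locus escapes the flag only if some containing insert holds it interior
  interior <- rep(FALSE, n)
  interior[unique(qi[margin >= config$amplicon_end_margin])] <- TRUE
  near_end <- covered & !interior

  if (nrow(runs)) {
    rg <- gi_to_gr(runs, seqlevels = lv)
    in_hp <- IRanges::overlapsAny(lg, rg)
    d <- GenomicRanges::distanceToNearest(lg, rg)
    dist <- rep(Inf, n)
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    near_hp <- dist <= config$proximity_window
  } else {
    in_hp <- near_hp <- rep(FALSE, n)
  }

  data.frame(uncovered = !covered, in_homopolymer = in_hp,
             near_homopolymer = near_hp, near_amplicon_end = near_end)
}
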