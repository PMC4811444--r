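# Sanger workload planning: whole-gene sequencing estimates and minimal
# rescue sets for panel blind spots. A rescue reaction reads ~150 bp of
# target, so covering a set of point loci is a minimum fixed-length window
# cover, solved exactly by the left-to-right greedy.

#' Sanger planning configuration
#' @param reaction_len Readable target length of one reaction, bp
#'   (default 150).
#' @return List of class `plan_config`.
#' @export
plan_config <- function(reaction_len = 150L) {
  reaction_len <- as.integer(reaction_len)
  if (is.na(reaction_len) || reaction_len < 1L) {
    stop("reaction_len must be a positive integer")
  }
  structure(list(reaction_len = reaction_len), class = "plan_config")
}

#' Reactions needed to Sanger-sequence a whole gene
#'
#' One reaction per `reaction_len` bp of exon, counted per exon: an exon
#' shorter than `reaction_len` takes one reaction, a longer one
#' `ceiling(length / reaction_len)`.
#'
#' @param exons Exon `data.frame` (columns `start`, `end`) for one gene, or
#'   a numeric vector of exon lengths.
#' @param config A [plan_config()].
#' @return Integer reaction count.
#' @examples
#' full_gene_reactions(c(100, 50))   # 2
#' full_gene_reactions(3426)         # 23
#' @export
full_gene_reactions <- function(exons, config = plan_config()) {
  len <- if (is.data.frame(exons)) exons$end - exons$start else exons
  if (length(len) == 0L) stop("transcript must have at least one exon")
  L <- config$reaction_len
  sum(ifelse(len < L, 1L, ceiling(len / L)))
}

#' Minimal Sanger rescue set for blind-spot loci on one sequence
#'
#' Computes the minimum number of fixed-length windows covering all loci
#' with the left-to-right greedy (place a window at each leftmost uncovered
#' locus), which is exact for fixed-length point covering. Duplicate loci
#' are deduplicated silently.
#'
#' @param loci Integer vector of 0-based positions on one sequence.
#' @param config A [plan_config()].
#' @return List of class `sanger_plan`: `reactions` (interval `data.frame`),
#'   `n_reactions`, `covered_loci`.
#' @export
rescue_reactions <- function(loci, config = plan_config()) {
  if (length(loci) == 0L) stop("loci must be non-empty")
  loci <- sort(unique(as.integer(loci)))
  L <- config$reaction_len
  starts <- integer(0L)
  horizon <- -1L
  for (p in loci) {
    if (p > horizon) {
      starts <- c(starts, p)
      horizon <- p + L - 1L
    }
  }
  structure(list(reactions = data.frame(start = starts, end = starts + L),
                 n_reactions = length(starts),
                 covered_loci = length(loci)),
            class = "sanger_plan")
}

#' @export
print.sanger_plan <- function(x, ...) {
  cat(sprintf("sanger_plan: %d reaction(s) covering %d locus/loci\n",
              x$n_reactions, x$covered_loci))
  invisible(x)
}

#' Rescue plan over multiple sequences
#'
#' @param loci `data.frame` with columns `chrom` and `pos` (0-based).
#' @param config A [plan_config()].
#' @return List with per-chrom `sanger_plan`s, total `n_reactions`, and a
#'   BED-ready `reactions` table.
#' @export
rescue_reactions_by_chrom <- function(loci, config = plan_config()) {
  stopifnot(all(c("chrom", "pos") %in% names(loci)))
  plans <- lapply(split(loci$pos, loci$chrom), rescue_reactions,
                  config = config)
  reactions <- do.call(rbind, lapply(names(plans), function(nm) {
    cbind(chrom = nm, plans[[nm]]$reactions, stringsAsFactors = FALSE)
  }))
  list(plans = plans,
       n_reactions = sum(vapply(plans, `[[`, integer(1L), "n_reactions")),
       reactions = reactions)
}

#' Write a rescue plan as BED plus a count summary line
#' @param plan Output of [rescue_reactions_by_chrom()].
#' @param path Output BED path (the summary goes to a `.summary.txt`
#'   sibling file).
#' @export
write_plan_bed <- function(plan, path) {
  write_bed(plan$reactions, path)
  writeLines(sprintf("n_reactions\t%d", plan$n_reactions),
             paste0(path, ".summary.txt"))
  invisible(path)
}
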