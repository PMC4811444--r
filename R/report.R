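# The panel report: per-gene catalogue counts, callability tiers, panel
# sensitivity, Sanger workload, and overall composition/specificity. All
# percentages are rounded half-up (1 decimal for rates, integers for cohort
# fractions); half-up is applied uniformly even where published tables mix
# rounding conventions.

#' Round half-up
#'
#' `round()` in R rounds half to even; panel reports conventionally round
#' half away from zero, so 0.05 -> 0.1 at one decimal. A tiny epsilon guards
#' against binary representation of decimal halves.
#'
#' @param x Numeric vector (non-negative use is assumed).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Panel sensitivity
#'
#' Fraction of catalogue variants the assay could detect
#' (callable / total), as a percentage rounded half-up to one decimal.
#'
#' @param n_total Catalogue size (> 0).
#' @param n_uncallable Number of uncallable variants.
#' @return Percentage.
#' @examples
#' sensitivity(6953, 65)  # 99.1
#' @export
sensitivity <- function(n_total, n_uncallable) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_uncallable < 0 | n_uncallable > n_total)) {
    stop("n_uncallable must lie in [0, n_total]")
  }
  round_half_up(100 * (n_total - n_uncallable) / n_total, 1L)
}

#' Tier and reason composition of an audit
#'
#' Percentages of AUTOMATIC / REVIEW / UNCALLABLE variants, the combined
#' "challenging" fraction (REVIEW + UNCALLABLE), and the uncallable
#' sub-reasons: homopolymer indels and unamplifiable (not covered) loci.
#' All percentages are over the full catalogue, rounded half-up to one
#' decimal.
#'
#' @param results Audit `data.frame` from [audit_catalogue()] (columns
#'   `tier`, `reasons`).
#' @return Named list of counts (`n_*`) and percentages (`pct_*`).
#' @export
composition <- function(results) {
  if (nrow(results) == 0L) stop("results must be non-empty")
  n <- nrow(results)
  n_auto <- sum(results$tier == "AUTOMATIC")
  n_review <- sum(results$tier == "REVIEW")
  n_unc <- sum(results$tier == "UNCALLABLE")
  unc <- results$tier == "UNCALLABLE"
  n_hp <- sum(unc & grepl("homopolymer_indel", results$reasons))
  n_gap <- sum(unc & grepl("not_covered", results$reasons))
  list(n_total = n, n_automatic = n_auto, n_review = n_review,
       n_uncallable = n_unc, n_hp_indel = n_hp, n_unamplifiable = n_gap,
       pct_automatic = round_half_up(100 * n_auto / n, 1L),
       pct_review = round_half_up(100 * n_review / n, 1L),
       pct_uncallable = round_half_up(100 * n_unc / n, 1L),
       pct_challenging = round_half_up(100 * (n_review + n_unc) / n, 1L),
       pct_hp_indel = round_half_up(100 * n_hp / n, 1L),
       pct_unamplifiable = round_half_up(100 * n_gap / n, 1L))
}

#' Confirmation-based specificity
#'
#' Specificity in the orthogonal-confirmation sense: the fraction of
#' reported variants confirmed by an independent method (not the
#' epidemiological true-negative rate). With nothing reported the value is
#' not applicable and `NA` is returned.
#'
#' @param n_reported Variants reported by the assay.
#' @param n_confirmed Of those, variants confirmed orthogonally.
#' @return Percentage rounded half-up to one decimal, or `NA` when
#'   `n_reported` is 0.
#' @examples
#' specificity(13, 13)  # 100
#' @export
specificity <- function(n_reported, n_confirmed) {
  if (n_confirmed < 0 || n_confirmed > n_reported) {
    stop("n_confirmed must lie in [0, n_reported]")
  }
  if (n_reported == 0) return(NA_real_)
  round_half_up(100 * n_confirmed / n_reported, 1L)
}

#' Build the panel report
#'
#' Aggregates the audit, catalogue, transcript model and Sanger planning
#' into one table with a row per gene and a Total row: coding bp, per-source
#' catalogue counts, total variants, whole-gene Sanger estimate, tier counts
#' and sensitivity. Overall composition, specificity and the blind-spot
#' rescue workload are attached as the `overall` element.
#'
#' @param audit Audit `data.frame` from [audit_catalogue()].
#' @param catalogue The audited `catalogue`.
#' @param exons Exon `data.frame` covering every gene in the audit.
#' @param config A [plan_config()].
#' @param confirmations Optional `data.frame` with columns `key` and logical
#'   `confirmed` (orthogonal confirmation of reported variants).
#' @param rescue Optional precomputed output of
#'   [rescue_reactions_by_chrom()]; computed from the audit's UNCALLABLE
#'   loci when `NULL`.
#' @return Object of class `panel_report`: list with `table` (per-gene +
#'   Total rows) and `overall`.
#' @export
build_report <- function(audit, catalogue, exons, config = plan_config(),
                         confirmations = NULL, rescue = NULL) {
  genes <- sort(unique(audit$gene))
  missing <- setdiff(genes, unique(exons$gene))
  if (length(missing)) {
    stop("gene(s) in audit but absent from transcripts: ",
         paste(missing, collapse = ", "))
  }
  cv <- catalogue$variants
  cbp <- coding_length(exons)
  rows <- lapply(genes, function(g) {
    a <- audit[audit$gene == g, , drop = FALSE]
    v <- cv[cv$gene == g, , drop = FALSE]
    ex <- exons[exons$gene == g, , drop = FALSE]
    data.frame(
      gene = g,
      coding_bp = unname(cbp[g]),
      n_germline_db = sum(v$in_germline_db),
      n_somatic_db = sum(v$in_somatic_db),
      n_total = nrow(a),
      n_sanger_full_gene = full_gene_reactions(ex, config),
      n_automatic = sum(a$tier == "AUTOMATIC"),
      n_review = sum(a$tier == "REVIEW"),
      n_uncallable = sum(a$tier == "UNCALLABLE"),
      sensitivity_pct = sensitivity(nrow(a), sum(a$tier == "UNCALLABLE")),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(
    gene = "Total", coding_bp = sum(tab$coding_bp),
    n_germline_db = sum(tab$n_germline_db),
    n_somatic_db = sum(tab$n_somatic_db),
    n_total = sum(tab$n_total),
    n_sanger_full_gene = sum(tab$n_sanger_full_gene),
    n_automatic = sum(tab$n_automatic), n_review = sum(tab$n_review),
    n_uncallable = sum(tab$n_uncallable),
    sensitivity_pct = sensitivity(sum(tab$n_total), sum(tab$n_uncallable)),
    stringsAsFactors = FALSE)
  tab <- rbind(tab, total)
  rownames(tab) <- NULL

  overall <- composition(audit)
  if (is.null(rescue)) {
    unc <- audit[audit$tier == "UNCALLABLE", , drop = FALSE]
    rescue <- if (nrow(unc)) {
      rescue_reactions_by_chrom(
        data.frame(chrom = unc$chrom, pos = unc$start), config)
    }
  }
  overall$n_rescue_reactions <- if (is.null(rescue)) 0L
                                else rescue$n_reactions
  if (!is.null(confirmations)) {
    overall$n_reported <- nrow(confirmations)
    overall$n_confirmed <- sum(confirmations$confirmed)
    overall$specificity_pct <- specificity(overall$n_reported,
                                           overall$n_confirmed)
  } else {
    overall$n_reported <- NA_integer_
    overall$n_confirmed <- NA_integer_
    overall$specificity_pct <- NA_real_
  }
  structure(list(table = tab, overall = overall), class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Panel callability report",
      "(specificity = confirmed fraction of reported variants)\n\n")
  print(x$table, row.names = FALSE)
  o <- x$overall
  cat(sprintf(
    "\ncomposition: automatic %.1f%% | review %.1f%% | uncallable %.1f%%",
    o$pct_automatic, o$pct_review, o$pct_uncallable))
  cat(sprintf(
    "\nchallenging %.1f%% (homopolymer indel %.1f%%, unamplifiable %.1f%%)",
    o$pct_challenging, o$pct_hp_indel, o$pct_unamplifiable))
  cat(sprintf("\nblind-spot rescue reactions: %d", o$n_rescue_reactions))
  if (!is.na(o$specificity_pct)) {
    cat(sprintf("\nspecificity: %.1f%% (%d/%d confirmed)",
                o$specificity_pct, o$n_confirmed, o$n_reported))
  }
  cat("\n")
  invisible(x)
}

#' Write the panel report
#'
#' `write_report_tsv` writes the per-gene table as TSV with the overall
#' metrics appended as `# key value` comment lines; `write_report_json`
#' writes the full report (table + overall reason breakdown) as JSON.
#'
#' @param report A `panel_report`.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "panel_report"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  o <- report$overall
  writeLines(sprintf("# %s\t%s", names(o),
                     vapply(o, function(v) as.character(v), character(1L))),
             con)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "panel_report"))
  jsonlite::write_json(list(table = report$table, overall = report$overall),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a confirmation table
#'
#' Two columns: variant `key` and `confirmed` (yes/no or TRUE/FALSE).
#'
#' @param path File path.
#' @return `data.frame` with `key` and logical `confirmed`.
#' @export
read_confirmations_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$confirmed <- tolower(as.character(tab$confirmed)) %in%
    c("yes", "true", "1", "y")
  tab
}
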