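# Classification of observed tumour/normal variants: mutation type from
# HGVS, pathogenicity from a small rule set (premature stop codons are
# pathogenic for BRCA genes), germline vs somatic origin from the matched
# normal VAF.

MUTATION_TYPES <- c("frameshift", "nonsense", "missense", "inframe_deletion",
                    "synonymous", "other")
CLASSIFICATIONS <- c("pathogenic", "likely_pathogenic_same_codon", "benign",
                     "VUS")

AA3 <- "(Ter|[A-Z][a-z]{2})"

# Parse a protein HGVS string into (kind, codon). Covers the constructs of
# this problem space -- substitutions (incl. Ter), fs, del, dup, delins, "=".
# Anything else errors loudly rather than guessing.
parse_hgvs_p <- function(s) {
  x <- sub("^p\\.", "", trimws(s))
  x <- sub("^\\((.*)\\)$", "\\1", x)  # p.(Xxx123Yyy) form
  m <- regexec(paste0("^", AA3, "([0-9]+)", AA3, "fs(Ter([0-9]+|\\?))?$"), x)
  g <- regmatches(x, m)[[1L]]
  if (length(g)) {
    return(list(kind = "frameshift", codon = as.integer(g[3L])))
  }
  m <- regexec(paste0("^", AA3, "([0-9]+)(", AA3, "|=|\\*)$"), x)
  g <- regmatches(x, m)[[1L]]
  if (length(g)) {
    ref <- g[2L]; codon <- as.integer(g[3L]); alt <- g[4L]
    kind <- if (alt == "=" || alt == ref) "synonymous"
            else if (alt == "Ter" || alt == "*") "nonsense"
            else "missense"
    return(list(kind = kind, codon = codon))
  }
  m <- regexec(paste0("^", AA3, "([0-9]+)(_", AA3, "([0-9]+))?",
                      "(del|dup|delins", AA3, "*)$"), x)
  g <- regmatches(x, m)[[1L]]
  if (length(g)) {
    op <- g[7L]
    kind <- if (op == "del") "inframe_deletion" else "other"
    return(list(kind = kind, codon = as.integer(g[3L])))
  }
  stop("unparseable protein HGVS token: ", s)
}

# Minimal coding-HGVS parse used when no protein annotation is available.
parse_hgvs_c <- function(s) {
  x <- sub("^c\\.", "", trimws(s))
  m <- regexec("^([0-9]+)([ACGT])>([ACGT])$", x)
  if (length(regmatches(x, m)[[1L]])) {
    return(list(kind = "substitution", len = 1L))
  }
  m <- regexec("^([0-9]+)(_([0-9]+))?(del|dup)([ACGT]*)$", x)
  g <- regmatches(x, m)[[1L]]
  if (length(g)) {
    from <- as.integer(g[2L])
    to <- if (g[4L] == "") from else as.integer(g[4L])
    return(list(kind = g[5L], len = to - from + 1L))
  }
  m <- regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", x)
  g <- regmatches(x, m)[[1L]]
  if (length(g)) return(list(kind = "ins", len = nchar(g[4L])))
  m <- regexec("^([0-9]+)(_([0-9]+))?delins([ACGT]+)$", x)
  g <- regmatches(x, m)[[1L]]
  if (length(g)) {
    from <- as.integer(g[2L])
    to <- if (g[4L] == "") from else as.integer(g[4L])
    return(list(kind = "delins", len = nchar(g[5L]) - (to - from + 1L)))
  }
  stop("unparseable coding HGVS token: ", s)
}

#' Classify the mutation type of an observed variant
#'
#' Protein HGVS drives the call: `fs` means frameshift, a substitution to
#' `Ter` nonsense, `del` without `fs` an in-frame deletion, a single-residue
#' substitution missense, `=` synonymous. When only coding HGVS is
#' available, indels are typed by length modulo 3 (frameshift vs in-frame);
#' substitutions without protein annotation are `other`.
#'
#' @param hgvs_p Protein HGVS string (may be empty/`NA`).
#' @param hgvs_c Coding HGVS string (may be empty/`NA`).
#' @return One of `frameshift`, `nonsense`, `missense`, `inframe_deletion`,
#'   `synonymous`, `other`.
#' @examples
#' classify_mutation_type("p.Gln1777ProfsTer74")  # frameshift
#' classify_mutation_type("p.Gln563Ter")          # nonsense
#' classify_mutation_type("p.Val1709del")         # inframe_deletion
#' classify_mutation_type("p.Pro1770Leu")         # missense
#' @export
classify_mutation_type <- function(hgvs_p = NA, hgvs_c = NA) {
  has_p <- !is.na(hgvs_p) && nzchar(hgvs_p) && hgvs_p != "p.?"
  has_c <- !is.na(hgvs_c) && nzchar(hgvs_c)
  if (!has_p && !has_c) stop("need at least one HGVS string")
  if (has_p) return(parse_hgvs_p(hgvs_p)$kind)
  p <- parse_hgvs_c(hgvs_c)
  switch(p$kind,
         substitution = "other",
         delins = if (p$len %% 3L != 0L) "frameshift" else "other",
         del = if (p$len %% 3L != 0L) "frameshift" else "inframe_deletion",
         dup = ,
         ins = if (p$len %% 3L != 0L) "frameshift" else "other")
}

# Submitter-entry counts from per-source significance strings ("|"-joined).
sig_counts <- function(...) {
  entries <- tolower(unlist(strsplit(stats::na.omit(c(...)), "[|;,]")))
  entries <- trimws(entries)
  c(pathogenic = sum(grepl("pathogenic", entries) & !grepl("benign", entries)),
    benign = sum(grepl("benign", entries)))
}

#' Classify pathogenicity of observed variants
#'
#' Rule order: (1) a catalogue record whose submitter entries are
#' majority-pathogenic makes the variant pathogenic; (2) frameshift or
#' nonsense mutations are pathogenic (premature stop codon); (3) an
#' unrecorded missense sharing its protein codon with a recorded pathogenic
#' missense is `likely_pathogenic_same_codon`; (4) population allele
#' frequency >= 1\% with majority-benign submitter entries is benign; (5)
#' everything else is a VUS. The rules form a total function: every variant
#' receives exactly one classification.
#'
#' @param observed `data.frame` of observed variants with columns
#'   `gene`, `hgvs_c`, `hgvs_p` (and anything else, carried through).
#' @param mutation_type Character vector from [classify_mutation_type()]
#'   (computed from the HGVS columns when omitted).
#' @param catalogue A `catalogue` object or a plain `data.frame` of known
#'   variants with columns `gene`, `hgvs_c`, `hgvs_p`, `sig_germline`,
#'   `sig_somatic`, `population_af`.
#' @return Character vector of classifications.
#' @export
classify_pathogenicity <- function(observed, mutation_type = NULL,
                                   catalogue = NULL) {
  known <- if (inherits(catalogue, "catalogue")) catalogue$variants
           else if (is.null(catalogue)) {
             data.frame(gene = character(), hgvs_c = character(),
                        hgvs_p = character(), sig_germline = character(),
                        sig_somatic = character(), population_af = numeric(),
                        stringsAsFactors = FALSE)
           } else catalogue
  if (is.null(mutation_type)) {
    mutation_type <- mapply(classify_mutation_type, observed$hgvs_p,
                            observed$hgvs_c, USE.NAMES = FALSE)
  }
  kc <- t(vapply(seq_len(nrow(known)), function(i) {
    sig_counts(known$sig_germline[i], known$sig_somatic[i])
  }, numeric(2L)))
  if (nrow(known) == 0L) kc <- matrix(0, 0L, 2L)
  k_path_major <- nrow(known) > 0 & kc[, 1L] > kc[, 2L] & kc[, 1L] > 0
  k_benign_major <- nrow(known) > 0 & kc[, 2L] > kc[, 1L]
  k_codon <- vapply(known$hgvs_p, function(p) {
    if (is.na(p) || !nzchar(p)) return(NA_integer_)
    tryCatch(parse_hgvs_p(p)$codon, error = function(e) NA_integer_)
  }, integer(1L), USE.NAMES = FALSE)
  k_missense <- vapply(known$hgvs_p, function(p) {
    if (is.na(p) || !nzchar(p)) return(FALSE)
    tryCatch(parse_hgvs_p(p)$kind == "missense", error = function(e) FALSE)
  }, logical(1L), USE.NAMES = FALSE)

  n <- nrow(observed)
  out <- character(n)
  for (i in seq_len(n)) {
    hit <- which(known$gene == observed$gene[i] &
                 !is.na(known$hgvs_c) & !is.na(observed$hgvs_c[i]) &
                 known$hgvs_c == observed$hgvs_c[i])
    matched <- length(hit) > 0L
    af <- if (matched) known$population_af[hit[1L]] else NA_real_
    if (matched && any(k_path_major[hit])) {
      out[i] <- "pathogenic"
    } else if (mutation_type[i] %in% c("frameshift", "nonsense")) {
      out[i] <- "pathogenic"
    } else if (mutation_type[i] == "missense" && !matched &&
               same_codon_pathogenic(observed$hgvs_p[i], observed$gene[i],
                                     known, k_codon, k_missense,
                                     k_path_major)) {
      out[i] <- "likely_pathogenic_same_codon"
    } else if (!is.na(af) && af >= 0.01 && matched &&
               any(k_benign_major[hit])) {
      out[i] <- "benign"
    } else {
      out[i] <- "VUS"
    }
  }
  out
}

same_codon_pathogenic <- function(hgvs_p, gene, known, k_codon, k_missense,
                                  k_path_major) {
  if (is.na(hgvs_p) || !nzchar(hgvs_p)) return(FALSE)
  codon <- tryCatch(parse_hgvs_p(hgvs_p)$codon, error = function(e) NA)
  if (is.na(codon)) return(FALSE)
  any(known$gene == gene & k_missense & !is.na(k_codon) & k_codon == codon &
      k_path_major)
}

#' Thresholds for germline/somatic assignment from matched normal DNA
#'
#' @param germline_min_normal_vaf Normal-tissue VAF at or above which a
#'   variant is constitutional (default 0.20, well below the heterozygous
#'   expectation of 0.5).
#' @param somatic_max_normal_vaf Normal VAF at or below which the variant is
#'   absent from the germline (default 0.05, the sequencing-noise ceiling).
#' @param homozygous_min_tumour_vaf Tumour VAF at or above which the tumour
#'   is homozygous for the variant or has lost the wild-type allele
#'   (default 0.85).
#' @return List of class `origin_config`.
#' @export
origin_config <- function(germline_min_normal_vaf = 0.20,
                          somatic_max_normal_vaf = 0.05,
                          homozygous_min_tumour_vaf = 0.85) {
  if (somatic_max_normal_vaf >= germline_min_normal_vaf) {
    stop("somatic_max_normal_vaf must be below germline_min_normal_vaf")
  }
  structure(list(germline_min_normal_vaf = germline_min_normal_vaf,
                 somatic_max_normal_vaf = somatic_max_normal_vaf,
                 homozygous_min_tumour_vaf = homozygous_min_tumour_vaf),
            class = "origin_config")
}

#' Assign germline/somatic origin and tumour zygosity
#'
#' A variant present in matched normal DNA at heterozygous-like VAF is
#' germline; one absent from the normal is somatic; in-between (or unknown
#' normal) is undetermined. A tumour VAF at or above
#' `homozygous_min_tumour_vaf` marks homozygosity or loss of the wild-type
#' allele (LOH), the pattern of a germline-heterozygous variant whose tumour
#' lost the other allele.
#'
#' @param tumour_vaf,normal_vaf Numeric vectors of VAFs (normal may be `NA`).
#' @param config An [origin_config()].
#' @return `data.frame` with `origin` (germline/somatic/undetermined) and
#'   `tumour_zygosity` (heterozygous/homozygous_or_LOH).
#' @export
assign_origin <- function(tumour_vaf, normal_vaf,
                          config = origin_config()) {
  if (anyNA(tumour_vaf)) stop("tumour VAF must be present")
  origin <- ifelse(is.na(normal_vaf), "undetermined",
            ifelse(normal_vaf >= config$germline_min_normal_vaf, "germline",
            ifelse(normal_vaf <= config$somatic_max_normal_vaf, "somatic",
                   "undetermined")))
  zyg <- ifelse(tumour_vaf >= config$homozygous_min_tumour_vaf,
                "homozygous_or_LOH", "heterozygous")
  data.frame(origin = origin, tumour_zygosity = zyg,
             stringsAsFactors = FALSE)
}

#' Summarize pathogenic findings over a cohort
#'
#' A sample counts as mutated when it carries at least one call classified
#' `pathogenic` or `likely_pathogenic_same_codon`. Reports the mutated
#' fraction (percentage rounded half-up to an integer), per-gene mutated
#' sample counts, and whether mutations in different genes were mutually
#' exclusive across samples.
#'
#' @param calls `data.frame` with columns `sample_id`, `gene`,
#'   `classification`.
#' @param cohort_size Total number of samples assayed (>= number of distinct
#'   `sample_id`s).
#' @return List with `n_mutated_samples`, `per_gene` (named counts),
#'   `pct_mutated`, `mutually_exclusive`.
#' @export
cohort_summary <- function(calls, cohort_size) {
  n_samples <- length(unique(calls$sample_id))
  if (cohort_size < n_samples) {
    stop("cohort_size is smaller than the number of distinct samples")
  }
  hit <- calls$classification %in% c("pathogenic",
                                     "likely_pathogenic_same_codon")
  mut <- unique(calls[hit, c("sample_id", "gene")])
  n_mut <- length(unique(mut$sample_id))
  per_gene <- vapply(split(mut$sample_id, mut$gene),
                     function(s) length(unique(s)), integer(1L))
  excl <- !any(table(mut$sample_id) > 1L)
  list(n_mutated_samples = n_mut,
       per_gene = per_gene,
       pct_mutated = round_half_up(100 * n_mut / cohort_size, 0L),
       mutually_exclusive = excl)
}

#' Read observed variants from TSV
#'
#' Expected columns: `sample_id`, `gene`, `hgvs_c`, `hgvs_p`, `tumour_vaf`,
#' `normal_vaf`.
#'
#' @param path File path.
#' @return `data.frame` of observed variants.
#' @export
read_observed_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write pathogenicity calls as a case-table-shaped TSV
#'
#' @param calls `data.frame` with sample, gene, HGVS, mutation type, origin
#'   and classification columns.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- intersect(c("sample_id", "gene", "hgvs_c", "hgvs_p",
                      "mutation_type", "origin", "tumour_zygosity",
                      "classification"), names(calls))
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
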