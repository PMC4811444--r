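# Variant catalogues (ClinVar-like germline and COSMIC-like somatic) are kept
# in one canonical representation so records from both databases unify:
# 0-based start, alleles in VCF-anchored form after left-normalization
# (SNVs fully trimmed, indels keep one shared leading base). The dedup key is
# (chrom, start, ref, alt).

SOURCE_TAGS <- c("GERMLINE_DB", "SOMATIC_DB")

variant_key <- function(chrom, start, ref, alt) {
  paste(chrom, start, ref, alt, sep = ":")
}

#' Infer the variant type from its canonical alleles
#'
#' @param ref,alt Allele strings (VCF-anchored canonical form).
#' @return Character vector over `SNV`, `INS`, `DEL`, `DELINS`.
#' @export
infer_var_type <- function(ref, alt) {
  rl <- nchar(ref); al <- nchar(alt)
  type <- rep("DELINS", length(ref))
  type[rl == 1L & al == 1L] <- "SNV"
  ins <- al > rl & substr(alt, 1L, rl) == ref
  del <- rl > al & substr(ref, 1L, al) == alt
  type[ins] <- "INS"
  type[del] <- "DEL"
  type
}

#' Construct a variant catalogue
#'
#' @param variants `data.frame` with at least `chrom`, `start` (0-based),
#'   `ref`, `alt`, `gene`. Optional: `var_type` (inferred when missing),
#'   logical source flags `in_germline_db` / `in_somatic_db`, per-source
#'   significance strings `sig_germline` / `sig_somatic` (submitter entries
#'   joined with `|`), `population_af` (fraction in \[0,1\], `NA` = unknown),
#'   `hgvs_c`, `hgvs_p`.
#' @param reference Optional named reference vector; when supplied, each
#'   `ref` allele is checked against the reference sequence at its locus.
#' @param source When given (one of `GERMLINE_DB`, `SOMATIC_DB`), the whole
#'   catalogue is tagged with that source.
#' @return Object of class `catalogue`: list with element `variants` and the
#'   per-source counts available via [per_source_counts()].
#' @export
catalogue <- function(variants, reference = NULL, source = NULL) {
  need <- c("chrom", "start", "ref", "alt", "gene")
  if (!all(need %in% names(variants))) {
    stop("catalogue variants need columns: ", paste(need, collapse = ", "))
  }
  v <- variants
  v$chrom <- as.character(v$chrom)
  v$start <- as.integer(v$start)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  v$gene <- as.character(v$gene)
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  if (any(nchar(v$ref) > 101L | nchar(v$alt) > 101L)) {
    stop("indels longer than 100 bp are out of catalogue scope")
  }
  if (!is.null(source)) {
    source <- match.arg(source, SOURCE_TAGS)
    v$in_germline_db <- source == "GERMLINE_DB"
    v$in_somatic_db <- source == "SOMATIC_DB"
  }
  if (is.null(v$in_germline_db)) v$in_germline_db <- FALSE
  if (is.null(v$in_somatic_db)) v$in_somatic_db <- FALSE
  if (is.null(v$sig_germline)) v$sig_germline <- NA_character_
  if (is.null(v$sig_somatic)) v$sig_somatic <- NA_character_
  if (is.null(v$population_af)) v$population_af <- NA_real_
  if (is.null(v$hgvs_c)) v$hgvs_c <- NA_character_
  if (is.null(v$hgvs_p)) v$hgvs_p <- NA_character_
  v$var_type <- infer_var_type(v$ref, v$alt)
  if (!is.null(reference)) {
    obs <- reference_slice(reference, v$chrom, v$start, v$start + nchar(v$ref))
    if (any(obs != v$ref)) {
      stop(sum(obs != v$ref), " variant(s) whose ref allele disagrees with ",
           "the reference sequence")
    }
  }
  key <- variant_key(v$chrom, v$start, v$ref, v$alt)
  if (anyDuplicated(key)) {
    stop("duplicate variant keys in catalogue: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = ", "))
  }
  v <- v[order(v$chrom, v$start, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  structure(list(variants = v), class = "catalogue")
}

reference_slice <- function(reference, chrom, start, end) {
  out <- character(length(chrom))
  for (nm in unique(chrom)) {
    i <- chrom == nm
    if (is.null(reference[[nm]])) stop("sequence absent from reference: ", nm)
    out[i] <- substring(reference[[nm]], start[i] + 1L, end[i])
  }
  out
}

#' Per-source variant counts of a catalogue
#' @param x A `catalogue`.
#' @return Named integer vector over the source tags.
#' @export
per_source_counts <- function(x) {
  stopifnot(inherits(x, "catalogue"))
  c(GERMLINE_DB = sum(x$variants$in_germline_db),
    SOMATIC_DB = sum(x$variants$in_somatic_db))
}

#' @export
print.catalogue <- function(x, ...) {
  cnt <- per_source_counts(x)
  cat(sprintf(
    "catalogue: %d variants (%d germline-db, %d somatic-db) in %d gene(s)\n",
    nrow(x$variants), cnt[["GERMLINE_DB"]], cnt[["SOMATIC_DB"]],
    length(unique(x$variants$gene))))
  invisible(x)
}

#' Number of variants in a catalogue
#' @param x A `catalogue`.
#' @export
length.catalogue <- function(x) nrow(x$variants)

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_,
         character(1L))
}

#' Read a variant catalogue from VCF
#'
#' Multi-allelic records are split into one variant per alternate allele;
#' 1-based VCF positions are converted to the internal 0-based convention.
#' Records whose REF disagrees with the reference are rejected with a logged
#' warning rather than an error, mirroring how a database snapshot with a
#' handful of stale records is handled in practice.
#'
#' @param path Path to a VCF (4.2) file.
#' @param source Source tag, `GERMLINE_DB` or `SOMATIC_DB`; `NULL` reads the
#'   per-record `SRC` INFO field instead (as written by
#'   [write_catalogue_vcf()]).
#' @param reference Optional named reference vector used to validate REF
#'   alleles.
#' @param sig_key,af_key,gene_key,hgvsc_key,hgvsp_key INFO keys holding the
#'   clinical significance, population allele frequency, gene symbol and
#'   HGVS strings.
#' @return A `catalogue`.
#' @export
read_catalogue_vcf <- function(path, source = NULL, reference = NULL,
                               sig_key = "SIG", af_key = "AF",
                               gene_key = "GENE", hgvsc_key = "HGVSC",
                               hgvsp_key = "HGVSP") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), nalt)
  info <- fix$INFO[idx]
  v <- data.frame(
    chrom = fix$CHROM[idx],
    start = as.integer(fix$POS[idx]) - 1L,
    ref = toupper(fix$REF[idx]),
    alt = toupper(unlist(alts)),
    gene = info_field(info, gene_key),
    stringsAsFactors = FALSE)
  sig <- info_field(info, sig_key)
  af <- suppressWarnings(as.numeric(info_field(info, af_key)))
  v$hgvs_c <- info_field(info, hgvsc_key)
  v$hgvs_p <- info_field(info, hgvsp_key)
  v$population_af <- af
  if (is.null(source)) {
    src <- info_field(info, "SRC")
    if (all(is.na(src))) stop("no source tag given and no SRC INFO field")
    v$in_germline_db <- grepl("GERMLINE_DB", src)
    v$in_somatic_db <- grepl("SOMATIC_DB", src)
    v$sig_germline <- info_field(info, "SIG_G")
    v$sig_somatic <- info_field(info, "SIG_S")
  } else {
    source <- match.arg(source, SOURCE_TAGS)
    v$in_germline_db <- source == "GERMLINE_DB"
    v$in_somatic_db <- source == "SOMATIC_DB"
    v$sig_germline <- ifelse(v$in_germline_db, sig, NA_character_)
    v$sig_somatic <- ifelse(v$in_somatic_db, sig, NA_character_)
  }
  if (!is.null(reference)) {
    obs <- reference_slice(reference, v$chrom, v$start, v$start + nchar(v$ref))
    bad <- obs != v$ref
    if (any(bad)) {
      warning(sum(bad), " record(s) rejected: REF disagrees with reference")
      v <- v[!bad, , drop = FALSE]
    }
  }
  catalogue(v)
}

#' Write a catalogue as VCF 4.2
#'
#' Source tags, per-source significance, gene, allele frequency and HGVS
#' strings are stored in INFO; [read_catalogue_vcf()] with `source = NULL`
#' round-trips the catalogue unchanged.
#'
#' @param x A `catalogue`.
#' @param path Output path.
#' @export
write_catalogue_vcf <- function(x, path) {
  stopifnot(inherits(x, "catalogue"))
  v <- x$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Source databases\">",
    "##INFO=<ID=SIG_G,Number=1,Type=String,Description=\"Germline-db significance entries\">",
    "##INFO=<ID=SIG_S,Number=1,Type=String,Description=\"Somatic-db significance entries\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"Coding HGVS\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein HGVS\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  src <- ifelse(v$in_germline_db & v$in_somatic_db, "GERMLINE_DB|SOMATIC_DB",
         ifelse(v$in_somatic_db, "SOMATIC_DB", "GERMLINE_DB"))
  info <- paste0("GENE=", v$gene, ";SRC=", src)
  opt <- function(key, val) ifelse(is.na(val), "", paste0(";", key, "=", val))
  info <- paste0(info, opt("SIG_G", v$sig_germline),
                 opt("SIG_S", v$sig_somatic),
                 opt("AF", ifelse(is.na(v$population_af), NA,
                                  format(v$population_af, digits = 15L,
                                         scientific = FALSE, trim = TRUE))),
                 opt("HGVSC", v$hgvs_c), opt("HGVSP", v$hgvs_p))
  rows <- paste(v$chrom, v$start + 1L, ".", v$ref, v$alt, ".", ".", info,
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Left-align + trim one variant against its reference sequence (0-based
# start). Canonical form: SNVs fully trimmed; indels anchored on one shared
# leading base at the leftmost equivalent position (bcftools-norm style).
left_normalize_one <- function(seq, start, ref, alt) {
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L && (rl > 1L || al > 1L) &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      last_r <- substr(ref, rl, rl)
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (start == 0L) {
          # cannot shift past the sequence start: keep the anchored form
          ref <- paste0(ref, last_r)
          alt <- paste0(alt, last_r)
          break
        }
        b <- substr(seq, start, start)  # base at 0-based index start - 1
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        start <- start - 1L
      }
    } else {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    start <- start + 1L
  }
  list(start = start, ref = ref, alt = alt)
}

#' Left-normalize a variant
#'
#' Shifts indels to their leftmost equivalent representation and trims shared
#' flanking bases (indels keep the single VCF anchor base); SNVs are
#' unchanged. Idempotent; two representations normalize to the same key iff
#' their implied haplotypes are identical.
#'
#' @param variant One-row `data.frame` (or list) with `chrom`, `start`,
#'   `ref`, `alt`.
#' @param reference Named reference vector.
#' @return The variant with normalized `start`, `ref`, `alt`.
#' @export
left_normalize <- function(variant, reference) {
  seq <- reference[[variant$chrom]]
  if (is.null(seq)) stop("sequence absent from reference: ", variant$chrom)
  n <- left_normalize_one(seq, as.integer(variant$start),
                          toupper(variant$ref), toupper(variant$alt))
  variant$start <- n$start
  variant$ref <- n$ref
  variant$alt <- n$alt
  variant
}

#' Left-normalize every variant of a catalogue
#'
#' Representations that collapse onto the same key after normalization (the
#' way the same indel can be written differently by two databases) are
#' merged: source flags are OR-ed and the first non-missing annotation wins.
#'
#' @param x A `catalogue`.
#' @param reference Named reference vector.
#' @return A normalized `catalogue`.
#' @export
normalize_catalogue <- function(x, reference) {
  stopifnot(inherits(x, "catalogue"))
  v <- x$variants
  todo <- which(nchar(v$ref) > 1L | nchar(v$alt) > 1L)
  for (i in todo) {
    n <- left_normalize_one(reference[[v$chrom[i]]], v$start[i],
                            v$ref[i], v$alt[i])
    v$start[i] <- n$start
    v$ref[i] <- n$ref
    v$alt[i] <- n$alt
  }
  key <- variant_key(v$chrom, v$start, v$ref, v$alt)
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)),
            " representation(s) unified during normalization")
    v <- merge_variant_rows(v, key)
  }
  catalogue(v, reference = reference)
}

coalesce_chr <- function(a, b) ifelse(is.na(a), b, a)

merge_variant_rows <- function(v, key) {
  first <- !duplicated(key)
  out <- v[first, , drop = FALSE]
  idx <- match(key, key[first])
  for (j in which(!first)) {
    k <- idx[j]
    if (out$gene[k] != v$gene[j]) {
      stop("conflicting gene labels for variant key ", key[j])
    }
    out$in_germline_db[k] <- out$in_germline_db[k] || v$in_germline_db[j]
    out$in_somatic_db[k] <- out$in_somatic_db[k] || v$in_somatic_db[j]
    out$sig_germline[k] <- coalesce_chr(out$sig_germline[k], v$sig_germline[j])
    out$sig_somatic[k] <- coalesce_chr(out$sig_somatic[k], v$sig_somatic[j])
    out$population_af[k] <- ifelse(is.na(out$population_af[k]),
                                   v$population_af[j], out$population_af[k])
    out$hgvs_c[k] <- coalesce_chr(out$hgvs_c[k], v$hgvs_c[j])
    out$hgvs_p[k] <- coalesce_chr(out$hgvs_p[k], v$hgvs_p[j])
  }
  out
}

#' Merge two normalized catalogues
#'
#' Union keyed by (chrom, start, ref, alt). Entries present in both inputs
#' carry both source tags with their significance strings side by side, so
#' `|union| = |a| + |b| - |overlap|`. Merging is commutative and associative
#' on normalized catalogues; conflicting gene labels for one key are an
#' error.
#'
#' @param a,b `catalogue` objects normalized against the same reference.
#' @return The merged `catalogue`.
#' @export
merge_catalogues <- function(a, b) {
  stopifnot(inherits(a, "catalogue"), inherits(b, "catalogue"))
  v <- rbind(a$variants, b$variants)
  key <- variant_key(v$chrom, v$start, v$ref, v$alt)
  catalogue(merge_variant_rows(v, key))
}

#' Flag variants outside the panel design space
#'
#' The design space is the union of coding exons extended by a junction
#' margin on each side; variants exiting it are flagged `out_of_design` but
#' retained.
#'
#' @param x A `catalogue`.
#' @param exons Exon `data.frame`.
#' @param margin Junction margin in bp (default 50, matching exon +/- 50 bp
#'   intron designs).
#' @return The catalogue with a logical `out_of_design` column.
#' @export
flag_out_of_design <- function(x, exons, margin = 50L) {
  stopifnot(inherits(x, "catalogue"))
  v <- x$variants
  lv <- sort(unique(c(v$chrom, exons$chrom)))
  design <- GenomicRanges::reduce(gi_to_gr(
    data.frame(chrom = exons$chrom,
               start = pmax(exons$start - margin, 0L),
               end = exons$end + margin), seqlevels = lv))
  vg <- gi_to_gr(data.frame(chrom = v$chrom, start = v$start,
                            end = v$start + nchar(v$ref)), seqlevels = lv)
  x$variants$out_of_design <- !IRanges::overlapsAny(vg, design,
                                                    type = "within")
  x
}

#' Export a catalogue as a hotspot TSV
#'
#' One row per variant with 1-based position, the file that drives
#' hotspot-forced evaluation.
#'
#' @param x A `catalogue`.
#' @param path Output path.
#' @export
write_hotspots_tsv <- function(x, path) {
  stopifnot(inherits(x, "catalogue"))
  v <- x$variants
  src <- ifelse(v$in_germline_db & v$in_somatic_db, "GERMLINE_DB|SOMATIC_DB",
         ifelse(v$in_somatic_db, "SOMATIC_DB", "GERMLINE_DB"))
  out <- data.frame(gene = v$gene, chrom = v$chrom, pos = v$start + 1L,
                    ref = v$ref, alt = v$alt, sources = src,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
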