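# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration / per-base masks / closed forms) kept separate
# from the code paths it checks.

# Apply a variant to a sequence, returning the alternate haplotype.
apply_variant <- function(seq, start, ref, alt) {
  stopifnot(substr(seq, start + 1L, start + nchar(ref)) == ref)
  paste0(substr(seq, 1L, start), alt,
         substr(seq, start + nchar(ref) + 1L, nchar(seq)))
}

# Leftmost equivalent representation of a pure indel, by scanning every
# position for haplotype equality. Returns the anchored (start, ref, alt).
oracle_canonical_indel <- function(seq, start, ref, alt) {
  hap <- apply_variant(seq, start, ref, alt)
  L <- nchar(seq)
  # equivalent indel placements form a contiguous interval, so the leftmost
  # placement with an anchor base (p >= 1) is the canonical VCF form
  if (nchar(hap) < L) {            # deletion
    dl <- L - nchar(hap)
    for (p in 1:(L - dl)) {
      cand <- paste0(substr(seq, 1L, p), substr(seq, p + dl + 1L, L))
      if (cand == hap) {
        return(list(start = p - 1L,
                    ref = substr(seq, p, p + dl),
                    alt = substr(seq, p, p)))
      }
    }
  } else {                          # insertion
    k <- nchar(hap) - L
    for (p in 1:L) {
      pre_ok <- substr(hap, 1L, p) == substr(seq, 1L, p)
      suf_ok <- substr(hap, p + k + 1L, nchar(hap)) ==
        substr(seq, p + 1L, L)
      if (pre_ok && suf_ok) {
        ins <- substr(hap, p + 1L, p + k)
        return(list(start = p - 1L,
                    ref = substr(seq, p, p),
                    alt = paste0(substr(seq, p, p), ins)))
      }
    }
  }
  stop("oracle failed to find a representation")
}

# Exhaustive minimum fixed-length window cover for a set of point loci.
bf_min_cover <- function(loci, L) {
  loci <- sort(unique(loci))
  if (!length(loci)) return(0L)
  l <- loci[1L]
  cand <- unique(c(loci, loci - L + 1L))
  cand <- cand[cand <= l & cand >= l - L + 1L]
  best <- Inf
  for (s in cand) {
    rest <- loci[loci > s + L - 1L]
    best <- min(best, 1L + bf_min_cover(rest, L))
  }
  best
}

# Two-sided Fisher exact p by hypergeometric tail enumeration over all
# tables with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0L, c1 - r2):min(r1, c1)
  px <- stats::dhyper(x, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(px[px <= pobs * (1 + 1e-7)])
}

# A small, fast study geometry for property tests.
small_genes <- function() {
  data.frame(
    gene = c("G1", "G2"),
    transcript_id = c("G1-syn.1", "G2-syn.1"),
    coding_bp = c(900L, 1200L),
    n_exons = c(3L, 4L),
    n_cat_a = c(40L, 60L),
    n_cat_b = c(10L, 15L),
    n_overlap = c(5L, 5L),
    n_review = c(6L, 8L),
    n_unc_hp = c(1L, 2L),
    n_unc_gap = c(0L, 4L),
    n_hp_runs = c(2L, 3L),
    n_gap_windows = c(0L, 1L),
    n_mutated = c(2L, 1L),
    stringsAsFactors = FALSE)
}

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, genes = small_genes(), n_samples = 3L, ...)
}

# A one-contig toy world for unit tests of the classifier.
toy_world <- function() {
  seq <- paste0("GATCGATCGT", strrep("A", 7L), "GTCGATCGAT",
                "CGTACGTACG", "TAGCTAGCTA", "GCATGCATGC")
  reference <- c(chrT = seq)
  panel <- amplicon_panel(data.frame(chrom = "chrT", start = 0L, end = 40L,
                                     pool = 1L))
  runs <- homopolymer_runs(reference, 4L)
  list(reference = reference, panel = panel, runs = runs)
}

toy_pileup <- function(variants, ...) {
  defaults <- data.frame(sample_id = "S1", ref_fwd = 250L, ref_rev = 250L,
                         alt_fwd = 0L, alt_rev = 0L, other = 0L,
                         mean_bq = 30, mean_mq = 50)
  out <- cbind(data.frame(chrom = variants$chrom, pos = variants$start,
                          ref = variants$ref, alt = variants$alt,
                          stringsAsFactors = FALSE),
               defaults[rep(1L, nrow(variants)), ])
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  rownames(out) <- NULL
  out
}
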