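# Synthetic study generator. Emulates the data a two-gene amplicon panel
# study produces: a reference with planted homopolymer runs, a tiling
# amplicon design with deliberate coverage gaps, germline/somatic variant
# catalogues with a known overlap, per-hotspot pileups with a
# homopolymer-length-dependent indel error model, and a tumour/normal
# cohort. Every planted variant carries a truth label so the audit can be
# scored against ground truth.
#
# Randomness: one seed in sim_config; each top-level generator draws from a
# stream seeded at a fixed offset (reference +0, catalogues +1, pileups +2,
# cohort +3), so generators are reproducible both standalone and composed,
# and adding a generator never perturbs earlier outputs.

BASES <- c("A", "C", "G", "T")

#' Study-shaped gene geometry
#'
#' Per-gene defaults mirroring the published two-gene audit: coding sizes
#' 5,659 and 10,262 bp over 24 and 27 exons; catalogue geometry 2,522/398
#' germline/somatic entries with 79 shared for the first gene and
#' 3,584/673/145 for the second (union 2,841 + 4,112 = 6,953, raw sum
#' 7,177, overlap 224); planted callability tiers 320/509 review and 1/64
#' uncallable (the second gene's 64 split into 12 homopolymer-indel blind
#' spots and 52 variants in 2 unamplifiable windows); 8 and 5 mutated
#' samples in the cohort.
#'
#' @return `data.frame` with one row per gene.
#' @export
sim_genes_paper <- function() {
  data.frame(
    gene = c("BRCA1", "BRCA2"),
    transcript_id = c("BRCA1-syn.1", "BRCA2-syn.1"),
    coding_bp = c(5659L, 10262L),
    n_exons = c(24L, 27L),
    n_cat_a = c(2522L, 3584L),
    n_cat_b = c(398L, 673L),
    n_overlap = c(79L, 145L),
    n_review = c(320L, 509L),
    n_unc_hp = c(1L, 12L),
    n_unc_gap = c(0L, 52L),
    n_hp_runs = c(12L, 18L),
    n_gap_windows = c(0L, 2L),
    n_mutated = c(8L, 5L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: the
#' [sim_genes_paper()] geometry, 47 samples, mean hotspot depth 500 reads
#' (comfortably inside the caller's operating regime), tumour purity 0.8
#' (post-microdissection cellularity), and a homopolymer indel error rate
#' linear in run length, `min(rate_base * L, rate_cap)` per read.
#'
#' @param seed Integer master seed.
#' @param genes Per-gene geometry table (see [sim_genes_paper()]).
#' @param intron_len bp of intron placed around every exon.
#' @param amplicon_len Amplicon insert length, bp.
#' @param amplicon_step Tiling step between insert starts, bp.
#' @param amplicon_overhang bp of intron covered beyond each exon/segment
#'   end (keeps exon-edge loci away from insert boundaries).
#' @param gap_width Width of each deliberately unamplifiable window, bp.
#' @param depth_mean Mean per-hotspot depth (Poisson), reads.
#' @param n_samples Cohort size.
#' @param purity Tumour cell fraction in (0, 1].
#' @param hp_indel_rate_base Per-read spurious indel rate per bp of run
#'   length.
#' @param hp_indel_rate_cap Cap on the spurious indel rate.
#' @param strand_bias_fraction Fraction of clean catalogue loci given
#'   one-sided alternate reads (a planted strand-bias artefact channel;
#'   default 0).
#' @param clean_indel_fraction Fraction of clean catalogue variants that are
#'   1-bp deletions rather than SNVs.
#' @param mean_base_quality,mean_mapping_quality Phred means of the
#'   simulated quality summaries.
#' @param ctx_config The [context_config()] the geometry is laid out
#'   against.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genes = sim_genes_paper(),
                       intron_len = 400L, amplicon_len = 120L,
                       amplicon_step = 100L, amplicon_overhang = 10L,
                       gap_width = 20L, depth_mean = 500,
                       n_samples = 47L, purity = 0.8,
                       hp_indel_rate_base = 0.01, hp_indel_rate_cap = 0.2,
                       strand_bias_fraction = 0,
                       clean_indel_fraction = 0.1,
                       mean_base_quality = 32, mean_mapping_quality = 55,
                       ctx_config = context_config()) {
  stopifnot(purity > 0, purity <= 1,
            strand_bias_fraction >= 0, strand_bias_fraction <= 1,
            clean_indel_fraction >= 0, clean_indel_fraction <= 1,
            hp_indel_rate_cap >= 0, hp_indel_rate_cap <= 1,
            amplicon_step < amplicon_len,
            amplicon_overhang >= ctx_config$amplicon_end_margin)
  if (any(genes$n_overlap > pmin(genes$n_cat_a, genes$n_cat_b))) {
    stop("n_overlap cannot exceed either catalogue size")
  }
  if (any(genes$n_review + genes$n_unc_hp + genes$n_unc_gap >
          genes$n_cat_a + genes$n_cat_b - genes$n_overlap)) {
    stop("planted non-automatic counts exceed the catalogue size")
  }
  structure(list(seed = as.integer(seed), genes = genes,
                 intron_len = as.integer(intron_len),
                 amplicon_len = as.integer(amplicon_len),
                 amplicon_step = as.integer(amplicon_step),
                 amplicon_overhang = as.integer(amplicon_overhang),
                 gap_width = as.integer(gap_width),
                 depth_mean = depth_mean, n_samples = as.integer(n_samples),
                 purity = purity,
                 hp_indel_rate_base = hp_indel_rate_base,
                 hp_indel_rate_cap = hp_indel_rate_cap,
                 strand_bias_fraction = strand_bias_fraction,
                 clean_indel_fraction = clean_indel_fraction,
                 mean_base_quality = mean_base_quality,
                 mean_mapping_quality = mean_mapping_quality,
                 ctx_config = ctx_config),
            class = "sim_config")
}

# Mutate every maximal run of length > 3 outside protected intervals until
# none remains. `protect` is a 0-based interval data.frame on this sequence.
break_long_runs <- function(chars, protect = NULL) {
  protected <- rep(FALSE, length(chars))
  if (!is.null(protect) && nrow(protect)) {
    for (i in seq_len(nrow(protect))) {
      protected[(protect$start[i] + 1L):protect$end[i]] <- TRUE
    }
  }
  pkey <- if (is.null(protect) || !nrow(protect)) character(0L)
          else paste(protect$start, protect$end)
  for (iter in 1:100) {
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    bad <- which(r$lengths > 3L &
                 !(paste(starts, ends) %in% pkey))
    if (!length(bad)) return(chars)
    for (b in bad) {
      idx <- (starts[b] + 1L):ends[b]
      free <- idx[!protected[idx]]
      pick <- free[(free - starts[b]) %% 4L == 0L]
      if (!length(pick)) pick <- free[1L]
      for (p in pick) {
        left <- if (p > 1L) chars[p - 1L] else ""
        right <- if (p < length(chars)) chars[p + 1L] else ""
        cand <- setdiff(BASES, c(chars[p], left, right))
        if (!length(cand)) cand <- setdiff(BASES, chars[p])
        chars[p] <- cand[1L]
      }
    }
  }
  stop("could not eliminate accidental homopolymer runs")
}

split_exon_sizes <- function(total, n) {
  base <- total %/% n
  sizes <- rep(base, n)
  extra <- total - base * n
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate the synthetic reference
#'
#' One contig per gene: exons of near-equal size separated by introns, a
#' random background sequence with no accidental homopolymer run longer
#' than 3 bp, planted maximal runs of recorded position/base/length (one
#' per hosting exon, so planted runs sit far apart), and the designated
#' unamplifiable windows. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_reference`: `reference` (named sequences),
#'   `exons`, `runs` (truth table of planted runs), `gaps` (unamplifiable
#'   windows), `genes`.
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  genes <- config$genes
  run_len_cycle <- c(6L, 5L, 7L, 4L, 8L, 6L, 9L, 5L, 7L, 6L, 4L, 8L)
  reference <- character(0L)
  exons <- runs <- gaps <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    sizes <- split_exon_sizes(g$coding_bp, g$n_exons)
    intron <- config$intron_len
    exon_start <- intron + cumsum(c(0L, (sizes + intron)[-g$n_exons]))
    exon_end <- exon_start + sizes
    contig_len <- sum(sizes) + (g$n_exons + 1L) * intron
    chars <- sample(BASES, contig_len, replace = TRUE)

    # unamplifiable windows: centred in the last n_gap_windows exons
    gap_exons <- if (g$n_gap_windows > 0L) {
      seq(g$n_exons, by = -1L, length.out = g$n_gap_windows)
    } else integer(0L)
    gdf <- NULL
    if (length(gap_exons)) {
      gs <- exon_start[gap_exons] +
        (sizes[gap_exons] - config$gap_width) %/% 2L
      gdf <- data.frame(chrom = g$gene, start = gs,
                        end = gs + config$gap_width,
                        stringsAsFactors = FALSE)
    }

    # planted runs: one per hosting exon, margin 12 bp from exon edges
    host <- setdiff(seq_len(g$n_exons), gap_exons)
    if (g$n_hp_runs > length(host)) {
      stop("not enough exons to host ", g$n_hp_runs, " homopolymer runs")
    }
    host <- host[seq_len(g$n_hp_runs)]
    rdf <- NULL
    if (length(host)) {
      lens <- rep_len(run_len_cycle, g$n_hp_runs)
      margin <- 12L
      avail <- sizes[host] - 2L * margin - lens
      if (any(avail < 0L)) stop("exons too small to host homopolymer runs")
      rs <- exon_start[host] + margin +
        vapply(avail, function(a) sample.int(a + 1L, 1L) - 1L, integer(1L))
      base <- sample(BASES, g$n_hp_runs, replace = TRUE)
      for (k in seq_along(rs)) {
        span <- (rs[k] + 1L):(rs[k] + lens[k])
        chars[span] <- base[k]
        for (fl in c(rs[k], rs[k] + lens[k] + 1L)) {  # 1-based flanks
          if (fl >= 1L && fl <= contig_len && chars[fl] == base[k]) {
            nb <- c(if (fl > 1L) chars[fl - 1L],
                    if (fl < contig_len) chars[fl + 1L])
            chars[fl] <- setdiff(BASES, c(base[k], nb))[1L]
          }
        }
      }
      rdf <- data.frame(chrom = g$gene, start = rs, end = rs + lens,
                        base = base, length = lens, stringsAsFactors = FALSE)
    }
    chars <- break_long_runs(chars, protect = rdf)
    reference[g$gene] <- paste(chars, collapse = "")
    exons[[gi]] <- data.frame(gene = g$gene, transcript_id = g$transcript_id,
                              chrom = g$gene, start = exon_start,
                              end = exon_end, stringsAsFactors = FALSE)
    runs[[gi]] <- rdf
    gaps[[gi]] <- gdf
  }
  empty_runs <- data.frame(chrom = character(), start = integer(),
                           end = integer(), base = character(),
                           length = integer(), stringsAsFactors = FALSE)
  empty_gaps <- data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  runs <- do.call(rbind, c(runs[!vapply(runs, is.null, logical(1L))],
                           list(empty_runs)))
  gaps <- do.call(rbind, c(gaps[!vapply(gaps, is.null, logical(1L))],
                           list(empty_gaps)))
  structure(list(reference = reference,
                 exons = do.call(rbind, exons),
                 runs = runs[order(runs$chrom, runs$start), , drop = FALSE],
                 gaps = gaps, genes = genes),
            class = "sim_reference")
}

#' Generate the tiling amplicon panel
#'
#' Each exon (split at unamplifiable windows) is tiled with fixed-length
#' inserts at a constant step, overhanging `amplicon_overhang` bp into the
#' flanking intron — but stopping exactly at unamplifiable window edges, so
#' the windows stay uncovered. Pool ids cycle over three multiplex pools.
#'
#' @param simref A `sim_reference`.
#' @param config The [sim_config()] used to build it.
#' @return An `amplicon_panel` with 3 pools.
#' @export
generate_panel <- function(simref, config) {
  A <- config$amplicon_len
  step <- config$amplicon_step
  oh <- config$amplicon_overhang
  out <- list()
  for (i in seq_len(nrow(simref$exons))) {
    ex <- simref$exons[i, ]
    gp <- simref$gaps[simref$gaps$chrom == ex$chrom &
                      simref$gaps$start >= ex$start &
                      simref$gaps$end <= ex$end, , drop = FALSE]
    bounds <- sort(c(ex$start, ex$end, gp$start, gp$end))
    for (s in seq(1L, length(bounds) - 1L, by = 2L)) {
      seg_start <- bounds[s]
      seg_end <- bounds[s + 1L]
      lb <- if (seg_start %in% gp$end) seg_start else seg_start - oh
      rb <- if (seg_end %in% gp$start) seg_end else seg_end + oh
      n_amp <- max(1L, ceiling((rb - lb - A) / step) + 1L)
      starts <- lb + step * (seq_len(n_amp) - 1L)
      starts[n_amp] <- rb - A
      if (starts[n_amp] < lb && seg_end %in% gp$start) {
        stop("segment between unamplifiable windows shorter than one ",
             "amplicon")
      }
      starts <- pmax(starts, lb)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ex$chrom, start = unique(starts),
        end = unique(starts) + A, stringsAsFactors = FALSE)
    }
  }
  amp <- do.call(rbind, out)
  amp$pool <- rep_len(1:3, nrow(amp))
  amplicon_panel(amp, n_pools = 3L)
}

# Intervening-base distance from positions to the nearest interval.
dist_to_intervals <- function(pos, starts, ends) {
  d <- rep(Inf, length(pos))
  for (k in seq_along(starts)) {
    dk <- ifelse(pos < starts[k], starts[k] - pos - 1L,
          ifelse(pos >= ends[k], pos - ends[k], 0L))
    d <- pmin(d, dk)
  }
  d
}

# Sample n (position, alt-index) pairs without replacement.
sample_snv_keys <- function(pos_pool, ref_base, n) {
  total <- 3L * length(pos_pool)
  if (n > total) stop("not enough eligible positions to plant variants")
  pick <- sample.int(total, n)
  pi <- (pick - 1L) %/% 3L + 1L
  ai <- (pick - 1L) %% 3L + 1L
  ref <- ref_base[pi]
  alt <- vapply(seq_len(n),
                function(i) setdiff(BASES, ref[i])[ai[i]], character(1L))
  data.frame(start = pos_pool[pi], ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Generate the two variant catalogues with truth labels
#'
#' Plants, per gene, the configured numbers of clean (AUTOMATIC),
#' near-homopolymer (REVIEW), homopolymer-indel and in-gap (UNCALLABLE)
#' variants at eligible positions of the synthetic geometry, then splits
#' the planted keys into a germline-db catalogue, a somatic-db catalogue
#' and the configured overlap. All variants are emitted in canonical
#' left-normalized form.
#'
#' @param config A [sim_config()].
#' @param simref The matching `sim_reference`.
#' @return List with `catalogue_a` (germline-db), `catalogue_b`
#'   (somatic-db), and `truth` (one row per planted key: category, planted
#'   tier/reason, nearest run length).
#' @export
generate_catalogues <- function(config, simref) {
  set.seed(config$seed + 1L)
  D <- config$ctx_config$proximity_window
  E <- config$ctx_config$amplicon_end_margin
  all_rows <- list()
  for (gi in seq_len(nrow(config$genes))) {
    g <- config$genes[gi, ]
    seqchars <- strsplit(simref$reference[[g$gene]], "")[[1L]]
    ex <- simref$exons[simref$exons$gene == g$gene, , drop = FALSE]
    rn <- simref$runs[simref$runs$chrom == g$gene, , drop = FALSE]
    gp <- simref$gaps[simref$gaps$chrom == g$gene, , drop = FALSE]
    pos <- unlist(mapply(function(s, e) s:(e - 1L), ex$start, ex$end,
                         SIMPLIFY = FALSE))
    refb <- seqchars[pos + 1L]
    run_dist <- dist_to_intervals(pos, rn$start, rn$end)
    in_gap <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(gp))) {
      in_gap <- in_gap | (pos >= gp$start[k] & pos < gp$end[k])
    }
    near_gap <- !in_gap & dist_to_intervals(pos, gp$start, gp$end) < E

    clean_ok <- run_dist > D & !in_gap & !near_gap
    review_ok <- run_dist <= D & !in_gap & !near_gap

    n_total <- g$n_cat_a + g$n_cat_b - g$n_overlap
    n_clean <- n_total - g$n_review - g$n_unc_hp - g$n_unc_gap

    # homopolymer-indel blind spots: a 1-bp deletion of the run base,
    # anchored on the (differing) base before the run -- already canonical
    hp <- NULL
    if (g$n_unc_hp > 0L) {
      if (g$n_unc_hp > nrow(rn)) {
        stop("more homopolymer blind spots requested than planted runs")
      }
      ri <- seq_len(g$n_unc_hp)
      anchor <- rn$start[ri] - 1L
      hp <- data.frame(start = anchor,
                       ref = paste0(seqchars[anchor + 1L], rn$base[ri]),
                       alt = seqchars[anchor + 1L],
                       category = "hp_indel", run_len = rn$length[ri],
                       stringsAsFactors = FALSE)
    }

    gap_keys <- NULL
    if (g$n_unc_gap > 0L) {
      gap_keys <- sample_snv_keys(pos[in_gap], refb[in_gap], g$n_unc_gap)
      gap_keys$category <- "gap"
      gap_keys$run_len <- NA_integer_
    }

    review_keys <- sample_snv_keys(pos[review_ok], refb[review_ok],
                                   g$n_review)
    review_keys$category <- "near_hp"
    review_keys$run_len <- vapply(review_keys$start, function(p) {
      d <- ifelse(p < rn$start, rn$start - p - 1L,
           ifelse(p >= rn$end, p - rn$end, 0L))
      rn$length[which.min(d)]
    }, integer(1L))

    n_ci <- round(config$clean_indel_fraction * n_clean)
    clean_snv <- sample_snv_keys(pos[clean_ok], refb[clean_ok],
                                 n_clean - n_ci)
    clean_snv$category <- "clean"
    clean_snv$run_len <- NA_integer_
    clean_del <- NULL
    if (n_ci > 0L) {
      # leftmost 1-bp deletions: the base before the deleted one differs;
      # the anchored span reaches 1 bp further left than the sampled
      # position, so the context margins are one base stricter
      gap_dist <- dist_to_intervals(pos, gp$start, gp$end)
      ok <- clean_ok & run_dist > D + 1L & (!is.finite(gap_dist) |
                                            gap_dist > E) &
        pos > 0L & seqchars[pos] != seqchars[pos + 1L]
      cand <- pos[ok]
      if (n_ci > length(cand)) stop("not enough clean deletion positions")
      p <- sort(sample(cand, n_ci))
      clean_del <- data.frame(start = p - 1L,
                              ref = paste0(seqchars[p], seqchars[p + 1L]),
                              alt = seqchars[p],
                              category = "clean", run_len = NA_integer_,
                              stringsAsFactors = FALSE)
    }

    keys <- rbind(clean_snv, clean_del, review_keys, hp, gap_keys)
    keys$chrom <- g$gene
    keys$gene <- g$gene
    key_id <- variant_key(keys$chrom, keys$start, keys$ref, keys$alt)
    if (anyDuplicated(key_id)) {
      keys <- keys[!duplicated(key_id), , drop = FALSE]
    }
    if (nrow(keys) != n_total) {
      stop("planted key collision: got ", nrow(keys), " of ", n_total)
    }

    # source assignment: A-only / B-only / both
    lab <- sample(c(rep("A", g$n_cat_a - g$n_overlap),
                    rep("B", g$n_cat_b - g$n_overlap),
                    rep("AB", g$n_overlap)))
    keys$in_germline_db <- lab %in% c("A", "AB")
    keys$in_somatic_db <- lab %in% c("B", "AB")
    sig_pool <- c("Pathogenic", "Likely_pathogenic", "Benign",
                  "Likely_benign", "Uncertain_significance")
    keys$sig_germline <- ifelse(
      keys$in_germline_db,
      sample(sig_pool, nrow(keys), replace = TRUE,
             prob = c(0.3, 0.1, 0.2, 0.1, 0.3)), NA_character_)
    keys$sig_somatic <- ifelse(keys$in_somatic_db, "Pathogenic",
                               NA_character_)
    benign <- !is.na(keys$sig_germline) &
      keys$sig_germline %in% c("Benign", "Likely_benign")
    keys$population_af <- ifelse(benign, round(stats::runif(nrow(keys),
                                                            0.01, 0.3), 4L),
                                 NA_real_)
    all_rows[[gi]] <- keys
  }
  v <- do.call(rbind, all_rows)
  planted <- c(clean = "AUTOMATIC", near_hp = "REVIEW",
               hp_indel = "UNCALLABLE", gap = "UNCALLABLE")
  reason <- c(clean = NA_character_, near_hp = "near_homopolymer",
              hp_indel = "homopolymer_indel", gap = "not_covered")
  truth <- data.frame(
    key = variant_key(v$chrom, v$start, v$ref, v$alt),
    chrom = v$chrom, start = v$start, ref = v$ref, alt = v$alt,
    gene = v$gene, category = v$category,
    planted_tier = unname(planted[v$category]),
    planted_reason = unname(reason[v$category]),
    run_len = v$run_len, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "ref", "alt", "gene", "sig_germline",
            "sig_somatic", "population_af")
  a <- v[v$in_germline_db, cols]
  a$sig_somatic <- NA_character_
  b <- v[v$in_somatic_db, cols]
  b$sig_germline <- NA_character_
  list(catalogue_a = catalogue(a, reference = simref$reference,
                               source = "GERMLINE_DB"),
       catalogue_b = catalogue(b, reference = simref$reference,
                               source = "SOMATIC_DB"),
       truth = truth)
}

#' Simulate per-hotspot pileups for every sample
#'
#' Depth is Poisson around `depth_mean` (0 at unamplifiable loci); strands
#' split Binomial(0.5). At a homopolymer-indel hotspot inside a run of
#' length L, reads supporting the spurious indel appear at per-read rate
#' `min(hp_indel_rate_base * L, hp_indel_rate_cap)`; near-run SNV hotspots
#' receive the same rate as reads supporting neither allele. A configurable
#' fraction of clean loci can be given one-sided alternate reads to emulate
#' strand-bias artefacts.
#'
#' @param config A [sim_config()].
#' @param simref The matching `sim_reference`.
#' @param cat The merged audited `catalogue`.
#' @param truth Truth table from [generate_catalogues()].
#' @param panel The `amplicon_panel`.
#' @return Pileup `data.frame` in the layout [audit_catalogue()] consumes.
#' @export
simulate_pileups <- function(config, simref, cat, truth, panel) {
  set.seed(config$seed + 2L)
  v <- cat$variants
  key <- variant_key(v$chrom, v$start, v$ref, v$alt)
  tr <- truth[match(key, truth$key), ]
  lv <- sort(unique(v$chrom))
  vg <- gi_to_gr(data.frame(chrom = v$chrom, start = v$start,
                            end = v$start + nchar(v$ref)), seqlevels = lv)
  cov <- gi_to_gr(covered_regions(panel), seqlevels = lv)
  covered <- IRanges::overlapsAny(vg, cov, type = "within")

  rate <- config$hp_indel_rate_base * ifelse(is.na(tr$run_len), 0,
                                             tr$run_len)
  rate <- pmin(rate, config$hp_indel_rate_cap)
  alt_rate <- ifelse(!is.na(tr$category) & tr$category == "hp_indel",
                     rate, 0)
  other_rate <- ifelse(!is.na(tr$category) & tr$category == "near_hp",
                       rate, 0)
  sb <- rep(FALSE, length(key))
  if (config$strand_bias_fraction > 0) {
    clean_idx <- which(!is.na(tr$category) & tr$category == "clean")
    n_sb <- round(config$strand_bias_fraction * length(clean_idx))
    sb[sample(clean_idx, n_sb)] <- TRUE
  }

  K <- length(key)
  S <- config$n_samples
  n <- K * S
  kidx <- rep(seq_len(K), times = S)
  depth <- ifelse(covered[kidx], stats::rpois(n, config$depth_mean), 0L)
  alt_p <- ifelse(sb[kidx], 0.10, alt_rate[kidx])
  alt <- stats::rbinom(n, depth, alt_p)
  other <- stats::rbinom(n, depth - alt, other_rate[kidx])
  ref <- depth - alt - other
  alt_f <- ifelse(sb[kidx], alt, stats::rbinom(n, alt, 0.5))
  alt_r <- alt - alt_f
  ref_f <- stats::rbinom(n, ref, 0.5)
  data.frame(
    sample_id = rep(sprintf("S%02d", seq_len(S)), each = K),
    chrom = v$chrom[kidx], pos = v$start[kidx],
    ref = v$ref[kidx], alt = v$alt[kidx],
    ref_fwd = ref_f, ref_rev = ref - ref_f,
    alt_fwd = alt_f, alt_rev = alt_r, other = other,
    mean_bq = round(stats::rnorm(n, config$mean_base_quality, 1.5), 2L),
    mean_mq = round(stats::rnorm(n, config$mean_mapping_quality, 2), 2L),
    stringsAsFactors = FALSE)
}

AA_NAMES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
              "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
              "Thr", "Trp", "Tyr", "Val")

#' Simulate a tumour/normal cohort of observed variants
#'
#' Plants pathogenic mutations in the configured number of samples per gene
#' (mutually exclusive across genes): frameshift and nonsense mutations
#' (some recorded in the knowledge table, some not), one in-frame deletion
#' recorded as Pathogenic, and one unrecorded missense whose codon carries
#' a recorded pathogenic missense. Common benign polymorphisms are spread
#' over the cohort. VAFs are binomial draws at Poisson depth: germline
#' heterozygous ~0.5 in both tissues, somatic ~purity/2 in tumour and ~0 in
#' normal, LOH cases at (1+purity)/2 in tumour.
#'
#' @param config A [sim_config()].
#' @return List with `observed` (sample-level variant table), `knowledge`
#'   (catalogue-shaped known-variant table) and `truth` (planted origin,
#'   zygosity and expected classification per record).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed + 3L)
  genes <- config$genes
  S <- config$n_samples
  n_mut <- sum(genes$n_mutated)
  if (n_mut > S) stop("more mutated samples than cohort size")
  samples <- sprintf("C%02d", seq_len(S))
  mut_samples <- sample(samples, n_mut)
  gene_of <- rep(genes$gene, genes$n_mutated)

  aa <- function(n) sample(AA_NAMES, n, replace = TRUE)
  rec <- list()
  knowledge <- list()
  used_codons <- integer(0L)
  for (i in seq_len(n_mut)) {
    g <- gene_of[i]
    cbp <- genes$coding_bp[genes$gene == g]
    repeat {
      cpos <- sample.int(cbp - 10L, 1L)
      codon <- (cpos - 1L) %/% 3L + 1L
      if (!codon %in% used_codons) break
    }
    used_codons <- c(used_codons, codon)
    kind_pool <- if (g == genes$gene[1L]) {
      c("fs_del", "fs_del", "fs_del", "fs_dup", "fs_del", "nonsense",
        "inframe_del", "missense_same_codon")
    } else {
      c("fs_del", "fs_del", "fs_del", "fs_dup", "nonsense")
    }
    gi_block <- which(gene_of == g)  # index within this gene's block
    k <- match(i, gi_block)
    kind <- rep_len(kind_pool, length(gi_block))[k]
    b <- sample(BASES, 1L)
    hc <- switch(kind,
      fs_del = sprintf("c.%ddel%s", cpos, b),
      fs_dup = sprintf("c.%ddup%s", cpos, b),
      nonsense = sprintf("c.%d%s>%s", cpos, b,
                         sample(setdiff(BASES, b), 1L)),
      inframe_del = sprintf("c.%d_%ddel", cpos, cpos + 2L),
      missense_same_codon = sprintf("c.%d%s>%s", cpos, b,
                                    sample(setdiff(BASES, b), 1L)))
    hp <- switch(kind,
      fs_del = ,
      fs_dup = sprintf("p.%s%d%sfsTer%d", aa(1L), codon, aa(1L),
                       sample(5:60, 1L)),
      nonsense = sprintf("p.%s%dTer", aa(1L), codon),
      inframe_del = sprintf("p.%s%ddel", aa(1L), codon),
      missense_same_codon = sprintf("p.%s%d%s", "Pro", codon, "Leu"))
    recorded <- kind %in% c("inframe_del") ||
      (kind %in% c("fs_del", "fs_dup", "nonsense") && k %% 2L == 1L)
    if (recorded) {
      knowledge[[length(knowledge) + 1L]] <- data.frame(
        gene = g, hgvs_c = hc, hgvs_p = hp, sig_germline = "Pathogenic",
        sig_somatic = NA_character_, population_af = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (kind == "missense_same_codon") {
      knowledge[[length(knowledge) + 1L]] <- data.frame(
        gene = g, hgvs_c = sprintf("c.%d%s>%s", cpos, b, "G"),
        hgvs_p = sprintf("p.Pro%dArg", codon),
        sig_germline = "Pathogenic", sig_somatic = NA_character_,
        population_af = NA_real_, stringsAsFactors = FALSE)
    }
    # origins: gene 1 all germline (2 with LOH); gene 2: 2 germline
    # (1 with LOH), the rest somatic
    origin <- if (g == genes$gene[1L]) "germline"
              else if (k <= 2L) "germline" else "somatic"
    loh <- (g == genes$gene[1L] && k <= 2L) ||
           (g == genes$gene[2L] && k == 1L)
    rec[[length(rec) + 1L]] <- data.frame(
      sample_id = mut_samples[i], gene = g, hgvs_c = hc, hgvs_p = hp,
      planted_origin = origin, planted_loh = loh,
      expected_class = if (kind == "missense_same_codon")
        "likely_pathogenic_same_codon" else "pathogenic",
      stringsAsFactors = FALSE)
  }

  # common benign polymorphisms spread over the cohort
  snp <- data.frame(
    gene = rep(genes$gene[min(2L, nrow(genes))], 3L),
    hgvs_c = c("c.1114A>C", "c.865A>C", "c.3119G>A"),
    hgvs_p = c("p.Asn372His", "p.Asn289His", "p.Ser1040Asn"),
    sig_germline = c("Benign|Benign|Benign|Benign|Pathogenic",
                     paste(rep("Benign", 7L), collapse = "|"),
                     paste(c(rep("Benign", 5L), rep("Likely_benign", 3L),
                             "Uncertain_significance", "Pathogenic"),
                           collapse = "|")),
    sig_somatic = NA_character_,
    population_af = c(0.25, 0.07, 0.01), stringsAsFactors = FALSE)
  snp$gene[3L] <- genes$gene[1L]
  knowledge[[length(knowledge) + 1L]] <- snp
  carriers_n <- pmin(c(24L, 3L, 2L), S)
  carriers <- lapply(carriers_n, function(k) sample(samples, k))
  for (j in 1:3) {
    for (s in carriers[[j]]) {
      rec[[length(rec) + 1L]] <- data.frame(
        sample_id = s, gene = snp$gene[j], hgvs_c = snp$hgvs_c[j],
        hgvs_p = snp$hgvs_p[j], planted_origin = "germline",
        planted_loh = FALSE, expected_class = "benign",
        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rec)
  n <- nrow(obs)
  td <- stats::rpois(n, config$depth_mean)
  nd <- stats::rpois(n, config$depth_mean)
  p_t <- ifelse(obs$planted_loh, (1 + config$purity) / 2,
         ifelse(obs$planted_origin == "germline", 0.5, config$purity / 2))
  p_n <- ifelse(obs$planted_origin == "germline", 0.5, 0.003)
  obs$tumour_vaf <- stats::rbinom(n, td, p_t) / pmax(td, 1L)
  obs$normal_vaf <- stats::rbinom(n, nd, p_n) / pmax(nd, 1L)
  truth <- obs[, c("sample_id", "gene", "hgvs_c", "planted_origin",
                   "planted_loh", "expected_class")]
  observed <- obs[, c("sample_id", "gene", "hgvs_c", "hgvs_p",
                      "tumour_vaf", "normal_vaf")]
  list(observed = observed, knowledge = do.call(rbind, knowledge),
       truth = truth)
}

#' Run the whole synthetic study
#'
#' Generates reference, panel, catalogues, pileups and cohort in a fixed
#' order from one seed; optionally writes every artefact (FASTA, BED, exon
#' TSV, catalogue VCFs, pileup and truth TSVs) to a directory.
#'
#' @param seed Master seed (used when `config` is not supplied).
#' @param config Optional [sim_config()] overriding the default study
#'   geometry.
#' @param out_dir Optional output directory.
#' @return List with every generated object: `config`, `reference`,
#'   `exons`, `runs`, `gaps`, `panel`, `catalogue_a`, `catalogue_b`, merged
#'   `catalogue`, audit `truth`, `pileups`, and `cohort`.
#' @export
simulate_study <- function(seed = 1L, config = NULL, out_dir = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  simref <- generate_reference(config)
  panel <- generate_panel(simref, config)
  cats <- generate_catalogues(config, simref)
  merged <- merge_catalogues(cats$catalogue_a, cats$catalogue_b)
  pileups <- simulate_pileups(config, simref, merged, cats$truth, panel)
  cohort <- simulate_cohort(config)
  out <- list(config = config, reference = simref$reference,
              exons = simref$exons, runs = simref$runs, gaps = simref$gaps,
              panel = panel, catalogue_a = cats$catalogue_a,
              catalogue_b = cats$catalogue_b, catalogue = merged,
              truth = cats$truth, pileups = pileups, cohort = cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reference(simref$reference, file.path(out_dir, "reference.fa"))
    write_bed(panel$amplicons, file.path(out_dir, "panel.bed"))
    write_exon_table(simref$exons, file.path(out_dir, "exons.tsv"))
    write_catalogue_vcf(cats$catalogue_a,
                        file.path(out_dir, "catalogue_germline.vcf"))
    write_catalogue_vcf(cats$catalogue_b,
                        file.path(out_dir, "catalogue_somatic.vcf"))
    write_pileup_tsv(pileups, file.path(out_dir, "pileups.tsv"))
    utils::write.table(cats$truth, file.path(out_dir, "truth_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$observed,
                       file.path(out_dir, "cohort_observed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth,
                       file.path(out_dir, "truth_cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
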