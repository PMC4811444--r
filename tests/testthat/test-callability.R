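test_that("strand balance test is a two-sided Fisher exact", {
  expect_equal(strand_balance_test(50, 50, 25, 25), 1, tolerance = 1e-9)
  expect_equal(strand_balance_test(100, 100, 30, 0),
               oracle_fisher(100, 100, 30, 0), tolerance = 1e-9)
  # doubling a balanced table never pushes p above 1
  expect_lte(strand_balance_test(100, 100, 50, 50), 1)
  expect_error(strand_balance_test(0, 0, 0, 0), "all-zero")
  expect_error(strand_balance_test(-1, 2, 3, 4), "non-negative")
})

test_that("evaluate_hotspot follows the decision cascade", {
  w <- toy_world()
  cfg <- caller_config()
  ctx_cfg <- context_config()
  ctx_at <- function(v) {
    ctx <- annotate_context(
      genomic_interval(v$chrom, v$start, v$start + nchar(v$ref)),
      w$panel, w$runs, ctx_cfg, reference = w$reference)
    ctx$hp_indel <- is_homopolymer_indel(
      data.frame(chrom = v$chrom, start = v$start, ref = v$ref,
                 alt = v$alt), w$runs, ctx_cfg)
    ctx
  }

  # clean covered SNV with strong balanced support
  v <- list(chrom = "chrT", start = 25L, ref = "G", alt = "T")
  pu <- pileup_column("chrT", 25L, list(G = c(250, 250), T = c(250, 250)),
                      30, 50)
  r <- evaluate_hotspot(v, pu, ctx_at(v), cfg)
  expect_equal(r$status, "VARIANT")
  expect_equal(r$tier, "AUTOMATIC")
  expect_length(r$reasons, 0)

  # locus outside all inserts
  v <- list(chrom = "chrT", start = 45L, ref = "T", alt = "C")
  r <- evaluate_hotspot(v, NULL, ctx_at(v), cfg)
  expect_equal(r$status, "NOCALL")
  expect_equal(r$tier, "UNCALLABLE")
  expect_equal(r$reasons, "not_covered")

  # 1-bp deletion of A inside the 7-bp A-run (anchored before the run)
  v <- list(chrom = "chrT", start = 9L, ref = "TA", alt = "T")
  pu <- pileup_column("chrT", 9L, list(T = c(200, 200), `-A` = c(30, 30)),
                      30, 50)
  r <- evaluate_hotspot(v, pu, ctx_at(v), cfg)
  expect_equal(r$status, "NOCALL")
  expect_equal(r$tier, "UNCALLABLE")
  expect_equal(r$reasons, "homopolymer_indel")

  # single-strand alternate support at good depth
  v <- list(chrom = "chrT", start = 25L, ref = "G", alt = "T")
  pu <- pileup_column("chrT", 25L, list(G = c(180, 180), T = c(40, 0)),
                      30, 50)
  r <- evaluate_hotspot(v, pu, ctx_at(v), cfg)
  expect_equal(r$status, "NOCALL")
  expect_equal(r$tier, "REVIEW")
  expect_true("strand_bias" %in% r$reasons)

  # near-homopolymer context keeps the VAF call but demotes to REVIEW
  v <- list(chrom = "chrT", start = 7L, ref = "C", alt = "T")
  pu <- pileup_column("chrT", 7L, list(C = c(250, 250)), 30, 50)
  r <- evaluate_hotspot(v, pu, ctx_at(v), cfg)
  expect_equal(r$status, "REFERENCE")
  expect_equal(r$tier, "REVIEW")
  expect_equal(r$reasons, "near_homopolymer")

  # depth 0 with covered context is a reviewable low-depth no-call
  v <- list(chrom = "chrT", start = 25L, ref = "G", alt = "T")
  r <- evaluate_hotspot(v, NULL, ctx_at(v), cfg)
  expect_equal(r$status, "NOCALL")
  expect_equal(r$tier, "REVIEW")
  expect_equal(r$reasons, "low_depth")

  # quality failures are flagged with their own reasons
  pu <- pileup_column("chrT", 25L, list(G = c(250, 250)), 10, 50)
  expect_true("low_base_quality" %in%
                evaluate_hotspot(v, pu, ctx_at(v), cfg)$reasons)
  pu <- pileup_column("chrT", 25L, list(G = c(250, 250)), 30, 10)
  expect_true("poor_mapping" %in%
                evaluate_hotspot(v, pu, ctx_at(v), cfg)$reasons)
  pu <- pileup_column("chrT", 25L, list(G = c(485, 485), T = c(15, 15)),
                      30, 50)
  expect_true("noisy" %in% evaluate_hotspot(v, pu, ctx_at(v), cfg)$reasons)
})

test_that("a mixed-sequence insertion beside a run is not a homopolymer indel", {
  w <- toy_world()
  v <- data.frame(chrom = "chrT", start = 9L, ref = "T", alt = "TAC")
  expect_false(is_homopolymer_indel(v, w$runs))
  v2 <- data.frame(chrom = "chrT", start = 9L, ref = "T", alt = "TA")
  expect_true(is_homopolymer_indel(v2, w$runs))
  # pure-repeat indel far from any long run
  v3 <- data.frame(chrom = "chrT", start = 30L, ref = "T", alt = "TA")
  expect_false(is_homopolymer_indel(v3, w$runs))
  # 3-bp pure insertion exceeds the single/double-base rule
  v4 <- data.frame(chrom = "chrT", start = 9L, ref = "T", alt = "TAAA")
  expect_false(is_homopolymer_indel(v4, w$runs))
})

test_that("audit_catalogue classifies planted construction exactly", {
  ref <- c(cA = paste(rep("GATC", 50), collapse = ""))
  panel <- amplicon_panel(data.frame(chrom = "cA", start = 0L, end = 120L))
  starts <- c(seq(20L, 90L, by = 10L), 150L, 160L)  # last 2 in a gap
  bases <- substring(ref[["cA"]], starts + 1L, starts + 1L)
  v <- catalogue(data.frame(
    chrom = "cA", start = starts, ref = bases,
    alt = ifelse(bases == "A", "T", "A"), gene = "G"), reference = ref)
  pu <- toy_pileup(v$variants)
  aud <- audit_catalogue(v, pu, panel, ref)
  expect_equal(sum(aud$tier == "UNCALLABLE"), 2L)
  expect_true(all(aud$tier[aud$start >= 150L] == "UNCALLABLE"))
  expect_equal(sum(aud$tier == "AUTOMATIC"), 8L)
  expect_true(all(aud$status[aud$tier == "AUTOMATIC"] == "REFERENCE"))
  # partition invariant
  expect_equal(sum(table(aud$tier)), length(v))
  # determinism
  expect_identical(aud, audit_catalogue(v, pu, panel, ref))
})

test_that("worst tier across samples wins and no-call frequency is recorded", {
  ref <- c(cA = paste(rep("GATC", 30), collapse = ""))
  panel <- amplicon_panel(data.frame(chrom = "cA", start = 0L, end = 120L))
  v <- catalogue(data.frame(chrom = "cA", start = 50L, ref = "T",
                            alt = "C", gene = "G"))
  good <- toy_pileup(v$variants, sample_id = "S1")
  bad <- toy_pileup(v$variants, sample_id = "S2",
                    ref_fwd = 10L, ref_rev = 10L)  # depth 20 < 100
  aud <- audit_catalogue(v, rbind(good, bad), panel, ref)
  expect_equal(aud$tier, "REVIEW")
  expect_equal(aud$reasons, "low_depth")
  expect_equal(aud$nocall_freq, 0.5)
})

test_that("missing pileups at covered loci warn and demote to REVIEW", {
  ref <- c(cA = paste(rep("GATC", 30), collapse = ""))
  panel <- amplicon_panel(data.frame(chrom = "cA", start = 0L, end = 120L))
  v <- catalogue(data.frame(chrom = "cA", start = c(40L, 50L), ref = "T",
                            alt = "C", gene = "G"))
  pu <- toy_pileup(v$variants[1, , drop = FALSE])
  expect_warning(aud <- audit_catalogue(v, pu, panel, ref), "no pileup")
  expect_equal(aud$tier[aud$start == 50L], "REVIEW")
  expect_equal(aud$reasons[aud$start == 50L], "low_depth")
})

test_that("removing an amplicon never improves any tier", {
  for (seed in 1:5) {
    sim <- simulate_study(seed = seed, config = small_config(seed = seed))
    aud <- audit_catalogue(sim$catalogue, sim$pileups, sim$panel,
                           sim$reference)
    rank <- c(AUTOMATIC = 0, REVIEW = 1, UNCALLABLE = 2)
    amp <- sim$panel$amplicons
    drop <- sample(nrow(amp), 1)
    panel2 <- amplicon_panel(amp[-drop, ], n_pools = sim$panel$n_pools)
    aud2 <- audit_catalogue(sim$catalogue, sim$pileups, panel2,
                            sim$reference)
    expect_identical(aud2$key, aud$key)
    expect_true(all(rank[aud2$tier] >= rank[aud$tier]))
  }
})

test_that("review overrides replace statuses at report time", {
  res <- data.frame(key = c("k1", "k2"), status = c("NOCALL", "NOCALL"),
                    stringsAsFactors = FALSE)
  ov <- data.frame(key = "k2", status = "VARIANT")
  out <- apply_overrides(res, ov)
  expect_equal(out$status, c("NOCALL", "VARIANT"))
})
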