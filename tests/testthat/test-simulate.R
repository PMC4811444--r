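test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_reference(small_config(seed = 9))
  b <- generate_reference(small_config(seed = 9))
  expect_identical(a$reference, b$reference)
  expect_identical(a$runs, b$runs)
  c <- generate_reference(small_config(seed = 10))
  expect_false(identical(a$reference, c$reference))

  s1 <- simulate_study(seed = 9, config = small_config(seed = 9))
  s2 <- simulate_study(seed = 9, config = small_config(seed = 9))
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$catalogue$variants, s2$catalogue$variants)
  expect_identical(s1$cohort$observed, s2$cohort$observed)
})

test_that("planted homopolymer runs are recovered exactly by the scanner", {
  simref <- generate_reference(small_config(seed = 2))
  found <- homopolymer_runs(simref$reference, 4L)
  planted <- simref$runs[order(simref$runs$chrom, simref$runs$start), ]
  rownames(planted) <- rownames(found) <- NULL
  expect_equal(found, planted)

  # no planted runs -> nothing of length >= 4 anywhere
  g <- small_genes()
  g$n_hp_runs <- 0L
  g$n_unc_hp <- 0L
  g$n_review <- 0L
  bare <- generate_reference(sim_config(seed = 3, genes = g))
  expect_equal(nrow(homopolymer_runs(bare$reference, 4L)), 0L)
})

test_that("catalogue geometry matches the configured counts", {
  cfg <- small_config(seed = 4)
  simref <- generate_reference(cfg)
  cats <- generate_catalogues(cfg, simref)
  expect_equal(length(cats$catalogue_a), sum(cfg$genes$n_cat_a))
  expect_equal(length(cats$catalogue_b), sum(cfg$genes$n_cat_b))
  m <- merge_catalogues(cats$catalogue_a, cats$catalogue_b)
  expect_equal(length(m),
               sum(cfg$genes$n_cat_a + cfg$genes$n_cat_b -
                     cfg$genes$n_overlap))
  both <- m$variants$in_germline_db & m$variants$in_somatic_db
  expect_equal(sum(both), sum(cfg$genes$n_overlap))
  # planted composition matches the gene table
  tt <- table(cats$truth$category)
  expect_equal(unname(tt["near_hp"]), sum(cfg$genes$n_review))
  expect_equal(unname(tt["hp_indel"]), sum(cfg$genes$n_unc_hp))
  expect_equal(unname(tt["gap"]), sum(cfg$genes$n_unc_gap))
})

test_that("generator truth labels agree with the package's own context", {
  cfg <- small_config(seed = 6)
  sim <- simulate_study(seed = 6, config = cfg)
  v <- sim$catalogue$variants
  key <- sprintf("%s:%d:%s:%s", v$chrom, v$start, v$ref, v$alt)
  tr <- sim$truth[match(key, sim$truth$key), ]
  runs <- homopolymer_runs(sim$reference, 4L)
  ctx <- annotate_context(
    data.frame(chrom = v$chrom, start = v$start,
               end = v$start + nchar(v$ref)),
    sim$panel, runs, reference = sim$reference)
  hp <- is_homopolymer_indel(v, runs)
  expect_true(all(ctx$uncovered[tr$category == "gap"]))
  expect_true(all(!ctx$uncovered[tr$category != "gap"]))
  expect_true(all(hp[tr$category == "hp_indel"]))
  expect_true(all(!hp[tr$category != "hp_indel"]))
  expect_true(all(ctx$near_homopolymer[tr$category == "near_hp"]))
  clean <- tr$category == "clean"
  expect_true(all(!ctx$near_homopolymer[clean]))
  expect_true(all(!ctx$near_amplicon_end[clean]))
})

test_that("pileup error model follows the configured rates", {
  cfg <- small_config(seed = 8, depth_mean = 1000)
  sim <- simulate_study(seed = 8, config = cfg)
  p <- sim$pileups
  tr <- sim$truth
  key <- sprintf("%s:%d:%s:%s", p$chrom, p$pos, p$ref, p$alt)
  cat_of <- tr$category[match(key, tr$key)]
  depth <- p$ref_fwd + p$ref_rev + p$alt_fwd + p$alt_rev + p$other

  # unamplifiable loci have depth 0; covered loci Poisson around the mean
  expect_true(all(depth[cat_of == "gap"] == 0))
  cov_depth <- depth[cat_of != "gap"]
  expect_gt(mean(cov_depth), 950)
  expect_lt(mean(cov_depth), 1050)

  # spurious indel fraction at a homopolymer blind spot ~ min(e0 * L, cap)
  hp <- cat_of == "hp_indel" & depth > 0
  run_len <- tr$run_len[match(key, tr$key)]
  expected <- pmin(cfg$hp_indel_rate_base * run_len[hp],
                   cfg$hp_indel_rate_cap)
  observed <- (p$alt_fwd + p$alt_rev)[hp] / depth[hp]
  se <- sqrt(expected * (1 - expected) / depth[hp])
  expect_true(all(abs(observed - expected) < 4 * se + 1e-9))

  # clean loci carry no alternate support at all
  expect_true(all((p$alt_fwd + p$alt_rev)[cat_of == "clean"] == 0))
})

test_that("planted strand-bias loci are flagged by the audit", {
  cfg <- small_config(seed = 12, strand_bias_fraction = 0.2)
  sim <- simulate_study(seed = 12, config = cfg)
  aud <- audit_catalogue(sim$catalogue, sim$pileups, sim$panel,
                         sim$reference)
  expect_gt(sum(grepl("strand_bias", aud$reasons)), 0)
  # one-sided alt reads at VAF 0.1 must never be called AUTOMATIC
  sb <- grepl("strand_bias", aud$reasons)
  expect_true(all(aud$tier[sb] == "REVIEW"))
})

test_that("cohort VAFs follow the purity model and origins are recoverable", {
  cfg <- small_config(seed = 14)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  obs <- co$observed
  som <- tr$planted_origin == "somatic"
  germ_het <- tr$planted_origin == "germline" & !tr$planted_loh
  loh <- tr$planted_loh
  expect_true(all(abs(obs$tumour_vaf[som] - cfg$purity / 2) < 0.15))
  expect_true(all(obs$normal_vaf[som] < 0.05))
  expect_true(all(abs(obs$tumour_vaf[germ_het] - 0.5) < 0.15))
  expect_true(all(abs(obs$normal_vaf[germ_het] - 0.5) < 0.15))
  expect_true(all(obs$tumour_vaf[loh] > 0.8))

  ori <- assign_origin(obs$tumour_vaf, obs$normal_vaf)
  expect_true(all(ori$origin == tr$planted_origin))
  expect_true(all((ori$tumour_zygosity == "homozygous_or_LOH") ==
                    tr$planted_loh))
})

test_that("a small study round-trips end to end with exact tier recovery", {
  sim <- simulate_study(seed = 16, config = small_config(seed = 16))
  aud <- audit_catalogue(sim$catalogue, sim$pileups, sim$panel,
                         sim$reference)
  tr <- sim$truth[match(aud$key, sim$truth$key), ]
  expect_equal(aud$tier, tr$planted_tier)
  # partition invariant
  expect_equal(sum(table(aud$tier)), length(sim$catalogue))
})

test_that("study artefacts are written in standard formats", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(seed = 18, config = small_config(seed = 18),
                        out_dir = dir)
  ref <- read_reference(file.path(dir, "reference.fa"))
  expect_identical(ref, sim$reference)
  panel <- read_panel_bed(file.path(dir, "panel.bed"))
  expect_equal(panel$amplicons, sim$panel$amplicons)
  exons <- read_exon_table(file.path(dir, "exons.tsv"))
  expect_equal(coding_length(exons), coding_length(sim$exons))
  cat_a <- read_catalogue_vcf(file.path(dir, "catalogue_germline.vcf"),
                              source = NULL, reference = ref)
  expect_equal(length(cat_a), length(sim$catalogue_a))
  pu <- read_pileup_tsv(file.path(dir, "pileups.tsv"))
  expect_equal(nrow(pu), nrow(sim$pileups))
  expect_equal(pu$pos, sim$pileups$pos)
})
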