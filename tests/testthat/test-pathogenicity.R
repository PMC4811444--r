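knowledge <- read.table(
  system.file("extdata", "brca_knowledge_table.tsv", package = "callaudit"),
  sep = "\t", header = TRUE, stringsAsFactors = FALSE,
  na.strings = c("NA", ""))

observed_cases <- read_observed_tsv(
  system.file("extdata", "ovarian_cohort_observed_synthetic_vafs.tsv",
              package = "callaudit"))

test_that("mutation types are read off HGVS notation", {
  expect_equal(classify_mutation_type("p.Gln1777ProfsTer74"), "frameshift")
  expect_equal(classify_mutation_type("p.Gln563Ter"), "nonsense")
  expect_equal(classify_mutation_type("p.Val1709del"), "inframe_deletion")
  expect_equal(classify_mutation_type("p.Pro1770Leu"), "missense")
  expect_equal(classify_mutation_type("p.Ser1040="), "synonymous")
  expect_equal(classify_mutation_type("p.Val802GlufsTer7"), "frameshift")
  expect_equal(classify_mutation_type("p.Glu23_Val24del"),
               "inframe_deletion")
  expect_equal(classify_mutation_type("p.Ala2delinsGlyTrp"), "other")
  # coding-only fallback: length modulo 3
  expect_equal(classify_mutation_type(NA, "c.2405_2406delTG"), "frameshift")
  expect_equal(classify_mutation_type(NA, "c.5125_5127delGTT"),
               "inframe_deletion")
  expect_equal(classify_mutation_type(NA, "c.5329dupC"), "frameshift")
  expect_equal(classify_mutation_type(NA, "c.1687C>T"), "other")
  expect_error(classify_mutation_type("p.Bogus!!"), "unparseable")
  expect_error(classify_mutation_type(NA, NA), "HGVS")
})

test_that("mutation typing agrees with a codon-arithmetic oracle", {
  set.seed(31)
  code <- Biostrings::GENETIC_CODE
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           `*` = "Ter")
  # a stop-free CDS of 60 codons
  sense <- names(code)[code != "*"]
  for (rep in 1:40) {
    cds <- paste(sample(sense, 60, replace = TRUE), collapse = "")
    kind <- sample(c("sub", "del", "ins"), 1)
    if (kind == "sub") {
      pos <- sample(nchar(cds), 1)
      old <- substr(cds, pos, pos)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      mut <- cds
      substr(mut, pos, pos) <- new
      codon_i <- (pos - 1) %/% 3 + 1
      from <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
      to <- substr(mut, 3 * codon_i - 2, 3 * codon_i)
      truth <- if (code[[to]] == "*") "nonsense"
               else if (code[[to]] == code[[from]]) "synonymous"
               else "missense"
      hp <- if (truth == "synonymous") {
        sprintf("p.%s%d=", aa3[[code[[from]]]], codon_i)
      } else {
        sprintf("p.%s%d%s", aa3[[code[[from]]]], codon_i,
                aa3[[code[[to]]]])
      }
    } else {
      len <- sample(1:6, 1)
      pos <- sample(nchar(cds) - len, 1)
      codon_i <- (pos - 1) %/% 3 + 1
      from <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
      truth <- if (len %% 3 != 0) "frameshift"
               else if (kind == "del") "inframe_deletion" else "other"
      hp <- if (truth == "frameshift") {
        sprintf("p.%s%d%sfsTer9", aa3[[code[[from]]]], codon_i, "Ser")
      } else if (truth == "inframe_deletion") {
        sprintf("p.%s%d_%s%ddel", aa3[[code[[from]]]], codon_i, "Gly",
                codon_i + len %/% 3 - 1)
      } else {
        sprintf("p.%s%d_%s%ddup", aa3[[code[[from]]]], codon_i, "Gly",
                codon_i + 1)
      }
    }
    expect_equal(classify_mutation_type(hp), truth, info = hp)
  }
})

test_that("pathogenicity rules classify the published case set", {
  mt <- mapply(classify_mutation_type, observed_cases$hgvs_p,
               observed_cases$hgvs_c, USE.NAMES = FALSE)
  expect_equal(mt, observed_cases$published_type)
  cls <- classify_pathogenicity(observed_cases, mt, knowledge)
  missense <- observed_cases$hgvs_p == "p.Pro1770Leu"
  expect_true(all(cls[!missense] == "pathogenic"))
  expect_equal(cls[missense], "likely_pathogenic_same_codon")
})

test_that("each pathogenicity rule fires in order", {
  obs <- data.frame(
    gene = c("BRCA1", "BRCA2", "BRCA1", "BRCA2", "BRCA1"),
    hgvs_c = c("c.5125_5127delGTT",  # recorded pathogenic in-frame del
               "c.8614G>T",          # unrecorded nonsense
               "c.5309C>T",          # unrecorded, same-codon pathogenic
               "c.1114A>C",          # common, majority-benign
               "c.9A>G"),            # unrecorded missense, nothing known
    hgvs_p = c("p.Val1709del", "p.Glu2872Ter", "p.Pro1770Leu",
               "p.Asn372His", "p.Lys3Glu"),
    stringsAsFactors = FALSE)
  cls <- classify_pathogenicity(obs, catalogue = knowledge)
  expect_equal(cls, c("pathogenic", "pathogenic",
                      "likely_pathogenic_same_codon", "benign", "VUS"))
})

test_that("a single dissenting pathogenic submitter does not outweigh benign", {
  # eight benign-ish, one uncertain, one pathogenic, 1% frequency -> benign
  obs <- data.frame(gene = "BRCA1", hgvs_c = "c.3119G>A",
                    hgvs_p = "p.Ser1040Asn", stringsAsFactors = FALSE)
  expect_equal(classify_pathogenicity(obs, catalogue = knowledge), "benign")
})

test_that("origin assignment follows the matched-normal thresholds", {
  o <- assign_origin(0.46, 0.49)
  expect_equal(o$origin, "germline")
  expect_equal(o$tumour_zygosity, "heterozygous")

  o <- assign_origin(0.38, 0.00)
  expect_equal(o$origin, "somatic")
  expect_equal(o$tumour_zygosity, "heterozygous")

  o <- assign_origin(0.92, 0.51)
  expect_equal(o$origin, "germline")
  expect_equal(o$tumour_zygosity, "homozygous_or_LOH")

  expect_equal(assign_origin(0.4, 0.10)$origin, "undetermined")
  expect_equal(assign_origin(0.4, NA)$origin, "undetermined")

  # monotone in normal VAF: germline can never flip to somatic by raising it
  ranks <- c(somatic = 0, undetermined = 1, germline = 2)
  vafs <- seq(0, 0.6, by = 0.01)
  o <- assign_origin(rep(0.4, length(vafs)), vafs)$origin
  expect_true(all(diff(ranks[o]) >= 0))
})

test_that("cohort summary counts mutated samples, not variants", {
  calls <- data.frame(
    sample_id = c("a", "b", "c", "c", "d"),
    gene = c("BRCA1", "BRCA1", "BRCA2", "BRCA2", "BRCA1"),
    classification = c("pathogenic", "likely_pathogenic_same_codon",
                       "pathogenic", "pathogenic", "benign"),
    stringsAsFactors = FALSE)
  s <- cohort_summary(calls, 47)
  expect_equal(s$n_mutated_samples, 3L)
  expect_equal(s$pct_mutated, 6)  # 3/47 = 6.38 -> 6
  expect_true(s$mutually_exclusive)

  # two samples sharing one variant key are two mutated samples
  shared <- data.frame(sample_id = c("s1", "s2"), gene = "BRCA1",
                       classification = "pathogenic")
  expect_equal(cohort_summary(shared, 47)$n_mutated_samples, 2L)

  # 13 of 47 rounds to 28%
  thirteen <- data.frame(sample_id = sprintf("m%02d", 1:13),
                         gene = rep(c("BRCA1", "BRCA2"), c(8, 5)),
                         classification = "pathogenic")
  s13 <- cohort_summary(thirteen, 47)
  expect_equal(s13$pct_mutated, 28)
  expect_equal(unname(s13$per_gene[c("BRCA1", "BRCA2")]), c(8L, 5L))

  expect_equal(cohort_summary(
    data.frame(sample_id = "a", gene = "g", classification = "VUS"),
    10)$pct_mutated, 0)
  expect_error(cohort_summary(thirteen, 5), "cohort_size")

  # a sample mutated in both genes breaks mutual exclusivity
  dual <- data.frame(sample_id = c("x", "x"), gene = c("BRCA1", "BRCA2"),
                     classification = "pathogenic")
  expect_false(cohort_summary(dual, 47)$mutually_exclusive)
})
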