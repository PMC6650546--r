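test_that("gc_content matches direct counting", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("ATGN"), "non-ACGT")
})

test_that("gc3_content counts third positions, stop excluded", {
  expect_equal(gc3_content("ATGGCC"), 1)
  expect_equal(gc3_content("ATGAAATTT"), 1 / 3)
  expect_equal(gc3_content("ATGAAATAA"), 0.5)  # stop dropped: ATG, AAA remain
})

test_that("gc3 equals gc of the concatenated third bases", {
  set.seed(11)
  for (i in 1:10) {
    cds <- random_cds(120)
    thirds <- paste(substring(cds, seq(3, nchar(cds), 3),
                              seq(3, nchar(cds), 3)), collapse = "")
    expect_equal(gc3_content(cds), gc_content(thirds))
  }
})

test_that("pyrimidine_fraction counts C+T over the whole sequence", {
  expect_equal(pyrimidine_fraction("AAGGGG"), 0)
  expect_equal(pyrimidine_fraction("CCTTTT"), 1)
  expect_equal(pyrimidine_fraction("ACGTAT"), 0.5)
})

test_that("element_per_codon reproduces the nucleobase formulas", {
  expect_equal(element_per_codon("AAAAAA"), c(C = 15, H = 15, N = 15, O = 0))
  expect_equal(element_per_codon("TTTTTT"), c(C = 12, H = 12, N = 6, O = 6))
  # terminal stop excluded from the per-codon average
  expect_equal(element_per_codon("AAAAAATAA"), c(C = 15, H = 15, N = 15, O = 0))
})

test_that("element_per_codon is invariant under codon permutation", {
  set.seed(5)
  cds <- random_cds(60)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  shuffled <- paste(sample(codons), collapse = "")
  expect_equal(element_per_codon(cds), element_per_codon(shuffled))
})

test_that("synonymous purine-to-pyrimidine third-base swaps never raise N", {
  ct <- codon_table()
  set.seed(7)
  cds <- random_cds(200)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  swapped <- vapply(codons, function(cod) {
    fam <- ct$families[[ct$code[[cod]]]]
    if (substr(cod, 3, 3) %in% c("A", "G")) {
      pyr <- fam[substr(fam, 1, 2) == substr(cod, 1, 2) &
                   substr(fam, 3, 3) %in% c("C", "T")]
      if (length(pyr)) return(pyr[1])
    }
    cod
  }, character(1L))
  before <- element_per_codon(cds)
  after <- element_per_codon(paste(swapped, collapse = ""))
  expect_lte(after[["N"]], before[["N"]])
  expect_lt(after[["N"]], before[["N"]])  # some swap always fires at n = 200
})

test_that("amino_acid_usage returns normalized frequencies", {
  u <- amino_acid_usage("MKMK")
  expect_equal(u[["M"]], 0.5)
  expect_equal(u[["K"]], 0.5)
  expect_equal(sum(u), 1)
  expect_equal(amino_acid_usage("G")[["G"]], 1)
  set.seed(3)
  expect_equal(sum(amino_acid_usage(translate_cds(random_cds(100)))), 1)
})

test_that("class comparison separates planted prebiotic enrichment", {
  cls <- amino_acid_classes()
  # proteins of only prebiotic residues: modern sample all zero
  pre_only <- replicate(5, paste(sample(cls$prebiotic, 60, replace = TRUE),
                                 collapse = ""))
  res <- class_usage_comparison(pre_only)
  expect_true(all(res$modern == 0))
  expect_gt(res$median_prebiotic, res$median_modern)

  # identical class usage by construction: each residue once per protein
  balanced <- replicate(4, paste(c(cls$prebiotic, cls$modern), collapse = ""))
  res0 <- class_usage_comparison(balanced)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$statistic, 0)

  # planted shift: prebiotic residues drawn 3x as often
  set.seed(21)
  aas <- c(cls$prebiotic, cls$modern)
  probs <- rep(c(3, 1), each = 10)
  shifted <- replicate(30, paste(
    sample(aas, 200, replace = TRUE, prob = probs), collapse = ""))
  res1 <- class_usage_comparison(shifted)
  expect_lt(res1$p_value, 0.01)
  expect_gt(res1$statistic, 0)
})

test_that("composition_record assembles all per-gene fields", {
  rec <- composition_record("ATGAAATAA", gene_id = "g1")
  expect_equal(rec$gene_id, "g1")
  expect_equal(rec$length_codons, 2L)
  expect_equal(rec$gc, 1 / 9)
  expect_equal(rec$pyrimidine, 2 / 9)
})
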