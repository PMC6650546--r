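test_that("rscu follows the k * n / sum(n) definition", {
  r <- rscu(c(AAA = 3, AAG = 1))
  expect_equal(r[["AAA"]], 1.5)
  expect_equal(r[["AAG"]], 0.5)
  # single codon used in a 4-fold family
  r4 <- rscu(c(GGT = 7))
  expect_equal(r4[["GGT"]], 4)
  expect_equal(r4[["GGA"]], 0)
  expect_equal(r4[["GGC"]], 0)
  # absent families are NA, not zero
  expect_true(is.na(r[["TTT"]]))
})

test_that("uniform within-family usage gives RSCU 1 everywhere", {
  r <- rscu(codon_counts(uniform_codon_cds(5)))
  expect_equal(unname(r), rep(1, 61))
})

test_that("rscu values within a represented family sum to the family size", {
  set.seed(9)
  r <- rscu(codon_counts(random_cds(500)))
  ct <- codon_table()
  for (fam in ct$families) {
    if (!any(is.na(r[fam]))) {
      expect_equal(sum(r[fam]), length(fam))
    }
  }
})

test_that("relative adaptiveness scales RSCU to the family maximum", {
  w <- relative_adaptiveness(c(AAA = 3, AAG = 1), pseudocount = 0)
  expect_equal(w[["AAA"]], 1)
  expect_equal(w[["AAG"]], 1 / 3)
  w_eq <- relative_adaptiveness(codon_counts(uniform_codon_cds(2)),
                                pseudocount = 0)
  expect_equal(unname(w_eq), rep(1, 61), ignore_attr = TRUE)
  # pseudocount keeps unused codons positive: counts (99.5, 0) + 0.5 each
  w_ps <- relative_adaptiveness(c(AAA = 99.5, AAG = 0), pseudocount = 0.5)
  expect_equal(w_ps[["AAG"]], 0.5 / 100)
})

test_that("cai is the geometric mean over multi-codon families", {
  w <- stats::setNames(rep(1, 61), codon_table()$sense_codons)
  expect_equal(cai("AAAGGT", w), 1)
  w["GGT"] <- 0.2
  expect_equal(cai("AAAGGT", w), sqrt(0.2))
  # ATG is in a single-codon family and never changes the CAI
  expect_equal(cai("AAAGGTATG", w), cai("AAAGGT", w))
})

test_that("cai is permutation-invariant and rises with optimal codons", {
  g <- default_genome()
  w <- relative_adaptiveness(g$cds)
  set.seed(13)
  cds <- random_cds(150)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  expect_equal(cai(paste(sample(codons), collapse = ""), w), cai(cds, w))
  # replace one non-optimal codon by its family-optimal sibling
  ct <- codon_table()
  idx <- which(vapply(codons, function(cod) {
    fam <- ct$families[[ct$code[[cod]]]]
    length(fam) > 1 && w[[cod]] < max(w[fam])
  }, logical(1L)))[1]
  fam <- ct$families[[ct$code[[codons[idx]]]]]
  codons[idx] <- fam[which.max(w[fam])]
  expect_gt(cai(paste(codons, collapse = ""), w), cai(cds, w))
})

test_that("enc reproduces Wright's homozygosity arithmetic", {
  # Lys counts (3, 1): n = 4, sum p^2 = 10/16, F = (4 * 10/16 - 1)/3 = 0.5
  val <- enc(c(AAA = 3, AAG = 1, GGT = 2, GGC = 2))
  f <- attr(val, "F_by_class")
  expect_equal(f[["F2"]], 0.5)
  # Gly counts (2, 2): n = 4, sum p^2 = 1/2, F = (2 - 1)/3 = 1/3
  expect_equal(f[["F4"]], 1 / 3)
})

test_that("enc attains its theoretical limits", {
  expect_equal(as.numeric(enc(uniform_codon_cds(100))), 61)
  expect_equal(as.numeric(enc(one_codon_per_aa_cds(10))), 20)
})

test_that("enc of a long uniform random sequence sits at the unbiased limit", {
  set.seed(17)
  value <- as.numeric(enc(random_cds(10000)))
  expect_gte(value, 60)
  expect_lte(value, 61)
})

test_that("enc is permutation-invariant and errors on hopeless input", {
  set.seed(19)
  cds <- random_cds(100)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  expect_equal(as.numeric(enc(paste(sample(codons), collapse = ""))),
               as.numeric(enc(cds)))
  expect_error(enc("ATG"), "no synonymous family")
})

test_that("stronger GC3 bias lowers ENC monotonically", {
  set.seed(23)
  gc3_targets <- seq(0.55, 0.95, by = 0.1)
  encs <- numeric(length(gc3_targets))
  gc3s <- numeric(length(gc3_targets))
  aa <- stats::setNames(rep(1 / 20, 20), names(codon_table()$families))
  for (i in seq_along(gc3_targets)) {
    prof <- make_profile(target_gc3 = gc3_targets[i], bias_strength = 2)
    gene <- codonaudit:::sample_gene(3000, aa, prof)
    encs[i] <- as.numeric(enc(gene))
    gc3s[i] <- gc3_content(gene)
  }
  fit <- linear_fit(gc3s, encs)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.01)
  expect_true(all(diff(encs) < 0))
})

test_that("percentile ranks follow the fraction-at-or-below convention", {
  expect_equal(percentile_ranks(c(4, 1, 3, 2)), c(100, 25, 75, 50))
  expect_equal(max(percentile_ranks(rnorm(10))), 100)
  expect_equal(percentile_ranks(c(2, 2, 2)), c(100, 100, 100))
  expect_error(percentile_ranks(numeric(0)), "non-empty")
})

test_that("accuracy regression inputs pair max RSCU with usage", {
  # gene: 2 glycines all GGT + 18 other residues, one codon each
  ct <- codon_table()
  others <- setdiff(names(ct$families), c("G", "M", "W"))
  gene <- paste(c(rep("GGT", 2),
                  vapply(others[1:17], function(a) ct$families[[a]][1],
                         character(1L)),
                  "ATG"), collapse = "")
  inputs <- accuracy_regression_inputs(c(a = gene, b = gene))
  expect_false(any(inputs$aa %in% c("M", "W")))
  gly <- inputs[inputs$aa == "G", ]
  expect_equal(gly$max_rscu, 4)
  expect_equal(gly$usage, 0.1)
  # identical genes: medians equal the single gene's values
  single_rscu <- rscu(codon_counts(gene))
  expect_equal(gly$max_rscu, max(single_rscu[ct$families[["G"]]]))
})
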