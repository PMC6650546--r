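test_that("transcriptome composition is an abundance-weighted base count", {
  res <- transcriptome_composition(c(g1 = 1), c(g1 = "AAATTT"))
  expect_equal(res$fractions, c(A = 0.5, G = 0, C = 0, U = 0.5))
  res2 <- transcriptome_composition(c(g1 = 1, g2 = 1),
                                    c(g1 = "AAA", g2 = "TTT"))
  expect_equal(res2$fractions[["A"]], 0.5)
  expect_equal(res2$fractions[["U"]], 0.5)
  expect_equal(sum(res2$fractions), 1)
  # scale invariance
  res3 <- transcriptome_composition(c(g1 = 10, g2 = 10),
                                    c(g1 = "AAA", g2 = "TTT"))
  expect_equal(res3$fractions, res2$fractions)
  # weighting: g1 3x more abundant
  res4 <- transcriptome_composition(c(g1 = 3, g2 = 1),
                                    c(g1 = "AAA", g2 = "TTT"))
  expect_equal(res4$fractions[["A"]], 0.75)
  expect_error(transcriptome_composition(c(gX = 1), c(g1 = "AAA")),
               "no overlap")
})

test_that("removal shifts equal the two-term hand calculation", {
  expr <- c(g1 = 2, g2 = 1)
  cds <- c(g1 = "GGGGGG", g2 = "TTTTTT")
  sets <- data.frame(gene_id = "g1", set = "op")
  res <- removal_effect(expr, cds, sets, "op")
  # full: 12 G vs 6 U -> purine 2/3; after removal: all U -> purine 0
  expect_equal(res$shift_purine, 100 * (2 / 3 - 0))
  expect_equal(res$shift_gc, 100 * (2 / 3 - 0))
  expect_equal(res$shift_u, 100 * (1 / 3 - 1))
  expect_equal(sum(res$shift_bases), 0)
  # removing a zero-abundance set shifts nothing
  expr0 <- c(g1 = 0, g2 = 1)
  res0 <- removal_effect(expr0, cds, sets, "op")
  expect_equal(res0$shift_purine, 0)
  expect_equal(res0$shift_u, 0)
  expect_error(removal_effect(c(g1 = 1, g2 = 0), cds, sets, "op"), "empties")
})

test_that("random-combination nulls are seeded and directional", {
  cds <- stats::setNames(rep("ACGTAA", 10), paste0("g", 1:10))
  res <- random_combination_null(cds, focal = c("g1", "g2", "g3"),
                                 statistic = "pyrimidine", n_draws = 50,
                                 seed = 5)
  expect_equal(res$exceedance, 0)  # identical sequences, strict inequality
  res2 <- random_combination_null(cds, focal = c("g1", "g2", "g3"),
                                  statistic = "pyrimidine", n_draws = 50,
                                  seed = 5)
  expect_identical(res$draw_means, res2$draw_means)
  expect_error(random_combination_null(cds[1:2], "g1", k = 3), "fewer than k")
})

test_that("a background-drawn focal set has exceedance near one half", {
  set.seed(43)
  cds <- stats::setNames(vapply(1:80, function(i) random_cds(100),
                                character(1L)), paste0("g", 1:80))
  ex <- vapply(1:30, function(i) {
    focal <- sample(names(cds), 3)
    random_combination_null(cds, focal, statistic = "pyrimidine",
                            n_draws = 200)$exceedance
  }, numeric(1L))
  expect_gt(mean(ex), 0.35)
  expect_lt(mean(ex), 0.65)
})

test_that("element deltas decompose around the genome mean", {
  cds <- c(g1 = "AAAAAA", g2 = "TTTTTT")
  sets <- data.frame(gene_id = c("g1", "g2"), set = c("sa", "sb"))
  d <- element_delta(cds, sets)
  # adenine-only gene: 15 C/codon vs mean 13.5
  expect_equal(d$delta_C[d$set == "sa"], 1.5)
  expect_equal(d$delta_C[d$set == "sb"], -1.5)
  expect_equal(d$delta_C[d$set == "genome"], 0)
  expect_equal(d$delta_O[d$set == "genome"], 0)
  # partition identity: sum of n * delta over a partition is 0
  g <- default_genome()
  labels <- data.frame(
    gene_id = names(g$cds),
    set = rep(c("p1", "p2", "p3"), length.out = length(g$cds)))
  dp <- element_delta(g$cds, labels)
  for (el in c("delta_C", "delta_H", "delta_N", "delta_O")) {
    parts <- dp[dp$set != "genome", ]
    expect_equal(sum(parts$n * parts[[el]]), 0, tolerance = 1e-9)
  }
})

test_that("abundance-element correlations behave at the extremes", {
  cds <- c(g1 = "AAAAAA", g2 = "AAATTT", g3 = "TTTTTT", g4 = "AAAAAT")
  elemN <- vapply(cds, function(s) element_per_codon(s)[["N"]], numeric(1L))
  expr <- stats::setNames(2 * elemN + 1, names(cds))  # exact affine function
  res <- abundance_element_correlation(expr, cds)
  expect_equal(res$r[res$element == "N"], 1)
  # constant element composition across genes errors
  const <- c(g1 = "AAAAAA", g2 = "AAAAAA", g3 = "AAAAAA")
  expect_error(abundance_element_correlation(c(g1 = 1, g2 = 2, g3 = 3), const),
               "zero variance")
  # independent draws stay weakly correlated
  set.seed(47)
  big <- stats::setNames(vapply(1:500, function(i) random_cds(80),
                                character(1L)), paste0("g", 1:500))
  expr_big <- stats::setNames(rlnorm(500), names(big))
  res_big <- abundance_element_correlation(expr_big, big)
  expect_true(all(abs(res_big$r) < 0.15))
})
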