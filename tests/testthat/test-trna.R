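wc_only_rules <- data.frame(
  codon3 = c("U", "C", "A", "G"),
  anticodon1 = c("A", "G", "U", "C"),
  class = "watson_crick",
  s = 0,
  stringsAsFactors = FALSE
)

test_that("default pairing rules load with Watson-Crick minima", {
  rules <- pairing_rules()
  expect_setequal(names(rules), c("codon3", "anticodon1", "class", "s"))
  wc <- rules[rules$class == "watson_crick", ]
  wb <- rules[rules$class == "wobble", ]
  expect_true(all(wc$s == 0))
  expect_true(all(wb$s > 0))
  expect_false(is.null(attr(rules, "table_md5")))
})

test_that("a complete exact pool gives equal W under exact-only pairing", {
  pool <- stats::setNames(rep(2L, 61),
                          vapply(codon_table()$sense_codons,
                                 codonaudit:::wc_anticodon, character(1L)))
  W <- absolute_adaptiveness(pool, wc_only_rules)
  expect_equal(unname(W), rep(2, 61), ignore_attr = TRUE)
  expect_length(attr(W, "uncovered"), 0L)
})

test_that("W combines exact and wobble contributions linearly", {
  # codon GAA (ends A): exact anticodon UUC, wobble AUC at s = 0.5
  rules <- data.frame(codon3 = c("A", "A"), anticodon1 = c("U", "A"),
                      class = c("watson_crick", "wobble"), s = c(0, 0.5),
                      stringsAsFactors = FALSE)
  W <- absolute_adaptiveness(c(UUC = 2, AUC = 1), rules)
  expect_equal(W[["GAA"]], 2 * 1 + 1 * 0.5)
  # doubling every tGCN doubles W and leaves the tAI unchanged
  W2 <- absolute_adaptiveness(c(UUC = 4, AUC = 2), rules)
  expect_equal(W2[["GAA"]], 2 * W[["GAA"]])
  cds <- "GAAGAA"
  expect_equal(tai(cds, W2)$tai, tai(cds, W)$tai)
})

test_that("tai is a geometric mean of normalized adaptiveness", {
  W <- stats::setNames(rep(0, 61), codon_table()$sense_codons)
  W["AAA"] <- 2
  W["GGT"] <- 1
  expect_equal(tai("AAAAAA", W)$tai, 1)
  expect_equal(tai("AAAGGT", W)$tai, sqrt(0.5))
  # permutation invariance
  set.seed(31)
  g <- default_genome()
  Wg <- absolute_adaptiveness(g$trna_pool)
  cds <- substr(g$cds[[1]], 1, nchar(g$cds[[1]]) - 3)  # drop terminal stop
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  expect_equal(tai(paste(sample(codons), collapse = ""), Wg)$tai,
               tai(cds, Wg)$tai)
  # never exceeds 1; equals 1 only for max-w codons
  tais <- vapply(g$cds[1:20], function(s) tai(s, Wg)$tai, numeric(1L))
  expect_true(all(tais <= 1))
  expect_true(all(tais < 1))
})

test_that("tai handles W = 0 codons by exclusion or imputation", {
  W <- stats::setNames(rep(0, 61), codon_table()$sense_codons)
  W["AAA"] <- 1
  W["GGT"] <- 0.5
  res <- tai("AAAGGTTTT", W)  # TTT unreadable
  expect_equal(res$n_zero_w, 1L)
  expect_equal(res$tai, sqrt(0.5))
  res_imp <- tai("AAAGGTTTT", W, zero_w = "impute")
  expect_equal(res_imp$tai, sqrt(0.5))  # imputing the mean log changes nothing
  W0 <- stats::setNames(rep(0, 61), codon_table()$sense_codons)
  W0["AAA"] <- 1
  expect_error(tai("GGTGGT", W0), "W = 0")
})

test_that("network edges follow the pairing rules exactly", {
  # anticodon GAA reads UUC (Watson-Crick) and UUU (wobble G:U)
  prof <- rscu(codon_counts(uniform_codon_cds(1)))
  net <- build_network(list(genome = prof), c(GAA = 3))
  expect_equal(nrow(net), 2L)
  expect_setequal(net$codon, c("TTT", "TTC"))
  expect_setequal(net$pairing_class, c("watson_crick", "wobble"))
  expect_true(all(net$tGCN == 3))
  expect_true(all(net$rscu_genome == 1))
  expect_error(build_network(list(x = c(AAA = 1)), c(GAA = 1)),
               "does not cover")
})

test_that("edge sets match a brute-force pairing oracle", {
  set.seed(37)
  rules <- pairing_rules()
  for (i in 1:5) {
    pool_size <- sample(4:10, 1)
    anticodons <- unique(replicate(pool_size, paste(
      sample(c("A", "C", "G", "U"), 3, replace = TRUE), collapse = "")))
    pool <- stats::setNames(sample(1:5, length(anticodons), replace = TRUE),
                            anticodons)
    net <- build_network(list(g = rscu(codon_counts(uniform_codon_cds(1)))),
                         pool, rules)
    expected <- 0L
    for (codon in codon_table()$sense_codons) {
      for (ac in anticodons) {
        if (oracle_pairs(codon, ac, rules)) {
          expected <- expected + 1L
          expect_true(any(net$codon == codon & net$anticodon == ac))
        }
      }
    }
    expect_equal(nrow(net), expected)
  }
})

test_that("access curves are monotone and match brute-force recounts", {
  set.seed(41)
  g <- default_genome()
  pool <- g$trna_pool[1:10]
  prof <- rscu(codon_counts(g$cds[1:20]))
  curve <- access_curve(prof, pool)
  expect_equal(curve$cutoff, seq(0, 2, by = 0.01))
  expect_true(all(diff(curve$accessible_tGCN) <= 0))
  # brute-force recount on a coarse grid
  rules <- pairing_rules()
  for (t in seq(0, 2, by = 0.25)) {
    acs <- names(pool)[vapply(names(pool), function(ac) {
      any(vapply(codon_table()$sense_codons, function(cod) {
        !is.na(prof[[cod]]) && prof[[cod]] >= t && oracle_pairs(cod, ac, rules)
      }, logical(1L)))
    }, logical(1L))]
    expect_equal(curve$accessible_tGCN[curve$cutoff == t],
                 sum(pool[acs]), ignore_attr = TRUE)
  }
  # cutoff above the maximum RSCU leaves nothing accessible
  high <- access_curve(prof, pool, cutoffs = max(prof, na.rm = TRUE) + 0.01)
  expect_equal(high$accessible_tGCN, 0)
})

test_that("missing anticodons for preferred codons depress the access curve", {
  # a set preferring Lys AAA: remove the only anticodons reading AAA
  prof_pref <- rscu(c(AAA = 9, AAG = 1))
  full_pool <- c(UUU = 5, CUU = 5)   # UUU reads AAA (exact) and AAG (wobble)
  depleted <- c(CUU = 5)             # CUU reads only AAG
  a_full <- access_curve(prof_pref, full_pool, cutoffs = c(0, 1, 1.5))
  a_depl <- access_curve(prof_pref, depleted, cutoffs = c(0, 1, 1.5))
  expect_true(all(a_depl$accessible_tGCN[2:3] < a_full$accessible_tGCN[2:3]))
})

test_that("access equality test reduces to the textbook 2x2 chi-square", {
  res <- access_equality_test(50, 40, 100)
  expect_equal(res$statistic, 50 / 45 + 50 / 55)
  same <- access_equality_test(30, 30, 60)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  extreme <- access_equality_test(1000, 0, 1000)
  expect_lt(extreme$p_value, 1e-10)
  expect_error(access_equality_test(1, 1, 0), "positive")
})
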