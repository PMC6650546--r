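# Shared fixtures and independent oracles used across the test files.

ct_fix <- codon_table()

# CDS using every sense codon `m` times (uniform usage of all 61 codons).
uniform_codon_cds <- function(m = 5L) {
  paste(rep(ct_fix$sense_codons, each = m), collapse = "")
}

# CDS using exactly one codon per amino acid, each `m` times.
one_codon_per_aa_cds <- function(m = 10L) {
  first <- vapply(ct_fix$families, `[`, character(1L), 1L)
  paste(rep(unname(first), each = m), collapse = "")
}

# Random valid CDS of n codons (no stops), uniform over sense codons.
random_cds <- function(n_codons) {
  paste(sample(ct_fix$sense_codons, n_codons, replace = TRUE), collapse = "")
}

# One default synthetic genome, built once and reused across tests.
default_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(genome_spec())
    }
    cache
  }
})

# --- independent oracles ------------------------------------------------------

# PERMANOVA pseudo-F computed from the Euclidean distance matrix (Anderson's
# distance-based formulation), independent of the package's group-sum path.
oracle_permanova_F <- function(x, labels) {
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(x)
  groups <- split(seq_len(n), labels)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1L)))
  a <- length(groups)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Exhaustive permutation p value from the distance-based oracle.
oracle_exhaustive_p <- function(x, labels) {
  n <- nrow(x)
  perms <- NULL
  gen <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in gen(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  perms <- gen(seq_len(n))
  f_obs <- oracle_permanova_F(x, labels)
  f_perm <- vapply(perms, function(p) oracle_permanova_F(x, labels[p]),
                   numeric(1L))
  mean(f_perm >= f_obs - 1e-12)
}

# Brute-force codon-anticodon pairing check, written from the biology rather
# than the package's vectorized matching: positions 2 and 3 of the 5'->3'
# anticodon must be Watson-Crick complements of codon positions 2 and 1, and
# the (codon3, anticodon1) wobble pair must be in the allowed table.
oracle_pairs <- function(codon_dna, anticodon_rna, rules) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  codon <- chartr("T", "U", codon_dna)
  c1 <- substr(codon, 1, 1); c2 <- substr(codon, 2, 2)
  c3 <- substr(codon, 3, 3)
  a1 <- substr(anticodon_rna, 1, 1); a2 <- substr(anticodon_rna, 2, 2)
  a3 <- substr(anticodon_rna, 3, 3)
  if (comp[[c1]] != a3 || comp[[c2]] != a2) return(FALSE)
  any(rules$codon3 == c3 & rules$anticodon1 == a1)
}
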