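# Statistical machinery applied by the audit: one-way PERMANOVA on codon
# profiles, paired Wilcoxon signed-rank, Welch t, chi-square of proportions
# and simple linear regression. Classical tests are delegated to stats::;
# the PERMANOVA (pseudo-F, R-squared, seeded permutation p, optional
# exhaustive enumeration) is implemented here because the audit needs seeded
# and exactly enumerable permutations.

#' RSCU feature matrix for ordination
#'
#' Genes x 61 sense codons RSCU matrix. Codons of families absent from a gene
#' are imputed as 0 for that gene's row (a gene cannot prefer a codon it
#' never uses); the imputation count is recorded in the \code{n_imputed}
#' attribute since it is a convention, not a fact of the data.
#'
#' @param cds_set Named character vector of CDSs.
#' @return Numeric matrix (rows = genes, columns = sense codons).
#' @export
rscu_matrix <- function(cds_set) {
  m <- t(vapply(cds_set, function(s) rscu(codon_counts(s)),
                numeric(length(.SENSE_CODONS))))
  n_imputed <- sum(is.na(m))
  m[is.na(m)] <- 0
  attr(m, "n_imputed") <- n_imputed
  m
}

# Pseudo-F and R2 of a one-way partition of Euclidean sums of squares.
permanova_F <- function(x, groups) {
  n <- nrow(x)
  a <- nlevels(groups)
  ss_total <- sum(sweep(x, 2L, colMeans(x))^2)
  group_sums <- rowsum(x, groups)
  n_g <- as.vector(table(groups))
  ss_within <- sum(x^2) - sum(group_sums^2 / n_g)
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(F = f, R2 = ss_between / ss_total)
}

# All permutations of seq_len(n) (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' One-way PERMANOVA on a feature matrix
#'
#' Permutational multivariate analysis of variance with Euclidean distances:
#' the pseudo-F statistic compares between-group to within-group sums of
#' squared distances, R-squared is the between-group share of the total, and
#' the p value is obtained by permuting group labels,
#' \code{p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)}. With
#' \code{exhaustive = TRUE} all label orders are enumerated instead (exact
#' permutation p; feasible for small n).
#'
#' @param x Numeric feature matrix (rows = observations), e.g.
#'   [rscu_matrix()] output.
#' @param labels Group labels (>= 2 groups, each with >= 1 row).
#' @param n_perm Number of random permutations (>= 99).
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive Enumerate all \code{nrow(x)!} label orders (n <= 9).
#' @return List: \code{F}, \code{R2}, \code{p_value}, \code{n_perm},
#'   \code{seed}, \code{exhaustive}.
#' @export
permanova <- function(x, labels, n_perm = 999L, seed = NULL,
                      exhaustive = FALSE) {
  x <- as.matrix(x)
  groups <- factor(labels)
  if (nlevels(groups) < 2L) {
    stop("PERMANOVA needs at least two groups", call. = FALSE)
  }
  if (nrow(x) != length(groups)) {
    stop("`labels` length must match rows of `x`", call. = FALSE)
  }
  if (sum(sweep(x, 2L, colMeans(x))^2) == 0) {
    stop("feature matrix is constant across observations", call. = FALSE)
  }
  obs <- permanova_F(x, groups)
  if (exhaustive) {
    if (nrow(x) > 9L) {
      stop("exhaustive enumeration limited to n <= 9 rows", call. = FALSE)
    }
    perms <- all_permutations(nrow(x))
    f_perm <- vapply(perms, function(p) permanova_F(x, groups[p])[["F"]],
                     numeric(1L))
    p_value <- mean(f_perm >= obs[["F"]] - 1e-12)
    n_used <- length(perms)
  } else {
    if (n_perm < 99L) {
      stop("use at least 99 permutations", call. = FALSE)
    }
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    f_perm <- vapply(seq_len(n_perm), function(i) {
      permanova_F(x, groups[sample.int(nrow(x))])[["F"]]
    }, numeric(1L))
    p_value <- (sum(f_perm >= obs[["F"]] - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]), p_value = p_value,
       n_perm = n_used, seed = seed, exhaustive = exhaustive)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are dropped
#' before ranking (Wilcoxon's original prescription). The exact null
#' distribution is used for n <= 25 pairs: via the signed-rank distribution
#' when |differences| are untied, and by full enumeration of the 2^n sign
#' assignments (which remains exact under tied ranks) for n <= 15 otherwise;
#' larger samples use the normal approximation with continuity correction.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return List: \code{statistic} (V, the positive-rank sum),
#'   \code{p_value}, \code{n_used} pairs after dropping zeros, \code{exact}.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L) {
    stop("`a` and `b` must be equal-length, non-empty", call. = FALSE)
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= 25L && !ties) {
    ht <- stats::wilcox.test(d, exact = TRUE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n_used = n, exact = TRUE))
  }
  if (n <= 15L && ties) {
    # enumerate all sign assignments; exact even with tied ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p_value <- min(1, 2 * min(mean(v_all <= v), mean(v_all >= v)))
    return(list(statistic = v, p_value = p_value, n_used = n, exact = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_used = n, exact = FALSE)
}

#' Welch two-sample t test
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List: \code{statistic}, \code{df}, \code{p_value},
#'   \code{conf_level} (the 99% reporting convention used throughout).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  ht <- stats::t.test(x, y)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, conf_level = 0.99)
}

#' Chi-square test of two proportions
#'
#' Classic 2x2 contingency chi-square (no continuity correction) on
#' \code{k1/n1} versus \code{k2/n2}.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two samples.
#' @return List: \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_square_proportions <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) {
    stop("totals must be positive", call. = FALSE)
  }
  if (k1 / n1 == k2 / n2) {
    return(list(statistic = 0, df = 1, p_value = 1))
  }
  ht <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Simple linear regression
#'
#' Ordinary least squares of y on x with the two-sided slope test.
#'
#' @param x,y Numeric vectors (>= 3 points, x non-constant).
#' @return List: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value} (slope), \code{n}.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L || stats::sd(x) == 0) {
    stop("need >= 3 points with variation in x", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = length(x))
}
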