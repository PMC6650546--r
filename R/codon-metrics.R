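# Codon usage metrics: codon counts, RSCU, relative adaptiveness w and CAI
# (dual reference), Wright's ENC, percentile ranks, and the per-amino-acid
# (median max-RSCU, median usage) pairs feeding the translation-accuracy
# regression.

#' Sense-codon counts of one or more coding sequences
#'
#' @param cds A CDS string or a (named) character vector of CDSs; terminal
#'   stop codons are dropped before counting.
#' @return Named integer vector over the 61 sense codons.
#' @export
codon_counts <- function(cds) {
  codons <- unlist(lapply(cds, function(s) sense_codons_of(validate_cds(s))),
                   use.names = FALSE)
  counts <- table(factor(codons, levels = .SENSE_CODONS))
  stats::setNames(as.integer(counts), .SENSE_CODONS)
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon c in a family of size k with counts n is
#' \code{k * n_c / sum(n)}: the observed count relative to its expectation
#' under uniform use within the synonymous family. Values within each
#' represented family average 1; codons of amino acids absent from the input
#' are \code{NA} (absent, not unpreferred).
#'
#' @param counts Named count vector over the 61 sense codons (see
#'   [codon_counts()]), or a CDS string/vector which is counted first.
#' @return Named numeric vector of RSCU values over the 61 sense codons.
#' @examples
#' rscu(c(AAA = 3, AAG = 1))["AAA"]  # 2 * 3/4 = 1.5
#' @export
rscu <- function(counts) {
  counts <- as_codon_counts(counts)
  out <- stats::setNames(rep(NA_real_, length(.SENSE_CODONS)), .SENSE_CODONS)
  ct <- codon_table()
  for (fam in ct$families) {
    total <- sum(counts[fam])
    if (total > 0) {
      out[fam] <- length(fam) * counts[fam] / total
    }
  }
  out
}

# Accept either a full/partial named count vector or sequences.
as_codon_counts <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% .SENSE_CODONS)) {
      stop("count vector must be named by sense codons", call. = FALSE)
    }
    counts <- stats::setNames(numeric(length(.SENSE_CODONS)), .SENSE_CODONS)
    counts[names(x)] <- x
    counts
  } else {
    codon_counts(x)
  }
}

#' Relative adaptiveness of codons against a reference set
#'
#' Computes the CAI weight w of every sense codon from reference codon
#' counts: RSCU within each family divided by the family's maximal RSCU.
#' Every reference count receives a pseudocount first so that codons unused
#' in the reference keep a small positive weight rather than zeroing the
#' geometric mean.
#'
#' @param counts Reference codon counts (named vector) or reference CDSs.
#' @param pseudocount Added to every sense-codon count (default 0.5).
#' @param reference Label stored on the result (e.g. \code{"genome"},
#'   \code{"ribosomal"}).
#' @return Named numeric vector of w in (0, 1] over the 61 sense codons, with
#'   attribute \code{reference}.
#' @export
relative_adaptiveness <- function(counts, pseudocount = 0.5,
                                  reference = "genome") {
  counts <- as_codon_counts(counts) + pseudocount
  r <- rscu(counts)
  ct <- codon_table()
  w <- r
  for (fam in ct$families) {
    w[fam] <- r[fam] / max(r[fam])
  }
  attr(w, "reference") <- reference
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness w over the codons of a coding
#' sequence, following the classic formulation: stop codons and the
#' single-codon families (Met/ATG, Trp/TGG) are excluded, since they carry no
#' synonymous choice.
#'
#' @param cds A valid CDS string.
#' @param w Adaptiveness vector from [relative_adaptiveness()].
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, w) {
  codons <- sense_codons_of(validate_cds(cds))
  ct <- codon_table()
  single <- unlist(ct$families[ct$degeneracy == 1L], use.names = FALSE)
  codons <- codons[!codons %in% single]
  if (length(codons) == 0L) {
    stop("CDS contains only single-family codons and stops", call. = FALSE)
  }
  exp(mean(log(w[codons])))
}

#' Effective number of codons (ENC)
#'
#' Wright's estimator of how many codons a sequence effectively uses: 20 when
#' one codon serves each amino acid (maximal bias) up to 61 for uniform use
#' of all sense codons. Per synonymous family the homozygosity is estimated
#' as \code{F = (n * sum(p^2) - 1) / (n - 1)} from the family's codon counts
#' (families with fewer than 2 codons observed are not estimable), class
#' averages are combined as \code{ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6}, and
#' the finite-sample result is clipped at 61 (never raised to 20, so that
#' defects surface). A missing 3-fold class is imputed as the mean of the
#' 2- and 4-fold homozygosities; any other missing class drops its term and
#' the result is rescaled by the maximum attainable over the represented
#' classes.
#'
#' @param cds A valid CDS string, or a named codon count vector.
#' @return ENC value (numeric scalar) with attribute \code{F_by_class}, the
#'   mean homozygosity per degeneracy class (NA where not estimable).
#' @export
enc <- function(cds) {
  counts <- as_codon_counts(cds)
  ct <- codon_table()
  fam_F <- lapply(ct$families[ct$degeneracy > 1L], function(fam) {
    n <- sum(counts[fam])
    if (n < 2) {
      return(NA_real_)
    }
    p <- counts[fam] / n
    f_hat <- (n * sum(p^2) - 1) / (n - 1)
    if (f_hat <= 0) NA_real_ else f_hat
  })
  deg <- ct$degeneracy[names(fam_F)]
  f_bar <- vapply(c(2L, 3L, 4L, 6L), function(k) {
    vals <- unlist(fam_F[deg == k])
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1L))
  names(f_bar) <- c("F2", "F3", "F4", "F6")

  n_fam <- c(F2 = 9, F3 = 1, F4 = 5, F6 = 3)   # families per class
  k_size <- c(F2 = 2, F3 = 3, F4 = 4, F6 = 6)  # codons per family
  if (is.na(f_bar["F3"]) && !is.na(f_bar["F2"]) && !is.na(f_bar["F4"])) {
    f_bar["F3"] <- (f_bar["F2"] + f_bar["F4"]) / 2
  }
  present <- !is.na(f_bar)
  if (!any(present)) {
    stop("CDS too short: no synonymous family estimable", call. = FALSE)
  }
  value <- 2 + sum(n_fam[present] / f_bar[present])
  if (!all(present)) {
    # rescale a partial estimate by the ratio of full to attainable maximum
    value <- value * 61 / (2 + sum(n_fam[present] * k_size[present]))
  }
  value <- min(value, 61)
  attr(value, "F_by_class") <- f_bar
  value
}

#' Percentile ranks within a distribution
#'
#' Converts values to percentile ranks on a 0-100 scale using the
#' "fraction less than or equal" convention: \code{rank(x) = 100 * #(v <= x) / N}.
#' Ties share a rank; the maximum always ranks 100.
#'
#' @param values Numeric vector of finite values.
#' @return Numeric vector of ranks in (0, 100], same order as the input.
#' @export
percentile_ranks <- function(values) {
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("`values` must be a non-empty vector of finite numbers", call. = FALSE)
  }
  vapply(values, function(x) 100 * mean(values <= x), numeric(1L))
}

#' Inputs for the translation-accuracy regression
#'
#' For a gene set, pairs per amino acid (degeneracy >= 2) the median (across
#' genes) RSCU of its most-preferred codon with the median fractional usage
#' of that amino acid across the set's proteins. Under selection for
#' translation accuracy, amino acids that a protein set uses more should show
#' stronger preference for a single optimal codon, giving a positive linear
#' relationship.
#'
#' @param cds_set Named character vector of CDSs (>= 2 genes).
#' @return data.frame with columns \code{aa}, \code{degeneracy},
#'   \code{max_rscu} (max over the family's codons of the median per-gene
#'   RSCU) and \code{usage} (median per-protein usage). Amino acids absent
#'   from every protein are dropped (and reported via the
#'   \code{dropped} attribute).
#' @export
accuracy_regression_inputs <- function(cds_set) {
  if (length(cds_set) < 2L) {
    stop("need at least two genes in the set", call. = FALSE)
  }
  rscu_mat <- t(vapply(cds_set, function(s) rscu(codon_counts(s)),
                       numeric(length(.SENSE_CODONS))))
  med_rscu <- apply(rscu_mat, 2L, stats::median, na.rm = TRUE)
  usage_mat <- t(vapply(cds_set, function(s) amino_acid_usage(translate_cds(s)),
                        numeric(20L)))
  med_usage <- apply(usage_mat, 2L, stats::median)
  ct <- codon_table()
  aas <- names(ct$degeneracy)[ct$degeneracy >= 2L]
  rows <- lapply(aas, function(a) {
    fam <- ct$families[[a]]
    mr <- suppressWarnings(max(med_rscu[fam], na.rm = TRUE))
    data.frame(aa = a, degeneracy = ct$degeneracy[[a]],
               max_rscu = ifelse(is.finite(mr), mr, NA_real_),
               usage = med_usage[[a]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- out$aa[is.na(out$max_rscu)]
  out <- out[!out$aa %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
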