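# Transcriptome budgets: abundance-weighted ribonucleotide composition,
# operon-removal shifts, random-combination nulls, per-set elemental deltas
# and the abundance-vs-element correlation.

base_counts_rna <- function(cds) {
  bases <- strsplit(toupper(cds), "")[[1L]]
  bases[bases == "T"] <- "U"
  counts <- table(factor(bases, levels = c("A", "G", "C", "U")))
  stats::setNames(as.numeric(counts), c("A", "G", "C", "U"))
}

#' Abundance-weighted ribonucleotide composition of a transcriptome
#'
#' Sums the base composition of every transcribed coding sequence weighted by
#' its normalized mRNA abundance, giving the ribonucleotide demand of the
#' transcriptome as fractions of A, G, C and U, plus the derived purine, GC
#' and U fractions.
#'
#' @param expression Named numeric vector: gene id to abundance.
#' @param cds Named character vector of CDSs.
#' @param floor Genes with abundance <= \code{floor} are treated as not
#'   transcribed (default 0).
#' @return List: \code{fractions} (A, G, C, U; sums to 1), \code{purine},
#'   \code{gc}, \code{u}, \code{n_genes} used, \code{missing_sequence}
#'   (expressed ids without a CDS).
#' @export
transcriptome_composition <- function(expression, cds, floor = 0) {
  expressed <- names(expression)[expression > floor]
  missing_sequence <- setdiff(expressed, names(cds))
  use <- intersect(expressed, names(cds))
  if (length(use) == 0L) {
    stop("no overlap between expressed genes and sequences", call. = FALSE)
  }
  counts <- vapply(use, function(g) base_counts_rna(cds[[g]]) * expression[[g]],
                   numeric(4L))
  totals <- rowSums(counts)
  fr <- totals / sum(totals)
  list(fractions = fr,
       purine = unname(fr["A"] + fr["G"]),
       gc = unname(fr["G"] + fr["C"]),
       u = unname(fr["U"]),
       n_genes = length(use),
       missing_sequence = missing_sequence)
}

#' Shift in transcriptome composition when a gene set is removed
#'
#' Recomputes the abundance-weighted ribonucleotide budget after deleting all
#' transcripts of one gene set and reports the shifts (before minus after) in
#' percentage points for the purine/pyrimidine balance, GC content and U
#' content, plus the per-base shifts.
#'
#' @param expression Named abundance vector.
#' @param cds Named CDS vector.
#' @param gene_sets data.frame (\code{gene_id}, \code{set}).
#' @param set Label of the set to remove.
#' @param floor Expression floor passed through.
#' @return List: \code{shift_purine}, \code{shift_gc}, \code{shift_u} (in
#'   percentage points) and \code{shift_bases} (named A/G/C/U vector, sums
#'   to 0).
#' @export
removal_effect <- function(expression, cds, gene_sets, set, floor = 0) {
  members <- gene_sets$gene_id[gene_sets$set == set]
  if (length(members) == 0L) {
    stop("no genes labelled '", set, "'", call. = FALSE)
  }
  full <- transcriptome_composition(expression, cds, floor = floor)
  kept <- expression[!names(expression) %in% members]
  if (!any(kept > floor & names(kept) %in% names(cds))) {
    stop("removing '", set, "' empties the transcriptome", call. = FALSE)
  }
  rest <- transcriptome_composition(kept, cds, floor = floor)
  list(
    shift_purine = 100 * (full$purine - rest$purine),
    shift_gc = 100 * (full$gc - rest$gc),
    shift_u = 100 * (full$u - rest$u),
    shift_bases = 100 * (full$fractions - rest$fractions)
  )
}

#' Random-combination null for a per-gene statistic
#'
#' Draws \code{n_draws} combinations of \code{k} distinct coding sequences,
#' computes the mean of a per-gene statistic for each draw, and reports the
#' exceedance: the fraction of draws strictly beyond the focal set's mean in
#' the stated direction. This is the resampling null used to ask how unusual
#' an operon's pyrimidine content or per-codon elemental demand is against
#' same-sized random gene combinations.
#'
#' @param cds Named CDS vector (the candidate universe; restrict it to
#'   transcribed genes upstream if desired).
#' @param focal Gene ids of the focal set.
#' @param statistic \code{"pyrimidine"} (per-gene pyrimidine fraction) or
#'   \code{"element"} (per-codon atoms of one element).
#' @param element Element for \code{statistic = "element"}: "C", "H", "N"
#'   or "O".
#' @param direction \code{"greater"} counts draws with mean strictly above
#'   the focal mean, \code{"less"} strictly below.
#' @param k Combination size (default 3, the size of a three-gene operon).
#' @param n_draws Number of combinations (default 1000).
#' @param seed Optional integer seed making the draws reproducible.
#' @return List: \code{statistic}, \code{element}, \code{focal_value},
#'   \code{draw_means}, \code{exceedance}, \code{k}, \code{n_draws},
#'   \code{direction}, \code{seed}.
#' @export
random_combination_null <- function(cds, focal,
                                    statistic = c("pyrimidine", "element"),
                                    element = c("C", "H", "N", "O"),
                                    direction = c("greater", "less"),
                                    k = 3L, n_draws = 1000L, seed = NULL) {
  statistic <- match.arg(statistic)
  element <- match.arg(element)
  direction <- match.arg(direction)
  if (!all(focal %in% names(cds))) {
    stop("focal gene(s) missing from `cds`", call. = FALSE)
  }
  if (length(cds) < k) {
    stop("fewer than k candidate sequences", call. = FALSE)
  }
  values <- switch(statistic,
    pyrimidine = vapply(cds, pyrimidine_fraction, numeric(1L)),
    element = vapply(cds, function(s) element_per_codon(s)[[element]],
                     numeric(1L)))
  focal_value <- mean(values[focal])
  if (!is.null(seed)) {
    set.seed(seed)
  }
  draw_means <- vapply(seq_len(n_draws), function(i) {
    mean(values[sample.int(length(values), k)])
  }, numeric(1L))
  exceedance <- switch(direction,
    greater = mean(draw_means > focal_value),
    less = mean(draw_means < focal_value))
  list(statistic = statistic,
       element = if (statistic == "element") element else NA_character_,
       focal_value = focal_value, draw_means = draw_means,
       exceedance = exceedance, k = as.integer(k),
       n_draws = as.integer(n_draws), direction = direction, seed = seed)
}

#' Per-set elemental demand relative to the genome-scale mean
#'
#' For each gene set, the unweighted mean per-codon atom demand of its
#' (transcribed) genes minus the mean over all (transcribed) genes. The
#' "genome" row is 0 by construction. An abundance-weighted variant of the
#' reference mean is reported alongside when an expression vector is given,
#' since both conventions are defensible.
#'
#' @param cds Named CDS vector.
#' @param gene_sets data.frame (\code{gene_id}, \code{set}).
#' @param transcribed Optional character vector restricting the universe to
#'   transcribed genes (default: all of \code{cds}).
#' @param expression Optional named abundance vector enabling the weighted
#'   reference columns.
#' @return data.frame: set, n, then \code{delta_C/H/N/O} (unweighted
#'   reference) and, if expression is given,
#'   \code{delta_weighted_C/H/N/O}.
#' @export
element_delta <- function(cds, gene_sets, transcribed = NULL,
                          expression = NULL) {
  universe <- if (is.null(transcribed)) names(cds) else
    intersect(transcribed, names(cds))
  if (length(universe) == 0L) {
    stop("empty transcribed universe", call. = FALSE)
  }
  elem <- t(vapply(cds[universe], element_per_codon, numeric(4L)))
  ref <- colMeans(elem)
  ref_w <- NULL
  if (!is.null(expression)) {
    wts <- expression[universe]
    wts[is.na(wts)] <- 0
    if (sum(wts) > 0) {
      ref_w <- colSums(elem * wts) / sum(wts)
    }
  }
  sets <- c(unique(gene_sets$set), "genome")
  rows <- lapply(sets, function(s) {
    ids <- if (s == "genome") universe else
      intersect(gene_sets$gene_id[gene_sets$set == s], universe)
    if (length(ids) == 0L) {
      row <- data.frame(set = s, n = 0L, delta_C = NA_real_, delta_H = NA_real_,
                        delta_N = NA_real_, delta_O = NA_real_)
    } else {
      d <- colMeans(elem[ids, , drop = FALSE]) - ref
      row <- data.frame(set = s, n = length(ids), delta_C = d[["C"]],
                        delta_H = d[["H"]], delta_N = d[["N"]],
                        delta_O = d[["O"]])
    }
    if (!is.null(ref_w)) {
      if (length(ids) == 0L) {
        row[paste0("delta_weighted_", c("C", "H", "N", "O"))] <- NA_real_
      } else {
        dw <- colMeans(elem[ids, , drop = FALSE]) - ref_w
        row[paste0("delta_weighted_", c("C", "H", "N", "O"))] <- as.list(dw)
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between per-codon elemental demand and mRNA abundance
#'
#' Pearson correlation (with Fisher-z 95% confidence interval) between each
#' element's per-codon atom count and the normalized mRNA abundance across
#' genes. Weak correlations support the claim that an operon's elemental
#' economy is a local feature, not a genome-wide abundance trend.
#'
#' @param expression Named abundance vector.
#' @param cds Named CDS vector.
#' @return data.frame: element, r, ci_low, ci_high, p_value, n.
#' @export
abundance_element_correlation <- function(expression, cds) {
  use <- intersect(names(expression), names(cds))
  if (length(use) < 3L) {
    stop("need >= 3 genes with both abundance and sequence", call. = FALSE)
  }
  elem <- t(vapply(cds[use], element_per_codon, numeric(4L)))
  ab <- expression[use]
  if (stats::sd(ab) == 0) {
    stop("abundance has zero variance", call. = FALSE)
  }
  rows <- lapply(c("C", "H", "N", "O"), function(e) {
    x <- elem[, e]
    if (stats::sd(x) == 0) {
      stop("per-codon ", e, " count has zero variance", call. = FALSE)
    }
    ht <- stats::cor.test(x, ab, method = "pearson", conf.level = 0.95)
    data.frame(element = e, r = unname(ht$estimate),
               ci_low = ht$conf.int[1L], ci_high = ht$conf.int[2L],
               p_value = ht$p.value, n = length(use),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
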