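# tRNA adaptation: pairing rules, absolute/relative adaptiveness W and w,
# the tAI, the bipartite codon-tRNA network and the tRNA-access curve.
#
# Anticodons are stored 5'->3' in the RNA alphabet. Read antiparallel against
# a codon, anticodon position 3 (3' end) pairs codon position 1, position 2
# pairs position 2, and position 1 (the wobble position, base 34 of the tRNA)
# pairs codon position 3. Positions 2 and 3 of the anticodon must be strict
# Watson-Crick complements of the codon; the wobble position follows the
# selective-constraint table.

#' Codon-anticodon pairing rules
#'
#' The wobble-position pairing table used for the tAI and the codon-tRNA
#' network: allowed (codon third base, anticodon first base) pairs with their
#' pairing class and selective constraint s in [0, 1] (Watson-Crick pairs have
#' s = 0; an anticodon contributes weight 1 - s). Anticodons beginning with A
#' are treated as inosine-modified, reading codons ending in U, C or A, the
#' standard assumption for bacteria. Defaults are the published tAI
#' constraints, shipped as an editable table
#' (\code{inst/extdata/pairing_s.tsv}) so alternative constraint sets can be
#' supplied as data.
#'
#' @param path Optional path to a TSV with columns \code{codon3},
#'   \code{anticodon1}, \code{class}, \code{s}; defaults to the shipped table.
#' @return data.frame with columns \code{codon3}, \code{anticodon1},
#'   \code{class} and \code{s}, with attribute \code{table_md5} identifying
#'   the constraint set in reports.
#' @export
pairing_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pairing_s.tsv", package = "codonaudit",
                        mustWork = TRUE)
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "character", "numeric"))
  stopifnot(all(c("codon3", "anticodon1", "class", "s") %in% names(rules)),
            all(rules$s >= 0 & rules$s <= 1))
  attr(rules, "table_md5") <- unname(tools::md5sum(path))
  rules
}

# All (codon, anticodon) pairs allowed between the 61 sense codons and the
# pool's anticodons. Returns a data.frame of edges with class, s and tGCN.
allowed_pairs <- function(pool, rules = pairing_rules()) {
  stopifnot(is.numeric(pool), !is.null(names(pool)))
  anticodons <- names(pool)
  edges <- list()
  for (codon in .SENSE_CODONS) {
    codon_rna <- dna_to_rna(codon)
    # anticodon positions 2-3 must be the reverse complement of codon 1-2
    stem <- reverse_complement_rna(substr(codon_rna, 1L, 2L))
    hit <- substr(anticodons, 2L, 3L) == stem
    for (ac in anticodons[hit]) {
      rule <- rules[rules$codon3 == substr(codon_rna, 3L, 3L) &
                      rules$anticodon1 == substr(ac, 1L, 1L), , drop = FALSE]
      if (nrow(rule) == 1L) {
        edges[[length(edges) + 1L]] <- data.frame(
          codon = codon, anticodon = ac, pairing_class = rule$class,
          s = rule$s, tGCN = unname(pool[ac]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(codon = character(0), anticodon = character(0),
                      pairing_class = character(0), s = numeric(0),
                      tGCN = numeric(0)))
  }
  do.call(rbind, edges)
}

#' Absolute adaptiveness W of every sense codon
#'
#' For each sense codon, \code{W = sum over pairable anticodons of
#' (1 - s) * tGCN}: the wobble-weighted tRNA gene copy supply available to
#' the codon. Codons with no pairable anticodon get W = 0 and are reported in
#' the \code{uncovered} attribute.
#'
#' @param pool Named numeric vector: anticodon (RNA, 5'->3') to tGCN.
#' @param rules Pairing-rule table from [pairing_rules()].
#' @return Named numeric vector W over the 61 sense codons, with attribute
#'   \code{uncovered} listing W = 0 codons.
#' @export
absolute_adaptiveness <- function(pool, rules = pairing_rules()) {
  edges <- allowed_pairs(pool, rules)
  W <- stats::setNames(numeric(length(.SENSE_CODONS)), .SENSE_CODONS)
  if (nrow(edges)) {
    contrib <- tapply((1 - edges$s) * edges$tGCN, edges$codon, sum)
    W[names(contrib)] <- contrib
  }
  attr(W, "uncovered") <- names(W)[W == 0]
  W
}

#' tRNA adaptation index (tAI) of a coding sequence
#'
#' Geometric mean over the sequence's sense codons of the normalized
#' adaptiveness \code{w = W / max(W)}. Stop codons are excluded; codons whose
#' W is 0 (unreadable under the pairing rules and pool) are by default
#' excluded from the geometric mean with their count recorded, or imputed
#' with the geometric mean of the nonzero w.
#'
#' @param cds A valid CDS string.
#' @param W Absolute adaptiveness from [absolute_adaptiveness()].
#' @param zero_w Handling of W = 0 codons: \code{"exclude"} (default) or
#'   \code{"impute"}.
#' @return List: \code{tai} in (0, 1], \code{n_codons} used,
#'   \code{n_zero_w} skipped/imputed codons.
#' @export
tai <- function(cds, W, zero_w = c("exclude", "impute")) {
  zero_w <- match.arg(zero_w)
  codons <- sense_codons_of(validate_cds(cds))
  if (max(W) <= 0) {
    stop("all codons have zero adaptiveness under this pool", call. = FALSE)
  }
  w <- W / max(W)
  wc <- w[codons]
  zero <- wc == 0
  if (all(zero)) {
    stop("every codon of the CDS has W = 0", call. = FALSE)
  }
  mean_log <- mean(log(wc[!zero]))
  if (zero_w == "exclude") {
    value <- exp(mean_log)
  } else {
    value <- exp((sum(log(wc[!zero])) + sum(zero) * mean_log) / length(wc))
  }
  list(tai = value, n_codons = length(wc), n_zero_w = sum(zero))
}

#' Bipartite codon-tRNA interaction network
#'
#' Enumerates every allowed (codon, anticodon) pair between the 61 sense
#' codons and the pool, attaching the pairing class, selective constraint,
#' tGCN of the anticodon, the codon's amino acid and one median-RSCU column
#' per supplied gene set. This is the protein-synthesis network used to ask
#' whether an operon's preferred codons grant privileged access to tRNA
#' isoacceptors.
#'
#' @param rscu_by_set Named list of per-set RSCU profiles (each a named
#'   vector over the 61 sense codons, typically the per-codon median across
#'   the set's genes).
#' @param pool Named tGCN vector.
#' @param rules Pairing-rule table.
#' @return data.frame edge list: codon, amino_acid, anticodon, pairing_class,
#'   s, tGCN, then one \code{rscu_<set>} column per set.
#' @export
build_network <- function(rscu_by_set, pool, rules = pairing_rules()) {
  if (!is.list(rscu_by_set) || is.null(names(rscu_by_set)) ||
      any(names(rscu_by_set) == "")) {
    stop("`rscu_by_set` must be a named list of RSCU profiles", call. = FALSE)
  }
  edges <- allowed_pairs(pool, rules)
  edges$amino_acid <- unname(.GENETIC_CODE[edges$codon])
  for (set in names(rscu_by_set)) {
    prof <- rscu_by_set[[set]]
    if (is.null(names(prof)) || !all(edges$codon %in% names(prof))) {
      stop("RSCU profile for set '", set, "' does not cover the sense codons",
           call. = FALSE)
    }
    edges[[paste0("rscu_", set)]] <- unname(prof[edges$codon])
  }
  edges[, c("codon", "amino_acid", "anticodon", "pairing_class", "s", "tGCN",
            paste0("rscu_", names(rscu_by_set)))]
}

#' tRNA access as a function of RSCU cutoff
#'
#' For cutoffs t over a grid (default 0 to 2 in steps of 0.01), counts the
#' total gene copies of anticodons pairable with at least one codon whose
#' set-median RSCU is >= t. The curve is non-increasing in t: raising the
#' preference threshold can only shrink the accessible pool. Comparing curves
#' across gene sets shows whether one set's codon preferences buy it access
#' to a different share of the tRNA pool.
#'
#' @param profile Named RSCU vector over sense codons (NA = absent family).
#' @param pool Named tGCN vector.
#' @param rules Pairing-rule table.
#' @param cutoffs Numeric grid of RSCU cutoffs.
#' @return data.frame with columns \code{cutoff} and \code{accessible_tGCN}.
#' @export
access_curve <- function(profile, pool, rules = pairing_rules(),
                         cutoffs = seq(0, 2, by = 0.01)) {
  edges <- allowed_pairs(pool, rules)
  edges$rscu <- unname(profile[edges$codon])
  acc <- vapply(cutoffs, function(t) {
    keep <- !is.na(edges$rscu) & edges$rscu >= t
    sum(pool[unique(edges$anticodon[keep])])
  }, numeric(1L))
  data.frame(cutoff = cutoffs, accessible_tGCN = acc)
}

#' Equality test of tRNA-access proportions at the curve endpoints
#'
#' Chi-square test (without continuity correction) comparing the proportion
#' of the tRNA pool accessible at the lowest and highest RSCU cutoffs
#' (conventionally t = 0 versus t = 2).
#'
#' @param accessible_low,accessible_high Accessible tGCN at the two cutoffs.
#' @param total Total tGCN of the pool.
#' @return List: \code{statistic}, \code{df}, \code{p_value}, and the two
#'   proportions.
#' @export
access_equality_test <- function(accessible_low, accessible_high, total) {
  if (total <= 0) {
    stop("total tGCN must be positive", call. = FALSE)
  }
  if (accessible_low == accessible_high) {
    return(list(statistic = 0, df = 1, p_value = 1,
                prop_low = accessible_low / total,
                prop_high = accessible_high / total))
  }
  ht <- suppressWarnings(
    stats::prop.test(c(accessible_low, accessible_high), c(total, total),
                     correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       prop_low = accessible_low / total, prop_high = accessible_high / total)
}
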