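# The end-to-end audit: composition -> RSCU/CAI/ENC -> tAI, network and
# access curves -> accuracy regression and amino-acid class comparison ->
# transcriptome budgets, removal shifts, resampling nulls and deltas ->
# summary statistics. Returns a classed object; write_report() serializes it.

#' Run the full codon-level operon audit
#'
#' Executes every stage of the audit on one genome: per-gene composition
#' (GC, GC3, pyrimidine fraction, per-codon elemental demand), RSCU, CAI
#' against the genome-wide and ribosomal references with within-genome
#' percentile ranks, Wright's ENC with the ENC ~ GC3 linear fit, the tAI
#' with percentile ranks, the codon-tRNA network and per-set tRNA-access
#' curves with the endpoint equality test, the translation-accuracy
#' regression and prebiotic-vs-modern class comparison per gene set, a
#' one-way PERMANOVA of RSCU profiles across source sets, and — when an
#' expression table is supplied — the abundance-weighted transcriptome
#' budget, per-set removal shifts, random-combination nulls for the focal
#' set (pyrimidine content and per-codon C/H/N/O demand), per-set elemental
#' deltas and the abundance-element correlations.
#'
#' Percentile ranks are computed within the supplied genome (one CDS set =
#' one organism); batch analyses of several organisms should loop over
#' genomes.
#'
#' @param cds Named character vector of coding sequences (see
#'   [read_cds_fasta()]).
#' @param gene_sets data.frame (\code{gene_id}, \code{set}); the label
#'   \code{"ribosomal"} marks the CAI reference set.
#' @param trna_pool Optional named tGCN vector; \code{NULL} skips the tAI,
#'   network and access stages.
#' @param expression Optional named abundance vector; \code{NULL} skips the
#'   budget stages.
#' @param focal_set Gene-set label audited against the resampling nulls
#'   (default: the first non-ribosomal label).
#' @param pseudocount CAI reference pseudocount.
#' @param rules Codon-anticodon pairing rules.
#' @param cutoffs RSCU cutoff grid of the access curves.
#' @param null_k,null_draws Combination size and draw count of the
#'   resampling nulls.
#' @param n_perm PERMANOVA permutation count.
#' @param expression_floor Abundance above which a gene counts as
#'   transcribed.
#' @param seed Integer seed for all resampling (PERMANOVA permutations and
#'   nulls).
#' @return Object of class \code{"codon_audit"}: \code{genes} (per-gene
#'   metric table), \code{set_summary}, \code{rscu_by_set}, \code{network},
#'   \code{access}, \code{stats}, \code{budget}, \code{nulls},
#'   \code{element_delta}, \code{meta}.
#' @export
codon_audit <- function(cds, gene_sets = NULL, trna_pool = NULL,
                        expression = NULL, focal_set = NULL,
                        pseudocount = 0.5, rules = pairing_rules(),
                        cutoffs = seq(0, 2, by = 0.01),
                        null_k = 3L, null_draws = 1000L, n_perm = 999L,
                        expression_floor = 0, seed = 1L) {
  if (is.null(names(cds)) || anyDuplicated(names(cds))) {
    stop("`cds` must be uniquely named", call. = FALSE)
  }
  for (g in names(cds)) {
    cds[[g]] <- validate_cds(cds[[g]], id = g)
  }
  labels <- gene_set_labels(gene_sets, names(cds))
  explicit_sets <- if (is.null(gene_sets)) character(0) else
    unique(gene_sets$set)
  if (is.null(focal_set)) {
    focal_set <- setdiff(explicit_sets, "ribosomal")[1L]
  }
  seed <- as.integer(seed)

  ## composition + codon metrics per gene -------------------------------------
  comp <- do.call(rbind, lapply(names(cds), function(g) {
    composition_record(cds[[g]], gene_id = g)
  }))
  comp$set <- unname(labels[comp$gene_id])

  w_genome <- relative_adaptiveness(cds, pseudocount = pseudocount,
                                    reference = "genome")
  ribo_ids <- names(labels)[labels == "ribosomal"]
  w_ribo <- NULL
  if (length(ribo_ids)) {
    w_ribo <- relative_adaptiveness(cds[ribo_ids], pseudocount = pseudocount,
                                    reference = "ribosomal")
  }

  genes <- comp
  genes$enc <- vapply(cds, function(s) as.numeric(enc(s)), numeric(1L))
  genes$cai_genome <- vapply(cds, cai, numeric(1L), w = w_genome)
  genes$cai_genome_rank <- percentile_ranks(genes$cai_genome)
  if (!is.null(w_ribo)) {
    genes$cai_ribosome <- vapply(cds, cai, numeric(1L), w = w_ribo)
    genes$cai_ribosome_rank <- percentile_ranks(genes$cai_ribosome)
  }

  ## tRNA adaptation -----------------------------------------------------------
  network <- NULL
  access <- NULL
  audit_stats <- list()
  if (!is.null(trna_pool)) {
    W <- absolute_adaptiveness(trna_pool, rules)
    tai_rec <- lapply(cds, tai, W = W)
    genes$tai <- vapply(tai_rec, `[[`, numeric(1L), "tai")
    genes$tai_rank <- percentile_ranks(genes$tai)
    genes$tai_zero_w_codons <- vapply(tai_rec, `[[`, numeric(1L), "n_zero_w")
  }

  ## per-set median RSCU profiles ----------------------------------------------
  rscu_gene <- rscu_matrix(cds)
  set_profile <- function(ids) {
    m <- rscu_gene[ids, , drop = FALSE]
    apply(m, 2L, stats::median)
  }
  profile_sets <- c(stats::setNames(lapply(explicit_sets, function(s) {
    set_profile(names(labels)[labels == s])
  }), explicit_sets), list(genome = set_profile(names(cds))))

  if (!is.null(trna_pool)) {
    network <- build_network(profile_sets, trna_pool, rules)
    access <- do.call(rbind, lapply(names(profile_sets), function(s) {
      curve <- access_curve(profile_sets[[s]], trna_pool, rules, cutoffs)
      curve$set <- s
      curve[, c("set", "cutoff", "accessible_tGCN")]
    }))
    audit_stats$access_equality <- stats::setNames(
      lapply(names(profile_sets), function(s) {
        sub <- access[access$set == s, ]
        access_equality_test(sub$accessible_tGCN[[1L]],
                             sub$accessible_tGCN[[nrow(sub)]],
                             sum(trna_pool))
      }), names(profile_sets))
  }

  ## per-set statistics ---------------------------------------------------------
  audit_stats$enc_gc3_fit <- linear_fit(genes$gc3, genes$enc)

  accuracy <- list()
  class_usage <- list()
  for (s in explicit_sets) {
    ids <- names(labels)[labels == s]
    if (length(ids) >= 2L) {
      inputs <- accuracy_regression_inputs(cds[ids])
      fit <- tryCatch(linear_fit(inputs$max_rscu, inputs$usage),
                      error = function(e) NULL)
      accuracy[[s]] <- list(inputs = inputs, fit = fit)
      class_usage[[s]] <- class_usage_comparison(
        vapply(cds[ids], translate_cds, character(1L)))
    }
  }
  audit_stats$accuracy_regression <- accuracy
  audit_stats$class_usage <- class_usage

  if (length(explicit_sets) >= 1L) {
    audit_stats$permanova <- permanova(rscu_gene, labels, n_perm = n_perm,
                                       seed = seed)
  }

  ## transcriptome budgets -------------------------------------------------------
  budget <- NULL
  removal <- NULL
  nulls <- NULL
  deltas <- NULL
  if (!is.null(expression)) {
    budget <- transcriptome_composition(expression, cds,
                                        floor = expression_floor)
    transcribed <- intersect(names(expression)[expression > expression_floor],
                             names(cds))
    removal <- stats::setNames(lapply(explicit_sets, function(s) {
      removal_effect(expression, cds, gene_sets, s, floor = expression_floor)
    }), explicit_sets)
    if (!is.null(focal_set) && !is.na(focal_set)) {
      focal_ids <- intersect(gene_sets$gene_id[gene_sets$set == focal_set],
                             transcribed)
      if (length(focal_ids)) {
        null_specs <- list(
          pyrimidine = list(statistic = "pyrimidine", element = "C",
                            direction = "greater"),
          C = list(statistic = "element", element = "C", direction = "less"),
          H = list(statistic = "element", element = "H", direction = "less"),
          N = list(statistic = "element", element = "N", direction = "less"),
          O = list(statistic = "element", element = "O", direction = "greater"))
        nulls <- lapply(seq_along(null_specs), function(i) {
          ns <- null_specs[[i]]
          random_combination_null(cds[transcribed], focal_ids,
                                  statistic = ns$statistic,
                                  element = ns$element,
                                  direction = ns$direction,
                                  k = null_k, n_draws = null_draws,
                                  seed = seed + i)
        })
        names(nulls) <- names(null_specs)
      }
    }
    deltas <- element_delta(cds, gene_sets, transcribed = transcribed,
                            expression = expression)
    audit_stats$abundance_element_correlation <-
      abundance_element_correlation(expression, cds)
  }

  ## set summary -----------------------------------------------------------------
  summarise_set <- function(ids, label) {
    sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
    med <- function(col) if (col %in% names(sub) && nrow(sub))
      stats::median(sub[[col]]) else NA_real_
    data.frame(set = label, n = nrow(sub),
               gc = med("gc"), gc3 = med("gc3"),
               pyrimidine = med("pyrimidine"), enc = med("enc"),
               cai_genome = med("cai_genome"),
               cai_genome_rank = med("cai_genome_rank"),
               cai_ribosome = med("cai_ribosome"),
               cai_ribosome_rank = med("cai_ribosome_rank"),
               tai = med("tai"), tai_rank = med("tai_rank"),
               stringsAsFactors = FALSE)
  }
  set_summary <- do.call(rbind, c(
    lapply(explicit_sets, function(s)
      summarise_set(names(labels)[labels == s], s)),
    list(summarise_set(names(cds), "genome"))))

  out <- list(
    genes = genes,
    set_summary = set_summary,
    rscu_by_set = profile_sets,
    network = network,
    access = access,
    stats = audit_stats,
    budget = budget,
    removal = removal,
    nulls = nulls,
    element_delta = deltas,
    meta = list(
      n_genes = length(cds),
      sets = explicit_sets,
      focal_set = if (is.null(focal_set)) NA_character_ else focal_set,
      pseudocount = pseudocount,
      s_table_md5 = attr(rules, "table_md5"),
      expression_floor = expression_floor,
      null_k = as.integer(null_k), null_draws = as.integer(null_draws),
      n_perm = as.integer(n_perm),
      seed = seed,
      package_version = as.character(utils::packageVersion("codonaudit"))))
  class(out) <- "codon_audit"
  out
}

#' @export
print.codon_audit <- function(x, ...) {
  cat("Codon-level operon audit:", x$meta$n_genes, "coding sequences\n")
  cat("  gene sets:", if (length(x$meta$sets))
    paste(x$meta$sets, collapse = ", ") else "(none)", "\n")
  if (!is.na(x$meta$focal_set)) {
    cat("  focal set:", x$meta$focal_set, "\n")
  }
  if (!is.null(x$stats$permanova)) {
    cat(sprintf("  PERMANOVA (RSCU ~ set): F = %.2f, R2 = %.2f, p = %.4g\n",
                x$stats$permanova$F, x$stats$permanova$R2,
                x$stats$permanova$p_value))
  }
  cat("  stages:",
      paste(c("composition", "codon metrics",
              if (!is.null(x$network)) "tRNA adaptation",
              if (!is.null(x$budget)) "transcriptome budget"),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a codon audit
#'
#' Prints the per-set summary table, the focal set's null exceedances and
#' the headline statistics.
#'
#' @param object A \code{codon_audit}.
#' @param ... Unused.
#' @return The set-summary data.frame, invisibly.
#' @export
summary.codon_audit <- function(object, ...) {
  print(object)
  cat("\nPer-set medians:\n")
  print(object$set_summary, row.names = FALSE, digits = 3)
  if (!is.null(object$nulls)) {
    cat("\nRandom-combination null exceedances (focal set '",
        object$meta$focal_set, "'):\n", sep = "")
    ex <- vapply(object$nulls, `[[`, numeric(1L), "exceedance")
    print(round(ex, 4))
  }
  invisible(object$set_summary)
}

#' Plot tRNA-access curves of an audit
#'
#' Base-graphics plot of accessible tRNA gene copies against the RSCU
#' cutoff, one line per gene set.
#'
#' @param x A \code{codon_audit} with the tRNA stage run.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.codon_audit <- function(x, ...) {
  if (is.null(x$access)) {
    stop("audit has no access curves (no tRNA pool supplied)", call. = FALSE)
  }
  sets <- unique(x$access$set)
  cuts <- sort(unique(x$access$cutoff))
  m <- vapply(sets, function(s) {
    sub <- x$access[x$access$set == s, ]
    sub$accessible_tGCN[order(sub$cutoff)]
  }, numeric(length(cuts)))
  graphics::matplot(cuts, m, type = "l", lty = 1, lwd = 2,
                    xlab = "RSCU cutoff", ylab = "accessible tRNA copies",
                    ...)
  graphics::abline(v = 1, lty = 3)
  graphics::legend("bottomleft", legend = sets, lty = 1, lwd = 2,
                   col = seq_along(sets), bty = "n")
  invisible(x)
}

#' Write an audit report to disk
#'
#' Serializes a \code{codon_audit} into per-gene metrics TSV, per-set
#' summary TSV, network edge-list TSV, access-curve TSV, budget/removal/
#' delta TSVs and a statistics JSON (with seeds, permutation counts and the
#' pairing-table hash). Output is byte-stable for a fixed audit object.
#'
#' @param audit A \code{codon_audit}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(audit, dir) {
  stopifnot(inherits(audit, "codon_audit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit_tsv <- function(x, name) {
    path <- file.path(dir, name)
    write_tsv(x, path)
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <<- c(files, path)
  }
  num_fmt <- function(df) {
    for (col in names(df)) {
      if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], 10)
    }
    df
  }
  emit_tsv(num_fmt(audit$genes), "genes.tsv")
  emit_tsv(num_fmt(audit$set_summary), "set_summary.tsv")
  if (!is.null(audit$network)) {
    emit_tsv(num_fmt(audit$network), "network.tsv")
    emit_tsv(num_fmt(audit$access), "access_curves.tsv")
  }
  if (!is.null(audit$budget)) {
    emit_json(audit$budget, "budget.json")
    emit_json(audit$removal, "removal_shifts.json")
    if (!is.null(audit$nulls)) {
      emit_json(audit$nulls, "nulls.json")
    }
    emit_tsv(num_fmt(audit$element_delta), "element_delta.tsv")
  }
  emit_json(audit$stats, "stats.json")
  emit_json(audit$meta, "metadata.json")
  invisible(files)
}
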