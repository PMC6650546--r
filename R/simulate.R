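# Synthetic-genome generator. Produces coding sequences, a gene-set map, a
# tRNA pool and an expression table with the statistical structure the audit
# assumes, including a planted three-gene operon carrying the methanotroph
# pmoCAB-like signature: GC3 below GC, pyrimidine enrichment, codon
# preferences shared with the ribosomal reference yet divergent from the
# genome background, top-of-genome expression, and a usage-coupled codon
# preference that plants the translation-accuracy regression.

# Average bacterial amino-acid composition used for background and ribosomal
# genes (fractions; normalized on use).
.AA_FREQ_DEFAULT <- c(
  A = 0.091, C = 0.012, D = 0.056, E = 0.061, F = 0.040, G = 0.076,
  H = 0.020, I = 0.061, K = 0.051, L = 0.101, M = 0.025, N = 0.040,
  P = 0.045, Q = 0.040, R = 0.051, S = 0.061, T = 0.056, V = 0.071,
  W = 0.012, Y = 0.030
)

# Planted-operon amino-acid composition: enriched in pyrimidine-encoded and
# prebiotic residues (Ser, Leu, Pro, Thr, Phe, Ala), as expected for a
# membrane enzyme under synthesis-cost selection.
.AA_FREQ_OPERON <- c(
  A = 0.100, C = 0.008, D = 0.040, E = 0.040, F = 0.070, G = 0.050,
  H = 0.012, I = 0.040, K = 0.030, L = 0.120, M = 0.020, N = 0.030,
  P = 0.090, Q = 0.020, R = 0.020, S = 0.120, T = 0.080, V = 0.050,
  W = 0.008, Y = 0.022
)

#' Build a synonymous codon-usage profile
#'
#' A usage profile assigns each amino-acid family a probability vector over
#' its synonymous codons, driven by third-base weights: the weight of a codon
#' is its third base's weight raised to \code{bias_strength}, renormalized
#' within the family. \code{bias_strength = 0} gives uniform within-family
#' usage; large values concentrate each family on its favoured third base
#' where the family allows it.
#'
#' @param target_gc3 Target GC3 fraction in [0, 1]; translated into
#'   third-base weights \code{(A, C, G, T) = ((1-g)/2, g/2, g/2, (1-g)/2)}.
#'   Ignored when \code{base3_weights} is given.
#' @param bias_strength Non-negative sharpening exponent (default 1).
#' @param base3_weights Optional named weight vector over \code{A, C, G, T}
#'   for fine control (e.g. pyrimidine-skewed third positions).
#' @return Named list (one element per amino acid) of probability vectors
#'   over the family's codons, with the weights stored as attributes.
#' @export
make_profile <- function(target_gc3 = NULL, bias_strength = 1,
                         base3_weights = NULL) {
  if (is.null(base3_weights)) {
    if (is.null(target_gc3) || !is.finite(target_gc3) ||
        target_gc3 < 0 || target_gc3 > 1) {
      stop("`target_gc3` must be a fraction in [0, 1]", call. = FALSE)
    }
    base3_weights <- c(A = (1 - target_gc3) / 2, C = target_gc3 / 2,
                       G = target_gc3 / 2, T = (1 - target_gc3) / 2)
  }
  if (!all(c("A", "C", "G", "T") %in% names(base3_weights)) ||
      any(base3_weights < 0) || sum(base3_weights) == 0) {
    stop("`base3_weights` must be non-negative weights over A, C, G, T",
         call. = FALSE)
  }
  if (bias_strength < 0) {
    stop("`bias_strength` must be >= 0", call. = FALSE)
  }
  ct <- codon_table()
  profile <- lapply(ct$families, function(fam) {
    w <- base3_weights[substr(fam, 3L, 3L)]^bias_strength
    if (sum(w) == 0) {           # family has no allowed third base: fall back
      w <- rep(1, length(fam))
    }
    stats::setNames(as.numeric(w / sum(w)), fam)
  })
  attr(profile, "base3_weights") <- base3_weights
  attr(profile, "bias_strength") <- bias_strength
  profile
}

# Couple codon preference to amino-acid demand (the translation-accuracy
# structure): mix each family's weight vector with a point mass on its
# favoured codon so that the favoured codon's expected RSCU is linear in the
# amino acid's relative usage, m = 1 + coupling * u/max(u), capped just
# below the family size. Families keep their third-base character; only the
# degree of concentration tracks usage.
plant_accuracy <- function(profile, aa_freq, coupling) {
  u <- aa_freq[names(profile)] / max(aa_freq)
  out <- profile
  for (a in names(profile)) {
    v <- profile[[a]]
    k <- length(v)
    if (k < 2L) {
      next
    }
    top <- which.max(v)
    target <- min(1 + coupling * u[[a]], k - 0.05)
    lambda <- (target / k - v[[top]]) / (1 - v[[top]])
    lambda <- max(0, lambda)
    v <- (1 - lambda) * v
    v[[top]] <- v[[top]] + lambda
    out[[a]] <- v / sum(v)
  }
  attributes(out) <- attributes(profile)
  out
}

# Expected sense-codon usage under an amino-acid frequency and a profile.
expected_codon_usage <- function(aa_freq, profile) {
  aa_freq <- aa_freq / sum(aa_freq)
  u <- stats::setNames(numeric(length(.SENSE_CODONS)), .SENSE_CODONS)
  for (a in names(profile)) {
    u[names(profile[[a]])] <- aa_freq[[a]] * profile[[a]]
  }
  u
}

#' Specification of a synthetic genome
#'
#' Collects every parameter of the generator with defaults chosen to emulate
#' a single high-GC methanotroph-like genome: a GC3-rich background, a
#' sharper pyrimidine-leaning ribosomal reference, and a planted three-gene
#' operon whose codon usage is low-GC3, pyrimidine-enriched, rank-aligned
#' with the ribosomal preference but divergent from the background, highly
#' expressed, and accuracy-coupled (within-family sharpening grows with
#' amino-acid usage).
#'
#' @param n_background Number of unlabelled background genes.
#' @param n_ribosomal Number of genes labelled \code{"ribosomal"}.
#' @param operon_size Number of planted-operon genes.
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   in codons.
#' @param min_length Minimum gene length in codons.
#' @param aa_freq Background/ribosomal amino-acid frequencies.
#' @param operon_aa_freq Planted-operon amino-acid frequencies.
#' @param background_base3,ribosomal_base3,operon_base3 Third-base weight
#'   vectors of the three usage profiles.
#' @param accuracy_coupling Usage-coupled sharpening strength of the planted
#'   profile (0 disables).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of mRNA abundance.
#' @param operon_boost Multiplicative expression boost of the planted operon.
#' @param trna_scale Scale of tGCN relative to expected background codon
#'   usage (copies are \code{max(1, round(trna_scale * usage))}).
#' @param exclude_c3_anticodons Drop anticodons with cytosine at the 3' end
#'   from the pool (the type Ia methanotroph feature); unreadable codons are
#'   re-covered with a single-copy Watson-Crick anticodon.
#' @param planted Logical; \code{FALSE} draws the operon from the background
#'   profile and amino-acid frequencies with no expression boost, abolishing
#'   every planted signature.
#' @param seed Integer seed governing all draws.
#' @return A list of class \code{"genome_spec"}.
#' @export
genome_spec <- function(n_background = 330L, n_ribosomal = 30L,
                        operon_size = 3L,
                        length_meanlog = log(250), length_sdlog = 0.25,
                        min_length = 60L,
                        aa_freq = .AA_FREQ_DEFAULT,
                        operon_aa_freq = .AA_FREQ_OPERON,
                        background_base3 = c(A = 0.10, C = 0.25,
                                             G = 0.50, T = 0.15),
                        ribosomal_base3 = c(A = 0.05, C = 0.45,
                                            G = 0.12, T = 0.38),
                        operon_base3 = c(A = 0.08, C = 0.40,
                                         G = 0.06, T = 0.46),
                        accuracy_coupling = 3,
                        expr_meanlog = log(50), expr_sdlog = 1.2,
                        operon_boost = 400,
                        trna_scale = 90,
                        exclude_c3_anticodons = TRUE,
                        planted = TRUE,
                        seed = 101L) {
  spec <- list(n_background = as.integer(n_background),
               n_ribosomal = as.integer(n_ribosomal),
               operon_size = as.integer(operon_size),
               length_meanlog = length_meanlog, length_sdlog = length_sdlog,
               min_length = as.integer(min_length),
               aa_freq = aa_freq / sum(aa_freq),
               operon_aa_freq = operon_aa_freq / sum(operon_aa_freq),
               background_base3 = background_base3,
               ribosomal_base3 = ribosomal_base3,
               operon_base3 = operon_base3,
               accuracy_coupling = accuracy_coupling,
               expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
               operon_boost = operon_boost,
               trna_scale = trna_scale,
               exclude_c3_anticodons = isTRUE(exclude_c3_anticodons),
               planted = isTRUE(planted),
               seed = as.integer(seed))
  stopifnot(spec$n_background > 0L, spec$n_ribosomal > 0L,
            spec$operon_size > 0L, spec$min_length > 0L,
            spec$operon_boost > 0, spec$trna_scale > 0)
  class(spec) <- "genome_spec"
  spec
}

sample_gene <- function(n_codons, aa_freq, profile) {
  aa_seq <- sample(names(aa_freq), n_codons, replace = TRUE, prob = aa_freq)
  codons <- character(n_codons)
  for (a in unique(aa_seq)) {
    idx <- which(aa_seq == a)
    fam <- profile[[a]]
    codons[idx] <- sample(names(fam), length(idx), replace = TRUE, prob = fam)
  }
  paste0(paste(codons, collapse = ""), "TAA")
}

# Watson-Crick anticodon (RNA, 5'->3') of a DNA codon.
wc_anticodon <- function(codon) {
  reverse_complement_rna(dna_to_rna(codon))
}

build_trna_pool <- function(usage, trna_scale, exclude_c3, rules) {
  pool <- stats::setNames(numeric(0), character(0))
  for (codon in names(usage)) {
    ac <- wc_anticodon(codon)
    copies <- max(1L, round(trna_scale * usage[[codon]]))
    pool[ac] <- if (ac %in% names(pool)) pool[[ac]] + copies else copies
  }
  if (exclude_c3) {
    pool <- pool[substr(names(pool), 3L, 3L) != "C"]
  }
  # guarantee every sense codon is readable under the pairing rules
  repeat {
    W <- absolute_adaptiveness(pool, rules)
    uncovered <- attr(W, "uncovered")
    if (length(uncovered) == 0L) {
      break
    }
    ac <- wc_anticodon(uncovered[[1L]])
    pool[ac] <- if (ac %in% names(pool)) pool[[ac]] + 1L else 1L
  }
  pool <- pool[order(names(pool))]
  stats::setNames(as.integer(pool), names(pool))
}

#' Generate a synthetic genome with a planted operon
#'
#' Draws coding sequences gene by gene (amino acids from the spec's
#' frequency vector, codons from the gene's usage profile, terminal TAA
#' appended), assembles the gene-set map ("ribosomal" plus the planted
#' operon), builds a tRNA pool proportional to expected background codon
#' usage (Watson-Crick anticodons, optionally without 3'-cytosine
#' anticodons), and samples log-normal mRNA abundances with the planted
#' operon boosted. All randomness flows from \code{spec$seed}.
#'
#' @param spec A [genome_spec()].
#' @return A list of class \code{"codon_genome"}: \code{cds} (named CDS
#'   vector), \code{gene_sets}, \code{trna_pool}, \code{expression},
#'   \code{truth} (the planted parameters and seed) and \code{spec}.
#' @export
simulate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  rules <- pairing_rules()

  prof_bg <- make_profile(base3_weights = spec$background_base3)
  prof_ribo <- make_profile(base3_weights = spec$ribosomal_base3,
                            bias_strength = 1.5)
  if (spec$planted) {
    prof_op <- make_profile(base3_weights = spec$operon_base3)
    if (spec$accuracy_coupling > 0) {
      prof_op <- plant_accuracy(prof_op, spec$operon_aa_freq,
                                  spec$accuracy_coupling)
    }
    aa_op <- spec$operon_aa_freq
  } else {
    prof_op <- prof_bg
    aa_op <- spec$aa_freq
  }

  n_total <- spec$n_background + spec$n_ribosomal + spec$operon_size
  ids <- c(sprintf("bg_%04d", seq_len(spec$n_background)),
           sprintf("ribo_%03d", seq_len(spec$n_ribosomal)),
           sprintf("operon_%d", seq_len(spec$operon_size)))
  role <- rep(c("background", "ribosomal", "operon"),
              c(spec$n_background, spec$n_ribosomal, spec$operon_size))
  lengths <- pmax(spec$min_length,
                  round(stats::rlnorm(n_total, spec$length_meanlog,
                                      spec$length_sdlog)))
  cds <- character(n_total)
  for (i in seq_len(n_total)) {
    cds[i] <- switch(role[i],
      background = sample_gene(lengths[i], spec$aa_freq, prof_bg),
      ribosomal = sample_gene(lengths[i], spec$aa_freq, prof_ribo),
      operon = sample_gene(lengths[i], aa_op, prof_op))
  }
  names(cds) <- ids

  gene_sets <- data.frame(
    gene_id = ids[role != "background"],
    set = ifelse(role[role != "background"] == "ribosomal",
                 "ribosomal", "planted_operon"),
    stringsAsFactors = FALSE)

  usage_bg <- expected_codon_usage(spec$aa_freq, prof_bg)
  trna_pool <- build_trna_pool(usage_bg, spec$trna_scale,
                               spec$exclude_c3_anticodons, rules)

  expression <- stats::rlnorm(n_total, spec$expr_meanlog, spec$expr_sdlog)
  if (spec$planted) {
    expression[role == "operon"] <- expression[role == "operon"] *
      spec$operon_boost
  }
  names(expression) <- ids

  out <- list(
    cds = cds,
    gene_sets = gene_sets,
    trna_pool = trna_pool,
    expression = expression,
    truth = list(planted = spec$planted,
                 operon_genes = ids[role == "operon"],
                 operon_set = "planted_operon",
                 operon_base3 = spec$operon_base3,
                 accuracy_coupling = spec$accuracy_coupling,
                 operon_boost = if (spec$planted) spec$operon_boost else 1,
                 seed = spec$seed),
    spec = spec)
  class(out) <- "codon_genome"
  out
}

#' @export
print.codon_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$cds), "coding sequences\n")
  cat("  gene sets:",
      paste(sprintf("%s (n=%d)", names(table(x$gene_sets$set)),
                    as.integer(table(x$gene_sets$set))), collapse = ", "),
      "\n")
  cat("  tRNA pool:", length(x$trna_pool), "anticodons,",
      sum(x$trna_pool), "gene copies\n")
  cat("  planted operon:", if (x$truth$planted)
    paste(x$truth$operon_genes, collapse = ", ") else "disabled",
    "\n")
  cat("  seed:", x$truth$seed, "\n")
  invisible(x)
}

#' Write a synthetic genome to the pipeline's file formats
#'
#' Emits \code{cds.fasta}, \code{gene_sets.tsv}, \code{trna_pool.tsv},
#' \code{expression.tsv} and \code{metadata.json} (planted truth record and
#' seed) into a directory, byte-stable for a fixed genome.
#'
#' @param genome A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "codon_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cds = file.path(dir, "cds.fasta"),
    gene_sets = file.path(dir, "gene_sets.tsv"),
    trna = file.path(dir, "trna_pool.tsv"),
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.json"))
  writeLines(paste0(">", names(genome$cds), "\n", unname(genome$cds)),
             paths[["cds"]])
  write_tsv(genome$gene_sets, paths[["gene_sets"]])
  write_tsv(data.frame(anticodon = names(genome$trna_pool),
                       copies = unname(genome$trna_pool)), paths[["trna"]])
  write_tsv(data.frame(gene_id = names(genome$expression),
                       abundance = unname(genome$expression)),
            paths[["expression"]])
  jsonlite::write_json(genome$truth, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
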