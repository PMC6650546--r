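# Nucleotide- and amino-acid-level composition of single coding sequences:
# GC, GC3, pyrimidine fraction, per-codon elemental demand, amino-acid usage
# and the prebiotic-vs-modern class comparison.

#' GC content of a sequence
#'
#' @param seq Non-empty ACGT string (whole sequence, stop codon included:
#'   the stop is transcribed and costs nucleotides like any other triplet).
#' @return Fraction of G+C over the sequence length.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("`seq` must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop("non-ACGT character in sequence", call. = FALSE)
  }
  bases <- strsplit(seq, "")[[1L]]
  mean(bases %in% c("G", "C"))
}

#' GC3: GC content at the third codon position
#'
#' Fraction of codons whose third base is G or C, excluding a terminal stop
#' codon (GC3 is a codon-family metric; the stop belongs to no family).
#'
#' @param cds A valid CDS string.
#' @return Fraction in [0, 1].
#' @examples
#' gc3_content("ATGGCC")  # 1
#' @export
gc3_content <- function(cds) {
  cds <- validate_cds(cds)
  codons <- sense_codons_of(cds)
  if (length(codons) == 0L) {
    stop("no sense codons after dropping the terminal stop", call. = FALSE)
  }
  third <- substr(codons, 3L, 3L)
  mean(third %in% c("G", "C"))
}

#' Pyrimidine fraction of a coding sequence
#'
#' Fraction of pyrimidine residues (C + U, i.e. C + T on the DNA sense
#' strand) over the whole transcribed sequence, stop codon included.
#'
#' @param cds A valid CDS string.
#' @return Fraction in [0, 1].
#' @export
pyrimidine_fraction <- function(cds) {
  cds <- validate_cds(cds)
  bases <- strsplit(cds, "")[[1L]]
  mean(bases %in% c("C", "T"))
}

#' Elemental demand per codon of a transcript
#'
#' Mean number of C, H, N and O atoms per codon contributed by the nucleobases
#' of the transcript (sense strand read as RNA, terminal stop excluded). The
#' invariant ribose-phosphate backbone is omitted: it adds the same constant
#' per residue and cancels in all comparisons.
#'
#' @param cds A valid CDS string.
#' @return Named numeric vector with elements \code{C}, \code{H}, \code{N},
#'   \code{O} (atoms per codon).
#' @examples
#' element_per_codon("AAAAAA")  # 3 adenines per codon: C=15, H=15, N=15, O=0
#' @export
element_per_codon <- function(cds) {
  cds <- validate_cds(cds)
  codons <- sense_codons_of(cds)
  if (length(codons) == 0L) {
    stop("no sense codons after dropping the terminal stop", call. = FALSE)
  }
  bases <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  bases[bases == "T"] <- "U"
  totals <- colSums(.BASE_ATOMS[bases, , drop = FALSE])
  totals / length(codons)
}

#' Amino-acid usage of a protein
#'
#' @param protein Non-empty one-letter-code protein string.
#' @return Named 20-vector of fractional usages (sums to 1), ordered
#'   alphabetically by one-letter code.
#' @export
amino_acid_usage <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0L) {
    stop("`protein` must be a single non-empty string", call. = FALSE)
  }
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (!all(aa %in% .AMINO_ACIDS)) {
    stop("non-standard amino acid in protein", call. = FALSE)
  }
  counts <- table(factor(aa, levels = .AMINO_ACIDS))
  stats::setNames(as.vector(counts) / length(aa), .AMINO_ACIDS)
}

#' Full composition record of one coding sequence
#'
#' @param cds A valid CDS string.
#' @param gene_id Identifier used in the output.
#' @return One-row data.frame: gene id, length in codons (terminal stop
#'   excluded), GC, GC3, pyrimidine fraction and per-codon C/H/N/O demand.
#' @export
composition_record <- function(cds, gene_id = "<cds>") {
  cds <- validate_cds(cds, id = gene_id)
  elems <- element_per_codon(cds)
  data.frame(
    gene_id = gene_id,
    length_codons = length(sense_codons_of(cds)),
    gc = gc_content(cds),
    gc3 = gc3_content(cds),
    pyrimidine = pyrimidine_fraction(cds),
    atoms_C = elems[["C"]],
    atoms_H = elems[["H"]],
    atoms_N = elems[["N"]],
    atoms_O = elems[["O"]],
    stringsAsFactors = FALSE
  )
}

#' Prebiotic-versus-modern amino-acid usage comparison
#'
#' For each protein the fractional usage of every amino acid is computed; the
#' twenty values per protein are split into the prebiotic and modern classes
#' and the pooled samples are compared with a two-sided Welch t test (results
#' are conventionally read at the 99% confidence level). Proteins biased
#' toward inexpensive (prebiotic) residues give a positive mean difference.
#'
#' @param proteins Character vector (length >= 2) of protein strings.
#' @param classes Output of [amino_acid_classes()].
#' @return List: per-class pooled usage samples, per-class medians, the Welch
#'   t statistic, degrees of freedom and two-sided p value.
#' @export
class_usage_comparison <- function(proteins, classes = amino_acid_classes()) {
  if (length(proteins) < 2L) {
    stop("need at least two proteins", call. = FALSE)
  }
  usage <- t(vapply(proteins, amino_acid_usage, numeric(20L)))
  pre <- as.vector(usage[, classes$prebiotic, drop = FALSE])
  mod <- as.vector(usage[, classes$modern, drop = FALSE])
  if (stats::var(pre) + stats::var(mod) == 0 && mean(pre) == mean(mod)) {
    # both samples constant and equal: no effect by construction
    ht <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = 1)
  } else {
    ht <- stats::t.test(pre, mod)
  }
  list(
    prebiotic = pre,
    modern = mod,
    median_prebiotic = stats::median(pre),
    median_modern = stats::median(mod),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    conf_level = 0.99
  )
}
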