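# Genetic code, nucleobase chemistry and amino-acid class tables.
# Everything downstream (composition, RSCU/CAI/ENC, tAI, budgets) reads these.

# Standard genetic code in NCBI codon order (third base cycling fastest).
# Bacterial CDSs use the standard codon -> amino acid map; alternative start
# codons do not matter for whole-CDS metrics.
.CODE_STRING <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
.DNA_BASES <- c("T", "C", "A", "G")

.all_codons <- paste0(
  rep(.DNA_BASES, each = 16L),
  rep(rep(.DNA_BASES, each = 4L), times = 4L),
  rep(.DNA_BASES, times = 16L)
)

.GENETIC_CODE <- stats::setNames(strsplit(.CODE_STRING, "")[[1L]], .all_codons)
.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]
.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
.AMINO_ACIDS <- sort(unique(.GENETIC_CODE[.SENSE_CODONS]))

# Nucleobase atomic composition (free base): adenine C5H5N5, guanine C5H5N5O,
# cytosine C4H5N3O, uracil C4H4N2O2.  The ribose-phosphate backbone adds the
# same constant per residue and cancels in every comparison made here.
.BASE_ATOMS <- matrix(
  c(5, 5, 5, 0,
    5, 5, 5, 1,
    4, 5, 3, 1,
    4, 4, 2, 2),
  nrow = 4L, byrow = TRUE,
  dimnames = list(c("A", "G", "C", "U"), c("C", "H", "N", "O"))
)

.PREBIOTIC_DEFAULT <- c("G", "A", "D", "E", "V", "S", "I", "L", "P", "T")

#' Standard genetic code tables
#'
#' Returns the standard (bacterial) genetic code together with the synonymous
#' codon families and per-amino-acid degeneracy used throughout the package.
#'
#' @return A list with components:
#'   \describe{
#'     \item{code}{named character vector, codon (DNA alphabet) to one-letter
#'       amino acid; stop codons are \code{"*"}.}
#'     \item{families}{named list, amino acid to its synonymous sense codons.}
#'     \item{degeneracy}{named integer vector, amino acid to family size
#'       (1, 2, 3, 4 or 6).}
#'     \item{sense_codons, stop_codons}{character vectors of the 61 sense and
#'       3 stop codons.}
#'   }
#' @examples
#' ct <- codon_table()
#' ct$degeneracy[["L"]]  # leucine is 6-fold degenerate
#' @export
codon_table <- function() {
  families <- split(.SENSE_CODONS, .GENETIC_CODE[.SENSE_CODONS])
  list(
    code = .GENETIC_CODE,
    families = families,
    degeneracy = vapply(families, length, integer(1L)),
    sense_codons = .SENSE_CODONS,
    stop_codons = .STOP_CODONS
  )
}

#' Nucleobase atom counts
#'
#' Atom counts (C, H, N, O) of the four RNA nucleobases. Purines (A, G) carry
#' five nitrogen atoms against three (C) or two (U) for the pyrimidines, which
#' is the chemical basis of transcript elemental-economy arguments.
#'
#' @param base Optional base (one of \code{"A"}, \code{"G"}, \code{"C"},
#'   \code{"U"}; \code{"T"} is accepted and read as \code{"U"}). When missing,
#'   the full 4 x 4 matrix is returned.
#' @return A named numeric vector (C, H, N, O) for a single base, or the full
#'   matrix with one row per base.
#' @examples
#' base_atoms("A")  # C5 H5 N5 O0
#' @export
base_atoms <- function(base) {
  if (missing(base)) {
    return(.BASE_ATOMS)
  }
  stopifnot(is.character(base), length(base) == 1L)
  base <- toupper(base)
  if (base == "T") base <- "U"
  if (!base %in% rownames(.BASE_ATOMS)) {
    stop("unknown base: ", base, call. = FALSE)
  }
  .BASE_ATOMS[base, ]
}

#' Prebiotic and modern amino-acid classes
#'
#' Partition of the 20 standard amino acids into ten "prebiotic" amino acids
#' (available from abiotic chemistry, metabolically inexpensive) and ten
#' "modern" amino acids (requiring evolved biosynthetic pathways, expensive).
#' The default prebiotic set is the consensus early-amino-acid set
#' {Gly, Ala, Asp, Glu, Val, Ser, Ile, Leu, Pro, Thr}; it is configurable
#' because the literature offers slight variants and downstream cost
#' comparisons are sensitive to the split.
#'
#' @param prebiotic Character vector of exactly 10 distinct one-letter codes.
#' @return List with character vectors \code{prebiotic} and \code{modern}
#'   (the complementary ten).
#' @examples
#' amino_acid_classes()$prebiotic
#' @export
amino_acid_classes <- function(prebiotic = .PREBIOTIC_DEFAULT) {
  prebiotic <- unique(toupper(prebiotic))
  if (length(prebiotic) != 10L || !all(prebiotic %in% .AMINO_ACIDS)) {
    stop("`prebiotic` must name exactly 10 of the 20 standard amino acids",
         call. = FALSE)
  }
  list(prebiotic = sort(prebiotic),
       modern = sort(setdiff(.AMINO_ACIDS, prebiotic)))
}

# -- sequence helpers ---------------------------------------------------------

split_codons <- function(dna) {
  n <- nchar(dna)
  substring(dna, seq.int(1L, n, by = 3L), seq.int(3L, n, by = 3L))
}

validate_cds <- function(dna, id = "<cds>") {
  if (!is.character(dna) || length(dna) != 1L || is.na(dna)) {
    stop("CDS must be a single character string (", id, ")", call. = FALSE)
  }
  dna <- toupper(dna)
  if (nchar(dna) == 0L) {
    stop("empty sequence (", id, ")", call. = FALSE)
  }
  if (grepl("[^ACGT]", dna)) {
    stop("non-ACGT character in CDS (", id, ")", call. = FALSE)
  }
  if (nchar(dna) %% 3L != 0L) {
    stop("CDS length not a multiple of 3 (", id, ")", call. = FALSE)
  }
  codons <- split_codons(dna)
  aa <- .GENETIC_CODE[codons]
  internal_stop <- which(aa == "*")
  internal_stop <- internal_stop[internal_stop != length(codons)]
  if (length(internal_stop)) {
    stop("internal stop codon at codon ", internal_stop[1L], " (", id, ")",
         call. = FALSE)
  }
  dna
}

# Codons of a validated CDS with the terminal stop (if any) removed.
sense_codons_of <- function(dna) {
  codons <- split_codons(toupper(dna))
  n <- length(codons)
  if (n > 0L && .GENETIC_CODE[codons[n]] == "*") {
    codons <- codons[-n]
  }
  codons
}

#' Translate a coding sequence
#'
#' Translates a DNA coding sequence under the standard genetic code. A single
#' terminal stop codon is allowed and dropped; internal stop codons, non-ACGT
#' characters and lengths that are not multiples of 3 are errors.
#'
#' @param dna A single DNA string (case-insensitive).
#' @return The protein as a one-letter-code string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(dna) {
  dna <- validate_cds(dna)
  codons <- sense_codons_of(dna)
  if (length(codons) == 0L) {
    stop("CDS consists only of a stop codon", call. = FALSE)
  }
  paste(.GENETIC_CODE[codons], collapse = "")
}

reverse_complement_rna <- function(x) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1L))
}

dna_to_rna <- function(x) gsub("T", "U", x, fixed = TRUE)
rna_to_dna <- function(x) gsub("U", "T", x, fixed = TRUE)
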