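# Readers and writers for the file formats the audit touches:
# CDS FASTA, tRNA-pool / expression / gene-set TSVs.  All TSVs are written
# tab-delimited, UTF-8, "." decimal, with a header, so diffs stay readable.

#' Read coding sequences from a FASTA file
#'
#' Loads one DNA record per CDS, uppercases it and validates it (length a
#' multiple of 3, ACGT alphabet only, no internal stop codon).
#'
#' @param path FASTA file path.
#' @param on_invalid What to do with records failing validation:
#'   \code{"error"} (default) aborts naming the offending record,
#'   \code{"skip"} drops it with a warning listing the rejected ids.
#' @return Named character vector of validated CDS strings (names are the
#'   first whitespace-delimited token of each FASTA header).
#' @export
read_cds_fasta <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  dna <- toupper(as.character(seqs))
  names(dna) <- ids
  bad <- character(0)
  for (i in seq_along(dna)) {
    ok <- tryCatch({
      validate_cds(dna[[i]], id = ids[[i]])
      TRUE
    }, error = function(e) {
      if (on_invalid == "error") stop(e)
      FALSE
    })
    if (!ok) bad <- c(bad, ids[[i]])
  }
  if (length(bad)) {
    warning("rejected ", length(bad), " invalid record(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    dna <- dna[!ids %in% bad]
  }
  dna
}

#' Read a tRNA pool table
#'
#' Reads a two-column TSV (\code{anticodon}, \code{copies}) of tRNA gene copy
#' numbers (tGCN). Anticodons are 5'->3' triplets in the DNA or RNA alphabet;
#' they are normalized to RNA (T -> U) and duplicate rows are summed.
#'
#' @param path TSV file path with header columns \code{anticodon} and
#'   \code{copies}.
#' @return Named integer vector: anticodon (RNA, 5'->3') to tGCN.
#' @export
read_trna_pool <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("anticodon", "copies") %in% names(tab))) {
    stop("tRNA pool table needs columns 'anticodon' and 'copies'", call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("empty tRNA pool table", call. = FALSE)
  }
  ac <- dna_to_rna(toupper(tab$anticodon))
  if (any(nchar(ac) != 3L | grepl("[^ACGU]", ac))) {
    stop("malformed anticodon(s): ",
         paste(unique(tab$anticodon[nchar(ac) != 3L | grepl("[^ACGU]", ac)]),
               collapse = ", "), call. = FALSE)
  }
  copies <- tab$copies
  if (any(!is.finite(copies)) || any(copies < 0)) {
    stop("tGCN copies must be non-negative finite numbers", call. = FALSE)
  }
  pool <- tapply(as.integer(copies), ac, sum)
  pool <- stats::setNames(as.integer(pool), names(pool))
  if (!any(pool > 0L)) {
    stop("tRNA pool has no anticodon with positive copy number", call. = FALSE)
  }
  pool
}

#' Read a normalized mRNA abundance table
#'
#' @param path TSV with header columns \code{gene_id} and \code{abundance}
#'   (non-negative, normalized mRNA units).
#' @param cds Optional named CDS vector; gene ids absent from it are reported
#'   with a warning.
#' @return Named numeric vector: gene id to abundance.
#' @export
read_expression_table <- function(path, cds = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "abundance") %in% names(tab))) {
    stop("expression table needs columns 'gene_id' and 'abundance'",
         call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id rows in expression table", call. = FALSE)
  }
  if (any(!is.finite(tab$abundance)) || any(tab$abundance < 0)) {
    stop("abundances must be non-negative finite numbers", call. = FALSE)
  }
  expr <- stats::setNames(as.numeric(tab$abundance), tab$gene_id)
  if (!any(expr > 0)) {
    stop("expression table has no positive abundance", call. = FALSE)
  }
  if (!is.null(cds)) {
    missing_ids <- setdiff(names(expr), names(cds))
    if (length(missing_ids)) {
      warning("expression table gene(s) absent from CDS set: ",
              paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  expr
}

#' Read a gene-set membership table
#'
#' Reads a TSV with header columns \code{gene_id} and \code{set}. The label
#' \code{"ribosomal"} marks the reference set of ribosomal-protein genes and
#' \code{"genome"} is reserved for the implicit background (every gene), so it
#' may not be used as an explicit label. A gene may carry at most one label.
#'
#' @param path TSV file path.
#' @param cds Optional named CDS vector used to flag labelled genes that have
#'   no sequence.
#' @return A data.frame with columns \code{gene_id} and \code{set}.
#' @export
read_gene_sets <- function(path, cds = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "set") %in% names(tab))) {
    stop("gene-set table needs columns 'gene_id' and 'set'", call. = FALSE)
  }
  tab <- tab[, c("gene_id", "set")]
  tab <- unique(tab)
  if (anyDuplicated(tab$gene_id)) {
    dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
    stop("conflicting set labels for gene(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(tab$set == "genome")) {
    stop("'genome' is the reserved implicit background label", call. = FALSE)
  }
  if (!is.null(cds)) {
    missing_ids <- setdiff(tab$gene_id, names(cds))
    if (length(missing_ids)) {
      warning("gene-set table gene(s) absent from CDS set: ",
              paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  tab
}

# Shared TSV writer: deterministic formatting for byte-stable reports.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

gene_set_labels <- function(gene_sets, gene_ids) {
  labels <- rep("genome", length(gene_ids))
  names(labels) <- gene_ids
  if (!is.null(gene_sets) && nrow(gene_sets)) {
    hit <- gene_sets$gene_id %in% gene_ids
    labels[gene_sets$gene_id[hit]] <- gene_sets$set[hit]
  }
  labels
}
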