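#' Construct a genome record
#'
#' A `genome_record` is one contig: an id, its DNA sequence and an ordered
#' table of gene features. All internal coordinates are 0-based half-open;
#' GenBank and GFF3 I/O convert at the boundary.
#'
#' @param contig_id Non-empty contig identifier.
#' @param sequence DNA string (A/C/G/T/N).
#' @param features Feature table as built by [gene_feature()] rows or an
#'   equivalent data frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `kind`, `protein`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(contig_id, sequence, features = empty_features()) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L,
            nzchar(contig_id), is.character(sequence), length(sequence) == 1L)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand", "kind", "protein")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  validate_features(features, nchar(sequence))
  structure(list(contig_id = contig_id,
                 sequence = toupper(sequence),
                 features = features),
            class = "genome_record")
}

#' Build one gene feature row
#'
#' @param gene_id Feature identifier.
#' @param start,end 0-based half-open interval on the contig.
#' @param strand `"+"` or `"-"`.
#' @param kind `"CDS"`, `"pseudo"` or `"other"`.
#' @param protein Amino-acid string (stop codon excluded) or `NA`.
#' @return One-row data frame.
#' @export
gene_feature <- function(gene_id, start, end, strand = "+", kind = "CDS",
                         protein = NA_character_) {
  stopifnot(start < end, strand %in% c("+", "-"),
            kind %in% c("CDS", "pseudo", "other"))
  data.frame(gene_id = gene_id, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             protein = protein, stringsAsFactors = FALSE)
}

empty_features <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), protein = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, contig_len) {
  if (!nrow(features)) return(invisible(TRUE))
  if (any(features$start >= features$end))
    stop("feature with start >= end")
  if (any(features$start < 0L) || any(features$end > contig_len))
    stop("feature interval outside [0, contig length)")
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(features$kind %in% c("CDS", "pseudo", "other")))
    stop("kind must be CDS, pseudo or other")
  invisible(TRUE)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d features\n",
              x$contig_id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Reverse-complement a genome record
#'
#' Flips the contig sequence and remaps every feature interval and strand.
#' Classification is expected to be invariant under this operation.
#'
#' @param record A [genome_record()].
#' @return The flipped `genome_record`.
#' @export
reverse_complement_record <- function(record) {
  len <- nchar(record$sequence)
  seq_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(record$sequence)))
  f <- record$features
  if (nrow(f)) {
    new_start <- len - f$end
    new_end <- len - f$start
    f$start <- new_start
    f$end <- new_end
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  genome_record(record$contig_id, seq_rc, f)
}
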