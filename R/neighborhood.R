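# Gene-context extraction around HicA-domain-bearing genes. Upstream and
# downstream are relative to the focal gene's own strand (5' -> 3'), so the
# classification rules read in transcription order and are invariant under
# contig reverse-complementation.

#' Find HicA-domain-bearing focal genes
#'
#' Every CDS whose architecture contains at least one `HicA_dsRBD` hit, in
#' contig order. Fusions (SMC-HicA, HicA-HicB) are focal too; `pseudo`
#' features never are.
#'
#' @param record A [genome_record()].
#' @param architectures Named list `gene_id -> architecture` from
#'   [scan_genome()].
#' @return Feature-table subset (data frame) of focal genes.
#' @export
find_hica_loci <- function(record, architectures) {
  f <- record$features
  has_hica <- vapply(seq_len(nrow(f)), function(i) {
    if (f$kind[i] != "CDS") return(FALSE)
    a <- architectures[[f$gene_id[i]]]
    !is.null(a) && any(a$domain_label == "HicA_dsRBD")
  }, logical(1))
  out <- f[has_hica, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intergenic gap between two features on the same contig
#'
#' For `a` starting at or before `b`: `b$start - a$end` in the 0-based
#' half-open convention. Negative values are overlap lengths; 0 means the
#' genes abut.
#'
#' @param a,b Feature rows with `a$start <= b$start`.
#' @return Integer nucleotides.
#' @export
intergenic_gap <- function(a, b) {
  if (!is.null(a$contig_id) && !is.null(b$contig_id) &&
      !identical(a$contig_id, b$contig_id))
    stop("features lie on different contigs")
  stopifnot(a$start <= b$start)
  as.integer(b$start - a$end)
}

#' Linkage category of an intergenic gap
#'
#' `overlapping` iff the gap is negative; `closely_linked` iff
#' `0 <= gap <= max_gap` (boundary inclusive); otherwise `distal`. Short gaps
#' and overlaps between toxin and antitoxin genes indicate translational
#' coupling.
#'
#' @param gap Integer gap (vectorized).
#' @param max_gap Inclusive upper bound for close linkage (default 10 nt).
#' @return Character vector over `{overlapping, closely_linked, distal}`.
#' @export
coupling_flag <- function(gap, max_gap = 10L) {
  ifelse(gap < 0L, "overlapping",
         ifelse(gap <= max_gap, "closely_linked", "distal"))
}

#' Build the gene context around a focal gene
#'
#' Collects up to `window_genes` neighbors on each side of the focal gene
#' (strand-relative: "downstream" follows the focal gene in its own reading
#' direction), with signed intergenic gaps to the focal gene and attached
#' architectures.
#'
#' @param record A [genome_record()].
#' @param focal One feature row of `record$features`.
#' @param window_genes Neighbors per side (default 5).
#' @param architectures Named list from [scan_genome()].
#' @return A `locus_context` object.
#' @export
build_context <- function(record, focal, window_genes = 5L,
                          architectures = list()) {
  f <- record$features
  idx <- which(f$gene_id == focal$gene_id & f$start == focal$start)
  if (!length(idx)) stop("focal gene not found in record")
  idx <- idx[1]
  left_idx <- rev(seq_len(idx - 1L))
  right_idx <- if (idx < nrow(f)) (idx + 1L):nrow(f) else integer()
  take <- function(ids) ids[seq_len(min(window_genes, length(ids)))]
  left_idx <- take(left_idx)
  right_idx <- take(right_idx)

  side_tab <- function(ids, side) {
    if (!length(ids)) return(NULL)
    tab <- f[ids, , drop = FALSE]
    tab$side <- side
    tab$rank <- seq_along(ids)
    tab$gap_nt <- vapply(ids, function(j) {
      if (f$start[j] >= focal$start) intergenic_gap(focal, f[j, ])
      else intergenic_gap(f[j, ], focal)
    }, integer(1))
    tab
  }
  # contig-coordinate sides, then swap if the focal gene is on '-'
  left <- side_tab(left_idx, "upstream")
  right <- side_tab(right_idx, "downstream")
  if (focal$strand == "-") {
    if (!is.null(left)) left$side <- "downstream"
    if (!is.null(right)) right$side <- "upstream"
  }
  neighbors <- rbind(left, right)
  if (is.null(neighbors)) {
    neighbors <- cbind(empty_features(),
                       data.frame(side = character(), rank = integer(),
                                  gap_nt = integer()))
  }
  rownames(neighbors) <- NULL
  structure(list(contig_id = record$contig_id,
                 focal = focal,
                 focal_arch = architectures[[focal$gene_id]] %||% empty_hits(),
                 neighbors = neighbors,
                 architectures = architectures,
                 window_genes = as.integer(window_genes)),
            class = "locus_context")
}

#' @export
print.locus_context <- function(x, ...) {
  cat(sprintf("<locus_context> %s on %s [%d, %d) %s: %d neighbors\n",
              x$focal$gene_id, x$contig_id, x$focal$start, x$focal$end,
              x$focal$strand, nrow(x$neighbors)))
  invisible(x)
}

# rank-k neighbor table on one strand-relative side
context_side <- function(ctx, side) {
  nb <- ctx$neighbors[ctx$neighbors$side == side, , drop = FALSE]
  nb[order(nb$rank), , drop = FALSE]
}

#' Write a neighborhood table as TSV
#'
#' @param contexts List of [build_context()] results.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_neighborhood_table <- function(contexts, path) {
  rows <- lapply(contexts, function(ctx) {
    nb <- ctx$neighbors
    if (!nrow(nb)) return(NULL)
    labels <- vapply(nb$gene_id, function(g) {
      a <- ctx$architectures[[g]]
      if (is.null(a) || !nrow(a)) "" else
        paste(a$domain_label, collapse = ",")
    }, character(1))
    data.frame(contig = ctx$contig_id, focal_id = ctx$focal$gene_id,
               neighbor_id = nb$gene_id, side = nb$side, rank = nb$rank,
               gap_nt = nb$gap_nt, labels = labels, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(contig = character(), focal_id = character(),
                      neighbor_id = character(), side = character(),
                      rank = integer(), gap_nt = integer(),
                      labels = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
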