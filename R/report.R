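# Per-class summary statistics: counts, length ranges, linkage fractions and
# pseudogene discards, with an optional 95%-identity redundancy filter on the
# toxin sequences (greedy, ordered by locus id, so results are deterministic).

#' Summarize class assignments
#'
#' One row per class 1-14 (plus an `unclassified` row): locus count, HicA and
#' HicB length ranges, closely-linked and overlapping counts, the
#' closely-linked percentage, and the number of pseudogene candidates
#' discarded from the count. Percentages are kept at full precision; the
#' print method rounds to whole percent.
#'
#' @param assignments Data frame from [classify_genome()].
#' @param redundancy_filter If `TRUE`, drop loci whose HicA protein is at
#'   least `identity_threshold` identical to an already-kept HicA (greedy,
#'   ordered by `locus_id`).
#' @param identity_threshold Redundancy threshold (default 0.95), computed as
#'   global-alignment matches over the shorter sequence.
#' @return A `class_summary` data frame.
#' @export
summarize_classes <- function(assignments, redundancy_filter = FALSE,
                              identity_threshold = 0.95) {
  tab <- assignments
  if (redundancy_filter && nrow(tab) > 1L) {
    tab <- tab[order(tab$locus_id), , drop = FALSE]
    kept <- integer()
    for (i in seq_len(nrow(tab))) {
      dup <- any(vapply(kept, function(j) {
        a <- tab$focal_protein[i]; b <- tab$focal_protein[j]
        if (is.na(a) || is.na(b)) return(FALSE)
        al <- global_align(a, b)
        al$matches / min(nchar(a), nchar(b)) >= identity_threshold
      }, logical(1)))
      if (!dup) kept <- c(kept, i)
    }
    tab <- tab[kept, , drop = FALSE]
  }
  class_key <- ifelse(is.na(tab$class_id), "unclassified",
                      as.character(tab$class_id))
  levels <- c(as.character(1:14), "unclassified")
  rows <- lapply(levels, function(cl) {
    sub <- tab[class_key == cl, , drop = FALSE]
    pseudo <- sub$pseudogene_candidate
    counted <- sub[!pseudo, , drop = FALSE]
    n <- nrow(counted)
    rng <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) c(NA_integer_, NA_integer_) else range(x)
    }
    ha <- rng(counted$focal_len)
    # the recorded partner is a HicB only for the bicistronic TA classes;
    # for classes 9/10 it is the pVip gene and carries no antitoxin length
    hb <- if (cl %in% as.character(1:8)) rng(counted$partner_len)
          else c(NA_integer_, NA_integer_)
    ncl <- sum(counted$closely_linked); nov <- sum(counted$overlapping)
    data.frame(class_id = cl, n_loci = n,
               hica_len_min = ha[1], hica_len_max = ha[2],
               hicb_len_min = hb[1], hicb_len_max = hb[2],
               n_closely_linked = ncl, n_overlapping = nov,
               pct_closely_linked = if (n) 100 * ncl / n else NA_real_,
               n_pseudogene_discarded = sum(pseudo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("class_summary", "data.frame")
  out
}

#' @export
print.class_summary <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$pct_closely_linked <- ifelse(
    is.na(shown$pct_closely_linked), NA,
    sprintf("%d%%", round(shown$pct_closely_linked)))
  print.data.frame(shown[shown$n_loci > 0 | shown$n_pseudogene_discarded > 0,
                         , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Write class summaries as TSV and JSON
#'
#' The JSON keeps percentages at full precision.
#'
#' @param summary A [summarize_classes()] result.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return `summary`, invisibly.
#' @export
write_summary <- function(summary, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(as.data.frame(summary), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(summary), json, digits = NA,
                         na = "null")
  invisible(summary)
}

#' Write one TSV sheet per class
#'
#' Mirrors a supplementary-table layout: one file per class with per-locus
#' accession, lengths, gap and flags.
#'
#' @param assignments Data frame from [classify_genome()].
#' @param dir Output directory (created if absent).
#' @return Vector of written paths, invisibly.
#' @export
write_class_sheets <- function(assignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  class_key <- ifelse(is.na(assignments$class_id), "unclassified",
                      as.character(assignments$class_id))
  paths <- character()
  for (cl in unique(class_key)) {
    sub <- assignments[class_key == cl,
                       c("locus_id", "contig", "focal_len", "partner_id",
                         "partner_len", "gap_nt", "closely_linked",
                         "overlapping", "pseudogene_candidate"),
                       drop = FALSE]
    p <- file.path(dir, sprintf("class_%s.tsv", cl))
    utils::write.table(sub, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
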