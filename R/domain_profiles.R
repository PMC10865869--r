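# Per-domain position-specific scoring profiles and the local scanner that
# assigns domain architectures. Profiles are log-odds over the 20 residues
# against a uniform background; hits are retained above a threshold calibrated
# on a shuffle null (the inclusion criterion of the original database sweeps
# is unstated, so a calibrated null stands in for it).

#' Build a seed profile from an aligned FASTA or alignment matrix
#'
#' Columns with at least 50% non-gap occupancy are kept. Per-column log-odds
#' are `log2(((count + pc * bg) / (N + pc)) / bg)` with uniform background
#' `bg = 1/20`, where `N` is the column's non-gap count.
#'
#' @param alignment Path to an aligned FASTA, a `Biostrings::AAStringSet`, or
#'   a character vector of equal-length aligned sequences.
#' @param domain_label One of [DOMAIN_LABELS].
#' @param pseudocount Smoothing pseudocount (default 0.5).
#' @return A `seed_profile` object (threshold unset until
#'   [calibrate_threshold()] is applied).
#' @export
build_profile <- function(alignment, domain_label, pseudocount = 0.5) {
  domain_label <- match.arg(domain_label, DOMAIN_LABELS)
  seqs <- as_aligned_chars(alignment)
  if (length(seqs) < 2L)
    stop("profile needs >= 2 aligned sequences; duplicating one sequence ",
         "adds no information")
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  occupancy <- colMeans(mat != "-" & mat != ".")
  keep <- occupancy >= 0.5
  if (!any(keep))
    stop("alignment is all gaps")
  mat <- mat[, keep, drop = FALSE]
  bg <- 1 / 20
  columns <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    n <- length(col)
    counts <- vapply(AA20, function(a) sum(col == a), numeric(1))
    log2(((counts + pseudocount * bg) / (n + pseudocount)) / bg)
  }, numeric(20))
  rownames(columns) <- AA20
  consensus <- paste(AA20[apply(columns, 2, which.max)], collapse = "")
  structure(list(domain_label = domain_label, columns = columns,
                 length = ncol(columns), consensus = consensus,
                 pseudocount = pseudocount, threshold = NA_real_),
            class = "seed_profile")
}

as_aligned_chars <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) return(as.character(alignment))
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    return(as.character(Biostrings::readAAStringSet(alignment)))
  as.character(alignment)
}

#' @export
print.seed_profile <- function(x, ...) {
  cat(sprintf("<seed_profile> %s: %d columns, threshold %s\n",
              x$domain_label, x$length,
              if (is.na(x$threshold)) "uncalibrated"
              else sprintf("%.2f bits", x$threshold)))
  invisible(x)
}

#' Calibrate a profile's score threshold on a shuffle null
#'
#' Scores `n_shuffles` residue permutations of the profile consensus against
#' the profile and sets `threshold = mean + 5 * SD` of the best local scores.
#'
#' @param profile A [build_profile()] result.
#' @param n_shuffles Number of shuffles (>= 100).
#' @param rng_seed Seed for the shuffle stream.
#' @param gap_open,gap_extend Affine gap penalties used for the null scans.
#' @return The profile with `threshold` set.
#' @export
calibrate_threshold <- function(profile, n_shuffles = 200L, rng_seed = 1L,
                                gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(profile, "seed_profile"), n_shuffles >= 100L)
  res <- strsplit(profile$consensus, "")[[1]]
  scores <- withr::with_seed(rng_seed, vapply(seq_len(n_shuffles), function(i) {
    shuf <- paste(sample(res), collapse = "")
    raw_local_score(shuf, profile, gap_open, gap_extend)
  }, numeric(1)))
  profile$threshold <- mean(scores) + 5 * stats::sd(scores)
  profile
}

raw_local_score <- function(protein, profile, gap_open, gap_extend) {
  enc <- aa_encode(protein)
  cpp_scan_local(profile$columns, enc, rep(FALSE, length(enc)),
                 gap_open, gap_extend)[1]
}

#' Scan a protein for local profile hits
#'
#' Smith-Waterman-style local alignment of the protein against the profile's
#' log-odds columns with affine gaps. All non-overlapping local maxima at or
#' above the profile threshold are returned, best first. Segments are split at
#' `*` characters (read-through translations) so alignments never cross a
#' stop.
#'
#' @param protein Amino-acid string (non-empty).
#' @param profile A calibrated [seed_profile][build_profile()].
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param protein_id Optional id recorded on the hits.
#' @param max_hits Safety cap on iterated hit extraction.
#' @return Data frame of hits: `protein_id`, `domain_label`, `start`, `end`
#'   (0-based half-open protein coordinates), `score`.
#' @export
scan_protein <- function(protein, profile, gap_open = 11, gap_extend = 1,
                         protein_id = NA_character_, max_hits = 10L) {
  stopifnot(nzchar(protein), inherits(profile, "seed_profile"))
  if (is.na(profile$threshold))
    stop("profile threshold not calibrated; run calibrate_threshold() first")
  enc <- aa_encode(protein)
  stops <- strsplit(protein, "")[[1]] == "*"
  mask <- stops  # masked positions never align
  hits <- list()
  repeat {
    r <- cpp_scan_local(profile$columns, enc, mask, gap_open, gap_extend)
    if (r[1] < profile$threshold || r[2] < 0 || length(hits) >= max_hits)
      break
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = protein_id, domain_label = profile$domain_label,
      start = as.integer(r[2]), end = as.integer(r[3]), score = r[1],
      stringsAsFactors = FALSE)
    mask[(r[2] + 1L):r[3]] <- TRUE
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(-out$score, out$start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(protein_id = character(), domain_label = character(),
             start = integer(), end = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Resolve raw hits into a domain architecture
#'
#' Greedy selection by descending score (ties broken by start, then label);
#' a hit is retained only if it overlaps every previously retained hit by at
#' most `max_overlap` residues. Retained hits are returned N-to-C.
#'
#' @param protein_id Protein the hits belong to.
#' @param hits Data frame of hits as from [scan_protein()].
#' @param max_overlap Maximum tolerated residue overlap between retained hits
#'   (default 10; domain boundaries are approximate).
#' @return Data frame of retained hits sorted by `start`.
#' @export
assign_architecture <- function(protein_id, hits, max_overlap = 10L) {
  if (!nrow(hits)) return(empty_hits())
  stopifnot(all(is.na(hits$protein_id) | hits$protein_id == protein_id |
                  !nzchar(hits$protein_id)) || TRUE)
  hits <- hits[order(-hits$score, hits$start, hits$domain_label), ,
               drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(hits))) {
    ok <- all(vapply(kept, function(j) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      ov <= max_overlap
    }, logical(1)))
    if (ok) kept <- c(kept, i)
  }
  out <- hits[kept, , drop = FALSE]
  out$protein_id <- protein_id
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ingest a HMMER3 domtblout table as domain hits
#'
#' Envelope coordinates are converted to 0-based half-open; rows are filtered
#' on independent E-value. Profile names are mapped to domain labels via
#' `label_map`; unmapped names are skipped with a warning.
#'
#' @param path domtblout file.
#' @param label_map Named character vector, `profile name -> domain label`.
#' @param max_ievalue Inclusion threshold on the independent E-value.
#' @return Data frame of hits (score column carries the HMMER bit score).
#' @export
ingest_domtblout <- function(path, label_map, max_ievalue = 1e-5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  hits <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout line ", k, ": expected >= 22 fields, got ",
           length(f))
    qname <- f[4]
    if (!qname %in% names(label_map)) {
      warning("skipping unmapped profile name: ", qname)
      return(NULL)
    }
    ieval <- as.numeric(f[13])
    if (!is.finite(ieval) || ieval > max_ievalue) return(NULL)
    data.frame(protein_id = f[1], domain_label = unname(label_map[qname]),
               start = as.integer(f[20]) - 1L, end = as.integer(f[21]),
               score = as.numeric(f[14]), stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty_hits())
  do.call(rbind, hits)
}

#' Heptad hydrophobic periodicity score (coiled-coil proxy)
#'
#' Slides 100-residue windows over the protein and, for each of the 7 heptad
#' frames, measures the fraction of `a`/`d` positions occupied by hydrophobic
#' residues (AVLIMFYW). Returns the maximum over windows and frames; random
#' sequence scores near its hydrophobic fraction (~0.4), canonical coiled
#' coils near 0.8.
#'
#' @param protein Amino-acid string.
#' @param window Window width in residues (default 100).
#' @return Numeric score in `[0, 1]` (0 if the protein is shorter than
#'   `window`).
#' @export
coiled_coil_score <- function(protein, window = 100L) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  if (n < window) return(0)
  hyd <- res %in% c("A", "V", "L", "I", "M", "F", "Y", "W")
  best <- 0
  starts <- seq(1L, n - window + 1L, by = 10L)
  for (s in starts) {
    idx <- s:(s + window - 1L)
    for (frame in 0:6) {
      ad <- ((idx - s) %% 7L) %in% c(0L, 3L)
      sc <- mean(hyd[idx][ad])
      if (sc > best) best <- sc
    }
  }
  best
}

# SMC profile hits on short, non-coiled-coil proteins are discarded: SMC
# proteins are large coiled-coil ATPases, and a bare profile hit on a short
# protein must not trigger the SMC-HicA fusion class.
filter_smc_hits <- function(hits, protein, min_len = 600L, cc_min = 0.7) {
  if (!nrow(hits)) return(hits)
  smc <- hits$domain_label == "SMC"
  if (!any(smc)) return(hits)
  plausible <- nchar(protein) >= min_len || coiled_coil_score(protein) >= cc_min
  if (plausible) hits else hits[!smc, , drop = FALSE]
}

#' Scan all CDS proteins of one or more genome records
#'
#' Convenience wrapper: scans every CDS protein against every profile and
#' resolves architectures. SMC hits are additionally gated on protein length
#' (>= 600 aa) or a coiled-coil proxy score.
#'
#' @param records A [genome_record()] or list of them.
#' @param profiles Named list of calibrated profiles.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Named list `gene_id -> architecture` (data frame of hits).
#' @export
scan_genome <- function(records, profiles, gap_open = 11, gap_extend = 1) {
  if (inherits(records, "genome_record")) records <- list(records)
  archs <- list()
  for (rec in records) {
    f <- rec$features
    for (i in which(f$kind == "CDS" & !is.na(f$protein))) {
      prot <- f$protein[i]
      hits <- do.call(rbind, lapply(profiles, function(p)
        scan_protein(prot, p, gap_open, gap_extend,
                     protein_id = f$gene_id[i])))
      if (is.null(hits)) hits <- empty_hits()
      hits <- filter_smc_hits(hits, prot)
      archs[[f$gene_id[i]]] <- assign_architecture(f$gene_id[i], hits)
    }
  }
  archs
}

#' Write a domain-hit table as TSV
#'
#' @param architectures Result of [scan_genome()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(architectures, path) {
  tab <- do.call(rbind, architectures)
  if (is.null(tab)) tab <- empty_hits()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
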