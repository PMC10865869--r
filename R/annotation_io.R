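# GenBank flat-file and GFF3+FASTA I/O. One internal convention everywhere:
# 0-based half-open intervals; both formats are converted at the boundary
# (their 1-based inclusive coordinates never appear inside the package).

#' Translate a CDS feature
#'
#' Extracts the feature's nucleotides (reverse-complemented for `-` strand),
#' translates with the prokaryotic genetic code (table 11), strips a terminal
#' stop codon and renders internal stops as `*` so that read-through screens
#' can see them. Alternative start codons (ATG/GTG/TTG) translate to M.
#'
#' @param record A [genome_record()].
#' @param feature One feature row from `record$features`.
#' @param partial If `TRUE`, a length not divisible by 3 is tolerated and
#'   trailing bases are dropped; otherwise it is an error.
#' @return Amino-acid string.
#' @export
translate_cds <- function(record, feature, partial = FALSE) {
  stopifnot(feature$start >= 0, feature$end <= nchar(record$sequence))
  nt <- substr(record$sequence, feature$start + 1L, feature$end)
  if (feature$strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  translate_nt(nt, partial = partial)
}

translate_nt <- function(nt, partial = FALSE) {
  extra <- nchar(nt) %% 3L
  if (extra != 0L) {
    if (!partial)
      stop("CDS length not divisible by 3 (use partial = TRUE to truncate)")
    nt <- substr(nt, 1L, nchar(nt) - extra)
  }
  if (!nchar(nt)) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
  # initiation handling: ATG/GTG/TTG (only) read as M at position 1
  if (substr(nt, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    substr(aa, 1L, 1L) <- "M"
  sub("\\*$", "", aa)
}

# ---- GenBank ---------------------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses LOCUS/FEATURES/ORIGIN blocks. CDS features with a `/translation`
#' qualifier keep that protein; others (including `join()` locations) are
#' translated from the spliced sequence. `/pseudo` features are retained with
#' `kind = "pseudo"`.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return List of [genome_record()] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (!length(locus_at))
    stop("no LOCUS line found in ", path)
  ends <- c(locus_at[-1] - 1L, length(lines))
  lapply(seq_along(locus_at), function(k) {
    parse_genbank_record(lines[locus_at[k]:ends[k]], offset = locus_at[k] - 1L)
  })
}

parse_genbank_record <- function(lines, offset = 0L) {
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(locus_fields) < 2L)
    stop("malformed LOCUS line at line ", offset + 1L, ": ", lines[1])
  contig_id <- locus_fields[2]

  feat_at <- grep("^FEATURES", lines)
  orig_at <- grep("^ORIGIN", lines)
  if (length(feat_at) != 1L)
    stop("malformed or missing FEATURES block in record ", contig_id,
         " near line ", offset + 1L)
  if (length(orig_at) != 1L)
    stop("missing ORIGIN block in record ", contig_id)

  seq_lines <- lines[(orig_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_lines <- if (orig_at > feat_at + 1L)
    lines[(feat_at + 1L):(orig_at - 1L)] else character()
  features <- parse_genbank_features(feat_lines, sequence)
  genome_record(contig_id, sequence, features)
}

parse_genbank_features <- function(lines, sequence) {
  starts <- grep("^ {5}\\S", lines)
  feats <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    chunk <- lines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
    if (key == "source") next
    loc <- sub("^ {5}\\S+\\s+", "", chunk[1])
    quals <- chunk[-1]
    # continuation lines of the location (no '/' yet)
    while (length(quals) && !grepl("^\\s*/", quals[1])) {
      loc <- paste0(loc, trimws(quals[1]))
      quals <- quals[-1]
    }
    q <- parse_qualifiers(quals)
    parsed <- parse_gb_location(loc)
    kind <- if (key == "CDS") {
      if (any(c("pseudo", "pseudogene") %in% names(q))) "pseudo" else "CDS"
    } else "other"
    gene_id <- q[["locus_tag"]] %||% q[["gene"]] %||% q[["protein_id"]] %||%
      paste0("feat_", length(feats) + 1L)
    protein <- NA_character_
    if (kind == "CDS") {
      if (!is.null(q[["translation"]])) {
        protein <- gsub("\\s", "", q[["translation"]])
      } else {
        protein <- tryCatch(
          translate_gb_parts(sequence, parsed$parts, parsed$strand),
          error = function(e) NA_character_)
      }
    }
    feats[[length(feats) + 1L]] <- gene_feature(
      gene_id, parsed$start, parsed$end, parsed$strand, kind, protein)
  }
  if (length(feats)) do.call(rbind, feats) else empty_features()
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  starts <- grep("^\\s*/", lines)
  out <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    txt <- paste(trimws(lines[from:to]), collapse = "")
    txt <- sub("^/", "", txt)
    if (grepl("=", txt)) {
      name <- sub("=.*$", "", txt)
      val <- sub("^[^=]*=", "", txt)
      val <- gsub("^\"|\"$", "", val)
      out[[name]] <- val
    } else {
      out[[txt]] <- TRUE
    }
  }
  out
}

# Parse a GenBank location string into strand + ordered parts (0-based
# half-open). Handles a..b, complement(...), join(...), and partial markers.
parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc))
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  pieces <- strsplit(loc, ",")[[1]]
  parts <- lapply(pieces, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else {
      stop("cannot parse location piece: ", p)
    }
    c(ab[1] - 1L, ab[2])  # 1-based inclusive -> 0-based half-open
  })
  c(list(start = min(vapply(parts, `[`, integer(1), 1L)),
         end = max(vapply(parts, `[`, integer(1), 2L)),
         strand = strand),
    parts = list(parts))
}

translate_gb_parts <- function(sequence, parts, strand) {
  nt <- paste(vapply(parts, function(p) substr(sequence, p[1] + 1L, p[2]),
                     character(1)), collapse = "")
  if (strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  translate_nt(nt)
}

#' Write genome records as a GenBank flat file
#'
#' Deterministic output (fixed LOCUS date) so that identical inputs produce
#' byte-identical files.
#'
#' @param records List of [genome_record()] objects (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  out <- unlist(lapply(records, format_genbank_record))
  writeLines(out, path)
  invisible(path)
}

format_genbank_record <- function(record) {
  len <- nchar(record$sequence)
  lines <- c(
    sprintf("LOCUS       %-16s %6d bp    DNA     linear   UNK 01-JAN-2000",
            record$contig_id, len),
    "DEFINITION  synthetic contig.",
    sprintf("ACCESSION   %s", record$contig_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len))
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (f$kind[i] == "other") "misc_feature" else "CDS"
    lines <- c(lines, sprintf("     %-16s%s", key, loc),
               wrap_qualifier("locus_tag", f$gene_id[i]))
    if (f$kind[i] == "pseudo")
      lines <- c(lines, "                     /pseudo")
    if (f$kind[i] == "CDS" && !is.na(f$protein[i]))
      lines <- c(lines, wrap_qualifier("translation", f$protein[i]))
  }
  lines <- c(lines, "ORIGIN")
  seq_lc <- tolower(record$sequence)
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substr(seq_lc, p, min(p + 59L, len))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

wrap_qualifier <- function(name, value) {
  txt <- sprintf("/%s=\"%s\"", name, value)
  width <- 58L
  pieces <- substring(txt, seq(1L, nchar(txt), width),
                      pmin(seq(width, nchar(txt) + width - 1L, width),
                           nchar(txt)))
  paste0("                     ", pieces)
}

# ---- GFF3 + FASTA ----------------------------------------------------------

#' Read a GFF3 + FASTA annotation pair
#'
#' CDS features without a supplied protein are translated with table 11.
#'
#' @param gff GFF3 file (as written by [write_gff_fasta()] or any GFF3 with
#'   `CDS`/`pseudogene` rows carrying `ID` attributes).
#' @param fasta Contig FASTA whose ids match the GFF seqids.
#' @return List of [genome_record()] objects, one per seqid appearing in the
#'   FASTA (contigs without features get empty feature tables).
#' @export
read_gff_fasta <- function(gff, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff)
  seqids <- as.character(GenomicRanges::seqnames(gr))
  missing_ids <- setdiff(unique(seqids), names(seqs))
  if (length(missing_ids))
    stop("GFF seqids absent from FASTA: ", paste(missing_ids, collapse = ", "))
  lapply(names(seqs), function(ctg) {
    sel <- which(seqids == ctg)
    feats <- empty_features()
    if (length(sel)) {
      sub <- gr[sel]
      type <- as.character(sub$type)
      kind <- ifelse(type == "CDS", "CDS",
                     ifelse(type == "pseudogene", "pseudo", "other"))
      ids <- if (!is.null(sub$ID)) as.character(sub$ID) else
        paste0("feat_", seq_along(sel))
      ids[is.na(ids)] <- paste0("feat_", which(is.na(ids)))
      feats <- do.call(rbind, lapply(seq_along(sel), function(i) {
        gene_feature(ids[i],
                     BiocGenerics::start(sub)[i] - 1L,
                     BiocGenerics::end(sub)[i],
                     as.character(BiocGenerics::strand(sub))[i],
                     kind[i])
      }))
    }
    rec <- genome_record(ctg, as.character(seqs[[ctg]]), feats)
    # fill in proteins for CDS rows
    f <- rec$features
    for (i in which(f$kind == "CDS" & is.na(f$protein))) {
      f$protein[i] <- tryCatch(translate_cds(rec, f[i, ]),
                               error = function(e) NA_character_)
    }
    rec$features <- f
    rec
  })
}

#' Write genome records as GFF3 + FASTA
#'
#' Emits 1-based inclusive coordinates, `ID=` and (for CDS rows)
#' `translation_length=` attributes.
#'
#' @param records List of [genome_record()] objects (or a single one).
#' @param gff,fasta Output paths.
#' @return `gff`, invisibly.
#' @export
write_gff_fasta <- function(records, gff, fasta) {
  if (inherits(records, "genome_record")) records <- list(records)
  lines <- "##gff-version 3"
  for (rec in records)
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              rec$contig_id, nchar(rec$sequence)))
  for (rec in records) {
    f <- rec$features
    for (i in seq_len(nrow(f))) {
      type <- switch(f$kind[i], CDS = "CDS", pseudo = "pseudogene", "gene")
      attrs <- sprintf("ID=%s", f$gene_id[i])
      if (f$kind[i] == "CDS" && !is.na(f$protein[i]))
        attrs <- paste0(attrs, sprintf(";translation_length=%d",
                                       nchar(f$protein[i])))
      lines <- c(lines, paste(rec$contig_id, "hicontext", type,
                              f$start[i] + 1L, f$end[i], ".", f$strand[i],
                              if (type == "CDS") "0" else ".", attrs,
                              sep = "\t"))
    }
  }
  writeLines(lines, gff)
  seqs <- Biostrings::DNAStringSet(
    vapply(records, function(r) r$sequence, character(1)))
  names(seqs) <- vapply(records, function(r) r$contig_id, character(1))
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(gff)
}

#' Export CDS proteins as FASTA
#'
#' @param records List of [genome_record()] objects.
#' @param path Output FASTA.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  prots <- character()
  for (rec in records) {
    f <- rec$features
    keep <- f$kind == "CDS" & !is.na(f$protein)
    p <- f$protein[keep]
    names(p) <- f$gene_id[keep]
    prots <- c(prots, p)
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prots), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
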