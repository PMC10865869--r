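# Synthetic annotated genomes with ground-truth labels for all 14 HicA
# genetic-context configurations, plus the decoys that confound real genome
# scans (pseudogene HicBs, solitary antitoxins, neighboring TA modules,
# transposases, RelE-pVip pairs). Every quantity is drawn from one seeded
# stream so a build is reproducible down to the emitted bytes.

ANCESTOR_LENGTHS <- c(HicA_dsRBD = 55L, HicB_pRNaseH = 50L, DBD_HTH = 45L,
                      DBD_RHH = 45L, DBD_PhdYefM = 45L, SharedDomain = 55L,
                      pVip = 280L, SMC = 700L, RelE = 90L, DUF1902 = 55L,
                      NERD = 80L)

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Mutate a protein at a fixed per-site substitution rate
#'
#' Each site (the initiator M excepted) is substituted with probability
#' `divergence` by a uniformly drawn different residue; no indels.
#'
#' @param protein Amino-acid string.
#' @param divergence Per-site substitution probability in `[0, 0.5)`.
#' @param protect_first Keep position 1 fixed (default `TRUE`).
#' @return Mutated protein string.
#' @export
mutate_protein <- function(protein, divergence, protect_first = TRUE) {
  stopifnot(divergence >= 0, divergence < 0.5)
  res <- strsplit(protein, "")[[1]]
  hit <- stats::runif(length(res)) < divergence
  if (protect_first && length(hit)) hit[1] <- FALSE
  for (i in which(hit)) {
    res[i] <- sample(setdiff(AA20, res[i]), 1L)
  }
  paste(res, collapse = "")
}

#' Generate domain ancestors and their detection profiles
#'
#' For each domain label, draws a random ancestor protein of
#' label-appropriate length (HicA 55 aa, HicB partial RNase H 50, DBDs 45,
#' Shared Domain 55, pVip 280, SMC 700, RelE 90, DUF1902 55, NERD 80) and
#' builds a calibrated profile from 8 mutated copies at 15% divergence.
#'
#' @param rng_seed Integer seed; the same seed reproduces the same world.
#' @param n_shuffles Shuffles for threshold calibration (default 120).
#' @return Named list `label -> list(ancestor, profile)`.
#' @export
make_ancestors <- function(rng_seed = 1L, n_shuffles = 120L) {
  withr::with_seed(rng_seed, {
    out <- list()
    for (label in names(ANCESTOR_LENGTHS)) {
      anc <- random_protein(ANCESTOR_LENGTHS[[label]])
      copies <- vapply(seq_len(8L), function(i)
        mutate_protein(anc, 0.15, protect_first = FALSE), character(1))
      prof <- build_profile(copies, label)
      prof <- calibrate_threshold(prof, n_shuffles,
                                  rng_seed = rng_seed + match(
                                    label, names(ANCESTOR_LENGTHS)))
      out[[label]] <- list(ancestor = anc, profile = prof)
    }
    out
  })
}

#' Extract the calibrated profiles from a [make_ancestors()] world
#'
#' @param ancestors A [make_ancestors()] result.
#' @return Named list of `seed_profile`s.
#' @export
profiles_from_world <- function(ancestors) {
  lapply(ancestors, function(x) x$profile)
}

# ---- back-translation ------------------------------------------------------

codon_sets <- function() {
  gc11 <- Biostrings::getGeneticCode("11")
  sense <- gc11[gc11 != "*"]
  sets <- split(names(sense), unname(sense))
  lapply(sets, sort)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# Uniform synonymous back-translation; start codon fixed to ATG (the designed
# proteins all begin with M), stop codon drawn uniformly.
back_translate <- function(protein, sets = codon_sets()) {
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(seq_along(res), function(i) {
    s <- sets[[res[i]]]
    if (is.null(s)) stop("cannot back-translate residue ", res[i])
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

# ---- overlap realization ---------------------------------------------------

# Make gene B start |g| nt before gene A ends by finding synonymous codon
# choices (plus A's stop and B's start codon) under which the shared
# nucleotides agree. Returns the adjusted nucleotide strings or NULL.
solve_overlap <- function(nt_a, prot_a, nt_b, prot_b, g,
                          sets = codon_sets()) {
  ov <- -g
  la <- nchar(nt_a)
  if (ov < 1L || ov > 20L || ov >= nchar(nt_b) || ov >= la) return(NULL)
  a_cod <- strsplit(gsub("(.{3})", "\\1 ", nt_a), " ")[[1]]
  b_cod <- strsplit(gsub("(.{3})", "\\1 ", nt_b), " ")[[1]]
  n_a <- length(a_cod)   # includes the stop codon
  first_a <- ((la - ov) %/% 3L) + 1L  # first A codon touching the overlap
  a_idx <- first_a:n_a
  a_choices <- lapply(a_idx, function(ci) {
    if (ci == n_a) STOP_CODONS else sets[[substr(prot_a, ci, ci)]]
  })
  b_needed <- seq_len((ov + 2L) %/% 3L)  # B codons touching the overlap
  b_choices <- lapply(b_needed, function(ci) {
    if (ci == 1L) START_CODONS else sets[[substr(prot_b, ci, ci)]]
  })
  # DFS over A-side codons; B codons are then matched against the fixed
  # overlap pattern.
  combos <- expand.grid(lapply(a_choices, identity),
                        stringsAsFactors = FALSE)
  if (nrow(combos) > 2e5) return(NULL)
  for (r in seq_len(nrow(combos))) {
    a_try <- a_cod
    a_try[a_idx] <- unlist(combos[r, ])
    tail_a <- substr(paste(a_try, collapse = ""), la - ov + 1L, la)
    ok <- TRUE
    b_try <- b_cod
    for (ci in b_needed) {
      from <- (ci - 1L) * 3L + 1L
      pat <- vapply(1:3, function(p) {
        pos <- from + p - 1L
        if (pos <= ov) substr(tail_a, pos, pos) else ""
      }, character(1))
      match_ok <- vapply(b_choices[[ci]], function(cod) {
        all(pat == "" | pat == strsplit(cod, "")[[1]])
      }, logical(1))
      if (!any(match_ok)) { ok <- FALSE; break }
      b_try[ci] <- b_choices[[ci]][which(match_ok)[1]]
    }
    if (ok)
      return(list(nt_a = paste(a_try, collapse = ""),
                  nt_b = paste(b_try, collapse = "")))
  }
  NULL
}

# ---- locus specification ---------------------------------------------------

DECOY_KINDS <- c("pseudogene_hicb", "solitary_hicb", "neighbor_vapBC",
                 "neighbor_relBE", "transposase", "relE_pvip_pair")

CLASS_DEFAULT_GAPS <- c(`1` = 2L, `2` = 6L, `3` = 15L, `4` = 8L, `5` = -4L,
                        `6` = 2L, `7` = 0L, `8` = 4L, `9` = 50L, `10` = 50L,
                        `11` = NA, `12` = NA, `13` = NA, `14` = NA)

CLASS_DEFAULT_HICB <- c(`1` = 80L, `2` = 85L, `3` = 120L, `4` = 120L,
                        `5` = 105L, `6` = 105L, `7` = 225L, `8` = 345L,
                        `9` = NA, `10` = NA, `11` = NA, `12` = NA,
                        `13` = NA, `14` = NA)

#' Specify one synthetic locus
#'
#' @param class_id Genetic-context class, 1-14.
#' @param hica_len Focal toxin length in aa (`NULL` = class default).
#' @param hicb_len Antitoxin length in aa where the class has one
#'   (`NULL` = class default).
#' @param gap_nt Intergenic gap between the two locus genes (negative =
#'   overlap, >= -20); `NULL` = class default.
#' @param divergence Per-site substitution rate from the domain ancestors,
#'   in `[0, 0.5)`.
#' @param strand `"+"`, `"-"`, or `NULL` to draw at build time.
#' @param decoys Subset of
#'   `c("pseudogene_hicb", "solitary_hicb", "neighbor_vapBC",
#'   "neighbor_relBE", "transposase", "relE_pvip_pair")`.
#' @param rng_seed Optional per-locus seed (otherwise the build stream is
#'   used).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(class_id, hica_len = NULL, hicb_len = NULL,
                           gap_nt = NULL, divergence = 0.1, strand = NULL,
                           decoys = character(), rng_seed = NULL) {
  stopifnot(class_id %in% 1:14, divergence >= 0, divergence < 0.5,
            all(decoys %in% DECOY_KINDS))
  if ("pseudogene_hicb" %in% decoys && !class_id %in% c(3L, 4L))
    stop("pseudogene_hicb decoys are built from Class 3/4 loci")
  key <- as.character(class_id)
  if (is.null(gap_nt)) gap_nt <- CLASS_DEFAULT_GAPS[[key]]
  if (!is.na(gap_nt) && gap_nt < -20L)
    stop("overlaps beyond -20 nt are not constructible; nearest feasible ",
         "gap is -20")
  if (is.null(hicb_len)) hicb_len <- CLASS_DEFAULT_HICB[[key]]
  if (is.null(hica_len))
    hica_len <- switch(key, `6` = 125L, `8` = 95L, 70L)
  structure(list(class_id = as.integer(class_id), hica_len = hica_len,
                 hicb_len = hicb_len, gap_nt = gap_nt,
                 divergence = divergence, strand = strand, decoys = decoys,
                 rng_seed = rng_seed),
            class = "synthetic_spec")
}

#' Default spec set covering the 14 configurations
#'
#' @param per_class Loci per class.
#' @param divergence Per-site substitution rate.
#' @param decoys Decoys attached to every spec (default none).
#' @return List of [synthetic_spec()]s, classes cycling 1-14.
#' @export
default_class_specs <- function(per_class = 1L, divergence = 0.1,
                                decoys = character()) {
  specs <- list()
  for (rep in seq_len(per_class))
    for (cl in 1:14)
      specs[[length(specs) + 1L]] <- synthetic_spec(
        cl, divergence = divergence,
        decoys = intersect(decoys, if (cl %in% 3:4) DECOY_KINDS
                           else setdiff(DECOY_KINDS, "pseudogene_hicb")))
  specs
}

# ---- protein layouts per class ---------------------------------------------

# A gene plan is a list of segments; each segment is either a domain label
# (mutated ancestor copy) or an integer (random pad of that many residues).
# The realized protein is "M" + segments, padded at the end to total_len.
compose_protein <- function(segments, total_len, ancestors, divergence) {
  parts <- character()
  doms <- list()
  pos <- 1L  # after initiator M
  for (seg in segments) {
    if (is.character(seg)) {
      dom <- mutate_protein(ancestors[[seg]]$ancestor, divergence,
                            protect_first = FALSE)
      doms[[length(doms) + 1L]] <- list(label = seg, start = pos,
                                        end = pos + nchar(dom))
      parts <- c(parts, dom)
      pos <- pos + nchar(dom)
    } else {
      parts <- c(parts, random_protein(seg))
      pos <- pos + seg
    }
  }
  body <- paste(parts, collapse = "")
  if (1L + nchar(body) > total_len)
    stop("segments exceed total length ", total_len)
  pad <- total_len - 1L - nchar(body)
  list(protein = paste0("M", body, random_protein(pad)), domains = doms)
}

hica_plan <- function(spec) {
  if (spec$class_id == 6L) list(2L, "HicA_dsRBD", 4L, "SharedDomain")
  else list(2L, "HicA_dsRBD")
}

hicb_plan <- function(spec) {
  switch(as.character(spec$class_id),
         `1` = , `2` = list(2L, "HicB_pRNaseH"),
         `3` = list(2L, "HicB_pRNaseH", 3L, "DBD_HTH"),
         `4` = list(2L, "HicB_pRNaseH", 3L, "DBD_RHH"),
         `5` = , `6` = list(2L, "DBD_PhdYefM", 3L, "HicB_pRNaseH"),
         `7` = list(2L, "HicB_pRNaseH", 3L, "DUF1902"),
         `8` = list(2L, 170L, 60L, "HicB_pRNaseH"),
         NULL)
}

fused_plan <- function(spec, dbd) {
  switch(as.character(spec$class_id),
         `11` = list(plan = list(2L, "HicA_dsRBD", 4L, "HicB_pRNaseH",
                                 4L, dbd), len = 165L),
         `12` = list(plan = list(10L, "HicB_pRNaseH", 12L, "HicA_dsRBD"),
                     len = 135L),
         `13` = list(plan = list(300L, "HicA_dsRBD"), len = 380L),
         `14` = list(plan = list("SMC", 4L, "HicA_dsRBD"), len = 762L))
}

# ---- locus construction ----------------------------------------------------

#' Build one synthetic locus
#'
#' Constructs the genes of one class configuration (mutated domain proteins,
#' uniform-synonymous back-translation, flanking DNA, the specified gap or
#' overlap, decoy genes) as a genome-record fragment plus its truth-table
#' row. Overlaps are realized by finding codon choices under which the two
#' genes genuinely share nucleotides in compatible frames.
#'
#' @param spec A [synthetic_spec()].
#' @param ancestors A [make_ancestors()] world.
#' @param locus_tag Prefix for gene ids (default `"L1"`).
#' @return List with `sequence`, `features` (fragment-relative), and `truth`
#'   (one-row data frame).
#' @export
build_locus <- function(spec, ancestors, locus_tag = "L1") {
  builder <- function() build_locus_impl(spec, ancestors, locus_tag)
  if (is.null(spec$rng_seed)) builder()
  else withr::with_seed(spec$rng_seed, builder())
}

build_locus_impl <- function(spec, ancestors, locus_tag) {
  sets <- codon_sets()
  cl <- spec$class_id
  strand <- spec$strand %||% sample(c("+", "-"), 1L)
  pseudo <- "pseudogene_hicb" %in% spec$decoys

  genes <- list()  # each: list(id, protein, role) in contig order
  gaps <- integer()  # gap before gene i (i >= 2)
  add_gene <- function(id, protein, gap_before) {
    genes[[length(genes) + 1L]] <<- list(id = id, protein = protein)
    if (length(genes) > 1L) gaps <<- c(gaps, gap_before)
  }

  hica <- NULL; hicb <- NULL
  if (cl %in% 1:8) {
    hica <- compose_protein(hica_plan(spec), spec$hica_len, ancestors,
                            spec$divergence)$protein
    hicb <- compose_protein(hicb_plan(spec), spec$hicb_len, ancestors,
                            spec$divergence)$protein
    a_first <- cl %in% c(1L, 3L, 4L)  # hicAB order; others are hicBA
    ida <- paste0(locus_tag, "_hicA"); idb <- paste0(locus_tag, "_hicB")
    if (a_first) {
      add_gene(ida, hica, NA)
      add_gene(idb, hicb, spec$gap_nt)
    } else {
      add_gene(idb, hicb, NA)
      add_gene(ida, hica, spec$gap_nt)
    }
  } else if (cl %in% 9:10) {
    hica <- compose_protein(hica_plan(spec), spec$hica_len, ancestors,
                            spec$divergence)$protein
    pvip <- compose_protein(list(2L, "pVip"), 290L, ancestors,
                            spec$divergence)$protein
    if (cl == 9L) {  # hicA upstream of the pVip gene
      add_gene(paste0(locus_tag, "_hicA"), hica, NA)
      add_gene(paste0(locus_tag, "_pVip"), pvip, spec$gap_nt)
    } else {
      add_gene(paste0(locus_tag, "_pVip"), pvip, NA)
      add_gene(paste0(locus_tag, "_hicA"), hica, spec$gap_nt)
    }
  } else {
    dbd <- sample(c("DBD_HTH", "DBD_RHH"), 1L)
    fp <- fused_plan(spec, dbd)
    fused <- compose_protein(fp$plan, fp$len, ancestors, spec$divergence)
    hica <- fused$protein
    add_gene(paste0(locus_tag, "_fused"), fused$protein, NA)
  }
  focal_id <- paste0(locus_tag, if (cl %in% 11:14) "_fused" else "_hicA")

  # pseudogene decoy: truncate the DBD-bearing hicB by an in-frame stop
  truncate_at <- NA_integer_
  if (pseudo) {
    truncate_at <- 61L  # residues kept; the DBD is downstream of the stop
  }

  # decoy genes appended downstream of the locus
  append_decoys(spec$decoys, locus_tag, ancestors, spec$divergence,
                add_gene)

  # realize nucleotides
  nts <- lapply(genes, function(g) back_translate(g$protein, sets))
  # overlap between the two locus genes, when requested
  if (length(genes) >= 2L && !is.na(spec$gap_nt) && spec$gap_nt < 0L) {
    solved <- NULL
    for (try in seq_len(50L)) {
      solved <- solve_overlap(nts[[1]], genes[[1]]$protein,
                              nts[[2]], genes[[2]]$protein,
                              spec$gap_nt, sets)
      if (!is.null(solved)) break
      # codon choice alone may not suffice: the junction-adjacent pad
      # residues (never domain residues) are redrawn, then re-encoded
      pa <- genes[[1]]$protein; na <- nchar(pa)
      substr(pa, na - 1L, na) <- random_protein(2L)
      genes[[1]]$protein <- pa
      pb <- genes[[2]]$protein
      substr(pb, 2L, 3L) <- random_protein(2L)
      genes[[2]]$protein <- pb
      nts[[1]] <- back_translate(genes[[1]]$protein, sets)
      nts[[2]] <- back_translate(genes[[2]]$protein, sets)
    }
    if (is.null(solved))
      stop("overlap of ", spec$gap_nt, " nt not constructible for this ",
           "locus; nearest feasible gap is ", spec$gap_nt + 1L)
    nts[[1]] <- solved$nt_a; nts[[2]] <- solved$nt_b
  }

  # pseudogene truncation happens on the nucleotide string: an engineered
  # stop after `truncate_at` residues; the DBD codons stay downstream
  if (pseudo) {
    idb_pos <- which(vapply(genes, function(g)
      grepl("_hicB$", g$id), logical(1)))[1]
    nt <- nts[[idb_pos]]
    head_nt <- substr(nt, 1L, truncate_at * 3L)
    rest <- substr(nt, truncate_at * 3L + 1L, nchar(nt))
    nts[[idb_pos]] <- paste0(head_nt, "TAA", rest)
    genes[[idb_pos]]$protein <- substr(genes[[idb_pos]]$protein, 1L,
                                       truncate_at)
    genes[[idb_pos]]$annotated_len <- (truncate_at + 1L) * 3L
  }

  # assemble the fragment
  flank <- 60L
  seq_parts <- random_dna(flank)
  feats <- list()
  pos <- flank
  for (i in seq_along(genes)) {
    if (i > 1L) {
      g <- gaps[i - 1L]
      if (is.na(g)) g <- 150L
      if (g > 0L) {
        seq_parts <- c(seq_parts, random_dna(g))
        pos <- pos + g
      } else if (g < 0L) {
        # the overlap nucleotides are already on the contig
        last <- seq_parts[length(seq_parts)]
        seq_parts[length(seq_parts)] <- substr(last, 1L, nchar(last) + g)
        pos <- pos + g
      }
    }
    nt <- nts[[i]]
    ann_len <- genes[[i]]$annotated_len %||% nchar(nt)
    seq_parts <- c(seq_parts, nt)
    feats[[i]] <- gene_feature(genes[[i]]$id, pos, pos + ann_len, "+",
                               "CDS", genes[[i]]$protein)
    pos <- pos + nchar(nt)
  }
  seq_parts <- c(seq_parts, random_dna(flank))
  fragment <- genome_record(locus_tag, paste(seq_parts, collapse = ""),
                            do.call(rbind, feats))
  if (strand == "-") fragment <- reverse_complement_record(fragment)

  truth <- data.frame(
    locus_id = focal_id, class_id = cl,
    is_decoy = pseudo, gap_nt = spec$gap_nt,
    hica_len = nchar(hica),
    hicb_len = if (is.null(hicb)) NA_integer_ else
      if (pseudo) truncate_at else nchar(hicb),
    strand = strand, divergence = spec$divergence,
    decoys = paste(spec$decoys, collapse = ","),
    stringsAsFactors = FALSE)
  list(sequence = fragment$sequence, features = fragment$features,
       truth = truth)
}

append_decoys <- function(decoys, locus_tag, ancestors, divergence,
                          add_gene) {
  mk <- function(plan, len) compose_protein(plan, len, ancestors,
                                            divergence)$protein
  if ("solitary_hicb" %in% decoys)
    add_gene(paste0(locus_tag, "_dec_hicB"),
             mk(list(2L, "HicB_pRNaseH"), 115L), 400L)
  if ("neighbor_vapBC" %in% decoys) {
    add_gene(paste0(locus_tag, "_dec_vapB"), mk(list(110L), 112L), 400L)
    add_gene(paste0(locus_tag, "_dec_vapC"), mk(list(128L), 130L), 2L)
  }
  if ("neighbor_relBE" %in% decoys) {
    add_gene(paste0(locus_tag, "_dec_relB"), mk(list(113L), 115L), 400L)
    add_gene(paste0(locus_tag, "_dec_relE"), mk(list(2L, "RelE"), 120L), 0L)
  }
  if ("transposase" %in% decoys)
    add_gene(paste0(locus_tag, "_dec_tnp"), mk(list(298L), 300L), 400L)
  if ("relE_pvip_pair" %in% decoys) {
    add_gene(paste0(locus_tag, "_dec_relE2"), mk(list(2L, "RelE"), 120L),
             400L)
    add_gene(paste0(locus_tag, "_dec_pVip2"), mk(list(2L, "pVip"), 290L),
             50L)
  }
}

#' Build a synthetic annotated genome
#'
#' Concatenates the loci of `specs` with >= 500 nt spacers (or packs them
#' tightly when `island = TRUE`, emulating a defense island where eight TA
#' loci fit in ~7 kb), and optionally writes GenBank, GFF3+FASTA, protein
#' FASTA and the truth TSV.
#'
#' @param specs List of [synthetic_spec()]s.
#' @param ancestors A [make_ancestors()] world.
#' @param island Pack loci tightly (default `FALSE`).
#' @param rng_seed Build seed (default 1).
#' @param contig_id Contig name (default `"synctg1"`).
#' @param out_dir If non-`NULL`, write `<basename>.gbk`, `.gff3`, `.fna`,
#'   `.faa` and `<basename>_truth.tsv` there.
#' @param basename Output basename (default `"synthetic"`).
#' @return List with `record` (a [genome_record()]) and `truth` (data frame,
#'   one row per focal locus, with the build seed recorded).
#' @export
build_genome <- function(specs, ancestors, island = FALSE, rng_seed = 1L,
                         contig_id = "synctg1", out_dir = NULL,
                         basename = "synthetic") {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  built <- withr::with_seed(rng_seed, {
    lapply(seq_along(specs), function(i)
      build_locus(specs[[i]], ancestors,
                  locus_tag = sprintf("L%03d", i)))
  })
  seqs <- character(); feats <- list(); truths <- list()
  pos <- 0L
  spacers <- withr::with_seed(rng_seed + 1L, {
    if (island) 60L + sample(0:60, length(built), replace = TRUE)
    else 500L + sample(0:200, length(built), replace = TRUE)
  })
  spacer_dna <- withr::with_seed(rng_seed + 2L, {
    vapply(spacers, random_dna, character(1))
  })
  for (i in seq_along(built)) {
    if (i > 1L) {
      seqs <- c(seqs, spacer_dna[i])
      pos <- pos + spacers[i]
    }
    b <- built[[i]]
    f <- b$features
    f$start <- f$start + pos
    f$end <- f$end + pos
    feats[[i]] <- f
    truths[[i]] <- b$truth
    seqs <- c(seqs, b$sequence)
    pos <- pos + nchar(b$sequence)
  }
  record <- genome_record(contig_id, paste(seqs, collapse = ""),
                          do.call(rbind, feats))
  truth <- do.call(rbind, truths)
  truth$seed <- rng_seed
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_genbank(record, file.path(out_dir, paste0(basename, ".gbk")))
    write_gff_fasta(record, file.path(out_dir, paste0(basename, ".gff3")),
                    file.path(out_dir, paste0(basename, ".fna")))
    write_protein_fasta(record, file.path(out_dir, paste0(basename, ".faa")))
    utils::write.table(truth,
                       file.path(out_dir, paste0(basename, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(record = record, truth = truth)
}

#' Simulate per-class HicA families for the phylogeny benchmark
#'
#' Draws one anchor per class by heavy mutation of the HicA ancestor (classes
#' are well separated), then `n_per_class` members per class, each mutated at
#' `divergence / 2` from its anchor so pairwise within-class divergence is
#' about `divergence`.
#'
#' @param ancestors A [make_ancestors()] world.
#' @param classes Class labels to emulate (default 1:10).
#' @param n_per_class Members per class (default 10).
#' @param divergence Target within-class pairwise divergence (default 0.2).
#' @param rng_seed Seed.
#' @return Data frame with `id`, `class`, `protein`.
#' @export
simulate_hica_families <- function(ancestors, classes = 1:10,
                                   n_per_class = 10L, divergence = 0.2,
                                   rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    anc <- ancestors$HicA_dsRBD$ancestor
    rows <- list()
    for (cl in classes) {
      anchor <- mutate_protein(anc, 0.45, protect_first = FALSE)
      for (k in seq_len(n_per_class)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("c%02d_s%02d", cl, k), class = cl,
          protein = mutate_protein(anchor, divergence / 2,
                                   protect_first = FALSE),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
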