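# The 14-class rule engine. Rules are evaluated in a fixed precedence:
# fusions (14, 11, 12, 13) > pVip adjacency (9, 10) > DBD-bearing bicistronic
# partners (5/6, 3, 4) > long DBD-less HicBs (7, 8) > small DBD-less HicBs
# (1, 2); anything else is unclassified. More specific evidence outranks the
# permissive size-only rules. Every assignment carries the evidence trail of
# the satisfied predicates so that a classification can be audited and
# replayed.

#' Classification rule configuration
#'
#' Length ranges are closed intervals in amino acids; gaps are nucleotides.
#' Defaults follow the published class definitions, with the Class 1 and
#' Class 8 HicB ranges widened to the union of the two printed variants
#' (67-97 vs 60-87 aa, and 331-356 vs 342-356 aa).
#'
#' @param small_hicb_range_c1 Class 1 HicB length range (default `c(60, 97)`).
#' @param small_hicb_range_c2 Class 2 HicB length range (default `c(63, 103)`).
#' @param hicb_range_c7 Class 7 HicB length range (default `c(216, 233)`).
#' @param hicb_range_c8 Class 8 HicB length range (default `c(331, 356)`).
#' @param shared_domain_len Shared Domain length range (default `c(45, 70)`).
#' @param fused_c13_range Class 13 fused-protein length range
#'   (default `c(340, 440)`).
#' @param fused_small_max Upper length bound for the small fused Class 12
#'   (default 340, the lower bound of the Class 13 range).
#' @param smc_min_len Minimum SMC fusion protein length (default 600 aa).
#' @param pvip_max_gap Maximum hicA-pVip intergenic gap (default 300 nt).
#' @param closely_linked_max_gap Inclusive gap bound for "closely linked"
#'   (default 10 nt).
#' @param partner_max_gap Maximum gap for a neighbor to count as an operon
#'   partner (default 300 nt).
#' @return A `class_rule_config` list.
#' @export
class_rule_config <- function(small_hicb_range_c1 = c(60L, 97L),
                              small_hicb_range_c2 = c(63L, 103L),
                              hicb_range_c7 = c(216L, 233L),
                              hicb_range_c8 = c(331L, 356L),
                              shared_domain_len = c(45L, 70L),
                              fused_c13_range = c(340L, 440L),
                              fused_small_max = 340L,
                              smc_min_len = 600L,
                              pvip_max_gap = 300L,
                              closely_linked_max_gap = 10L,
                              partner_max_gap = 300L) {
  cfg <- list(small_hicb_range_c1 = small_hicb_range_c1,
              small_hicb_range_c2 = small_hicb_range_c2,
              hicb_range_c7 = hicb_range_c7,
              hicb_range_c8 = hicb_range_c8,
              shared_domain_len = shared_domain_len,
              fused_c13_range = fused_c13_range,
              fused_small_max = fused_small_max,
              smc_min_len = smc_min_len,
              pvip_max_gap = pvip_max_gap,
              closely_linked_max_gap = closely_linked_max_gap,
              partner_max_gap = partner_max_gap)
  for (nm in grep("range", names(cfg), value = TRUE)) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("range ", nm, " must be c(lo, hi) with lo <= hi")
  }
  structure(cfg, class = "class_rule_config")
}

in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

arch_hit <- function(arch, label) {
  sel <- which(arch$domain_label == label)
  if (!length(sel)) NULL else arch[sel[1], , drop = FALSE]
}

has_dbd <- function(arch) {
  any(arch$domain_label %in% c("DBD_HTH", "DBD_RHH", "DBD_PhdYefM"))
}

# Rank-1 strand-relative neighbor accepted as an operon partner: a CDS,
# co-oriented with the focal gene, within partner_max_gap.
ta_partner <- function(ctx, side, cfg) {
  nb <- context_side(ctx, side)
  if (!nrow(nb)) return(NULL)
  cand <- nb[1, , drop = FALSE]
  if (cand$kind != "CDS" || cand$strand != ctx$focal$strand ||
      cand$gap_nt > cfg$partner_max_gap || is.na(cand$protein))
    return(NULL)
  list(feat = cand,
       arch = ctx$architectures[[cand$gene_id]] %||% empty_hits(),
       gap = cand$gap_nt, len = nchar(cand$protein))
}

# Nearest co-oriented neighbor within pvip_max_gap (non-co-oriented genes are
# skipped; the published definition says only "adjacent").
pvip_partner <- function(ctx, side, cfg) {
  nb <- context_side(ctx, side)
  for (i in seq_len(nrow(nb))) {
    cand <- nb[i, , drop = FALSE]
    if (cand$strand != ctx$focal$strand) next
    if (cand$gap_nt > cfg$pvip_max_gap) return(NULL)
    arch <- ctx$architectures[[cand$gene_id]] %||% empty_hits()
    if (any(arch$domain_label == "pVip"))
      return(list(feat = cand, arch = arch, gap = cand$gap_nt,
                  len = if (is.na(cand$protein)) NA_integer_
                        else nchar(cand$protein)))
    return(NULL)  # nearest co-oriented neighbor is not a pVip
  }
  NULL
}

ev <- function(rule, observation) {
  data.frame(rule = rule, observation = observation, stringsAsFactors = FALSE)
}

rule_hit <- function(class_id, evidence, partner = NULL) {
  list(class_id = class_id, evidence = evidence, partner = partner)
}

# ---- individual class rules ------------------------------------------------

rule_class14 <- function(ctx, cfg) {
  a <- ctx$focal_arch
  smc <- arch_hit(a, "SMC"); hica <- arch_hit(a, "HicA_dsRBD")
  if (is.null(smc) || is.null(hica) || hica$start <= smc$start) return(NULL)
  rule_hit(14L, rbind(
    ev("focal_smc", sprintf("SMC@%d-%d", smc$start, smc$end)),
    ev("focal_hica_cterm", sprintf("HicA@%d-%d", hica$start, hica$end)),
    ev("focal_len", nchar(ctx$focal$protein))))
}

rule_class11 <- function(ctx, cfg) {
  a <- ctx$focal_arch
  hica <- arch_hit(a, "HicA_dsRBD"); hicb <- arch_hit(a, "HicB_pRNaseH")
  dbd <- arch_hit(a, "DBD_HTH") %||% arch_hit(a, "DBD_RHH")
  if (is.null(hica) || is.null(hicb) || is.null(dbd)) return(NULL)
  if (!(hica$start < hicb$start && hicb$start < dbd$start)) return(NULL)
  rule_hit(11L, rbind(
    ev("focal_order", sprintf("HicA@%d < HicB@%d < %s@%d", hica$start,
                              hicb$start, dbd$domain_label, dbd$start))))
}

rule_class12 <- function(ctx, cfg) {
  a <- ctx$focal_arch
  hica <- arch_hit(a, "HicA_dsRBD"); hicb <- arch_hit(a, "HicB_pRNaseH")
  len <- nchar(ctx$focal$protein)
  if (is.null(hica) || is.null(hicb) || hicb$start >= hica$start ||
      len >= cfg$fused_small_max) return(NULL)
  rule_hit(12L, rbind(
    ev("focal_order", sprintf("HicB@%d < HicA@%d", hicb$start, hica$start)),
    ev("focal_len_small", len)))
}

rule_class13 <- function(ctx, cfg) {
  a <- ctx$focal_arch
  hica <- arch_hit(a, "HicA_dsRBD")
  len <- nchar(ctx$focal$protein)
  if (is.null(hica) || !in_range(len, cfg$fused_c13_range) ||
      hica$start < len / 2) return(NULL)
  rule_hit(13L, rbind(
    ev("focal_hica_cterm", sprintf("HicA@%d-%d of %d aa", hica$start,
                                   hica$end, len)),
    ev("focal_len_in_c13_range", len)))
}

rule_class9 <- function(ctx, cfg) {
  p <- pvip_partner(ctx, "downstream", cfg)
  if (is.null(p)) return(NULL)
  rule_hit(9L, ev("pvip_downstream",
                  sprintf("%s gap=%d", p$feat$gene_id, p$gap)), p)
}

rule_class10 <- function(ctx, cfg) {
  p <- pvip_partner(ctx, "upstream", cfg)
  if (is.null(p)) return(NULL)
  rule_hit(10L, ev("pvip_upstream",
                   sprintf("%s gap=%d", p$feat$gene_id, p$gap)), p)
}

rule_class5_6 <- function(ctx, cfg) {
  p <- ta_partner(ctx, "upstream", cfg)
  if (is.null(p)) return(NULL)
  phd <- arch_hit(p$arch, "DBD_PhdYefM"); rh <- arch_hit(p$arch, "HicB_pRNaseH")
  if (is.null(phd) || is.null(rh) || phd$start >= rh$start) return(NULL)
  evd <- rbind(
    ev("partner_phdyefm_nterm", sprintf("%s PhdYefM@%d < pRNaseH@%d",
                                        p$feat$gene_id, phd$start, rh$start)))
  hica <- arch_hit(ctx$focal_arch, "HicA_dsRBD")
  shared <- arch_hit(ctx$focal_arch, "SharedDomain")
  if (!is.null(shared) && !is.null(hica) && shared$start >= hica$end - 10L) {
    evd <- rbind(evd, ev("focal_shared_domain",
                         sprintf("SharedDomain@%d-%d", shared$start,
                                 shared$end)))
    rule_hit(6L, evd, p)
  } else {
    rule_hit(5L, evd, p)
  }
}

rule_class3 <- function(ctx, cfg) bicistronic_dbd_rule(ctx, cfg, "DBD_HTH", 3L)
rule_class4 <- function(ctx, cfg) bicistronic_dbd_rule(ctx, cfg, "DBD_RHH", 4L)

bicistronic_dbd_rule <- function(ctx, cfg, dbd_label, class_id) {
  p <- ta_partner(ctx, "downstream", cfg)
  if (is.null(p)) return(NULL)
  rh <- arch_hit(p$arch, "HicB_pRNaseH"); dbd <- arch_hit(p$arch, dbd_label)
  if (is.null(rh) || is.null(dbd) || dbd$start <= rh$start) return(NULL)
  rule_hit(class_id, ev(paste0("partner_", tolower(dbd_label), "_cterm"),
                        sprintf("%s pRNaseH@%d < %s@%d", p$feat$gene_id,
                                rh$start, dbd_label, dbd$start)), p)
}

rule_class7 <- function(ctx, cfg)
  long_hicb_rule(ctx, cfg, cfg$hicb_range_c7, 7L)
rule_class8 <- function(ctx, cfg)
  long_hicb_rule(ctx, cfg, cfg$hicb_range_c8, 8L)

long_hicb_rule <- function(ctx, cfg, range, class_id) {
  p <- ta_partner(ctx, "upstream", cfg)
  if (is.null(p) || has_dbd(p$arch) || !in_range(p$len, range)) return(NULL)
  evd <- rbind(ev("partner_no_dbd", p$feat$gene_id),
               ev("partner_len_in_range", p$len))
  duf <- arch_hit(p$arch, "DUF1902")
  if (!is.null(duf))  # supporting evidence only, never required
    evd <- rbind(evd, ev("partner_duf1902",
                         sprintf("DUF1902@%d-%d", duf$start, duf$end)))
  rule_hit(class_id, evd, p)
}

rule_class1 <- function(ctx, cfg)
  small_hicb_rule(ctx, cfg, "downstream", cfg$small_hicb_range_c1, 1L)
rule_class2 <- function(ctx, cfg)
  small_hicb_rule(ctx, cfg, "upstream", cfg$small_hicb_range_c2, 2L)

small_hicb_rule <- function(ctx, cfg, side, range, class_id) {
  p <- ta_partner(ctx, side, cfg)
  if (is.null(p) || has_dbd(p$arch) || !in_range(p$len, range)) return(NULL)
  rule_hit(class_id, rbind(
    ev("partner_no_dbd", p$feat$gene_id),
    ev("partner_len_in_range", p$len)), p)
}

CLASS_RULES <- list(class14 = rule_class14, class11 = rule_class11,
                    class12 = rule_class12, class13 = rule_class13,
                    class9 = rule_class9, class10 = rule_class10,
                    class5_6 = rule_class5_6, class3 = rule_class3,
                    class4 = rule_class4, class7 = rule_class7,
                    class8 = rule_class8, class1 = rule_class1,
                    class2 = rule_class2)

#' Classify one HicA locus
#'
#' Evaluates the class rules in precedence order and returns the first match
#' with its evidence trail; loci matching no rule are returned as
#' unclassified, never dropped.
#'
#' @param ctx A [build_context()] for a HicA-domain-bearing focal gene.
#' @param config A [class_rule_config()].
#' @return A `class_assignment` list: `locus_id`, `contig`, `class_id`
#'   (integer or `NA` = unclassified), `rule`, `evidence` (data frame),
#'   partner info, linkage flags.
#' @export
classify_locus <- function(ctx, config = class_rule_config()) {
  res <- NULL; rule_name <- NA_character_
  for (nm in names(CLASS_RULES)) {
    res <- CLASS_RULES[[nm]](ctx, config)
    if (!is.null(res)) { rule_name <- nm; break }
  }
  partner <- res$partner
  gap <- if (!is.null(partner)) partner$gap else NA_integer_
  flag <- if (!is.na(gap)) coupling_flag(gap, config$closely_linked_max_gap)
          else NA_character_
  structure(list(
    locus_id = ctx$focal$gene_id,
    contig = ctx$contig_id,
    class_id = if (is.null(res)) NA_integer_ else res$class_id,
    rule = rule_name,
    evidence = if (is.null(res)) ev(character(), character()) else res$evidence,
    focal_len = nchar(ctx$focal$protein),
    focal_protein = ctx$focal$protein,
    partner_id = if (is.null(partner)) NA_character_ else partner$feat$gene_id,
    partner_len = if (is.null(partner)) NA_integer_ else partner$len,
    gap_nt = gap,
    closely_linked = isTRUE(flag == "closely_linked"),
    overlapping = isTRUE(flag == "overlapping"),
    pseudogene_candidate = FALSE), class = "class_assignment")
}

#' Replay an assignment's decisive rule against its context
#'
#' Audit helper: re-evaluates the recorded rule predicate on the context and
#' checks it reproduces the class id, and that no higher-precedence rule
#' fires.
#'
#' @param ctx The [build_context()] the assignment came from.
#' @param assignment A [classify_locus()] result.
#' @param config The configuration used.
#' @return `TRUE` if the evidence is sufficient to reproduce the class id.
#' @export
replay_evidence <- function(ctx, assignment, config = class_rule_config()) {
  if (is.na(assignment$class_id))
    return(all(vapply(CLASS_RULES, function(r) is.null(r(ctx, config)),
                      logical(1))))
  res <- CLASS_RULES[[assignment$rule]](ctx, config)
  if (is.null(res) || res$class_id != assignment$class_id) return(FALSE)
  earlier <- names(CLASS_RULES)[seq_len(match(assignment$rule,
                                              names(CLASS_RULES)) - 1L)]
  all(vapply(earlier, function(nm) is.null(CLASS_RULES[[nm]](ctx, config)),
             logical(1)))
}

#' Screen a small HicB for pseudogene status
#'
#' A candidate Class 1/2 HicB is flagged as a likely pseudogene (its operon
#' discarded from Class 1/2 counts) if either (a) in-frame read-through
#' translation past its stop codon, for up to `max_readthrough` nucleotides,
#' yields a segment scoring above threshold against the HTH or RHH profiles
#' (a DNA-binding domain truncated off by a premature stop), or (b) a supplied
#' reference HicB that carries a DBD matches the candidate at >= 95% identity
#' over the candidate's full length.
#'
#' @param record The [genome_record()] containing the gene.
#' @param hicb The HicB feature row.
#' @param profiles Named list of calibrated profiles (needs `DBD_HTH`,
#'   `DBD_RHH`).
#' @param reference_hicbs Optional data frame with columns `protein`,
#'   `has_dbd`.
#' @param max_readthrough Read-through extent in nucleotides (default 300).
#' @param min_identity Identity threshold for branch (b) (default 0.95).
#' @return `TRUE` if the locus is a pseudogene candidate.
#' @export
pseudogene_screen <- function(record, hicb, profiles,
                              reference_hicbs = NULL,
                              max_readthrough = 300L, min_identity = 0.95) {
  dbd_profiles <- profiles[intersect(c("DBD_HTH", "DBD_RHH"), names(profiles))]
  # (a) read-through translation past the annotated stop
  len <- nchar(record$sequence)
  if (hicb$strand == "+") {
    avail <- len - hicb$end
    from <- hicb$end; to <- hicb$end + min(max_readthrough, avail)
    ext <- substr(record$sequence, from + 1L, to)
  } else {
    avail <- hicb$start
    from <- hicb$start - min(max_readthrough, avail); to <- hicb$start
    ext <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(record$sequence, from + 1L, to))))
  }
  if (avail < max_readthrough)
    warning("read-through window truncated at contig end (",
            avail, " nt available)")
  if (nchar(ext) >= 3L) {
    aa <- translate_nt(ext, partial = TRUE)
    if (nzchar(aa)) {
      for (p in dbd_profiles) {
        if (nrow(scan_protein(aa, p))) return(TRUE)
      }
    }
  }
  # (b) near-identity to a reference HicB that has a DBD
  if (!is.null(reference_hicbs) && !is.na(hicb$protein)) {
    refs <- as.data.frame(reference_hicbs, stringsAsFactors = FALSE)
    for (i in which(as.logical(refs$has_dbd))) {
      al <- global_align(hicb$protein, refs$protein[i])
      if (al$matches / nchar(hicb$protein) >= min_identity) return(TRUE)
    }
  }
  FALSE
}

#' Classify every HicA locus in a set of genome records
#'
#' Runs the profile scan, focal-gene detection, context extraction, rule
#' engine and (for Class 1/2 calls) the pseudogene screen, and annotates each
#' contig's RelE-next-to-pVip association as an auxiliary flag.
#'
#' @param records A [genome_record()] or list of them.
#' @param profiles Named list of calibrated profiles.
#' @param config A [class_rule_config()].
#' @param window_genes Neighbors per side for context building (default 5).
#' @param reference_hicbs Optional references for the pseudogene screen.
#' @param screen_pseudogenes Run the pseudogene screen on Class 1/2 calls.
#' @param architectures Precomputed [scan_genome()] result (optional).
#' @return Data frame with one row per focal locus (`locus_id`, `contig`,
#'   `class_id`, lengths, partner, gap, flags, semicolon-joined evidence) with
#'   the per-locus contexts and assignments attached as attributes.
#' @export
classify_genome <- function(records, profiles, config = class_rule_config(),
                            window_genes = 5L, reference_hicbs = NULL,
                            screen_pseudogenes = TRUE,
                            architectures = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (is.null(architectures)) architectures <- scan_genome(records, profiles)
  assignments <- list(); contexts <- list()
  for (rec in records) {
    loci <- find_hica_loci(rec, architectures)
    relE_pvip <- relE_pvip_pairs(rec, architectures, config)
    for (i in seq_len(nrow(loci))) {
      focal <- loci[i, , drop = FALSE]
      ctx <- build_context(rec, focal, window_genes, architectures)
      asg <- classify_locus(ctx, config)
      if (screen_pseudogenes && !is.na(asg$class_id) &&
          asg$class_id %in% c(1L, 2L) && !is.na(asg$partner_id)) {
        partner <- rec$features[rec$features$gene_id == asg$partner_id, ,
                                drop = FALSE][1, , drop = FALSE]
        asg$pseudogene_candidate <- pseudogene_screen(
          rec, partner, profiles, reference_hicbs)
        if (asg$pseudogene_candidate)
          asg$evidence <- rbind(asg$evidence,
                                ev("pseudogene_screen", "flagged"))
      }
      asg$relE_pvip_in_contig <- nrow(relE_pvip) > 0L
      key <- paste(rec$contig_id, focal$gene_id, sep = ":")
      assignments[[key]] <- asg
      contexts[[key]] <- ctx
    }
  }
  tab <- assignments_table(assignments)
  attr(tab, "assignments") <- assignments
  attr(tab, "contexts") <- contexts
  tab
}

relE_pvip_pairs <- function(record, architectures, config) {
  f <- record$features
  rows <- list()
  if (nrow(f) < 2L) return(data.frame())
  lab <- function(i, l) {
    a <- architectures[[f$gene_id[i]]]
    !is.null(a) && any(a$domain_label == l)
  }
  for (i in seq_len(nrow(f) - 1L)) {
    gap <- intergenic_gap(f[i, ], f[i + 1L, ])
    if (gap > config$pvip_max_gap) next
    if ((lab(i, "RelE") && lab(i + 1L, "pVip")) ||
        (lab(i, "pVip") && lab(i + 1L, "RelE")))
      rows[[length(rows) + 1L]] <- data.frame(
        a = f$gene_id[i], b = f$gene_id[i + 1L], gap_nt = gap,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}

assignments_table <- function(assignments) {
  if (!length(assignments)) {
    return(data.frame(locus_id = character(), contig = character(),
                      class_id = integer(), focal_len = integer(),
                      partner_id = character(), partner_len = integer(),
                      gap_nt = integer(), closely_linked = logical(),
                      overlapping = logical(), pseudogene_candidate = logical(),
                      relE_pvip_in_contig = logical(), evidence = character(),
                      focal_protein = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(locus_id = a$locus_id, contig = a$contig,
               class_id = a$class_id, focal_len = a$focal_len,
               partner_id = a$partner_id, partner_len = a$partner_len,
               gap_nt = a$gap_nt, closely_linked = a$closely_linked,
               overlapping = a$overlapping,
               pseudogene_candidate = a$pseudogene_candidate,
               relE_pvip_in_contig = isTRUE(a$relE_pvip_in_contig),
               evidence = paste(sprintf("%s=%s", a$evidence$rule,
                                        a$evidence$observation),
                                collapse = ";"),
               focal_protein = a$focal_protein,
               stringsAsFactors = FALSE)
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' Read a rule configuration from a YAML file
#'
#' Every [class_rule_config()] field may be given; absent fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `class_rule_config`.
#' @export
read_rule_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(class_rule_config)))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  do.call(class_rule_config, lapply(vals, function(v)
    if (is.numeric(v)) as.integer(v) else v))
}

#' Dump per-locus evidence trails as JSON
#'
#' @param tab Result of [classify_genome()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_evidence_json <- function(tab, path) {
  assignments <- attr(tab, "assignments")
  out <- lapply(assignments, function(a)
    list(locus_id = a$locus_id, contig = a$contig,
         class_id = if (is.na(a$class_id)) "unclassified" else a$class_id,
         rule = a$rule, evidence = a$evidence,
         flags = list(closely_linked = a$closely_linked,
                      overlapping = a$overlapping,
                      pseudogene_candidate = a$pseudogene_candidate)))
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a classification table as TSV
#'
#' @param tab Result of [classify_genome()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(tab, path) {
  out <- tab[, setdiff(names(tab), "focal_protein"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
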