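# Shared synthetic world, built once per test run. The seed is fixed so
# every expectation below is on one reproducible realization.

.world_cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.world_cache$world))
    .world_cache$world <- make_ancestors(42)
  .world_cache$world
}

test_profiles <- function() profiles_from_world(test_world())

# one locus per class at 10% divergence, written and re-read through GenBank
test_genome14 <- function() {
  if (is.null(.world_cache$g14)) {
    specs <- default_class_specs(per_class = 1, divergence = 0.1)
    .world_cache$g14 <- build_genome(specs, test_world(), rng_seed = 7)
  }
  .world_cache$g14
}

test_classification14 <- function() {
  if (is.null(.world_cache$tab14)) {
    g <- test_genome14()
    .world_cache$tab14 <- suppressWarnings(
      classify_genome(g$record, test_profiles()))
  }
  .world_cache$tab14
}

# hand-assembled locus context with stubbed architectures, for boundary and
# precedence tests that need exact control over lengths and domain layouts
fake_ctx <- function(focal_arch, partner_arch = NULL, partner_len = 80L,
                     gap = 2L, partner_side = "downstream",
                     focal_len = 70L, strand = "+", partner_strand = strand) {
  mkprot <- function(n) paste0("M", strrep("A", n - 1L))
  focal_nt_len <- 3L * (focal_len + 1L)
  partner_nt_len <- 3L * (partner_len + 1L)
  left_first <- (partner_side == "downstream") == (strand == "-")
  if (left_first) {
    p_start <- 100L
    f_start <- p_start + partner_nt_len + gap
  } else {
    f_start <- 100L
    p_start <- f_start + focal_nt_len + gap
  }
  feats <- rbind(
    gene_feature("focal", f_start, f_start + focal_nt_len, strand, "CDS",
                 mkprot(focal_len)),
    if (!is.null(partner_arch) || TRUE)
      gene_feature("partner", p_start, p_start + partner_nt_len,
                   partner_strand, "CDS", mkprot(partner_len)))
  total <- max(feats$end) + 100L
  rec <- genome_record("fakectg", strrep("A", total), feats)
  archs <- list(focal = focal_arch,
                partner = partner_arch %||% hicontext:::empty_hits())
  focal <- rec$features[rec$features$gene_id == "focal", , drop = FALSE]
  build_context(rec, focal, window_genes = 5L, architectures = archs)
}

fake_arch <- function(...) {
  # fake_arch("HicA_dsRBD", c(2, 57), "SharedDomain", c(60, 115))
  args <- list(...)
  labels <- args[seq(1, length(args), 2)]
  spans <- args[seq(2, length(args), 2)]
  do.call(rbind, lapply(seq_along(labels), function(i)
    data.frame(protein_id = "x", domain_label = labels[[i]],
               start = spans[[i]][1], end = spans[[i]][2], score = 50,
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
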