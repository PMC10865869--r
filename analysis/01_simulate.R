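#!/usr/bin/env Rscript
# Step 1: generate the synthetic study genomes.
#
# Two fixtures are built from one seeded domain world:
#   - fig2_exemplars: one locus per genetic-context class (divergence 0.1),
#     the worked example the classifier is demonstrated on;
#   - benchmark140: ten loci per class at 20% divergence, the round-trip
#     accuracy benchmark.
# Both are written as GenBank + GFF3/FASTA + truth tables under results/.

suppressPackageStartupMessages(library(hicontext))

dir.create("results", showWarnings = FALSE)

world <- make_ancestors(42)

g14 <- build_genome(default_class_specs(per_class = 1, divergence = 0.1),
                    world, rng_seed = 7, out_dir = "results",
                    basename = "fig2_exemplars")
cat(sprintf("fig2_exemplars: %d loci, %d bp\n",
            nrow(g14$truth), nchar(g14$record$sequence)))

g140 <- build_genome(default_class_specs(per_class = 10, divergence = 0.2),
                     world, rng_seed = 11, out_dir = "results",
                     basename = "benchmark140")
cat(sprintf("benchmark140: %d loci, %d bp\n",
            nrow(g140$truth), nchar(g140$record$sequence)))

island <- build_genome(
  lapply(rep(c(1L, 2L), 4), function(cl) synthetic_spec(cl,
                                                        divergence = 0.1)),
  world, island = TRUE, rng_seed = 13, out_dir = "results",
  basename = "defense_island")
span <- with(subset(island$record$features,
                    gene_id %in% island$truth$locus_id),
             max(start) - min(start))
cat(sprintf("defense_island: 8 TA loci spanning %d bp (<= 7 kb: %s)\n",
            span, span <= 7000))
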