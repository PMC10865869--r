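test_that("GenBank coordinates convert to the internal 0-based half-open convention", {
  gbk <- tempfile(fileext = ".gbk")
  nt <- paste(rep("ACGTACGTAC", 30), collapse = "")
  cds <- substr(nt, 101, 196)
  writeLines(c(
    "LOCUS       ctg1                 300 bp    DNA     linear   UNK 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     CDS             101..196",
    '                     /locus_tag="g1"',
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(substr(nt, 1, 60))),
    sprintf("%9d %s", 61, tolower(substr(nt, 61, 120))),
    sprintf("%9d %s", 121, tolower(substr(nt, 121, 180))),
    sprintf("%9d %s", 181, tolower(substr(nt, 181, 240))),
    sprintf("%9d %s", 241, tolower(substr(nt, 241, 300))),
    "//"), gbk)
  rec <- read_genbank(gbk)[[1]]
  expect_equal(rec$contig_id, "ctg1")
  expect_equal(rec$features$start, 100L)
  expect_equal(rec$features$end, 196L)
  expect_equal(rec$features$strand, "+")
  expect_equal(nchar(rec$sequence), 300L)
})

test_that("GenBank and GFF3 round trips preserve the feature table exactly", {
  g <- test_genome14()
  gbk <- tempfile(fileext = ".gbk")
  write_genbank(g$record, gbk)
  rec2 <- read_genbank(gbk)[[1]]
  cols <- c("gene_id", "start", "end", "strand", "kind")
  expect_identical(rec2$features[, cols], g$record$features[, cols])
  expect_identical(rec2$features$protein, g$record$features$protein)
  expect_identical(rec2$sequence, g$record$sequence)

  gff <- tempfile(fileext = ".gff3"); fna <- tempfile(fileext = ".fna")
  write_gff_fasta(rec2, gff, fna)
  rec3 <- read_gff_fasta(gff, fna)[[1]]
  expect_identical(rec3$features[, cols], g$record$features[, cols])
  # proteins re-derived from sequence equal the originals
  expect_identical(rec3$features$protein, g$record$features$protein)
})

test_that("a join() CDS on the minus strand translates the spliced sequence", {
  # oracle: splice the two exons, reverse-complement, per-codon lookup
  set.seed(21)
  exon2 <- "ATGGCT"; exon1 <- "GGTTTCTAA"  # genomic order: part1, part2
  filler <- paste(sample(c("A","C","G","T"), 30, replace = TRUE),
                  collapse = "")
  seqnt <- paste0(filler,
                  oracle_revcomp(exon1), strrep("A", 10),
                  oracle_revcomp(exon2), filler)
  # parts listed 5'->3' on the minus strand read as complement(join(p1,p2))
  p1 <- c(30L, 39L)   # holds revcomp(exon1)
  p2 <- c(49L, 55L)   # holds revcomp(exon2)
  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    sprintf("LOCUS       joined  %d bp    DNA     linear   UNK 01-JAN-2000",
            nchar(seqnt)),
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             complement(join(%d..%d,%d..%d))",
            p1[1] + 1L, p1[2], p2[1] + 1L, p2[2]),
    '                     /locus_tag="j1"',
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seqnt)),
    "//"), gbk)
  rec <- read_genbank(gbk)[[1]]
  spliced <- paste0(substr(seqnt, p1[1] + 1L, p1[2]),
                    substr(seqnt, p2[1] + 1L, p2[2]))
  expect_identical(rec$features$protein, oracle_translate(spliced, "-"))
  expect_identical(rec$features$protein, "MAGF")
})

test_that("translate_cds matches a per-codon lookup oracle on random ORFs", {
  expect_identical(
    translate_cds(genome_record("c", "ATGGGCTAA",
                                gene_feature("g", 0, 9, "+", "CDS")),
                  gene_feature("g", 0, 9, "+", "CDS")),
    "MG")
  expect_identical(
    translate_cds(genome_record("c", "TTAGCCCAT",
                                gene_feature("g", 0, 9, "-", "CDS")),
                  gene_feature("g", 0, 9, "-", "CDS")),
    "MG")
  set.seed(7)
  for (i in seq_len(1000)) {
    n_codons <- sample(2:100, 1)
    nt <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
                collapse = "")
    strand <- sample(c("+", "-"), 1)
    rec <- genome_record("c", nt, gene_feature("g", 0, nchar(nt), strand))
    got <- translate_cds(rec, rec$features[1, ])
    expect_identical(got, oracle_translate(nt, strand))
  }
})

test_that("alternative start codons translate to M and internal stops to *", {
  rec <- genome_record("c", "GTGTGAGGC", gene_feature("g", 0, 9, "+"))
  expect_identical(translate_cds(rec, rec$features[1, ]), "M*G")
})

test_that("malformed or inconsistent annotation inputs raise informative errors", {
  bad <- tempfile()
  writeLines(c("FEATURES", "ORIGIN", "//"), bad)
  expect_error(read_genbank(bad), "LOCUS")
  # CDS extending past the contig
  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       c2      30 bp    DNA     linear   UNK 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..60",
    "ORIGIN",
    sprintf("%9d %s", 1, strrep("acgtacgtac", 3)),
    "//"), gbk)
  expect_error(read_genbank(gbk), "outside")
  # GFF seqid absent from FASTA
  gff <- tempfile(fileext = ".gff3"); fna <- tempfile(fileext = ".fna")
  writeLines(c("##gff-version 3",
               "ghost\thicontext\tCDS\t1\t9\t.\t+\t0\tID=g1"), gff)
  writeLines(c(">present", "ACGTACGTAC"), fna)
  expect_error(read_gff_fasta(gff, fna), "ghost")
  # CDS length not divisible by 3
  rec <- genome_record("c", "ACGTACGTAC", gene_feature("g", 0, 10, "+"))
  expect_error(translate_cds(rec, rec$features[1, ]), "divisible")
  expect_identical(translate_cds(rec, rec$features[1, ], partial = TRUE),
                   oracle_translate("ACGTACGTA"))
})

test_that("empty GFF with FASTA yields records with zero features", {
  gff <- tempfile(fileext = ".gff3"); fna <- tempfile(fileext = ".fna")
  writeLines("##gff-version 3", gff)
  writeLines(c(">ctgA", "ACGTACGTACGT"), fna)
  recs <- read_gff_fasta(gff, fna)
  expect_length(recs, 1L)
  expect_equal(nrow(recs[[1]]$features), 0L)
})
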