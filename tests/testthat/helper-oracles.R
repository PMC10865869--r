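# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings) wherever they check one.

# hand-coded codon table (prokaryotic code; differs from the standard code
# only in which codons may initiate, handled separately)
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

# per-codon lookup translation: strips a terminal stop, keeps internal '*',
# maps alternative start codons to M
oracle_translate <- function(nt, strand = "+") {
  if (strand == "-") nt <- oracle_revcomp(nt)
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  aa <- unname(ORACLE_CODONS[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (length(aa) && codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

AA20_T <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

random_aa <- function(n) paste(sample(AA20_T, n, replace = TRUE),
                               collapse = "")

# brute-force best local score of a protein against a profile: maximum over
# all substring pairs of the path-enumerated global score (floored at 0)
oracle_local_score <- function(protein, columns, open, ext) {
  enc <- match(strsplit(protein, "")[[1]], AA20_T)
  n <- length(enc); L <- ncol(columns)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(L)) for (j2 in j1:L) {
      S <- matrix(columns[cbind(rep(enc[i1:i2], times = j2 - j1 + 1),
                                rep(j1:j2, each = i2 - i1 + 1))],
                  nrow = i2 - i1 + 1)
      best <- max(best, hicontext:::cpp_enum_global(S, open, ext))
    }
  best
}

# exhaustive maximum-score subset of hits compatible under the <=10-residue
# pairwise overlap rule
oracle_best_subset <- function(hits, max_overlap = 10L) {
  n <- nrow(hits)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2L) {
      sc <- sum(hits$score[idx])
    } else {
      ok <- TRUE
      for (a in idx) for (b in idx) if (a < b) {
        ov <- min(hits$end[a], hits$end[b]) - max(hits$start[a], hits$start[b])
        if (ov > max_overlap) ok <- FALSE
      }
      sc <- if (ok) sum(hits$score[idx]) else -Inf
    }
    best <- max(best, sc)
  }
  best
}
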