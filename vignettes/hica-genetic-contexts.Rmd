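---
title: "Classifying HicA toxin-domain loci by genetic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying HicA toxin-domain loci by genetic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicontext)
```

## The problem

HicA is a small mRNA-cleaving toxin (50–100 aa, dsRBD fold with
α-β-β-β-α topology) found throughout bacteria and archaea, classically
encoded in a bicistronic *hicAB* operon next to its HicB antitoxin. Genome
surveys show the HicA domain in a much wider variety of genetic
arrangements: operons whose HicB has no recognizable DNA-binding domain
(DBD), reversed *hicBA* gene orders, HicBs with HTH, RHH or Phd/YefM DBDs,
unusually long HicBs, *hicA* genes adjacent to prokaryotic Viperin (pVip)
anti-phage genes, monocistronic fusions of the toxin and antitoxin domains,
and a fusion of HicA to an SMC ATPase. Fourteen such configurations can be
distinguished, and several of them align with anti-phage defense functions.

`hicontext` implements that classification as a reproducible pipeline: it
reads annotated genomes, assigns domain architectures to every protein,
inspects the gene neighborhood of every HicA-domain gene, and applies an
explicit, auditable rule set that assigns each locus to one of the fourteen
genetic-context classes (or leaves it `unclassified` — loci are never
silently dropped). Supporting stages compute per-class summary statistics,
a distance-based phylogeny with a class-clustering statistic, and rigid-body
structure superposition with iterative pair pruning. A synthetic-annotation
generator produces ground-truth-labelled genomes for every configuration so
that the entire pipeline is testable without any downloads.

## Domain detection

Domains are detected with per-domain position-specific scoring profiles.
A profile is built from an aligned FASTA of seed sequences
(`build_profile()`): columns with at least 50% occupancy are kept, and each
column stores log-odds
`log2(((count + pc * bg) / (N + pc)) / bg)` with a pseudocount `pc = 0.5`
and uniform background `bg = 1/20`. The uniform background keeps small seed
alignments usable and the arithmetic independently checkable.

Proteins are scanned by Smith–Waterman-style local alignment against the
profile columns with affine gaps (defaults `gap_open = 11`,
`gap_extend = 1`, the common protein-search convention; a gap of length L
costs `gap_open + L * gap_extend`). All non-overlapping local maxima above
the profile threshold are reported. The dynamic programming runs in C++;
the test suite checks it against a brute-force enumeration of all local
alignments on small instances.

**Score thresholds.** Published genome surveys of this family do not state
an inclusion threshold, so each profile is calibrated against its own
shuffle null (`calibrate_threshold()`): the threshold is the mean plus five
standard deviations of the best local score over (by default) 120–200
residue permutations of the profile consensus, under a fixed seed. This is
reproducible and conservative; with the synthetic world's profiles it
yields ≥ 95% sensitivity at 30% query divergence with a false-label rate
below 5% (measured in the test suite).

**Architectures.** Overlapping hits are resolved greedily by descending
score (ties by start, then label), tolerating up to 10 residues of overlap
between retained hits, since domain boundaries in this family are
approximate. An SMC hit alone is not believed on a short protein: SMC
proteins are large coiled-coil ATPases, so SMC hits are kept only on
proteins of ≥ 600 aa or with a heptad hydrophobic-periodicity score ≥ 0.7
in some 100-residue window. Users with HMMER results can substitute
`ingest_domtblout()` for the built-in scanner.

## Neighborhoods and linkage

For every CDS whose architecture contains a HicA dsRBD hit,
`build_context()` collects up to five genes on each side. Sides are
strand-relative — "downstream" means downstream in the focal gene's own
reading direction — which makes the class rules read in transcription order
and classification invariant under reverse-complementing a contig (a tested
property).

Intergenic gaps use the internal 0-based half-open convention:
`gap = b$start - a$end`, so 0 means abutting genes and negative values are
overlap lengths. A pair is *closely linked* when `0 ≤ gap ≤ 10` nt
(boundary inclusive) and *overlapping* when `gap < 0`; short gaps and
overlaps indicate translational coupling. The 10-nt bound is configurable
(`closely_linked_max_gap`); the source literature prints the criterion with
an inverted inequality sign in one place, and this package follows the
translational-coupling reading (short separations), which matches how the
term is used for the compact classes.

A neighbor counts as an *operon partner* only if it is the rank-1 neighbor
on its side, a CDS, co-oriented with the focal gene, and within
`partner_max_gap` (default 300 nt). The distance bound is this package's
addition: without it, the nearest gene across an arbitrarily long
intergenic region would be accepted as a partner, which is not how operons
work and misfires as soon as several loci share a contig. pVip adjacency
uses the same logic with its own bound (`pvip_max_gap`, default 300 nt) but
skips non-co-oriented intervening genes, since the defining observation is
only that the genes are "adjacent".

## The fourteen-class rule engine

`classify_locus()` evaluates rules in a fixed precedence and stops at the
first match:

1. **Fusions** — class 14 (SMC + C-terminal HicA on one CDS), class 11
   (HicA + HicB-RNase-H + C-terminal HTH/RHH), class 12 (HicB N-terminal,
   HicA C-terminal, total < 340 aa), class 13 (C-terminal HicA, total
   340–440 aa).
2. **pVip adjacency** — class 9 (*hicA* upstream of the pVip gene), class
   10 (*hicA* downstream).
3. **DBD-bearing bicistronic operons** — classes 5/6 (upstream HicB with
   N-terminal Phd/YefM; class 6 when the toxin also carries a C-terminal
   Shared Domain), class 3 (downstream HicB with C-terminal HTH), class 4
   (C-terminal RHH).
4. **Long DBD-less HicBs** — class 7 (216–233 aa), class 8 (331–356 aa).
5. **Small DBD-less HicBs** — class 1 (downstream, 60–97 aa), class 2
   (upstream, 63–103 aa).

More specific evidence (a fusion, an accessory anti-phage gene, an explicit
DBD) outranks the permissive size-only rules; the classes are mutually
exclusive by construction but no published tie-break exists, so the
precedence is stated here as a design decision and every rule decision is
recorded in an evidence trail that `replay_evidence()` can re-check against
the context.

Length ranges are closed intervals and configurable
(`class_rule_config()`). Two ranges are printed inconsistently in the
source literature; this package defaults to the unions — class 1 HicB
`[60, 97]` aa (67–97 in one place, 60–87 in another) and class 8
`[331, 356]` (331–356 vs 342–356) — to avoid false `unclassified` calls.
The class 12/13 boundary (`fused_small_max = 340`) is set to the lower
bound of the published class 13 range, the only anchor available. A locus
that is pVip-adjacent *and* has a qualifying HicB partner is assigned class
9/10, with the partner recorded in the evidence: pVip adjacency is treated
as the defining context.

Two auxiliary annotations are not classes: a RelE-architecture gene
adjacent to a pVip gene raises a per-contig association flag, and DUF1902
hits on class 7 HicBs are logged as supporting evidence only (the original
identification of that domain used structure searches, which are outside
this package's scope).

**Pseudogene screen.** A small DBD-less HicB can be a pseudogene — a
DBD-bearing HicB truncated by a premature stop. For Class 1/2 calls,
`pseudogene_screen()` flags the locus if (a) in-frame read-through
translation past the annotated stop (up to 300 nt) scores above threshold
against the HTH or RHH profiles, or (b) a user-supplied reference HicB with
a DBD matches the candidate at ≥ 95% identity over the candidate's full
length. Flagged loci stay in the output but are discarded from class
counts (`n_pseudogene_discarded`). Branch (a) is a local, reproducible
surrogate for the database-comparison procedure used in the original
survey, which required remote searches.

## Summaries

`summarize_classes()` reports per class: locus count, toxin and antitoxin
length ranges (the antitoxin column is filled only for the bicistronic
classes 1–8), closely-linked and overlapping counts, the closely-linked
percentage (full precision in files, rounded to whole percent for display,
matching the style of the source survey), and pseudogene discards. An
optional redundancy filter drops loci whose toxin is ≥ 95% identical
(global-alignment matches over the shorter sequence) to an already-kept
toxin, greedily in `locus_id` order for determinism.

## Phylogeny and class clustering

Distances are `1 − identity` from pairwise Needleman–Wunsch alignments
(BLOSUM62, affine gaps 11/1), with identity counted over alignment columns
excluding terminal gaps. No progressive multiple alignment is built: the
clustering statistic needs only the distance matrix, and pairwise distances
keep every value independently recomputable. Trees are Saitou–Nei neighbor
joining (via `ape`), with taxa ordered lexicographically before joining so
tie-breaks are deterministic, and negative branch-length estimates clamped
to zero with the deficit moved to the sister branch (standard practice,
logged when it happens). NJ is exact on additive matrices, which the test
suite exploits: on 100 random trees the topology and branch lengths are
recovered to machine precision.

Class clustering is quantified as *nearest-neighbor purity*: the fraction
of sequences whose nearest neighbor in the distance matrix shares their
class label (ties broken lexicographically; members of singleton classes
are excluded from the denominator). On the synthetic classes-1–10
benchmark — ten sequences per class, ~25% within-class divergence, well
separated class anchors — purity is ≥ 0.9, echoing at testable scale the
observation that class members form clusters. The known bifurcation of one
natural class into two clusters depends on the real accession set and is
not modeled.

## Superposition with pruned pairs

`kabsch()` computes the least-squares rigid superposition (SVD form,
reflections excluded, `det(R) = +1`), pairing residues by index — inputs
are expected to be pre-aligned, as structure-alignment pairings are out of
scope. `prune_superpose()` iterates: fit, drop pairs with residual distance
above the cutoff (default 2.0 Å, the matchmaker-style convention; the
original figures do not state their cutoff), refit; it stops when nothing
is dropped, at `max_iter`, or rather than going below 3 pairs. The reported
RMSD is over the kept pairs — the "RMSD between N pruned atom pairs"
quantity. The published RMSD values themselves are not reproduced here:
they compare predicted structure models whose generation is not
deterministic at desk scale, so the tests assert the procedure's exact
properties (zero RMSD under rigid motions, recovery after planting a 10-Å
outlier, equivalence to plain Kabsch at infinite cutoff) instead.

## The synthetic-annotation generator

`make_ancestors()` draws one random ancestor protein per domain label
(HicA 55 aa, HicB partial RNase H 50, DBDs 45, Shared Domain 55, pVip 280,
SMC 700, RelE 90, DUF1902 55, NERD 80) and builds each detection profile
from 8 copies mutated at 15% divergence. `build_locus()` composes genes per
class (initiator M, short random pads, mutated domain copies, random tail
pad), back-translates with uniform synonymous codon choice, and embeds the
genes in random intergenic DNA at the specified gap. Negative gaps are
realized genuinely: the two genes share nucleotides, found by a search over
synonymous codon choices, stop-codon choice and start-codon choice
(ATG/GTG/TTG) — with junction-adjacent pad residues redrawn when codon
freedom alone cannot satisfy the overlap. Overlaps are limited to −20 nt to
keep frames constructible. The mutation model is substitution-only at a
uniform per-site rate (divergence < 0.5); indels are deliberately omitted
so that detection-sensitivity results stay interpretable.

Decoys emulate the confounders of real scans: a class 3 operon whose HicB
is truncated by an engineered in-frame stop ahead of its HTH (the
pseudogene case — the DBD codons remain on the contig, so read-through
finds them), solitary antitoxins, neighboring *vapBC*/*relBE*-like gene
pairs, transposase-sized ORFs, and RelE–pVip pairs. `build_genome()`
concatenates loci with ≥ 500 nt spacers, or packs them within a ~7 kb
window in `island = TRUE` mode, emulating defense islands in which eight TA
loci can share 7 kb of DNA.

What the generator does **not** emulate: realistic codon usage and GC
content, promoters and operators, indel divergence (optional nowhere),
inter-class sequence homology structure (all classes share one HicA
ancestor), and the empirical distribution of intergenic gaps — each class
uses one configured default gap unless a spec overrides it, so linkage
fractions computed on default synthetic genomes are properties of the
configuration, not re-estimates of the published fractions (31% of 119 for
class 3, 41% of 171 for class 4), which would require the original
per-locus supplementary tables. Passing round-trip tests therefore
demonstrates the pipeline's internal correctness, not its sensitivity on
real, deeply diverged genomes.

## Problem sizes and reproducibility

The worked example and tests use: a 14-locus fixture (one exemplar per
class, 10% divergence, seed 7); a 140-locus benchmark (ten per class, 20%
divergence) on which the classifier recovers ≥ 95% of truth labels (and
100% at zero divergence); a 100-sequence phylogeny benchmark; 100 random
additive matrices for NJ; and brute-force alignment checks up to 12
residues. These sizes make every stage rerunnable in minutes on one CPU.
Every random draw flows from named integer seeds; the same seed reproduces
a build byte-for-byte, including the emitted GenBank.

## Known limitations

- Profiles are not profile HMMs: no insert-state model, no E-value theory;
  the calibrated-null threshold is a stated surrogate for unspecified
  published search settings.
- Rule-based classification inherits the ambiguity of boundary cases: a
  HicB one residue outside a configured range is `unclassified` rather than
  fuzzy-matched; ranges are configurable (also via `read_rule_config()`,
  which accepts a YAML file).
- On densely packed contigs (defense islands), rank-1 adjacency can pick a
  neighboring locus's gene as a partner when strands and distances allow
  it; the co-orientation and `partner_max_gap` requirements bound but do
  not eliminate this.
- The pseudogene screen's read-through branch requires the truncation and
  its lost DBD to lie within 300 nt downstream on the contig.
- Pairing for superposition is positional; no sequence- or
  structure-based pairing is generated.
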