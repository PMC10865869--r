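# Distance-based phylogeny of HicA domain sequences and the class-clustering
# statistic. Distances are pairwise global-alignment identities (no
# progressive multiple alignment: the clustering statistic needs only a
# distance matrix); the tree is Saitou-Nei neighbor joining.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch with affine gaps over BLOSUM62. Identity is matches over
#' alignment columns, excluding terminal gap columns.
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (length-L gap costs
#'   `gap_open + L * gap_extend`).
#' @return List with `score`, `identity`, `matches`, `columns` (the
#'   non-terminal-gap column count) and the two aligned strings.
#' @export
global_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend)
  # pattern()/subject() return the aligned span clipped of terminal gap
  # columns, with internal gaps as '-'
  pa <- as.character(Biostrings::pattern(al))
  pb <- as.character(Biostrings::subject(al))
  id <- aligned_identity(pa, pb)
  list(score = Biostrings::score(al),
       identity = id$identity, matches = id$matches, columns = id$columns,
       aligned_a = pa, aligned_b = pb)
}

aligned_identity <- function(pa, pb) {
  ra <- charToRaw(pa); rb <- charToRaw(pb)
  matches <- sum(ra == rb & ra != charToRaw("-"))
  columns <- length(ra)
  list(identity = if (columns) matches / columns else 0,
       matches = matches, columns = columns)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Pairwise identity-distance matrix
#'
#' `d = 1 - fractional identity` for each sequence pair.
#'
#' @param seqs Named character vector of proteins, or a data frame with
#'   columns `id` and `protein`.
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
distance_matrix <- function(seqs) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id; prots <- seqs$protein
  } else {
    ids <- names(seqs); prots <- unname(seqs)
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique ids")
  n <- length(prots)
  stopifnot(n >= 3L)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(prots[(i + 1L):n]),
      Biostrings::AAString(prots[i]), type = "global",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
    pa <- as.character(Biostrings::pattern(al))
    pb <- as.character(Biostrings::subject(al))
    for (k in seq_along(pa)) {
      idy <- aligned_identity(pa[k], pb[k])$identity
      d[i, i + k] <- d[i + k, i] <- 1 - idy
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on an identity-distance matrix. Rows and
#' columns are ordered lexicographically by id before joining so tie-breaks
#' are deterministic; negative branch-length estimates are clamped to zero
#' with the deficit transferred to the sister branch.
#'
#' @param D Symmetric distance matrix with id dimnames.
#' @return An [ape::ape-package] `phylo` tree (unrooted).
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L, !is.null(rownames(D)))
  if (any(!is.finite(D))) stop("non-finite distances")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tree <- ape::nj(D)
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree, max_pass = 10L) {
  for (pass in seq_len(max_pass)) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tree$edge[e, 1L]
      sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
      if (length(sibs)) {
        tree$edge.length[sibs[1L]] <-
          tree$edge.length[sibs[1L]] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
    message("clamped ", length(neg), " negative NJ branch length(s)")
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Nearest-neighbor class purity
#'
#' Fraction of sequences whose nearest neighbor (smallest distance, ties
#' broken lexicographically by id) carries the same class label. Members of
#' singleton classes are excluded from the denominator (their own class has
#' no possible same-class neighbor) with a warning.
#'
#' @param D Distance matrix with id dimnames.
#' @param labels Named vector mapping id to class label.
#' @return Purity in `[0, 1]`.
#' @export
class_purity <- function(D, labels) {
  ids <- rownames(D)
  labels <- labels[ids]
  if (length(unique(labels)) < 2L)
    stop("need at least 2 classes")
  counts <- table(labels)
  singleton <- names(counts)[counts == 1L]
  use <- !(labels %in% singleton)
  if (any(!use))
    warning("excluding ", sum(!use), " member(s) of singleton classes")
  ord <- order(ids)  # lexicographic tie-break
  hits <- vapply(which(use), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    cand <- ord[which.min(d[ord])]
    labels[cand] == labels[i]
  }, logical(1))
  mean(hits)
}

#' Write a tree in Newick format
#'
#' Leaf labels containing whitespace or Newick metacharacters are quoted.
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  needs_quote <- grepl("[\\s(),:;\\[\\]']", tree$tip.label, perl = TRUE)
  originals <- tree$tip.label[needs_quote]
  # placeholders survive write.tree unmangled; the quoted originals are
  # substituted into the serialized string afterwards
  placeholders <- sprintf("xQUOTEDTIPx%dx", seq_along(originals))
  tree$tip.label[needs_quote] <- placeholders
  txt <- ape::write.tree(tree)
  for (i in seq_along(originals))
    txt <- sub(placeholders[i],
               sprintf("'%s'", gsub("'", "''", originals[i])), txt,
               fixed = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' Inverse of [write_newick()] (quoted labels are unquoted).
#'
#' @param path File or Newick string.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path)
          else ape::read.tree(text = path)
  quoted <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[quoted] <- gsub(
    "''", "'", sub("^'(.*)'$", "\\1", tree$tip.label[quoted]))
  tree
}
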