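test_that("global alignment identity behaves at the extremes", {
  set.seed(41)
  s <- random_aa(50)
  expect_equal(global_align(s, s)$identity, 1.0)
  expect_equal(global_align("AAAA", "CCCC")$identity, 0.0)
})

test_that("global alignment scores equal the brute-force path enumeration", {
  set.seed(43)
  B <- hicontext:::blosum62()
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- random_aa(n); b <- random_aa(m)
    S <- matrix(as.numeric(B[strsplit(a, "")[[1]], strsplit(b, "")[[1]],
                             drop = FALSE]), nrow = n)
    expect_equal(global_align(a, b)$score,
                 hicontext:::cpp_enum_global(S, 11, 1), tolerance = 1e-6)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and order-invariant", {
  set.seed(47)
  seqs <- setNames(vapply(1:5, function(i) random_aa(40), character(1)),
                   paste0("s", 1:5))
  D <- distance_matrix(seqs)
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_true(all(D >= 0 & D <= 1))
  perm <- sample(5)
  D2 <- distance_matrix(seqs[perm])
  expect_equal(D2[names(seqs), names(seqs)], D, tolerance = 1e-12)
  # identical sequences are at distance zero
  same <- setNames(rep(random_aa(30), 3), paste0("t", 1:3))
  expect_true(all(distance_matrix(same) == 0))
  expect_error(distance_matrix(setNames(rep("MAA", 3), c("a", "a", "b"))),
               "unique")
  # pairwise recomputation oracle
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], 1 - global_align(seqs[[i]], seqs[[j]])$identity)
})

test_that("neighbor joining recovers additive trees exactly", {
  library(ape)
  set.seed(53)
  for (i in 1:30) {
    ntax <- sample(4:8, 1)
    tr <- ape::rtree(ntax, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    ord <- sort(rownames(D))
    D <- D[ord, ord]
    # additivity check (four-point condition) on a sampled quartet
    q <- sample(ord, 4)
    sums <- c(D[q[1], q[2]] + D[q[3], q[4]],
              D[q[1], q[3]] + D[q[2], q[4]],
              D[q[1], q[4]] + D[q[2], q[3]])
    expect_lte(sort(sums, decreasing = TRUE)[1] -
                 sort(sums, decreasing = TRUE)[2], 1e-10)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0,
                 ignore_attr = TRUE)
    D2 <- ape::cophenetic.phylo(est)[ord, ord]
    expect_lt(max(abs(D2 - D)), 1e-8)
  }
})

test_that("a star-like equal matrix yields zero internal branch lengths", {
  n <- 5
  D <- matrix(1, n, n); diag(D) <- 0
  rownames(D) <- colnames(D) <- letters[1:n]
  tr <- nj_tree(D)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
  expect_true(all(tr$edge.length >= 0))
})

test_that("the unrooted topology is invariant to taxon input order", {
  set.seed(59)
  tr0 <- ape::rtree(6, rooted = FALSE)
  D <- ape::cophenetic.phylo(tr0)
  perm <- sample(6)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("class purity separates constructed classes and is ~0.5 for random labels", {
  world <- test_world()
  # two well-separated families: within 10%, between ~60%
  fam <- simulate_hica_families(world, classes = 1:2, n_per_class = 8,
                                divergence = 0.10, rng_seed = 61)
  D <- distance_matrix(setNames(fam$protein, fam$id))
  expect_equal(class_purity(D, setNames(fam$class, fam$id)), 1.0)
  # random balanced labels on unstructured sequences
  set.seed(67)
  seqs <- setNames(vapply(1:100, function(i) random_aa(50), character(1)),
                   sprintf("r%03d", 1:100))
  Dr <- distance_matrix(seqs)
  labs <- setNames(rep(1:2, each = 50), names(seqs))
  p <- class_purity(Dr, labs)
  expect_gt(p, 0.5 - 0.15)
  expect_lt(p, 0.5 + 0.15)
  # singleton classes are excluded from the denominator: one tight family
  # plus one distant singleton scores purity 1 over the family members
  fam1 <- simulate_hica_families(world, classes = 3, n_per_class = 8,
                                 divergence = 0.10, rng_seed = 69)
  seqs1 <- setNames(c(fam1$protein, random_aa(55)), c(fam1$id, "lone"))
  D1 <- distance_matrix(seqs1)
  labs2 <- setNames(c(fam1$class, 99), names(seqs1))
  expect_warning(p2 <- class_purity(D1, labs2), "singleton")
  expect_equal(p2, 1.0)
  expect_error(class_purity(Dr, setNames(rep(1, 100), names(seqs))),
               "2 classes")
})

test_that("Newick output round-trips, including quoted labels and path lengths", {
  d3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3)
  rownames(d3) <- colnames(d3) <- c("A", "B", "C")
  txt <- write_newick(nj_tree(d3))
  expect_match(txt, "^\\(.*A:1.*\\);$")
  t3 <- read_newick(txt)
  expect_setequal(t3$tip.label, c("A", "B", "C"))
  # labels with spaces are quoted and survive
  tr <- nj_tree(d3)
  tr$tip.label[1] <- "tip one"
  txt2 <- write_newick(tr)
  expect_match(txt2, "'tip one'", fixed = TRUE)
  expect_true("tip one" %in% read_newick(txt2)$tip.label)
  # 50-leaf tree: path-length matrix preserved through serialization
  set.seed(71)
  big <- ape::rtree(50, rooted = FALSE)
  path <- tempfile(fileext = ".nwk")
  write_newick(big, path)
  back <- read_newick(path)
  ord <- sort(big$tip.label)
  expect_lt(max(abs(ape::cophenetic.phylo(big)[ord, ord] -
                      ape::cophenetic.phylo(back)[ord, ord])), 1e-9)
})
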