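test_that("profile columns equal hand-computed log-odds and obey the occupancy rule", {
  # 4 sequences, 3 columns; column 2 is {A, A, A, -} (75% occupancy, kept),
  # column 3 is {-, -, -, W} (25% occupancy, dropped)
  aln <- c("RA-", "KA-", "RA-", "R-W")
  prof <- build_profile(aln, "DBD_HTH", pseudocount = 0.5)
  expect_equal(prof$length, 2L)
  bg <- 1 / 20
  lo <- function(count, n) log2(((count + 0.5 * bg) / (n + 0.5)) / bg)
  expect_equal(unname(prof$columns["R", 1]), lo(3, 4))
  expect_equal(unname(prof$columns["K", 1]), lo(1, 4))
  expect_equal(unname(prof$columns["A", 1]), lo(0, 4))
  expect_equal(unname(prof$columns["A", 2]), lo(3, 3))  # N = non-gap rows
  expect_equal(unname(prof$consensus), "RA")

  expect_error(build_profile("RNDKL", "DBD_HTH"), "2 aligned")
  expect_error(build_profile(c("---", "---"), "DBD_HTH"), "gap")
  expect_error(build_profile(c("AC", "ACG"), "DBD_HTH"), "equal length")
})

test_that("a profile of identical sequences scores its consensus as the sum of column maxima", {
  set.seed(11)
  seqs <- rep(random_aa(30), 4)
  prof <- build_profile(seqs, "HicA_dsRBD")
  prof <- calibrate_threshold(prof, 120, rng_seed = 4)
  hits <- scan_protein(prof$consensus, prof)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 30L)
  expect_equal(hits$score, sum(apply(prof$columns, 2, max)))
  # the reversed consensus scores below threshold
  rev_cons <- paste(rev(strsplit(prof$consensus, "")[[1]]), collapse = "")
  expect_equal(nrow(scan_protein(rev_cons, prof)), 0L)
})

test_that("local profile scores equal the brute-force path enumeration on tiny instances", {
  set.seed(13)
  for (i in seq_len(12)) {
    L <- sample(3:6, 1)
    seqs <- vapply(1:3, function(k) random_aa(L), character(1))
    prof <- build_profile(seqs, "HicA_dsRBD")
    prof$threshold <- -Inf
    prot <- random_aa(sample(4:12, 1))
    impl <- hicontext:::raw_local_score(prot, prof, 11, 1)
    expect_equal(impl, oracle_local_score(prot, prof$columns, 11, 1),
                 tolerance = 1e-9)
  }
})

test_that("threshold calibration is deterministic, separates the self-score, and is stable", {
  world <- test_world()
  prof <- world$HicA_dsRBD$profile
  t1 <- calibrate_threshold(prof, 120, rng_seed = 9)$threshold
  t2 <- calibrate_threshold(prof, 120, rng_seed = 9)$threshold
  expect_identical(t1, t2)
  self_score <- hicontext:::raw_local_score(prof$consensus, prof, 11, 1)
  expect_lt(t1, self_score)

  # independent re-implementation of the shuffle null (brute-force scorer,
  # small profile so the enumeration stays cheap)
  set.seed(2)
  small <- build_profile(vapply(1:4, function(k) random_aa(7), character(1)),
                         "DBD_RHH")
  impl_thr <- calibrate_threshold(small, 150, rng_seed = 5)$threshold
  res <- strsplit(small$consensus, "")[[1]]
  scores <- withr::with_seed(5, vapply(seq_len(150), function(i) {
    oracle_local_score(paste(sample(res), collapse = ""), small$columns,
                       11, 1)
  }, numeric(1)))
  ind_thr <- mean(scores) + 5 * sd(scores)
  expect_equal(impl_thr, ind_thr, tolerance = 0.1 * abs(ind_thr))
})

test_that("architecture assignment keeps compatible hits greedily and matches the subset oracle", {
  h <- function(label, start, end, score)
    data.frame(protein_id = "p", domain_label = label, start = start,
               end = end, score = score, stringsAsFactors = FALSE)
  # disjoint hits are both kept, N-to-C
  a <- assign_architecture("p", rbind(h("HicA_dsRBD", 0, 55, 40),
                                      h("HicB_pRNaseH", 60, 120, 35)))
  expect_equal(a$domain_label, c("HicA_dsRBD", "HicB_pRNaseH"))
  # heavy overlap resolved by score
  b <- assign_architecture("p", rbind(h("DBD_HTH", 80, 130, 30),
                                      h("DBD_RHH", 85, 125, 20)))
  expect_equal(b$domain_label, "DBD_HTH")
  # a frozen 6-hit instance equals the exhaustive max-score compatible subset
  set.seed(31)
  hits <- do.call(rbind, lapply(1:6, function(i) {
    s <- sample(0:80, 1)
    h(sample(DOMAIN_LABELS, 1), s, s + sample(20:50, 1), runif(1, 5, 50))
  }))
  kept <- assign_architecture("p", hits)
  expect_equal(sum(kept$score), oracle_best_subset(hits), tolerance = 1e-9)
  # deterministic under input permutation
  perm <- assign_architecture("p", hits[sample(1:6), ])
  expect_equal(kept, perm)
})

test_that("domtblout ingestion converts envelopes, filters E-values and skips unmapped rows", {
  dom <- tempfile()
  row <- function(target, query, ieval, from, to)
    paste(target, "-", "120", query, "-", "60", "1e-20", "55.1", "0.1",
          "1", "1", "1e-21", ieval, "54.0", "0.1", "1", "60", "4", "59",
          from, to, "0.98", "-", sep = " ")
  writeLines(c("# comment", row("protA", "HicA_hmm", "1e-12", "5", "60"),
               row("protB", "Mystery_hmm", "1e-12", "3", "44"),
               row("protC", "HicA_hmm", "0.5", "5", "60")), dom)
  hits <- NULL
  expect_warning(hits <- ingest_domtblout(dom, c(HicA_hmm = "HicA_dsRBD")),
                 "Mystery_hmm")
  expect_equal(nrow(hits), 1L)  # protC fails the i-Evalue filter
  expect_equal(hits$protein_id, "protA")
  expect_equal(hits$domain_label, "HicA_dsRBD")
  expect_equal(hits$start, 4L)
  expect_equal(hits$end, 60L)

  empty <- tempfile(); writeLines(c("# only", "# comments"), empty)
  expect_equal(nrow(ingest_domtblout(empty, c(a = "SMC"))), 0L)
  bad <- tempfile(); writeLines("too few fields", bad)
  expect_error(ingest_domtblout(bad, c(a = "SMC")), "line 1")
})

test_that("profiles detect diverged domain copies and reject shuffled decoys", {
  world <- test_world()
  set.seed(17)
  labels <- c("HicA_dsRBD", "HicB_pRNaseH", "DBD_HTH", "DBD_PhdYefM")
  n_pos <- 0L; n_detected <- 0L; n_neg <- 0L; n_false <- 0L
  for (lab in labels) {
    prof <- world[[lab]]$profile
    anc <- world[[lab]]$ancestor
    for (k in 1:25) {
      q <- mutate_protein(anc, 0.30, protect_first = FALSE)
      hits <- scan_protein(q, prof)
      n_pos <- n_pos + 1L
      n_detected <- n_detected + as.integer(nrow(hits) > 0)
      shuf <- paste(sample(strsplit(anc, "")[[1]]), collapse = "")
      n_neg <- n_neg + 1L
      n_false <- n_false + as.integer(nrow(scan_protein(shuf, prof)) > 0)
    }
  }
  expect_gte(n_detected / n_pos, 0.95)
  expect_lt(n_false / n_neg, 0.05)
})

test_that("SMC hits on short non-coiled-coil proteins are discarded", {
  world <- test_world()
  smc_prof <- world$SMC$profile
  # a 700-aa SMC ancestor passes the length gate
  rec_ok <- genome_record("c", strrep("A", 10),
                          hicontext:::empty_features())
  long_prot <- paste0("M", world$SMC$ancestor)
  hits <- scan_protein(long_prot, smc_prof, protein_id = "g")
  expect_gt(nrow(hits), 0)
  expect_true("SMC" %in%
                hicontext:::filter_smc_hits(hits, long_prot)$domain_label)
  # the same domain grafted into a short protein is rejected
  short_prot <- paste0("M", substr(world$SMC$ancestor, 1, 200))
  short_hits <- scan_protein(short_prot, smc_prof, protein_id = "g")
  if (nrow(short_hits))
    expect_false("SMC" %in%
                   hicontext:::filter_smc_hits(short_hits,
                                               short_prot)$domain_label)
})
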