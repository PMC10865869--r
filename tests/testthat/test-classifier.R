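test_that("one exemplar per configuration receives its own class", {
  g <- test_genome14()
  tab <- test_classification14()
  m <- merge(g$truth, tab, by = "locus_id")
  expect_equal(nrow(m), 14L)
  expect_equal(m$class_id.y, m$class_id.x)
  expect_equal(sort(unique(m$class_id.y)), 1:14)
})

test_that("class assignments are invariant under contig reverse-complementation", {
  g <- test_genome14()
  flipped <- reverse_complement_record(g$record)
  tab_f <- suppressWarnings(classify_genome(flipped, test_profiles()))
  tab <- test_classification14()
  ord <- order(tab$locus_id); ord_f <- order(tab_f$locus_id)
  expect_equal(tab_f$class_id[ord_f], tab$class_id[ord])
  expect_equal(tab_f$gap_nt[ord_f], tab$gap_nt[ord])
})

test_that("recorded evidence replays to the same class and no higher rule fires", {
  tab <- test_classification14()
  assignments <- attr(tab, "assignments")
  contexts <- attr(tab, "contexts")
  for (key in names(assignments)) {
    expect_true(replay_evidence(contexts[[key]], assignments[[key]]),
                info = key)
    expect_gt(nrow(assignments[[key]]$evidence), 0)
  }
})

test_that("HicB length range endpoints are inclusive on both sides", {
  hica <- fake_arch("HicA_dsRBD", c(2, 57))
  plain_b <- fake_arch("HicB_pRNaseH", c(2, 48))
  cfg <- class_rule_config()
  cases <- list(
    list(side = "downstream", len = 60L, class = 1L),
    list(side = "downstream", len = 97L, class = 1L),
    list(side = "downstream", len = 98L, class = NA_integer_),
    list(side = "upstream", len = 63L, class = 2L),
    list(side = "upstream", len = 103L, class = 2L),
    list(side = "upstream", len = 216L, class = 7L),
    list(side = "upstream", len = 233L, class = 7L),
    list(side = "upstream", len = 331L, class = 8L),
    list(side = "upstream", len = 356L, class = 8L),
    list(side = "upstream", len = 234L, class = NA_integer_),
    list(side = "upstream", len = 62L, class = NA_integer_))
  for (cs in cases) {
    ctx <- fake_ctx(hica, plain_b, partner_len = cs$len, gap = 2,
                    partner_side = cs$side)
    got <- classify_locus(ctx, cfg)$class_id
    expect_equal(got, cs$class, info = sprintf("%s %d", cs$side, cs$len))
  }
})

test_that("rule precedence puts fusions and pVip adjacency above partner rules", {
  cfg <- class_rule_config()
  # an SMC-HicA fusion outranks everything else
  smc_fusion <- fake_arch("SMC", c(1, 690), "HicA_dsRBD", c(700, 755))
  ctx <- fake_ctx(smc_fusion, fake_arch("HicB_pRNaseH", c(2, 48)),
                  partner_len = 80, focal_len = 762)
  expect_equal(classify_locus(ctx, cfg)$class_id, 14L)
  # pVip adjacency beats a qualifying small HicB on the other side
  hica <- fake_arch("HicA_dsRBD", c(2, 57))
  ctx2 <- fake_ctx(hica, fake_arch("pVip", c(2, 280)), partner_len = 290,
                   gap = 50, partner_side = "downstream")
  expect_equal(classify_locus(ctx2, cfg)$class_id, 9L)
  ctx3 <- fake_ctx(hica, fake_arch("pVip", c(2, 280)), partner_len = 290,
                   gap = 50, partner_side = "upstream")
  expect_equal(classify_locus(ctx3, cfg)$class_id, 10L)
  # Shared Domain upgrades class 5 to class 6
  phd_b <- fake_arch("DBD_PhdYefM", c(2, 46), "HicB_pRNaseH", c(50, 99))
  hica6 <- fake_arch("HicA_dsRBD", c(2, 57), "SharedDomain", c(62, 116))
  ctx5 <- fake_ctx(hica, phd_b, partner_len = 105, partner_side = "upstream")
  ctx6 <- fake_ctx(hica6, phd_b, partner_len = 105, partner_side = "upstream",
                   focal_len = 125)
  expect_equal(classify_locus(ctx5, cfg)$class_id, 5L)
  expect_equal(classify_locus(ctx6, cfg)$class_id, 6L)
})

test_that("non-co-oriented or distant neighbors never count as operon partners", {
  hica <- fake_arch("HicA_dsRBD", c(2, 57))
  plain_b <- fake_arch("HicB_pRNaseH", c(2, 48))
  divergent <- fake_ctx(hica, plain_b, partner_len = 80, gap = 2,
                        partner_strand = "-")
  expect_true(is.na(classify_locus(divergent)$class_id))
  far <- fake_ctx(hica, plain_b, partner_len = 80, gap = 400)
  expect_true(is.na(classify_locus(far)$class_id))
  solitary <- fake_ctx(hica, NULL, partner_len = 300, gap = 800)
  expect_true(is.na(classify_locus(solitary)$class_id))
})

test_that("pseudogene decoys are flagged and intact small HicBs are not", {
  world <- test_world()
  profiles <- test_profiles()
  specs <- list(synthetic_spec(3, divergence = 0.05,
                               decoys = "pseudogene_hicb", strand = "+"),
                synthetic_spec(1, divergence = 0.05, strand = "+"))
  g <- build_genome(specs, world, rng_seed = 19)
  tab <- suppressWarnings(classify_genome(g$record, profiles))
  pseudo_locus <- g$truth$locus_id[g$truth$is_decoy]
  intact_locus <- g$truth$locus_id[!g$truth$is_decoy]
  expect_true(tab$pseudogene_candidate[tab$locus_id == pseudo_locus])
  expect_false(tab$pseudogene_candidate[tab$locus_id == intact_locus])
})

test_that("reference-identity branch of the pseudogene screen fires at 95%", {
  world <- test_world()
  profiles <- test_profiles()
  # an intact class 1 locus whose HicB is a truncated copy of a reference
  # HicB that carries a DBD
  g <- build_genome(synthetic_spec(1, divergence = 0, strand = "+"),
                    world, rng_seed = 23)
  rec <- g$record
  hicb <- rec$features[grepl("_hicB$", rec$features$gene_id), , drop = FALSE]
  ref_dbd <- paste0(hicb$protein, strrep("W", 45))  # candidate + a fake DBD
  refs <- data.frame(protein = ref_dbd, has_dbd = TRUE,
                     stringsAsFactors = FALSE)
  expect_true(suppressWarnings(
    pseudogene_screen(rec, hicb, profiles, reference_hicbs = refs)))
  refs_no <- data.frame(protein = ref_dbd, has_dbd = FALSE,
                        stringsAsFactors = FALSE)
  expect_false(suppressWarnings(
    pseudogene_screen(rec, hicb, profiles, reference_hicbs = refs_no)))
})

test_that("a RelE gene beside a pVip gene raises the auxiliary association flag", {
  world <- test_world()
  profiles <- test_profiles()
  g <- build_genome(synthetic_spec(1, divergence = 0.05, strand = "+",
                                   decoys = "relE_pvip_pair"),
                    world, rng_seed = 29)
  tab <- suppressWarnings(classify_genome(g$record, profiles))
  expect_true(all(tab$relE_pvip_in_contig))
  g2 <- build_genome(synthetic_spec(1, divergence = 0.05, strand = "+"),
                     world, rng_seed = 29)
  tab2 <- suppressWarnings(classify_genome(g2$record, profiles))
  expect_false(any(tab2$relE_pvip_in_contig))
})

test_that("an empty genome classifies to an empty table", {
  rec <- genome_record("empty", strrep("A", 500))
  tab <- classify_genome(rec, test_profiles())
  expect_equal(nrow(tab), 0L)
})
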