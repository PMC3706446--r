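test_that("presets carry the canonical thresholds", {
  ms <- enrichment_preset("mel_specific")
  expect_equal(ms$fold_vs_others, 2)
  expect_equal(ms$p_max, 0.05)
  expect_equal(ms$fold_vs_embryo, 8)
  si <- enrichment_preset("shared_identity")
  expect_equal(si$within_fold, 2)
  expect_equal(si$min_rpkm, 4)
  expect_equal(si$fold_vs_embryo, 100)
  is <- enrichment_preset("irid_stringent")
  expect_equal(is$fold_vs_others, 30)
  expect_equal(is$fold_vs_embryo, 100)
  expect_true(is.na(is$p_max))
  expect_error(enrichment_preset("nope"), "shared_identity")
  expect_error(filter_spec("specific", c("mel", "rpe"), fold_vs_others = 2),
               "exactly one")
  expect_error(filter_spec("pairwise_shared", "mel", fold_vs_others = 2),
               "exactly two")
})

test_that("reference tables pass exactly their defining presets", {
  tables <- list(
    list(name = "shared_identity", preset = "shared_identity", n = 28),
    list(name = "mel_rpe_top", preset = "mel_rpe_stringent", n = 38),
    list(name = "mel_irid_top", preset = "mel_irid_stringent", n = 15),
    list(name = "irid_top", preset = "irid_stringent", n = 30))
  for (tb in tables) {
    prof <- reference_profile(tb$name)
    calls <- apply_filter(prof, tb$preset)
    expect_equal(sum(calls$pass), tb$n, info = tb$name)
    expect_equal(nrow(calls), tb$n, info = tb$name)
  }
  # a gene expressed 50-fold over embryo fails the 100-fold identity rule
  g <- expression_profile(data.frame(gene = "g", mel = 50, rpe = 50,
                                     irid = 50, embryo = 1))
  expect_false(apply_filter(g, "shared_identity")$pass)
  # zero embryo means an infinite fold, which passes
  z <- expression_profile(data.frame(gene = "z", mel = 50, rpe = 50,
                                     irid = 50, embryo = 0))
  expect_true(apply_filter(z, "shared_identity")$pass)
})

test_that("apply_filter equals the brute-force conjunction oracle", {
  specs <- list(
    enrichment_preset("shared_identity"),
    enrichment_preset("mel_rpe_shared"),
    enrichment_preset("irid_specific"),
    enrichment_preset("mel_irid_stringent"),
    enrichment_preset("irid_stringent"),
    filter_spec("specific", "rpe", fold_vs_others = 3, fold_vs_embryo = 5,
                min_rpkm = 2, p_max = 0.1, embryo_rule = "any"),
    filter_spec("shared_all", c("mel", "rpe", "irid"), within_fold = 3,
                min_rpkm = 1, fold_vs_embryo = 10, embryo_rule = "max"))
  for (seed in 1:6) {
    prof <- random_profile(500, seed = seed)
    for (spec in specs) {
      calls <- apply_filter(prof, spec)
      expect_equal(calls$pass, brute_filter_oracle(prof, spec),
                   info = paste(spec$mode, "seed", seed))
    }
  }
})

test_that("tightening any threshold never adds genes to a pass set", {
  prof <- random_profile(800, seed = 99)
  base <- filter_spec("pairwise_shared", c("mel", "irid"),
                      fold_vs_others = 2, fold_vs_embryo = 4, p_max = 0.2)
  pass0 <- apply_filter(prof, base)$pass
  variants <- list(
    filter_spec("pairwise_shared", c("mel", "irid"), fold_vs_others = 5,
                fold_vs_embryo = 4, p_max = 0.2),
    filter_spec("pairwise_shared", c("mel", "irid"), fold_vs_others = 2,
                fold_vs_embryo = 20, p_max = 0.2),
    filter_spec("pairwise_shared", c("mel", "irid"), fold_vs_others = 2,
                fold_vs_embryo = 4, p_max = 0.01),
    filter_spec("pairwise_shared", c("mel", "irid"), fold_vs_others = 2,
                fold_vs_embryo = 4, min_rpkm = 5, p_max = 0.2))
  for (v in variants) {
    passv <- apply_filter(prof, v)$pass
    expect_true(all(!passv | pass0))  # passv subset of pass0
  }
})

test_that("the guanine pathway report flags enrichment as printed", {
  prof <- reference_profile("guanine_pathway")
  groups <- split(prof$gene, prof$group)
  rep <- pathway_report(prof, groups, target = "irid", p_max = 0.05)
  r <- rep$report
  imp <- r[r$gene == "impdh1b", ]
  expect_equal(imp$fold_vs_mel, 71.28297, tolerance = 1e-5)
  expect_true(imp$sig_vs_mel)
  ads <- r[r$gene == "adssl", ]
  expect_equal(ads$fold_vs_mel, 0.7019231, tolerance = 1e-6)
  expect_false(ads$sig_vs_mel)  # 0.7-fold is not enrichment
  prt <- r[r$gene == "prtfdc1", ]
  expect_equal(prt$fold_vs_mel, 198.641, tolerance = 1e-4)
  expect_true(prt$sig_vs_mel)
  expect_equal(prt$fold_vs_embryo, Inf)
  # ak1 is higher in melanocytes: significant p but not enriched
  ak1 <- r[r$gene == "ak1", ]
  expect_false(ak1$sig_vs_mel)

  # missing genes are reported, not dropped; empty intersections error
  rep2 <- pathway_report(prof, list(extra = c("impdh1b", "ghost")))
  expect_equal(rep2$missing$gene, "ghost")
  expect_error(pathway_report(prof, list(x = "ghost")), "none of the group")
  expect_error(pathway_report(prof, list()), "at least one")
})

test_that("preset classifiers recover planted classes on simulated data", {
  # quick two-simulation version of the full 20-seed acceptance check
  des <- study_design(n_genes = 4000)
  presets <- c(pairwise_mel_rpe = "mel_rpe_shared",
               pairwise_mel_irid = "mel_irid_shared",
               pairwise_rpe_irid = "rpe_irid_shared",
               specific_mel = "mel_specific",
               specific_irid = "irid_specific",
               specific_rpe = "rpe_specific")
  sn <- sd <- fp <- nc <- 0
  for (s in 1:2) {
    tr <- generate_truth(des, fold_margin = 2, dispersion = 0.2, seed = s)
    cm <- simulate_counts(tr, des, seed = 100 + s)
    prof <- all_pair_stats(compute_rpkm(cm))
    for (cl in names(presets)) {
      calls <- apply_filter(prof, presets[[cl]])
      planted <- tr$class == cl
      sn <- sn + sum(calls$pass & planted); sd <- sd + sum(planted)
      fp <- fp + sum(calls$pass & !planted); nc <- nc + sum(calls$pass)
    }
  }
  expect_gte(sn / sd, 0.90)
  expect_lte(fp / nc, 0.10)
})
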