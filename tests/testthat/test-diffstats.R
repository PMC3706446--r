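test_that("pooled t-test matches its closed form and degenerate contract", {
  res <- gene_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  # antisymmetry in group order
  rev <- gene_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)

  expect_equal(gene_ttest(c(5, 5, 5), c(5, 5, 5))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(gene_ttest(c(0, 0), c(0, 0))[c("t", "p")], list(t = 0, p = 1))
  expect_warning(z <- gene_ttest(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(z$p, 0)
  expect_error(gene_ttest(1, c(1, 2)), "replicates")

  # agreement with the reference implementation on random draws
  set.seed(9)
  for (k in 1:10) {
    a <- rlnorm(sample(2:8, 1), 1, 1)
    b <- rlnorm(sample(2:8, 1), 1.5, 1)
    ours <- gene_ttest(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("fold change sentinels behave as the filters expect", {
  expect_equal(fold_change(816.19, 11.45), 71.28297, tolerance = 1e-5)
  expect_equal(fold_change(5, 0), Inf)
  expect_true(is.nan(fold_change(0, 0)))
  expect_error(fold_change(-1, 2), "non-negative")
  expect_equal(fold_change(c(4, 0), c(2, 5)), c(2, 0))
})

test_that("profile assembly reproduces means and per-pair p-values", {
  des <- small_design(n_genes = 150)
  tr <- generate_truth(des, seed = 12)
  cm <- simulate_counts(tr, des, seed = 13)
  rp <- compute_rpkm(cm)
  prof <- all_pair_stats(rp)
  expect_s3_class(prof, "expression_profile")
  expect_equal(nrow(prof), 150)

  means <- average_by_celltype(rp)
  expect_equal(prof$mel, unname(means[, "mel"]))
  expect_equal(prof$embryo, unname(means[, "embryo"]))
  # spot-check p-values against the scalar t-test
  ann <- rp$libraries
  g <- which(prof$mel > 1)[1]
  expect_equal(prof$p_mel_irid[g],
               gene_ttest(rp$rpkm[g, ann$cell_type == "mel"],
                          rp$rpkm[g, ann$cell_type == "irid"])$p)

  # identical groups give p = 1 everywhere
  counts <- matrix(5L, 1, 6, dimnames = list("g1", sprintf("L%d", 1:6)))
  libs <- data.frame(library_id = colnames(counts),
                     cell_type = rep(c("mel", "rpe", "irid"), each = 2),
                     total_reads = 1e6, stringsAsFactors = FALSE)
  one <- all_pair_stats(compute_rpkm(count_matrix(counts, c(g1 = 1000), libs)))
  expect_equal(one$p_mel_rpe, 1)
  expect_equal(one$p_rpe_irid, 1)
})

test_that("planted 16-fold specific genes reach p < 0.05 in most simulations", {
  # 5 vs 11 replicates, fold 16 (margin 8), dispersion 0.2
  hits <- 0L; tot <- 0L
  des <- study_design(replicates = c(mel = 11, irid = 5, rpe = 5, embryo = 1),
                      n_genes = 120, total_reads = 1e6)
  for (s in 1:40) {
    tr <- generate_truth(des, class_proportions = c(background = 0.5,
                                                    specific_irid = 0.2,
                                                    unexpressed = 0.3),
                         fold_margin = 8, seed = s)
    cm <- simulate_counts(tr, des, seed = 1000 + s)
    prof <- all_pair_stats(compute_rpkm(cm))
    idx <- tr$class == "specific_irid" & tr$baseline > 8
    hits <- hits + sum(prof$p_mel_irid[idx] < 0.05)
    tot <- tot + sum(idx)
  }
  expect_gte(hits / tot, 0.90)
})

test_that("windowed correlation matches the direct-loop definition", {
  # identical profiles correlate perfectly in every window
  n <- 60
  base <- data.frame(gene = sprintf("g%02d", 1:n), mel = (1:n) + 0.5,
                     rpe = (1:n) + 0.5, irid = rev(seq_len(n)) * 2,
                     embryo = seq_len(n) / 10)
  prof <- expression_profile(base)
  wp <- windowed_correlation(prof, w = 10)
  expect_equal(nrow(wp$windows[wp$windows$pair == "mel_rpe", ]), n - 10)
  expect_equal(unname(wp$average[["mel_rpe"]]), 1)
  # anti-correlated pair: every window at -1
  expect_equal(unname(wp$average[["mel_irid"]]), -1)

  # brute-force agreement at n = 2000, w = 100 to 1e-12
  rp <- random_profile(2000, seed = 42)
  wp2 <- windowed_correlation(rp, w = 100)
  for (pr in list(c("mel", "rpe"), c("rpe", "irid"))) {
    key <- paste(pr, collapse = "_")
    brute <- brute_window_avg(rp, pr, 100)
    got <- wp2$windows$r[wp2$windows$pair == key]
    expect_lt(max(abs(got - brute), na.rm = TRUE), 1e-12)
    expect_equal(unname(wp2$average[[key]]), mean(brute, na.rm = TRUE),
                 tolerance = 1e-12)
  }

  # relabeling genes (same embryo ordering) leaves the average unchanged
  rp3 <- rp
  rp3$gene <- sprintf("z%05d", seq_len(nrow(rp3)))  # same lexicographic order
  wp3 <- windowed_correlation(rp3, w = 100)
  expect_equal(wp3$average, wp2$average)

  # zero-variance windows are flagged and excluded from the average
  flat <- base
  flat$mel[1:20] <- 7
  flat$embryo <- seq_len(n)  # unique ordering
  wpf <- windowed_correlation(expression_profile(flat), w = 10)
  sub <- wpf$windows[wpf$windows$pair == "mel_rpe", ]
  expect_true(any(sub$degenerate))
  expect_equal(unname(wpf$average[["mel_rpe"]]),
               mean(sub$r[!sub$degenerate]))

  expect_error(windowed_correlation(prof, w = 2), "at least 3")
  expect_error(windowed_correlation(prof, w = n), "more genes")
})

test_that("average windowed correlation rises with shared-component weight", {
  set.seed(88)
  n <- 1500
  shared <- rlnorm(n, 2, 1.5)
  avg <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    mel <- rho * shared + (1 - rho) * rlnorm(n, 2, 1.5)
    rpe <- rho * shared + (1 - rho) * rlnorm(n, 2, 1.5)
    prof <- expression_profile(data.frame(
      gene = sprintf("g%04d", 1:n), mel = mel, rpe = rpe,
      irid = rlnorm(n, 2, 1.5), embryo = rlnorm(n, 0, 1)))
    windowed_correlation(prof, pairs = list(c("mel", "rpe")),
                         w = 200)$average[["mel_rpe"]]
  }, numeric(1))
  expect_true(all(diff(avg) > 0))
})
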