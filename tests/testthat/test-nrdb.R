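test_that("BLAST tabular hits parse with self-hit removal and diagnostics", {
  h <- read_blast_hits("a\tb\t95.0\t300")
  expect_equal(nrow(h), 1)
  expect_equal(h$query_id, "a")
  expect_equal(h$percent_identity, 95.0)
  expect_equal(h$alignment_length, 300)

  expect_equal(nrow(read_blast_hits("a\ta\t100.0\t500")), 0)

  full <- "q1\ts1\t98.50\t240\t3\t1\t1\t240\t10\t249\t1e-100\t430.2"
  h12 <- read_blast_hits(full)
  expect_equal(h12$mismatches, 3)
  expect_equal(h12$evalue, 1e-100)
  expect_equal(h12$bit_score, 430.2)

  expect_error(read_blast_hits("a\tb\tninety\t300"), "line 1")
  expect_error(read_blast_hits(c("a\tb\t90\t100", "a\tb")), "line 2")
})

test_that("local alignment identity agrees with the Smith-Waterman oracle", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  mer100 <- paste(sample(bases, 100, replace = TRUE), collapse = "")
  hits <- all_vs_all_identity(c(x = mer100, y = mer100))
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$alignment_length, 100)

  # 5 interior substitutions in a 100-mer: identity exactly 95.0
  s <- strsplit(mer100, "")[[1]]
  for (p in c(10, 30, 50, 70, 90)) s[p] <- setdiff(bases, s[p])[1]
  mut <- paste(s, collapse = "")
  hits2 <- all_vs_all_identity(c(x = mer100, y = mut))
  orc <- sw_oracle(mer100, mut)
  expect_equal(hits2$percent_identity, 95.0)
  expect_equal(hits2$percent_identity, orc$identity)
  expect_equal(hits2$alignment_length, orc$alignment_length)

  # dissimilar sequences: best local alignment is a bare single match,
  # too short for any coverage criterion (the oracle agrees)
  hits3 <- all_vs_all_identity(c(x = "ACGT", y = "TTTT"))
  orc3 <- sw_oracle("ACGT", "TTTT")
  expect_equal(hits3$alignment_length, orc3$alignment_length)
  expect_equal(hits3$alignment_length, 1)

  # random pairs, including a gapped one, match the oracle
  for (k in 1:5) {
    a <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    bvec <- strsplit(a, "")[[1]]
    bvec <- bvec[-sample(60, 2)]             # two deletions
    flip <- sample(length(bvec), 3)
    for (p in flip) bvec[p] <- setdiff(bases, bvec[p])[1]
    b <- paste(bvec, collapse = "")
    got <- all_vs_all_identity(c(a = a, b = b))
    orc <- sw_oracle(a, b)
    expect_equal(got$percent_identity, orc$identity, tolerance = 1e-12)
    expect_equal(got$alignment_length, orc$alignment_length)
  }

  expect_equal(nrow(all_vs_all_identity(character(0))), 0)
})

test_that("collapse excludes the smaller of each near-identical pair", {
  lens <- c(big = 500, small = 400)
  hits <- read_blast_hits("big\tsmall\t100.0\t400")
  res <- collapse_transcripts(lens, hits)
  expect_equal(res$removed_ids, "small")
  expect_equal(names(res$kept), "big")
  expect_equal(res$decisions$kept_id, "big")
  expect_equal(res$decisions$coverage, 1)

  # below the identity threshold: both kept
  res90 <- collapse_transcripts(lens, read_blast_hits("big\tsmall\t90.0\t400"))
  expect_equal(length(res90$removed_ids), 0)

  # strictly-greater semantics at the boundary
  res94 <- collapse_transcripts(lens, read_blast_hits("big\tsmall\t94.0\t400"))
  expect_equal(length(res94$removed_ids), 0)
  rescov <- collapse_transcripts(lens, read_blast_hits("big\tsmall\t99.0\t280"))
  expect_equal(length(rescov$removed_ids), 0)  # 280 = 0.70 * 400, not more

  expect_error(collapse_transcripts(lens, read_blast_hits("big\tghost\t99\t400")),
               "ghost")
})

test_that("greedy collapse equals the stepwise fixpoint oracle on chains", {
  # oracle: repeatedly rescan all actionable pairs in the stated order,
  # removing one transcript at a time until nothing is actionable
  fixpoint_oracle <- function(lens, hits, id_min = 94, cov_min = 0.70) {
    a <- pmin(hits$query_id, hits$subject_id)
    b <- pmax(hits$query_id, hits$subject_id)
    key <- paste(a, b)
    ord <- order(key, -hits$percent_identity, -hits$alignment_length)
    h <- hits[ord, ][!duplicated(key[ord]), ]
    alive <- setNames(rep(TRUE, length(lens)), names(lens))
    repeat {
      acted <- FALSE
      a <- pmin(h$query_id, h$subject_id); b <- pmax(h$query_id, h$subject_id)
      ok <- h$percent_identity > id_min &
        h$alignment_length > cov_min * pmin(lens[a], lens[b]) &
        alive[a] & alive[b]
      if (!any(ok)) break
      cand <- which(ok)
      cand <- cand[order(-h$percent_identity[cand],
                         -h$alignment_length[cand], a[cand], b[cand])]
      k <- cand[1]
      x <- a[k]; y <- b[k]
      drop <- if (lens[[x]] < lens[[y]] ||
                  (lens[[x]] == lens[[y]] && x > y)) x else y
      alive[[drop]] <- FALSE
    }
    sort(names(alive)[alive])
  }

  set.seed(17)
  for (trial in 1:20) {
    n <- 10
    ids <- sprintf("t%02d", 1:n)
    lens <- setNames(sample(200:900, n, replace = TRUE), ids)
    npair <- sample(6:14, 1)
    qs <- t(replicate(npair, sample(ids, 2)))
    hits <- data.frame(query_id = qs[, 1], subject_id = qs[, 2],
                       percent_identity = round(runif(npair, 88, 100), 2),
                       alignment_length = sample(100:900, npair, replace = TRUE),
                       stringsAsFactors = FALSE)
    res <- collapse_transcripts(lens, hits)
    expect_equal(sort(names(res$kept)), fixpoint_oracle(lens, hits))
  }
})

test_that("collapse is idempotent and monotone in its thresholds", {
  set.seed(23)
  sim <- generate_redundant_transcripts(10, duplicates = c(1, 3),
                                        mutation_rate = 0.02,
                                        length_range = c(200, 500), seed = 23)
  hits <- all_vs_all_identity(sim$transcripts)
  res <- collapse_transcripts(sim$transcripts, hits)
  # idempotence: re-collapsing the kept set removes nothing
  kept_ids <- names(res$kept)
  hits_kept <- hits[hits$query_id %in% kept_ids &
                      hits$subject_id %in% kept_ids, ]
  res2 <- collapse_transcripts(res$kept, hits_kept)
  expect_length(res2$removed_ids, 0)
  # monotonicity: stricter thresholds keep supersets
  for (idm in c(94, 96, 98, 99.5)) {
    r <- collapse_transcripts(sim$transcripts, hits, identity_min = idm)
    expect_true(all(names(res$kept) %in% names(r$kept)))
  }
  r_cov <- collapse_transcripts(sim$transcripts, hits, coverage_min = 0.9)
  expect_gte(length(r_cov$kept), length(res$kept))
})

test_that("collapse recovers planted cluster representatives", {
  ok <- 0L; tot <- 0L
  for (s in 1:3) {
    sim <- generate_redundant_transcripts(12, duplicates = c(1, 2),
                                          mutation_rate = 0.01,
                                          length_range = c(250, 700), seed = s)
    res <- collapse_transcripts(sim$transcripts)
    reps <- sim$truth$transcript_id[sim$truth$is_representative]
    for (cl in unique(sim$truth$cluster)) {
      ids <- sim$truth$transcript_id[sim$truth$cluster == cl]
      tot <- tot + 1L
      if (identical(intersect(names(res$kept), ids), intersect(reps, ids)))
        ok <- ok + 1L
    }
  }
  expect_gte(ok / tot, 0.95)
})
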