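# Independent oracles used across the suite. These deliberately take the
# slow, obvious route so they stay independent of the package internals.

# Exhaustive Smith-Waterman DP with linear gap penalty; returns percent
# identity (matches / alignment columns * 100) and alignment length of
# the best-scoring local alignment, with traceback.
sw_oracle <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  # 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  P <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (a[i] == b[j]) match else mismatch
      up <- H[i, j + 1] + gap
      left <- H[i + 1, j] + gap
      sc <- max(0, sub, up, left)
      H[i + 1, j + 1] <- sc
      P[i + 1, j + 1] <- if (sc == 0) 0L else if (sc == sub) 1L else
        if (sc == up) 2L else 3L
      if (sc > best) { best <- sc; bi <- i + 1L; bj <- j + 1L }
    }
  }
  if (best == 0) return(list(identity = 0, alignment_length = 0, score = 0))
  matches <- 0L; cols <- 0L
  i <- bi; j <- bj
  while (i > 1 && j > 1 && P[i, j] != 0L) {
    cols <- cols + 1L
    if (P[i, j] == 1L) {
      if (a[i - 1] == b[j - 1]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (P[i, j] == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(identity = 100 * matches / cols, alignment_length = cols, score = best)
}

# Per-gene brute-force evaluation of a filter spec as a plain conjunction
# of scalar criteria, written directly from the filter definitions.
brute_filter_oracle <- function(profile, spec) {
  fold <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else NaN
  }
  ge <- function(f, k) !is.nan(f) && f >= k
  others <- setdiff(c("mel", "rpe", "irid"), spec$targets)
  vapply(seq_len(nrow(profile)), function(g) {
    row <- profile[g, ]
    emb <- row$embryo
    if (spec$mode == "shared_all") {
      v <- c(row$mel, row$rpe, row$irid)
      w <- fold(max(v), min(v))
      if (!(!is.nan(w) && w <= spec$within_fold)) return(FALSE)
      if (min(v) < spec$min_rpkm) return(FALSE)
      enum <- switch(spec$embryo_rule, min = min(v), max = max(v), any = max(v))
      return(ge(fold(enum, emb), spec$fold_vs_embryo))
    }
    for (tg in spec$targets) {
      for (ot in others) {
        if (!ge(fold(row[[tg]], row[[ot]]), spec$fold_vs_others)) return(FALSE)
        if (spec$mode != "stringent" && !is.na(spec$p_max)) {
          pcols <- c(mel_rpe = "p_mel_rpe", mel_irid = "p_mel_irid",
                     rpe_irid = "p_rpe_irid")
          key <- paste(sort(factor(c(tg, ot),
                                   levels = c("mel", "rpe", "irid"))),
                       collapse = "_")
          pv <- row[[pcols[[key]]]]
          if (is.na(pv) || pv >= spec$p_max) return(FALSE)
        }
      }
    }
    tv <- unlist(row[spec$targets])
    if (spec$min_rpkm > 0 && min(tv) < spec$min_rpkm) return(FALSE)
    enum <- switch(spec$embryo_rule, min = min(tv), max = max(tv),
                   any = max(tv))
    ge(fold(enum, emb), spec$fold_vs_embryo)
  }, logical(1))
}

# Direct-loop windowed Pearson correlation (the statistic's definition).
brute_window_avg <- function(profile, pair, w) {
  ord <- order(profile$embryo, profile$gene, method = "radix")
  x <- profile[[pair[1]]][ord]
  y <- profile[[pair[2]]][ord]
  n <- length(x)
  r <- vapply(seq_len(n - w), function(i) {
    xx <- x[i:(i + w - 1)]; yy <- y[i:(i + w - 1)]
    if (stats::sd(xx) == 0 || stats::sd(yy) == 0) NA_real_ else cor(xx, yy)
  }, numeric(1))
  r
}

# A random expression profile with p-values, for property tests.
random_profile <- function(n, seed, p_cols = TRUE) {
  set.seed(seed)
  df <- data.frame(
    gene = sprintf("g%05d", seq_len(n)),
    mel = round(rlnorm(n, 1, 2), 2),
    rpe = round(rlnorm(n, 1, 2), 2),
    irid = round(rlnorm(n, 1, 2), 2),
    embryo = round(rlnorm(n, -1, 2) * rbinom(n, 1, 0.8), 2),
    stringsAsFactors = FALSE)
  if (p_cols) {
    df$p_mel_rpe <- runif(n)
    df$p_mel_irid <- runif(n)
    df$p_rpe_irid <- runif(n)
  }
  expression_profile(df)
}

small_design <- function(n_genes = 300, reps = c(mel = 3, irid = 3,
                                                 rpe = 3, embryo = 2),
                         total_reads = 1e6) {
  study_design(replicates = reps, n_genes = n_genes, total_reads = total_reads)
}
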