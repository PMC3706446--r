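#' Default planted-class proportions for the count simulator
#'
#' Gene classes encode the enrichment structure the classifier is meant
#' to recover: `background` genes are expressed equally everywhere
#' (including whole embryo), `housekeeping` likewise (kept as a separate
#' label for bookkeeping), `shared_all` genes are high in all three
#' pigment cell types and strongly diluted in whole embryo,
#' `pairwise_*` genes are enriched in two cell types over the third,
#' `specific_*` genes in a single cell type, and `unexpressed` genes are
#' silent. Proportions follow the observed structure of pigment-cell
#' transcriptomes: roughly a third of the gene universe appreciably
#' expressed, about 3% planted as enriched classes (the enrichment sets
#' actually recovered from purified pigment cells total a few hundred
#' genes out of ~25,000), the rest silent.
#'
#' @return named numeric vector summing to 1.
#' @export
default_class_proportions <- function() {
  c(background = 0.50, housekeeping = 0.05,
    shared_all = 0.002,
    pairwise_mel_rpe = 0.004, pairwise_mel_irid = 0.004,
    pairwise_rpe_irid = 0.004,
    specific_mel = 0.005, specific_irid = 0.005, specific_rpe = 0.005,
    unexpressed = 0.421)
}

.CLASS_LABELS <- names(default_class_proportions())

#' Generate per-gene ground truth for the count simulator
#'
#' Draws a gene universe with planted enrichment classes, heavy-tailed
#' (log-normal) baseline expression, per-cell-type fold multipliers and
#' a derived whole-embryo mean. Baselines of background/housekeeping
#' genes are calibrated so that the expected fraction of genes at or
#' above 1 RPKM per cell type equals `frac_expressed` (default 0.35,
#' matching the 30--40% of genes appreciably expressed in purified
#' pigment cells). The whole-embryo mean of each gene is a mixture: a
#' small weight (`mix_weight`) of the average cell-type signal -- pigment
#' cells are well under 1% of embryonic cells -- plus a bulk component
#' equal to the baseline for background/housekeeping genes, so planted
#' pigment genes come out 100--1000-fold diluted in whole embryo.
#'
#' Planted multipliers exceed the classifier's defining thresholds by
#' `fold_margin`: pairwise and specific classes are boosted
#' `2 * fold_margin`-fold in their target cell types, and shared_all
#' multipliers are jittered within `2^(1/fold_margin)`-fold of each
#' other with baselines kept at or above `enriched_floor` RPKM.
#'
#' @param design a [study_design()]; must include cell types `mel`,
#'   `irid`, `rpe` and `embryo`.
#' @param class_proportions named simplex over class labels (see
#'   [default_class_proportions()]); must sum to 1 within 1e-9.
#' @param fold_margin multiplicative safety margin (>= 1) by which
#'   planted effects exceed the defining thresholds.
#' @param frac_expressed target fraction of genes with expected RPKM
#'   >= 1 per cell type.
#' @param dispersion negative-binomial dispersion for all genes
#'   (variance = mu + dispersion * mu^2); 0 selects Poisson noise.
#' @param baseline_sdlog log-normal sd (natural log) of baseline RPKM.
#' @param enriched_floor minimum baseline RPKM for planted enriched
#'   classes, keeping them above detection/minimum-RPKM criteria.
#' @param mix_weight weight of the pigment-cell signal in the
#'   whole-embryo mixture.
#' @param rpkm_cap ceiling on expected per-gene RPKM in any cell type.
#'   RPKM is compositional (a single gene cannot carry a large fraction
#'   of a library's tags), and the most extreme values observed in
#'   purified pigment cells are ribosomal-protein genes around 23,500
#'   RPKM; genes whose drawn mean would exceed the cap are scaled down
#'   with their fold ratios preserved.
#' @param seed integer seed; all downstream draws derive from it.
#' @return a data frame of class `synthetic_truth` with one row per gene:
#'   `gene_id`, `class`, `baseline`, `mult_mel`, `mult_rpe`, `mult_irid`,
#'   `embryo_mean`, `dispersion`.
#' @examples
#' truth <- generate_truth(study_design(n_genes = 500, replicates =
#'   c(mel = 2, irid = 2, rpe = 2, embryo = 1), total_reads = 1e6), seed = 1)
#' table(truth$class)
#' @export
generate_truth <- function(design,
                           class_proportions = default_class_proportions(),
                           fold_margin = 2,
                           frac_expressed = 0.35,
                           dispersion = 0.2,
                           baseline_sdlog = 2,
                           enriched_floor = 8,
                           mix_weight = 1 / 300,
                           rpkm_cap = 25000,
                           seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  n <- design$n_genes
  if (n < 100) stop("`n_genes` must be at least 100 for truth generation")
  if (fold_margin < 1) stop("`fold_margin` must be >= 1")
  if (dispersion < 0) stop("`dispersion` must be non-negative")

  p <- class_proportions
  unknown <- setdiff(names(p), .CLASS_LABELS)
  if (length(unknown))
    stop("unknown class label in proportions: ", paste(unknown, collapse = ", "))
  bad <- names(p)[is.na(p) | p < 0]
  if (length(bad))
    stop("invalid proportion for class: ", paste(bad, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", format(sum(p)), ")")

  if (!is.null(seed)) set.seed(seed)
  classes <- if (length(p) == 1L) rep(names(p), n) else
    sample(names(p), n, replace = TRUE, prob = p)

  enriched_labels <- grep("^(shared_all|pairwise_|specific_)", .CLASS_LABELS,
                          value = TRUE)
  is_bg <- classes %in% c("background", "housekeeping")
  is_enriched <- classes %in% enriched_labels
  is_silent <- classes == "unexpressed"

  # calibrate background baselines so the overall expressed fraction hits target
  p_enr <- sum(p[intersect(names(p), enriched_labels)])
  p_bgc <- sum(p[intersect(names(p), c("background", "housekeeping"))])
  baseline <- numeric(n)
  if (any(is_bg)) {
    p_need <- (frac_expressed - p_enr) / p_bgc
    if (p_need <= 0 || p_need >= 1)
      stop("`frac_expressed` (", frac_expressed,
           ") is not attainable with these class proportions")
    meanlog <- baseline_sdlog * qnorm(p_need)
    baseline[is_bg] <- rlnorm(sum(is_bg), meanlog, baseline_sdlog)
  }
  if (any(is_enriched))
    baseline[is_enriched] <- enriched_floor +
      rlnorm(sum(is_enriched), meanlog = log(30), sdlog = 1.5)
  baseline[is_silent] <- 0

  mult <- matrix(1, n, 3, dimnames = list(NULL, .CELLS))
  sh <- classes == "shared_all"
  if (any(sh)) {
    half <- log(2) / (2 * fold_margin)
    for (cc in .CELLS)
      mult[sh, cc] <- exp(runif(sum(sh), -half, half))
  }
  boost <- 2 * fold_margin
  for (pr in .PAIRS) {
    lab <- paste0("pairwise_", pr[1], "_", pr[2])
    idx <- classes == lab
    if (any(idx)) mult[idx, pr] <- boost
  }
  for (cc in .CELLS) {
    idx <- classes == paste0("specific_", cc)
    if (any(idx)) mult[idx, cc] <- boost
  }

  # compositional ceiling: scale whole genes down so no expected cell
  # mean exceeds rpkm_cap; fold ratios are untouched
  max_mean <- baseline * apply(mult, 1, max)
  over <- max_mean > rpkm_cap
  if (any(over))
    baseline[over] <- baseline[over] * rpkm_cap / max_mean[over]

  cell_means <- baseline * mult
  bulk <- ifelse(is_bg, baseline, 0)
  embryo_mean <- mix_weight * rowMeans(cell_means) + bulk

  truth <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    class = classes,
    baseline = baseline,
    mult_mel = mult[, "mel"],
    mult_rpe = mult[, "rpe"],
    mult_irid = mult[, "irid"],
    embryo_mean = embryo_mean,
    dispersion = dispersion,
    stringsAsFactors = FALSE)
  attr(truth, "params") <- list(
    fold_margin = fold_margin, frac_expressed = frac_expressed,
    baseline_sdlog = baseline_sdlog, enriched_floor = enriched_floor,
    mix_weight = mix_weight, rpkm_cap = rpkm_cap)
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}

#' Expected RPKM per gene per condition implied by a synthetic truth
#'
#' @param truth a [generate_truth()] result.
#' @return numeric matrix, genes by `mel`, `rpe`, `irid`, `embryo`.
#' @export
expected_rpkm <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- cbind(mel = truth$baseline * truth$mult_mel,
             rpe = truth$baseline * truth$mult_rpe,
             irid = truth$baseline * truth$mult_irid,
             embryo = truth$embryo_mean)
  rownames(m) <- truth$gene_id
  m
}

#' Simulate a tag-count matrix from planted truth
#'
#' Draws integer tag counts per gene and library from a
#' negative-binomial with mean
#' `expected RPKM * length_kb * total_reads / 1e6` and the per-gene
#' dispersion stored in the truth (`dispersion = 0` falls back to
#' Poisson). Gene lengths are drawn log-normally with a median of 2 kb
#' (or supplied explicitly) and carried in the result so RPKM recovery
#' is exact. Library ids are `<cell_type>_<replicate>`.
#'
#' @param truth a [generate_truth()] result.
#' @param design the [study_design()] used to generate `truth`.
#' @param seed integer seed.
#' @param lengths optional numeric vector of gene lengths (bp).
#' @param length_meanlog,length_sdlog log-normal parameters for simulated
#'   gene lengths (defaults give median 2 kb).
#' @param map_budget maximum fraction of a library's declared reads that
#'   may align to genes in expectation. If a drawn gene universe would
#'   exceed it, all expected counts are rescaled by one global factor
#'   (fold changes preserved) with a warning -- mirroring the fact that
#'   aligned tags can never outnumber sequenced reads.
#' @return a [count_matrix()].
#' @examples
#' des <- study_design(n_genes = 200,
#'   replicates = c(mel = 2, irid = 2, rpe = 2, embryo = 1),
#'   total_reads = 1e6)
#' truth <- generate_truth(des, seed = 1)
#' cm <- simulate_counts(truth, des, seed = 1)
#' dim(cm)
#' @export
simulate_counts <- function(truth, design, seed = NULL, lengths = NULL,
                            length_meanlog = log(2000), length_sdlog = 0.45,
                            map_budget = 0.9) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "study_design"))
  n <- nrow(truth)
  if (n != design$n_genes)
    stop("truth (", n, " genes) and design (", design$n_genes, ") disagree")
  if (any(truth$dispersion < 0)) stop("`dispersion` must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(lengths)) {
    lengths <- pmax(100, round(rlnorm(n, length_meanlog, length_sdlog)))
  } else if (length(lengths) != n) {
    stop("`lengths` must have one entry per gene")
  }

  reps <- design$replicates
  libs <- do.call(rbind, lapply(names(reps), function(ct) {
    data.frame(library_id = sprintf("%s_%02d", ct, seq_len(reps[[ct]])),
               cell_type = ct, timepoint_hpf = 72,
               total_reads = design$total_reads,
               stringsAsFactors = FALSE)
  }))

  exp_rpkm <- expected_rpkm(truth)
  missing_ct <- setdiff(unique(libs$cell_type), colnames(exp_rpkm))
  if (length(missing_ct))
    stop("no planted expression for cell type: ", paste(missing_ct, collapse = ", "))

  len_kb <- lengths / 1000
  depth_m <- libs$total_reads / 1e6
  mu <- exp_rpkm[, libs$cell_type, drop = FALSE] *
    outer(len_kb, depth_m)
  over <- colSums(mu) / libs$total_reads
  if (max(over) > map_budget) {
    warning("expected aligned tags exceed ", map_budget,
            " of the declared depth; rescaling all means by ",
            signif(map_budget / max(over), 3))
    mu <- mu * (map_budget / max(over))
  }
  nm <- length(mu)
  disp <- rep(truth$dispersion, times = ncol(mu))
  counts <- numeric(nm)
  nb <- disp > 0
  if (any(nb))
    counts[nb] <- rnbinom(sum(nb), size = 1 / disp[nb], mu = as.vector(mu)[nb])
  if (any(!nb))
    counts[!nb] <- rpois(sum(!nb), as.vector(mu)[!nb])
  counts <- matrix(counts, nrow = n,
                   dimnames = list(truth$gene_id, libs$library_id))
  count_matrix(counts, setNames(lengths, truth$gene_id), libs)
}

#' Generate a redundant transcript set with known cluster structure
#'
#' Emits random nucleotide transcripts organised in clusters: one
#' full-length representative per cluster plus near-identical duplicates
#' that are 5'-truncated copies with point substitutions at
#' `mutation_rate`. Within-cluster pairs therefore exceed 94% identity
#' over the full length of the shorter member whenever
#' `mutation_rate < 0.06`; between-cluster identity is that of random
#' sequence. Serves as ground truth for the non-redundant collapse.
#'
#' @param n_clusters number of gene clusters (>= 1).
#' @param duplicates integer range `c(min, max)` of duplicates per cluster.
#' @param mutation_rate per-base substitution probability in `[0, 1)`.
#' @param length_range representative length range in bp.
#' @param truncation fractional length range of duplicates relative to
#'   their representative (strictly below 1 so the representative is the
#'   unique longest member).
#' @param seed integer seed; fixed seeds give byte-identical FASTA.
#' @return list with `transcripts` (a [Biostrings::DNAStringSet]) and
#'   `truth` (data frame: `transcript_id`, `cluster`, `is_representative`,
#'   `length`, `mutation_rate`).
#' @examples
#' sim <- generate_redundant_transcripts(3, duplicates = c(1, 2),
#'   length_range = c(200, 400), seed = 1)
#' sim$truth
#' @export
generate_redundant_transcripts <- function(n_clusters,
                                           duplicates = c(1, 3),
                                           mutation_rate = 0.01,
                                           length_range = c(500, 3000),
                                           truncation = c(0.6, 0.95),
                                           seed = NULL) {
  if (length(n_clusters) != 1L || is.na(n_clusters) || n_clusters < 1)
    stop("`n_clusters` must be a positive integer")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("`mutation_rate` must be in [0, 1)")
  if (truncation[2] >= 1 || truncation[1] <= 0)
    stop("`truncation` fractions must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")

  seqs <- character(0); ids <- character(0)
  cluster <- integer(0); is_rep <- logical(0)
  for (i in seq_len(n_clusters)) {
    L <- sample(length_range[1]:length_range[2], 1)
    rep_seq <- sample(bases, L, replace = TRUE)
    id <- sprintf("cl%03d_rep", i)
    seqs <- c(seqs, paste(rep_seq, collapse = ""))
    ids <- c(ids, id); cluster <- c(cluster, i); is_rep <- c(is_rep, TRUE)
    ndup <- if (duplicates[1] == duplicates[2]) duplicates[1] else
      sample(duplicates[1]:duplicates[2], 1)
    for (j in seq_len(ndup)) {
      Ld <- max(1L, floor(L * runif(1, truncation[1], truncation[2])))
      dup <- rep_seq[seq_len(Ld)]
      nmut <- rbinom(1, Ld, mutation_rate)
      if (nmut > 0) {
        pos <- sample.int(Ld, nmut)
        for (k in pos) dup[k] <- sample(setdiff(bases, dup[k]), 1)
      }
      seqs <- c(seqs, paste(dup, collapse = ""))
      ids <- c(ids, sprintf("cl%03d_dup%d", i, j))
      cluster <- c(cluster, i); is_rep <- c(is_rep, FALSE)
    }
  }
  transcripts <- Biostrings::DNAStringSet(setNames(seqs, ids))
  truth <- data.frame(transcript_id = ids, cluster = cluster,
                      is_representative = is_rep,
                      length = nchar(seqs),
                      mutation_rate = mutation_rate,
                      stringsAsFactors = FALSE)
  list(transcripts = transcripts, truth = truth)
}
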