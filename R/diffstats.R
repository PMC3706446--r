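#' Per-gene expression profile across pigment cell types
#'
#' The central substrate for enrichment classification: one row per
#' gene, with mean RPKM for melanocyte (`mel`), RPE (`rpe`), iridophore
#' (`irid`) and whole embryo (`embryo`), plus two-sided Student's t-test
#' p-values for the three cell-type pairs (`p_mel_rpe`, `p_mel_irid`,
#' `p_rpe_irid`). Embryo comparisons carry no p-values: pooled embryo
#' libraries have no biological replicate structure, so embryo criteria
#' are fold-change only.
#'
#' @param df data frame with at least columns `gene`, `mel`, `rpe`,
#'   `irid`; `embryo` and the pair p-value columns are optional (missing
#'   ones are filled with `NA`). Additional columns are preserved.
#' @return a data frame of class `expression_profile`.
#' @export
expression_profile <- function(df) {
  req <- c("gene", .CELLS)
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("profile is missing mandatory column: ", paste(miss, collapse = ", "))
  pcols <- c("p_mel_rpe", "p_mel_irid", "p_rpe_irid")
  for (cc in c("embryo", pcols)) if (!cc %in% names(df)) df[[cc]] <- NA_real_
  for (cc in c(.CELLS, "embryo", pcols)) {
    if (!is.numeric(df[[cc]]))
      stop("column '", cc, "' must be numeric")
  }
  neg <- vapply(.CELLS, function(cc) any(df[[cc]] < 0, na.rm = TRUE), logical(1))
  if (any(neg))
    stop("negative mean RPKM in column: ",
         paste(.CELLS[neg], collapse = ", "))
  for (cc in pcols) {
    bad <- !is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 1)
    if (any(bad)) stop("p-values in '", cc, "' outside [0, 1]")
  }
  if (anyDuplicated(df$gene)) stop("gene ids must be unique")
  front <- c("gene", "mel", "rpe", "irid", "embryo", pcols)
  df <- df[c(front, setdiff(names(df), front))]
  rownames(df) <- NULL
  class(df) <- c("expression_profile", "data.frame")
  df
}

#' Two-sample Student's t-test on replicate RPKM values
#'
#' Equal-variance (pooled) two-sample t statistic with
#' `df = nA + nB - 2` and a two-sided p-value, computed on linear RPKM
#' across replicate libraries. Degenerate inputs follow an explicit
#' contract: if both groups have zero variance and equal means, `t = 0`
#' and `p = 1`; zero pooled variance with unequal means yields an
#' infinite t and `p = 0` with a warning.
#'
#' @param a,b numeric vectors of replicate RPKM values (each length >= 2).
#' @return list with elements `t`, `df`, `p`.
#' @examples
#' gene_ttest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p ~ 0.0214
#' @export
gene_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("both groups need at least 2 replicates (got ", na, " and ", nb, ")")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    warning("zero variance with unequal means; reporting p = 0")
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# vectorized pooled t-test over matrix rows; returns p-values
.row_ttest_p <- function(ma, mb) {
  na <- ncol(ma); nb <- ncol(mb)
  df <- na + nb - 2
  va <- apply(ma, 1, stats::var)
  vb <- apply(mb, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  delta <- rowMeans(ma) - rowMeans(mb)
  p <- numeric(nrow(ma))
  zero <- sp2 == 0
  p[zero & delta == 0] <- 1
  if (any(zero & delta != 0)) {
    warning("zero variance with unequal means for ",
            sum(zero & delta != 0), " gene(s); reporting p = 0")
    p[zero & delta != 0] <- 0
  }
  ok <- !zero
  t <- delta[ok] / sqrt(sp2[ok] * (1 / na + 1 / nb))
  p[ok] <- 2 * pt(-abs(t), df)
  p
}

#' Fold change with explicit zero semantics
#'
#' `num / den` with the conventions used throughout the enrichment
#' filters: a positive numerator over a zero denominator is `Inf` (and
#' passes any "at least k-fold" criterion), while `0 / 0` is undefined
#' (`NaN`, failing every criterion). Vectorised.
#'
#' @param num,den non-negative mean RPKM values.
#' @return numeric vector of ratios (`Inf` / `NaN` sentinels included).
#' @examples
#' fold_change(816.19, 11.45)  # 71.28
#' fold_change(5, 0)           # Inf
#' fold_change(0, 0)           # NaN
#' @export
fold_change <- function(num, den) {
  if (any(num < 0, na.rm = TRUE) || any(den < 0, na.rm = TRUE))
    stop("fold change inputs must be non-negative")
  num / den
}

# fold >= k with sentinel semantics: Inf passes, NaN/NA fails
.fold_ge <- function(fold, k) {
  ok <- fold >= k
  ok[is.na(ok)] <- FALSE
  ok
}

#' Assemble an expression profile from an RPKM matrix
#'
#' Computes per-gene mean RPKM per cell type ([average_by_celltype()])
#' and pairwise equal-variance t-test p-values for the three cell-type
#' pairs. No multiple-testing correction is applied: downstream filters
#' threshold raw p-values (p < 0.05), as is conventional for this
#' enrichment scheme.
#'
#' @param rpkm an `rpkm_matrix` from [compute_rpkm()].
#' @param annotations optional library annotations (default: carried by
#'   `rpkm`).
#' @return an [expression_profile()].
#' @export
all_pair_stats <- function(rpkm, annotations = NULL) {
  stopifnot(inherits(rpkm, "rpkm_matrix"))
  if (is.null(annotations)) annotations <- rpkm$libraries
  ann <- annotations[match(colnames(rpkm$rpkm), annotations$library_id), ,
                     drop = FALSE]
  have_embryo <- "embryo" %in% ann$cell_type
  types <- c(.CELLS, if (have_embryo) "embryo")
  miss <- setdiff(.CELLS, ann$cell_type)
  if (length(miss))
    stop("no libraries for cell type: ", paste(miss, collapse = ", "))
  nrep <- table(ann$cell_type)
  small <- .CELLS[nrep[.CELLS] < 2]
  if (length(small))
    stop("cell type needs >= 2 replicate libraries for t-tests: ",
         paste(small, collapse = ", "))
  means <- average_by_celltype(rpkm, ann, cell_types = types)
  prof <- data.frame(gene = rownames(rpkm$rpkm),
                     mel = means[, "mel"], rpe = means[, "rpe"],
                     irid = means[, "irid"],
                     embryo = if (have_embryo) means[, "embryo"] else NA_real_,
                     stringsAsFactors = FALSE)
  for (pr in .PAIRS) {
    ma <- rpkm$rpkm[, ann$cell_type == pr[1], drop = FALSE]
    mb <- rpkm$rpkm[, ann$cell_type == pr[2], drop = FALSE]
    prof[[.pair_col(pr[1], pr[2])]] <- .row_ttest_p(ma, mb)
  }
  prof <- expression_profile(prof)
  attr(prof, "replicates") <- setNames(as.integer(nrep[types]), types)
  prof
}

#' Windowed Pearson correlation between cell-type profiles
#'
#' Correlation between two cell types' expression can be dominated by a
#' handful of extremely high outliers; this statistic instead sorts
#' genes by increasing whole-embryo expression (stable sort, ties broken
#' by gene id) and computes the Pearson correlation within every
#' overlapping window of `w` consecutive genes, reporting per-window
#' values and their unweighted average. Window starts run from 1 to
#' `n_genes - w`, giving `n_genes - w` windows (25,102 genes and
#' `w = 1000` give 24,102 windows). Windows where either vector has zero
#' variance yield `NA` and are flagged and excluded from the average.
#'
#' @param profile an [expression_profile()] with an `embryo` column.
#' @param pairs list of 2-element cell-type vectors; defaults to the
#'   three pigment cell-type pairs.
#' @param w window size in genes (>= 3).
#' @return list of class `window_profile`: `w`, `windows` (data frame
#'   `pair`, `start`, `r`, `degenerate`), and `average` (named vector of
#'   per-pair averages over non-degenerate windows).
#' @export
windowed_correlation <- function(profile, pairs = .PAIRS, w = 1000) {
  stopifnot(inherits(profile, "expression_profile"))
  if (w < 3) stop("`w` must be at least 3")
  n <- nrow(profile)
  if (n <= w) stop("need more genes (", n, ") than the window size (", w, ")")
  if (all(is.na(profile$embryo)))
    stop("profile has no embryo expression to order by")
  ord <- order(profile$embryo, profile$gene, method = "radix")
  prof <- profile[ord, , drop = FALSE]
  starts <- seq_len(n - w)
  win <- list(); avg <- numeric(0)
  for (pr in pairs) {
    r <- .rolling_pearson(prof[[pr[1]]], prof[[pr[2]]], w)
    key <- paste(pr[1], pr[2], sep = "_")
    win[[key]] <- data.frame(pair = key, start = starts, r = r,
                             degenerate = is.na(r), stringsAsFactors = FALSE)
    avg[key] <- mean(r, na.rm = TRUE)
  }
  structure(list(w = w, windows = do.call(rbind, win), average = avg),
            class = "window_profile")
}

# rolling Pearson over windows [i, i+w-1], i = 1..n-w, via cumulative
# sums; inputs are centred first for numerical stability
.rolling_pearson <- function(x, y, w) {
  n <- length(x)
  x <- x - mean(x); y <- y - mean(y)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(x * y))
  i <- seq_len(n - w)
  sx <- cx[i + w] - cx[i]; sy <- cy[i + w] - cy[i]
  sxx <- cxx[i + w] - cxx[i]; syy <- cyy[i + w] - cyy[i]
  sxy <- cxy[i + w] - cxy[i]
  vx <- sxx - sx * sx / w
  vy <- syy - sy * sy / w
  cov <- sxy - sx * sy / w
  r <- rep(NA_real_, n - w)
  ok <- vx > 0 & vy > 0
  r[ok] <- cov[ok] / sqrt(vx[ok] * vy[ok])
  pmin(1, pmax(-1, r))
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("window_profile: w = %d, %d windows per pair\n", x$w,
              sum(x$windows$pair == x$windows$pair[1])))
  for (k in names(x$average))
    cat(sprintf("  average r %-12s %.4f\n", k, x$average[[k]]))
  invisible(x)
}
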