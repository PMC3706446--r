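#' Convert tag counts to RPKM
#'
#' Reads per kilobase of cDNA per million mapped reads:
#' `rpkm = count / (length_bp / 1000) / (total_reads / 1e6)`, exactly.
#' A zero count maps to zero RPKM.
#'
#' @param counts a [count_matrix()].
#' @return object of class `rpkm_matrix`: list with `rpkm` (numeric
#'   matrix, same axes as the counts), `lengths`, and `libraries`.
#' @examples
#' cm <- count_matrix(matrix(1000, 1, 1, dimnames = list("g1", "L1")),
#'                    lengths = c(g1 = 2000),
#'                    libraries = data.frame(library_id = "L1",
#'                      cell_type = "mel", total_reads = 1e7))
#' compute_rpkm(cm)$rpkm  # 50
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- counts$libraries$total_reads
  if (any(totals <= 0)) stop("library totals must be positive")
  bad <- is.na(counts$lengths) | counts$lengths <= 0
  if (any(bad))
    stop("zero or missing gene length for: ",
         paste(head(names(counts$lengths)[bad], 5), collapse = ", "))
  len_kb <- counts$lengths / 1000
  rpkm <- sweep(counts$counts / len_kb, 2, totals / 1e6, "/")
  structure(list(rpkm = rpkm, lengths = counts$lengths,
                 libraries = counts$libraries),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat(sprintf("rpkm_matrix: %d genes x %d libraries\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

#' Average RPKM per cell type
#'
#' Unweighted arithmetic mean of per-library RPKM over each cell type's
#' libraries (averaging normalized values, not pooled counts).
#'
#' @param rpkm an `rpkm_matrix` from [compute_rpkm()], or a bare numeric
#'   matrix with library columns.
#' @param annotations optional library annotation data frame
#'   (`library_id`, `cell_type`); defaults to the annotations carried by
#'   `rpkm`.
#' @param cell_types cell types to average; defaults to all annotated
#'   types. A requested type with no libraries is an error.
#' @return numeric matrix, genes by cell type, of mean RPKM.
#' @export
average_by_celltype <- function(rpkm, annotations = NULL, cell_types = NULL) {
  if (inherits(rpkm, "rpkm_matrix")) {
    if (is.null(annotations)) annotations <- rpkm$libraries
    mat <- rpkm$rpkm
  } else {
    mat <- as.matrix(rpkm)
  }
  if (is.null(annotations))
    stop("library annotations are required")
  ann <- annotations[match(colnames(mat), annotations$library_id), , drop = FALSE]
  if (anyNA(ann$cell_type))
    stop("every library must be annotated with exactly one cell type")
  if (is.null(cell_types)) cell_types <- unique(ann$cell_type)
  cols <- lapply(cell_types, function(ct) {
    sel <- ann$cell_type == ct
    if (!any(sel)) stop("no libraries annotated as cell type '", ct, "'")
    rowMeans(mat[, sel, drop = FALSE])
  })
  out <- matrix(unlist(cols), nrow = nrow(mat),
                dimnames = list(rownames(mat), cell_types))
  out
}

#' Detected gene sets per cell type
#'
#' A gene counts as detected in a cell type when its mean RPKM is at or
#' above the baseline threshold `theta` (inclusive boundary; set
#' `inclusive = FALSE` for a strict threshold).
#'
#' @param means numeric matrix of mean RPKM, genes by cell type (e.g.
#'   from [average_by_celltype()]), or an [expression_profile()].
#' @param theta detection threshold in RPKM (> 0), default 1.
#' @param inclusive whether the boundary value itself is detected.
#' @return list with `genes` (per cell type, character vectors of
#'   detected gene ids) and `n_detected` (named integer vector).
#' @export
detect_expressed <- function(means, theta = 1, inclusive = TRUE) {
  if (theta <= 0) stop("`theta` must be positive")
  if (inherits(means, "expression_profile")) {
    cols <- intersect(c(.CELLS, "embryo"), names(means))
    m <- as.matrix(means[cols])
    rownames(m) <- means$gene
    means <- m
  }
  means <- as.matrix(means)
  cmp <- if (inclusive) `>=` else `>`
  genes <- lapply(colnames(means), function(ct) {
    rownames(means)[cmp(means[, ct], theta)]
  })
  names(genes) <- colnames(means)
  list(genes = genes, n_detected = vapply(genes, length, integer(1)))
}

# one nested permutation draw per library: the depth-d subsample is the
# tabulation of the first d tags of a random permutation of the
# library's tag multiset, so subsamples at increasing depth are nested.
.library_permutation <- function(counts_col) {
  gene_idx <- rep.int(seq_along(counts_col), counts_col)
  gene_idx[sample.int(length(gene_idx))]
}

#' Subsample tags from each library without replacement
#'
#' Draws exactly `depth` aligned tags per library from its gene-count
#' vector (a multivariate hypergeometric draw, realised as a random
#' permutation of the library's tags). For a fixed seed the draw at a
#' smaller depth is a subset of the draw at a larger depth, so repeated
#' calls with the same seed yield nested subsamples. The declared
#' library total of the result is set to `depth`, so recomputed RPKM
#' values refer to the subsampled depth.
#'
#' @param counts a [count_matrix()].
#' @param depth number of tags to keep per library (> 0 and at most each
#'   library's aligned-tag total).
#' @param seed integer seed.
#' @return a [count_matrix()] at the subsampled depth.
#' @export
subsample_counts <- function(counts, depth, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (depth <= 0) stop("`depth` must be positive")
  tag_totals <- colSums(counts$counts)
  if (any(depth > tag_totals))
    stop("`depth` exceeds aligned tags for library: ",
         paste(counts$libraries$library_id[depth > tag_totals], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  sub <- vapply(seq_len(ncol(counts$counts)), function(j) {
    perm <- .library_permutation(counts$counts[, j])
    tabulate(perm[seq_len(depth)], nbins = nrow(counts$counts))
  }, numeric(nrow(counts$counts)))
  dimnames(sub) <- dimnames(counts$counts)
  libs <- counts$libraries
  libs$total_reads <- depth
  count_matrix(sub, counts$lengths, libs)
}

#' Sequencing-depth saturation of gene detection
#'
#' For each library, seed and depth, subsamples the library's aligned
#' tags to that depth (nested across depths within a seed) and counts
#' the genes detected at `theta` RPKM, with RPKM recomputed at the
#' subsampled depth. This traces how gene detection saturates with
#' sequencing depth.
#'
#' @param counts a [count_matrix()].
#' @param depths increasing vector of subsampling depths (reads); depths
#'   exceeding a library's aligned tags are evaluated at full depth.
#' @param theta detection threshold in RPKM.
#' @param seeds integer vector of subsampling seeds.
#' @param inclusive detection boundary convention, as in
#'   [detect_expressed()].
#' @return data frame of class `saturation_curve`: `library_id`, `seed`,
#'   `depth`, `n_detected`.
#' @export
saturation_curve <- function(counts, depths, theta = 1, seeds = 1L,
                             inclusive = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.unsorted(depths, strictly = FALSE))
    stop("`depths` must be sorted ascending")
  if (theta <= 0) stop("`theta` must be positive")
  cmp <- if (inclusive) `>=` else `>`
  len_kb <- counts$lengths / 1000
  res <- list(); r <- 0L
  for (j in seq_len(ncol(counts$counts))) {
    col <- counts$counts[, j]
    total <- sum(col)
    for (s in seeds) {
      set.seed(s)
      perm <- .library_permutation(col)
      for (d in depths) {
        dd <- min(d, total)
        subc <- tabulate(perm[seq_len(dd)], nbins = length(col))
        # count >= theta * len_kb * depth/1e6  <=>  RPKM >= theta
        thr <- theta * len_kb * dd / 1e6
        r <- r + 1L
        res[[r]] <- data.frame(
          library_id = counts$libraries$library_id[j],
          seed = s, depth = d, n_detected = sum(cmp(subc, thr)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("saturation_curve", "data.frame")
  out
}
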