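#' Tag-count matrix with gene lengths and library metadata
#'
#' Container for integer sequence-tag counts per gene per library, the
#' raw input to RPKM quantification. Carries gene lengths (bp) and a
#' library annotation table with the declared total read count of each
#' library (uniquely aligned tags are a subset of these).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   libraries in columns (colnames = library ids).
#' @param lengths numeric vector of gene lengths in bp, named by gene id
#'   or in row order.
#' @param libraries data frame with columns `library_id`, `cell_type`,
#'   `timepoint_hpf`, `total_reads`, one row per column of `counts`.
#' @return an object of class `count_matrix`.
#' @seealso [compute_rpkm()], [simulate_counts()], [read_counts()]
#' @export
count_matrix <- function(counts, lengths, libraries) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("`counts` must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("`counts` must have library ids as colnames")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    stop("`lengths` must have one entry per gene")
  bad <- is.na(lengths) | lengths < 1
  if (any(bad))
    stop("zero or missing gene length for: ",
         paste(head(rownames(counts)[bad], 5), collapse = ", "))
  req <- c("library_id", "cell_type", "total_reads")
  if (!all(req %in% names(libraries)))
    stop("`libraries` must contain columns: ", paste(req, collapse = ", "))
  if (!"timepoint_hpf" %in% names(libraries)) libraries$timepoint_hpf <- NA_real_
  libraries <- libraries[match(colnames(counts), libraries$library_id), , drop = FALSE]
  if (anyNA(libraries$library_id))
    stop("every count column needs a matching `library_id` row in `libraries`")
  over <- colSums(counts) > libraries$total_reads
  if (any(over))
    stop("aligned tag counts exceed declared total reads for library: ",
         paste(libraries$library_id[over], collapse = ", "))
  structure(
    list(counts = counts, lengths = setNames(lengths, rownames(counts)),
         libraries = libraries),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$libraries$cell_type), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
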