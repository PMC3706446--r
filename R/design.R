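#' Study design for a pigment-cell sequencing experiment
#'
#' Describes the library layout of a purified pigment cell experiment:
#' which cell types were sequenced, how many independently isolated
#' replicate libraries each has, the size of the gene universe, and the
#' sequencing depth per library. The defaults mirror the original study
#' design: 11 melanocyte, 5 iridophore and 5 RPE libraries plus 3 pooled
#' whole-embryo libraries over a universe of 25,102 non-redundant genes.
#'
#' @param replicates named integer vector of replicate libraries per
#'   condition. Names are cell-type labels; `"embryo"` denotes pooled
#'   whole-embryo libraries.
#' @param n_genes number of gene records in the non-redundant database.
#' @param total_reads declared sequencing depth (reads) per library.
#'   A minority of reads align uniquely to the gene database, as in real
#'   tag libraries.
#' @return an object of class `study_design`.
#' @examples
#' study_design()
#' study_design(replicates = c(mel = 3, irid = 3, rpe = 3, embryo = 2),
#'              n_genes = 500, total_reads = 2e5)
#' @export
study_design <- function(replicates = c(mel = 11, irid = 5, rpe = 5, embryo = 3),
                         n_genes = 25102,
                         total_reads = 5e6) {
  if (is.null(names(replicates)) || any(!nzchar(names(replicates))))
    stop("`replicates` must be a named vector of per-cell-type library counts")
  replicates <- vapply(replicates, as.integer, integer(1))
  if (any(replicates < 1L))
    stop("every replicate count must be >= 1 (offending: ",
         paste(names(replicates)[replicates < 1L], collapse = ", "), ")")
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) stop("`n_genes` must be a positive integer")
  if (total_reads < 1e5) stop("`total_reads` must be at least 1e5")
  structure(
    list(replicates = replicates, n_genes = n_genes,
         total_reads = as.numeric(total_reads)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_genes, "genes;",
      paste(sprintf("%s=%d", names(x$replicates), x$replicates), collapse = ", "),
      sprintf("libraries; %g reads/library\n", x$total_reads))
  invisible(x)
}

.design_cells <- function(design) {
  setdiff(names(design$replicates), "embryo")
}
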