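#' Read an expression profile TSV
#'
#' Expects a header row with at least `gene`, `mel`, `rpe`, `irid`;
#' `embryo` and the pairwise p-value columns (`p_mel_rpe`, `p_mel_irid`,
#' `p_rpe_irid`) are optional. Numerics may use decimal or scientific
#' notation (`1.30E-03`, case-insensitive). Unknown columns are
#' preserved as opaque annotations. Gene ids are taken verbatim,
#' including colons and dots (`si:dkey-72l14.7`, `zgc:158345`).
#'
#' @param path TSV file path.
#' @return an [expression_profile()].
#' @export
read_profile <- function(path) {
  if (!file.size(path) || !length(readLines(path, n = 1)))
    stop("empty profile file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, colClasses = "character")
  if (!nrow(df)) stop("profile has a header but no rows: ", path)
  if (!"gene" %in% names(df))
    stop("profile is missing mandatory column: gene")
  numeric_cols <- setdiff(names(df), "gene")
  known_num <- intersect(c(.CELLS, "embryo",
                           "p_mel_rpe", "p_mel_irid", "p_rpe_irid"),
                         names(df))
  for (cc in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- is.na(parsed) & !is.na(df[[cc]]) & nzchar(df[[cc]])
    if (any(bad)) {
      if (cc %in% known_num)
        stop("non-numeric value '", df[[cc]][which(bad)[1]], "' in column '",
             cc, "', row ", which(bad)[1])
      next  # unknown columns may be free text; keep verbatim
    }
    df[[cc]] <- parsed
  }
  expression_profile(df)
}

#' Write an expression profile TSV
#'
#' Full-precision output so that `read_profile(write_profile(x))`
#' round-trips to within 1e-9.
#'
#' @param profile an [expression_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  out <- as.data.frame(profile)
  for (cc in names(out))
    if (is.numeric(out[[cc]]))
      out[[cc]] <- formatC(out[[cc]], digits = 15, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag-count matrix and library metadata from TSV
#'
#' The count table has columns `gene_id`, `length_bp`, then one column
#' per library; the metadata table has `library_id`, `cell_type`,
#' `timepoint_hpf`, `total_reads`.
#'
#' @param counts_path,meta_path TSV paths.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, meta_path) {
  ct <- read.delim(counts_path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE)
  for (req in c("gene_id", "length_bp"))
    if (!req %in% names(ct))
      stop("count table is missing mandatory column: ", req)
  meta <- read.delim(meta_path, header = TRUE, sep = "\t", quote = "",
                     check.names = FALSE)
  libcols <- setdiff(names(ct), c("gene_id", "length_bp"))
  counts <- as.matrix(ct[libcols])
  rownames(counts) <- ct$gene_id
  count_matrix(counts, setNames(ct$length_bp, ct$gene_id), meta)
}

#' Write a tag-count matrix and library metadata to TSV
#'
#' @param counts a [count_matrix()].
#' @param counts_path,meta_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(counts, counts_path, meta_path) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(gene_id = rownames(counts$counts),
                   length_bp = as.integer(counts$lengths),
                   counts$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(counts$libraries, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' Write enrichment calls to TSV
#'
#' @param calls an `enrichment_calls` data frame from [apply_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Bundled reference expression profiles
#'
#' Small curated RPKM tables for zebrafish pigment cell types, taken
#' from a published transcriptome study of purified melanocytes,
#' iridophores and RPE versus pooled 3 dpf whole embryos:
#'
#' * `shared_identity`: 28 genes co-enriched in all three pigment cell
#'   types (within 2-fold, minimum 4 RPKM, 100-fold over embryo).
#' * `mel_rpe_top`: the 38 most highly expressed genes co-enriched in
#'   melanocytes and RPE.
#' * `mel_irid_top`: 15 genes co-enriched in melanocytes and iridophores.
#' * `irid_top`: 30 genes with high-stringency iridophore enrichment.
#' * `guanine_pathway`: 34 guanine-synthesis-related enzymes with
#'   iridophore-vs-melanocyte and iridophore-vs-RPE p-values.
#' * `marker_panel`: 15 candidate control genes (no embryo column) with
#'   all three pairwise p-values.
#'
#' @param name one of the table names above.
#' @return an [expression_profile()] (for `guanine_pathway`, with an
#'   extra `group` column naming the associated pathway).
#' @export
reference_profile <- function(name = c("shared_identity", "mel_rpe_top",
                                       "mel_irid_top", "irid_top",
                                       "guanine_pathway", "marker_panel")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("profile_", name, ".tsv"),
                      package = "pigmentExpr", mustWork = TRUE)
  read_profile(path)
}
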