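#' Parse pairwise similarity hits in BLAST tabular format
#'
#' Reads tab-separated hits in the 12-column BLAST `outfmt 6` dialect
#' (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score). Lines with fewer columns are accepted down to the first
#' four mandatory fields. Self-hits (query == subject) are dropped.
#'
#' @param input path to a hits file, or a character vector of lines.
#' @return data frame of class `similarity_hits` with columns
#'   `query_id`, `subject_id`, `percent_identity`, `alignment_length`
#'   plus any optional outfmt-6 columns present.
#' @examples
#' read_blast_hits(c("a\tb\t95.0\t300", "a\ta\t100.0\t500"))
#' @export
read_blast_hits <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else as.character(input)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.as_similarity_hits(NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed hit line (need >= 4 tab-separated fields) at line ",
         paste(which(nf < 4), collapse = ", "))
  opt_names <- c("mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")
  ncol_out <- min(max(nf), 12L)
  rows <- lapply(fields, function(f) c(f[seq_len(min(length(f), 12L))],
                                       rep(NA, ncol_out - min(length(f), 12L))))
  m <- do.call(rbind, rows)
  pid <- suppressWarnings(as.numeric(m[, 3]))
  alen <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(pid))
    stop("non-numeric identity field at line ",
         paste(which(is.na(pid)), collapse = ", "))
  if (anyNA(alen))
    stop("non-numeric alignment length at line ",
         paste(which(is.na(alen)), collapse = ", "))
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     percent_identity = pid, alignment_length = alen,
                     stringsAsFactors = FALSE)
  if (ncol_out > 4)
    for (j in 5:ncol_out)
      hits[[opt_names[j - 4L]]] <- suppressWarnings(as.numeric(m[, j]))
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  .as_similarity_hits(hits)
}

.as_similarity_hits <- function(hits) {
  if (is.null(hits) || !nrow(hits))
    hits <- data.frame(query_id = character(0), subject_id = character(0),
                       percent_identity = numeric(0),
                       alignment_length = numeric(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

#' All-vs-all local alignment identity
#'
#' Desk-scale stand-in for an all-by-all BLAST search: computes, for each
#' unordered pair of transcripts, the best local (Smith-Waterman)
#' alignment under unit match/mismatch scores and a linear gap penalty,
#' and reports percent identity (matches / alignment columns * 100) and
#' the alignment length in columns. Quadratic in sequence length --
#' intended for at most a few hundred sequences.
#'
#' @param transcripts a named [Biostrings::DNAStringSet] or named
#'   character vector of nucleotide sequences.
#' @param match,mismatch,gap alignment scores (gap is the per-column
#'   linear penalty, applied as a positive cost).
#' @return a `similarity_hits` data frame (one row per unordered pair).
#' @examples
#' s <- c(a = "ACGTACGTACGT", b = "ACGTACGTACGT")
#' all_vs_all_identity(s)
#' @export
all_vs_all_identity <- function(transcripts, match = 1, mismatch = -1, gap = 2) {
  if (is.character(transcripts))
    transcripts <- Biostrings::DNAStringSet(transcripts)
  n <- length(transcripts)
  ids <- names(transcripts)
  if (n > 0 && (is.null(ids) || any(!nzchar(ids))))
    stop("transcripts must be named")
  if (n < 2) return(.as_similarity_hits(NULL))
  submat <- matrix(as.numeric(mismatch), 5, 5,
                   dimnames = list(c("A", "C", "G", "T", "N"),
                                   c("A", "C", "G", "T", "N")))
  diag(submat) <- match
  submat["N", "N"] <- mismatch  # N never counts as a match
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    aln <- Biostrings::pairwiseAlignment(
      transcripts[idx], transcripts[[i]], type = "local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = abs(gap))
    cols <- nchar(aln)
    out[[i]] <- data.frame(
      query_id = ids[i], subject_id = ids[idx],
      percent_identity = ifelse(cols > 0,
                                100 * Biostrings::nmatch(aln) / cols, 0),
      alignment_length = cols,
      stringsAsFactors = FALSE)
  }
  .as_similarity_hits(do.call(rbind, out))
}

#' Collapse near-redundant transcripts into a non-redundant set
#'
#' Implements the non-redundant cDNA database rule: whenever two
#' transcripts share a similarity hit of greater than `identity_min`
#' percent identity covering more than `coverage_min` of the (by
#' default) shorter sequence's length, the smaller of the two is
#' excluded. Hits are treated as undirected (asymmetric records for a
#' pair are merged keeping the maximum-identity one) and processed in a
#' deterministic greedy order: descending identity, then descending
#' alignment length, then pair ids. A transcript already removed can
#' neither remove others nor be removed again; the result is the
#' fixpoint of this greedy procedure, so re-running the collapse on the
#' kept set removes nothing.
#'
#' @param transcripts a named [Biostrings::DNAStringSet], or a named
#'   numeric vector of transcript lengths (bp) when sequences are not
#'   needed.
#' @param hits a `similarity_hits` data frame ([read_blast_hits()] /
#'   [all_vs_all_identity()]); computed with [all_vs_all_identity()]
#'   when `NULL` and sequences were supplied.
#' @param identity_min strict percent-identity threshold (default 94:
#'   pairs must exceed it).
#' @param coverage_min strict coverage threshold as a fraction of the
#'   reference length (default 0.70).
#' @param coverage_of which sequence's length defines coverage:
#'   `"shorter"` (default; the reading consistent with always excluding
#'   the smaller record), `"longer"`, or `"subject"`.
#' @return list of class `collapse_result` with `kept` (same type as
#'   `transcripts`), `removed_ids`, and `decisions` (data frame with
#'   `removed_id`, `kept_id`, `percent_identity`, `alignment_length`,
#'   `coverage`).
#' @examples
#' lens <- c(long = 500, short = 400)
#' hits <- read_blast_hits("long\tshort\t100.0\t400")
#' collapse_transcripts(lens, hits)$removed_ids
#' @export
collapse_transcripts <- function(transcripts, hits = NULL,
                                 identity_min = 94, coverage_min = 0.70,
                                 coverage_of = c("shorter", "longer", "subject")) {
  coverage_of <- match.arg(coverage_of)
  if (is.character(transcripts))
    transcripts <- Biostrings::DNAStringSet(transcripts)
  if (inherits(transcripts, "DNAStringSet")) {
    lens <- setNames(Biostrings::width(transcripts), names(transcripts))
  } else {
    lens <- transcripts
    if (is.null(names(lens))) stop("transcript lengths must be named")
  }
  if (anyDuplicated(names(lens)))
    stop("transcript ids must be unique")
  if (is.null(hits)) {
    if (!inherits(transcripts, "DNAStringSet"))
      stop("`hits` must be supplied when only lengths are given")
    hits <- all_vs_all_identity(transcripts)
  }
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(lens))
  if (length(unknown))
    stop("hit references unknown transcript id: ",
         paste(head(unknown, 5), collapse = ", "))

  decisions <- data.frame(removed_id = character(0), kept_id = character(0),
                          percent_identity = numeric(0),
                          alignment_length = numeric(0),
                          coverage = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    # merge asymmetric duplicates per unordered pair: keep max identity,
    # then max alignment length
    a <- pmin(hits$query_id, hits$subject_id)
    b <- pmax(hits$query_id, hits$subject_id)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -hits$percent_identity, -hits$alignment_length)
    h <- hits[ord, , drop = FALSE]
    h <- h[!duplicated(key[ord]), , drop = FALSE]
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)

    ref_len <- switch(coverage_of,
      shorter = pmin(lens[a], lens[b]),
      longer  = pmax(lens[a], lens[b]),
      subject = lens[h$subject_id])
    coverage <- h$alignment_length / ref_len
    keep <- h$percent_identity > identity_min &
      h$alignment_length > coverage_min * ref_len
    h <- h[keep, , drop = FALSE]
    a <- a[keep]; b <- b[keep]; coverage <- coverage[keep]

    if (nrow(h)) {
      ord <- order(-h$percent_identity, -h$alignment_length, a, b)
      h <- h[ord, , drop = FALSE]
      a <- a[ord]; b <- b[ord]; coverage <- coverage[ord]
      alive <- setNames(rep(TRUE, length(lens)), names(lens))
      rem <- kept <- character(0); ri <- 0L
      dec_pid <- dec_len <- dec_cov <- numeric(0)
      for (k in seq_len(nrow(h))) {
        x <- a[k]; y <- b[k]
        if (!alive[[x]] || !alive[[y]]) next
        # remove the smaller; on equal lengths the lexicographically
        # larger id goes
        if (lens[[x]] < lens[[y]] ||
            (lens[[x]] == lens[[y]] && x > y)) {
          drop_id <- x; keep_id <- y
        } else {
          drop_id <- y; keep_id <- x
        }
        alive[[drop_id]] <- FALSE
        ri <- ri + 1L
        rem[ri] <- drop_id; kept[ri] <- keep_id
        dec_pid[ri] <- h$percent_identity[k]
        dec_len[ri] <- h$alignment_length[k]
        dec_cov[ri] <- coverage[k]
      }
      decisions <- data.frame(removed_id = rem, kept_id = kept,
                              percent_identity = dec_pid,
                              alignment_length = dec_len,
                              coverage = dec_cov, stringsAsFactors = FALSE)
    }
  }
  removed <- decisions$removed_id
  kept_ids <- setdiff(names(lens), removed)
  kept <- if (inherits(transcripts, "DNAStringSet"))
    transcripts[kept_ids] else lens[kept_ids]
  structure(list(kept = kept, removed_ids = removed, decisions = decisions),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("collapse_result: %d kept, %d removed\n",
              length(x$kept), length(x$removed_ids)))
  invisible(x)
}
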