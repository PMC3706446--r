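#' Declarative enrichment filter specification
#'
#' A filter is a conjunction of per-gene criteria over an
#' [expression_profile()]. Four shapes exist:
#'
#' * `shared_all` -- all three pigment cell types within `within_fold` of
#'   each other (max/min ratio), each at or above `min_rpkm`, and
#'   enriched at least `fold_vs_embryo` over whole embryo.
#' * `pairwise_shared` -- two target cell types each at least
#'   `fold_vs_others` over the third (with t-test p strictly below
#'   `p_max` when set), and over embryo by `fold_vs_embryo`.
#' * `specific` -- one target over both other cell types, same structure.
#' * `stringent` -- a pairwise/specific shape without the p criterion,
#'   used for the high-stringency table presets.
#'
#' Conventions: "at least k-fold" is inclusive (`>= k`); `Inf` folds
#' (zero denominator, positive numerator) pass any fold criterion;
#' undefined folds (`0/0`) fail; p criteria are strictly `<`. The embryo
#' criterion has no p component. `embryo_rule` controls which target
#' means must clear the embryo fold: `"min"` (every target; strictest,
#' the default), `"max"` (the highest target), or `"any"`.
#'
#' @param mode one of `"shared_all"`, `"pairwise_shared"`, `"specific"`,
#'   `"stringent"`.
#' @param targets target cell types (3 for shared_all, 2 for
#'   pairwise_shared, 1 for specific, 1 or 2 for stringent), drawn from
#'   `"mel"`, `"rpe"`, `"irid"`.
#' @param fold_vs_others fold threshold over each non-target cell type.
#' @param fold_vs_embryo fold threshold over whole embryo.
#' @param min_rpkm minimum mean RPKM required of every target.
#' @param p_max raw p-value bound in (0, 1], or `NA` for no p criterion.
#' @param within_fold (shared_all only) maximum max/min ratio among the
#'   three cell types.
#' @param embryo_rule see Details.
#' @return object of class `filter_spec`.
#' @seealso [enrichment_preset()] for the named presets,
#'   [apply_filter()] to evaluate.
#' @export
filter_spec <- function(mode = c("shared_all", "pairwise_shared", "specific",
                                 "stringent"),
                        targets,
                        fold_vs_others = NULL,
                        fold_vs_embryo = 1,
                        min_rpkm = 0,
                        p_max = NA_real_,
                        within_fold = NULL,
                        embryo_rule = c("min", "max", "any")) {
  mode <- match.arg(mode)
  embryo_rule <- match.arg(embryo_rule)
  unknown <- setdiff(targets, .CELLS)
  if (length(unknown))
    stop("unknown target cell type: ", paste(unknown, collapse = ", "))
  nt <- length(targets)
  if (mode == "shared_all" && nt != 3)
    stop("shared_all names all three cell types")
  if (mode == "pairwise_shared" && nt != 2)
    stop("pairwise_shared names exactly two targets")
  if (mode == "specific" && nt != 1)
    stop("specific names exactly one target")
  if (mode == "stringent" && !nt %in% 1:2)
    stop("stringent names one or two targets")
  if (mode == "shared_all") {
    if (is.null(within_fold) || within_fold < 1)
      stop("shared_all requires `within_fold` >= 1")
  } else {
    if (is.null(fold_vs_others) || fold_vs_others < 1)
      stop("`fold_vs_others` must be >= 1")
  }
  if (fold_vs_embryo < 1) stop("`fold_vs_embryo` must be >= 1")
  if (min_rpkm < 0) stop("`min_rpkm` must be >= 0")
  if (!is.na(p_max) && (p_max <= 0 || p_max > 1))
    stop("`p_max` must lie in (0, 1] or be NA")
  if (mode %in% c("shared_all", "stringent") && !is.na(p_max))
    stop("`p_max` applies only to pairwise_shared and specific filters")
  structure(list(mode = mode, targets = targets,
                 fold_vs_others = fold_vs_others,
                 fold_vs_embryo = fold_vs_embryo,
                 min_rpkm = min_rpkm, p_max = p_max,
                 within_fold = within_fold, embryo_rule = embryo_rule),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("filter_spec:", x$mode, "| targets:", paste(x$targets, collapse = "+"))
  if (!is.null(x$within_fold)) cat(" | within", x$within_fold, "fold")
  if (!is.null(x$fold_vs_others)) cat(" |", x$fold_vs_others, "fold vs others")
  cat(" |", x$fold_vs_embryo, "fold vs embryo")
  if (x$min_rpkm > 0) cat(" | min", x$min_rpkm, "RPKM")
  if (!is.na(x$p_max)) cat(" | p <", x$p_max)
  cat("\n")
  invisible(x)
}

.PRESETS <- list(
  # genes indicative of a shared pigment-cell identity
  shared_identity = list(mode = "shared_all", targets = c("mel", "rpe", "irid"),
                         within_fold = 2, min_rpkm = 4, fold_vs_embryo = 100),
  # pairwise co-enrichment (shared function / developmental origin)
  mel_rpe_shared = list(mode = "pairwise_shared", targets = c("mel", "rpe"),
                        fold_vs_others = 2, fold_vs_embryo = 8, p_max = 0.05),
  mel_irid_shared = list(mode = "pairwise_shared", targets = c("mel", "irid"),
                         fold_vs_others = 2, fold_vs_embryo = 8, p_max = 0.05),
  rpe_irid_shared = list(mode = "pairwise_shared", targets = c("rpe", "irid"),
                         fold_vs_others = 2, fold_vs_embryo = 8, p_max = 0.05),
  # cell-type specific enrichment
  mel_specific = list(mode = "specific", targets = "mel",
                      fold_vs_others = 2, fold_vs_embryo = 8, p_max = 0.05),
  irid_specific = list(mode = "specific", targets = "irid",
                       fold_vs_others = 2, fold_vs_embryo = 8, p_max = 0.05),
  rpe_specific = list(mode = "specific", targets = "rpe",
                      fold_vs_others = 2, fold_vs_embryo = 8, p_max = 0.05),
  # high-stringency headline-table presets
  mel_rpe_stringent = list(mode = "stringent", targets = c("mel", "rpe"),
                           fold_vs_others = 10, fold_vs_embryo = 10,
                           min_rpkm = 10),
  mel_irid_stringent = list(mode = "stringent", targets = c("mel", "irid"),
                            fold_vs_others = 5, fold_vs_embryo = 10),
  irid_stringent = list(mode = "stringent", targets = "irid",
                        fold_vs_others = 30, fold_vs_embryo = 100))

#' Named enrichment filter presets
#'
#' Returns the exact thresholds of the canonical pigment-cell filters:
#'
#' * `shared_identity`: all three cell types within 2-fold of each
#'   other, minimum 4 RPKM, 100-fold over embryo.
#' * `mel_rpe_shared`, `mel_irid_shared`, `rpe_irid_shared`: both
#'   targets at least 2-fold over the third cell type (p < 0.05) and
#'   8-fold over embryo.
#' * `mel_specific`, `irid_specific`, `rpe_specific`: target at least
#'   2-fold over the other two cell types (p < 0.05) and 8-fold over
#'   embryo.
#' * `mel_rpe_stringent`: melanocyte and RPE each at least 10-fold over
#'   iridophore and embryo, minimum 10 RPKM.
#' * `mel_irid_stringent`: melanocyte and iridophore each at least
#'   5-fold over RPE and 10-fold over embryo.
#' * `irid_stringent`: iridophore at least 30-fold over melanocyte and
#'   RPE, 100-fold over embryo.
#'
#' @param name preset name (see above).
#' @return a [filter_spec()].
#' @examples
#' enrichment_preset("irid_stringent")
#' @export
enrichment_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(.PRESETS))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.PRESETS), collapse = ", "))
  do.call(filter_spec, .PRESETS[[name]])
}

#' Evaluate an enrichment filter over a profile
#'
#' Applies a [filter_spec()] gene by gene and reports the verdict along
#' with every criterion boolean and the fold changes and p-values used,
#' so calls are fully auditable. The verdict is the conjunction of all
#' criterion booleans.
#'
#' @param profile an [expression_profile()] (or data frame coercible to
#'   one).
#' @param spec a [filter_spec()] or preset name.
#' @return data frame of class `enrichment_calls`: `gene`, `pass`,
#'   per-criterion logical columns, and the folds/p-values evaluated.
#' @examples
#' prof <- expression_profile(data.frame(gene = "g", mel = 50, rpe = 50,
#'                                       irid = 50, embryo = 1))
#' apply_filter(prof, enrichment_preset("shared_identity"))$pass  # 50x < 100x
#' @export
apply_filter <- function(profile, spec) {
  if (is.character(spec)) spec <- enrichment_preset(spec)
  stopifnot(inherits(spec, "filter_spec"))
  if (!inherits(profile, "expression_profile"))
    profile <- expression_profile(profile)
  needs_embryo <- spec$fold_vs_embryo > 1
  if (needs_embryo && all(is.na(profile$embryo)))
    stop("filter requires whole-embryo means but the profile has none")

  out <- data.frame(gene = profile$gene, stringsAsFactors = FALSE)
  crit <- list()

  if (spec$mode == "shared_all") {
    hi <- do.call(pmax, profile[.CELLS])
    lo <- do.call(pmin, profile[.CELLS])
    within <- fold_change(hi, lo)
    crit$within_fold_ok <- !is.na(within) & within <= spec$within_fold
    crit$min_rpkm_ok <- lo >= spec$min_rpkm
    emb_num <- switch(spec$embryo_rule, min = lo, max = hi, any = hi)
    out$fold_embryo <- fold_change(emb_num, profile$embryo)
    crit$embryo_ok <- .fold_ge(out$fold_embryo, spec$fold_vs_embryo)
    out$within_fold <- within
  } else {
    others <- setdiff(.CELLS, spec$targets)
    use_p <- spec$mode != "stringent" && !is.na(spec$p_max)
    for (tg in spec$targets) {
      for (ot in others) {
        fcol <- paste0("fold_", tg, "_vs_", ot)
        out[[fcol]] <- fold_change(profile[[tg]], profile[[ot]])
        crit[[paste0(fcol, "_ok")]] <- .fold_ge(out[[fcol]], spec$fold_vs_others)
        if (use_p) {
          pcol <- .pair_col(tg, ot)
          out[[pcol]] <- profile[[pcol]]
          pok <- profile[[pcol]] < spec$p_max
          pok[is.na(pok)] <- FALSE
          crit[[paste0("p_", tg, "_vs_", ot, "_ok")]] <- pok
        }
      }
    }
    if (spec$min_rpkm > 0) {
      min_target <- do.call(pmin, profile[spec$targets])
      crit$min_rpkm_ok <- min_target >= spec$min_rpkm
    }
    tmat <- profile[spec$targets]
    emb_num <- switch(spec$embryo_rule,
                      min = do.call(pmin, tmat),
                      max = do.call(pmax, tmat),
                      any = do.call(pmax, tmat))
    out$fold_embryo <- fold_change(emb_num, profile$embryo)
    crit$embryo_ok <- .fold_ge(out$fold_embryo, spec$fold_vs_embryo)
  }

  for (k in names(crit)) out[[k]] <- crit[[k]]
  out$pass <- Reduce(`&`, crit)
  front <- c("gene", "pass")
  out <- out[c(front, setdiff(names(out), front))]
  attr(out, "spec") <- spec
  attr(out, "n_pass") <- sum(out$pass)
  class(out) <- c("enrichment_calls", "data.frame")
  out
}

#' @export
print.enrichment_calls <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("enrichment_calls (%s): %d of %d genes pass\n",
              sp$mode, attr(x, "n_pass"), nrow(x)))
  invisible(x)
}

#' Pathway-level fold-change report
#'
#' For curated gene groups (pathway label -> gene ids), reports each
#' gene's mean RPKM per condition, its fold change in the target cell
#' type versus each comparator cell type and versus whole embryo, and a
#' significance flag per comparator (enriched above the comparator with
#' raw p strictly below `p_max`). Genes absent from the profile are
#' listed, not silently dropped. The default target (`irid`) with
#' comparators melanocyte and RPE reproduces the guanine-synthesis
#' enrichment report for iridophores.
#'
#' @param profile an [expression_profile()] with the pairwise p-value
#'   columns populated.
#' @param groups named list of gene id vectors, or a data frame with
#'   columns `group` and `gene`.
#' @param target target cell type of the report.
#' @param p_max significance bound for the enrichment flags.
#' @return list of class `pathway_report` with `report` (data frame:
#'   `group`, `gene`, the four means, `fold_vs_<comparator>`,
#'   `fold_vs_embryo`, `sig_vs_<comparator>`) and `missing` (data frame
#'   of group/gene pairs not found).
#' @export
pathway_report <- function(profile, groups, target = "irid", p_max = 0.05) {
  stopifnot(inherits(profile, "expression_profile"))
  if (is.data.frame(groups))
    groups <- split(groups$gene, groups$group)
  if (!length(groups) || !sum(lengths(groups)))
    stop("`groups` must name at least one gene")
  if (!target %in% .CELLS) stop("unknown target cell type: ", target)
  comparators <- setdiff(.CELLS, target)

  gdf <- data.frame(group = rep(names(groups), lengths(groups)),
                    gene = unlist(groups, use.names = FALSE),
                    stringsAsFactors = FALSE)
  found <- gdf$gene %in% profile$gene
  missing <- gdf[!found, , drop = FALSE]
  gdf <- gdf[found, , drop = FALSE]
  if (!nrow(gdf))
    stop("none of the group genes are present in the profile")
  idx <- match(gdf$gene, profile$gene)
  rep_df <- cbind(gdf, profile[idx, c(.CELLS, "embryo")])
  for (cmp in comparators) {
    rep_df[[paste0("fold_vs_", cmp)]] <-
      fold_change(profile[[target]][idx], profile[[cmp]][idx])
    pv <- profile[[.pair_col(target, cmp)]][idx]
    rep_df[[paste0("p_vs_", cmp)]] <- pv
    enriched <- rep_df[[paste0("fold_vs_", cmp)]] > 1
    enriched[is.na(enriched)] <- FALSE
    rep_df[[paste0("sig_vs_", cmp)]] <- enriched & !is.na(pv) & pv < p_max
  }
  rep_df$fold_vs_embryo <- fold_change(profile[[target]][idx],
                                       profile$embryo[idx])
  rownames(rep_df) <- NULL; rownames(missing) <- NULL
  structure(list(report = rep_df, missing = missing, target = target,
                 p_max = p_max),
            class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("pathway_report (%s): %d genes in %d groups; %d missing\n",
              x$target, nrow(x$report), length(unique(x$report$group)),
              nrow(x$missing)))
  invisible(x)
}
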