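#' Pipeline configuration
#'
#' Collects every knob of the synthetic end-to-end pipeline with
#' validation at construction time. Defaults mirror the reference study
#' design and filter thresholds.
#'
#' @param out_dir output directory for result TSVs and the manifest.
#' @param seed root integer seed for all stochastic stages.
#' @param design a [study_design()].
#' @param theta detection threshold (RPKM).
#' @param window_size window for [windowed_correlation()]; `NA` skips
#'   the windowed-correlation stage (the default for small designs it
#'   would be ill-defined on is `min(1000, n_genes %/% 4)`).
#' @param identity_min,coverage_min non-redundant collapse thresholds.
#' @param presets enrichment presets to evaluate (see
#'   [enrichment_preset()]).
#' @param p_max raw p bound used by the pairwise/specific presets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            design = study_design(),
                            theta = 1,
                            window_size = min(1000, design$n_genes %/% 4),
                            identity_min = 94,
                            coverage_min = 0.70,
                            presets = names(.PRESETS),
                            p_max = 0.05) {
  stopifnot(inherits(design, "study_design"))
  if (theta <= 0) stop("`theta` must be positive")
  if (p_max <= 0 || p_max > 1) stop("`p_max` must lie in (0, 1]")
  if (identity_min < 0 || identity_min > 100)
    stop("`identity_min` must lie in [0, 100]")
  if (coverage_min <= 0 || coverage_min > 1)
    stop("`coverage_min` must lie in (0, 1]")
  bad <- setdiff(presets, names(.PRESETS))
  if (length(bad)) stop("unknown preset: ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 theta = theta, window_size = window_size,
                 identity_min = identity_min, coverage_min = coverage_min,
                 presets = presets, p_max = p_max),
            class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognised
#' keys: `seed`, `n_genes`, `reps_mel`, `reps_irid`, `reps_rpe`,
#' `reps_embryo`, `total_reads`, `theta`, `window_size`, `identity_min`,
#' `coverage_min`, `p_max`, `presets` (comma-separated). Every numeric
#' field is validated against its legal range.
#'
#' @param path configuration file.
#' @param out_dir output directory (paths are kept out of the flat file).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k, default) if (k %in% names(vals)) as.numeric(vals[[k]]) else default
  reps <- c(mel = num("reps_mel", 11), irid = num("reps_irid", 5),
            rpe = num("reps_rpe", 5), embryo = num("reps_embryo", 3))
  design <- study_design(replicates = reps,
                         n_genes = num("n_genes", 25102),
                         total_reads = num("total_reads", 5e6))
  presets <- if ("presets" %in% names(vals))
    trimws(strsplit(vals[["presets"]], ",")[[1]]) else names(.PRESETS)
  pipeline_config(out_dir = out_dir,
                  seed = num("seed", 1),
                  design = design,
                  theta = num("theta", 1),
                  window_size = num("window_size", min(1000, design$n_genes %/% 4)),
                  identity_min = num("identity_min", 94),
                  coverage_min = num("coverage_min", 0.70),
                  presets = presets,
                  p_max = num("p_max", 0.05))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes simulate -> quantify -> stats -> windowed correlation ->
#' classify on a synthetic data set with planted truth, writes all
#' result TSVs plus a JSON run manifest (config, seed, per-stage row
#' counts, file checksums), and logs each filter's pass count to stderr.
#' Identical configuration and seed produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stages <- list()
  outfile <- function(f) file.path(config$out_dir, f)

  say("[simulate] planting truth and drawing counts (seed ", config$seed, ")")
  truth <- generate_truth(config$design, seed = config$seed)
  counts <- simulate_counts(truth, config$design, seed = config$seed + 1L)
  write.table(as.data.frame(truth), outfile("truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_counts(counts, outfile("counts.tsv"), outfile("libraries.tsv"))
  stages$simulate <- list(rows = nrow(truth), libraries = ncol(counts$counts))

  say("[quantify] RPKM, cell-type means, detection at theta = ", config$theta)
  rpkm <- compute_rpkm(counts)
  det <- detect_expressed(average_by_celltype(rpkm), theta = config$theta)
  stages$quantify <- list(rows = nrow(rpkm$rpkm),
                          n_detected = as.list(det$n_detected))
  say("[quantify] genes detected: ",
      paste(sprintf("%s=%d", names(det$n_detected), det$n_detected),
            collapse = ", "))

  say("[stats] pairwise t-tests and profile assembly")
  profile <- all_pair_stats(rpkm)
  write_profile(profile, outfile("profile.tsv"))
  stages$stats <- list(rows = nrow(profile))

  if (!is.na(config$window_size) && config$window_size >= 3 &&
      nrow(profile) > config$window_size) {
    say("[windowcorr] w = ", config$window_size)
    wp <- windowed_correlation(profile, w = config$window_size)
    write.table(wp$windows, outfile("window_correlation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stages$windowcorr <- list(rows = nrow(wp$windows),
                              average = as.list(wp$average))
  }

  say("[classify] evaluating ", length(config$presets), " presets")
  summary_rows <- list()
  for (ps in config$presets) {
    calls <- apply_filter(profile, ps)
    write_results(calls, outfile(paste0("calls_", ps, ".tsv")))
    say("[classify] ", ps, ": ", attr(calls, "n_pass"), " genes pass")
    summary_rows[[ps]] <- data.frame(preset = ps, n_pass = attr(calls, "n_pass"),
                                     stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  write.table(summary, outfile("classify_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages$classify <- as.list(setNames(summary$n_pass, summary$preset))

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pigmentExpr")),
    seed = config$seed,
    config = config[setdiff(names(config), c("design", "out_dir"))],
    design = list(replicates = as.list(config$design$replicates),
                  n_genes = config$design$n_genes,
                  total_reads = config$design$total_reads),
    stages = stages,
    outputs = lapply(setNames(files, basename(files)),
                     function(f) list(md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
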