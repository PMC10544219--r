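#' Configuration for an end-to-end run
#'
#' Collects every tunable of the pipeline with the tool's defaults: 30 bp
#' windows, depth thresholds 10/20/30/40/50, adjusted p-value threshold
#' 0.1, merge distance 15 bp, reporting score threshold 0.95.
#'
#' @param annotation Path to the GTF annotation.
#' @param reference Path to the reference FASTA.
#' @param sites Path to the strand-resolved site table (BED6 dialect).
#' @param coverage Path to the per-base coverage bedGraph.
#' @param out_dir Output directory (created if missing).
#' @param conversion Conversion label; default `"C>T"`.
#' @param window_size Window width in bp; default 30.
#' @param thresholds Depth-stratum thresholds; default
#'   `c(10, 20, 30, 40, 50)`.
#' @param alpha Adjusted p-value threshold; default 0.1.
#' @param merge_distance Merge gap in bp; default 15.
#' @param score_threshold Score at or above which clusters are flagged
#'   `reportable` in the output (all clusters are kept); default 0.95.
#' @param include_zero_windows,stratify_depth,adjust Passed to
#'   [fit_background()] / [test_windows()].
#' @param seed Optional seed recorded in the run report (the deterministic
#'   pipeline itself draws no random numbers).
#' @return Object of class `run_config`.
#' @export
run_config <- function(annotation, reference, sites, coverage, out_dir,
                       conversion = "C>T", window_size = 30L,
                       thresholds = c(10L, 20L, 30L, 40L, 50L),
                       alpha = 0.1, merge_distance = 15L,
                       score_threshold = 0.95,
                       include_zero_windows = FALSE, stratify_depth = TRUE,
                       adjust = "global", seed = NULL) {
  cfg <- list(annotation = annotation, reference = reference,
              sites = sites, coverage = coverage, out_dir = out_dir,
              conversion = parse_conversion(conversion),
              window_size = as.integer(window_size),
              thresholds = thresholds, alpha = alpha,
              merge_distance = as.integer(merge_distance),
              score_threshold = score_threshold,
              include_zero_windows = include_zero_windows,
              stratify_depth = stratify_depth, adjust = adjust,
              seed = seed)
  for (f in c("annotation", "reference", "sites", "coverage"))
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  structure(cfg, class = "run_config")
}

#' Run the full cluster-calling pipeline
#'
#' Executes annotation windowing, edit/substrate tabulation, background
#' fitting, zero-truncated Poisson testing with BH adjustment, window
#' merging and cluster scoring, writing every stage's table to the output
#' directory. Identical configuration and inputs yield byte-identical
#' outputs; any stage error aborts the run with the stage name and removes
#' partial outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages; default `FALSE`.
#' @return Invisibly, a list with `windows`, `stats`, `fit`, `tests`,
#'   `clusters` and `report` (a character vector also written to
#'   `run_report.txt`).
#' @export
run_end_to_end <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  outs <- file.path(config$out_dir,
                    c("windows.bed", "window_stats.tsv", "rates.tsv",
                      "window_tests.tsv", "clusters.bed",
                      "run_report.txt"))
  names(outs) <- c("windows", "stats", "rates", "tests", "clusters",
                   "report")
  on_error <- function(stage) function(e) {
    suppressWarnings(file.remove(outs[file.exists(outs)]))
    stop_stage(stage, e)
  }
  say <- function(...) if (!quiet) message(...)

  say("stage windows: tiling annotation")
  windows <- tryCatch({
    w <- make_windows(config$annotation, config$window_size)
    write_windows_bed(w, outs["windows"])
    w
  }, error = on_error("windows"))

  say("stage tabulate: aggregating edit and substrate instances")
  stats <- tryCatch({
    sites <- read_edit_sites(config$sites)
    coverage <- read_coverage(config$coverage)
    s <- aggregate_windows(windows, sites, coverage, config$conversion,
                           config$reference)
    write_window_stats(s, outs["stats"])
    s
  }, error = on_error("tabulate"))

  say("stage model: fitting background and testing windows")
  res <- tryCatch({
    if (nrow(stats) == 0L || !any(stats$edit_instances >= 1L)) {
      list(fit = NULL, tests = empty_tests())
    } else {
      fit <- fit_background(
        stats, thresholds = config$thresholds,
        include_zero_windows = config$include_zero_windows,
        stratify_depth = config$stratify_depth)
      tests <- test_windows(stats, fit, adjust = config$adjust)
      list(fit = fit, tests = tests)
    }
  }, error = on_error("model"))
  fit <- res$fit; tests <- res$tests
  tryCatch({
    if (!is.null(fit))
      write.table(fit$rates, outs["rates"], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    else
      writeLines(paste("region_class", "bin_upper", "rate", "n_windows",
                       "fallback", sep = "\t"), outs["rates"])
    write.table(tests, outs["tests"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }, error = on_error("model"))

  say("stage clusters: merging and scoring")
  clusters <- tryCatch({
    cl <- call_clusters(tests, alpha = config$alpha,
                        merge_distance = config$merge_distance)
    write_clusters_bed(cl, outs["clusters"])
    cl
  }, error = on_error("clusters"))

  report <- tryCatch({
    rep_lines <- run_report(config, windows, stats, tests, clusters)
    writeLines(rep_lines, outs["report"])
    rep_lines
  }, error = on_error("report"))

  say(sprintf("done: %d windows, %d tested, %d clusters",
              length(windows), nrow(tests), length(clusters)))
  invisible(list(windows = windows, stats = stats, fit = fit,
                 tests = tests, clusters = clusters, report = report,
                 paths = as.list(outs)))
}

empty_tests <- function() {
  cbind(empty_window_stats(),
        data.frame(lambda = numeric(0), p_raw = numeric(0),
                   p_adj = numeric(0)))
}

run_report <- function(config, windows, stats, tests, clusters) {
  inputs <- c(annotation = config$annotation, reference = config$reference,
              sites = config$sites, coverage = config$coverage)
  sums <- tools::md5sum(inputs)
  reportable <- if (length(clusters))
    sum(!is.na(clusters$score) & clusters$score >= config$score_threshold)
  else 0L
  c("editclust run report",
    "",
    "[parameters]",
    sprintf("conversion = %s", config$conversion$label),
    sprintf("window_size = %d", config$window_size),
    sprintf("depth_thresholds = %s",
            paste(config$thresholds, collapse = ",")),
    sprintf("alpha = %g", config$alpha),
    sprintf("merge_distance = %d", config$merge_distance),
    sprintf("score_threshold = %g", config$score_threshold),
    sprintf("include_zero_windows = %s", config$include_zero_windows),
    sprintf("stratify_depth = %s", config$stratify_depth),
    sprintf("adjust = %s", config$adjust),
    sprintf("seed = %s",
            if (is.null(config$seed)) "none" else config$seed),
    "",
    "[inputs]",
    sprintf("%s = %s (md5 %s)", names(inputs), inputs, sums),
    "",
    "[counts]",
    sprintf("windows = %d", length(windows)),
    sprintf("windows_with_substrate = %d", nrow(stats)),
    sprintf("windows_tested = %d", nrow(tests)),
    sprintf("windows_selected = %d",
            sum(tests$p_adj <= config$alpha)),
    sprintf("clusters = %d", length(clusters)),
    sprintf("clusters_at_score_threshold = %d", reportable))
}
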