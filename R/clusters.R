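#' Select significant windows
#'
#' @param tests Tested windows from [test_windows()].
#' @param alpha Adjusted p-value threshold in (0, 1]; default 0.1.
#' @return Rows of `tests` with `p_adj <= alpha`, order preserved.
#' @export
select_windows <- function(tests, alpha = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (is.null(tests$p_adj)) stop("tests must carry a p_adj column")
  tests[tests$p_adj <= alpha, , drop = FALSE]
}

#' Merge significant windows into clusters
#'
#' Windows of the same gene, region class, chromosome and strand whose gap
#' (`next start - previous end - 1` bases between them) is at most
#' `merge_distance` are merged into one cluster. Pooled cluster counts are
#' the sums over member windows; since member windows tile their region
#' without overlap this equals re-aggregating over the union of member
#' spans.
#'
#' @param selected Selected window rows from [select_windows()] (any
#'   window-stats data.frame works; unsorted input is sorted internally).
#' @param merge_distance Maximum gap in bp bridged by a merge; default 15.
#' @return `GRanges` of clusters sorted by (chromosome, start) with
#'   metadata columns `cluster_id`, `gene_id`, `region_class`,
#'   `n_windows`, `member_window_ids` (comma-separated),
#'   `substrate_instances`, `edit_instances`, `distinct_edited_positions`
#'   and `edit_fraction`.
#' @export
merge_windows <- function(selected, merge_distance = 15L) {
  merge_distance <- as.integer(merge_distance)
  if (is.na(merge_distance) || merge_distance < 0L)
    stop("merge_distance must be a non-negative integer")
  if (nrow(selected) == 0L) return(empty_clusters())
  selected <- selected[order(selected$chrom, selected$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    selected$chrom, IRanges::IRanges(selected$start, selected$end),
    strand = selected$strand)
  key <- paste(selected$gene_id, selected$region_class, sep = "\r")
  parts <- lapply(split(seq_len(nrow(selected)), key), function(idx) {
    red <- GenomicRanges::reduce(gr[idx],
                                 min.gapwidth = merge_distance + 1L,
                                 with.revmap = TRUE)
    members <- lapply(red$revmap, function(m) idx[m])
    red$revmap <- NULL
    list(ranges = red, members = members)
  })
  ranges <- suppressWarnings(do.call(c, unname(lapply(parts, `[[`, "ranges"))))
  members <- do.call(c, unname(lapply(parts, `[[`, "members")))
  sub <- vapply(members, function(m) sum(selected$substrate_instances[m]),
                numeric(1))
  ed <- vapply(members, function(m) sum(selected$edit_instances[m]),
               numeric(1))
  np <- vapply(members, function(m)
    sum(selected$distinct_edited_positions[m]), numeric(1))
  gid <- vapply(members, function(m) selected$gene_id[m[1]], character(1))
  cls <- vapply(members, function(m) selected$region_class[m[1]],
                character(1))
  ids <- vapply(members, function(m)
    paste(selected$window_id[m], collapse = ","), character(1))
  S4Vectors::mcols(ranges) <- S4Vectors::DataFrame(
    cluster_id = NA_character_, gene_id = gid, region_class = cls,
    n_windows = lengths(members), member_window_ids = ids,
    substrate_instances = sub, edit_instances = as.integer(ed),
    distinct_edited_positions = as.integer(np),
    edit_fraction = ed / sub)
  ranges <- BiocGenerics::sort(ranges, ignore.strand = TRUE)
  ranges$cluster_id <- sprintf("cluster_%d", seq_along(ranges))
  ranges
}

empty_clusters <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cluster_id = character(0), gene_id = character(0),
    region_class = character(0), n_windows = integer(0),
    member_window_ids = character(0), substrate_instances = numeric(0),
    edit_instances = integer(0), distinct_edited_positions = integer(0),
    edit_fraction = numeric(0))
  gr
}

#' Fit the negative-binomial cluster score model
#'
#' The score model has a single parameter: the mean cluster edit fraction
#' of the sample, clamped away from 0 and 1.
#'
#' @param clusters Cluster `GRanges` from [merge_windows()].
#' @return An object of class `nb_score_model` (`p_bar`, `n_clusters`), or
#'   `NULL` with a warning when fewer than two clusters are available (the
#'   sample mean is then meaningless and scores are reported missing).
#' @export
fit_score_model <- function(clusters) {
  if (length(clusters) < 2L) {
    warning("fewer than two clusters; no score model fitted")
    return(NULL)
  }
  p_bar <- mean(clusters$edit_fraction)
  p_bar <- min(max(p_bar, 1e-9), 1 - 1e-9)
  structure(list(p_bar = p_bar, n_clusters = length(clusters)),
            class = "nb_score_model")
}

#' @export
print.nb_score_model <- function(x, ...) {
  cat("Negative-binomial cluster score model: p_bar =",
      signif(x$p_bar, 6), "fitted from", x$n_clusters, "clusters\n")
  invisible(x)
}

#' Score clusters against the sample's mean edit fraction
#'
#' With `k` edit instances and `r = substrate - k` unedited instances, the
#' score is the CDF, at `k`, of the negative binomial counting edits
#' accumulated before `r` non-edits when each substrate instance is edited
#' with probability `p_bar`. Scores near 1 mark clusters whose edit
#' fraction is high for the sample; a cluster at the sample mean scores
#' near the distribution's centre. All-edited clusters (`r = 0`) score 1.
#'
#' @param clusters Cluster `GRanges`.
#' @param model An `nb_score_model`, or `NULL` to fit one from `clusters`.
#' @return `clusters` with a `score` column appended (`NA` when no model
#'   can be fitted).
#' @export
score_clusters <- function(clusters, model = NULL) {
  if (length(clusters) == 0L) {
    clusters$score <- numeric(0)
    return(clusters)
  }
  if (any(clusters$substrate_instances <= 0))
    stop("clusters must carry substrate instances to be scored")
  if (is.null(model)) model <- fit_score_model(clusters)
  if (is.null(model)) {
    clusters$score <- NA_real_
    return(clusters)
  }
  k <- clusters$edit_instances
  r <- clusters$substrate_instances - k
  score <- ifelse(r <= 0, 1, pnbinom(k, size = pmax(r, 1), 1 - model$p_bar))
  clusters$score <- score
  clusters
}

#' Window-size tuning efficiency score
#'
#' Balances the two competing demands of a good clustering: many edit
#' sites per cluster, and a small genomic footprint so cluster coordinates
#' stay precise. The default form is the ratio of the mean number of
#' distinct edited positions per cluster to the mean cluster length in bp.
#'
#' @param clusters Cluster `GRanges` (at least one).
#' @param variant `"ratio_of_means"` (default) or `"total_footprint"`
#'   (mean sites per cluster divided by the summed cluster length).
#' @return A non-negative number; higher is better.
#' @export
efficiency_score <- function(clusters,
                             variant = c("ratio_of_means",
                                         "total_footprint")) {
  variant <- match.arg(variant)
  if (length(clusters) == 0L)
    stop("efficiency score is undefined for zero clusters")
  sites <- mean(clusters$distinct_edited_positions)
  if (variant == "ratio_of_means")
    sites / mean(BiocGenerics::width(clusters))
  else
    sites / sum(BiocGenerics::width(clusters))
}

#' Intersect cluster sets across biological replicates
#'
#' A cluster from the first set is retained iff it overlaps (by at least
#' one base, on the same strand) at least one cluster in every other set.
#' Retained clusters keep their first-set coordinates and statistics.
#'
#' @param cluster_sets List of two or more cluster `GRanges`.
#' @return The filtered first set.
#' @export
intersect_replicates <- function(cluster_sets) {
  if (!is.list(cluster_sets) || length(cluster_sets) < 2L)
    stop("need at least two replicate cluster sets")
  first <- cluster_sets[[1]]
  keep <- rep(TRUE, length(first))
  for (other in cluster_sets[-1]) {
    keep <- keep & (GenomicRanges::countOverlaps(
      first, other, ignore.strand = FALSE) > 0L)
  }
  first[keep]
}

#' Per-cluster edit-fraction ratio between two conditions
#'
#' For clusters shared between conditions, computes the ratio of the mean
#' edit fraction across condition-A replicates to the mean across
#' condition-B replicates, and flags clusters whose shift is directionally
#' consistent (every A replicate on the same side of every B replicate).
#'
#' @param fractions_a,fractions_b Numeric matrices of cluster edit
#'   fractions, one row per shared cluster, one column per replicate.
#' @return `data.frame` with columns `ratio` (`NA` when the B mean is
#'   zero), `consistent` and `defined`.
#' @export
compare_conditions <- function(fractions_a, fractions_b) {
  fractions_a <- as.matrix(fractions_a); fractions_b <- as.matrix(fractions_b)
  if (nrow(fractions_a) != nrow(fractions_b))
    stop("condition matrices must describe the same clusters")
  mean_a <- rowMeans(fractions_a); mean_b <- rowMeans(fractions_b)
  defined <- mean_b > 0
  ratio <- ifelse(defined, mean_a / mean_b, NA_real_)
  lo_a <- apply(fractions_a, 1, min); hi_a <- apply(fractions_a, 1, max)
  lo_b <- apply(fractions_b, 1, min); hi_b <- apply(fractions_b, 1, max)
  consistent <- (hi_a < lo_b) | (lo_a > hi_b)
  data.frame(ratio = ratio, consistent = consistent, defined = defined)
}

#' Pooled edit fraction of arbitrary intervals in one sample
#'
#' Re-aggregates substrate and edit instances of a sample over fixed
#' intervals (typically shared clusters), for cross-condition comparison.
#'
#' @param intervals `GRanges` (strand used for substrate orientation).
#' @param sites,coverage,conversion,reference As in [aggregate_windows()].
#' @return Numeric vector of edit fractions, `NA` where an interval has no
#'   substrate.
#' @export
cluster_fractions <- function(intervals, sites, coverage, conversion,
                              reference) {
  if (length(intervals) == 0L) return(numeric(0))
  win <- granges_strip(intervals)
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(
    window_id = sprintf("iv_%d", seq_along(win)),
    gene_id = sprintf("iv_%d", seq_along(win)),
    region_class = "exon", index = seq_along(win))
  stats <- aggregate_windows(win, sites, coverage, conversion, reference)
  out <- rep(NA_real_, length(win))
  out[match(stats$window_id, win$window_id)] <- stats$edit_fraction
  out
}

#' Select, merge and score clusters in one call
#'
#' @param tests Tested windows from [test_windows()].
#' @param alpha Adjusted p-value threshold; default 0.1.
#' @param merge_distance Merge gap in bp; default 15.
#' @param score_threshold Optional score filter applied after scoring;
#'   `NULL` (default) keeps all clusters.
#' @return Scored cluster `GRanges`.
#' @export
call_clusters <- function(tests, alpha = 0.1, merge_distance = 15L,
                          score_threshold = NULL) {
  clusters <- score_clusters(
    merge_windows(select_windows(tests, alpha), merge_distance))
  if (!is.null(score_threshold) && length(clusters) > 0L)
    clusters <- clusters[!is.na(clusters$score) &
                           clusters$score >= score_threshold]
  clusters
}

#' Write clusters as BED6 plus statistics columns
#'
#' The BED score column mirrors the cluster score scaled to \[0, 1000\];
#' full-precision statistics follow in extra columns.
#'
#' @param clusters Scored cluster `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  score <- if (length(clusters)) clusters$score else numeric(0)
  bed_score <- ifelse(is.na(score), 0L, as.integer(round(score * 1000)))
  df <- granges_to_bed(
    clusters, name = clusters$cluster_id, score = bed_score,
    extra = data.frame(
      gene_id = clusters$gene_id, region_class = clusters$region_class,
      substrate_instances = clusters$substrate_instances,
      edit_instances = clusters$edit_instances,
      distinct_edited_positions = clusters$distinct_edited_positions,
      edit_fraction = clusters$edit_fraction,
      score = ifelse(is.na(score), NA, score),
      stringsAsFactors = FALSE))
  write_bed(df, path)
  invisible(path)
}
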