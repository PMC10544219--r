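#' Scan a reference for an IUPAC motif
#'
#' Matches an RNA or DNA motif (U is treated as T) on the requested
#' strand(s); minus-strand scanning searches the reverse complement on the
#' genomic forward sequence. Overlapping matches are all reported.
#'
#' @param reference Named `DNAStringSet` or FASTA path.
#' @param motif IUPAC string, e.g. `"GCAUG"`.
#' @param strands Character vector of strands to scan; default both.
#' @param regions Optional `GRanges`; matches are restricted to those
#'   overlapping these regions (strand-aware).
#' @return `GRanges` of motif matches with strand set.
#' @export
scan_motif <- function(reference, motif, strands = c("+", "-"),
                       regions = NULL) {
  reference <- load_reference(reference)
  motif <- chartr("Uu", "Tt", toupper(as.character(motif)))
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (nchar(motif) == 0L ||
      !all(strsplit(motif, "")[[1]] %in% iupac))
    stop("motif must be a non-empty IUPAC string")
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  out <- list()
  for (str in strands) {
    pat <- if (str == "-")
      Biostrings::reverseComplement(Biostrings::DNAString(motif))
    else Biostrings::DNAString(motif)
    hits <- Biostrings::vmatchPattern(pat, reference, fixed = FALSE)
    for (chrom in names(reference)) {
      ir <- hits[[chrom]]
      if (length(ir) == 0L) next
      out[[length(out) + 1L]] <-
        GenomicRanges::GRanges(chrom, ir, strand = str)
    }
  }
  gr <- if (length(out)) suppressWarnings(do.call(c, out)) else
    GenomicRanges::GRanges()
  if (!is.null(regions) && length(gr) > 0L)
    gr <- IRanges::subsetByOverlaps(gr, regions, ignore.strand = FALSE)
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Fraction of clusters overlapping a feature set
#'
#' @param clusters Cluster `GRanges`.
#' @param features Feature `GRanges` (e.g. eCLIP peaks, motif matches, or
#'   their union).
#' @param slop Symmetric extension of cluster bounds in bp before the
#'   overlap test; default 0.
#' @param ignore_strand Ignore strand when testing overlap; default
#'   `FALSE`.
#' @return Fraction in \[0, 1\] of clusters with at least 1 bp of overlap;
#'   0 when either set is empty.
#' @export
overlap_fraction <- function(clusters, features, slop = 0L,
                             ignore_strand = FALSE) {
  if (length(clusters) == 0L || length(features) == 0L) return(0)
  if (slop > 0L) {
    clusters <- GenomicRanges::trim(suppressWarnings(
      clusters + as.integer(slop)))
  }
  mean(GenomicRanges::countOverlaps(
    clusters, features, ignore.strand = ignore_strand) > 0L)
}

#' Shuffle-null enrichment of cluster/feature overlap
#'
#' Relocates every cluster to a uniformly random start within its parent
#' region (its host exon or intron), preserving length and strand, and
#' recomputes the feature-overlap fraction for each of `n_shuffles`
#' artificial cluster sets. Enrichment is the observed fraction divided by
#' the mean null fraction.
#'
#' @param clusters Cluster `GRanges`.
#' @param parents `GRanges` of candidate parent regions; each cluster is
#'   assigned the first parent that fully contains it. Clusters longer
#'   than every candidate parent stay in place, with a warning.
#' @param features Feature `GRanges`.
#' @param n_shuffles Number of artificial cluster sets; default 30.
#' @param seed Optional seed; the caller's RNG state is untouched.
#' @param slop,ignore_strand Passed to [overlap_fraction()].
#' @return Object of class `shuffle_null`: list with `observed`,
#'   `null_overlap_fractions`, `null_mean`, `null_sd`, `enrichment` (`NA`
#'   and flagged when undefined), `n_shuffles`, `seed`.
#' @export
shuffle_enrichment <- function(clusters, parents, features,
                               n_shuffles = 30L, seed = NULL, slop = 0L,
                               ignore_strand = FALSE) {
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 1L)
    stop("n_shuffles must be >= 1")
  observed <- overlap_fraction(clusters, features, slop, ignore_strand)
  hits <- GenomicRanges::findOverlaps(clusters, parents, type = "within",
                                      ignore.strand = TRUE)
  parent_of <- rep(NA_integer_, length(clusters))
  first <- !duplicated(S4Vectors::queryHits(hits))
  parent_of[S4Vectors::queryHits(hits)[first]] <-
    S4Vectors::subjectHits(hits)[first]
  if (anyNA(parent_of) && length(clusters) > 0L)
    warning(sum(is.na(parent_of)),
            " cluster(s) not contained in any parent region are kept in ",
            "place during shuffling")
  nulls <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      shuf <- clusters
      ok <- !is.na(parent_of)
      if (any(ok)) {
        pw <- BiocGenerics::width(parents)[parent_of[ok]]
        cw <- BiocGenerics::width(clusters)[ok]
        ps <- BiocGenerics::start(parents)[parent_of[ok]]
        new_start <- ps + floor(runif(sum(ok)) * (pw - cw + 1))
        r <- IRanges::ranges(shuf)
        r[ok] <- IRanges::IRanges(as.integer(new_start),
                                  width = cw)
        IRanges::ranges(shuf) <- r
      }
      overlap_fraction(shuf, features, slop, ignore_strand)
    }, numeric(1))
  })
  null_mean <- mean(nulls)
  enrichment <- if (observed > 0 && null_mean > 0)
    observed / null_mean else NA_real_
  structure(list(observed = observed, null_overlap_fractions = nulls,
                 null_mean = null_mean, null_sd = stats::sd(nulls),
                 enrichment = enrichment, n_shuffles = n_shuffles,
                 seed = seed),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat("Shuffle-null overlap enrichment\n")
  cat(sprintf("  observed overlap fraction: %.4f\n", x$observed))
  cat(sprintf("  null mean (sd) over %d shuffles: %.4f (%.4f)\n",
              x$n_shuffles, x$null_mean,
              ifelse(is.na(x$null_sd), 0, x$null_sd)))
  cat("  enrichment:",
      if (is.na(x$enrichment)) "undefined (no observed or null overlap)"
      else sprintf("%.3f", x$enrichment), "\n")
  invisible(x)
}

#' Read a BED6 feature file
#'
#' @param path BED file path (3 to 6 columns).
#' @return Sorted `GRanges` (strand `*` when absent).
#' @export
read_features_bed <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}
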