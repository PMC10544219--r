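#' Configuration for the synthetic dataset generator
#'
#' Describes a self-contained editing experiment: a random reference with
#' multi-exon genes on alternating strands, piecewise-constant read
#' coverage spanning all depth strata, uniform per-substrate background
#' editing, and planted high-rate foci that play the role of true
#' enzyme-deposition sites.
#'
#' @param n_genes Number of genes; default 40.
#' @param n_exons Exons per gene; default 3.
#' @param exon_length,intron_length Region lengths in bp; defaults 300/500.
#' @param intergenic_gap Unexpressed gap between genes in bp; default 200.
#' @param coverage_levels Depth levels of the per-tile coverage mixture;
#'   default `c(5, 15, 25, 35, 45, 80)` so every depth stratum of the
#'   default background model is populated.
#' @param coverage_probs Mixture weights; default uniform.
#' @param coverage_tile Width of constant-coverage tiles in bp; default 50.
#' @param background_rate Per-substrate probability of a spurious edit
#'   outside foci; default 0.001.
#' @param n_foci Number of planted foci; default 50.
#' @param focus_rate Per-substrate edit probability inside foci; default
#'   0.05.
#' @param focus_length Focus length in bp; default 60.
#' @param focus_coverage_levels Coverage levels used for tiles overlapping
#'   foci; default `c(35, 45, 80)` so planted signal is well covered.
#' @param conversion [conversion_spec()] or label; default `"C>T"`.
#' @param seed Optional integer seed for [generate_dataset()].
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 40L, n_exons = 3L,
                              exon_length = 300L, intron_length = 500L,
                              intergenic_gap = 200L,
                              coverage_levels = c(5, 15, 25, 35, 45, 80),
                              coverage_probs = NULL,
                              coverage_tile = 50L,
                              background_rate = 0.001,
                              n_foci = 50L, focus_rate = 0.05,
                              focus_length = 60L,
                              focus_coverage_levels = c(35, 45, 80),
                              conversion = "C>T", seed = NULL) {
  conversion <- parse_conversion(conversion)
  if (is.null(coverage_probs))
    coverage_probs <- rep(1 / length(coverage_levels),
                          length(coverage_levels))
  cfg <- list(n_genes = as.integer(n_genes), n_exons = as.integer(n_exons),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_gap = as.integer(intergenic_gap),
              coverage_levels = coverage_levels,
              coverage_probs = coverage_probs,
              coverage_tile = as.integer(coverage_tile),
              background_rate = background_rate,
              n_foci = as.integer(n_foci), focus_rate = focus_rate,
              focus_length = as.integer(focus_length),
              focus_coverage_levels = focus_coverage_levels,
              conversion = conversion, seed = seed)
  with(cfg, {
    stopifnot(n_genes >= 1, n_exons >= 1, exon_length >= 1,
              intron_length >= 1, coverage_tile >= 1,
              length(coverage_levels) == length(coverage_probs))
    if (!(background_rate >= 0 && background_rate < focus_rate &&
          focus_rate <= 1))
      stop("need 0 <= background_rate < focus_rate <= 1")
  })
  n_regions <- cfg$n_genes * (2L * cfg$n_exons - 1L)
  if (cfg$n_foci > n_regions)
    stop("n_foci exceeds the number of host regions (", n_regions, ")")
  min_host <- if (cfg$n_exons > 1L)
    min(cfg$exon_length, cfg$intron_length) else cfg$exon_length
  if (cfg$focus_length > min_host)
    stop("focus_length exceeds the shortest host region")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic editing dataset configuration\n")
  cat(sprintf("  %d genes (%d exons of %d bp, introns of %d bp)\n",
              x$n_genes, x$n_exons, x$exon_length, x$intron_length))
  cat(sprintf("  background rate %.4g, %d foci of %d bp at rate %.4g\n",
              x$background_rate, x$n_foci, x$focus_length, x$focus_rate))
  cat("  coverage levels:", paste(x$coverage_levels, collapse = ", "),
      "per", x$coverage_tile, "bp tile;", x$conversion$label,
      "conversion\n")
  invisible(x)
}

#' Generate a synthetic editing dataset
#'
#' Builds reference, annotation, per-base coverage, strand-resolved edit
#' sites and truth foci with the statistical structure the background model
#' assumes: every editable position with coverage `c` receives
#' `Binomial(c, rate)` edited reads, where `rate` is the focus rate inside
#' planted foci and the background rate elsewhere. Positions with at least
#' one edited read become edit sites. All outputs are mutually consistent
#' (site totals equal coverage) and deterministic under the configured
#' seed.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; when given, `reference.fa`,
#'   `genes.gtf`, `coverage.bedGraph`, `sites.bed` and `foci.bed` are
#'   written there.
#' @return List of class `sim_dataset` with elements `reference`
#'   (`DNAStringSet`), `models` (`gene_models`), `coverage` (`RleList`),
#'   `sites` (`GRanges`), `foci` (`GRanges`), `config` and, when written,
#'   `paths`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ds <- with_seed(config$seed, generate_dataset_impl(config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      reference = file.path(dir, "reference.fa"),
      annotation = file.path(dir, "genes.gtf"),
      coverage = file.path(dir, "coverage.bedGraph"),
      sites = file.path(dir, "sites.bed"),
      foci = file.path(dir, "foci.bed"))
    Biostrings::writeXStringSet(ds$reference, paths$reference)
    write_gtf(ds$models, paths$annotation)
    write_bedgraph(ds$coverage, paths$coverage)
    write_edit_sites(ds$sites, paths$sites)
    write_bed(granges_to_bed(ds$foci,
                             name = sprintf("focus_%d", seq_along(ds$foci)),
                             score = 0),
              paths$foci)
    ds$paths <- paths
  }
  ds
}

## length-safe single draw (sample() treats a length-1 x as 1:x)
sample_one <- function(x, prob = NULL) {
  if (length(x) == 1L) x else sample(x, 1L, prob = prob)
}

generate_dataset_impl <- function(config) {
  chrom <- "chrS"
  glen <- config$n_exons * config$exon_length +
    (config$n_exons - 1L) * config$intron_length
  gap <- config$intergenic_gap
  gene_starts <- gap + (seq_len(config$n_genes) - 1L) * (glen + gap) + 1L
  total_len <- config$n_genes * (glen + gap) + gap
  seqchars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  reference <- Biostrings::DNAStringSet(
    setNames(paste(seqchars, collapse = ""), chrom))

  strands <- rep(c("+", "-"), length.out = config$n_genes)
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(gene_starts, width = glen), strand = strands,
    gene_id = gene_ids)
  names(genes) <- gene_ids

  exon_list <- vector("list", config$n_genes)
  region_list <- list()        # all exons+introns, focus host candidates
  for (i in seq_len(config$n_genes)) {
    offs <- gene_starts[i] +
      (seq_len(config$n_exons) - 1L) *
      (config$exon_length + config$intron_length)
    ex <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(offs, width = config$exon_length),
      strand = strands[i])
    exon_list[[i]] <- ex
    regs <- ex
    if (config$n_exons > 1L) {
      ints <- GenomicRanges::GRanges(
        chrom,
        IRanges::IRanges(offs[-config$n_exons] + config$exon_length,
                         width = config$intron_length),
        strand = strands[i])
      regs <- c(ex, ints)
    }
    region_list[[i]] <- regs
  }
  exons <- GenomicRanges::GRangesList(exon_list)
  names(exons) <- gene_ids
  models <- structure(list(genes = genes, exons = exons),
                      class = "gene_models")
  hosts <- suppressWarnings(do.call(c, region_list))

  ## plant foci in distinct host regions
  foci <- GenomicRanges::GRanges()
  if (config$n_foci > 0L) {
    pick <- sort(sample(length(hosts), config$n_foci))
    host <- hosts[pick]
    off <- floor(runif(config$n_foci) *
                   (BiocGenerics::width(host) - config$focus_length + 1))
    foci <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(BiocGenerics::start(host) + as.integer(off),
                       width = config$focus_length),
      strand = BiocGenerics::strand(host))
  }

  ## piecewise-constant coverage over gene bodies
  covv <- numeric(total_len)
  focus_mask <- rep(FALSE, total_len)
  if (length(foci) > 0L)
    for (i in seq_along(foci))
      focus_mask[BiocGenerics::start(foci)[i]:BiocGenerics::end(foci)[i]] <-
        TRUE
  for (i in seq_len(config$n_genes)) {
    s <- gene_starts[i]; e <- s + glen - 1L
    tile_starts <- seq(s, e, by = config$coverage_tile)
    for (ts in tile_starts) {
      te <- min(ts + config$coverage_tile - 1L, e)
      lev <- if (any(focus_mask[ts:te]))
        sample_one(config$focus_coverage_levels)
      else
        sample_one(config$coverage_levels, config$coverage_probs)
      covv[ts:te] <- lev
    }
  }
  coverage <- IRanges::RleList(S4Vectors::Rle(as.integer(covv)))
  names(coverage) <- chrom

  ## binomial edits at editable positions within genes
  conv <- config$conversion
  site_pos <- integer(0); site_edit <- integer(0); site_tot <- integer(0)
  site_strand <- character(0)
  for (i in seq_len(config$n_genes)) {
    s <- gene_starts[i]; e <- s + glen - 1L
    base <- if (strands[i] == "-") complement_base(conv$ref_base) else
      conv$ref_base
    pos <- s - 1L + which(seqchars[s:e] == base)
    if (length(pos) == 0L) next
    cov_here <- covv[pos]
    rate <- ifelse(focus_mask[pos], config$focus_rate,
                   config$background_rate)
    edited <- rbinom(length(pos), size = cov_here, prob = rate)
    hit <- edited >= 1L & cov_here > 0
    if (!any(hit)) next
    site_pos <- c(site_pos, pos[hit])
    site_edit <- c(site_edit, edited[hit])
    site_tot <- c(site_tot, as.integer(cov_here[hit]))
    site_strand <- c(site_strand, rep(strands[i], sum(hit)))
  }
  sites <- if (length(site_pos)) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(site_pos, width = 1L), strand = site_strand,
    edited_reads = site_edit, total_reads = site_tot,
    confidence = rep(1, length(site_pos)))
  else empty_sites()
  sites <- BiocGenerics::sort(sites, ignore.strand = TRUE)

  structure(list(reference = reference, models = models,
                 coverage = coverage, sites = sites, foci = foci,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic editing dataset:", length(x$models$genes), "genes,",
      length(x$sites), "edit sites,", length(x$foci), "planted foci\n")
  invisible(x)
}

write_gtf <- function(models, path) {
  lines <- character(0)
  for (i in seq_along(models$genes)) {
    g <- models$genes[i]; gid <- names(models$genes)[i]
    str <- as.character(BiocGenerics::strand(g))
    attr_g <- sprintf('gene_id "%s";', gid)
    lines <- c(lines, paste(
      as.character(GenomeInfoDb::seqnames(g)), "editclust", "gene",
      BiocGenerics::start(g), BiocGenerics::end(g), ".", str, ".",
      attr_g, sep = "\t"))
    ex <- models$exons[[i]]
    for (j in seq_along(ex)) {
      attr_e <- sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
      lines <- c(lines, paste(
        as.character(GenomeInfoDb::seqnames(ex[j])), "editclust", "exon",
        BiocGenerics::start(ex[j]), BiocGenerics::end(ex[j]), ".", str,
        ".", attr_e, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_bedgraph <- function(coverage, path) {
  lines <- character(0)
  for (chrom in names(coverage)) {
    rle <- coverage[[chrom]]
    ends <- cumsum(S4Vectors::runLength(rle))
    starts <- c(0L, head(ends, -1L))
    vals <- S4Vectors::runValue(rle)
    keep <- vals != 0
    lines <- c(lines, paste(chrom, starts[keep], ends[keep], vals[keep],
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Emit a minimal SAM file consistent with a synthetic dataset
#'
#' For every constant-coverage tile within a gene, emits `coverage`
#' identical-span reads on the gene's strand, then distributes each edited
#' position's edited reads over distinct read indices so that per-position
#' pileup counts reproduce the dataset's site table exactly. Intended for
#' exercising the alignment pileup path on small inputs.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param path Output SAM path.
#' @param seed Seed controlling which reads carry each edit; default 1.
#' @return `path`, invisibly.
#' @export
write_synthetic_sam <- function(dataset, path, seed = 1L) {
  cfg <- dataset$config
  chrom <- names(dataset$reference)[1]
  refchars <- strsplit(as.character(dataset$reference[[1]]), "",
                       fixed = TRUE)[[1]]
  genes <- dataset$models$genes
  sites <- dataset$sites
  spos <- BiocGenerics::start(sites)
  conv <- cfg$conversion
  covrle <- dataset$coverage[[chrom]]
  records <- list()
  with_seed(seed, {
    for (i in seq_along(genes)) {
      gs <- BiocGenerics::start(genes)[i]; ge <- BiocGenerics::end(genes)[i]
      str <- as.character(BiocGenerics::strand(genes))[i]
      alt <- if (str == "-") complement_base(conv$alt_base) else
        conv$alt_base
      flag <- if (str == "-") 16L else 0L
      tile_starts <- seq(gs, ge, by = cfg$coverage_tile)
      for (ts in tile_starts) {
        te <- min(ts + cfg$coverage_tile - 1L, ge)
        c0 <- as.integer(covrle[ts])
        if (c0 == 0L) next
        seqs <- matrix(rep(refchars[ts:te], c0), nrow = c0, byrow = TRUE)
        in_tile <- which(spos >= ts & spos <= te)
        for (k in in_tile) {
          ridx <- sample.int(c0, sites$edited_reads[k])
          seqs[ridx, spos[k] - ts + 1L] <- alt
        }
        qual <- strrep("I", te - ts + 1L)
        cig <- paste0(te - ts + 1L, "M")
        for (r in seq_len(c0)) {
          records[[length(records) + 1L]] <- paste(
            sprintf("read_%d_%d_%d", i, ts, r), flag, chrom, ts, 60L,
            cig, "*", 0L, 0L, paste(seqs[r, ], collapse = ""), qual,
            sep = "\t")
        }
      }
    }
  })
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, length(refchars)))
  writeLines(c(header, unlist(records)), path)
  invisible(path)
}

#' Precision, recall and F1 of called clusters against truth foci
#'
#' A truth focus is recovered when at least one called cluster overlaps it
#' by at least one base; a called cluster is a true positive when it
#' overlaps any focus. With zero called clusters, precision is reported as
#' 1 with a `zero_calls` flag.
#'
#' @param called Cluster `GRanges`.
#' @param truth Truth foci `GRanges`.
#' @param ignore_strand Ignore strand in the overlap test; default `FALSE`.
#' @return List with `precision`, `recall`, `f1`, `n_called`, `n_truth`,
#'   `zero_calls`.
#' @export
evaluate_recovery <- function(called, truth, ignore_strand = FALSE) {
  n_called <- length(called); n_truth <- length(truth)
  zero_calls <- n_called == 0L
  tp <- if (zero_calls) 0L else
    sum(GenomicRanges::countOverlaps(called, truth,
                                     ignore.strand = ignore_strand) > 0L)
  recovered <- if (n_truth == 0L) 0L else
    sum(GenomicRanges::countOverlaps(truth, called,
                                     ignore.strand = ignore_strand) > 0L)
  precision <- if (zero_calls) 1 else tp / n_called
  recall <- if (n_truth == 0L) NA_real_ else recovered / n_truth
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_called = n_called, n_truth = n_truth, zero_calls = zero_calls)
}
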