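#' Read a strand-resolved per-site edit table
#'
#' Parses a SAILOR-style BED6 dialect in which the name column holds
#' `"edited_reads,total_reads"` and the score column a confidence in
#' \[0,1\]. Coordinates are converted from BED (0-based half-open) to
#' 1-based positions.
#'
#' @param path Path to the site table.
#' @param min_confidence Sites below this confidence are dropped before
#'   aggregation; default 0 (keep everything, as all candidate sites are
#'   meant to face the Poisson filter).
#' @return `GRanges` of width-1 sites sorted by (chromosome, position),
#'   with metadata columns `edited_reads`, `total_reads`, `confidence`.
#' @export
read_edit_sites <- function(path, min_confidence = 0) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("malformed site table '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (is.null(df) || nrow(df) == 0L) return(empty_sites())
  counts <- strsplit(df$name, ",", fixed = TRUE)
  bad_len <- lengths(counts) != 2L
  if (any(bad_len))
    stop("site table line ", which(bad_len)[1],
         ": name field must be 'edited_reads,total_reads'")
  m <- matrix(suppressWarnings(as.numeric(unlist(counts))),
              ncol = 2L, byrow = TRUE)
  if (anyNA(m) || any(m != floor(m)))
    stop("site table line ", which(is.na(m[, 1]) | is.na(m[, 2]) |
                                   m[, 1] != floor(m[, 1]) |
                                   m[, 2] != floor(m[, 2]))[1],
         ": non-integer read counts")
  edited <- as.integer(m[, 1]); total <- as.integer(m[, 2])
  if (any(edited < 1L))
    stop("site table line ", which(edited < 1L)[1],
         ": sites must carry at least one edited read")
  if (any(edited > total))
    stop("site table line ", which(edited > total)[1],
         ": edited_reads exceeds total_reads")
  if (any(df$score < 0 | df$score > 1))
    stop("confidence values must lie in [0, 1]")
  sites <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
    edited_reads = edited, total_reads = total, confidence = df$score)
  if (any(BiocGenerics::width(sites) != 1L))
    stop("edit sites must be single positions")
  sites <- sites[sites$confidence >= min_confidence]
  BiocGenerics::sort(sites, ignore.strand = TRUE)
}

empty_sites <- function() {
  GenomicRanges::GRanges(edited_reads = integer(0), total_reads = integer(0),
                         confidence = numeric(0))
}

#' Write an edit-site table in the package's BED6 dialect
#'
#' @param sites `GRanges` as returned by [read_edit_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edit_sites <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# name = edited_reads,total_reads; score = confidence", con)
  df <- granges_to_bed(
    sites, name = paste(sites$edited_reads, sites$total_reads, sep = ","),
    score = sites$confidence)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base coverage track from a bedGraph file
#'
#' @param path Path to a bedGraph (`chrom start end value`, 0-based
#'   half-open).
#' @return A per-chromosome `RleList` of integer coverage.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}

coverage_at <- function(coverage, chrom, pos) {
  if (!chrom %in% names(coverage)) return(rep(0, length(pos)))
  rle <- coverage[[chrom]]
  out <- rep(0, length(pos))
  ok <- pos >= 1L & pos <= length(rle)
  out[ok] <- as.numeric(rle[pos[ok]])
  out
}

#' Aggregate per-window edit and substrate instances from sites + coverage
#'
#' For every window, substrate instances are counted at read level: the sum,
#' over window positions whose transcript-oriented reference base equals the
#' conversion's source base, of the read coverage at that position. For
#' minus-strand windows the genomic base compared is the complement of the
#' source base. Edit instances are the summed `edited_reads` of
#' strand-matched sites inside the window.
#'
#' @param windows `GRanges` from [make_windows()].
#' @param sites `GRanges` from [read_edit_sites()].
#' @param coverage `RleList` from [read_coverage()], or a list with
#'   elements `"+"` and `"-"` of such tracks for strand-resolved coverage.
#' @param conversion A [conversion_spec()] (or label like `"C>T"`).
#' @param reference A named `DNAStringSet`, or path to a FASTA file.
#' @return A `data.frame` of per-window statistics with columns
#'   `window_id`, `chrom`, `start`, `end` (1-based, closed), `strand`,
#'   `gene_id`, `region_class`, `substrate_instances`, `edit_instances`,
#'   `distinct_edited_positions`, `read_depth` (floor of mean per-base
#'   coverage) and `edit_fraction`. Only windows with at least one substrate
#'   instance are emitted; windows with zero edits remain (they are skipped
#'   later by the zero-truncated test but may inform rate estimation).
#' @details Sites falling at positions with zero recorded coverage raise a
#'   validation error; sites whose reference base does not match the
#'   conversion's editable base on their strand are dropped with a warning.
#' @export
aggregate_windows <- function(windows, sites, coverage, conversion,
                              reference) {
  conversion <- parse_conversion(conversion)
  reference <- load_reference(reference)
  if (length(windows) == 0L) return(empty_window_stats())

  ## validate sites against coverage and reference
  if (length(sites) > 0L) {
    chr <- as.character(GenomeInfoDb::seqnames(sites))
    pos <- BiocGenerics::start(sites)
    covs <- vapply(seq_along(sites), function(i)
      coverage_at(strand_coverage(coverage,
                                  as.character(BiocGenerics::strand(sites))[i]),
                  chr[i], pos[i]), numeric(1))
    if (any(covs <= 0))
      stop("edit site at ", chr[which(covs <= 0)[1]], ":",
           pos[which(covs <= 0)[1]],
           " has zero recorded coverage")
    want <- ifelse(as.character(BiocGenerics::strand(sites)) == "-",
                   complement_base(conversion$ref_base),
                   conversion$ref_base)
    have <- reference_base_at(reference, chr, pos)
    mism <- have != want
    if (any(mism)) {
      warning(sum(mism), " site(s) at positions whose reference base does ",
              "not match the ", conversion$label,
              " conversion were ignored")
      sites <- sites[!mism]
    }
  }

  n <- length(windows)
  substrate <- numeric(n); depth <- numeric(n)
  wchr <- as.character(GenomeInfoDb::seqnames(windows))
  wstr <- as.character(BiocGenerics::strand(windows))
  wstart <- BiocGenerics::start(windows); wend <- BiocGenerics::end(windows)
  for (chrom in unique(wchr)) {
    if (!chrom %in% names(reference))
      stop("contig '", chrom, "' absent from the reference")
    seqchars <- strsplit(as.character(reference[[chrom]]), "", fixed = TRUE)[[1]]
    for (str in c("+", "-")) {
      sel <- which(wchr == chrom & wstr == str)
      if (length(sel) == 0L) next
      base <- if (str == "-") complement_base(conversion$ref_base) else
        conversion$ref_base
      ind <- as.numeric(seqchars == base)
      cov <- strand_coverage(coverage, str)
      covv <- if (chrom %in% names(cov))
        as.numeric(cov[[chrom]]) else numeric(0)
      len <- length(seqchars)
      covv <- c(covv, numeric(max(0L, len - length(covv))))[seq_len(len)]
      cs_sub <- cumsum(covv * ind)
      cs_cov <- cumsum(covv)
      s <- wstart[sel]; e <- pmin(wend[sel], len)
      substrate[sel] <- cs_sub[e] - ifelse(s > 1L, cs_sub[s - 1L], 0)
      depth[sel] <- floor((cs_cov[e] - ifelse(s > 1L, cs_cov[s - 1L], 0)) /
                            (wend[sel] - wstart[sel] + 1L))
    }
  }

  edits <- integer(n); npos <- integer(n)
  if (length(sites) > 0L) {
    hits <- GenomicRanges::findOverlaps(sites, windows, ignore.strand = FALSE)
    if (length(hits) > 0L) {
      tab <- tapply(sites$edited_reads[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), sum)
      edits[as.integer(names(tab))] <- as.integer(tab)
      cnt <- table(S4Vectors::subjectHits(hits))
      npos[as.integer(names(cnt))] <- as.integer(cnt)
    }
  }

  keep <- substrate > 0
  stats <- data.frame(
    window_id = windows$window_id, chrom = wchr, start = wstart,
    end = wend, strand = wstr, gene_id = windows$gene_id,
    region_class = windows$region_class,
    substrate_instances = substrate, edit_instances = edits,
    distinct_edited_positions = npos, read_depth = as.integer(depth),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(stats) <- NULL
  stats$edit_fraction <- stats$edit_instances / stats$substrate_instances
  if (any(stats$edit_instances > stats$substrate_instances))
    warning("some windows carry more edit than substrate instances; ",
            "check that coverage and site table describe the same sample")
  stats
}

empty_window_stats <- function() {
  data.frame(window_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             gene_id = character(0), region_class = character(0),
             substrate_instances = numeric(0), edit_instances = integer(0),
             distinct_edited_positions = integer(0),
             read_depth = integer(0), edit_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

strand_coverage <- function(coverage, strand) {
  if (methods::is(coverage, "RleList") || methods::is(coverage, "SimpleList"))
    return(coverage)
  if (is.list(coverage) && all(c("+", "-") %in% names(coverage)))
    return(coverage[[strand]])
  stop("coverage must be an RleList or a list with elements '+' and '-'")
}

load_reference <- function(reference) {
  if (is.character(reference)) {
    if (!file.exists(reference))
      stop("reference FASTA not found: ", reference)
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
  }
  stopifnot(methods::is(reference, "DNAStringSet"))
  reference
}

reference_base_at <- function(reference, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    if (!chrom[i] %in% names(reference))
      stop("contig '", chrom[i], "' absent from the reference")
    as.character(Biostrings::subseq(reference[[chrom[i]]], pos[i], pos[i]))
  }, character(1))
}

#' Tabulate substrate and edit instances directly from aligned reads
#'
#' The pileup path: substrate instances are read bases covering positions
#' whose transcript-oriented reference base equals the conversion's source
#' base, counting only reads aligned on the window's strand; edit instances
#' are read bases equal to the conversion's product base at those
#' positions. On identical inputs this agrees exactly with
#' [aggregate_windows()] fed a coverage track and site table derived from
#' the same alignments.
#'
#' @param alignments Path to a coordinate-sorted SAM or BAM file.
#' @param reference Named `DNAStringSet` or FASTA path.
#' @param conversion A [conversion_spec()] or label.
#' @param windows `GRanges` from [make_windows()].
#' @return A `data.frame` with the same columns as [aggregate_windows()].
#' @export
pileup_substrates <- function(alignments, reference, conversion, windows) {
  conversion <- parse_conversion(conversion)
  reference <- load_reference(reference)
  bam <- as_bam(alignments)
  pp <- Rsamtools::PileupParam(
    max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  n <- length(windows)
  substrate <- numeric(n); edits <- integer(n); npos <- integer(n)
  depth <- numeric(n)
  wchr <- as.character(GenomeInfoDb::seqnames(windows))
  wstr <- as.character(BiocGenerics::strand(windows))
  pchr <- as.character(p$seqnames); pstr <- as.character(p$strand)
  for (i in seq_len(n)) {
    if (!wchr[i] %in% names(reference))
      stop("contig '", wchr[i], "' absent from the reference")
    sel <- pchr == wchr[i] & pstr == wstr[i] &
      p$pos >= BiocGenerics::start(windows[i]) &
      p$pos <= BiocGenerics::end(windows[i])
    sub <- p[sel, , drop = FALSE]
    depth[i] <- floor(sum(sub$count) / BiocGenerics::width(windows[i]))
    if (nrow(sub) == 0L) next
    ref_base <- if (wstr[i] == "-")
      complement_base(conversion$ref_base) else conversion$ref_base
    alt_base <- if (wstr[i] == "-")
      complement_base(conversion$alt_base) else conversion$alt_base
    upos <- unique(sub$pos)
    bases <- reference_base_at(reference, rep(wchr[i], length(upos)), upos)
    editable <- upos[bases == ref_base]
    at <- sub[sub$pos %in% editable, , drop = FALSE]
    substrate[i] <- sum(at$count)
    ed <- at[as.character(at$nucleotide) == alt_base, , drop = FALSE]
    edits[i] <- sum(ed$count)
    npos[i] <- length(unique(ed$pos))
  }
  keep <- substrate > 0
  stats <- data.frame(
    window_id = windows$window_id, chrom = wchr,
    start = BiocGenerics::start(windows), end = BiocGenerics::end(windows),
    strand = wstr, gene_id = windows$gene_id,
    region_class = windows$region_class,
    substrate_instances = substrate, edit_instances = edits,
    distinct_edited_positions = npos, read_depth = as.integer(depth),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(stats) <- NULL
  stats$edit_fraction <- stats$edit_instances / stats$substrate_instances
  stats
}

as_bam <- function(alignments) {
  if (grepl("\\.bam$", alignments, ignore.case = TRUE)) {
    if (!file.exists(paste0(alignments, ".bai")))
      Rsamtools::indexBam(alignments)
    return(alignments)
  }
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(alignments, dest, overwrite = TRUE,
                   indexDestination = TRUE)
}

#' Write / read the per-window statistics table
#'
#' Tab-delimited with a header; coordinates are 1-based and closed as in
#' the in-memory representation.
#'
#' @param stats A window-stats `data.frame` from [aggregate_windows()].
#' @param path File path.
#' @return `path` (write) or the `data.frame` (read).
#' @export
write_window_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
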