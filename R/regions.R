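#' Parse gene models from a Gencode-style GTF
#'
#' Reads `gene` and `exon` features, unions exons across transcripts of the
#' same gene, and returns one model per `gene_id`. Genes are ordered by
#' (chromosome, start, gene_id) so downstream output is deterministic.
#'
#' @param path Path to a GTF file with `gene_id "..."` attributes.
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{`GRanges` of gene spans, named by gene_id.}
#'     \item{exons}{`GRangesList` of unioned exons, parallel to `genes`.}
#'   }
#' @details Exons of one gene must share its chromosome and strand and lie
#'   within the gene span; violations raise an error naming the gene. Genes
#'   without exon records use their full span as a single exon.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 100L)
  if (length(first) < 100L &&
      !any(nzchar(first) & !startsWith(first, "#"))) {
    return(structure(list(genes = GenomicRanges::GRanges(),
                          exons = GenomicRanges::GRangesList()),
                     class = "gene_models"))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) {
    return(structure(list(genes = GenomicRanges::GRanges(),
                          exons = GenomicRanges::GRangesList()),
                     class = "gene_models"))
  }
  if (is.null(gr$gene_id)) stop("GTF has no gene_id attributes")
  type <- as.character(gr$type)
  genes_gr <- gr[type == "gene"]
  exons_gr <- gr[type == "exon"]
  if (length(genes_gr) == 0L && length(exons_gr) == 0L)
    stop("GTF contains neither gene nor exon features")

  ## gene spans: explicit gene rows, else the exon hull per gene_id
  if (length(genes_gr) == 0L) {
    sp <- S4Vectors::split(exons_gr, exons_gr$gene_id)
    genes_gr <- unlist(range(sp), use.names = FALSE)
    genes_gr$gene_id <- names(sp)
  }
  if (anyDuplicated(genes_gr$gene_id))
    stop("duplicated gene feature for gene_id: ",
         genes_gr$gene_id[duplicated(genes_gr$gene_id)][1])
  ord <- order(as.character(GenomeInfoDb::seqnames(genes_gr)),
               BiocGenerics::start(genes_gr),
               genes_gr$gene_id)
  genes_gr <- genes_gr[ord]
  names(genes_gr) <- genes_gr$gene_id

  exn <- S4Vectors::split(exons_gr,
                          factor(exons_gr$gene_id, levels = names(genes_gr)))
  exn <- GenomicRanges::reduce(exn)   # union across transcripts
  ## genes lacking exon rows: whole span is exonic
  empty <- S4Vectors::elementNROWS(exn) == 0L
  if (any(empty)) {
    filler <- S4Vectors::split(granges_strip(genes_gr[empty]),
                               seq_len(sum(empty)))
    names(filler) <- names(genes_gr)[empty]
    exn[empty] <- filler
  }
  validate_gene_models(genes_gr, exn)
  structure(list(genes = genes_gr, exons = exn), class = "gene_models")
}

granges_strip <- function(gr) {
  GenomicRanges::granges(gr)
}

validate_gene_models <- function(genes, exons) {
  for (i in seq_along(genes)) {
    g <- genes[i]
    e <- exons[[i]]
    if (length(e) == 0L) next
    same_chr <- all(as.character(GenomeInfoDb::seqnames(e)) ==
                    as.character(GenomeInfoDb::seqnames(g)))
    inside <- all(BiocGenerics::start(e) >= BiocGenerics::start(g) &
                  BiocGenerics::end(e) <= BiocGenerics::end(g))
    if (!same_chr || !inside)
      stop("exon outside gene span for gene ", names(genes)[i])
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", length(x$genes), "genes,",
      sum(S4Vectors::elementNROWS(x$exons)), "unioned exons\n")
  invisible(x)
}

#' Derive introns as the within-gene complement of the exon union
#'
#' @param models A `gene_models` object from [read_gene_models()].
#' @return A `GRangesList` of introns parallel to `models$genes`; genes
#'   whose exon union covers their span get zero introns.
#' @export
derive_introns <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  spans <- granges_strip(models$genes)
  introns <- GenomicRanges::psetdiff(
    spans, methods::as(models$exons, "GRangesList"))
  names(introns) <- names(models$genes)
  introns
}

#' Tile regions into fixed-size windows
#'
#' Each region is split left-to-right (genomic orientation, regardless of
#' strand) into consecutive windows of `window_size` base pairs; a shorter
#' remainder window is kept at the region's right edge.
#'
#' @param regions `GRanges` of regions to tile (one gene, one region class).
#' @param region_class `"exon"` or `"intron"`.
#' @param gene_id Gene identifier used in window ids.
#' @param window_size Window width in bp; default 30.
#' @return `GRanges` of windows with metadata columns `window_id`
#'   (`gene_id:region_class:index`), `gene_id`, `region_class` and `index`
#'   (1-based ordinal within gene and class, increasing along the genome).
#' @export
tile_windows <- function(regions, region_class, gene_id, window_size = 30L) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("window_size must be >= 1")
  region_class <- match.arg(region_class, c("exon", "intron"))
  if (length(regions) == 0L) {
    w <- GenomicRanges::GRanges()
    S4Vectors::mcols(w) <- S4Vectors::DataFrame(
      window_id = character(0), gene_id = character(0),
      region_class = character(0), index = integer(0))
    return(w)
  }
  regions <- BiocGenerics::sort(regions)
  win <- unlist(GenomicRanges::slidingWindows(
    regions, width = window_size, step = window_size), use.names = FALSE)
  win <- BiocGenerics::sort(win)
  idx <- seq_along(win)
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(
    window_id = sprintf("%s:%s:%d", gene_id, region_class, idx),
    gene_id = gene_id, region_class = region_class, index = idx)
  win
}

#' Tile all genes of an annotation into exon and intron windows
#'
#' @param models A `gene_models` object, or a path to a GTF file.
#' @param window_size Window width in bp; default 30.
#' @return `GRanges` of windows for every gene and both region classes
#'   (introns only where present), sorted by (chromosome, start), with the
#'   metadata columns of [tile_windows()]. Window strand is the gene strand.
#' @export
make_windows <- function(models, window_size = 30L) {
  if (is.character(models)) models <- read_gene_models(models)
  stopifnot(inherits(models, "gene_models"))
  introns <- derive_introns(models)
  out <- vector("list", 2L * length(models$genes))
  k <- 0L
  for (i in seq_along(models$genes)) {
    gid <- names(models$genes)[i]
    str <- as.character(BiocGenerics::strand(models$genes[i]))
    ex <- models$exons[[i]]
    BiocGenerics::strand(ex) <- str
    k <- k + 1L
    out[[k]] <- tile_windows(ex, "exon", gid, window_size)
    int <- introns[[i]]
    if (length(int) > 0L) {
      BiocGenerics::strand(int) <- str
      k <- k + 1L
      out[[k]] <- tile_windows(int, "intron", gid, window_size)
    }
  }
  win <- suppressWarnings(do.call(c, out[seq_len(k)]))
  BiocGenerics::sort(win, ignore.strand = TRUE)
}

#' Write windows as BED6 + gene_id + region_class
#'
#' Coordinates are converted to BED's 0-based half-open convention; the
#' name column carries the window id.
#'
#' @param windows `GRanges` from [make_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  df <- granges_to_bed(
    windows, name = windows$window_id, score = 0,
    extra = data.frame(gene_id = windows$gene_id,
                       region_class = windows$region_class,
                       stringsAsFactors = FALSE))
  write_bed(df, path)
  invisible(path)
}

#' Read windows written by [write_windows_bed()]
#'
#' @param path Path to the 8-column windows BED.
#' @return `GRanges` with the same metadata columns as [make_windows()].
#' @export
read_windows_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name",
                                 "score", "strand", "gene_id",
                                 "region_class"))
  win <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = df$strand)
  idx <- as.integer(sub(".*:", "", df$name))
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(
    window_id = df$name, gene_id = df$gene_id,
    region_class = df$region_class, index = idx)
  win
}
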