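## Independent reference implementations used to check the package's
## statistical routines. These deliberately use naive direct computation.

# direct pmf summation for the zero-truncated Poisson upper tail
ztp_oracle <- function(k, lambda) {
  kmax <- max(k + 200, ceiling(lambda + 40 * sqrt(lambda) + 200))
  sum(dpois(seq(k, kmax), lambda)) / (1 - exp(-lambda))
}

# brute-force Benjamini-Hochberg step-up adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# transitive-closure merge of intervals keyed by gene/class, gap tolerance d
merge_oracle <- function(df, d) {
  out <- list()
  for (key in unique(paste(df$gene_id, df$region_class))) {
    sub <- df[paste(df$gene_id, df$region_class) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    groups <- list()
    cur <- sub[1, , drop = FALSE]
    cur_end <- sub$end[1]
    cur_rows <- 1L
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - cur_end - 1 <= d) {
        cur_end <- max(cur_end, sub$end[i])
        cur_rows <- c(cur_rows, i)
      } else {
        groups[[length(groups) + 1L]] <-
          list(start = min(sub$start[cur_rows]), end = cur_end,
               n = length(cur_rows),
               substrate = sum(sub$substrate_instances[cur_rows]),
               edits = sum(sub$edit_instances[cur_rows]))
        cur_rows <- i
        cur_end <- sub$end[i]
      }
    }
    groups[[length(groups) + 1L]] <-
      list(start = min(sub$start[cur_rows]), end = cur_end,
           n = length(cur_rows),
           substrate = sum(sub$substrate_instances[cur_rows]),
           edits = sum(sub$edit_instances[cur_rows]))
    out[[key]] <- groups
  }
  out
}

# random non-overlapping window set in stats-table form
random_window_set <- function(n, gene_id = "g", region_class = "exon",
                              chrom = "chr1", strand = "+") {
  starts <- sort(sample.int(2000, n))
  widths <- sample(5:30, n, replace = TRUE)
  ends <- starts + widths - 1L
  # enforce non-overlap by pushing starts right
  for (i in seq_len(n)[-1]) {
    if (starts[i] <= ends[i - 1]) {
      shift <- ends[i - 1] - starts[i] + 1L + sample.int(40, 1)
      starts[i] <- starts[i] + shift
      ends[i] <- ends[i] + shift
    }
  }
  data.frame(window_id = sprintf("%s:%s:%d", gene_id, region_class,
                                 seq_len(n)),
             chrom = chrom, start = starts, end = ends, strand = strand,
             gene_id = gene_id, region_class = region_class,
             substrate_instances = sample(20:400, n, replace = TRUE),
             edit_instances = sample(1:20, n, replace = TRUE),
             distinct_edited_positions = sample(1:5, n, replace = TRUE),
             read_depth = sample(5:80, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# naive per-position tabulation over windows (position loop; no cumsum)
brute_force_window_stats <- function(windows, sites, coverage, conversion,
                                     reference) {
  conversion <- editclust::parse_conversion(conversion)
  seqs <- lapply(as.list(as.character(reference)), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  res <- lapply(seq_along(windows), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(windows[i]))
    str <- as.character(BiocGenerics::strand(windows[i]))
    base <- if (str == "-") chartr("ACGT", "TGCA", conversion$ref_base) else
      conversion$ref_base
    pos <- BiocGenerics::start(windows[i]):BiocGenerics::end(windows[i])
    covv <- as.numeric(coverage[[chrom]][pos])
    editable <- seqs[[chrom]][pos] == base
    substrate <- sum(covv[editable])
    sel <- as.character(GenomeInfoDb::seqnames(sites)) == chrom &
      as.character(BiocGenerics::strand(sites)) == str &
      BiocGenerics::start(sites) %in% pos
    c(substrate = substrate,
      edits = sum(sites$edited_reads[sel]),
      npos = sum(sel),
      depth = floor(mean(covv)))
  })
  do.call(rbind, res)
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
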