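#' Define a base conversion
#'
#' A conversion specifies which transcript-oriented reference base is
#' editable (the substrate) and which base an edit produces, e.g. C>T for
#' APOBEC1-style C-to-U editing or A>G for ADAR-style A-to-I editing.
#'
#' @param ref_base Single character, the editable reference base (A/C/G/T).
#' @param alt_base Single character, the edited base; must differ from
#'   `ref_base`.
#' @return An object of class `conversion_spec` with fields `ref_base`,
#'   `alt_base` and `label` (e.g. `"C>T"`).
#' @examples
#' conversion_spec("C", "T")
#' conversion_spec("A", "G")
#' @export
conversion_spec <- function(ref_base, alt_base) {
  ref_base <- toupper(as.character(ref_base))
  alt_base <- toupper(as.character(alt_base))
  bases <- c("A", "C", "G", "T")
  if (length(ref_base) != 1L || !ref_base %in% bases)
    stop("ref_base must be one of A, C, G, T")
  if (length(alt_base) != 1L || !alt_base %in% bases)
    stop("alt_base must be one of A, C, G, T")
  if (ref_base == alt_base)
    stop("ref_base and alt_base must differ")
  structure(
    list(ref_base = ref_base, alt_base = alt_base,
         label = paste0(ref_base, ">", alt_base)),
    class = "conversion_spec"
  )
}

#' Parse a conversion label such as "C>T"
#'
#' @param label Character like `"C>T"` or `"A>G"`; a `conversion_spec` is
#'   passed through unchanged.
#' @return A [conversion_spec()].
#' @export
parse_conversion <- function(label) {
  if (inherits(label, "conversion_spec")) return(label)
  parts <- strsplit(toupper(as.character(label)), ">", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("conversion label must look like 'C>T'")
  conversion_spec(parts[1], parts[2])
}

#' @export
print.conversion_spec <- function(x, ...) {
  cat("Base conversion:", x$label, "\n")
  invisible(x)
}

complement_base <- function(base) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[base])
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream; seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## 1-based GRanges -> BED data.frame (0-based half-open), extra mcols appended
granges_to_bed <- function(gr, name = ".", score = 0, extra = NULL) {
  if (length(gr) == 0L) {
    df <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), name = character(0),
                     score = numeric(0), strand = character(0),
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df <- cbind(df, extra[0, , drop = FALSE])
    return(df)
  }
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = name,
    score = score,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
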