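#' Validate a genomic-interval data frame
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` in
#' 0-based half-open (BED-native) coordinates. 1-based coordinates appear only
#' in human-facing reports.
#'
#' @param x data frame with at least `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   rows.
#' @export
validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x)) stop("intervals must be a data.frame", call. = FALSE)
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$chrom) | !nzchar(as.character(x$chrom)) |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stop(sprintf(
      "malformed %s at row(s) %s: need non-empty chrom and 0 <= start < end",
      what, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.order_intervals <- function(x) x[order(x$chrom, x$start, x$end), , drop = FALSE]

#' Merge genomic intervals
#'
#' Overlapping and bookended (end == start) intervals on the same chromosome
#' are collapsed into one; the covered base set is preserved exactly. Input may
#' be unsorted and span several chromosomes.
#'
#' @param x interval data frame (`chrom`, `start`, `end`).
#' @param sources optional character vector (or list of label sets), one per
#'   input row, e.g. the cell line a ChIP peak came from. The merged output
#'   then carries a `sources` list column with the union of labels of all
#'   contributing inputs.
#' @return data frame of disjoint, non-touching intervals sorted by
#'   (chrom, start).
#' @export
merge_intervals <- function(x, sources = NULL) {
  validate_intervals(x)
  if (!is.null(sources) && length(sources) != nrow(x)) {
    stop("'sources' must have one element per interval", call. = FALSE)
  }
  if (nrow(x) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    if (!is.null(sources)) out$sources <- list()
    return(out)
  }
  pieces <- lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    ir <- IRanges::IRanges(start = x$start[idx] + 1L, end = x$end[idx])
    red <- IRanges::reduce(ir)  # default min.gapwidth = 1 merges bookended
    out <- data.frame(chrom = x$chrom[idx][1L],
                      start = BiocGenerics::start(red) - 1L,
                      end = BiocGenerics::end(red))
    if (!is.null(sources)) {
      hits <- IRanges::findOverlaps(red, ir)
      src <- sources[idx]
      out$sources <- lapply(seq_along(red), function(i) {
        sort(unique(unlist(src[S4Vectors::subjectHits(hits)[
          S4Vectors::queryHits(hits) == i]])))
      })
    }
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  .order_intervals(out)
}

#' Assign per-chromosome binding-site identifiers
#'
#' Merged peak intervals become binding sites with a 1-based ordinal per
#' chromosome, assigned in ascending start order, and an id rendered as
#' `"chr{N}_BS{ordinal}"`. The numbering is deterministic for a given merged
#' peak set.
#'
#' @param merged merged interval data frame (see [merge_intervals()]);
#'   overlapping input is an error.
#' @param sources optional per-interval label sets carried through (defaults
#'   to a `sources` column of `merged` if present).
#' @return data frame with columns `chrom`, `start`, `end`, `ordinal`,
#'   `site_id` (and `sources`).
#' @export
assign_binding_sites <- function(merged, sources = NULL) {
  validate_intervals(merged, what = "binding site")
  if (is.null(sources) && !is.null(merged$sources)) sources <- merged$sources
  out <- merged[, c("chrom", "start", "end")]
  if (!is.null(sources)) out$sources <- sources
  out <- .order_intervals(out)
  for (idx in split(seq_len(nrow(out)), out$chrom)) {
    if (length(idx) > 1 &&
        any(out$start[idx][-1] < out$end[idx][-length(idx)])) {
      stop("input contains overlapping intervals; run merge_intervals() first",
           call. = FALSE)
    }
  }
  ord <- stats::ave(out$start, out$chrom, FUN = seq_along)
  out$ordinal <- as.integer(ord)
  out$site_id <- paste0(out$chrom, "_BS", out$ordinal)
  rownames(out) <- NULL
  out
}

#' Half-open interval overlap test
#'
#' @param a,b interval data frames (rows are recycled as usual).
#' @return logical vector: TRUE where same chromosome and
#'   `a.start < b.end && b.start < a.end`.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Read a BED3/BED6 file into a 0-based interval data frame
#'
#' @param path BED file path (tab-separated, 0-based half-open).
#' @return data frame with `chrom`, `start`, `end` and, when present in the
#'   file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr))
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) out$name <- md$name
  if (!is.null(md$score)) out$score <- md$score
  str <- as.character(BiocGenerics::strand(gr))
  if (any(str != "*")) out$strand <- str
  out
}

#' Write intervals to BED in deterministic (chrom, start) order
#'
#' @param x interval data frame; optional `name`, `score`, `strand` columns
#'   are emitted as BED fields 4-6.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- .order_intervals(x)
  str <- if (!is.null(x$strand)) x$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = str)
  if (!is.null(x$name)) gr$name <- x$name
  if (!is.null(x$score)) gr$score <- x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
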