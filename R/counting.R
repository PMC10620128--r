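#' Amplicon layout for pooled-screen sequencing reads
#'
#' Reads carry a variable-length stagger (to increase base diversity), an
#' 8-nt sample barcode, then the invariant vector sequence ending in the
#' anchor that immediately precedes the 20-nt protospacer. Extraction is
#' anchor-based (exact match), not positional, because the stagger makes
#' positions variable.
#'
#' @param anchor constant sequence immediately 5' of the protospacer;
#'   default is the last 9 nt of the left cloning flank.
#' @param barcode optional 8-nt sample barcode (used by the simulator and
#'   demultiplexer).
#' @param stagger_range integer range of stagger lengths.
#' @return list of class `amplicon_layout`.
#' @export
amplicon_layout <- function(anchor = "GAAACACCG", barcode = NULL,
                            stagger_range = c(9L, 18L)) {
  if (!nzchar(anchor)) stop("anchor must be non-empty", call. = FALSE)
  if (!grepl(paste0(anchor, "$"), oligo_flanks()$left)) {
    warning("anchor is not a suffix of the standard left flank")
  }
  if (!is.null(barcode) && nchar(barcode) != 8) {
    stop("barcode must be 8 nt", call. = FALSE)
  }
  structure(list(anchor = anchor, barcode = barcode,
                 stagger_range = as.integer(stagger_range)),
            class = "amplicon_layout")
}

#' Extract protospacers from reads by anchor match
#'
#' Locates the first exact occurrence of the anchor in each read and returns
#' the 20 nt that follow; `NA` (an "unassigned" read) when the anchor is
#' absent or fewer than 20 nt remain.
#'
#' @param reads character vector of read sequences.
#' @param layout [amplicon_layout()].
#' @return character vector of 20-nt protospacers, with `NA` for
#'   unparseable reads.
#' @export
extract_protospacer <- function(reads, layout = amplicon_layout()) {
  pos <- regexpr(layout$anchor, reads, fixed = TRUE)
  from <- pos + nchar(layout$anchor)
  out <- substring(reads, from, from + 19L)
  out[pos < 0 | nchar(out) < 20L] <- NA_character_
  out
}

#' Count protospacers against a library by exact match
#'
#' Each extracted protospacer increments exactly the library entry it equals;
#' reads with any mismatch to every entry are tallied as unmatched. The
#' result is order-invariant in the input.
#'
#' @param protospacers character vector (20-nt sequences; `NA` = unassigned
#'   read).
#' @param library library manifest with unique `name` and `protospacer`
#'   columns.
#' @return named integer vector of counts (one per library entry) with a
#'   `"qc"` attribute: `n_reads`, `n_assigned`, `n_matched`, `n_unmatched`,
#'   `n_unassigned`.
#' @export
count_exact <- function(protospacers, library) {
  if (anyDuplicated(library$protospacer)) {
    stop("library protospacers must be unique", call. = FALSE)
  }
  idx <- match(protospacers, library$protospacer)
  counts <- tabulate(idx, nbins = nrow(library))
  names(counts) <- library$name
  qc <- list(n_reads = length(protospacers),
             n_assigned = sum(!is.na(protospacers)),
             n_matched = sum(counts),
             n_unmatched = sum(!is.na(protospacers) & is.na(idx)),
             n_unassigned = sum(is.na(protospacers)))
  attr(counts, "qc") <- qc
  counts
}

#' Count one FASTQ sample against a library
#'
#' @param path FASTQ file (plain or gzipped).
#' @param library library manifest.
#' @param layout [amplicon_layout()].
#' @return as [count_exact()].
#' @export
count_fastq <- function(path, library, layout = amplicon_layout()) {
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  count_exact(extract_protospacer(reads, layout), library)
}

#' Demultiplex reads by the exact 8-nt barcode preceding the anchor
#'
#' @param reads character vector of read sequences.
#' @param barcodes named character vector, sample -> 8-nt barcode.
#' @param layout [amplicon_layout()].
#' @return named list of read vectors, one per sample, plus `"unassigned"`.
#' @export
demultiplex_reads <- function(reads, barcodes, layout = amplicon_layout()) {
  pos <- regexpr(layout$anchor, reads, fixed = TRUE)
  bc <- substring(reads, pos - 8L, pos - 1L)
  bc[pos < 9L] <- NA_character_
  sample <- names(barcodes)[match(bc, barcodes)]
  sample[is.na(sample)] <- "unassigned"
  split(reads, factor(sample, levels = c(names(barcodes), "unassigned")))
}

#' Write / read a count matrix TSV
#'
#' Rows are library entries, columns samples; first column holds entry
#' names.
#'
#' @param counts integer matrix with row and column names.
#' @param path file path.
#' @return `path` / integer matrix.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(name = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
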