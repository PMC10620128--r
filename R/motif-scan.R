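#' The E-box motif set
#'
#' The canonical CACGTG plus the two common non-canonical pairs CACATG/CATGTG
#' and CACGCG/CGCGTG. The set is closed under reverse complement, so scanning
#' the plus strand alone finds every occurrence on either strand exactly once.
#'
#' @return character vector of 6-mers.
#' @export
ebox_motifs <- function() {
  c("CACGTG", "CACATG", "CATGTG", "CACGCG", "CGCGTG")
}

.check_motif_set <- function(motifs) {
  if (length(motifs) == 0 || any(nchar(motifs) != 6) ||
      any(grepl("[^ACGT]", motifs))) {
    stop("motif set must be non-empty 6-mers over {A,C,G,T}", call. = FALSE)
  }
  if (!all(reverse_complement(motifs) %in% motifs)) {
    stop("motif set is not closed under reverse complement", call. = FALSE)
  }
  invisible(motifs)
}

#' Scan binding sites for E-box motif occurrences
#'
#' Every plus-strand occurrence of a motif inside a binding site is reported
#' once, labelled by its plus-strand hexamer. Because the motif set is
#' reverse-complement closed, this covers both strands without double
#' counting. Windows containing N are skipped.
#'
#' @param genome `DNAStringSet`.
#' @param sites binding-site table from [assign_binding_sites()] (needs
#'   `chrom`, `start`, `end`, `site_id`).
#' @param motifs motif set, default [ebox_motifs()]; must be
#'   reverse-complement closed.
#' @return data frame sorted by (chrom, start) with one row per E-box:
#'   `chrom`, `start`, `end`, `hexamer`, `site_id`, `ebox_id`
#'   (`"{site_id}_{hexamer}"`), `exonic` (initialised to `FALSE`).
#' @export
scan_eboxes <- function(genome, sites, motifs = ebox_motifs()) {
  .check_motif_set(motifs)
  validate_intervals(sites, what = "binding site")
  if (is.null(sites$site_id)) {
    stop("sites need a 'site_id' column; see assign_binding_sites()",
         call. = FALSE)
  }
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    w <- sites$end[i] - sites$start[i]
    if (w < 6) next
    seq <- fetch_sequence(genome, sites$chrom[i], sites$start[i], sites$end[i])
    off <- seq_len(w - 5L)
    hex <- substring(seq, off, off + 5L)
    hit <- hex %in% motifs  # windows with N never match a pure-ACGT motif
    if (!any(hit)) next
    rows[[i]] <- data.frame(
      chrom = sites$chrom[i],
      start = sites$start[i] + off[hit] - 1L,
      end = sites$start[i] + off[hit] + 5L,
      hexamer = hex[hit],
      site_id = sites$site_id[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      hexamer = character(), site_id = character())
  }
  out <- .order_intervals(out)
  out$ebox_id <- if (nrow(out)) paste0(out$site_id, "_", out$hexamer)
  else character(0)
  out$exonic <- logical(nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag E-boxes overlapping coding exons
#'
#' An E-box is exonic when its 6-bp interval overlaps at least one
#' coding-exon base (half-open semantics; bookended does not count).
#' Exonic E-boxes are excluded from guide design downstream but retained in
#' reports.
#'
#' @param eboxes E-box table from [scan_eboxes()].
#' @param coding_exons interval data frame of coding exons (merged
#'   internally).
#' @return `eboxes` with the `exonic` flag set.
#' @export
flag_exonic <- function(eboxes, coding_exons) {
  validate_intervals(coding_exons, what = "coding exon")
  eboxes$exonic <- FALSE
  if (nrow(eboxes) == 0 || nrow(coding_exons) == 0) return(eboxes)
  exons <- merge_intervals(coding_exons)
  for (chr in unique(eboxes$chrom)) {
    ei <- which(eboxes$chrom == chr)
    xi <- which(exons$chrom == chr)
    if (!length(xi)) next
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(eboxes$start[ei] + 1L, eboxes$end[ei]),
      IRanges::IRanges(exons$start[xi] + 1L, exons$end[xi]))
    eboxes$exonic[ei] <- hits
  }
  eboxes
}
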