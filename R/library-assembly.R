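#' Constant synthesis-oligo flanks
#'
#' The cloning-vector homology arms placed around every 20-nt protospacer in
#' the synthesis pool: a 41-nt left arm ending in `GAAACACCG` and a 43-nt
#' right arm, giving a 104-nt oligo.
#'
#' @return list with `left` (41 nt) and `right` (43 nt).
#' @export
oligo_flanks <- function() {
  list(left = "TTTCTTGGCTTTATATATCTTGTGGAAAGGACGAAACACCG",
       right = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGT")
}

#' Assemble the final sgRNA library
#'
#' Deduplicates targeting guides by protospacer sequence library-wide (a
#' sequence cutting in several E-boxes appears once, with all E-box ids in
#' `targets`), names targeting entries `"{ebox_id}_sg{i}"` with `i` assigned
#' in genomic order within each E-box, appends non-targeting and
#' positive-control entries, and renders each 104-nt synthesis oligo as
#' left flank + protospacer + right flank.
#'
#' @param guides guide table from [enumerate_guides()] (optionally already
#'   filtered and annotated with `n_offtargets_le2mm`, `cfd_specificity`).
#' @param non_targeting character vector of 20-nt control sequences.
#' @param positive_controls data frame with `name` and `protospacer`.
#' @param flanks see [oligo_flanks()].
#' @return data frame with columns `name`, `ebox_id`, `chrom`, `ebox_start`,
#'   `ebox_end`, `hexamer`, `protospacer`, `pam`, `strand`, `cut_bond`,
#'   `n_offtargets_le2mm`, `cfd_specificity`, `targets`, `category`,
#'   `oligo`; attribute `"summary"` holds per-category counts. A sequence
#'   duplicated across categories is a validation error.
#' @export
assemble_library <- function(guides, non_targeting = character(),
                             positive_controls = NULL,
                             flanks = oligo_flanks()) {
  .check_proto <- function(x, what) {
    if (length(x) && (any(nchar(x) != 20) || any(grepl("[^ACGT]", x)))) {
      stop(sprintf("%s sequences must be 20 nt over {A,C,G,T}", what),
           call. = FALSE)
    }
  }
  .check_proto(guides$protospacer, "targeting")
  .check_proto(non_targeting, "non-targeting")
  if (!is.null(positive_controls)) {
    .check_proto(positive_controls$protospacer, "positive-control")
  }

  targ <- NULL
  if (nrow(guides) > 0) {
    g <- guides[order(guides$chrom, guides$ebox_start, guides$cut_bond,
                      guides$strand), , drop = FALSE]
    sg_i <- stats::ave(seq_len(nrow(g)), g$ebox_id, FUN = seq_along)
    g$name <- paste0(g$ebox_id, "_sg", sg_i)
    # library-wide dedup by sequence; union of targeted E-boxes retained
    tgt <- vapply(split(g$ebox_id, g$protospacer),
                  function(x) paste(unique(x), collapse = ","), "")
    first <- !duplicated(g$protospacer)
    targ <- g[first, , drop = FALSE]
    targ$targets <- unname(tgt[targ$protospacer])
    targ$category <- "targeting"
  }

  blank <- function(name, proto, category) {
    data.frame(name = name, ebox_id = NA_character_, chrom = NA_character_,
               ebox_start = NA_integer_, ebox_end = NA_integer_,
               hexamer = NA_character_, protospacer = proto,
               pam = NA_character_, strand = NA_character_,
               cut_bond = NA_integer_,
               n_offtargets_le2mm = NA_integer_,
               cfd_specificity = NA_real_,
               targets = "", category = category,
               stringsAsFactors = FALSE)
  }
  cols <- c("name", "ebox_id", "chrom", "ebox_start", "ebox_end", "hexamer",
            "protospacer", "pam", "strand", "cut_bond",
            "n_offtargets_le2mm", "cfd_specificity", "targets", "category")
  if (!is.null(targ)) {
    for (cc in setdiff(cols, names(targ))) targ[[cc]] <- NA
    targ <- targ[, cols]
  }
  nt <- if (length(non_targeting)) {
    blank(sprintf("NT_%04d", seq_along(non_targeting)),
          non_targeting, "non_targeting")
  }
  pc <- if (!is.null(positive_controls) && nrow(positive_controls)) {
    blank(positive_controls$name, positive_controls$protospacer,
          "positive_control")
  }
  out <- rbind(targ, nt, pc)
  if (is.null(out) || nrow(out) == 0) {
    stop("library is empty: no guides and no controls", call. = FALSE)
  }
  if (anyDuplicated(out$protospacer)) {
    bad <- unique(out$protospacer[duplicated(out$protospacer)])
    stop(sprintf("duplicated protospacer sequence(s) across entries: %s",
                 paste(utils::head(bad, 3), collapse = ", ")),
         call. = FALSE)
  }
  out$oligo <- paste0(flanks$left, out$protospacer, flanks$right)
  rownames(out) <- NULL
  attr(out, "summary") <- as.list(table(out$category))
  out
}

#' Write a library manifest TSV
#'
#' Tab-separated, deterministic row order (targeting entries in genomic
#' order, then controls), list columns flattened.
#'
#' @param library output of [assemble_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
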