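#' Design an E-box-disrupting sgRNA library end to end
#'
#' Chains the whole design: merge ChIP peaks, assign binding-site ids, scan
#' for E-boxes, flag and exclude coding-exon E-boxes, enumerate
#' PAM-compatible guides whose cut bond lies inside an E-box, apply the
#' mismatch/seed off-target retention rule genome-wide, optionally score
#' specificity, and assemble the synthesis library with controls.
#'
#' @param genome `DNAStringSet`.
#' @param peaks ChIP-peak interval data frame; an optional `source` column
#'   (cell-line label) is tracked through merging.
#' @param coding_exons optional coding-exon intervals; E-boxes overlapping
#'   any exon base are excluded from design.
#' @param motifs motif set, default [ebox_motifs()].
#' @param non_targeting,positive_controls control sequences passed to
#'   [assemble_library()].
#' @param check_offtargets apply the retention rule (searching every locus
#'   up to 2 mismatches with an NGG PAM)?
#' @param score_cfd also compute a CFD-style specificity per retained guide
#'   (off-target search widened to 3 mismatches)?
#' @param cfd activity table for scoring, see [load_cfd_matrix()].
#' @return object of class `ebox_design`: list with `sites`, `eboxes`,
#'   `guides` (all candidates, with `retained` flag), `library` (the final
#'   manifest) and `summary` (counts at each filtering stage).
#' @export
design_ebox_library <- function(genome, peaks, coding_exons = NULL,
                                motifs = ebox_motifs(),
                                non_targeting = character(),
                                positive_controls = NULL,
                                check_offtargets = TRUE,
                                score_cfd = FALSE,
                                cfd = NULL) {
  src <- if (!is.null(peaks$source)) peaks$source
  merged <- merge_intervals(peaks, sources = src)
  sites <- assign_binding_sites(merged)
  eboxes <- scan_eboxes(genome, sites, motifs)
  if (!is.null(coding_exons) && nrow(coding_exons) > 0) {
    eboxes <- flag_exonic(eboxes, coding_exons)
  }
  design_set <- eboxes[!eboxes$exonic, , drop = FALSE]
  guides <- enumerate_guides(genome, design_set)

  guides$retained <- TRUE
  guides$n_offtargets_le2mm <- NA_integer_
  guides$cfd_specificity <- NA_real_
  if (nrow(guides) > 0 && (check_offtargets || score_cfd)) {
    max_mm <- if (score_cfd) 3L else 2L
    per_seq <- lapply(unique(guides$protospacer), function(p) {
      st <- find_offtarget_sites(p, genome, max_mismatches = max_mm)
      on <- mark_on_target(st, design_set)
      off2 <- st$n_mismatches <= 2 & !on
      list(pass = passes_offtarget_rule(st[st$n_mismatches <= 2, ,
                                           drop = FALSE],
                                        on[st$n_mismatches <= 2]),
           n_off = sum(off2),
           cfd = if (score_cfd) {
             cfd_specificity(p, st, on,
                             cfd = if (is.null(cfd)) load_cfd_matrix() else cfd)
           } else NA_real_)
    })
    names(per_seq) <- unique(guides$protospacer)
    idx <- match(guides$protospacer, names(per_seq))
    if (check_offtargets) {
      guides$retained <- vapply(per_seq, `[[`, logical(1), "pass")[idx]
    }
    guides$n_offtargets_le2mm <- vapply(per_seq, `[[`,
                                        integer(1), "n_off")[idx]
    guides$cfd_specificity <- vapply(per_seq, `[[`, numeric(1), "cfd")[idx]
  }

  kept <- guides[guides$retained, , drop = FALSE]
  library <- assemble_library(kept, non_targeting = non_targeting,
                              positive_controls = positive_controls)
  summary <- list(
    n_peaks_input = nrow(peaks),
    n_binding_sites = nrow(sites),
    n_eboxes = nrow(eboxes),
    n_eboxes_exonic = sum(eboxes$exonic),
    n_eboxes_candidate = nrow(design_set),
    n_guides_candidate = length(unique(guides$protospacer)),
    n_guides_retained = length(unique(kept$protospacer)),
    n_eboxes_targeted = length(unique(kept$ebox_id)),
    n_library_entries = nrow(library),
    categories = attr(library, "summary"))
  structure(list(sites = sites, eboxes = eboxes, guides = guides,
                 library = library, summary = summary),
            class = "ebox_design")
}

#' @export
print.ebox_design <- function(x, ...) {
  s <- x$summary
  cat("E-box CRISPR library design\n")
  cat(sprintf("  peaks in: %d -> merged binding sites: %d\n",
              s$n_peaks_input, s$n_binding_sites))
  cat(sprintf("  E-boxes found: %d (exonic, excluded: %d)\n",
              s$n_eboxes, s$n_eboxes_exonic))
  cat(sprintf("  candidate guides (unique): %d; retained after off-target rule: %d\n",
              s$n_guides_candidate, s$n_guides_retained))
  cat(sprintf("  E-boxes targeted: %d of %d candidates\n",
              s$n_eboxes_targeted, s$n_eboxes_candidate))
  cat(sprintf("  library entries: %d (%s)\n", s$n_library_entries,
              paste(sprintf("%s %s", unlist(s$categories),
                            names(s$categories)), collapse = ", ")))
  invisible(x)
}
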