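#' Overlap of hit sets across cell lines
#'
#' For k = 1..n, the targets present in exactly k of the input sets; the
#' per-k totals sum to the size of the union.
#'
#' @param hit_sets named list of character vectors (per-cell-line hit ids).
#' @return list with `membership` (data frame: `target`, `n_sets`, `sets`),
#'   `by_k` (data frame: `k`, `n_targets`) and `n_union`.
#' @export
intersect_hits <- function(hit_sets) {
  if (length(hit_sets) < 2) stop("need at least 2 hit sets", call. = FALSE)
  if (is.null(names(hit_sets))) {
    names(hit_sets) <- paste0("set", seq_along(hit_sets))
  }
  u <- sort(unique(unlist(hit_sets)))
  inset <- vapply(hit_sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) inset <- matrix(inset, nrow = 1)
  k <- rowSums(inset)
  membership <- data.frame(
    target = u, n_sets = k,
    sets = apply(inset, 1, function(z) {
      paste(names(hit_sets)[z], collapse = ",")
    }),
    stringsAsFactors = FALSE)
  by_k <- data.frame(k = seq_along(hit_sets),
                     n_targets = vapply(seq_along(hit_sets),
                                        function(i) sum(k == i), 1L))
  list(membership = membership, by_k = by_k, n_union = length(u))
}

#' Nearest TSS genes within a window of each E-box
#'
#' For each E-box, the single nearest transcription start site at or left of
#' the E-box midpoint and the single nearest at or right of it, each
#' reported only when the midpoint-to-TSS distance is within the window
#' (boundary inclusive). Ties are broken by lexicographic gene name.
#'
#' @param eboxes E-box table (`chrom`, `start`, `end`, `ebox_id`).
#' @param tss_table data frame with `gene`, `chrom`, `tss` (0-based
#'   position) and optionally `strand`.
#' @param window maximum distance in bp (default 50000).
#' @return data frame: `ebox_id`, `side` ("left"/"right"), `gene`, `tss`,
#'   `distance`. E-boxes with no TSS in range contribute no rows.
#' @export
nearest_tss_genes <- function(eboxes, tss_table, window = 50000) {
  if (!all(c("gene", "chrom", "tss") %in% names(tss_table))) {
    stop("tss_table needs columns gene, chrom, tss", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(eboxes))) {
    mid <- (eboxes$start[i] + eboxes$end[i]) %/% 2L
    tt <- tss_table[tss_table$chrom == eboxes$chrom[i], , drop = FALSE]
    if (!nrow(tt)) next
    for (side in c("left", "right")) {
      cand <- if (side == "left") tt[tt$tss <= mid, , drop = FALSE]
      else tt[tt$tss >= mid, , drop = FALSE]
      if (!nrow(cand)) next
      d <- abs(cand$tss - mid)
      cand <- cand[order(d, cand$gene), , drop = FALSE]
      best <- cand[1, ]
      dist <- abs(best$tss - mid)
      if (dist <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          ebox_id = eboxes$ebox_id[i], side = side, gene = best$gene,
          tss = best$tss, distance = dist, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ebox_id = character(), side = character(),
                      gene = character(), tss = integer(),
                      distance = integer())
  }
  rownames(out) <- NULL
  out
}
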