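#' Enumerate all PAM-compatible guides cutting inside E-boxes
#'
#' A guide "targets" an E-box when the Cas9 blunt-cut phosphodiester bond --
#' between protospacer nt 17 and 18, i.e. 3 nt 5' of the NGG PAM -- falls
#' strictly inside the 6-mer (one of its 5 internal bonds). Both strands are
#' searched: an NGG PAM on the minus strand appears as CCN on the plus
#' strand. Cut bonds are between-base indices: bond `p` sits between 0-based
#' positions `p - 1` and `p`.
#'
#' @param genome `DNAStringSet`.
#' @param eboxes E-box table ([scan_eboxes()]); exonic rows are refused.
#' @return data frame with one row per (E-box, guide placement):
#'   `protospacer` (20 nt, 5'->3' on its strand), `pam` (3 nt), `strand`,
#'   `chrom`, `start`, `end` (protospacer interval, 0-based half-open),
#'   `cut_bond`, `ebox_id`, `hexamer`, `ebox_start`, `ebox_end`,
#'   `cut_label` (hexamer with `*` at the cut, e.g. `"CACAT*G"`).
#'   An E-box too close to a contig edge for any placement simply
#'   contributes no rows.
#' @export
enumerate_guides <- function(genome, eboxes) {
  if (nrow(eboxes) > 0 && any(eboxes$exonic)) {
    stop("refusing to design guides for exonic E-boxes; filter them first",
         call. = FALSE)
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  rows <- vector("list", nrow(eboxes))
  chr_cache <- new.env(parent = emptyenv())
  get_chr <- function(chrom) {
    if (is.null(chr_cache[[chrom]])) {
      chr_cache[[chrom]] <- as.character(genome[[chrom]])
    }
    chr_cache[[chrom]]
  }
  for (i in seq_len(nrow(eboxes))) {
    chrom <- eboxes$chrom[i]
    s <- eboxes$start[i]
    len <- lens[[chrom]]
    cs <- get_chr(chrom)
    acc <- list()
    for (p in (s + 1L):(s + 5L)) {   # the 5 internal bonds of the 6-mer
      # plus strand: protospacer [p-17, p+3), PAM [p+3, p+6) must be NGG
      g <- p - 17L
      if (g >= 0L && g + 23L <= len &&
          substr(cs, g + 22L, g + 23L) == "GG") {
        proto <- substr(cs, g + 1L, g + 20L)
        pam <- substr(cs, g + 21L, g + 23L)
        if (!grepl("N", proto, fixed = TRUE)) {
          acc[[length(acc) + 1L]] <- list(proto, pam, "+", g, p)
        }
      }
      # minus strand: protospacer [p-3, p+17), plus-strand CCN at [p-6, p-3)
      g <- p - 3L
      if (g >= 3L && g + 20L <= len &&
          substr(cs, g - 2L, g - 1L) == "CC") {
        raw <- substr(cs, g + 1L, g + 20L)
        if (!grepl("N", raw, fixed = TRUE)) {
          proto <- reverse_complement(raw)
          pam <- reverse_complement(substr(cs, g - 2L, g))
          acc[[length(acc) + 1L]] <- list(proto, pam, "-", g, p)
        }
      }
    }
    if (!length(acc)) next
    rows[[i]] <- data.frame(
      protospacer = vapply(acc, `[[`, "", 1L),
      pam = vapply(acc, `[[`, "", 2L),
      strand = vapply(acc, `[[`, "", 3L),
      chrom = chrom,
      start = vapply(acc, function(a) as.integer(a[[4L]]), 1L),
      cut_bond = vapply(acc, function(a) as.integer(a[[5L]]), 1L),
      ebox_id = eboxes$ebox_id[i],
      hexamer = eboxes$hexamer[i],
      ebox_start = s,
      ebox_end = eboxes$end[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protospacer = character(), pam = character(),
                      strand = character(), chrom = character(),
                      start = integer(), cut_bond = integer(),
                      ebox_id = character(), hexamer = character(),
                      ebox_start = integer(), ebox_end = integer())
  }
  out$end <- out$start + 20L
  dup <- duplicated(out[, c("protospacer", "chrom", "start", "strand",
                            "ebox_id")])
  out <- out[!dup, , drop = FALSE]
  out$cut_label <- if (nrow(out)) {
    cut_annotation(out$hexamer, out$cut_bond - out$ebox_start)
  } else character(0)
  out <- out[order(out$chrom, out$ebox_start, out$cut_bond, out$strand), ]
  rownames(out) <- NULL
  out[, c("protospacer", "pam", "strand", "chrom", "start", "end",
          "cut_bond", "ebox_id", "hexamer", "ebox_start", "ebox_end",
          "cut_label")]
}

#' Render a cut-site annotation inside a hexamer
#'
#' @param hexamer motif string(s).
#' @param offset bond offset(s) within the motif, 1..5 (bond between motif
#'   positions `offset` and `offset + 1`).
#' @return hexamer with `*` inserted at the cut bond, e.g. `"CACAT*G"`.
#' @export
cut_annotation <- function(hexamer, offset) {
  if (any(offset < 1 | offset > 5)) {
    stop("cut bond must be one of the 5 internal bonds (offset 1-5)",
         call. = FALSE)
  }
  paste0(substr(hexamer, 1, offset), "*",
         substr(hexamer, offset + 1, nchar(hexamer)))
}
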