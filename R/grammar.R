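#' Strand-symmetrized flank nucleotide counts around E-boxes
#'
#' E-boxes are (quasi)palindromic and read on either strand, so each E-box
#' contributes both orientation readings of its flanking window: the
#' plus-strand window and its reverse complement. The resulting profile
#' satisfies `count(+k, b) == count(-k, complement(b))` exactly by
#' construction, and each position's counts sum to `2 * n_eboxes` on N-free
#' input (N bases are excluded from tallies).
#'
#' @param eboxes E-box table (`chrom`, `start`, `end`).
#' @param genome `DNAStringSet`.
#' @param K flank width in bp (positions -K..-1, +1..+K relative to the
#'   6-mer); must be positive. E-boxes with fewer than K bases of context
#'   are dropped with a warning.
#' @return object of class `flank_profile`: list with `counts`
#'   (2K x 4 matrix, rows "-K".."-1","+1".."+K", columns A,C,G,T),
#'   `n_eboxes`, `K`, `n_dropped`.
#' @export
pooled_flank_counts <- function(eboxes, genome, K = 10) {
  if (length(K) != 1 || is.na(K) || K <= 0) {
    stop("flank width K must be a positive integer", call. = FALSE)
  }
  K <- as.integer(K)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  fits <- eboxes$start - K >= 0 & eboxes$end + K <= lens[eboxes$chrom]
  if (any(!fits)) {
    warning(sprintf("dropping %d E-box(es) with < %d bases of context",
                    sum(!fits), K))
  }
  eb <- eboxes[fits, , drop = FALSE]
  pos_labels <- c(paste0("-", K:1), paste0("+", 1:K))
  counts <- matrix(0L, nrow = 2L * K, ncol = 4,
                   dimnames = list(pos_labels, c("A", "C", "G", "T")))
  if (nrow(eb) > 0) {
    # tally plus-strand bases at every offset, then add the mirrored
    # complement tally (the reverse-complement reading of each window)
    plus <- counts
    offsets <- c(-(K:1), 1:K)
    for (oi in seq_along(offsets)) {
      o <- offsets[oi]
      pos0 <- if (o < 0) eb$start + o else eb$end + o - 1L
      bases <- character(nrow(eb))
      for (chr in unique(eb$chrom)) {
        sel <- eb$chrom == chr
        bases[sel] <- substring(as.character(genome[[chr]]),
                                pos0[sel] + 1L, pos0[sel] + 1L)
      }
      tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
      plus[oi, ] <- as.integer(tab)   # N bases fall outside the levels
    }
    mirror <- plus[rev(seq_len(2L * K)), c("T", "G", "C", "A")]
    dimnames(mirror) <- dimnames(plus)
    counts <- plus + mirror
  }
  structure(list(counts = counts, n_eboxes = nrow(eb), K = K,
                 n_dropped = sum(!fits)),
            class = "flank_profile")
}

#' @export
print.flank_profile <- function(x, ...) {
  cat(sprintf("flank profile: %d E-boxes, K = %d (%d dropped)\n",
              x$n_eboxes, x$K, x$n_dropped))
  print(utils::head(x$counts, 3))
  invisible(x)
}

#' Chi-squared goodness-of-fit of essential vs background flank composition
#'
#' Per position +1..+K (the negative side is the mirror image under the
#' symmetry invariant): a 4-category goodness-of-fit of the essential
#' counts against expected proportions taken from the background profile
#' (treated as fixed; df = 3), plus a 1-vs-rest 2-category test per
#' nucleotide (df = 1). Cells with expected count < 5 are flagged; a
#' background category with probability zero that the essential profile
#' observes is handled with a continuity guard (+0.5 to background counts)
#' and flagged.
#'
#' @param essential,background `flank_profile` objects with the same K.
#' @return data frame: `position` (+1..+K), `nucleotide` ("all" or a base),
#'   `chi2`, `df`, `p`, `padj` (BH over all rows), `stars`,
#'   `min_expected`, `low_expected`, `zero_guard`.
#' @export
flank_gof_test <- function(essential, background) {
  if (!inherits(essential, "flank_profile") ||
      !inherits(background, "flank_profile")) {
    stop("inputs must be flank_profile objects", call. = FALSE)
  }
  if (essential$K != background$K) {
    stop("profiles have different flank widths", call. = FALSE)
  }
  K <- essential$K
  rows <- list()
  for (k in seq_len(K)) {
    lab <- paste0("+", k)
    obs <- essential$counts[lab, ]
    bg <- background$counts[lab, ]
    guard <- any(bg == 0 & obs > 0)
    if (guard) bg <- bg + 0.5
    p0 <- bg / sum(bg)
    n <- sum(obs)
    expd <- n * p0
    chi2 <- sum((obs - expd)^2 / expd)
    rows[[length(rows) + 1L]] <- data.frame(
      position = k, nucleotide = "all", chi2 = chi2, df = 3L,
      p = stats::pchisq(chi2, df = 3, lower.tail = FALSE),
      min_expected = min(expd), zero_guard = guard,
      stringsAsFactors = FALSE)
    for (b in colnames(essential$counts)) {
      o2 <- c(obs[b], n - obs[b])
      e2 <- n * c(p0[b], 1 - p0[b])
      chi2b <- sum((o2 - e2)^2 / e2)
      rows[[length(rows) + 1L]] <- data.frame(
        position = k, nucleotide = b, chi2 = chi2b, df = 1L,
        p = stats::pchisq(chi2b, df = 1, lower.tail = FALSE),
        min_expected = min(e2), zero_guard = guard,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$stars <- cut(out$p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                   labels = c("****", "***", "**", "*", ""))
  out$low_expected <- out$min_expected < 5
  rownames(out) <- NULL
  out
}

#' Position frequency matrix for logo rendering
#'
#' Row-normalized flank frequencies (each position sums to 1), in a plain
#' matrix consumable by sequence-logo renderers.
#'
#' @param profile `flank_profile`.
#' @return numeric matrix, positions x A/C/G/T.
#' @export
logo_matrix <- function(profile) {
  if (!inherits(profile, "flank_profile") || profile$n_eboxes == 0) {
    stop("empty flank profile", call. = FALSE)
  }
  rs <- rowSums(profile$counts)
  if (any(rs == 0)) stop("profile has positions with zero counts",
                         call. = FALSE)
  profile$counts / rs
}
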