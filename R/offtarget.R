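#' Find genomic off-target sites of a guide
#'
#' Returns every locus on either strand with an NGG PAM whose 20-nt
#' protospacer-aligned sequence is within `max_mismatches` of the guide,
#' including the perfect-match (0-mismatch) on-target locus. Mismatch
#' positions are in protospacer coordinates 1-20, 1 = PAM-distal 5' end.
#'
#' Candidate matching uses `Biostrings::matchPattern` (no indels); PAM and
#' mismatch bookkeeping are applied on top.
#'
#' @param protospacer 20-nt guide sequence over {A,C,G,T}.
#' @param genome `DNAStringSet`.
#' @param max_mismatches maximum Hamming distance searched. The retention
#'   rule needs completeness up to 2; CFD scoring is usually run at 3.
#' @return data frame: `chrom`, `start`, `end` (protospacer interval,
#'   0-based half-open), `strand`, `pam`, `target_seq` (genomic 20-mer in
#'   protospacer orientation), `n_mismatches`, `mismatch_positions` (list
#'   column), `cut_bond`.
#' @export
find_offtarget_sites <- function(protospacer, genome, max_mismatches = 2) {
  if (length(protospacer) != 1 || nchar(protospacer) != 20 ||
      grepl("[^ACGT]", protospacer)) {
    stop("protospacer must be a single 20-nt string over {A,C,G,T}",
         call. = FALSE)
  }
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  pvec <- strsplit(protospacer, "")[[1]]
  rc <- reverse_complement(protospacer)
  rows <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    len <- length(subject)
    cs <- as.character(subject)
    # plus strand: 20-mer match followed by NGG
    st <- BiocGenerics::start(Biostrings::matchPattern(
      protospacer, subject, max.mismatch = max_mismatches,
      with.indels = FALSE))
    if (length(st)) {
      st <- st[st + 22L <= len & substring(cs, st + 21L, st + 22L) == "GG"]
    }
    for (s in st) {
      tgt <- substring(cs, s, s + 19L)
      mm <- which(strsplit(tgt, "")[[1]] != pvec)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 1L, end = s + 19L, strand = "+",
        pam = substring(cs, s + 20L, s + 22L), target_seq = tgt,
        n_mismatches = length(mm), stringsAsFactors = FALSE)
      rows[[length(rows)]]$mismatch_positions <- list(mm)
    }
    # minus strand: revcomp match preceded (on plus) by CCN
    st <- BiocGenerics::start(Biostrings::matchPattern(
      rc, subject, max.mismatch = max_mismatches, with.indels = FALSE))
    if (length(st)) {
      st <- st[st >= 4L]
      st <- st[substring(cs, st - 3L, st - 2L) == "CC"]
    }
    for (s in st) {
      tgt <- reverse_complement(substring(cs, s, s + 19L))
      mm <- which(strsplit(tgt, "")[[1]] != pvec)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 1L, end = s + 19L, strand = "-",
        pam = reverse_complement(substring(cs, s - 3L, s - 1L)),
        target_seq = tgt, n_mismatches = length(mm),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$mismatch_positions <- list(mm)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      pam = character(), target_seq = character(),
                      n_mismatches = integer())
    out$mismatch_positions <- list()
    out$cut_bond <- integer()
    return(out)
  }
  out$cut_bond <- ifelse(out$strand == "+", out$start + 17L, out$start + 3L)
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Mark which perfect-match sites are intended on-targets
#'
#' A 0-mismatch site counts as intended when its cut bond lies strictly
#' inside any library E-box; every other perfect match is an off-target
#' (and will reject the guide under the retention rule).
#'
#' @param sites output of [find_offtarget_sites()].
#' @param eboxes library E-box table (the designable, non-exonic set).
#' @return logical vector along the rows of `sites`.
#' @export
mark_on_target <- function(sites, eboxes) {
  if (nrow(sites) == 0) return(logical(0))
  on <- logical(nrow(sites))
  cand <- which(sites$n_mismatches == 0)
  for (i in cand) {
    sel <- eboxes$chrom == sites$chrom[i] &
      sites$cut_bond[i] >= eboxes$start + 1L &
      sites$cut_bond[i] <= eboxes$start + 5L
    on[i] <- any(sel)
  }
  on
}

#' Apply the off-target retention rule
#'
#' A guide is kept only when every off-target site has at least three
#' mismatches, or at least two mismatches of which at least one falls in the
#' seed region (protospacer nt 9-20, PAM-proximal). Equivalently, a guide is
#' rejected as soon as any off-target has 0 or 1 mismatches, or exactly 2
#' mismatches both within nt 1-8.
#'
#' @param sites site table from [find_offtarget_sites()], complete up to 2
#'   mismatches.
#' @param on_target logical vector flagging intended sites (see
#'   [mark_on_target()]); these are ignored by the rule.
#' @param seed_start first seed position (default 9).
#' @return TRUE when the guide is retained.
#' @export
passes_offtarget_rule <- function(sites,
                                  on_target = rep(FALSE, nrow(sites)),
                                  seed_start = 9L) {
  if (nrow(sites) == 0) return(TRUE)
  stopifnot(length(on_target) == nrow(sites))
  off <- sites[!on_target, , drop = FALSE]
  if (nrow(off) == 0) return(TRUE)
  in_seed <- vapply(off$mismatch_positions,
                    function(p) any(p >= seed_start), logical(1))
  all(off$n_mismatches >= 3 | (off$n_mismatches >= 2 & in_seed))
}
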