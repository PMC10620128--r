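#' Load the packaged mismatch-activity (CFD-style) table
#'
#' Cutting-frequency-determination scoring multiplies an empirical activity
#' penalty per mismatched position. The table shipped with this package,
#' `cfd_matrix_synthetic.tsv`, is a synthetic stand-in constructed with the
#' same indexing as published CFD tables (position 1-20 from the PAM-distal
#' end x guide base x genomic target base) and the qualitative shape of
#' measured data (PAM-proximal mismatches most penalized); it is not the
#' empirically measured matrix. Supply your own table via `path` to score
#' with measured activities.
#'
#' @param path TSV with columns `position`, `guide_base`, `target_base`,
#'   `activity`.
#' @return named numeric vector keyed `"position:guide:target"`.
#' @export
load_cfd_matrix <- function(path = system.file("extdata",
                                               "cfd_matrix_synthetic.tsv",
                                               package = "eboxscreen")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "guide_base", "target_base", "activity")
  if (!all(need %in% names(m))) {
    stop("CFD table must have columns position, guide_base, target_base, activity",
         call. = FALSE)
  }
  stats::setNames(m$activity,
                  paste(m$position, m$guide_base, m$target_base, sep = ":"))
}

#' Per-site CFD: product of per-position mismatch penalties
#'
#' A site with 0 mismatches scores 1 (empty product).
#'
#' @param protospacer 20-nt guide sequence.
#' @param target_seq genomic 20-mer in protospacer orientation.
#' @param cfd matrix from [load_cfd_matrix()].
#' @return numeric in \[0, 1\]. A mismatch pair absent from the table is a
#'   configuration error.
#' @export
site_cfd <- function(protospacer, target_seq, cfd = load_cfd_matrix()) {
  g <- strsplit(protospacer, "")[[1]]
  t <- strsplit(target_seq, "")[[1]]
  if (length(g) != 20 || length(t) != 20) {
    stop("protospacer and target_seq must be 20 nt", call. = FALSE)
  }
  mm <- which(g != t)
  if (!length(mm)) return(1)
  keys <- paste(mm, g[mm], t[mm], sep = ":")
  act <- cfd[keys]
  if (any(is.na(act))) {
    stop(sprintf("missing CFD matrix entry for %s",
                 paste(keys[is.na(act)], collapse = ", ")), call. = FALSE)
  }
  prod(act)
}

#' Guide-level CFD specificity score
#'
#' Aggregates per-site CFD over all off-target sites as
#' `100 / (1 + sum(site CFD))`: 100 when no off-targets exist, and
#' monotonically non-increasing as off-targets are added.
#'
#' @param protospacer 20-nt guide sequence.
#' @param sites site table from [find_offtarget_sites()] (ideally searched
#'   at `max_mismatches >= 3`).
#' @param on_target logical vector flagging intended sites to exclude from
#'   the sum.
#' @param cfd matrix from [load_cfd_matrix()].
#' @return score in (0, 100\].
#' @export
cfd_specificity <- function(protospacer, sites,
                            on_target = rep(FALSE, nrow(sites)),
                            cfd = load_cfd_matrix()) {
  off <- sites[!on_target, , drop = FALSE]
  if (nrow(off) == 0) return(100)
  tot <- sum(vapply(off$target_seq, site_cfd, numeric(1),
                    protospacer = protospacer, cfd = cfd))
  100 / (1 + tot)
}
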