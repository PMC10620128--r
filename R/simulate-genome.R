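.rand_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one planted site: 10-nt pad | 20-nt protospacer (hexamer at nt 13-18) |
# N | GG | 10-nt pad. The guide cutting between protospacer nt 17/18 then
# cuts between motif positions 5 and 6, strictly inside the E-box.
.make_cassette <- function(hexamer, motifs, gc) {
  for (try in 1:100) {
    proto <- paste0(.rand_dna(12, gc), hexamer, .rand_dna(2, gc))
    site <- paste0(.rand_dna(10, gc), proto, .rand_dna(1, gc), "GG",
                   .rand_dna(10, gc))
    off <- seq_len(nchar(site) - 5L)
    hits <- which(substring(site, off, off + 5L) %in% motifs)
    if (identical(hits, 23L)) {       # exactly the planted occurrence
      return(list(site = site, protospacer = proto))
    }
  }
  stop("could not build a clean site cassette; unlucky random context",
       call. = FALSE)
}

#' Build a toy genome with planted E-boxes, exons and off-target decoys
#'
#' Generates a small multi-chromosome genome in which every planted E-box
#' sits inside a binding-site "peak" with a guaranteed guide placement
#' (PAM present, cut bond between motif positions 5 and 6), a chosen
#' fraction of E-boxes overlap planted coding exons, and near-duplicate
#' copies of planted protospacers (decoys) are inserted elsewhere with
#' specified mismatch positions so that the off-target retention rule is
#' exercised. Deterministic under `seed`.
#'
#' @param n_chromosomes number of chromosomes ("chr1", "chr2", ...).
#' @param chrom_length length of each chromosome in bp.
#' @param n_eboxes_per_motif planted E-boxes per motif in `motifs`.
#' @param motifs motif set, default [ebox_motifs()].
#' @param fraction_exonic fraction of planted E-boxes overlapped by a
#'   planted coding exon.
#' @param n_decoys number of off-target decoys (cycled over planted guides).
#' @param decoy_mismatch_positions list of integer vectors of protospacer
#'   positions (1-20) mutated in each decoy, recycled; the default plants
#'   both rule-rejecting ({3,7}: two mismatches, none in seed) and
#'   rule-passing ({3,15}) decoys.
#' @param gc genome GC content.
#' @param seed mandatory RNG seed.
#' @return list: `genome` (`DNAStringSet`), `peaks` (binding-site intervals
#'   with `source`), `eboxes` (truth table with `exonic` flag), `exons`,
#'   `guides` (planted guide per E-box), `decoys` (with `rejects_guide`
#'   truth per the retention rule).
#' @export
make_genome <- function(n_chromosomes = 2, chrom_length = 20000,
                        n_eboxes_per_motif = 2, motifs = ebox_motifs(),
                        fraction_exonic = 0, n_decoys = 0,
                        decoy_mismatch_positions = list(c(3L, 7L),
                                                        c(3L, 15L)),
                        gc = 0.41, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  .check_motif_set(motifs)
  withr::local_seed(seed)

  hexamers <- rep(motifs, each = n_eboxes_per_motif)
  n_ebox <- length(hexamers)
  site_w <- 43L
  decoy_w <- 23L
  widths <- c(rep(site_w, n_ebox), rep(decoy_w, n_decoys))
  n_feat <- length(widths)
  chrom_of <- rep_len(seq_len(n_chromosomes), n_feat)

  starts <- integer(n_feat)
  for (ch in seq_len(n_chromosomes)) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    seg <- chrom_length %/% length(idx)
    if (seg < max(widths[idx]) + 60L) {
      stop("placement error: too many features for the requested length",
           call. = FALSE)
    }
    jitter <- sample.int(seg - max(widths[idx]) - 40L, length(idx),
                         replace = TRUE)
    starts[idx] <- (seq_along(idx) - 1L) * seg + 20L + jitter
  }

  chrom_names <- paste0("chr", seq_len(n_chromosomes))
  seqs <- vapply(chrom_names, function(x) .rand_dna(chrom_length, gc), "")

  eboxes <- peaks <- guides <- vector("list", n_ebox)
  for (i in seq_len(n_ebox)) {
    cas <- .make_cassette(hexamers[i], motifs, gc)
    ch <- chrom_of[i]
    s0 <- starts[i]
    substr(seqs[ch], s0 + 1L, s0 + site_w) <- cas$site
    eb_start <- s0 + 10L + 12L
    peaks[[i]] <- data.frame(chrom = chrom_names[ch], start = s0,
                             end = s0 + site_w, source = "sim",
                             stringsAsFactors = FALSE)
    eboxes[[i]] <- data.frame(chrom = chrom_names[ch], start = eb_start,
                              end = eb_start + 6L, hexamer = hexamers[i],
                              exonic = FALSE, stringsAsFactors = FALSE)
    guides[[i]] <- data.frame(chrom = chrom_names[ch],
                              protospacer = cas$protospacer,
                              start = s0 + 10L, end = s0 + 30L,
                              strand = "+", cut_bond = eb_start + 5L,
                              ebox_start = eb_start,
                              stringsAsFactors = FALSE)
  }
  eboxes <- do.call(rbind, eboxes)
  peaks <- do.call(rbind, peaks)
  guides <- do.call(rbind, guides)

  n_exonic <- round(fraction_exonic * n_ebox)
  exons <- NULL
  if (n_exonic > 0) {
    which_ex <- seq_len(n_exonic)
    eboxes$exonic[which_ex] <- TRUE
    exons <- data.frame(chrom = eboxes$chrom[which_ex],
                        start = pmax(eboxes$start[which_ex] - 3L, 0L),
                        end = eboxes$end[which_ex] + 3L,
                        stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(chrom = character(), start = integer(),
                        end = integer())
  }

  decoys <- NULL
  if (n_decoys > 0) {
    rows <- vector("list", n_decoys)
    for (j in seq_len(n_decoys)) {
      gi <- (j - 1L) %% n_ebox + 1L
      mm <- sort(as.integer(
        decoy_mismatch_positions[[(j - 1L) %%
                                    length(decoy_mismatch_positions) + 1L]]))
      proto <- strsplit(guides$protospacer[gi], "")[[1]]
      for (pos in mm) {
        proto[pos] <- sample(setdiff(c("A", "C", "G", "T"), proto[pos]), 1)
      }
      decoy_seq <- paste0(paste(proto, collapse = ""),
                          .rand_dna(1, gc), "GG")
      fi <- n_ebox + j
      ch <- chrom_of[fi]
      s0 <- starts[fi]
      substr(seqs[ch], s0 + 1L, s0 + decoy_w) <- decoy_seq
      rejects <- !(length(mm) >= 3 || (length(mm) >= 2 && any(mm >= 9)))
      rows[[j]] <- data.frame(
        chrom = chrom_names[ch], start = s0, end = s0 + decoy_w,
        guide_protospacer = guides$protospacer[gi],
        decoy_protospacer = substr(decoy_seq, 1, 20),
        mismatch_positions = paste(mm, collapse = ","),
        n_mismatches = length(mm), rejects_guide = rejects,
        stringsAsFactors = FALSE)
    }
    decoys <- do.call(rbind, rows)
  } else {
    decoys <- data.frame(chrom = character(), start = integer(),
                         end = integer(), guide_protospacer = character(),
                         decoy_protospacer = character(),
                         mismatch_positions = character(),
                         n_mismatches = integer(),
                         rejects_guide = logical())
  }

  list(genome = as_genome(seqs), peaks = peaks, eboxes = eboxes,
       exons = exons, guides = guides, decoys = decoys)
}
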