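#' Simulate guide-level screen counts under the negative-binomial model
#'
#' Counts are drawn as `NB(mean = depth * q_g * s_j * 2^(x_j * beta_t),
#' dispersion alpha)` with `x_j = 1` for T1 samples, variance
#' `mu + alpha * mu^2`. Guide abundances `q_g` are log-normal (library
#' cloning inequality); spiked targets carry a true log2 fold change
#' `beta`. Deterministic under `seed`.
#'
#' @param n_targets number of targets (E-boxes).
#' @param guides_per_target guides per target.
#' @param depth mean reads per guide at unit size factor.
#' @param dispersion NB dispersion alpha.
#' @param n_spiked number of targets with a true effect.
#' @param beta true log2 fold change of spiked targets (negative =
#'   depleted).
#' @param n_replicates replicates per condition (T0/T1 each).
#' @param abundance_sdlog log-normal sd of guide abundances.
#' @param sample_depths optional per-sample depth multipliers (length
#'   `2 * n_replicates`, order T0 replicates then T1 replicates).
#' @param seed mandatory RNG seed.
#' @return list: `counts` (guide x sample integer matrix), `design`
#'   (`sample`, `condition`, `replicate`), `target_map` (`entry`,
#'   `target`), `truth` (`target`, `beta`, `spiked`).
#' @export
simulate_screen_counts <- function(n_targets, guides_per_target = 2,
                                   depth = 500, dispersion = 0.05,
                                   n_spiked = 0, beta = -2,
                                   n_replicates = 2,
                                   abundance_sdlog = 0.25,
                                   sample_depths = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(depth > 0, dispersion > 0, n_targets >= 1)
  withr::local_seed(seed)

  n_g <- n_targets * guides_per_target
  targets <- sprintf("EB%05d", seq_len(n_targets))
  entry_target <- rep(targets, each = guides_per_target)
  entries <- paste0(entry_target, "_sg",
                    rep(seq_len(guides_per_target), n_targets))

  betas <- stats::setNames(rep(0, n_targets), targets)
  spiked <- character()
  if (n_spiked > 0) {
    spiked <- sample(targets, n_spiked)
    betas[spiked] <- beta
  }
  q <- stats::rlnorm(n_g, meanlog = 0, sdlog = abundance_sdlog) /
    exp(abundance_sdlog^2 / 2)

  samples <- c(paste0("sim_r", seq_len(n_replicates), "_T0"),
               paste0("sim_r", seq_len(n_replicates), "_T1"))
  x <- rep(c(0, 1), each = n_replicates)
  if (is.null(sample_depths)) sample_depths <- rep(1, length(samples))
  stopifnot(length(sample_depths) == length(samples))

  counts <- matrix(0L, nrow = n_g, ncol = length(samples),
                   dimnames = list(entries, samples))
  beta_g <- betas[entry_target]
  for (j in seq_along(samples)) {
    mu <- depth * q * sample_depths[j] * 2^(x[j] * beta_g)
    counts[, j] <- as.integer(stats::rnbinom(n_g, mu = mu,
                                             size = 1 / dispersion))
  }
  list(counts = counts,
       design = data.frame(sample = samples,
                           condition = rep(c("T0", "T1"),
                                           each = n_replicates),
                           replicate = rep(seq_len(n_replicates), 2),
                           stringsAsFactors = FALSE),
       target_map = data.frame(entry = entries, target = entry_target,
                               stringsAsFactors = FALSE),
       truth = data.frame(target = targets, beta = unname(betas),
                          spiked = targets %in% spiked,
                          stringsAsFactors = FALSE))
}

#' Simulate amplicon FASTQ reads for one sample
#'
#' Emits one read per count unit: random 9-18-nt stagger + 8-nt sample
#' barcode + anchor + protospacer + 10-nt filler, then applies independent
#' per-base substitution errors at rate `error_rate`. Pre-anchor segments
#' are resampled if they happen to contain the anchor, so with
#' `error_rate = 0` exact counting reproduces the input column exactly.
#'
#' @param counts named integer vector (library entry -> read count).
#' @param protospacers named character vector (entry -> 20-nt sequence).
#' @param layout [amplicon_layout()]; its `barcode` (default `"ACGTACGT"`
#'   when unset) is embedded in each read.
#' @param error_rate per-base substitution probability.
#' @param seed mandatory RNG seed.
#' @param path optional FASTQ output file (written via Biostrings).
#' @return character vector of reads (invisibly when `path` is given), with
#'   attribute `"truth"` = entry name per read.
#' @export
simulate_fastq <- function(counts, protospacers,
                           layout = amplicon_layout(), error_rate = 0,
                           seed, path = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  withr::local_seed(seed)
  counts <- counts[counts > 0]
  entries <- rep(names(counts), counts)
  n <- length(entries)
  bc <- if (is.null(layout$barcode)) "ACGTACGT" else layout$barcode
  if (n == 0) {
    reads <- character()
  } else {
    proto <- protospacers[entries]
    if (any(is.na(proto))) {
      stop("protospacers missing for some counted entries", call. = FALSE)
    }
    rand_parts <- function(lens) {
      tot <- sum(lens)
      ltr <- sample(c("A", "C", "G", "T"), tot, replace = TRUE)
      vapply(split(ltr, rep(seq_along(lens), lens)), paste,
             character(1), collapse = "")
    }
    stag_len <- sample(layout$stagger_range[1]:layout$stagger_range[2],
                       n, replace = TRUE)
    stagger <- rand_parts(stag_len)
    filler <- rand_parts(rep(10L, n))
    reads <- paste0(stagger, bc, layout$anchor, proto, filler)
    # the anchor must first occur where intended; resample colliders
    expect_at <- stag_len + nchar(bc) + 1L
    for (it in 1:20) {
      bad <- which(regexpr(layout$anchor, reads, fixed = TRUE) != expect_at)
      if (!length(bad)) break
      stagger[bad] <- rand_parts(stag_len[bad])
      reads[bad] <- paste0(stagger[bad], bc, layout$anchor, proto[bad],
                           filler[bad])
    }
    if (error_rate > 0) {
      lens <- nchar(reads)
      n_err <- stats::rbinom(n, lens, error_rate)
      for (i in which(n_err > 0)) {
        ch <- strsplit(reads[i], "")[[1]]
        at <- sample.int(lens[i], n_err[i])
        ch[at] <- vapply(ch[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
        reads[i] <- paste(ch, collapse = "")
      }
    }
  }
  attr(reads, "truth") <- entries
  if (!is.null(path)) {
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- sprintf("read%07d %s", seq_len(n), entries)
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = qual)
    return(invisible(reads))
  }
  reads
}
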