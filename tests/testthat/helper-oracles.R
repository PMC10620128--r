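# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: per-base set arithmetic for intervals,
# character-level sliding-window scans for guides and off-targets.

# covered bases of an interval table as "chrom:pos" keys
oracle_base_set <- function(x) {
  if (nrow(x) == 0) return(character())
  unlist(lapply(seq_len(nrow(x)), function(i) {
    paste0(x$chrom[i], ":", seq(x$start[i], x$end[i] - 1L))
  }))
}

rand_proto <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, "")
}

rand_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 1000,
                           max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exhaustive sliding-window Hamming scan over both strands with PAM check
oracle_offtargets <- function(protospacer, genome, max_mm) {
  p <- strsplit(protospacer, "")[[1]]
  rcp <- strsplit(eboxscreen::reverse_complement(protospacer), "")[[1]]
  res <- list()
  for (chrom in names(genome)) {
    s <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    L <- length(s)
    if (L < 23) next
    nw <- L - 19L
    mmp <- integer(nw)
    mmm <- integer(nw)
    for (k in 1:20) {
      seg <- s[k:(k + nw - 1L)]
      mmp <- mmp + (seg != p[k])
      mmm <- mmm + (seg != rcp[k])
    }
    w <- which(mmp <= max_mm)
    w <- w[w + 22L <= L]
    w <- w[s[w + 21L] == "G" & s[w + 22L] == "G"]
    for (wi in w) {
      row <- data.frame(chrom = chrom, start = wi - 1L, strand = "+",
                        n_mismatches = mmp[wi], stringsAsFactors = FALSE)
      row$mismatch_positions <- list(which(s[wi:(wi + 19L)] != p))
      res[[length(res) + 1L]] <- row
    }
    w <- which(mmm <= max_mm)
    w <- w[w >= 4L]
    w <- w[s[w - 3L] == "C" & s[w - 2L] == "C"]
    for (wi in w) {
      tgt <- eboxscreen::reverse_complement(
        paste(s[wi:(wi + 19L)], collapse = ""))
      mm <- which(strsplit(tgt, "")[[1]] != p)
      row <- data.frame(chrom = chrom, start = wi - 1L, strand = "-",
                        n_mismatches = length(mm), stringsAsFactors = FALSE)
      row$mismatch_positions <- list(mm)
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      strand = character(), n_mismatches = integer())
    out$mismatch_positions <- list()
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# the retention rule applied directly from an oracle site table
oracle_rule <- function(sites, on_target) {
  off <- sites[!on_target, , drop = FALSE]
  if (nrow(off) == 0) return(TRUE)
  all(vapply(seq_len(nrow(off)), function(i) {
    mm <- off$mismatch_positions[[i]]
    length(mm) >= 3 || (length(mm) >= 2 && any(mm >= 9))
  }, logical(1)))
}

# exhaustive placement oracle: every protospacer window on either strand
# whose PAM is present and whose cut bond is one of the E-box's 5 internal
# bonds (small toys only)
oracle_enumerate <- function(genome, chrom, ebox_start) {
  cs <- as.character(genome[[chrom]])
  L <- nchar(cs)
  res <- list()
  bonds <- (ebox_start + 1L):(ebox_start + 5L)
  for (g in 0:(L - 23L)) {
    if (substr(cs, g + 22L, g + 23L) == "GG" && (g + 17L) %in% bonds) {
      proto <- substr(cs, g + 1L, g + 20L)
      if (!grepl("N", proto, fixed = TRUE)) {
        res[[length(res) + 1L]] <- data.frame(
          protospacer = proto, strand = "+", start = g,
          cut_bond = g + 17L, stringsAsFactors = FALSE)
      }
    }
  }
  for (g in 3:(L - 20L)) {
    if (substr(cs, g - 2L, g - 1L) == "CC" && (g + 3L) %in% bonds) {
      raw <- substr(cs, g + 1L, g + 20L)
      if (!grepl("N", raw, fixed = TRUE)) {
        res[[length(res) + 1L]] <- data.frame(
          protospacer = eboxscreen::reverse_complement(raw),
          strand = "-", start = g, cut_bond = g + 3L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(protospacer = character(), strand = character(),
                      start = integer(), cut_bond = integer())
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# a one-E-box table as scan_eboxes would emit it, for toy genomes
toy_ebox <- function(chrom, start, hexamer, site = "BS1") {
  data.frame(chrom = chrom, start = start, end = start + 6L,
             hexamer = hexamer, site_id = paste0(chrom, "_", site),
             ebox_id = paste0(chrom, "_", site, "_", hexamer),
             exonic = FALSE, stringsAsFactors = FALSE)
}

# symmetric flank profile drawn from a per-position base model; the +1
# genomic base has P(G) = pG1, the -1 base mirrors it with P(C) = pG1,
# all other positions are uniform
sim_flank_profile <- function(n, K, pG1 = 0.25) {
  bases <- c("A", "C", "G", "T")
  draw <- function(prob) sample(bases, n, replace = TRUE, prob = prob)
  pos_labels <- c(paste0("-", K:1), paste0("+", 1:K))
  plus <- matrix(0L, 2 * K, 4, dimnames = list(pos_labels, bases))
  other <- (1 - pG1) / 3
  for (lab in pos_labels) {
    prob <- rep(0.25, 4)
    if (lab == "+1") prob <- c(other, other, pG1, other)
    if (lab == "-1") prob <- c(other, pG1, other, other)
    plus[lab, ] <- as.integer(table(factor(draw(prob), levels = bases)))
  }
  mirror <- plus[rev(seq_len(2 * K)), c("T", "G", "C", "A")]
  dimnames(mirror) <- dimnames(plus)
  structure(list(counts = plus + mirror, n_eboxes = n, K = K,
                 n_dropped = 0L),
            class = "flank_profile")
}
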