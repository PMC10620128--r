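test_that("both orientation readings are pooled into a symmetric profile", {
  # E-box at [10, 16) with G at +1 (position 16) and A at -1 (position 9)
  seq <- paste0(strrep("T", 9), "A", "CACGTG", "G", strrep("T", 9))
  g <- as_genome(c(chr1 = seq))
  eb <- toy_ebox("chr1", 10L, "CACGTG")
  pr <- pooled_flank_counts(eb, g, K = 3)
  expect_equal(unname(pr$counts["+1", "G"]), 1L)   # plus reading
  expect_equal(unname(pr$counts["-1", "C"]), 1L)   # its mirrored reading
  expect_equal(unname(pr$counts["-1", "A"]), 1L)   # plus reading at -1
  expect_equal(unname(pr$counts["+1", "T"]), 1L)   # its mirrored reading
  expect_equal(unname(rowSums(pr$counts)), rep(2L, 6))
})

test_that("profiles satisfy the mirror-complement identity exactly", {
  fx <- make_genome(n_chromosomes = 2, chrom_length = 30000,
                    n_eboxes_per_motif = 10, seed = 41)
  for (K in c(5, 10, 20)) {
    pr <- pooled_flank_counts(fx$eboxes, fx$genome, K = K)
    mirrored <- pr$counts[rev(seq_len(2 * K)), c("T", "G", "C", "A")]
    dimnames(mirrored) <- dimnames(pr$counts)
    expect_identical(pr$counts, mirrored)
    expect_equal(unname(rowSums(pr$counts)),
                 rep(2L * pr$n_eboxes, 2 * K))
  }
  expect_error(pooled_flank_counts(fx$eboxes, fx$genome, K = 0),
               "positive")
})

test_that("E-boxes too close to a contig edge are dropped with a warning", {
  g <- as_genome(c(chr1 = paste0("AC", "CACGTG", strrep("T", 40))))
  eb <- rbind(toy_ebox("chr1", 2L, "CACGTG"),
              toy_ebox("chr1", 20L, "CACGTG"))
  expect_warning(pr <- pooled_flank_counts(eb, g, K = 10), "dropping 1")
  expect_equal(pr$n_eboxes, 1L)
  expect_equal(pr$n_dropped, 1L)
})

test_that("goodness-of-fit is zero on proportional profiles", {
  pr <- sim_flank_profile(200, K = 5)
  gof <- flank_gof_test(pr, pr)
  expect_true(all(gof$chi2 < 1e-9))
  expect_true(all(gof$p > 0.999999))
  expect_equal(nrow(gof), 5 * 5)  # "all" + 4 bases per position
})

test_that("the Pearson statistic matches the hand-computed example", {
  mk <- function(counts_p1) {
    m <- matrix(50L, 4, 4, dimnames = list(c("-2", "-1", "+1", "+2"),
                                           c("A", "C", "G", "T")))
    m["+1", ] <- as.integer(counts_p1)
    m["-1", ] <- m["+1", c("T", "G", "C", "A")]  # mirror-complement row
    structure(list(counts = m, n_eboxes = sum(counts_p1) / 2, K = 2L,
                   n_dropped = 0L), class = "flank_profile")
  }
  ess <- mk(c(10, 10, 10, 70))
  bg <- mk(c(250, 250, 250, 250))
  gof <- flank_gof_test(ess, bg)
  row <- gof[gof$position == 1 & gof$nucleotide == "all", ]
  expect_equal(row$chi2, 108)
  expect_equal(row$df, 3L)

  # doubling both profiles doubles the statistic (documented n-dependence)
  ess2 <- mk(2 * c(10, 10, 10, 70))
  gof2 <- flank_gof_test(ess2, bg)
  expect_equal(gof2$chi2[gof2$position == 1 & gof2$nucleotide == "all"],
               216)
})

test_that("zero-probability background categories trip the continuity guard", {
  mk <- function(counts_p1) {
    m <- matrix(50L, 2, 4, dimnames = list(c("-1", "+1"),
                                           c("A", "C", "G", "T")))
    m["+1", ] <- as.integer(counts_p1)
    m["-1", ] <- m["+1", c("T", "G", "C", "A")]
    structure(list(counts = m, n_eboxes = sum(counts_p1) / 2, K = 1L,
                   n_dropped = 0L), class = "flank_profile")
  }
  gof <- flank_gof_test(mk(c(5, 5, 5, 5)), mk(c(0, 10, 10, 0)))
  expect_true(all(gof$zero_guard))
  expect_true(all(is.finite(gof$chi2)))
  expect_error(flank_gof_test(mk(c(1, 1, 1, 1)), sim_flank_profile(10, 3)),
               "different flank widths")
})

test_that("logo matrix row-normalizes and inherits the symmetry", {
  pr <- sim_flank_profile(500, K = 4)
  lm <- logo_matrix(pr)
  expect_equal(unname(rowSums(lm)), rep(1, 8))
  mirrored <- lm[rev(seq_len(8)), c("T", "G", "C", "A")]
  dimnames(mirrored) <- dimnames(lm)
  expect_equal(lm, mirrored)

  onehot <- structure(list(
    counts = matrix(c(0L, 0L, 200L, 0L, 0L, 200L, 0L, 0L), 2, 4,
                    byrow = TRUE,
                    dimnames = list(c("-1", "+1"), c("A", "C", "G", "T"))),
    n_eboxes = 100L, K = 1L, n_dropped = 0L), class = "flank_profile")
  expect_equal(unname(logo_matrix(onehot)["+1", ]), c(0, 1, 0, 0))
  empty <- structure(list(counts = matrix(0L, 2, 4), n_eboxes = 0L,
                          K = 1L, n_dropped = 0L), class = "flank_profile")
  expect_error(logo_matrix(empty), "empty")
})
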