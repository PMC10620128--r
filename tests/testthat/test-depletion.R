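std_design <- function() {
  data.frame(sample = c("r1_T0", "r2_T0", "r1_T1", "r2_T1"),
             condition = rep(c("T0", "T1"), each = 2),
             replicate = rep(1:2, 2), stringsAsFactors = FALSE)
}

test_that("aggregation sums member guides and conserves totals", {
  m <- matrix(c(10L, 20L, 30L, 5L,
                1L, 2L, 3L, 4L), ncol = 2,
              dimnames = list(c("a_sg1", "a_sg2", "a_sg3", "b_sg1"),
                              c("s1", "s2")))
  map <- data.frame(entry = rownames(m), target = c("A", "A", "A", "B"))
  agg <- aggregate_by_target(m, map)
  expect_equal(agg["A", "s1"], 60L)
  expect_equal(colSums(agg), colSums(m))

  # a guide mapping to two targets contributes to both rows
  map2 <- rbind(map, data.frame(entry = "b_sg1", target = "A"))
  agg2 <- aggregate_by_target(m, map2)
  expect_equal(agg2["A", "s1"], 65L)
  expect_equal(agg2["B", "s1"], 5L)

  expect_error(aggregate_by_target(m, map[1:3, ]), "b_sg1")
  expect_silent(aggregate_by_target(m, map[1:3, ], unmapped_ok = "b_sg1"))
})

test_that("size factors are equivariant and recover simulated depths", {
  m <- matrix(rpois(400, 100) + 1L, ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  m[, 2] <- m[, 1]
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  depths <- c(1, 1.3, 0.8, 1.5)
  sim <- simulate_screen_counts(n_targets = 250, guides_per_target = 2,
                                depth = 400, dispersion = 0.02,
                                sample_depths = depths, seed = 61)
  sf <- estimate_size_factors(sim$counts)
  rel <- (sf / exp(mean(log(sf)))) / (depths / exp(mean(log(depths))))
  expect_true(all(abs(rel - 1) < 0.02))

  zeroes <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  expect_error(estimate_size_factors(zeroes), "poscounts")
  expect_length(estimate_size_factors(zeroes, type = "poscounts"), 2)
})

test_that("identical T0/T1 profiles give log2FC 0 and no calls", {
  base <- matrix(rep(c(100L, 400L, 50L), 4), ncol = 4,
                 dimnames = list(c("A", "B", "C"),
                                 std_design()$sample))
  res <- nb_wald_test(base, std_design())
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-8)
  expect_true(all(res$p > 0.99))
  expect_equal(res$call, rep("ns", 3))
})

test_that("zero-total targets are excluded and reported", {
  m <- matrix(c(rep(10L, 4), rep(0L, 4), rep(30L, 4)), byrow = TRUE,
              nrow = 3, dimnames = list(c("A", "Z", "B"),
                                        std_design()$sample))
  res <- nb_wald_test(m, std_design())
  expect_equal(attr(res, "excluded"), "Z")
  expect_setequal(res$target, c("A", "B"))
})

test_that("degenerate designs are refused", {
  m <- matrix(10L, 3, 4, dimnames = list(c("A", "B", "C"),
                                         std_design()$sample))
  d1 <- std_design(); d1$condition <- "T0"
  expect_error(nb_wald_test(m, d1), "degenerate")
  d2 <- std_design()[c(1, 3, 4), ]
  expect_error(nb_wald_test(m[, d2$sample], d2), "at least 2")
})

test_that("spiked depletions are recovered with calibrated effect sizes", {
  sim <- simulate_screen_counts(n_targets = 400, guides_per_target = 2,
                                depth = 500, dispersion = 0.05,
                                n_spiked = 40, beta = -2, seed = 77)
  agg <- aggregate_by_target(sim$counts, sim$target_map)
  res <- nb_wald_test(agg, sim$design)
  spiked <- sim$truth$target[sim$truth$spiked]
  dep <- res$target[res$call == "depleted"]
  expect_gte(mean(spiked %in% dep), 0.9)
  expect_lt(abs(median(res$log2fc[res$target %in% spiked]) + 2), 0.2)
  expect_equal(sum(!(dep %in% spiked)), 0)

  # calls are monotone in the padj threshold
  res4 <- nb_wald_test(agg, sim$design, padj_threshold = 1e-4)
  expect_true(all(res4$target[res4$call == "depleted"] %in% dep))
})

test_that("results agree with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_screen_counts(n_targets = 300, guides_per_target = 2,
                                depth = 300, dispersion = 0.05,
                                n_spiked = 30, beta = -2, seed = 21)
  agg <- aggregate_by_target(sim$counts, sim$target_map)
  res <- nb_wald_test(agg, sim$design)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      agg[, sim$design$sample],
      data.frame(condition = factor(sim$design$condition,
                                    levels = c("T0", "T1"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    r2 <- DESeq2::results(dds)
  })
  expect_equal(unname(attr(res, "size_factors")),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-10)
  m <- match(res$target, rownames(r2))
  expect_gt(cor(res$log2fc, r2$log2FoldChange[m]), 0.999)
  expect_gt(cor(res$wald, r2$stat[m]), 0.99)
  ours <- res$call == "depleted"
  theirs <- !is.na(r2$padj[m]) & r2$padj[m] < 0.001 &
    r2$log2FoldChange[m] < 0
  expect_gt(mean(ours == theirs), 0.97)
})

test_that("replicate consistency requires the fold change in both replicates", {
  d <- std_design()
  base <- 1000L
  mk <- function(r1_ratio, r2_ratio) {
    c(base, base, as.integer(base * r1_ratio), as.integer(base * r2_ratio))
  }
  m <- rbind(g_in = mk(0.4, 0.4), g_out = mk(0.4, 0.6),
             g_flat = mk(1, 1), g_up = mk(3, 3))
  # pad with stable guides so size factors are ~1
  pad <- matrix(rep(500L, 4 * 50), ncol = 4,
                dimnames = list(paste0("pad", 1:50), NULL))
  m <- rbind(m, pad)
  colnames(m) <- d$sample
  hits <- replicate_consistency(m, d, fold_threshold = 2)
  expect_true("g_in" %in% hits)
  expect_false("g_out" %in% hits)
  expect_false("g_flat" %in% hits)
  up <- replicate_consistency(m, d, direction = "enriched")
  expect_true("g_up" %in% up)

  # brute-force oracle on simulated ratios
  sim <- simulate_screen_counts(n_targets = 100, guides_per_target = 2,
                                depth = 200, n_spiked = 20, beta = -2,
                                seed = 87)
  got <- replicate_consistency(sim$counts, sim$design)
  sf <- estimate_size_factors(sim$counts)
  norm <- sweep(sim$counts, 2, sf, "/")
  want <- rownames(norm)[
    (norm[, "sim_r1_T1"] + 0.5) / (norm[, "sim_r1_T0"] + 0.5) <= 0.5 &
      (norm[, "sim_r2_T1"] + 0.5) / (norm[, "sim_r2_T0"] + 0.5) <= 0.5]
  expect_setequal(got, want)
})

test_that("hit-set overlap counts targets by membership multiplicity", {
  out <- intersect_hits(list(x = c("A", "B"), y = c("B", "C")))
  expect_equal(out$membership$n_sets[out$membership$target == "B"], 2)
  expect_setequal(
    out$membership$target[out$membership$n_sets == 1], c("A", "C"))
  expect_equal(out$n_union, 3)

  same <- intersect_hits(list(a = c("x", "y"), b = c("x", "y"),
                              c = c("x", "y")))
  expect_equal(same$by_k$n_targets, c(0L, 0L, 2L))

  set.seed(31)
  sets <- lapply(1:4, function(i) sample(LETTERS, 10))
  names(sets) <- paste0("cl", 1:4)
  out <- intersect_hits(sets)
  u <- unique(unlist(sets))
  k_oracle <- vapply(u, function(t) {
    sum(vapply(sets, function(s) t %in% s, logical(1)))
  }, 1L)
  expect_equal(sum(out$by_k$n_targets), length(u))
  expect_equal(sort(out$membership$n_sets),
               sort(unname(k_oracle)))
  expect_error(intersect_hits(list(c("A"))), "at least 2")
})

test_that("nearest-TSS assignment respects the window and picks closest per side", {
  eb <- toy_ebox("chr1", 100000L, "CACGTG")  # midpoint 100003
  tss <- data.frame(gene = c("far_left", "near_left", "right", "off"),
                    chrom = c("chr1", "chr1", "chr1", "chr2"),
                    tss = c(100003L - 30000L, 100003L - 10000L,
                            100003L + 50000L, 5L))
  out <- nearest_tss_genes(eb, tss, window = 50000)
  expect_equal(out$gene[out$side == "left"], "near_left")
  expect_equal(out$gene[out$side == "right"], "right")  # inclusive boundary
  out2 <- nearest_tss_genes(eb, transform(tss, tss = tss + 1L),
                            window = 50000)
  expect_false("right" %in% out2$gene[out2$side == "right"])

  none <- nearest_tss_genes(toy_ebox("chr9", 500L, "CACGTG"), tss)
  expect_equal(nrow(none), 0)

  tie <- data.frame(gene = c("zeta", "alpha"), chrom = "chr1",
                    tss = c(99000L, 99000L))
  out3 <- nearest_tss_genes(eb, tie)
  expect_equal(out3$gene[out3$side == "left"], "alpha")
})
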