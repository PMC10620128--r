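test_that("planted E-boxes are recoverable and reproducible", {
  fx <- make_genome(n_chromosomes = 2, chrom_length = 20000,
                    n_eboxes_per_motif = 2, seed = 19)
  sites <- assign_binding_sites(merge_intervals(fx$peaks))
  found <- scan_eboxes(fx$genome, sites)
  expect_equal(nrow(found), nrow(fx$eboxes))
  expect_setequal(paste(found$chrom, found$start, found$hexamer),
                  paste(fx$eboxes$chrom, fx$eboxes$start,
                        fx$eboxes$hexamer))

  fx2 <- make_genome(n_chromosomes = 2, chrom_length = 20000,
                     n_eboxes_per_motif = 2, seed = 19)
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
  expect_identical(fx$decoys, fx2$decoys)
  expect_error(make_genome(n_chromosomes = 1, chrom_length = 500,
                           n_eboxes_per_motif = 3, seed = 1),
               "placement")
  expect_error(make_genome(n_chromosomes = 1), "seed")
})

test_that("the requested fraction of E-boxes overlaps planted exons", {
  fx <- make_genome(n_chromosomes = 2, chrom_length = 30000,
                    n_eboxes_per_motif = 2, fraction_exonic = 0.3,
                    seed = 23)
  n_overlap <- sum(vapply(seq_len(nrow(fx$eboxes)), function(i) {
    any(overlaps(fx$eboxes[i, ], fx$exons))
  }, logical(1)))
  expect_equal(n_overlap, 3)
  expect_equal(sum(fx$eboxes$exonic), 3)
})

test_that("planted decoys trip or pass the retention rule as labelled", {
  fx <- make_genome(n_chromosomes = 2, chrom_length = 30000,
                    n_eboxes_per_motif = 2, n_decoys = 10, seed = 37)
  eb <- cbind(fx$eboxes, ebox_id = paste0("eb", seq_len(nrow(fx$eboxes))))
  for (j in seq_len(nrow(fx$decoys))) {
    p <- fx$decoys$guide_protospacer[j]
    sites <- find_offtarget_sites(p, fx$genome, max_mismatches = 2)
    on <- mark_on_target(sites, eb)
    pass <- passes_offtarget_rule(sites, on)
    # a guide can have several decoys; it must fail if ANY decoy of this
    # guide is rejecting, so only check the implication for its own label
    if (fx$decoys$rejects_guide[j]) expect_false(pass)
  }
  # mismatch truth: the planted decoy differs exactly at the stated positions
  for (j in seq_len(nrow(fx$decoys))) {
    a <- strsplit(fx$decoys$guide_protospacer[j], "")[[1]]
    b <- strsplit(fx$decoys$decoy_protospacer[j], "")[[1]]
    expect_equal(which(a != b),
                 as.integer(strsplit(fx$decoys$mismatch_positions[j],
                                     ",")[[1]]))
  }
})

test_that("screen counts follow the NB model with spiked effects", {
  sim <- simulate_screen_counts(n_targets = 500, guides_per_target = 2,
                                depth = 500, dispersion = 0.05,
                                n_spiked = 50, beta = -2, seed = 67)
  expect_identical(
    sim$counts,
    simulate_screen_counts(n_targets = 500, guides_per_target = 2,
                           depth = 500, dispersion = 0.05, n_spiked = 50,
                           beta = -2, seed = 67)$counts)
  spiked_g <- sim$target_map$target %in% sim$truth$target[sim$truth$spiked]
  t0 <- rowMeans(sim$counts[, 1:2])
  t1 <- rowMeans(sim$counts[, 3:4])
  ratio <- (t1 + 0.5) / (t0 + 0.5)
  expect_lt(abs(median(ratio[spiked_g]) - 0.25), 0.05)
  expect_lt(abs(median(ratio[!spiked_g]) - 1), 0.05)

  # near-Poisson limit at huge depth: empirical log2FC hugs the truth
  lim <- simulate_screen_counts(n_targets = 50, guides_per_target = 4,
                                depth = 2e5, dispersion = 1e-6,
                                n_spiked = 10, beta = -2, seed = 68)
  agg <- aggregate_by_target(lim$counts, lim$target_map)
  lfc <- log2(rowMeans(agg[, 3:4]) / rowMeans(agg[, 1:2]))
  want <- stats::setNames(lim$truth$beta, lim$truth$target)[rownames(agg)]
  expect_true(all(abs(lfc - want) < 0.05))
})

test_that("FASTQ simulation degrades gracefully with the error rate", {
  counts <- stats::setNames(c(400L, 300L, 300L), c("g1", "g2", "g3"))
  set.seed(1)
  protos <- stats::setNames(rand_proto(3), names(counts))
  lib <- data.frame(name = names(counts), protospacer = unname(protos))

  reads0 <- simulate_fastq(counts, protos, seed = 5)
  cc0 <- count_exact(extract_protospacer(reads0), lib)
  expect_equal(unname(as.integer(cc0)), unname(counts))

  matched <- vapply(c(0, 0.005, 0.02, 0.08), function(eps) {
    reads <- simulate_fastq(counts, protos, error_rate = eps, seed = 5)
    sum(count_exact(extract_protospacer(reads), lib)) / sum(counts)
  }, numeric(1))
  expect_equal(matched[1], 1)
  expect_true(all(diff(matched) < 0))

  empty <- simulate_fastq(stats::setNames(integer(0), character(0)),
                          protos, seed = 2)
  expect_length(empty, 0)
})

test_that("count permutation invariance: counting is a pure fold", {
  set.seed(44)
  protos <- rand_proto(5)
  lib <- data.frame(name = paste0("g", 1:5), protospacer = protos)
  stream <- sample(c(protos[c(1, 1, 2, 3, 3, 3)], rand_proto(2)))
  c1 <- count_exact(stream, lib)
  c2 <- count_exact(rev(stream), lib)
  expect_equal(as.integer(c1), as.integer(c2))
})
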