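#' Aggregate guide-level counts to targets
#'
#' Read counts of all guides assigned to one E-box (or gene) are summed.
#' A guide mapped to several targets contributes to each of them; per-sample
#' totals over mapped entries are conserved for 1:1 mappings.
#'
#' @param counts integer matrix, rows = library entries, columns = samples.
#' @param target_map data frame with `entry`, `target` (an entry may appear
#'   on several rows).
#' @param unmapped_ok entry names allowed to be absent from the map
#'   (controls); any other unmapped row is an error listing the names.
#' @return integer matrix, rows = targets.
#' @export
aggregate_by_target <- function(counts, target_map,
                                unmapped_ok = character()) {
  missing <- setdiff(rownames(counts), c(target_map$entry, unmapped_ok))
  if (length(missing)) {
    stop(sprintf("entries missing from target map: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  map <- target_map[target_map$entry %in% rownames(counts), , drop = FALSE]
  sub <- counts[map$entry, , drop = FALSE]
  out <- rowsum(sub, group = map$target, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over rows (with all-positive counts) of the
#' ratio count / row geometric mean. Identical columns get identical
#' factors; scaling a column by `c` scales its factor by `c`.
#'
#' @param counts integer matrix.
#' @param type `"ratio"` (classical; needs >= 1 all-positive row) or
#'   `"poscounts"` (pseudo-reference over positive counts only, for
#'   zero-heavy matrices).
#' @return numeric vector of per-sample factors.
#' @export
estimate_size_factors <- function(counts, type = c("ratio", "poscounts")) {
  type <- match.arg(type)
  lc <- log(counts)
  if (type == "ratio") {
    loggeo <- rowMeans(lc)
    ok <- is.finite(loggeo)
    if (!any(ok)) {
      stop(paste("no row with all-positive counts;",
                 "use type = 'poscounts' (pseudo-reference fallback)"),
           call. = FALSE)
    }
    sf <- apply(lc[ok, , drop = FALSE], 2,
                function(x) exp(stats::median(x - loggeo[ok])))
  } else {
    loggeo <- apply(lc, 1, function(x) {
      x <- x[is.finite(x)]
      if (length(x)) mean(x) else NA_real_
    })
    ok <- !is.na(loggeo)
    sf <- apply(counts[ok, , drop = FALSE], 2, function(cnt) {
      r <- cnt / exp(loggeo[ok])
      exp(stats::median(log(r[cnt > 0])))
    })
  }
  stats::setNames(sf, colnames(counts))
}

# Dispersion machinery: per-target method-of-moments estimates, a parametric
# mean-dispersion trend alpha(mu) = a1/mu + a0 fitted by iteratively
# reweighted gamma regression, and per-target MAP shrinkage toward the trend
# under a log-normal prior with a Cox-Reid adjusted NB likelihood.
.fit_dispersions <- function(counts, sf, cond) {
  norm <- sweep(counts, 2, sf, "/")
  m <- ncol(counts)
  levs <- levels(cond)
  p <- length(levs)
  grp_mean <- vapply(levs, function(l) {
    rowMeans(norm[, cond == l, drop = FALSE])
  }, numeric(nrow(counts)))
  base_mean <- rowMeans(norm)
  xim <- mean(1 / sf)
  resid2 <- (norm - grp_mean[, as.integer(cond)])^2
  s2 <- rowSums(resid2) / (m - p)
  mom <- pmax((s2 - xim * base_mean) / base_mean^2, 1e-8)

  use <- base_mean > 0 & mom > 1e-7
  a0 <- stats::median(mom[use])
  a1 <- 0
  if (sum(use) >= 10) {
    keep <- use
    for (it in 1:4) {
      fit <- try(suppressWarnings(stats::glm(
        mom[keep] ~ I(1 / base_mean[keep]),
        family = stats::Gamma(link = "identity"),
        start = c(max(a0, 1e-4), max(a1, 1e-8)))), silent = TRUE)
      if (inherits(fit, "try-error")) break
      cf <- stats::coef(fit)
      a0 <- max(cf[1], 1e-8); a1 <- max(cf[2], 0)
      pred <- a1 / base_mean + a0
      keep_new <- use & mom / pred < 15 & mom / pred > 1e-4
      if (identical(keep_new, keep)) break
      keep <- keep_new
    }
  }
  trend <- pmax(a1 / base_mean + a0, 1e-8)

  lr <- log(mom[use]) - log(trend[use])
  slr2 <- stats::mad(lr)^2
  prior_var <- max(slr2 - trigamma((m - p) / 2), 0.25)
  prior_sd <- sqrt(prior_var)

  map <- numeric(nrow(counts))
  g_idx <- lapply(levs, function(l) which(cond == l))
  for (i in seq_len(nrow(counts))) {
    mu <- pmax(grp_mean[i, as.integer(cond)] * sf, 1e-8)
    y <- counts[i, ]
    lt <- log(trend[i])
    obj <- function(la) {
      a <- exp(la)
      ll <- sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
      w <- mu / (1 + a * mu)
      cr <- -0.5 * sum(vapply(g_idx, function(j) log(sum(w[j])),
                              numeric(1)))
      val <- ll + cr + stats::dnorm(la, mean = lt, sd = prior_sd,
                                    log = TRUE)
      if (!is.finite(val)) -1e12 else val
    }
    opt <- stats::optimize(obj, interval = c(log(1e-8), log(100)),
                           maximum = TRUE)
    map[i] <- exp(opt$maximum)
  }
  list(mom = mom, trend = trend, map = map, base_mean = base_mean,
       trend_coef = c(a0 = a0, a1 = a1), prior_sd = prior_sd)
}

#' Negative-binomial Wald test for target depletion
#'
#' Per target: size factors by median-of-ratios; dispersion by
#' method-of-moments, a parametric trend `alpha(mu) = a1/mu + a0`, and MAP
#' shrinkage toward the trend under a log-normal prior; then a
#' negative-binomial GLM `log mu = log s_j + q + beta * x_j` (x = 1 at the
#' endpoint T1), Wald statistic `beta / se(beta)` against the standard
#' normal, two-sided p, and Benjamini-Hochberg adjustment over all tested
#' targets. Depletion is a negative log2 fold change at T1. Targets with
#' zero total counts are excluded and reported in the `"excluded"`
#' attribute.
#'
#' @param counts integer matrix aggregated to targets (see
#'   [aggregate_by_target()]).
#' @param design data frame with `sample` (matching column names) and
#'   `condition` ("T0" reference / "T1").
#' @param padj_threshold significance cut-off for calls (default 0.001).
#' @param size_factor_type passed to [estimate_size_factors()].
#' @return data frame: `target`, `base_mean`, `log2fc`, `se`, `wald`, `p`,
#'   `padj`, `call` in {"depleted", "enriched", "ns"}; attributes
#'   `"dispersion"` (fit summary) and `"excluded"` (zero-count targets).
#' @export
nb_wald_test <- function(counts, design, padj_threshold = 0.001,
                         size_factor_type = "ratio") {
  if (is.null(design$sample) || is.null(design$condition)) {
    stop("design needs 'sample' and 'condition' columns", call. = FALSE)
  }
  counts <- counts[, design$sample, drop = FALSE]
  cond <- factor(design$condition, levels = c("T0", "T1"))
  if (any(is.na(cond)) || length(unique(cond)) < 2) {
    stop("degenerate design: need both T0 and T1 conditions", call. = FALSE)
  }
  if (any(table(cond) < 2)) {
    stop("need at least 2 samples per condition", call. = FALSE)
  }
  sf <- estimate_size_factors(counts, type = size_factor_type)
  keep <- rowSums(counts) > 0
  excluded <- rownames(counts)[!keep]
  cm <- counts[keep, , drop = FALSE]

  disp <- .fit_dispersions(cm, sf, cond)

  x01 <- as.integer(cond == "T1")
  lo <- log(sf)
  fit_one <- function(y, alpha) {
    th <- 1 / max(alpha, 1e-8)
    fit <- try(suppressWarnings(stats::glm(
      y ~ x01 + offset(lo),
      family = MASS::negative.binomial(theta = th, link = "log"))),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(c(NA_real_, NA_real_))
    co <- suppressWarnings(summary(fit, dispersion = 1)$coefficients)
    if (nrow(co) < 2) return(c(NA_real_, NA_real_))
    co[2, 1:2]
  }
  est <- t(vapply(seq_len(nrow(cm)),
                  function(i) fit_one(cm[i, ], disp$map[i]),
                  numeric(2)))
  log2fc <- est[, 1] / log(2)
  se <- est[, 2] / log(2)
  wald <- est[, 1] / est[, 2]
  p <- 2 * stats::pnorm(-abs(wald))
  padj <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", nrow(cm))
  call[!is.na(padj) & padj < padj_threshold & log2fc < 0] <- "depleted"
  call[!is.na(padj) & padj < padj_threshold & log2fc > 0] <- "enriched"
  res <- data.frame(target = rownames(cm), base_mean = disp$base_mean,
                    log2fc = log2fc, se = se, wald = wald, p = p,
                    padj = padj, call = call, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- disp[c("trend_coef", "prior_sd")]
  attr(res, "excluded") <- excluded
  res
}

#' Guides consistently fold-depleted (or enriched) in both replicates
#'
#' Normalized (median-of-ratios) T1/T0 ratios are computed per replicate
#' with a pseudocount of 0.5 to avoid division by zero; a guide qualifies
#' only when the threshold holds in every replicate.
#'
#' @param guide_counts integer matrix at guide level.
#' @param design data frame with `sample`, `condition` ("T0"/"T1") and
#'   `replicate`.
#' @param fold_threshold fold-change threshold (default 2).
#' @param direction `"depleted"` (ratio <= 1/fold in all replicates) or
#'   `"enriched"` (ratio >= fold).
#' @return character vector of guide names.
#' @export
replicate_consistency <- function(guide_counts, design, fold_threshold = 2,
                                  direction = c("depleted", "enriched")) {
  direction <- match.arg(direction)
  if (is.null(design$replicate)) {
    stop("design needs a 'replicate' column", call. = FALSE)
  }
  reps <- sort(unique(design$replicate))
  for (r in reps) {
    sub <- design[design$replicate == r, ]
    if (!all(c("T0", "T1") %in% sub$condition)) {
      stop("each replicate needs one T0 and one T1 sample", call. = FALSE)
    }
  }
  counts <- guide_counts[, design$sample, drop = FALSE]
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ok <- rep(TRUE, nrow(norm))
  for (r in reps) {
    s0 <- design$sample[design$replicate == r & design$condition == "T0"]
    s1 <- design$sample[design$replicate == r & design$condition == "T1"]
    ratio <- (rowMeans(norm[, s1, drop = FALSE]) + 0.5) /
      (rowMeans(norm[, s0, drop = FALSE]) + 0.5)
    ok <- ok & if (direction == "depleted") {
      ratio <= 1 / fold_threshold
    } else {
      ratio >= fold_threshold
    }
  }
  rownames(norm)[ok]
}
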