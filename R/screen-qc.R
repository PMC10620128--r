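#' Library uniformity: 90th/10th percentile skew ratio
#'
#' Percentiles use the linear-interpolation quantile (R type 7). Scale
#' invariant: multiplying all counts by a constant leaves the ratio
#' unchanged.
#'
#' @param counts one count-matrix column (integer vector).
#' @return ratio >= 1 in well-behaved libraries; `Inf` with a warning when
#'   the 10th percentile is zero.
#' @export
skew_ratio <- function(counts) {
  if (sum(counts > 0) < 10) {
    stop("need at least 10 entries with count > 0", call. = FALSE)
  }
  q <- stats::quantile(counts, c(0.1, 0.9), names = FALSE, type = 7)
  if (q[1] == 0) {
    warning("10th percentile is zero; skew ratio is infinite")
    return(Inf)
  }
  q[2] / q[1]
}

#' Per-guide fold coverage of a screen
#'
#' @param n_cells number of cells plated.
#' @param transduction_fraction fraction of cells transduced (0-1).
#' @param library_size number of constructs in the library.
#' @return `n_cells * transduction_fraction / library_size`, unrounded
#'   (display rounding is presentation-layer only).
#' @export
fold_coverage <- function(n_cells, transduction_fraction, library_size) {
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  n_cells * transduction_fraction / library_size
}

#' Single-infection fraction under the Poisson MOI model
#'
#' With transduced fraction `f`, the Poisson rate is `lambda = -ln(1 - f)`
#' and the probability that a transduced cell carries exactly one
#' integration is `P(X = 1 | X >= 1) = lambda * exp(-lambda) / f`, which
#' approaches 1 as `f -> 0`. At the common 30% transduction target this is
#' 0.832 (~85% of transduced cells carry a single virus).
#'
#' @param transduced_fraction fraction of cells transduced, strictly in
#'   (0, 1).
#' @return probability.
#' @export
single_infection_fraction <- function(transduced_fraction) {
  f <- transduced_fraction
  if (any(is.na(f)) || any(f <= 0) || any(f >= 1)) {
    stop("transduced_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  lambda <- -log1p(-f)
  lambda * exp(-lambda) / f
}
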