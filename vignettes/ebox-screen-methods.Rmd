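---
title: "Methods: designing and analysing E-box-disrupting CRISPR screens"
author: "eboxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and analysing E-box-disrupting CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eboxscreen)
```

# The problem

bHLH-LZ transcription factors such as MYC/MAX bind E-box motifs — the
palindromic `CACGTG` and the reverse-complement-paired variants
`CACATG/CATGTG` and `CACGCG/CGCGTG` — in promoters and enhancers. A pooled
CRISPR screen can ask which of the thousands of bound E-boxes a cancer cell
actually needs: mutate each motif with Cas9, grow the pool, and look for
guides that drop out between the selection timepoint (T0) and the endpoint
after ~20 population doublings (T1). This package implements the
computational side of that experiment: library design, read counting,
depletion testing, and the sequence-context ("grammar") analysis of the
motifs that score as essential.

# Coordinates and containers

All intervals are 0-based half-open, the native BED convention; 1-based
coordinates appear only in human-facing labels. Genomes are in-memory
`DNAStringSet`s; intervals, E-boxes, guides, and library entries are plain
data frames so that every intermediate is directly inspectable and
serialisable as TSV/BED. Binding sites receive per-chromosome ordinals in
ascending start order (`chr11_BS79`), assigned after merging. The merge
collapses overlapping *and* bookended intervals and nothing further — no
gap tolerance — because peak concatenation across sources should preserve
covered bases exactly. Source labels (which cell line contributed a peak)
are carried through merging as a per-site union, since the overlap-by-cell
line summaries need them and per-contributor identity is lost anyway once
intervals fuse.

# Library design

## What "targeting an E-box" means

Cas9 cuts bluntly 3 nt 5' of the `NGG` PAM, between protospacer nt 17 and
18. We call a guide *targeting* when that cut bond falls strictly inside
the 6-mer — one of its five internal phosphodiester bonds — so the repair
indel lands in the motif rather than beside it. Both strands are searched
(an `NGG` on the minus strand reads `CCN` on the plus strand), giving at
most five placements per strand per E-box. This geometric definition is the
package's own rule; it is consistent with cut-site annotations such as
`CACAT*G` (a cut directly before the last base) that one observes for
guides selected this way. Windows containing `N` are skipped.

Because the motif set is closed under reverse complement, scanning the plus
strand alone finds every occurrence on either strand exactly once; motif
sets that are not closed are rejected as a configuration error rather than
silently double-counted.

E-boxes overlapping any coding-exon base (half-open overlap, bookended
does not count) are flagged and excluded from design — disrupting a protein
would confound the readout — but retained in all reports. Exclusion is
applied at the E-box level; subtracting exon intervals from peaks before
scanning is a stricter variant that also removes non-exonic motifs near
exon boundaries, which is why we prefer the per-motif flag.

## Off-target filtering

For each candidate protospacer the genome is scanned on both strands for
`NGG`-adjacent 20-mers within 2 mismatches (`Biostrings::matchPattern`
provides the candidate matching; mismatch positions are then recomputed at
character level, numbered 1–20 from the PAM-distal end). A perfect-match
locus counts as *intended* only when its cut bond lies inside a library
E-box; any other perfect match is an off-target. The retention rule keeps
a guide only if every off-target has at least three mismatches, or at
least two with one in the seed region (nt 9–20). `NAG` PAMs are not
searched; the PAM space is a deliberate design constant, and widening it
only makes the filter stricter.

CFD-style specificity is reported as `100 / (1 + Σ site CFD)` where each
site's CFD is the product of per-position mismatch-activity penalties, 1
for a perfect match. The aggregation to a 0–100 scale is this package's
choice (100 = no off-targets; monotonically non-increasing as sites
accumulate). The packaged activity table is **synthetic**: it reproduces
the indexing (position × guide base × target base) and the qualitative
position profile of published cutting-frequency data — PAM-proximal
mismatches most penalised — but not the measured values, which are not
redistributable here. Scores computed with it rank guides sensibly but
should not be compared against thresholds from the literature; pass a
measured table to `load_cfd_matrix()` for that.

## Oligo assembly

Each library entry is a 104-nt synthesis oligo: a 41-nt left homology arm
ending in `GAAACACCG`, the 20-nt protospacer, and a 43-nt right arm.
Guides are deduplicated library-wide by protospacer sequence; a sequence
cutting in two E-boxes appears once with both ids in `targets`. Targeting
entries are named `{ebox_id}_sg{i}` with `i` assigned in genomic order.
Control categories (non-targeting, positive controls) must be disjoint in
sequence from the targeting set; a collision is an error, not a silent
dedup.

# Counting

Amplicon reads carry a 9–18-nt stagger (for base-composition diversity on
the sequencer), an 8-nt sample barcode, and the constant vector sequence
ending in the anchor `GAAACACCG` immediately 5' of the protospacer.
Because the stagger makes positions variable, extraction is anchor-based:
the 20 nt after the first exact anchor occurrence. Counting is strictly
exact-match — a protospacer with even one mismatch is tallied as
unmatched, never assigned. Demultiplexing likewise uses exact 8-nt barcode
identity. These choices trade a few percent of reads for zero
cross-assignment, the right trade-off when guide sequences differ by as
little as one base.

QC statistics: the skew ratio is the 90th/10th percentile of entry counts
(linear-interpolation quantiles; scale invariant), fold coverage is
`cells × transduction fraction / library size` (unrounded; rounding is
presentation-layer), and the single-infection fraction under a Poisson
MOI model is `λe^(−λ)/f` with `λ = −ln(1 − f)` — 0.832 at the usual 30%
transduction target, i.e. most transduced cells carry one integration.

# Depletion testing

Counts are summed over all guides of a target (E-box or gene) before
testing; a guide mapping to two E-boxes contributes to both. The test is a
negative-binomial Wald test with the standard components:

* **Size factors** by median-of-ratios over rows with all-positive counts
  (a positive-counts pseudo-reference is available for zero-heavy
  matrices). On simulated data these match DESeq2's estimator to machine
  precision, which the test suite asserts.
* **Dispersions**: per-target method-of-moments estimates; a parametric
  trend `α(μ) = a1/μ + a0` fitted by iteratively reweighted gamma
  regression with outlier exclusion; per-target MAP shrinkage toward the
  trend under a log-normal prior whose width is the spread of the
  log-residuals minus the expected sampling variance (floored at 0.25),
  using a Cox–Reid-adjusted NB likelihood. With two samples per condition
  the per-target estimates alone are far too noisy; the trend prior is
  what makes the Wald p-values calibrated.
* **Wald test**: per target, an NB GLM `log μ = log s_j + q + β x_j`
  (x = 1 at T1, T0 the reference) at the fixed shrunken dispersion;
  `β̂/se(β̂)` against the standard normal, two-sided; BH adjustment over
  all targets with nonzero totals (zero-total targets are excluded and
  reported). Calls use padj < 0.001: depleted if β̂ < 0, enriched if
  β̂ > 0. No independent filtering and no log2FC shrinkage are applied to
  calls.

The suite cross-checks the whole chain against DESeq2 on simulated
screens (log2FC correlation > 0.999, call agreement > 97%) — the external
package is the oracle there, never the implementation. Exact numerical
parity is not claimed; the dispersion-shrinkage details differ in minor
ways.

The replicate-consistency filter is separate and deliberately simple:
normalized T1/T0 ratio ≤ 1/2 (or ≥ 2 for enrichment) in *every* replicate,
with a pseudocount of 0.5 against division by zero.

Nearest-TSS annotation takes, per E-box, the closest TSS at or left of the
motif midpoint and the closest at or right, each only within 50 kb
(boundary inclusive; ties broken by gene name). Midpoint-to-TSS distance
is a convention choice — the 3-bp difference to edge-based distance is
immaterial at a 50-kb window.

# Flank grammar

E-boxes are (quasi)palindromic and read on either strand, so flanking
composition is only defined up to orientation. We therefore pool *both*
readings of every E-box — the plus-strand window and its reverse
complement — which makes the identity `count(+k, b) = count(−k,
complement(b))` hold exactly by construction and removes any strand
choice from the analysis. (Orienting non-palindromic motifs to a canonical
strand is the alternative; pooling is the default because the palindromic
`CACGTG` offers no orientation at all.) `N` bases are excluded from
tallies; E-boxes with less than K bases of context are dropped with a
warning.

Per flank position (+1..+K only; the negative side is the mirror image) a
4-category Pearson goodness-of-fit compares the essential profile against
expected proportions from the non-essential background, treated as fixed
(df = 3), plus 1-vs-rest tests per nucleotide (df = 1). The statistic
scales with n — doubling both profiles doubles χ² — which is inherent to
goodness-of-fit testing and documented rather than "corrected". Expected
cells < 5 are flagged; a zero-probability background category observed in
the essential profile trips a +0.5 continuity guard, also flagged. Raw p,
BH-adjusted p and significance stars (0.05/0.01/0.001/0.0001) are all
emitted; the stars follow the convention of screen figures, the BH column
is there because K × 5 tests per comparison deserve a correction even if
figure conventions omit one. K defaults to 10 for tests and 20 for logo
matrices.

# Simulators and what they do (not) show

`make_genome` plants E-boxes inside binding-site cassettes built so that a
guide placement is guaranteed (PAM present, cut bond between motif
positions 5 and 6), plants coding exons over a chosen fraction of motifs,
and inserts decoy protospacer copies with specified mismatch positions so
the retention rule has true positives and true negatives to find. Cassette
context is resampled until the site contains exactly one motif occurrence,
so truth tables are unambiguous. GC content defaults to 0.41
(human-like). Accidental additional PAMs or near-matches in the random
background are allowed — pipeline and oracle see the same genome, so
agreement checks remain exact.

`simulate_screen_counts` draws guide counts from
`NB(mean = depth × q_g × s_j × 2^(x_j β_t), dispersion α)` with variance
`μ + αμ²` — the same parameterisation the test assumes. Defaults are the
study conditions the package is tested under: 2 replicates per condition,
500 reads per guide, α = 0.05, 2 guides per target, log-normal guide
abundances with sdlog 0.25 (library-cloning inequality of a well-made
pool; the resulting skew ratio lands in the low single digits). Those
defaults were chosen once, as realistic screen conditions, and the
calibration tests are run at them.

`simulate_fastq` emits stagger + barcode + anchor + protospacer + filler
per read, resampling any pre-anchor segment that happens to contain the
anchor, so at error rate 0 the FASTQ→extract→count round trip is exact by
construction; with substitution errors the matched fraction decreases
monotonically. All generators take a mandatory seed and use a local RNG
stream.

What passing these simulations does *not* show: real screens have
PCR jackpots, GC-dependent amplification bias, multi-mapping guides,
copy-number artefacts (amplified regions produce cleavage-toxicity hits
unrelated to the targeted element), and guide-efficiency heterogeneity.
None of those are modelled; the simulators validate the statistical
machinery under its own assumptions, not the assumptions themselves.

# Numerical choices and problem sizes

Dispersion MAP optimisation is a 1-D golden-section search on log α over
[ln 1e-8, ln 100], with non-finite objective values mapped to a large
negative constant (degenerate zero-variance targets otherwise produce
NA objectives). The trend fit falls back to the median dispersion when
fewer than 10 usable targets exist. GLM fits that fail return NA rather
than aborting the whole screen. Ties in nearest-TSS distance break
lexicographically for determinism. The packaged test problem sizes —
50-kb two-chromosome fixture genomes, 200 enumeration contexts, 2,000
targets for calibration, 10^5-read counting round trips, 200 grammar
replicates — were chosen so the whole suite exercises every oracle at
meaningful scale while staying comfortable to run interactively.

# Known limitations

* No on-target efficiency model; all PAM-compatible guides rank equally
  apart from specificity.
* Off-target search is exhaustive over the supplied genome — intended for
  fixture-scale genomes and spot checks, not a drop-in for genome-wide
  human design without an index.
* The synthetic CFD table supports ranking and testing, not
  literature-comparable scores.
* The depletion model fits condition as the only covariate, per cell
  line; batch terms would need an extended design matrix.
* Exact reproduction of any particular published library's binding-site
  numbering or guide set is not claimed: ordinal assignment and the
  cut-bond rule are documented conventions of this package.
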