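# eboxscreen

Design and analysis of pooled CRISPR/Cas9 screens that disrupt
transcription-factor-bound **E-boxes** — the 6-bp motifs (canonical
`CACGTG`, non-canonical `CACATG/CATGTG` and `CACGCG/CGCGTG`) recognised by
bHLH-LZ factors such as MYC/MAX. Rather than knocking out genes, these
screens mutate the *binding sites themselves*: a drop in a guide's abundance
between the start (T0) and end (T1) of the screen flags an E-box whose
integrity the cells depend on.

The package covers the full computational workflow:

1. **Library design** — merge ChIP-seq peak intervals, assign per-chromosome
   binding-site ids (`chr11_BS79` style), scan for E-boxes on the
   (reverse-complement-closed) motif set, exclude motifs in coding exons,
   and enumerate every 20-nt protospacer with an `NGG` PAM (or `CCN` on the
   plus strand) whose blunt-cut bond — between protospacer nt 17/18, 3 nt
   5' of the PAM — falls strictly inside the 6-mer. Guides are filtered by
   the off-target retention rule: keep a guide only if every off-target
   locus has ≥ 3 mismatches, or ≥ 2 with at least one in the seed region
   (nt 9–20). CFD-style specificity scores
   (`100 / (1 + Σ per-site CFD)`) and 104-nt synthesis oligos
   (41-nt flank + protospacer + 43-nt flank) complete the manifest.
2. **Screen quantification** — anchor-based protospacer extraction from
   staggered/barcoded amplicon reads, strictly exact-match counting
   (a single mismatch is never counted), skew-ratio QC, fold-coverage and
   Poisson-MOI single-infection calculations.
3. **Depletion statistics** — guide counts summed per E-box or gene, then a
   negative-binomial Wald test: median-of-ratios size factors,
   method-of-moments dispersions shrunk toward a parametric trend
   `α(μ) = a1/μ + a0` under a log-normal prior, per-target GLM fit, and
   BH-adjusted two-sided p-values (hit cut-off padj < 0.001). A
   replicate-consistency filter (≥ 2-fold depleted in *both* replicates),
   hit-set overlaps across cell lines, and nearest-TSS-within-50-kb gene
   assignment round out the analysis.
4. **E-box grammar** — strand-symmetrized nucleotide profiles of the
   sequences flanking essential vs non-essential E-boxes (both orientation
   readings pooled, so `count(+k, b) = count(−k, complement(b))` exactly)
   with per-position chi-squared goodness-of-fit tests and a logo-ready
   frequency matrix.
5. **Simulators** — seeded toy genomes with planted E-boxes, coding exons
   and off-target decoys, NB-distributed screen counts with spiked
   depletions, and amplicon FASTQ — so the whole pipeline is testable with
   no external data.

## Worked example

```r
library(eboxscreen)

fx  <- make_genome(n_chromosomes = 2, chrom_length = 30000,
                   n_eboxes_per_motif = 3, fraction_exonic = 0.2,
                   n_decoys = 10, seed = 3)
des <- design_ebox_library(fx$genome, fx$peaks, fx$exons)
des
#> E-box CRISPR library design
#>   peaks in: 15 -> merged binding sites: 15
#>   E-boxes found: 15 (exonic, excluded: 3)
#>   candidate guides (unique): 20; retained after off-target rule: 17
#>   E-boxes targeted: 10 of 12 candidates
#>   library entries: 17 (17 targeting)

head(des$guides[des$guides$retained,
                c("protospacer", "pam", "strand", "ebox_id", "cut_label")], 3)
#>            protospacer pam strand         ebox_id cut_label
#> 2 ATTGGATTTGCTATGACATG TGG      + chr1_BS4_CATGTG   C*ATGTG
#> 5 TGCTGTCTACCCCAAACGCG TGG      - chr1_BS6_CACGCG   CACGC*G
#> 6 ACTGAAACTATCCACGCGTT TGG      + chr1_BS6_CACGCG   CACGC*G
```

Three of the fifteen E-boxes fall in coding exons and are excluded; the
off-target rule then rejects guides whose planted decoy copies carry two
non-seed mismatches. `cut_label` marks where Cas9 cuts inside the motif
(`CACGC*G` = between positions 5 and 6).

A simulated duplicate screen (2,000 targets, 100 spiked at log2FC = −2,
500 reads/guide) is recovered cleanly by the NB Wald test:

```r
sim <- simulate_screen_counts(n_targets = 2000, guides_per_target = 2,
                              depth = 500, n_spiked = 100, beta = -2,
                              seed = 4)
res <- nb_wald_test(aggregate_by_target(sim$counts, sim$target_map),
                    sim$design)
table(res$call)
#> depleted       ns
#>      100     1900

single_infection_fraction(0.3)   # Poisson MOI at 30% transduction
#> [1] 0.8322415
```

All 100 spiked targets are called depleted at padj < 0.001 with no false
positives, and the fitted log2 fold changes centre on the simulated −2.

A runnable end-to-end demo (design → simulate → count → test → grammar,
writing FASTA/BED/TSV outputs) ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "eboxscreen-demo.R", package = "eboxscreen"))')" \
    --seed 3 --outdir demo-out
```

## Notes

- Coordinates are 0-based half-open (BED-native) throughout; 1-based only
  in human-facing labels.
- The packaged CFD mismatch-activity table
  (`inst/extdata/cfd_matrix_synthetic.tsv`) is a synthetic stand-in with
  the published table's indexing and qualitative shape; supply a measured
  table to `load_cfd_matrix()` for production specificity scores.
- See the methods vignette (`vignettes/ebox-screen-methods.Rmd`) for the
  model details, parameter defaults and known limitations.
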