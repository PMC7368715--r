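# refstab

Choosing a housekeeping (reference) gene badly is one of the classic ways to
ruin a qRT-PCR experiment: every target-gene fold change is measured relative
to the reference, so an unstable reference silently rewrites the biology.
`refstab` implements the full desk workflow for selecting and validating
reference genes — aimed at molecular biologists moving from a transcriptome
dataset to a defensible qPCR normalization strategy:

1. **Transcriptome screening.** From a gene × sample FPKM matrix, compute per
   gene the mean expression, coefficient of variation
   CV% = 100·σ/μ, maximum fold change MFC = max/min, and a dispersion
   measure DPM built on the per-sample specificity measure
   SPM_i = x_i²/Σ_j x_j² (DPM = sd(SPM)·√n, 0 for uniform genes, 1 for
   one-hot genes). Candidates are the intersection of the four thresholded
   sets (defaults: mean FPKM ≥ 10, CV ≤ 20 %, DPM < 0.2, MFC < 2.5).
2. **Ct-based stability ranking** with four independent re-implementations:
   * **geNorm** — M_j = mean over genes k of sd_samples(log2 Q_j/Q_k), with
     stepwise exclusion and the pairwise-variation sequence
     V_n = sd(log2 NF_n/NF_{n+1}) (V < 0.15 ⇒ n genes suffice);
   * **NormFinder** — the model-based intra/intergroup variance
     decomposition, stability = |shrunken intergroup deviation| + its SE;
   * **BestKeeper** — descriptive Ct statistics; the std-value is the mean
     absolute deviation of Ct about the gene's central Ct, plus each gene's
     Pearson r against the per-sample geometric-mean index;
   * **ΔCt method** — mean over partner genes of sd_samples(Ct_j − Ct_k).
3. **Composite ranking (ComprFinder-style).** Each algorithm's column A is
   min-max standardized, A′_i = (A_i − A_min)/(A_max − A_min), and the final
   score is FS_i = (A′_i + B′_i + …)/n; genes are ranked by ascending FS.
   Because min-max standardization is affine-invariant, the composite is
   insensitive to the wildly different native scales of the four algorithms.
   A RefFinder-style geometric-mean-of-ranks comparator is included for
   side-by-side comparison.
4. **Validation.** Multi-gene normalization factors (per-sample geometric
   mean of the chosen genes' Ct), relative expression 2^−ΔCt with
   ΔCt = Ct_target − NF, paired t-tests between stages, Pearson correlation
   between normalization schemes, and amplification efficiency from dilution
   series (efficiency % = 100·(10^(−1/slope) − 1)).
5. **Simulators** that generate Ct and FPKM data with *planted* stability
   structure (per-gene noise SDs, level shifts, technical replicates), so the
   whole pipeline is testable against known ground truth.

## Worked example

Aggregate published stability values (the bundled goat-skin panel: 12
candidate genes across 39 skin samples) with the composite and the rank-based
aggregator:

```r
library(refstab)
tab <- goat_skin_tables()$stability
vals <- as.matrix(tab[, c("normfinder", "bestkeeper_std", "delta_ct")])
rownames(vals) <- tab$gene
series <- list(
  stability_series("NormFinder", setNames(vals[, 1], rownames(vals))),
  stability_series("BestKeeper", setNames(vals[, 2], rownames(vals))),
  stability_series("deltaCt",    setNames(vals[, 3], rownames(vals))))
head(compare_aggregators(series), 5)
#>    gene comprfinder_fs comprfinder_rank reffinder_score reffinder_rank
#> 1  SDHA     0.05454982                1        1.817121              1
#> 2 NCBP3     0.11487659                2        2.884499              2
#> 3  EEF2     0.14230577                3        3.476027              4
#> 4 PTPRA     0.14455893                4        2.904393              3
#> 5 EIF4H     0.19041247                5        5.313293              7
```

A low FS means a gene sits near the stable end of *every* algorithm's scale;
note how the two aggregators already disagree on rank 3 versus 4 because the
rank-based comparator discards the spacing between stability values. (With
only the three value columns available here, n = 3; the geNorm M column would
make it n = 4.)

Run everything on simulated data with a planted noise gradient (gene G01
least noisy … G12 noisiest):

```r
sim <- simulate_ct(ct_sim_spec(seed = 42))   # 12 genes, 48 samples, 3 reps
res <- stability_all(sim$ct)                 # geNorm+NormFinder+BestKeeper+ΔCt
comprfinder(res$series)
#> ComprFinder composite over 4 algorithms, 12 genes
#>    gene    FS rank
#> 1   G01 0.000    1
#> 2   G03 0.079    2
#> 3   G02 0.123    3
#> ...
#> 12  G12 0.994   12
round(res$genorm$v, 3)
#>   V2/V3   V3/V4   V4/V5   V5/V6 ...
#>   0.176   0.140   0.131   0.112 ...
```

The composite recovers the planted order at the extremes (G01 first, G12
last); the V sequence dropping below 0.15 from V3/V4 onward says three of
these simulated genes are enough for a normalization factor.

A thin command-line wrapper with subcommands
`screen | stability | aggregate | normalize | simulate | run` is installed at
`system.file("cli", "refstab.R", package = "refstab")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end workflow from scratch under the given
seed — synthetic FPKM screening, the full four-algorithm stability +
aggregation pipeline on a simulated four-factor Ct experiment, and the
validation utilities (relative expression, paired stage tests, dilution-series
efficiency) — and writes the target JSON to `--out`.
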