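---
title: "Methods: screening, ranking and validating reference genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, ranking and validating reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

qRT-PCR quantifies a target transcript *relative* to one or more reference
("housekeeping") genes assumed stable across the experimental conditions. A
reference gene that responds to the conditions biases every downstream fold
change. `refstab` supports the now-standard two-stage strategy: screen a
transcriptome-wide expression matrix for housekeeping-like candidates, then
rank the shortlisted candidates' measured Ct stability with several
algorithms and aggregate them into one ranking, followed by experimental
validation. This vignette records the models, the tunable parameters, the
numerical decisions, and what the test suite does and does not establish.

# Screening metrics

For a gene with FPKM vector $x_1,\dots,x_n$ across $n$ samples:

* mean FPKM $\bar x$ — candidates should be appreciably expressed
  (default threshold $\bar x \ge 10$, or alternatively the 80th percentile of
  all gene means; exactly one rule is active);
* $\mathrm{CV\%} = 100\, s/\bar x$ with $s$ the *sample* standard deviation
  ($n-1$ denominator; the convention is not universal, and at $n \approx 39$
  the difference is below print precision). Default: $\le 20\%$, inclusive;
* $\mathrm{MFC} = \max_i x_i / \min_i x_i$, undefined when $\min_i x_i = 0$
  (such genes are excluded from the MFC criterion rather than treated as
  infinitely variable, because zero-expression genes are prefiltered first).
  Default: $< 2.5$, strict;
* the specificity profile $\mathrm{SPM}_i = x_i^2 / \sum_j x_j^2$ and its
  dispersion $\mathrm{DPM} = \sqrt{n}\,\mathrm{sd}(\mathrm{SPM})$.
  Default: $< 0.2$, strict.

The candidate set is the four-way intersection. FPKM and CV thresholds are
inclusive and DPM/MFC strict, mirroring the usual "$\ge$ / $<$" phrasing of
screening protocols; tightening any threshold can only shrink the
intersection, a property the tests assert.

## Two DPM normalizations

The default `"spm-sd"` definition above has clean endpoints: exactly 0 for a
constant nonzero gene and exactly 1 for a one-hot gene, at every $n \ge 2$.
However, published screening tables in this literature often show DPM values
that track the CV itself (e.g. CV 8.4 % alongside DPM 0.083), which is
incompatible with the `"spm-sd"` scaling (at $n = 39$ it would give
$\approx 2\,\mathrm{CV}/\sqrt n \approx 0.027$ for that CV). Those printed
pairs are reproduced, to print precision, by
$$\mathrm{DPM} = \frac{\mathrm{cv}}{\sqrt{1+\mathrm{cv}^2}},\qquad
  \mathrm{cv} = s/\bar x,$$
equivalently $s / \sqrt{\bar x^2 + s^2}$ — a cosine-type normalization of the
dispersion. It is available as `dpm_method = "cv-rms"`, maps constants to 0,
is bounded by 1, but reaches 1 only asymptotically for one-hot genes. The
`"spm-sd"` form stays the default because its exact endpoints are what the
property suite pins down; a unit test verifies the `"cv-rms"` calibration
against the bundled goat-skin screening table. Both are invariant to positive
rescaling of a gene, so screening is insensitive to library-size convention.

# The four stability algorithms

All four operate on the collapsed Ct matrix (technical replicates averaged
arithmetically; no outlier rejection, since none is standard) and are
oriented lower-is-more-stable.

## Anchored quantities

geNorm and NormFinder work on relative quantities
$Q_{gs} = E_g^{\,\mathrm{Ct}_{\min,g}-\mathrm{Ct}_{gs}}$, anchored so each
gene's best sample has $Q = 1$. The amplification base defaults to $E = 2$
(perfect doubling) and may be set per gene from
`efficiency_from_dilutions()`; bases outside $[1.6, 2.1]$ are rejected as
implausible. The anchor is a pure convenience: both algorithms use only
ratios or log-differences, so results are anchor-invariant (tested), and
adding a per-gene constant to Ct changes nothing.

## geNorm

$M_j$ is the mean over partner genes $k$ of
$\mathrm{sd}_s\!\left(\log_2 Q_{js}/Q_{ks}\right)$. The least stable gene
(highest $M$) is excluded and $M$ recomputed until two genes remain. geNorm
cannot discriminate the final pair; to give downstream rank aggregation
distinct ranks 1 and 2, the pair is ordered by its $M$ at the three-gene
stage (a recorded tie rule, not part of the original algorithm). The
normalization factor $NF_n$ is the per-sample geometric mean of the top-$n$
genes' quantities and $V_n = \mathrm{sd}_s(\log_2 NF_n/NF_{n+1})$; the
conventional reading is that $V_n < 0.15$ means gene $n{+}1$ is unnecessary.
The stability series passed to aggregation is the full-panel $M$ (every gene
measured against the complete panel), not the stepwise-stage $M$; the
exclusion-order ranking is reported separately.

## NormFinder

On $y = \log_2 Q$, each sample's gene-average is subtracted
($z_{is} = y_{is} - \bar y_{\cdot s}$), which removes per-sample loading
differences but couples the genes; the intragroup variance estimates are
therefore bias-corrected,
$$\hat\sigma^2_{ig} = \frac{k}{k-2}\left(s^2_{ig} -
  \frac{\sum_l s^2_{lg}}{k(k-1)}\right),$$
and truncated at 0 (truncations are flagged on the result). Intergroup
deviations $d_{ig} = \bar z_{ig} - \bar z_{i\cdot}$ sum to zero over genes
and are shrunken by their signal-to-noise ratio
$\gamma^2/(\gamma^2 + \hat\sigma^2_{ig}/n_g)$, where $\gamma^2$ is the
method-of-moments estimate of the intergroup variance (also truncated at 0).
The per-group stability is $|\tilde d_{ig}| + \mathrm{SE}(\tilde d_{ig})$,
averaged over groups. Note a genuine degeneracy: when the data carry no real
group effect, $\hat\gamma^2 = 0$ and *every* gene's grouped stability is 0 —
the model is explicit that there is nothing to choose between genes on
intergroup grounds. The aggregation layer then flags the column as
non-discriminating and standardizes it to zeros. Without a design, the
ungrouped variant returns the bias-corrected variance of each gene's
deviation from the per-sample mean profile, which does rank noisy genes.
Group labels with fewer than two samples, or fewer than two groups, are
rejected.

## BestKeeper

Pure descriptive statistics on raw Ct: geometric/arithmetic means, range,
and the std-value — the mean absolute deviation about a central Ct. The
published descriptions are ambiguous about the centring; arithmetic-mean
centring is the default and geometric-mean centring is selectable (the two
differ in the third decimal on realistic Ct data). The per-sample BestKeeper
index is the geometric mean over genes, and each gene's Pearson $r$ against
the index is reported with a two-sided p-value. MAD $\le$ SD always (tested).

## Comparative ΔCt method

The stability of gene $j$ is the mean over partner genes $k$ of
$\mathrm{sd}_s(\mathrm{Ct}_{js} - \mathrm{Ct}_{ks})$. Per-sample constants
cancel in the differences (tested). Under independent per-gene noise with
SDs $\sigma_j$, a pair's expected ΔCt SD is $\sqrt{\sigma_j^2+\sigma_k^2}$,
which the simulator-convergence test uses as a closed-form oracle.

## Missing data

Readers flag missing Ct cells explicitly and never impute; each algorithm's
default policy is to error, with `missing = "drop-sample"` dropping samples
listwise within the analysed subset.

# Aggregation

Given $n \ge 2$ identically oriented series over the same genes, each column
is min-max standardized, $A'_i = (A_i - A_{\min})/(A_{\max}-A_{\min})$, and
$FS_i$ is the arithmetic mean of the standardized values; ranking is by
ascending $FS$ with lexicographic tie-breaks (the tie rule and the
missing-data behaviour — drop the gene with a warning, or error in strict
mode — are recorded decisions; the source method specifies neither). A
zero-range column is standardized to all zeros and flagged: an algorithm
that does not discriminate should not separate genes. $n$ is the number of
supplied algorithms, not a constant 4. Min-max standardization is invariant
under increasing affine transforms of a column, which is the precise sense
in which the composite is robust to the algorithms' scale differences; the
rank-based comparator (geometric mean of average ranks) is provided because
it is the common alternative, and the two coincide exactly when every column
orders the genes identically.

# Validation utilities

The multi-gene normalization factor is the per-sample *geometric mean of Ct
values* of the member genes (`"ct-geomean"`), because that is how validation
protocols in this literature phrase it; the geNorm-style geometric mean of
relative quantities is available as `"quantity-geomean"`. The two are not
equivalent: adding a constant $c$ cycles to all genes changes a Ct-geomean
NF by exactly $c$ only for single-gene schemes, while the quantity-geomean
NF makes relative expression exactly invariant to such shifts. The tests pin
the exact invariance to the quantity mode and first-order invariance to the
default mode. Relative expression is $2^{-\Delta Ct}$ with
$\Delta Ct = Ct_{target} - NF$. Stage comparisons use the classical paired
t-test (two-sided) keyed by subject; every sample must be pairable, and a
degenerate all-zero difference vector is reported as $t = 0$, $p = 1$ rather
than an error. Stars are fixed at $p<0.05$ (*) and $p<0.01$ (**) with no
multiple-testing correction, matching field practice for these validation
figures. Scheme correlations pool all targets × samples into one vector per
scheme (per-target matrices optional) with unadjusted two-sided p-values.
Dilution-series efficiency is $100\,(10^{-1/\text{slope}}-1)$ from the
least-squares slope of Ct on $\log_{10}$ input; non-negative slopes are
rejected as non-amplifying.

# The simulators and what a green test establishes

`simulate_ct()` draws
$Ct_{gs} = \text{baseline}_g + \text{shift}_g(\text{level}(s)) +
\mathcal N(0, \sigma_g)$ with independent technical-replicate jitter
(default 0.1 cycles, collapsed by the same code path as read data). The
default design mirrors a four-factor determination study — factors with
4/3/4/5 levels, 3 biological samples per level, 3 technical replicates — read
as *disjoint* level blocks (48 samples). The study this layout emulates
re-used samples across factors to reach 39 distinct samples; the
rank-recovery tests that need exactly 12 × 39 therefore use 13 disjoint
level blocks instead. Default baselines span 23–29 cycles and default
$\sigma_g$ 0.4–1.0 cycles, chosen once as a realistic dispersion range for
a candidate panel; no level shifts are planted by default, so the default
world is exchangeable across levels (and grouped NormFinder correctly
degenerates on it, see above). `simulate_fpkm()` draws lognormal expression
per class: housekeeping-like (median 50 FPKM, log-SD 0.08 ≈ 8 % CV, which
meets the default screening thresholds with high probability), variable
(median 8, log-SD 0.9) and all-zero genes.

The simulators deliberately omit several features of real data: shared
technical factors (plate/run effects correlated across genes), heavy-tailed
Ct outliers, amplification-efficiency heterogeneity, and count-level noise in
FPKM. A green rank-recovery test therefore establishes that the estimators
recover planted independent-noise structure, not that they are robust to
correlated artefacts; the invariance properties (per-sample offsets,
per-gene offsets, affine transforms) are the portable guarantees.

# Numerical decisions and limitations

* Collapsing replicates is an arithmetic mean with no replicate QC; an
  aberrant replicate propagates (documented, as no standard protocol
  prescribes rejection).
* Ct domain is $(0, 45]$; values outside it are input errors, not data.
* geNorm final-pair ordering, composite tie-breaks and constant-column
  handling are recorded conventions without a published reference.
* The NormFinder implementation follows the published estimators; published
  tools vary in log base, grouping convention and truncation details, so
  cross-tool agreement should be expected at rank level rather than value
  level.
* Identifiers are case-sensitive and whitespace-trimmed; delimiters are
  auto-detected from the header (tab, else comma); decimals use ".".
* The pipeline is deterministic given its inputs; the only randomness lives
  in the simulators, which take explicit integer seeds.
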