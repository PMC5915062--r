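---
title: "Spectral-count differential proteomics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential proteomics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmProteomics)
```

# The analysis problem

Laser-capture microdissection yields small, cell-type-pure tissue samples —
on the order of 8,000 cells per sample, which `estimateCellCount()` derives
from dissected area and section thickness under a cubic 10 µm cell model.
Shotgun proteomics of such samples produces a protein × sample table of
spectral counts: small nonnegative integers with many structural zeros,
because low-abundance proteins drop below the detection limit in some
samples. The package's central object, `SpectralCountExperiment`, wraps
this table and the per-sample annotations (group, age, FIGO stage) in a
`SummarizedExperiment`, with validity checks for integrality,
nonnegativity, unique identifiers, the closed group vocabulary and the
restriction of FIGO stages to cancer samples. FIGO stages beginning I/II
are classed early, III/IV late; matching is longest-prefix so "IIb" is
never misread as a stage-III string.

# Fold-changes and per-protein tests

Zeros make ratios and logarithms undefined, so zero counts are replaced by
a pseudocount before any log arithmetic. The replacement value 0.125 is a
fixed convention of this analysis (an eighth of a count, well below any
observable signal); it acts as the detection floor. The effect size is the
log2 ratio of group means of zero-replaced counts — not the mean of
per-sample log ratios — because it reproduces the floor arithmetic exactly:
a protein undetected in the whole reference group has its reference mean
floored at 0.125, so a test-group mean of 4 gives a linear ratio of 32
(log2 FC = 5). Swapping the contrast groups negates every fold-change
exactly.

The spectral-count literature does not prescribe a per-protein test, so the
choice is an explicit `contrastSpec()` switch with two options:

* `welch_log` — two-sided unequal-variance t test on log2 zero-replaced
  counts. The implementation is vectorised over proteins (row means and
  variances plus the Welch–Satterthwaite degrees of freedom) and is checked
  against `stats::t.test` in the test suite. When both groups are constant
  and equal the p-value is defined as 1; when constant and different it is
  the smallest positive double (the limit of the test), keeping p in
  (0, 1].
* `fisher_presence` — two-sided Fisher exact test (`stats::fisher.test`)
  on the 2×2 table of samples with versus without a count, where "present"
  means spectral count ≥ 1. The two-sided p-value follows the standard
  minimum-likelihood convention (sum of point probabilities no larger than
  the observed table's), which the suite verifies against exhaustive
  enumeration of all tables with the observed margins; note this is not
  the tail-doubling convention, which can differ by up to a factor of two
  in extreme tables.

`welch_log` is the default because graded abundance differences carry the
p-values of interest; `fisher_presence` exists because exclusivity-style
selection is presence/absence in nature.

# Selection regimes

Three regimes of increasing permissiveness:

1. **All-or-nothing** (`allOrNothing`): zero counts in *every* sample of
   the excluded groups (healthy epithelium and stroma), presence in at
   least `minPresent` target-group samples (default 7 of 11 early-cancer
   samples), and raw p < 0.05. Presence in allowed groups (late cancer) is
   ignored. The healthy/stroma mirror, `exclusiveInGroup`, defaults to
   presence in ≥ 6 of 13.
2. **Bonferroni** (`bonferroni`): strict p < α/m. The family size m is
   deliberately exposed: the number of proteins actually tested in a
   contrast (identified in at least one sample of either group) is the
   default, but published thresholds sometimes imply a different universe
   — single-peptide versus two-peptide identification totals differ — so
   `m` can be set explicitly rather than guessed.
3. **Benjamini–Hochberg** (`benjaminiHochberg`): step-up at q = 0.05 via
   `stats::p.adjust(method = "BH")`, with `adjusted <= q` as the rejection
   rule (equivalent to the classical largest-i step-up with ties rejected
   together; the suite proves equality against an independent brute-force
   step-up oracle on thousands of random p-vectors).

Bonferroni uses a strict inequality at the threshold (a printed cutoff is
used as an exclusive bound); BH uses the standard non-strict step-up
comparison. For equal α = q the regimes are nested: Bonferroni-significant
⇒ BH-significant ⇒ p < 0.05, which the suite asserts on random inputs.

# Gene-set enrichment and the permutation threshold

Proprietary pathway knowledge bases are out of scope; sets are plain GMT
entries (`readGMT`) over an explicit background universe, with 35 members
as the simulated default (a typical curated interaction-network size). The
score of a set is −log10 of the right-tailed hypergeometric probability
P(X ≥ overlap) (`stats::phyper`), reported unrounded — comparisons never
use rounded scores, since whether printed integer scores were rounded
before thresholding is unknowable in general.

The significance threshold is empirical: draw `repeats = 10` random lists
of the input-list size uniformly without replacement from the background,
record the *maximum* score over all sets per repeat, and take the upper
95% confidence limit of the mean maximum, mean + t(0.975, 9)·sd/√10. The
t quantile is the default reading of a "95% confidence level of the mean"
at n = 10; a normal quantile is available behind a flag and is slightly
narrower. A set is significant only on strict exceedance — a score equal
to the threshold fails. With zero variance across repeats the threshold
collapses to the constant score exactly.

# Clustering

`wardCluster` clusters rows of a value matrix (log2 zero-replaced counts)
under Ward's minimum-variance criterion with Euclidean distance, via
`stats::hclust(method = "ward.D2")` — the Lance–Williams update on squared
dissimilarities. Merge heights equal the square root of twice the increase
in within-cluster sum of squares; the suite verifies full agreement
(structure and heights) with a naive O(n³) Ward implementation on random
matrices. Proteins and samples are clustered independently
(`biclusterMatrix`); display-order seriation beyond the standard recursive
leaf order is out of scope since it affects presentation, not tree
structure. Ties in merge costs are resolved by `hclust`'s deterministic
scan order; property tests therefore use tie-free continuous data.

# PRM quantification

Isotope-dilution arithmetic: endogenous amount = (endogenous area / SIL
area) × spiked fmol × scale factor, the scale factor mapping the digested
aliquot to the whole lysate (4 when 50 of 200 µL were digested). A zero
SIL area yields NA ("not quantifiable"), never infinity. Protein roll-up
uses the median across the protein's peptides (robust to one interfered
transition; mean available), and ng = fmol × MW(Da) × 10⁻⁶.

Calibration (`fitCalibration`) is ordinary least squares of mean area on
level over the default series 0, 0.625, 1.25, 2.5, 5, 10, 20 fmol/µL in
triplicate, with R² on replicate means. Detection limits follow the
blank-based convention LOD = 3.3·σ_blank/slope, LOQ = 10·σ_blank/slope
with σ_blank the sd of level-0 replicates, falling back to the residual sd
of the fit when no blank replicates exist; per-level CV% = 100·sd/mean. A
non-positive slope marks the curve invalid rather than producing negative
limits. Per-sample normalisers such as tissue area or UV peak area are
accepted as an external divisor column, not computed internally.

# Transcriptome comparison

`compareToBackground` reduces each gene to its mean log2 FPKM across tumor
samples, then applies a two-sided Wilcoxon rank-sum test of the
differential genes against the proteome-identified background gene list,
with the direction reported as the difference of medians (the claim of
interest is usually "higher expressed", but the test is kept two-sided,
with a one-sided reading available from direction + p/2). Exact
enumeration is used when the smaller sample has ≤ 8 values and no ties;
otherwise the normal approximation with tie and continuity correction.
Genes absent from the expression table are reported, never silently
dropped; the verdict is significance at p < 0.01.

# The synthetic-data generator

`simulateStudy` emulates the data structure the analysis assumes, not raw
spectra: group sizes 11/11/13/13 (early cancer, late cancer, healthy
epithelium, stroma); baseline counts negative binomial with mean µ = 5 and
dispersion k = 2 (overdispersion is typical of spectral counting; k → ∞
recovers Poisson), thinned by independent per-sample dropout 0.25. These
defaults put the expected number of detected proteins per sample near
1,700 of 2,500 simulated — the depth of a deep LCM experiment. Planted
classes: 5% fc_up and 5% fc_down at ±2 log2 units in both cancer groups;
1.25% tumor-exclusive (structurally zero in healthy epithelium and stroma,
present in ≥ 8 of 11 early-cancer samples with zero-truncated counts,
ordinary counts allowed in late cancer) and 1.25% healthy-exclusive
(present in ≥ 6 of 13 healthy samples, zero elsewhere). All randomness
flows from one mandatory seed; no global state.

What the generator does **not** emulate: correlated missingness across
samples, sample-to-sample loading differences (no normalisation is applied
by default, matching the analysis), peptide-level identification
uncertainty, and shared peptides between proteins. Tests passing on this
generator therefore demonstrate the correctness of the arithmetic and the
selection logic under the stated model, not robustness to those real-data
features.

Companion generators: `simulateGeneSets` (one planted enriched set among
uniform random sets), `simulatePRMSeries` (linear signal with
multiplicative lognormal noise of a given CV; cv = 0 is exactly linear)
and `simulateExpression` (high expressers near log2 FPKM 5, undetectable
transcripts near −5, the rest intermediate near 3.5).

# Pipeline and reproducibility

`runPipeline` executes differential → selection → enrichment → clustering
(→ PRM, transcriptome when configured) from one YAML/list configuration.
The configuration is validated before any computation; outputs are staged
in a temporary directory and published only on success, so a failing stage
leaves no partial results. A `manifest.json` records version, seed,
parameters and row counts. All tables are TSV (UTF-8, tab, '.' decimal,
header line, floats at 6 significant digits), so identical configuration
and seed give byte-identical outputs.

Problem sizes used in the shipped test suite were chosen to exercise each
property at statistical scale while keeping a full run fast: studies of
300–2,500 proteins, 200 replicates for false-discovery calibration, 100
seeded runs for the permutation-threshold and Ward-oracle properties.

# Known limitations

* The per-protein test is a pragmatic choice, not a derived one; published
  spectral-count p-values cannot generally be attributed to a specific
  test, and neither candidate here claims to reproduce any particular
  published table exactly.
* Spectral counts are semi-quantitative; no normalisation (e.g. total
  count scaling) is applied by default, and abundance indices such as NSAF
  are out of scope.
* The enrichment module scores fixed, user-supplied gene sets; it does not
  build networks or reproduce proprietary knowledge-base content, so
  absolute scores depend entirely on the supplied collection and
  background.
* Absolute PRM amounts for whole lysates require per-sample scale factors
  and molecular weights supplied by the user; the package does not infer
  them.
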