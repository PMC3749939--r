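---
title: "stemchrom: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stemchrom: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemchrom)
```

stemchrom implements the quantitative analysis stack used in chromatin
studies of embryonic stem cells (ESCs): binned-Poisson ChIP-seq
enrichment calling and promoter bivalency classification, chromatin-
class-stratified expression statistics, NanoString-style count
normalization with a Monte Carlo FDR, FRAP mobile-fraction estimation,
and ChIP-qPCR/densitometry arithmetic. A synthetic-data module generates
every input with known ground truth, so each stage can be validated
end-to-end on a desktop without any sequencing data.

This vignette is the package's account of the underlying models, the
parameters that matter, and the design choices made where the methods
left details open.

## The binned-Poisson enrichment caller

ChIP-seq reads arrive as 5'-start + strand intervals (BED convention,
0-based half-open). The caller:

1. **extends** each read to the average immunoprecipitated fragment
   length (default 200 bp), from the 5' end in the read's direction,
   clipping at chromosome bounds;
2. **allocates** each extended fragment to the fixed-width bin (default
   25 bp) containing its midpoint — midpoint assignment counts each
   fragment exactly once, so track totals are conserved;
3. **tests** each bin against a Poisson background. The rate for bin
   *i* is
   `lambda_i = max(input_i, mean(input)) * (N_IP / N_input)`,
   the larger of the local input count and the genome-wide input mean,
   scaled by the library-size ratio. The p-value is the upper tail
   `P(X >= k_i; lambda_i)`. A bin is enriched when `p < 1e-9` **and**
   `(k_i + 1) / (lambda_i + 1) >= 5`;
4. **merges** adjacent enriched bins into regions (a single
   non-enriched bin splits regions by default; `merge_gap` relaxes
   this).

Choices worth noting:

* *Rate estimation.* A "Poissonian model" admits several rates; we use
  the conservative local/global maximum, which protects against local
  input pile-ups while retaining power in input deserts. Both
  components are exposed (`local_lambda = FALSE` uses the global mean
  alone), and the fold filter uses the same `lambda`, one consistent
  background for both criteria.
* *Pseudocount.* The fold uses one fragment in numerator and
  denominator. At calling depth this never changes a call (an enriched
  bin needs `k >= 12` even at `lambda = 1`); it only stabilises sparse
  bins.
* *No multiple-testing correction.* The method is a fixed `1e-9`
  threshold; at that stringency the expected number of false bins on a
  megabase-binned genome is far below one (`1e6 x 1e-9`), which the
  null-calibration tests confirm empirically.
* *Calibration anchor.* At scaled `lambda = 1` the smallest enriched
  count is 12: `P(X >= 12; 1) ~ 8.3e-10 < 1e-9 < P(X >= 11; 1)`. The
  test suite freezes this from an independent series summation of the
  Poisson density.

## Promoter classification

A mark flags a TSS when **either boundary** of one of its enriched
regions falls inside the closed-open window `[tss - w, tss + w)`,
`w = 2000` bp by default. Classes follow the bivalency rule: *bivalent*
= H3K4me3 and H3K27me3, *active* = H3K4me3 only, *unmarked* otherwise.
The boundary rule is applied literally (a region engulfing the whole
window with both boundaries outside it does not flag); with 25 bp bins
and promoter-scale regions this distinction is immaterial in practice.

TSS-centred displays mirror the two standard figures: a metagene
profile (per-bp extended-fragment coverage in TSS-relative coordinates,
minus-strand genes flipped so downstream is positive) and a
gene-by-offset density matrix over ±4 kb, rows ordered by summed
H3K27me3 density with lexicographic gene-id tie-breaks. Note that
per-bp *coverage* of 200 bp fragments blurs two flanking components at
±100 bp into a single plateau; the bimodal pattern is a property of the
binned fragment-midpoint density, which is what the matrix (and the
tests) use.

## Expression stratification

Isoform RPKMs are summed per TSS; per-gene fold changes are
`log2((B + c)/(A + c))` with `c = 1` RPKM. The pseudocount bounds fold
changes of silent genes and defines the `>1.5`-fold differential filter
(strict inequality) on pseudocounted ratios — the filter's reference
quantity is therefore explicit and reproducible. Gene-set overlap uses
the upper-tail hypergeometric test; the universe defaults to every gene
with a fold change (annotated TSS, expression table entry) and is
configurable. Class-stratified distributions are compared with the
two-sample two-sided Kolmogorov–Smirnov test (asymptotic p-values; the
test suite checks D against a direct CDF scan). Group locations are
summarised by medians and compared with the classic equal-variance
unpaired t-test. Fold-change matrices are clustered with Euclidean
distances; the linkage (only the metric is prescribed by convention) is
average/UPGMA and exposed as a flag.

## NanoString normalization and the Monte Carlo FDR

Values are `log2(count + 1)` anchored to the *geometric mean* of the
housekeeping genes (default Gapdh, Tubb5, Cltc): subtracting the mean
of housekeeping logs per sample. Housekeeping rows then average exactly
zero in every sample, and per-sample scale factors cancel (exactly at
pseudocount 0; within 0.01 log2 units for counts >= 100 otherwise).
`center_genes()` then expresses each gene relative to its own mean
across experiments, and calls are made at inclusive ±2-fold thresholds.

The Monte Carlo FDR needs a null, which the original description leaves
open. We use the minimal exchangeability null: the observed statistic
is the equal-variance t-test p-value comparing **per-sample median**
expression between the two groups; each of the (default 10,000)
iterations permutes the sample labels and recomputes it, and the FDR is
the fraction of null iterations at or below the p-value threshold. The
statistic is pluggable (`statistic` argument) for gene-level variants.
Under a true null the estimate converges to the threshold; the
calibration test verifies this within three binomial standard errors at
10,000 iterations using 50 samples per group — large groups are needed
because with few samples the permutation distribution is discrete and
the conditional rejection rate of a *single* dataset deviates from the
threshold by more than the Monte Carlo error.

## FRAP mobile fractions

Curves are normalized to the maximum pre-bleach intensity. With
`I_dip` the first post-bleach intensity and `I_sat` the mean of the
last `tail_window` frames, the endpoint estimator is

```
MF = (I_sat - I_dip) / (1 - I_dip).
```

The formula is sometimes printed with the numerator reversed; that
orientation is negative whenever fluorescence recovers, so we implement
the standard orientation and record the convention in the output. For a
single-exponential recovery with rate `k` truncated at time `T` after
the bleach, the estimator underestimates the true mobile fraction by
exactly `MF_true * exp(-k T)` — asserted against the closed form in the
tests, and negligible when `k T >= 5` (e.g. `k = 0.01/s` over a 14 min
window). `fit_recovery()` provides the model-based alternative
(`I(t) = I_dip + A(1 - e^{-kt})` by Levenberg–Marquardt least squares,
`MF = A/(1 - I_dip)`), flagging flat curves whose rate is
unidentifiable instead of failing. The endpoint estimator is the
default for fidelity to the printed formula; groups of per-cell mobile
fractions are compared with the standard unpaired t-test.

No photobleaching-decay correction is applied by default: acquisition
protocols of this kind are optimized to avoid monitoring bleach, and
unbleached controls justify the omission.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated:

* **Genome**: genes in disjoint 5 kb slots (TSS at slot centres, so
  spacing is guaranteed), classes i.i.d. from the supplied
  probabilities.
* **ChIP reads**: the input library is uniform; the IP library mixes
  the uniform background with two Gaussian fragment-midpoint components
  at ±100 bp (sd 50 bp) from each enriched TSS — the simplest shape
  producing the bimodal flanking pattern around the nucleosome-free
  region; all shape parameters are configurable. The downstream (+1
  nucleosome) component is scaled by `1 - depletion`, emulating mutant
  +1 depletion. Per-gene peak mass is calibrated so the expected
  IP/input density ratio over TSS ± 200 bp approximates the requested
  class fold; every library emits exactly `total_reads` reads. No
  sequencing error, mappability, duplicates or GC bias are simulated —
  passing tests therefore demonstrate the statistical machinery, not
  robustness to alignment artefacts.
* **Expression**: condition B = condition A × `2^shift(class)` ×
  lognormal noise (multiplicative noise being the simplest positive
  model for RPKM data), isoforms sharing their gene's TSS.
* **FRAP**: pre-bleach frames at 1, post-bleach single-exponential
  recovery with an immobile fraction and additive Gaussian noise; the
  bleach frame holds the dip.
* **NanoString**: `round(scale_s × base_g × 2^(effect + noise))` with
  housekeeping effects pinned at zero.

Peak breadth at bivalent versus active promoters is deliberately a free
parameter, not a calibrated one: the broader bivalent pattern is a
qualitative observation without a published spatial scale.

Every generator is a pure function of its seed and parameters
(`with_seed` restores the caller's RNG state). Each call uses a single
seeded stream rather than per-gene sub-streams; the trade-off is that
adding genes reshuffles subsequent draws, in exchange for fully
vectorised sampling — regeneration under a fixed configuration is what
the reproducibility contract guarantees.

## Problem sizes used in validation

The test and acceptance workloads are sized so the full suite runs in
well under a minute per module on one core: ground-truth recovery uses
a 4 Mb genome with 600 genes (~200 per class) and 1e6-read libraries;
null calibration uses ten pairs of 1e6-bin Poisson tracks; FRAP
recovery uses 14 cells per group at the 30 s / ~14 min acquisition
geometry with intensity noise sd 0.01 and a between-cell MF sd of 0.03
for the group-power study; the FDR calibration uses 30 genes × 100
samples and 10,000 permutations. These match the scales at which the
corresponding laboratory analyses operate (hundreds of promoters per
class, >= 14 cells per FRAP group, 10,000 Monte Carlo iterations).

## Limitations

* The caller models counts as Poisson; overdispersion beyond the
  local-rate adjustment (copy-number variation, PCR jackpots) is out of
  scope, as are peak-shape modelling, duplicate removal and mappability
  correction.
* Differential expression here means the pseudocounted fold-change
  filter; model-based differential testing belongs to dedicated tools.
* FRAP estimation starts from intensity traces; ROI extraction from
  images and reaction–diffusion modelling are out of scope.
* The Monte Carlo FDR interprets the published procedure as a label
  permutation of the median statistic; other resampling schemes can be
  supplied through the `statistic` hook but are not built in.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(seed = 42, outdir = "stemchrom_demo"))
report
```

The report prints the true-versus-called promoter class confusion
matrix, the differential/bivalent overlap p-value, the NanoString null
FDR and the FRAP group comparison; every file under `outdir` begins
with a provenance header recording the package version and master seed.
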