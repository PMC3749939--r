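# stemchrom

Quantitative analysis toolkit for chromatin studies of embryonic stem
cells (ESCs). It is aimed at epigenomics analysts who need the classic
promoter-centric ChIP-seq workflow — binned-Poisson enrichment calling
and bivalency classification — together with the downstream statistics
that usually accompany it: chromatin-class-stratified expression tests,
NanoString-style count normalization with a Monte Carlo FDR, FRAP
mobile-fraction estimation, and ChIP-qPCR/densitometry arithmetic. A
synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable without any external dataset.

## Methods at a glance

**Enrichment calling.** Reads (BED6, 5' start + strand) are extended to
the average fragment length (200 bp), allocated to 25 bp bins by
fragment midpoint, and tested against a Poisson background with rate

    lambda_i = max(input_i, mean(input)) * N_IP / N_input

per bin. A bin is enriched when the upper tail P(X >= k_i; lambda_i)
falls below 1e-9 **and** (k_i + 1)/(lambda_i + 1) >= 5; adjacent
enriched bins merge into regions. At scaled lambda = 1 the smallest
enriched count is k = 12.

**Promoter classes.** A mark flags a TSS when an enriched-region
boundary falls inside [TSS - 2 kb, TSS + 2 kb). Bivalent = H3K4me3 and
H3K27me3; active = H3K4me3 only; unmarked otherwise.

**Expression stratification.** Isoform RPKMs are summed per TSS;
log2((B + 1)/(A + 1)) fold changes are filtered at a strict 1.5-fold
threshold; set overlaps use the upper-tail hypergeometric test and
class distributions the two-sample Kolmogorov–Smirnov test; fold-change
matrices cluster under Euclidean distances.

**NanoString.** log2(count + 1) values are anchored to the geometric
mean of housekeeping genes (Gapdh, Tubb5, Cltc by default), centred per
gene, and called at inclusive ±2-fold thresholds. The Monte Carlo FDR
permutes sample labels of the per-sample median statistic (10,000
iterations by default) and reports the fraction of null iterations at
or below the p-value threshold.

**FRAP.** After normalization to the pre-bleach maximum, the mobile
fraction is MF = (I_sat - I_dip)/(1 - I_dip) with I_dip the first
post-bleach intensity and I_sat the terminal plateau; an exponential
fit I(t) = I_dip + A(1 - e^(-kt)) is available as a cross-check, and
groups are compared with the standard unpaired t-test.

**Quantification.** %Input = 2^(Cp(WCE) - Cp(IP)) × %WCE; relative
expression = 2^(Cp(control) - Cp(target)); densitometry folds are
wild-type/mutant band-ratio quotients with a ratio-of-means average.

See `vignettes/stemchrom-methods.Rmd` for the full account of the
models, parameters and design decisions.

## Worked example

The densitometry arithmetic on a wild-type transgene/H3 band ratio of
0.439 against mutant replicate ratios 0.255 and 0.219:

```r
library(stemchrom)
densitometry_fold_change(0.439, c(0.255, 0.219))
#> densitometry fold change: per replicate 1.72, 2.00; average 1.85
```

The per-replicate folds are 0.439/0.255 = 1.72 and 0.439/0.219 = 2.00;
the headline average is the ratio of means 0.439/0.237 = 1.85 — the
mutant retains roughly half the wild-type chromatin signal.

Estimating a mobile fraction from simulated recovery curves (30 s
frames for ~14 min, 14 cells, true MF 0.13):

```r
ps <- frap_sim_params(mf = 0.13, k = 0.01, i_dip = 0.5, dt = 30,
                      n_frames = 30, noise_sd = 0.01, seed = 7)
curves <- gen_frap_curves(ps, 14)
mobile_fraction(normalize_curve(curves[[1]]), tail_window = 3)
#> mobile fraction (cell001): 0.140  [I_dip 0.477, I_sat 0.550]
```

Cell 1 recovered 14% of its bleached deficit; averaging all 14 cells
gives 0.125, within the expected truncation- and noise-limited
tolerance of the true 0.13.

An end-to-end run on synthetic data with known ground truth:

```r
report <- run_pipeline(list(seed = 42))
report
#> stemchrom pipeline report (seed 42 )
#> promoter classes (true -> called):
#>           called
#> true       bivalent active unmarked
#>   bivalent       56      0        0
#>   active          0     82        0
#>   unmarked        0      0       62
#> differential genes: 56; bivalent overlap p = 5e-51
#> nanostring null FDR at p<=0.05: 0.110
#> wt: MF 0.144 +/- 0.006 (n=14)  vs  mutant: MF 0.199 +/- 0.006 (n=14)
#>   t = -6.535, df = 26, p = 6.291e-07
```

All 56 truly bivalent promoters are recovered by the caller, the
differential set coincides with the bivalent class (hypergeometric
p ≈ 5e-51), and the two FRAP groups (true MF 0.13 vs 0.20) separate at
p < 1e-6. Every output file under the run directory starts with a `#`
provenance header recording the package version and master seed.

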