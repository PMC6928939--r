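# qtmod

Module-based quantitative-trait genetic analysis of subcortical brain
volumes, for imaging-genetics researchers who want the full chain — genotype
QC, head-size normalization, structure clustering, module-volume GWAS,
anchored epistasis scan and interactive-SNP selection — as one tested,
reproducible R pipeline with a synthetic-data generator carrying planted
ground truth.

## The method

Volumes of 35 Freesurfer-segmented subcortical structures are first freed of
the head-size nuisance with the residual adjustment

```
ROI_norm(i) = ROI_raw(i) − ε_i · (ICV_raw − mean(ICV)),
```

where ε_i is the OLS slope of structure *i*'s raw volume on intracranial
volume fitted in normal controls only, and the ICV mean is taken over all
samples. Pearson correlations of the normalized volumes are clustered
(complete linkage on `1 − |r|`) into **k = 5 modules**; each module's trait
is the sum of its members' normalized volumes.

Each module trait is then scanned per SNP with the covariate-adjusted linear
model `trait ~ dosage + age + sex + education` (significance at p < 1×10⁻⁴,
strict); the five smallest p-values are the module's **main-effect SNPs**.
These act as anchors in a genome-wide SNP×SNP interaction scan of the full
model `trait ~ g1 + g2 + g1·g2 + covariates`, computed in matrix form as a
partial correlation but numerically identical to the explicit least-squares
fit. Pairs with p < 5×10⁻⁴ form a bipartite network, and the three partners
with the highest degree (number of distinct anchors hit) are the
**interactive-effect SNPs**.

Genotype QC follows the standard order: sample call rate ≥ 90%, X-heterozygosity
sex check, relatedness (PI_HAT > 0.2 drops one member of a pair), then variant
call rate ≥ 90%, Hardy–Weinberg exact test (excluded at p ≤ 5×10⁻⁷), MAF ≥ 10%,
and `indep-pairwise`-style LD pruning (window 50, step 5, r² 0.8).

## Worked example

```r
library(qtmod)

cfg <- run_config(seed = 1, sim = list(n_samples = 300, n_snps = 1000))
res <- run_pipeline(cfg)
res
#> <pipeline_result> seed 1: 300/300 samples, 989/1000 variants retained
#>   module ARI vs truth: 1.000
#>   M1: 3 significant; main: rs000885,rs000799,rs000565,rs000922,rs000155; interactive: rs000745,rs000864,rs000706
#>   M2: 2 significant; main: rs000372,rs000903,rs000445,rs000637,rs000039; interactive: rs000207,rs000150,rs000551
#>   ...
```

All 300 samples and 989 of 1000 variants survive QC (the removals are
variants whose in-sample MAF fell below 10%). The clustering recovers the
planted five-module partition exactly (adjusted Rand index 1.000). Looking
closer at module 1:

```r
dplyr::select(res$modules$M1$top_main, id, chrom, pos, beta, se, p)
#> # A tibble: 5 × 6
#>   id       chrom    pos  beta    se        p
#> 1 rs000885 20    555000  435.  64.8 9.88e-11
#> 2 rs000799 18    585000  330.  67.6 1.78e- 6
#> 3 rs000565 13    375000  406. 100.  6.38e- 5
#> 4 rs000922 21    450000 -359.  97.7 2.85e- 4
#> 5 rs000155 4     300000  350. 102.  6.97e- 4

res$truth$main_effects[res$truth$main_effects$module == 1, ]
#> # A tibble: 2 × 3
#>   snp      module  beta
#> 1 rs000885      1  369.
#> 2 rs000799      1  308.
```

The two planted main-effect SNPs for this module rank first and second, with
fitted betas (435 and 330 mm³ per allele) bracketing the planted values
(369 and 308). `res$modules$M1$interactive` lists the degree-selected
interaction partners with their minimum edge p-values, and
`res$report` collects per-module recovery metrics (`planted_main_rank`,
`planted_partners_selected`) machine-readably.

Every stage is also usable on its own — `simulate_genotypes()`,
`inject_defects()`, `run_qc()`, `fit_normalization()`, `cluster_modules()`,
`assoc_scan()`, `scan_anchors()`, `build_network()` — with broom-style
`tidy()`/`glance()` methods and `plot_manhattan()` /
`plot_correlation_heatmap()` for figures. `inst/scripts/qtmod.R` wraps the
pipeline for shell use with a YAML config. See the vignette
(`vignettes/quantitative-trait-modules.Rmd`) for the model details and
design choices.

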