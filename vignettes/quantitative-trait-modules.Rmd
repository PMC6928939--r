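---
title: "Module-based quantitative-trait genetic analysis of subcortical volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-based quantitative-trait genetic analysis of subcortical volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtmod)
```

## The analysis

qtmod implements a module-based quantitative-trait genetic analysis for
neurodegeneration cohorts. Instead of testing genetic association against a
binary diagnosis, the pipeline treats the summed volume of a *module* — a
cluster of subcortical brain structures whose volumes co-vary across
subjects — as a continuous GWAS response, and then looks for pairwise SNP
interactions anchored at each module's strongest main-effect loci. The
stages, in order:

1. **Genotype QC** (sample filters, then variant filters, then LD pruning);
2. **Head-size normalization** of 35 structure volumes;
3. **Clustering** of structures into k = 5 modules from the Pearson
   correlation of normalized volumes;
4. **Module-volume GWAS**, adjusted for age, sex and education;
5. **Anchored SNP×SNP interaction scan** against the genome;
6. **Degree-based selection** of interactive-effect SNPs.

A synthetic-data generator with planted, recorded ground truth makes the
whole chain testable end to end.

## Volume normalization

Head size is a nuisance scale factor for every regional volume. For
structure $i$ the package removes it with a residual adjustment:

$$\mathrm{ROI}^i_{norm} = \mathrm{ROI}^i_{raw} - \epsilon_i\,
  (\mathrm{ICV}_{raw} - \overline{\mathrm{ICV}}),$$

where $\epsilon_i$ is the OLS slope of the raw volume on raw intracranial
volume (ICV) fitted **in the normal-control group only**, while
$\overline{\mathrm{ICV}}$ is the mean over all samples. The slope is
NC-only because the volume/head-size relation is a statement about healthy
anatomy; in a patient group atrophy distorts it. Two identities pin the
formula down and are asserted in the tests: a sample whose ICV equals the
mean keeps its raw volumes, and adding a constant to every ICV (and hence
to the mean) changes nothing.

## Module construction

Pairwise Pearson correlations of the normalized volumes are converted to
the dissimilarity $d = 1 - |r|$ and clustered by complete-linkage
agglomeration; the tree is cut into $k = 5$ modules and each module's trait
is the **sum** of its members' normalized volumes. We use $|r|$ rather than
$r$ because ventricular volumes anti-correlate with tissue volumes while
clearly belonging to one coherent system; a `distance = "corr"` switch
gives the signed alternative. Merge ties are resolved by `stats::hclust`'s
deterministic ordering; with continuous volume data exact ties have measure
zero, and the suite checks agreement with a naive $O(n^3)$ agglomeration
oracle on random matrices.

The default roster encodes 22 structures, 13 of them bilateral, expanding
to 35 phenotypes. The reference partition used as the generator's truth
assigns them anatomically: limbic system (6), corpus callosum (5),
thalamus–cerebellum–brainstem–pallidum (11), neostriatum (4), ventricular
system (9).

## Genotype QC

Filters run in a fixed order — sample call rate $\ge 0.90$, X-heterozygosity
sex check, relatedness — then variant call rate $\ge 0.90$, Hardy–Weinberg
exact test (excluded at $p \le 5\times10^{-7}$), minor allele frequency
$\ge 0.10$, and finally windowed LD pruning (window 50 variants, step 5,
$r^2 > 0.8$ removes the lower-MAF member of a pair). Both call-rate and MAF
boundaries are inclusive; the HWE and significance cuts are as written.
Because variant statistics are recomputed on the filtered sample set,
re-running QC on its own output is a no-op.

Design points worth stating:

* **HWE exact test.** The two-sided exact test sums, over all heterozygote
  counts compatible with the observed allele counts, the probabilities no
  larger than the observed table's, computed with log-factorials and with
  allele labels canonicalized so the p-value is bitwise symmetric. The test
  suite checks it against an independent mode-anchored recurrence oracle,
  exhaustively for all tables up to n = 100 and on randomized tables to
  n = 200 (the full n ≤ 200 enumeration is ~1.4M tables; the sweep covers
  the same comparison at a practical size). X-flagged variants are tested
  on females only, since hemizygous male coding fails HWE by construction.
* **Relatedness.** PI_HAT is the IBS method-of-moments estimator with
  allele frequencies from the sample itself. The intermediate IBD-state
  probabilities are deliberately *not* clamped to the simplex before
  combining — clamping biases PI_HAT upward by a few hundredths for
  unrelated pairs, enough to push null pairs over the 0.2 exclusion
  threshold at a few thousand markers; only the final estimate is bounded
  to [0, 1]. Pairs above 0.2 lose the lower-call-rate member (ties drop
  the lexicographically larger id). Estimation runs on an internally
  LD-pruned autosomal subset.
* **Sex check.** Inferred male below 5% X heterozygosity, female above
  15%, undetermined between; only determined contradictions are flagged.
  The thresholds are generous for synthetic data, where the two groups sit
  at 0 and around $2\,\mathrm{MAF}(1-\mathrm{MAF})$.
* **LD pruning.** Within each window the worst offending pair (largest
  $r^2$, ties by smallest column index) is resolved first; removal prefers
  the lower-MAF member, then the later position. These tie-breaks are
  conventions fixed for reproducibility; the windowed result is checked
  against a single-window brute-force greedy oracle.

## Association and interaction models

The GWAS fits, per variant, `trait ~ intercept + dosage + age + sex +
education` and t-tests the dosage coefficient. The scan residualizes trait
and all dosages on the covariate design once (Frisch–Waugh–Lovell), which
is numerically identical to per-SNP fits — asserted against an `lm()`
oracle at $10^{-8}$ relative. Missing dosages are mean-imputed per SNP by
default (post-QC missingness is below 10%, and imputation keeps the matrix
form exact); a per-SNP case-deletion mode is available. Monomorphic
variants are flagged and reported at p = 1. Variants with $p < 10^{-4}$
(strict) are "significant"; the five smallest p-values are the module's
**main-effect SNPs**. No genomic control or mixed model is applied, and no
multiple-testing correction beyond the fixed threshold — the design this
package reproduces uses the plain covariate-adjusted linear scan.

The interaction test evaluates the product coefficient in the full model
`trait ~ intercept + g1 + g2 + g1*g2 + covariates`, computed as the partial
correlation between trait and raw-dosage product after projecting out
{intercept, covariates, g1, g2}, converted to a t statistic on
$n - (q + 4)$ degrees of freedom. Conditioning on both marginal dosages is
essential: a product-only test would conflate main and interaction effects,
so no such mode is offered. Products are formed on raw {0,1,2} codes —
centering is handled by the projection, keeping the statistic identical to
the explicit OLS fit. The scan tests each module's five anchors against all
non-anchor variants (anchor–anchor pairs are excluded; partner degrees then
count distinct anchors, matching how the published degree tables read),
keeps pairs with $p < 5\times10^{-4}$ strictly, and ranks partners by
degree, breaking ties by smallest edge p-value and then lexicographic id —
the tie-break is our convention, the published tables do not specify one.
The top three partners are the **interactive-effect SNPs**.

## The synthetic generator

`simulate_genotypes()` draws biallelic dosages under HWE with MAFs uniform
on a configurable interval, optional Markov-copying LD blocks (neighbor
allele copied with probability $\rho$, else redrawn, giving $r^2 \approx
\rho^{2d}$ decay and a controllable pruning workload), and an X-flagged
chromosome on which males carry a single haplotype. `simulate_phenotypes()`
then builds volumes as

$$\mathrm{ROI}_i = \mu_i + \epsilon_i(\mathrm{ICV} - \overline{\mathrm{ICV}})
 + \lambda_i F_{m(i)} + \tfrac{1}{|m(i)|}\Big(\textstyle\sum \beta g +
 \sum \beta_{12}\,\tilde g_1 \tilde g_2 + X\gamma_{m(i)}\Big) + e_i .$$

Choices that matter:

* ICV is Normal(1.5×10⁶ mm³, sd 1.5×10⁵), truncated positive — an
  anatomically plausible scale; default slopes $\epsilon_i = \mu_i /
  \overline{\mathrm{ICV}}$ make each structure scale proportionally.
* The per-module latent factor $F_m$ (default sd 0.05 with loadings
  $\lambda_i = \mu_i$, i.e. 5% common fractional variation against 3%
  residual noise) is what makes modules discoverable; the recovery tests
  run at factor sd 0.10 ("strong factors").
* Planted interaction effects multiply **centred** dosages so they do not
  leak into marginal effects — main-effect and interactive recovery stay
  separable tests.
* Effects stated per module trait are divided equally over members, so the
  summed module volume carries exactly the stated coefficient.
* Demographics are drawn per diagnosis group with the case fraction
  179/393 and group means/sds matching the cohort the pipeline emulates
  (age ≈ 75.4/75.7 y, education 14.65/16.07 y, MMSE 23.3/29.1,
  CDR-SB 4.3/0.03 for AD/NC).
* Planted effect sizes in the pipeline presets are expressed in units of
  each module trait's residual sd (default 0.6 and 0.5 sd per allele for
  main effects, 0.8 sd for interactions). The source study reports only
  p-values on restricted data, so no effect-size scale could be taken from
  it; these defaults were chosen once for testability — strong enough that
  recovery failures indicate bugs rather than power — not for biological
  realism.

What the generator deliberately does **not** emulate: realistic human LD
maps, population structure and cryptic relatedness beyond planted
duplicates, genotyping batch effects, non-Gaussian volume distributions,
and segmentation error correlated with disease severity. Passing recovery
tests therefore demonstrates correctness of the statistical machinery under
its own assumptions, not robustness on real imaging genetics data.

## Numerical choices and degenerate inputs

* Association and interaction p-values are floored at $10^{-300}$ only for
  Manhattan tables; results carry the raw values.
* A product term collinear with its conditioning set (e.g. when one
  genotype combination never occurs) is flagged and reported at p = 1, as
  is a monomorphic dosage in the GWAS.
* `interaction_test()` canonicalizes the order of its two dosage arguments,
  making the statistic bitwise symmetric.
* Zero-variance phenotypes abort correlation with an error naming the
  column; fewer than three NC samples or zero NC ICV variance abort the
  normalization fit.
* All stage randomness derives from a single master seed; two runs with the
  same configuration produce byte-identical output files.

## Problem sizes

The test suite and the acceptance script run the full chain at n = 500
samples × 5000 variants (about half a minute on one core), type-I
calibration at n = 400–500 with 1000–2000 replicates, power checks at 200
replicates against noncentral-t theory, and the HWE sweep described above.
These sizes were chosen so the whole suite completes in a few minutes while
keeping every binomial confidence interval tight enough to be meaningful.

## A short example

```{r example, eval = FALSE}
library(qtmod)

cfg <- run_config(seed = 1, sim = list(n_samples = 300, n_snps = 1000))
res <- run_pipeline(cfg)
res$report$module_ari          # 1 when the partition is recovered exactly
tidy(res$partition)            # phenotype -> module table
res$modules$M1$top_main        # the module's five main-effect SNPs
res$modules$M1$interactive     # its degree-selected interactive SNPs

# individual stages compose with the pipe as well:
G <- simulate_genotypes(200, 500, seed = 2)
qc <- run_qc(G)
tidy(qc$report)
```

## Known limitations

* The IBS-based PI_HAT has no small-sample allele-frequency correction;
  with at least ~1000 pruned markers its null spread is well inside the
  0.2 exclusion threshold, but estimates on a few hundred markers are
  noisy (and flagged below 50).
* Case deletion and mean imputation answer slightly different questions
  under informative missingness; QC keeps missingness below 10%, where the
  two agree closely.
* The roster, thresholds and k = 5 are fixed to the design this package
  reproduces; nothing prevents other values, but the reference partition
  and the bundled recovery checks assume the defaults.
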