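# dgrpanel

Analytics for harmonized phenomics on inbred reference panels such as the
*Drosophila* Genetic Reference Panel (DGRP), where each line is a fully
sequenced, near-homozygous genotype phenotyped across many independent
studies and both sexes. The package implements the analytical layer such a
resource needs once the phenotype tables are harmonized:

- **Harmonized data handling** — strict TSV/CSV input/output following the
  community data-sharing guidelines (canonical `DGRP_XXX` line ids, sex
  column `M`/`F`/`NA`, a single `NA` missing-value convention), with a
  validator that reports guideline violations.
- **Synthetic panels** — a fully seeded generator of genotypes (0/1
  homozygous coding, configurable MAF), the six known covariates
  (*Wolbachia* infection status plus five structural-variant factors) and
  block-correlated multi-study phenotypes with spiked causal effects, so
  every analysis is testable without any hosted data.
- **Cross-study correlation** — sex-stratified Spearman correlation
  (mid-ranks, two-sided t approximation) over all quantitative phenotype
  pairs, within- vs cross-study summaries, and focal-phenotype queries
  with Benjamini–Hochberg FDR control: for a family of m candidate
  p-values, q(i) = min over j ≥ rank(i) of m·p(j)/j, hits kept at q ≤ α.
- **Per-variant association (GWAS-lite)** — for each variant g passing the
  missingness (≤ 0.2) and MAF (≥ 0.01) filters, ordinary least squares of
  the rank-based inverse-normal transformed phenotype on
  [1, g, covariates], reporting the genotype term only
  (β, SE, t = β/SE, two-sided p on the residual df); QQ and threshold
  summaries including the Bonferroni threshold α/m; advisory
  Kruskal–Wallis / ANOVA / Shapiro–Wilk covariate screens; and
  phenome-wide (PheWAS) lookup of one variant across all stored results.
- **Fraction of extremeness (FoE)** — per phenotype, minimum-tie ranks r
  with cutoff c = ⌈0.15·r_max⌉; assignments −1 (r ≤ c), +1 (r ≥ r_max − c),
  else 0; per line and sex, FoE = (# of ±1)/(# phenotypes); adjusted value
  r/r_max reflected about 0.5; cross-sex extreme/moderate line discovery.

## Worked example

```r
library(dgrpanel)

cfg <- simConfig(nLines = 200, nVariants = 500, missingRate = 0,
                 causalEffects = data.frame(variant = 17L, beta = 1.5,
                                            study = 1L, pheno = 1L),
                 seed = 42)
sim <- simulatePanel(cfg)

## which phenotype pairs travel together?
recs <- correlateRegistry(sim$registry)
withinCrossSummary(recs)
#>    group   n median_abs_rho mean_abs_rho
#> 1 within  60     0.57689042   0.56205643
#> 2  cross 150     0.06175129   0.06544461

## covariate-adjusted association for study S01, phenotype ph01, females
y  <- phenotypeValues(sim$registry, "S01", "ph01", "F")
gw <- runGwas(y, sim$panel, sim$covariates)
head(gw$results[, c("variant_id", "beta", "se", "p")], 3)
#>   variant_id       beta        se            p
#> 1  3L:860770  0.9254968 0.1459454 1.732169e-09
#> 2  X:7153098 -0.9359591 0.2353879 1.001503e-04
#> 3 3R:9300920  0.4554239 0.1447734 1.933727e-03
```

The top hit `3L:860770` is the spiked causal variant (index 17): its
fitted effect 0.93 is the planted β = 1.5 after attenuation by
rank-normalizing and rescaling the phenotype (whose total variance the
causal term itself inflates), and it clears the next variant by five
orders of magnitude in p. The within-study mean |ρ| ≈ 0.56 against
cross-study ≈ 0.07 reflects the generator's correlation targets
(ρ_w = 0.6, ρ_x = 0.05).

An extremeness scan on the same registry:

```r
ext <- extremenessPipeline(sim$registry, minPhenos = 10)
head(ext$records, 2)
#>       line sex n_phenos       foe
#> 1 DGRP_001   F       15 0.4666667
#> 2 DGRP_001   M       15 0.4666667
crossSexPairings(ext$records, tol = 0.05)$extreme
#>       line     foe_F     foe_M  mean_foe
#> 1 DGRP_030 0.5333333 0.5333333 0.5333333
```

`DGRP_030` is the line whose female and male fractions of extremeness agree
within 0.05 while having the highest cross-sex mean — the "extreme pick".

A command-line wrapper ships as `exec/dgrpanel` with subcommands
`validate`, `simulate`, `correlate`, `gwas`, `phewas` and `extremeness`;
every run writes its outputs plus a `manifest.json` (options, input
digests, versions) under `--outdir`.

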