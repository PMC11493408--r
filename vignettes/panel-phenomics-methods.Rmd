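---
title: "Panel phenomics methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel phenomics methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrpanel)
```

This vignette documents the statistical machinery in `dgrpanel`, the
assumptions behind it, the defaults that matter, and the choices we made
where more than one reasonable design existed. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The setting

An inbred reference panel (the DGRP being the canonical example) consists
of a few hundred near-fully homozygous lines. Each line is one genotype,
shared across laboratories, so phenotypes accumulate over many independent
studies: line-by-phenotype matrices, measured per sex (`M`, `F`) or on
sex-mixed material (`NA`). The package works on three containers:
a `PhenotypeRegistry` (studies, per-phenotype descriptors with sex, unit
and dtype, and per-study tables), a `GenotypePanel` (lines × biallelic
variants, calls coded 0 = ref/ref, 1 = alt/alt — heterozygotes do not occur
in homozygous lines, so 0/1/2 dosage coding would be vacuous), and a
`CovariateTable` holding the six known covariates: endosymbiont
(*Wolbachia*) infection status plus five major structural-variant factors.
Line identifiers are canonicalized to `DGRP_` plus a zero-padded
three-digit number; published panels use at most three digits, so larger
numbers are rejected rather than padded wider.

## The synthetic panel generator

Every analysis must be testable without hosted data, so the generator is
first-class code, not a fixture. Its defaults are the study conditions the
rest of the package is validated under.

**Phenotypes.** Each phenotype $j$ in study $s$ for a line is

$$y_{s,j} = \sqrt{\rho_x}\,G + \sqrt{\rho_w - \rho_x}\,F_s + \sigma\,
\varepsilon_{s,j},$$

with a global factor $G$, a study factor $F_s$ and unique noise, all
standard normal per line. With $\sigma = \sqrt{1-\rho_w}$ (the default
derivation when `noiseSd = NA`) every phenotype has unit variance and the
expected correlation between two phenotypes is exactly $\rho_w$ within a
study and $\rho_x$ across studies. Every random component — including the
noise — is drawn as a correlated female/male pair at $\rho_{mf}$, so the
same trait measured in the two sexes correlates at exactly $\rho_{mf}$ in
expectation, independent of the study structure. Defaults
$\rho_w = 0.6$, $\rho_x = 0.05$ reproduce qualitatively the strong
within-study blocks seen in real cross-study correlation heatmaps;
$\rho_{mf} = 0.5$ encodes the moderate-to-strong cross-sex agreement
typical of organismal traits such as longevity. Spiked causal variants add
$g\beta$ to designated phenotypes in both sexes ($\beta$ on the
unit-variance phenotype scale; missing calls contribute the variant's mean
dosage so the planted signal is not confounded with missingness), and
covariate effects add $C\gamma$ to every phenotype, mimicking panel-wide
confounders like symbiont status.

**Genotypes and covariates.** Alt-allele frequencies are uniform on
`mafRange` (default [0.05, 0.5]); calls are independent across lines and
variants — linkage disequilibrium is deliberately absent because the
association model under test is per-variant, so LD affects interpretation,
never the fitted statistic. Variant classes are sampled in proportion to
the published panel composition (`dgrpVariantCatalog()`). The five
structural-variant covariates get geometrically decaying category
frequencies (one common standard arrangement, rarer alternatives);
symbiont prevalence defaults to 0.5.

**Missingness** is missing-completely-at-random, 10% for phenotype cells
and 2% for genotype calls by default. Real panels have structured
missingness (lines enter and leave studies in blocks); MCAR is the
simplest mechanism under which the per-variant complete-case model is
unbiased, and nothing downstream estimates a missingness mechanism. This
is the main respect in which passing tests do not speak to real data: the
generator also omits LD, batch effects within studies, and heteroscedastic
measurement error. What the tests *do* establish is the algebraic
correctness of every statistic and the calibration of the inference under
the stated model.

All generators are bit-reproducible: each derives its stream from
`seed` plus a small fixed offset, and restores the caller's RNG state.

## Correlation engine

Spearman's coefficient is computed as the Pearson correlation of mid-ranks
(average ranks for ties) on pairwise-complete observations; the two-sided
p-value uses $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom. Pairs with fewer than `minOverlap` shared lines (default 10 —
below that the t approximation is unreliable) or zero rank variance are
skipped and counted, never emitted as NaN, so downstream summaries stay
well-defined. Registry-wide correlation is stratified by sex and
restricted to quantitative phenotypes; dtype is declared metadata, not
inferred from the data, because inference from a handful of line means is
fragile.

FDR control is Benjamini–Hochberg, written out as the step-up rule
$q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$. For focal queries the family is
the focal phenotype's candidate set — one family per query, not the global
pair matrix — matching how "phenotypes correlated with trait X at 5% FDR"
is naturally read. Candidates match the focal sex by default; a flag
allows cross-sex pairing (matching on shared lines), since published focal
panels mix male and female phenotypes. Hits are partitioned by
average-linkage hierarchical clustering on distance $1-\rho$ of their
mutual correlation matrix, cut into three groups labelled by mean
correlation with the focal phenotype (≥ 0.8 focal-like, ≥ 0 correlated,
< 0 anti-correlated); linkage and the cut count are defaults, not claims —
nothing downstream consumes the labels.

## Association engine

The per-variant model mirrors the PLINK2 invocation used on the full
panel (`--glm hide-covar --quantile-normalize --variance-standardize
--geno 0.2 --maf 0.01`):

1. **Filters.** A variant is tested iff its missing-call fraction is
   ≤ 0.2 and its minor-allele frequency — computed on non-missing calls,
   folded to ≤ 0.5 — is ≥ 0.01. Reasons are mutually exclusive
   (missingness checked first) and exhaustive.
2. **Transform.** The phenotype is replaced by
   $\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with mid-ranks $r$ and
   Blom's offset $c = 3/8$ — the conventional choice where only
   "quantile normalization" is specified; the offset is a parameter.
   The transform makes every downstream p-value invariant under strictly
   increasing re-expressions of the phenotype. Covariates are not
   transformed by default (a documented open choice); categorical
   covariates enter as indicator contrasts against the most frequent
   category — a deterministic reference that needs no level ordering —
   and quantitative covariates are centered and unit-scaled when
   variance-standardization is on.
3. **Fit.** Ordinary least squares of the transformed phenotype on
   $[1, g, C]$, per-variant complete case (lines missing $y$ or $g$ are
   dropped for that variant only). Only the genotype row is reported:
   $\beta$, SE, $t=\beta/\mathrm{SE}$, and a two-sided p from the t
   distribution on the residual degrees of freedom. Variants monomorphic
   in the analysis sample, or collinear with the covariates, are skipped
   and counted. p-values are floored at the smallest positive double so
   that $-\log_{10} p$ plots never divide by zero.

The covariate screen (per-factor Kruskal–Wallis, one multifactor ANOVA
over all six covariates, Shapiro–Wilk on the raw phenotype) is advisory
only: the association model always includes all covariates. These three
tests are delegated to `stats::kruskal.test`, `stats::aov` and
`stats::shapiro.test`.

Threshold bookkeeping reports hit counts at the configurable thresholds
(defaults $10^{-3}$, $10^{-5}$, $10^{-6}$) and the Bonferroni threshold
$\alpha/m$; at the published catalog size $m = 4{,}438{,}427$ and
$\alpha = 0.05$ this is $1.126\times 10^{-8}$. A second published
Bonferroni figure corresponding to a post-filter variant count is not
reproducible because that count is not published.

**QQ calibration band.** `qqData()` pairs observed $-\log_{10} p$ with
expected quantiles $-\log_{10}((i-0.5)/m)$. For the calibration check in
the test suite the band is the *simultaneous* 95% order-statistics band
(beta quantiles at Šidák-adjusted pointwise level): under a calibrated
null essentially all points fall inside it. A pointwise 95% band is not
usable as a pass/fail criterion, because the expected fraction of points
outside it is exactly 5% by construction — each order statistic exits with
5% probability marginally — so any fixed allowance near 5% would be a coin
flip.

## Extremeness engine

The fraction-of-extremeness procedure is implemented verbatim:

- minimum-tie ranks per phenotype (ties share the minimum rank);
- cutoff $c = \lceil 0.15\,r_{\max}\rceil$ of the **maximum assigned
  rank**, rounded up to be inclusive at either end (raw 1.2 and 1.8 both
  become 2; exact integers unchanged). We use $r_{\max}$, not the count of
  ranked values, because the procedure is defined on ranks and the
  adjusted value divides by the max rank; the two coincide without ties;
- assignment $-1$ for $r \le c$, $+1$ for $r \ge r_{\max} - c$, else 0.
  The upper band is thereby one rank wider than the lower one for dense
  distinct ranks; the rule is kept as stated rather than symmetrized, and
  the asymmetry is observable in the assignment tables. Where the bands
  overlap ($c \ge r_{\max} - c$) the lower band wins and the phenotype is
  flagged degenerate;
- FoE per (line, sex) = (# of ±1)/(# phenotypes with a value); records
  with fewer than `minPhenos` (default 50) phenotype values are excluded
  per (line, sex), since extreme/moderate calls are made per plotted sex;
- adjusted value $r/r_{\max}$, reflected about 0.5 (strictly above 0.5
  only), so extremes at either tail map below 0.15. Because the rank
  cutoff is rounded up but the adjusted value is not, a value can be
  assigned ±1 while its adjusted value exceeds 0.15; the pipeline counts
  these rounding "violations" (e.g. with $r_{\max}=6$: $c=1$ and
  $1/6 = 0.167 > 0.15$, so every rank-1 assignment is a violation).

Cross-sex pairing considers lines whose female and male FoE differ by at
most `tol` (default 0.05) and returns the highest and lowest cross-sex
mean FoE as the extreme and moderate picks.

## Numerical and interface choices

- Harmonized TSVs serialize numbers at 17 significant digits, so
  write-then-read is the identity on doubles; the missing token on output
  is always the literal `NA` (readers accept empty cells too, with a
  warning when a file mixes conventions).
- Excel ingestion is out of scope; delimiters (tab/comma) are
  auto-detected from the header row.
- All CLI outputs are written atomically (temp file + rename) with a
  `manifest.json` capturing options, input MD5 digests and versions;
  determinism of `simulate` is byte-level given a seed.
- Problem sizes in the test suite — e.g. null calibration at 200 lines ×
  2000 variants × 10 seeds, recovery at 200 lines × 500 variants × 20
  replicates, FDR control over 50 seeded focal queries of 50 candidates —
  were chosen so Monte-Carlo error is small relative to the asserted
  tolerances (binomial standard error ≈ 0.0015 on the pooled type-I
  estimate) while the whole suite stays interactive.

## Known limitations

Per-variant fixed-effects OLS ignores relatedness and polygenic
background (no kinship/mixed model), which the six-covariate design does
not capture; genotype imputation, LD-aware analyses, meta-GWAS across
studies, gene-set enrichment and variant functional annotation are out of
scope. The generator's idealizations are listed above; conclusions about
real panels should treat the test results as verification of the
machinery, not as biological validation.
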