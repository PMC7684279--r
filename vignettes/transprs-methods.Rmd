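---
title: "Methods: transethnic PRS scoring, its statistics, and the liability-threshold simulator"
author: "transprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transethnic PRS scoring, its statistics, and the liability-threshold simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(transprs)
```

## The analysis this package implements

`transprs` carries a polygenic risk score (PRS) analysis from discovery GWAS
summary statistics and target genotype dosages to association and survival
statistics. The motivating design is transethnic: weights estimated in one
population (for example, European GWASs of four smoking behaviours — ever/never
initiation, age at initiation, cigarettes per day, and cessation) are applied
to an independent target cohort of another ancestry consisting of cases,
their unaffected first-degree relatives (FR), and healthy controls (HC).

The score for individual $i$ over a SNP set $S$ is the raw weighted allele
count

$$\mathrm{PRS}_i(S) = \sum_{v \in S} d_{iv}\, w_v,$$

where $d_{iv} \in [0,2]$ is the dosage of the counted (ALT) allele and $w_v$
is the discovery effect size on the log-odds scale for binary traits (logOR)
or the linear-regression $\beta$ for continuous ones. SNP sets are nested
p-value thresholds $S(P_T) = \{v : p_v \le P_T\}$ over the grid
$P_T \in \{10^{-4}, 10^{-3}, 0.01, 0.05, 0.1, 0.2, 0.5, 1\}$. Scores are raw
sums by default (no division by SNP count); z-standardized columns are
available for reporting and are exactly invariant to allele recoding.

Before scoring, variants pass:

1. **QC** (`variant_qc()`): duplicate ids, strand-ambiguous (A/T, C/G)
   alleles, Y-chromosome and mitochondrial variants, imputation quality
   `INFO < 0.9`, minor allele frequency below 0.01, and Hardy–Weinberg
   disequilibrium at an exact-test p below $10^{-6}$ (hard genotype calls
   only; fractional dosages skip the HWE screen). Each exclusion is logged
   once with its first failing rule, so the survivor set is independent of
   variant order. The MAF floor and HWE level are conventional GWAS screens;
   both are parameters of `qc_thresholds()`.
2. **Harmonization** (`harmonize_alleles()`): discovery effect alleles are
   reconciled with the target's counted allele — matching orientation keeps
   the weight, swapped orientation negates it, and for non-ambiguous SNPs the
   same two rules are retried after strand complementing. Ambiguous pairs are
   never complement-matched (the two strand readings are indistinguishable),
   which is why QC drops them by default.
3. **LD pruning** (`prune_window()`): greedy sliding-window thinning so that
   no retained pair within a 200-SNP window has squared dosage correlation
   above 0.25. The window/threshold pair is the classical
   "indep-pairwise"-style setting; the step defaults to 50 SNPs (a common
   companion choice — the method description we follow states the window and
   threshold only). Within a window the most correlated offending pair is
   resolved by dropping its lower-priority member: the larger discovery
   p-value under `priority = "p-value"`, the later variant under
   `priority = "order"` and on ties. $r^2$ is the squared Pearson correlation
   of dosages — the standard statistic on imputed data, where haplotype-phase
   EM estimates are unavailable — with missing dosages mean-imputed per
   variant, and zero-variance vectors contributing $r^2 = 0$ by convention.

## Association statistics

`fit_linear()` reports the ordinary-least-squares coefficient of the score, a
two-sided t-test, and the full model's **adjusted $R^2$**,
$1-(1-R^2)(n-1)/(n-p-1)$. `fit_logistic()` reports the Wald test and
**Nagelkerke's pseudo-$R^2$**

$$R^2_N = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}},$$

with $L_0$ the intercept-only and $L_1$ the full-model likelihood, computed
in log space from `glm` log-likelihoods. Both fits also report the increment
of the variance-explained measure over the covariates-only model. Logistic
separation is detected by a (near-)zero residual deviance or non-convergence
— not by coefficient magnitude, because raw-sum scores can have tiny scale
and therefore legitimately large coefficients. A constant score collapses the
logistic model to its null, reported as Nagelkerke 0 rather than an error.

`scan_thresholds()` fits one model per cutoff and reports the scan plus the
best cutoff by variance explained. P-values across cutoffs are deliberately
**not** corrected: neighbouring cutoffs give strongly correlated scores, and
the package instead quantifies the scan's selection optimism directly —
`prs_type1_calibration()` reports, under a null generator, both the
rejection rate at a pre-fixed cutoff (nominal) and at the scan's best cutoff
(inflated). Interpret a best-cutoff p-value accordingly.

Diagnosis enters two ways: a three-group linear trend with HC/FR/SCZ coded
0/1/2 (`group_trend()`; the equidistant coding is the reading under which an
adjusted $R^2$ for a "diagnostic status" outcome is defined, and under which
an unaffected first-degree relative — sharing half the case's genetic risk —
sits midway), and a two-group logistic case/control comparison. A
PRS-by-smoking-status interaction on case status is a logistic product-term
Wald test (`interaction_test()`). Because the headline three-group value
could be read with or without covariates, `run_pipeline()` emits both the
covariate-free scan and (if configured) covariate-adjusted scans;
`incremental_r2` separates the score's contribution in the latter.

Demographic-table statistics are recomputable from printed summaries:
`pearson_chi2()` is the uncorrected $\sum (O-E)^2/E$ test and
`anova_from_summaries()` rebuilds the one-way F-test from per-group
$(n, \bar x, s)$ triples — between-group sums of squares from
$n(\bar x - \bar{\bar x})^2$, within-group from $(n-1)s^2$. Initiation age is
compared across groups with Kaplan–Meier curves and the k-group log-rank test
(`km_logrank()`, backed by the survival package and oracle-tested against an
explicit risk-set computation): ever-smokers contribute their initiation age
as events, never-smokers are censored at interview age. When the discovery
definition of age at initiation is mirrored in a regression analysis the
outcome is log-transformed (`log_outcome: true` in the pipeline config); the
descriptive ANOVA uses the raw scale.

## The synthetic cohort generator

No individual-level study data are distributable, so the package ships a
generator whose defaults encode the study conditions the pipeline is
calibrated under:

* **Variant panel.** 20,000 biallelic SNPs in LD blocks of 50, MAF uniform on
  (0.05, 0.5), allele pairs with a transition excess so a realistic minority
  (~7%) is strand-ambiguous, imputation-quality scores with a small tail
  below 0.9. Haplotypes come from a Gaussian copula with AR(1) correlation
  0.8 within a block (strong local LD, as in dense imputed panels) and
  independence between blocks — the simplest structure that makes windowed
  pruning non-trivial. A diploid dosage is the sum of two independent
  haplotypes, so founder genotypes are in Hardy–Weinberg equilibrium by
  construction.
* **Architecture.** A spike-and-slab: 10% of variants are causal with
  bivariate-normal (discovery trait, liability) effect pairs of correlation
  `rg`. Effects are scaled analytically to the configured heritabilities
  ($h^2 = 0.5$ for the behavioural discovery trait, 0.8 for liability,
  echoing twin estimates for smoking behaviours and schizophrenia), and
  genetic values are standardized against an internal founder reference
  sample so in-cohort heritabilities are exact. `rg` defaults to 0.5; its
  true value is unknown beyond sign, and it is a free parameter.
* **Discovery GWAS.** The discovery phenotype is actually constructed
  (standardized genetic value plus Gaussian environment; for binary traits a
  logistic link whose latent genetic share equals $h^2$) and each SNP is
  marginally regressed, so betas, standard errors and p-values are internally
  consistent rather than noise-injected. Binary traits use per-SNP logistic
  fits and emit logOR weights.
* **Target cohort.** The liability-threshold model: liability = genetic value
  (variance $h^2_\ell$) + standard-normal environment; a case exceeds the
  $1-K$ quantile (prevalence $K = 0.01$ by default). Families (two parents,
  two children by per-variant Mendelian transmission, hence expected 50%
  allele sharing) are rejection-sampled in batches: an affected first child
  is the case, the sibling is retained as the FR only if unaffected, and
  controls are screened-unaffected founders. All relative types in the
  motivating design (parents/siblings/offspring) share the same expected
  relatedness, so one sibling mechanism suffices. An unreachable prevalence
  raises an informative error instead of looping.
* **Smoking phenotypes.** Driven by the discovery-side genetic value:
  ever/never and current/former through logistic links, age at initiation
  log-normal with a log-scale genetic shift, cigarettes per day
  negative-binomial. Group-level demographics (ages, sex ratios, education)
  mirror a mixed case/relative/control cohort. Rates and link strengths sit
  in `smoking_params` with defaults chosen once (ever rate 0.24, initiation
  age median ~20.5 years with sdlog 0.15, CPD mean 18 with dispersion 5,
  current-smoker rate 0.68).

What the generator does **not** emulate: real human LD maps or reference
panels, allele-frequency differences between ancestries (the transethnic
attenuation itself), X-chromosome dosages, assortative mating, or
genotyping/imputation error beyond the INFO annotation. Passing calibration
therefore shows the pipeline's statistics behave correctly under the model's
own assumptions — not that any particular real-data effect size is
recoverable.

## Calibration experiments and their problem sizes

The four calibration functions freeze desk-scale conditions (chosen for a
single CPU; the vignette states them as the package's own choices):

* `prs_type1_calibration()` — 200 replicates, 2,000 **independent** variants
  (`within_block_rho = 0`), 500 discovery / 200 target samples, `rg = 0`.
  With a finite panel the per-draw null is violated by construction: the
  score's population correlation with the trait's genetic value is a random
  $O(1/\sqrt{M_e})$ quantity even at `rg = 0`, so calibration requires
  $n \ll M_e$. The chosen sizes keep that inflation an order of magnitude
  below sampling noise — a real property of PRS type-I simulations worth
  knowing, not an artifact of this implementation.
* `prs_power_check()` — 10 seeds at the full stated conditions: 20,000
  LD-blocked variants, $h^2 = 0.5$, `rg = 0.5`, 2,000 discovery / 1,000
  target samples. Reported significance follows the study's own procedure
  (the best cutoff of the scan); the fixed-cutoff p-value is returned
  alongside.
* `prs_ordering_check()` — 20 seeds, `rg = 1`, $h^2 = 0.8$ both sides,
  130/56/146 target groups; prevalence 0.1 and 2,000 variants keep the
  family rejection sampling at desk scale without affecting the ordering
  property being tested.
* `prs_monotonicity_check()` — 5 seeds, discovery $n \in \{500, 2000,
  8000\}$ at 4,000 variants against a fixed target, recording the variance
  explained at $P_T \le 1$.

These functions skip QC and pruning (the association calibration does not
depend on them; both stages carry their own oracle-backed tests) and run the
harmonization → threshold → score → fit path.

## Numerical choices and degenerate inputs

* Hardy–Weinberg exact test: two-sided conditional test summing the
  probabilities of all heterozygote counts no more probable than observed;
  log-space factorials; tested against an independent recurrence
  implementation for all table sizes up to $n = 200$.
* Empty SNP set at a cutoff: scores 0 with a warning; the scan reports an NA
  row for a constant score instead of failing.
* Missing dosages: per-variant mean imputation by default; an `omit` policy
  rescales each individual by the absolute weight they carry.
* Pruning tie-breaks: equal priorities drop the later variant; the offending
  pair chosen per iteration is the one with the largest $r^2$ (first in
  column order on exact ties), making results order-deterministic.
* All generator randomness derives from one config seed through fixed
  per-operation offsets, so any stage can be re-run independently and
  fixture sets are byte-reproducible.
* Re-entrancy: `run_pipeline()` writes every intermediate (fixtures,
  exclusion log, kept-id list, per-trait profiles) as plain text, and its
  manifest hashes are reproducible for a fixed config and seed.

## Known limitations

* Dosage-based $r^2$ understates haplotype LD when phase matters; for
  pruning this is the standard compromise on imputed data.
* The three-group trend's equidistant coding is an interpretive choice; the
  two-group logistic comparison is emitted alongside so conclusions need not
  rest on it.
* Nagelkerke's $R^2$ is not comparable across outcome prevalences; compare
  it only within a scan.
* The generator's families are sibling pairs only, and case families with an
  unaffected sibling are slightly over-represented among retained cases — a
  mild, documented ascertainment feature of the rejection scheme.
* Quasi-complete separation that retains a nonzero deviance passes through
  with large standard errors (its Wald p-value is conservative) rather than
  being rejected.
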