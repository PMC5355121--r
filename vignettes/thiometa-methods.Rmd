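---
title: "Methods: pooling, dose normalization and the eQTL scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling, dose normalization and the eQTL scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiometa)
```

## The scientific question

NUDT15 dephosphorylates the active thioguanine metabolites of
azathioprine and 6-mercaptopurine. The missense variant rs116855232
(Arg139Cys; T risk allele, ~10% frequency in East Asians, rare in
Europeans) impairs that activity, so carriers accumulate cytotoxic
metabolites and develop myelotoxicity at doses tolerated by
non-carriers. The package synthesizes the case-control and dose-cohort
evidence for this association: odds ratios of myelotoxicity under the
standard genetic models, the maintenance-dose deficit of carriers, the
screening value of carrier status, and a cis-eQTL scan for
expression-level markers in the same gene.

## Data model

All analyses run off a *study set*: a tibble with one row per cohort,
genotype counts per arm, and per-genotype dose summaries
(`?study_set`). The packaged table (`table1_fixture()`) transcribes
the published characteristics of 15 cohort rows from 11 articles;
5 rows carry both endpoints, giving the published count of 7
myelotoxicity plus 13 dose endpoint-cohorts (20 in total). Absent
cells are `NA`, never zero: dose-only ALL cohorts have no control
arm, and single-patient TT groups have a mean but no SD, exactly as
printed.

Two transcription notes. One published cell is internally
inconsistent (the Hispanic ALL cohort's raw CT dose SD of 13.4 implies
a normalized SD of 0.204, yet 0.355 is printed; 0.355 back-computes to
a raw SD of 23.4, so the raw value is almost certainly a typo). The
fixture keeps both verbatim; analyses consume the printed *normalized*
values, which is also what the source analysis pooled. And one cohort
is labelled "Other" ethnicity because its ancestry composition was
never published; it is stored verbatim.

## Genetic models and pooling

`build_contrasts()` turns genotype counts into 2×2 tables. The allele
model counts each individual's two alleles as independent
observations (exposed = 2·TT + CT per arm) — the convention required
to reproduce the published forest-plot denominators. The dominant and
recessive models contrast carriers vs CC and TT vs the rest. For the
heterozygote effect we expose two contrasts: `"het"` (CT vs TT+CC)
and `"ct_vs_cc"` (CT vs CC only, dropping TT individuals). The
published heterozygote odds ratio (7.60, 95% CI 5.77–10.03) is
reproduced exactly by `"het"`, and its companion TT estimate is the
recessive model's 18.10 — so `"het"` is what the reporting functions
and acceptance checks use, while the CC-only-denominator contrast
remains available. Neither is a trend ("additive" in the strict
sense) test; no trend test is fitted.

Zero cells receive the per-study Haldane correction: 0.5 added to all
four cells of any table containing a zero. Tables whose exposed (or
unexposed) margin is zero in *both* arms carry no information about
the odds ratio and are excluded (in the packaged table this affects
one recessive-model study whose TT count is zero in both arms). This
convention — correction plus double-zero exclusion, Mantel–Haenszel
point estimate, Robins–Breslow–Greenland variance — reproduces the
published allele, recessive and heterozygote results to the printed
precision.

One published value resists every convention we tried: the
dominant-model OR is printed as 9.48 (7.20–12.47), while the packaged
counts give 9.37 (7.12–12.33) under the convention that matches all
other models exactly (alternatives — no correction, correction 1.0,
single-cell correction, treatment-arm correction, excluding the
all-control-non-carrier study — give 9.20–9.57, none 9.48). The
package reports the computed value; the corresponding acceptance test
documents the 1.1% discrepancy rather than papering over it.

Heterogeneity is Cochran's Q around the inverse-variance fixed
estimate with I² = max(0, (Q − (k−1))/Q)·100, floored at zero, and
the DerSimonian–Laird moment estimator for τ². Model selection
follows the published rule — fixed when I² < 50% *and* p > 0.1 — with
boundary cases resolving to random effects, the conservative choice
(the rule as stated is silent about, e.g., I² = 60% with p = 0.2).
Confidence intervals use the 1.96 normal quantile and p-values are
two-sided normal, matching the software family of the source
analysis.

A note on the MH/IV cross-check: the two fixed-effect estimators
agree within 2% on the dense allele, dominant and heterozygote
tables, and the test suite asserts exactly that. On the recessive
model they differ by ~21%, because four of the six usable tables
carry corrected zero cells — precisely the sparse regime where
inverse-variance weighting with Haldane corrections is known to be
biased relative to MH. We treat that divergence as expected behaviour,
not a defect, and the recessive headline number uses MH.

## Dose normalization and carrier combination

Doses are made comparable in three steps. 6-MP doses convert to
azathioprine equivalents (×2.08); per-kg doses convert to mg/m² via
the Meeh–Rubner surface area A = k·W^(2/3)/10⁴ (W in grams; k
defaults to 10.1, the customary human constant — the source never
states its k, but the packaged table already stores mg/m², so the
constant only matters for new data). Each study's per-genotype means
and SDs are then divided by that study's CC mean, making CC exactly 1
and cancelling any within-study unit or conversion choices.

CT and TT summaries are combined into one T-carrier group with the
exact pooled-sample formula
((n₁−1)s₁² + (n₂−1)s₂² + n₁n₂(m₁−m₂)²/N)/(N−1). The default policy
(`"singleton_exact"`) folds a TT group whenever its SD is known *or*
n = 1: for a singleton the (n−1)s² term vanishes, so the combination
is exact despite the unobservable SD, and dropping such patients would
discard information for no robustness gain. A TT group with n ≥ 2 but
no published SD cannot be combined honestly and the carrier group
falls back to CT only (one cohort in the packaged table). The stricter
`"drop_sd_less"` and the permissive `"zero_sd"` policies are
available; all three move the pooled mean difference by less than
0.02. Under the default the 13-cohort DerSimonian–Laird pooled mean
difference is −0.275 (95% CI −0.340 to −0.211), i.e. carriers
tolerate ~28% less drug, matching the published interval at its
printed precision.

The per-study effect is the unstandardized mean difference on the
normalized scale (carrier mean − 1) with SE = √(s₁²/n₁ + s₂²/n₂).
Standardized differences would not reproduce the published interval;
the printed CI is only consistent with raw mean differences on the
normalized scale. Group sizes are the cohort genotype totals (cases
plus controls where both arms exist), consistent with the published
total of 2745 dose patients.

## Publication bias and sensitivity

Egger's test is the classic regression of the standardized effect
θᵢ/seᵢ on precision 1/seᵢ by ordinary least squares; the intercept's
t-test (k−2 df) measures asymmetry. Begg's test computes Kendall's
τ-b between variance-stabilized deviates from the fixed pooled effect
and the study variances, with the tie-corrected normal approximation;
an exact permutation p-value is available for k ≤ 8 (the published
analyses have k = 7, where the normal approximation is customary).
Both tests hold their nominal type-I error to within sampling noise
over 500 simulated null meta-analyses in the test suite — worth
verifying because k = 7 is small for either test. Leave-one-out
re-pooling and funnel-plot coordinates round out the robustness
toolkit; on the packaged table every omission leaves the allele-model
CI above 1.

## The eQTL stage

Expression of one gene is regressed on additive variant-allele dosage
(0/1/2) per SNP with an intercept; the slope's t-test uses n−2 df.
Variants carried by fewer than 3 individuals are excluded (the
published threshold, boundary-inclusive); missing dosages drop the
sample for that SNP only; indels count any non-reference allele
toward dosage; no covariates are fitted, because none were published
(whether the published N = 447 regression pooled or adjusted
ancestries is unstated). Raw p-values are reported, as published;
Benjamini–Hochberg adjustment is an optional column. Genotypes load
from a delimited dosage matrix or a VCF (GT field); the published
window is chr13:48,582,000–48,622,000 on hg19, 1-based. Reproducing
the published promoter signal (P = 0.004 for rs554405994) needs the
external expression and genotype accessions, so the stage is
validated instead by closed-form equivalence (binary dosage ≡
two-sample t), equivariance, planted-effect recovery at n = 447, and
null-uniformity of scan p-values.

## What the simulators do and do not emulate

`simulate_meta_cohorts()` draws control genotypes from Hardy–Weinberg
at the control allele frequency and tilts the case allele frequency
by the study odds ratio on the odds scale before recombining — so the
allele-level OR is the designed quantity, matching the allele-model
estimand. Defaults (7 studies, frequency 0.1, OR 8, τ = 0) mirror
the published ensemble's scale. `simulate_dose_studies()` samples
Gaussian doses around a nominal CC mean of 60 mg/m² with CV 0.3 —
the scale and spread of the published ALL cohorts — and a designed
carrier reduction of 0.28. `simulate_eqtl_panel()` plants one causal
variant among Hardy–Weinberg nulls. None of the generators model
linkage disequilibrium, genotyping error, dose titration dynamics or
covariate structure; a green recovery test therefore establishes
estimator correctness under the stated model, not robustness to those
real-data features. All generators are pure functions of their seed
(Mersenne-Twister) and restore the caller's RNG state.

## Numerical and design choices

- Continuity correction 0.5 per study with a zero cell;
  double-zero-margin studies excluded — required to approximate the
  published forest numbers.
- Heterogeneity for MH pooling computed with inverse-variance weights
  around the IV estimate (standard practice; the source prints only
  the I² formula).
- Median of per-study rates for an even study count is the mean of the
  two central order statistics (the published 7-study case is odd and
  unaffected).
- Report JSONs serialize at full precision; rounding to the published
  2 decimal places is display-only.
- Exact tie handling in Begg's τ-b (tie-corrected variance), verified
  against base R's Kendall correlation on untied data.

## Known limitations

Only summary-level data are handled — no per-patient dose
trajectories, no Hardy–Weinberg testing (none was published), no
Peto or REML/profile-likelihood τ² (DerSimonian–Laird was the era's
standard), no trim-and-fill, and no meta-regression. The dominant
model's published 9.48 remains unexplained by any data-entry or
correction convention consistent with the other printed results; we
report the computed 9.37 and flag the gap rather than fitting to it.
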