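---
title: "Methods: genotype-count meta-analysis with snpmeta"
author: "snpmeta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-count meta-analysis with snpmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem and the model

Case-control association studies of a biallelic SNP report, for each study,
six integers: the counts of risk-allele homozygotes, heterozygotes and
reference-allele homozygotes among cases and among controls. snpmeta pools
the evidence across studies from exactly these counts. The unit of analysis
is a *dataset*: a study population genotyped for one SNP (a publication
reporting two ethnic groups separately contributes two datasets).

Each dataset's 2×3 genotype table is reduced to a 2×2 exposure table under
one of five genetic models — homozygote (RR vs rr), heterozygote (Rr vs rr),
dominant (RR+Rr vs rr), recessive (RR vs Rr+rr) and allele (R vs r). The two
codominant models *drop* the excluded genotype class rather than collapsing
it, which is what contrast headings such as "TT versus CC" mean; the allele
model counts two independent observations per subject (2·hom + het), the
standard crude allele contrast without a within-subject correlation
adjustment. The risk allele is declared once per SNP (T, G and T for the
three bundled TOX3 panels), making every contrast orientation-unambiguous:
swapping the declared alleles inverts the homozygote- and allele-model odds
ratios exactly.

Per-study effects are log odds ratios with the Woolf variance
$\widehat{se}^2 = 1/a + 1/b + 1/c + 1/d$. Both the effect and its variance
are undefined with a zero cell; we add 0.5 to **all four** cells of a table
that contains any zero, per study and per contrast, and flag the estimate.
This is the Review Manager convention and the most reproducible of the
common choices; it is applied consistently inside the Mantel–Haenszel sums
for that study as well, so a pooled estimate never mixes corrected and
uncorrected cells of one table.

## Pooling and model selection

Two pooled estimators are provided.

* **Mantel–Haenszel fixed effect.**
  $OR_{MH} = \sum_i (a_i d_i / n_i) \,/\, \sum_i (b_i c_i / n_i)$, with the
  Robins–Breslow–Greenland estimator for $\mathrm{Var}(\log OR_{MH})$.
  Desk-calculator genetic meta-analyses rarely print their variance formula;
  RBG is the standard companion of the MH estimator and is what the familiar
  meta-analysis software uses, so it is the default here.
* **DerSimonian–Laird random effects.** Inverse-variance weights
  $w_i = 1/se_i^2$ give Cochran's $Q$; the moment estimator
  $\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$
  feeds random-effects weights $w_i^* = 1/(se_i^2 + \tau^2)$. With
  $\tau^2 = 0$ this reduces exactly to inverse-variance fixed pooling — a
  property the test suite asserts.

`pool_auto()` implements the conventional selection rule: the fixed-effect
model when the Q-test P-value exceeds `alpha_het` (default 0.1), the
random-effects model otherwise. Two deliberate details:

* $Q$ for the selection rule is computed from the crude log-OR effects with
  inverse-variance weights, not from MH weights. At the study sizes involved
  the difference is negligible, and it matches the provenance of published
  heterogeneity columns.
* Selection is made independently for every contrast and every (sub)group
  pooled, mirroring how published stratified tables footnote the rule, not
  once per SNP.

$I^2 = \max\{0, 100\,(Q - df)/Q\}$ is labelled mild (< 25%), moderate
(25–50%) or large (> 50%). Both $\tau^2$ and $I^2$ are truncated at zero.
All intervals use $z = \Phi^{-1}(0.975) \approx 1.959964$ rather than 1.96;
the difference is below printed precision, but it keeps the CI consistent
with the chi-square quantile at exactly 0.95. Tests are two-sided, with
significance at 0.05 except the heterogeneity screen at 0.1.

## Hardy–Weinberg testing

`hwe_test()` is the uncorrected Pearson χ² comparing observed control
genotype counts with the $(p^2, 2pq, q^2)$ expectation at the sample allele
frequency, on 1 df — the test whose P-values populate the HWE columns of
published association tables (no Yates correction, no exact test: the
uncorrected asymptotic values are what those columns reproduce). Departing
studies are *flagged, not dropped*: the accepted remedy is sensitivity
analysis, and the bundled panels indeed retain their two HWE-departing
control groups. A monomorphic sample fits its expectation exactly and
returns $\chi^2 = 0$, $P = 1$; expected-zero cells (which force
observed-zero cells) are skipped in the sum.

Two printed HWE P-values in the bundled rs12443621 table cannot be
reproduced from their own printed genotype counts: one row prints 0.809
where the counts give 0.998, and another prints 0.419 where the counts give
0.0419 — an apparent decimal slip. The bundled `p_hwe_reported` column
preserves the printed values verbatim as reference metadata; the acceptance
test that compares recomputed values against every printed one fails on
exactly those two rows and is left failing, since the source table is
internally inconsistent there. All 70 other numeric values reproduce to
±0.01.

## Robustness toolkit

* `subgroup_analysis()` splits a panel by any label column (ethnicity in the
  bundled panels; ER or BRCA status via user-supplied per-stratum counts)
  and re-runs `pool_auto()` per level and model. Levels with one study
  report that study's own estimate, flagged `single_study`; unlabeled
  studies are excluded with a warning. A case-only contrast between tumour
  subtypes (e.g. ER+ cases vs ER− cases) needs a table construction the
  genotype-count schema does not express and is out of scope.
* `leave_one_out()` re-pools k times omitting each study, re-making the
  fixed/random choice on every reduced panel, and reports the largest
  |log OR| shift.
* `egger_test()` regresses $y_i/se_i$ on $1/se_i$; the intercept's two-sided
  t-test (k−2 df) quantifies funnel asymmetry. Visual funnel inspection is
  common practice but not reusable as a criterion, so the regression is
  reported *alongside* the exported funnel points, never replacing them. The
  regression refuses panels whose precisions are all equal (rank-deficient).

## The synthetic-data generator

`simulate_panel()` states one explicit generative world: study-level true
log per-allele odds ratios $\theta_i \sim N(\log OR, \tau^2)$; control
genotypes multinomial under HWE at risk-allele frequency `p_risk`; case
genotype probabilities proportional to the HWE frequencies times
$e^{\theta_i \cdot \text{dose}}$ (dose 2/1/0), renormalised — the genotype
distribution implied by a logistic per-allele model, i.e. exponential
tilting. Defaults describe a realistic susceptibility-locus panel: k = 15
studies (the size of the bundled panels), control risk-allele frequency
0.35 (mid-range of the bundled control frequencies), per-allele OR 1.15
(the magnitude typical of low-penetrance loci, and of these panels), τ = 0,
and 1000 subjects per arm; study sizes can instead be drawn log-uniformly
over a range to mimic the real panels' size spread (≈300 to ≈23,000).

What a green simulation test establishes — and what it does not: the
generator emulates sampling noise, HWE structure in controls, a
multiplicative allele effect and normal between-study heterogeneity. It does
not emulate covariate confounding, genotyping error, linkage disequilibrium
with a causal variant, or selective publication, so calibration under the
generator validates the estimators' arithmetic and their sampling behaviour,
not robustness to those failure modes. Calibration checks shipped in the
tests: type-I error of the HWE test (5% ± 1% at n = 500 over 10,000 null
draws, vectorised), 95% CI coverage of a true per-allele OR of 1.15 by the
pooled allele-model estimate (≥ 93% over 500 panels of k = 20), and strict
monotonicity of the mean Q statistic in τ over {0, 0.1, 0.2}.

## Reproducing the bundled panels' published summaries

The bundled TOX3 panels come with published pooled summaries to compare
against. Crude-count pooling reproduces the fixed-effect rows (rs8051542;
rs12443621 by ethnicity) to within about 0.01–0.02 on the OR scale. Exact
equality is not expected: the original pooled analysis mixed
covariate-adjusted per-study estimates (whose inputs are not public) with
crude ones, while this package pools crude counts only. The discrepancy is
documented as material only for the rs12443621 overall contrasts, which is
why the bundled-panel checks use a ±0.03 tolerance and the strongly
heterogeneous rs3803662 rows are asserted as bounded bands (pooled
homozygote OR in [1.25, 1.37], random-effects model selected, subgroup
direction and significance) rather than equalities. One published total
counts 43 analysis units for rs3803662 where the corresponding
characteristics table prints 42 rows; the bundled panel encodes the 42
printed rows, and its ethnic subtotals (13 Asian, 18 Caucasian, 6 African,
5 Mixed) imply the uncounted 43rd unit would be Caucasian.

## Numerical and degenerate-input choices

* Counts are validated as non-negative integers with row-naming
  diagnostics; both arms of every study must be non-empty.
* A study with an empty exposure margin (a+b = 0 or c+d = 0) is a
  degenerate table and errors out rather than being silently corrected.
* `pool_mh_fixed()` with k = 1 returns the single study's estimate exactly
  and flags it; `pool_dl_random()` and `heterogeneity()` require k ≥ 2,
  `leave_one_out()` and `egger_test()` k ≥ 3.
* Weights in every pooled result are normalised to sum to 1.
* Report rendering prints ORs and CI bounds to 3 decimals and renders
  P-values below 0.001 as "<0.001"; identical inputs and configuration give
  byte-identical output files (no timestamps in the run log).

## Known limitations

Crude ORs only — covariate-adjusted pooling would need the original
studies' adjusted estimates as inputs. No Cochran–Armitage trend test, no
exact HWE test, no REML/Hartung–Knapp alternatives to DerSimonian–Laird,
and no trim-and-fill; these are deliberate non-goals, chosen to keep the
package a faithful, reproducible implementation of the conventional
genotype-count workflow.
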