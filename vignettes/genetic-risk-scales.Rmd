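---
title: "Building and evaluating genetic point scales in 1:1 matched case-control studies"
author: "grscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating genetic point scales in 1:1 matched case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscale)
```

## The problem

The no-reflow phenomenon — failure of myocardial tissue perfusion after the
infarct-related artery has been mechanically reopened — complicates roughly
15% of primary PCI procedures in STEMI and carries a substantially worse
prognosis. Clinical predictors capture thrombus burden and ischemic time but
say little about a patient's constitutional susceptibility, which motivates
screening germline SNPs in pathways plausibly involved (endothelial
function, renin-angiotensin-aldosterone system, coagulation, platelet
function, folate metabolism) and condensing the significant ones into a
simple bedside point score.

`grscale` implements that workflow for the matched design used in this
setting: 1:1 case-control pairs matched on sex and age (±5 years,
inclusive). The package covers genotype ingestion and carrier-model
encoding, Hardy-Weinberg testing, matched-pair association statistics, a
filter cascade with risk-genotype orientation, point-score construction,
threshold/ROC evaluation, conditional logistic regression fitted from the
conditional likelihood, the matched-design sample-size arithmetic, and a
synthetic cohort generator that makes every stage testable without patient
data.

## Statistical model and procedure

### Carrier encodings

Genotypes are stored as alternative-allele doses (0, 1, 2). Two binary
collapses are used, named in the code by what they test rather than by the
"dominant"/"recessive" labels sometimes attached to them, because that usage
differs from conventional genetic-model nomenclature:

* `alt_carrier` — carries at least one alternative allele (dose ≥ 1);
* `ref_carrier` — carries at least one reference allele (dose ≤ 1).

### Matched association

For a binary exposure the information in a 1:1 matched design sits in the
discordant pairs: $b$ pairs where only the case is exposed, $c$ where only
the control is. The default test is McNemar's chi-square with continuity
correction, $\chi^2 = (|b-c|-1)^2/(b+c)$ on 1 df; the uncorrected statistic
and the central exact binomial test are available as options. The
conditional maximum-likelihood odds ratio is $b/c$ with the log-scale Wald
interval $\exp(\log(b/c) \pm z\sqrt{1/b+1/c})$. These choices reproduce, at
printed precision, every p-value and confidence interval of the study whose
summary tables ship with the package (see `noreflow_counts()`).

Pairs with a missing genotype at the SNP under test are deleted pairwise
(`complete_pairs()`); genotype missingness in this design arises from
sample hemolysis and is treated as missing completely at random. No
genotype imputation is attempted.

### Hardy-Weinberg testing

`hwe_test()` is the plain Pearson 1-df chi-square against expectations
$n((1-q)^2,\,2q(1-q),\,q^2)$ at the observed allele frequency $q$, without
continuity correction and without an exact fallback; a warning is emitted
when any expected class count is below 5, and monomorphic SNPs return
$\chi^2 = 0$, $p = 1$ with a warning rather than failing.

### The filter cascade

`select_snps()` keeps a SNP when its McNemar p-value is below 0.05 in at
least one carrier model, then excludes it if any of the following evidence
is present: missing-genotype fraction above 5%; Hardy-Weinberg p ≤ 0.05 in
*either* group; total-sample alternative allele frequency below 5%. When
both models are significant the `alt_carrier` model is preferred. The HWE
rule is applied in both groups deliberately — the stricter, symmetric
reading — although applying it in the control group alone selects the same
scale on the shipped study counts. Filter quantities that cannot be
computed (NA) do not exclude: filters act on evidence, not on its absence.

Each surviving SNP is oriented toward risk (`orient_risk()`): the carrier
class with the higher proportion among cases becomes the predicate scoring
one point; exactly equal proportions are an error rather than an arbitrary
choice. Points are unweighted, exactly one per component; the score of a
patient with any missing component genotype is missing.

### Threshold metrics and ROC

A patient is test-positive when the score is at or above the threshold —
the convention that reproduces every published confusion-matrix row.
`threshold_metrics()` reports the confusion cells with sensitivity,
specificity, PPV, NPV ($tn/(tn+fn)$, NA when nobody tests negative) and the
F-score as the harmonic mean of PPV and sensitivity (F1).
`optimal_threshold()` maximizes the F-score, breaking ties toward the
higher (more specific) threshold. The ROC curve takes one point per
threshold plus the origin; the AUC is the trapezoidal integral, which
equals the tie-corrected Mann-Whitney statistic $U/(n_1 n_2)$ (a property
the test suite checks against an independent computation and against
pROC). The AUC interval is Hanley-McNeil's normal approximation with
$Q_1 = A/(2-A)$ and $Q_2 = 2A^2/(1+A)$, truncated to $[0,1]$; on the
shipped study distribution it reproduces the published 0.611–0.838 to three
decimals. Reported values are conventionally rounded to 2 decimals for
table metrics and 3 for the AUC.

### Conditional logistic regression

For 1:1 sets the conditional likelihood reduces to
$\sum_i \log \sigma(\beta^\top d_i)$ over within-pair covariate differences
$d_i$, with no intercept. `clogit_fit()` is written from this likelihood
directly (the established proportional-hazards fitter is used in the test
suite only, as an independent cross-check): Newton-Raphson from
$\beta = 0$, step-halving whenever a step would decrease the likelihood,
convergence at gradient max-norm below 1e-8, at most 25 iterations. The
variance is the inverse observed information at the optimum. Complete
separation — a likelihood that increases without bound, detected as
$\|\beta\| > 10$ with a non-vanishing gradient — is a hard error, never a
huge coefficient; singular information is likewise an error suggesting
covariate removal. On one binary covariate the fit equals the
discordant-pair odds ratio $b/c$ exactly, a closed form the tests exploit.
The scale enters as a linear numeric covariate, giving a per-point odds
ratio.

### Sample-size arithmetic

`discordant_pairs_required()` implements the normal-approximation
(Connor-type) formula: with detectable conditional odds ratio $\psi$, a
discordant pair is case-exposed with probability $p_1 = \psi/(1+\psi)$ and

$$n_d = \left\lceil \frac{\left(z_{1-\alpha/2}/2 +
z_{power}\sqrt{p_1(1-p_1)}\right)^2}{(p_1 - 1/2)^2} \right\rceil.$$

`pairs_required()` converts $n_d$ to total pairs by dividing by the
discordance probability under within-pair exposure independence,
$P_{disc} = p_{case}(1-p_0) + p_0(1-p_{case})$ with
$p_{case} = \psi p_0/(1+p_0(\psi-1))$. At $\alpha = 0.05$, power 0.80,
$\psi = 4$, $p_0 = 0.5$ this gives 20 discordant pairs, 40 pairs, 80
patients. The formula approximates the *uncorrected* chi-square statistic;
the suite validates it by simulation at the returned discordant-pair count,
where the delivered power sits within ±0.05 of the target. The
continuity-corrected test is conservative when the discordant count is
left random at the total-pair design (empirical power nearer 0.73 at 40
pairs) — a known property of the correction, worth remembering when
planning.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions so that every stage has
a realistic input: genotypes drawn independently per SNP at Hardy-Weinberg
proportions with allele frequencies back-calculated from the study's
total-sample carrier counts (`default_sim_panel()`); a logistic outcome
model whose defaults encode the three published risk genotypes at their
reported conditional odds ratios (2.83, 5.33, 4.00) over a baseline logit
of −2.5, putting the population case fraction in the range reported for
this phenotype; demography of 73% males and ages near Normal(65, 8)
truncated to 30–95; greedy outcome-conditional 1:1 matching on sex and age
(closest age first, deterministic given the seed); and per-SNP MCAR
missingness at the study's reported rates (0–9%). The source population
defaults to 12 times the requested pairs, a margin under which sex/age
matching does not exhaust.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs (all loci independent), genotype-confounder
correlation (sex and age are independent of genotype), missing-at-random
as opposed to MCAR missingness, and any X-linked hemizygosity — rs1403543
sits on the X chromosome but is simulated, as it was analyzed, as a
diploid autosomal marker. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated design, not robustness to
population structure, LD, or informative missingness in real cohorts.

## Numerical and design choices

* Genotype strings are `"X/Y"` pairs, order-insensitive, matched against
  the panel's ref/alt labels; off-panel alleles become missing with a
  counted warning. Allele labels are short strings, not single characters,
  so the PAI-1 4G/5G promoter labels fit.
* Age matching is inclusive: $|\Delta age| \le 5$.
* The case group is always the phenotype-present group.
* Zero discordant cells make the odds ratio undefined; an optional
  Haldane-Anscombe 0.5 correction is available behind an explicit flag and
  warning.
* The duplicated "Positive predictive value" column in the published
  threshold table is read as PPV then NPV; $tn/(tn+fn)$ reproduces the
  printed second column.
* Percentages printed in the study tables round half away from zero; the
  reconstruction helpers honour that convention.

### Reconstructing group-level data, and its limits

The study published carrier counts with percentages per group but no
patient-level data. `noreflow_group_genotypes()` inverts these printed
integers: the group denominator is inferred where both carrier rows admit
exactly one size consistent with their percentages, then genotype classes
follow by inclusion-exclusion. Two SNPs (rs4762, rs699) are internally
inconsistent — their two rows imply different denominators — and are left
unresolved rather than guessed.

This reconstruction reproduces the published control-group Hardy-Weinberg
deviations exactly (rs1403543, rs1799983, rs1801394). In the case group,
however, the forced reconstruction crosses $p = 0.05$ at rs5186
($p = 0.0499$) and rs6046 ($p = 0.024$) where the source reports no
deviation; no standard test variant (corrected, uncorrected, exact)
reconciles all published flags with the printed counts at once. The
package keeps the faithful computation and documents the discrepancy
instead of special-casing those SNPs. None of this affects the selected
scale: neither SNP passes the significance screen.

## Problem sizes used for validation

The simulation-based checks in the test suite use: 200 replicates of
300-pair cohorts for per-point log-odds-ratio recovery and Wald coverage
(observed |bias| < 0.1 on the log scale); 1000 replicates at $n = 200$ for
the Hardy-Weinberg test's type-I rate (0.05 ± 0.02); 2000 replicates for
the McNemar power check at the designed discordant-pair count; and 1000
replicates for MCAR pair-retention, which matches the $(1-r)^2$
expectation. Exact small-instance checks (grid-search maximization of the
conditional likelihood on ≤ 8 pairs) bound the optimizer to within 1e-3 of
the brute-force optimum.

## Known limitations

* Only 1:1 matched sets are supported; m:n matching, Breslow/Efron tie
  handling and robust variances are out of scope.
* The scale is unweighted by construction; regression-weighted or
  penalized scores are not provided.
* The multivariate adjusted estimates of the source study are not
  numerically reproducible because pair-level covariates were never
  published; the fitter capability is validated by simulation and
  closed-form equivalences instead.
* The exact HWE test is intentionally absent: the workflow specifies the
  Pearson chi-square, and mixing tests would change the filter cascade.
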