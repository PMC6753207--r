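---
title: "Two-sample Mendelian randomization with mrivw: models, choices, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrivw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrivw)
```

## The causal question and the instrumental-variable model

Mendelian randomization treats germline genetic variants as instrumental
variables for an exposure: because alleles are randomly allocated at
conception, variant–outcome associations are protected from the
confounding and reverse causation that plague observational contrasts.
The two-sample flavour needs only published summary statistics — variant
effects on the exposure estimated in one study population and variant
effects on the outcome estimated in another, non-overlapping one.

`mrivw` was written for liability-on-liability questions of the form
"does genetic liability to cancer alter the risk of Alzheimer's disease?",
where the exposure side is a set of cancer-susceptibility lead SNPs from
GWAS and the outcome side is a large case-control meta-analysis of
Alzheimer's disease. Everything is expressed in per-allele log odds, so a
causal effect $\theta$ reads "change in log odds of the outcome per 1-unit
higher log odds of the exposure", reported as an odds ratio
$e^{\theta}$.

Validity rests on the three instrumental-variable assumptions: each
variant is (1) associated with the exposure, (2) independent of
confounders of the exposure–outcome relationship, and (3) affects the
outcome only through the exposure. The selection and sensitivity machinery
below exists to enforce (1) and to probe violations of (3).

## Instrument selection

Three rules reduce a candidate table of exposure-associated variants to a
valid instrument set:

* **Significance.** Only variants with exposure association
  $p < 5\times10^{-8}$ (strict inequality; the conventional genome-wide
  threshold) are retained — assumption (1).
* **Independence.** Within one cancer type, greedy pruning visits
  variants in order of ascending p-value and discards any later variant
  with $r^2 \ge 0.2$ against an accepted lead SNP. Ties in p-value break
  lexicographically by rsID so the output never depends on input row
  order. Pruning is deliberately per-cancer: the same variant may
  legitimately instrument two cancers, and pooled groups keep such
  duplicates as distinct rows (a `dedupe` switch offers the alternative).
* **Proxy substitution.** An instrument absent from the outcome dataset
  is replaced by its highest-$r^2$ proxy with $r^2 > 0.9$ (strict) that
  *is* present, with effect/other alleles re-assigned through the
  target-to-proxy allele correspondence; exposure-side statistics are
  inherited from the target unchanged, since the proxy merely stands in
  for it in the outcome lookup. No transitive proxy-of-proxy search is
  attempted. Instruments with no qualifying proxy are dropped and
  reported.

The selection report partitions every input rsID into exactly one of
five groups (kept, dropped at significance, pruned, proxied, dropped
without proxy), which the test suite asserts as an invariant.

## Harmonization

Exposure and outcome records are joined on rsID and aligned to the
exposure's effect allele. A swapped allele pair negates the outcome beta
(and nothing else); an irreconcilable pair drops the variant with a
recorded reason. Palindromic variants (A/T, C/G) cannot be strand-checked
from alleles alone; because effect-allele frequencies are often absent
from instrument tables, no frequency-based strand inference is attempted.
They are retained with a warning by default — the analysis this package
systematizes applied no palindromic exclusion — and a `drop_palindromic`
switch provides the stricter option. Note that the IVW estimate itself is
invariant to which of a variant's two alleles is declared the effect
allele (both betas flip sign, the ratio is unchanged), so harmonization
matters for getting each *pair* of studies onto one orientation, not for
the orientation itself.

## Estimation

Per instrument, the Wald ratio and its first-order variance are

$$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}, \qquad
\mathrm{var}_j = \mathrm{se}(\hat\beta_{Yj})^2 / \hat\beta_{Xj}^2 .$$

First-order weights ignore the exposure-side sampling error (NOME — no
measurement error), defensible when instruments come from very large
exposure GWAS; the generator below can violate NOME on demand to show the
resulting attenuation towards the null. The pooled fixed-effect estimate
is the inverse-variance weighted mean of the ratios with
$\mathrm{se} = (\sum_j w_j)^{-1/2}$; p-values use the standard normal, the
fixed-effect meta-analysis convention. Confidence intervals exponentiate
$\hat\theta_{IVW} \pm 1.959964\,\mathrm{se}$ — the quantile is carried at
full precision rather than 1.96 so that 2-decimal published-table rounding
is reproduced exactly; all rounding happens in the reporting layer only.
A single-instrument exposure (one susceptibility locus) cannot support a
pooled estimate: per-cancer pooling skips it with a message and the
variant still contributes to aggregate groups.

## Sensitivity analyses

**MR-Egger.** Weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ *with* intercept, first-order weights, after re-orienting
every instrument to a non-negative exposure beta (flipping the outcome
beta in tandem). The orientation is the estimator's defining convention:
without it the sign of a direct (pleiotropic) effect is an artifact of
allele labelling and a nonzero mean is unidentifiable. The intercept
estimates the average direct effect; its test uses a Student t reference
with $J-2$ degrees of freedom and the estimated residual scale — exactly a
weighted `lm()` summary — rather than a normal reference, which matters at
the small instrument counts (11–38) typical of per-cancer groups.

**Cochran's Q.** $Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$
against $\chi^2_{J-1}$, with the same first-order weights as the
estimator. Under NOME with a shared true effect this reference is exact,
which the calibration tests exploit.

**Leave-one-out.** The pooled estimate is recomputed $J$ times omitting
each instrument; stability of sign and precision across omissions rules
out single-SNP dominance.

**Funnel data.** Per-SNP $\hat\theta_j$ against instrument strength
$1/\mathrm{se}(\hat\theta_j)$ with the pooled estimate as reference.
Asymmetry — equivalently a correlation between effect and strength — is a
pleiotropy warning sign. The package exports the table; rendering is left
to any plotting layer, and no analysis depends on plots.

## Bayesian false-discovery assessment

Each pooled result is translated, irrespective of significance, into a
posterior probability of being a false discovery at priors
$\pi_1 \in \{0.5, 0.1, 0.01, 0.001\}$ that the null is false. Two
constructions are provided:

* **BFDP** (default): Wakefield's approximate Bayes factor
  $BF = \sqrt{(V+W)/V}\,\exp\!\big(-\tfrac{z^2}{2}\tfrac{W}{V+W}\big)$
  with $V = \mathrm{se}^2$, $z = \hat\theta/\mathrm{se}$, and a zero-mean
  normal alternative with variance $W$; the posterior of the null is
  $BF\cdot PO/(BF\cdot PO + 1)$ with prior odds $PO = (1-\pi_1)/\pi_1$.
  The default $W = (\log 1.2 / 1.959964)^2$ places 95% of alternative
  effects within odds ratios 1/1.2–1.2, matching the modest per-unit
  effects plausible for liability-scale exposures; `alt_prior_variance()`
  re-derives $W$ from any other bound.
* **FPRP**: the frequentist-flavoured false-positive report probability
  $\alpha\pi_0 / (\alpha\pi_0 + \mathrm{power}\cdot\pi_1)$ with
  $\alpha$ set to the observed p-value and power computed at the observed
  estimate from two-sided normal tails.

BFDP is the default because, applied to pooled estimates with
GWAS-meta-analysis-scale standard errors, it reproduces the
false-discovery magnitudes published for this class of analysis, whereas
the observed-alpha FPRP with power at the observed effect is an order of
magnitude smaller for strongly significant results (its power term is
pinned near one half). Both satisfy the same monotonicity properties
(rising as the prior weakens; FPRP rising in $\alpha$ and falling in
power), which the test suite sweeps.

## The synthetic-data generator

`simulate_two_sample()` emulates exactly the data structure the estimator
assumes: per-variant true exposure effects
$\beta_{Xj} \sim N(0, 0.15^2)$ magnitude-floored at 0.01 (ratios need
nonzero denominators), observed exposure betas equal to the truth under
NOME (default) or noised with $\mathrm{se}_X = 0.015$, and outcome betas
$\theta\,\beta_{Xj} + \alpha_j + N(0, \mathrm{se}_Y^2)$ with
$\mathrm{se}_Y = 0.02$, the scale of a meta-analysis with tens of
thousands of cases and controls. Pleiotropic intercepts $\alpha_j$ are
none, balanced ($N(0, 0.02^2)$), or directional (nonzero mean), defined
in the exposure-increasing allele orientation and rotated into each
variant's reported orientation. Allele pairs are random A/C/G/T draws,
identically oriented in both studies by default, with a `flip_fraction`
option that swaps outcome orientations to exercise harmonization.
`simulate_ld_fixture()` supplies block-diagonal LD matrices and
self-consistent proxy tables; `paper_scale_scenarios()` bundles six
scenarios at the instrument counts of a published multi-cancer analysis
(18, 38, 109, 68, 246, 314) with protective true odds ratios (0.91–0.98).
The default documentation seed is 20190919.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: realistic LD (blocks are uniform, not
drawn from population panels), case-control sampling and binary-exposure
dichotomization, winner's-curse inflation of discovery betas, allele
frequencies (no strand inference is exercisable), sample overlap between
the two studies, and population stratification.

## Calibration results and problem sizes

The acceptance suite re-derives, by simulation at fixed seeds: exact
agreement (to $10^{-10}$, observed $\sim10^{-16}$) between the IVW
estimate and a weighted no-intercept regression slope on 200 random sets
of 5–50 instruments; absolute bias within 3 Monte-Carlo standard errors
and 95% CI coverage within $0.95 \pm 0.02$ over 1,000 replicates at
$J = 50$, $\theta = \log 0.95$; Egger intercept-test size within
$0.05 \pm 0.015$ over 5,000 balanced-pleiotropy replicates and mean
intercept recovery under directional pleiotropy of 0.05; Cochran's Q size
within $0.05 \pm 0.01$ over 5,000 homogeneous replicates (and $Q = 0$
exactly for identical ratios); and end-to-end recovery of each
paper-scale scenario's effect through the full file-based pipeline.
These replicate counts keep each property at 3–5 standard errors of
resolving power while the whole suite runs in about a minute. Independent
oracles in the unit tests include `lm()` for both the IVW and Egger fits
and `metafor`'s fixed-effect meta-analysis for the pooled estimate, its
standard error, p-value, and Q.

## Numerical and degenerate-input choices

Strict inequalities at both selection boundaries ($p < 5\times10^{-8}$,
proxy $r^2 > 0.9$) and a closed lower boundary for pruning
($r^2 \ge 0.2$ prunes); p-value ties in pruning broken by rsID;
proxy-candidate ties broken by rsID after $r^2$; duplicate outcome keys
rejected at read time; `MarkerName` treated as an opaque key (rsID or
`chromosome:position`); zero exposure betas rejected at the Wald-ratio
stage with the variant named; Bayes factors computed on the log scale;
pipeline outputs carry no timestamps so reruns are byte-identical.

## Limitations

The package implements the fixed-effect IVW estimator with first-order
weights only — no random-effects IVW, weighted-median/mode estimators,
multivariable MR, or outlier-removal schemes — and consumes LD and proxy
information as files rather than computing $r^2$ from genotype panels.
Under heterogeneity (which Cochran's Q is there to detect) the
fixed-effect standard error understates uncertainty; under NOME
violations the estimate attenuates towards the null, which bounds but
does not remove the bias. The BFDR's alternative-effect convention is a
modelling choice; results at weak priors are sensitive to it.
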