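---
title: "Multiple-mediator mediation of mQTL SNP effects: models and methods"
author: "mqtlmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-mediator mediation of mQTL SNP effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlmed)
```

## The scientific problem

Several SNPs reproducibly associated with bladder cancer risk are also
*cis*-acting methylation quantitative trait loci (mQTL): each risk allele
shifts DNA methylation at one or more nearby CpG sites. `mqtlmed` asks how
much of such a SNP's effect on disease is transmitted *through* those
methylation changes. Because one SNP shifts several CpG sites
simultaneously, the mediators must be modelled jointly: individual CpG
contributions may reinforce or cancel one another, and a per-CpG analysis
would miss that.

The decomposition is counterfactual: the **natural direct effect (NDE)**
is the effect of carrying an extra risk allele with methylation held at
the level it would naturally take at the reference genotype; the
**natural indirect effect (NIE)** is the effect of moving methylation to
the level induced by the extra allele while the allele count itself is
held fixed; the **total effect (TE)** combines both.

## The estimator

For subject-level data with exposure $A$ (risk-allele count 0/1/2), $K$
mediators $M^{(1)},\dots,M^{(K)}$ (methylation M-values, the base-2 logit
of the proportion methylated), covariates $c$ and case status $Y$, two
regression models are fit:

$$\operatorname{logit} P(Y=1\mid a,m,c) = \theta_0 + \theta_1 a +
  \sum_{i=1}^{K}\theta_2^{(i)} m^{(i)} + \theta_4' c$$

fit among **all** subjects (cases and controls), and per mediator

$$E[M^{(i)}\mid a,c] = \beta_0^{(i)} + \beta_1^{(i)} a +
  \beta_2^{(i)\prime} c$$

fit among **controls only**. Under a rare outcome the controls
approximate the source population, which is what licenses the
controls-only mediator fit and the interpretation of the logistic
coefficients from a case-control sample. The package treats this
approximation as inherent to the design: it is documented, not
"corrected". On the per-risk-allele contrast ($a = 1$ vs $a^* = 0$):

$$OR^{NDE} = e^{\theta_1},\qquad
  OR^{NIE} = \exp\Big(\sum_{i=1}^{K}\beta_1^{(i)}\theta_2^{(i)}\Big),\qquad
  OR^{TE} = OR^{NDE}\cdot OR^{NIE}.$$

The product form of the NIE is what lets mediators cancel: a CpG that
gains methylation with the risk allele but is protective contributes a
negative term. For plug-in point estimates the TE identity is exact
(`runMediation` computes it that way); percentile-bootstrap interval
endpoints need not satisfy it, which is why the result object stores all
three intervals separately.

### NIE percent

Two conventions for "share of the total effect that is indirect" are
computed and always reported side by side:

* `or_ratio`: $100 \cdot OR^{NIE}/OR^{TE}$ (equivalently $100/OR^{NDE}$),
  the ratio-of-ORs definition. This is the package default.
* `proportion_mediated`: $100 \cdot OR^{NDE}(OR^{NIE}-1)/(OR^{NDE}
  OR^{NIE}-1)$, the excess-odds proportion, undefined when $OR^{TE}=1$
  (returned as `NA`).

The two can differ materially, and neither is uniformly standard in the
literature, which is exactly why both appear in every result row rather
than the package guessing for the user.

### Exposure-mediator interaction (K = 1)

For a single mediator the outcome model can include $\theta_3\, a\,m$.
Under a rare outcome and a normal mediator with residual variance
$\sigma^2$ the closed forms are

$$OR^{NDE} = \exp\{(\theta_1+\theta_3(\beta_0+\beta_1 a^* + \beta_2'c +
  \theta_2\sigma^2))(a-a^*) + \tfrac12\theta_3^2\sigma^2(a^2-a^{*2})\}$$
$$OR^{NIE} = \exp\{(\theta_2\beta_1+\theta_3\beta_1 a)(a-a^*)\},\qquad
  OR^{CDE}(m) = \exp\{(\theta_1+\theta_3 m)(a-a^*)\}.$$

With $\theta_3=0$ these reduce *exactly* to the no-interaction
estimators (a pinned test asserts this at $10^{-10}$). The covariate
profile $c$ defaults to the control-sample means of the encoded design
columns (`controlProfile()`): the estimand is conditional on $c$, no
single choice is canonical, and control means are the natural "typical
unexposed subject" under the rare-disease view. The profile is an
explicit argument for users who want a different reference.

## Inference

Confidence intervals are percentile bootstrap. Each of $B$ resamples
(default $B = 1000$) refits the outcome model on the resample and the
mediator models on its controls and recomputes all three log odds
ratios. Choices that pin down the numbers exactly:

* **Stratified resampling** (default): cases and controls are resampled
  separately, preserving the fixed case/control margin of the design.
  Unstratified resampling is available by flag.
* **Single RNG stream, documented draw order**: all resample index
  vectors are drawn up front from one stream seeded by the config seed
  (per resample: case indices, then control indices), so identical seed
  and inputs give bit-identical intervals.
* **Quantile definition**: the inclusive linear-interpolation quantile
  (`stats::quantile` type 7), fixed for reproducibility. Intervals are
  formed on the log-OR scale and exponentiated; percentile intervals are
  equivariant under monotone maps up to the interpolation between order
  statistics, so this is presentational.
* **Failed resamples** (non-convergence, separation, rank deficiency)
  are dropped and counted, never retried — retrying would bias the
  resampling distribution. More than 10% dropped is a hard inference
  error: at that point the model is too fragile for the data and a
  narrower covariate set or larger sample is needed, and the run log
  records the count per SNP.

## Numerical choices and degenerate inputs

* Logistic fitting is maximum likelihood (IRLS) with convergence
  tolerance $10^{-8}$ and at most 100 iterations. Separation is detected
  by divergence (an effect-formula coefficient beyond 30 in absolute
  value) and raised as an explicit error; no penalization is applied,
  because a reproducible failure is preferable to silent shrinkage.
* Rank deficiency or divergence in the columns whose coefficients enter
  the effect formulas (intercept, exposure, mediators, interaction) is a
  hard error, as are constant exposure, cohorts without both cases and
  controls, and missing values; the package is complete-case by design,
  with missingness handled up front by the ordered exclusion rules (a
  subject hit by several rules is attributed to the first — the counts
  then always reconcile). Aliased *nuisance* covariate columns are
  instead pivoted out with an `NA` coefficient, exactly as `lm`/`glm`
  do — in stratified resamples a rare covariate level can lose its only
  control, and erroring there would reject a third of the resamples for
  a coefficient the effects never use.
* Mediator residual variance uses the unbiased denominator
  $n - p - 2$ for a full-rank design with $p$ covariate columns (plus
  exposure and intercept), generalized to $n - \mathrm{rank}$ when a
  nuisance column is aliased.
* Beta-values are clamped to $[10^{-6}, 1-10^{-6}]$ before the base-2
  logit (normalized array data can contain exact 0/1); values outside
  $[0,1]$ are a domain error. `betaToMvalue`/`mvalueToBeta` invert each
  other to below $10^{-12}$.
* Hardy-Weinberg QC uses the 1-df chi-square goodness-of-fit test with
  expected counts from the observed allele frequency; the exact test
  would also have been defensible, but the chi-square is the
  conventional array-QC gate and is invariant to allele relabelling.
  Monomorphic input is flagged rather than tested. The call-rate gate is
  strict (rate $>$ 0.99 by default): 99 of 100 calls fails.
* Covariate encoding is schema-driven: declared level sets with the
  first level as reference (reference for race/ethnicity is the largest
  group), enrollment years 1994--1995, 1996, 1997, 1998 coded 1--4 as a
  single continuous column, and a fixed column order — so estimates are
  invariant to the column order of the raw input, and unseen levels fail
  loudly instead of silently extending the design.
* Table output rounds through `sprintf("%.2f")`, i.e. the nearest
  representable binary value is rounded ("1.005" stored slightly below
  1.005 prints "1.00"); a pinned test documents this.

## The synthetic cohort generator

`simTruth`/`simulateCaseControl` generate a nested case-control study
with the structure the estimator assumes, plus the generating parameters
as an oracle:

1. genotypes Binomial(2, RAF) — Hardy-Weinberg;
2. covariates from study-like control marginals: smoking never/former/
   current at 0.55/0.41/0.04, pack-years structurally zero for never
   smokers and log-normal (meanlog 2.85, sdlog 1 — median about 17
   pack-years, roughly 29% above 30) otherwise, age uniform within
   50--59/60--69/70--79 bands at 0.24/0.48/0.28, enrollment year,
   trial arm, race/ethnicity and extraction method from categorical
   marginals, follow-up uniform on 1--15 years; all overridable;
3. mediators linear in the allele count on the M-value scale with
   independent Gaussian residuals (default sd 0.5 M-units, a typical
   mid-methylation array dispersion);
4. disease from the logistic model, with the intercept tuned by
   bisection so the population prevalence hits its target (default 0.01,
   within 10% relative tolerance, at most 60 iterations; bracket
   $[-40, 10]$ on the log-odds scale);
5. cases and controls sampled without replacement (default 412/424, the
   nested case-control design size), from a population sized at 1.3
   times the count implied by the prevalence — enough that exhausting
   the cases is a rare, explicit error.

Covariate effects default to a smoking-driven disease gradient (current
vs never log-OR $\log 4$, former $\log 1.5$, 0.01 per pack-year) and to
**zero** effects of covariates on the mediators: no reference effect
sizes exist for the latter, and zero keeps the closed-form oracle exact
under the rare-outcome regime while remaining configurable.

`simTruthFromMqtl` converts the packaged per-CpG homozygote beta-scale
differences into per-allele M-value effects at a chosen baseline
(splitting the homozygote difference additively across the two allele
steps — an approximation, since the source effect sizes are differences
of *medians* of proportions) and scales $\theta_2$ proportionally to
$\beta_1$ so the true log NIE takes a requested value exactly.
`simulateStudy` builds one multi-SNP population (independent SNPs, each
acting through its own CpGs) and writes the four input tables the reader
consumes, which is what the demo config exercises end to end.

Two oracles cross-check each other: `closedFormTruth` plugs the
generating coefficients into the effect formulas, and
`mcCounterfactualTruth` evaluates the counterfactual contrast by direct
simulation — common residuals across exposure levels, averaging disease
*probabilities* rather than drawing outcomes, so the evaluator is
deterministic given its seed and precise enough for a 2% agreement
check.

### What passing the simulation studies does and does not show

The generator reproduces the *statistical* structure the estimator
relies on: HWE genotypes, linear mQTL effects on the M scale, a rare
logistic outcome, case-control sampling. It deliberately omits array
batch effects, probe-level noise, cell-type composition (itself a
potential mediator, hence excluded from adjustment), correlated CpG
residuals (available via configuration but off by default), matched-pair
sampling (matching covariates are simulated, but no explicit pairing),
and linkage disequilibrium between SNPs. Calibration on these cohorts
therefore validates the estimator and its implementation — not
robustness to those real-data complications.

## Calibration study sizes

The packaged checks use: 200 replicates at 1000/1000 cases/controls for
null calibration of the NIE (no SNP-to-methylation path; median
estimated $OR^{NIE}$ within [0.98, 1.02]); 200 replicates at 2000/2000
for recovery of a true log NIE of 0.10 spread over five mediators with
fixture-scale effect sizes (mean within $\pm 0.02$); 200 replicates at
the study size 412/424 with $B = 200$ for bootstrap coverage (95%
intervals covering truth 90--99% of the time); and a Monte-Carlo
population of 500,000 at prevalence 0.005 for the oracle cross-check
(2% relative agreement). These sizes give Monte-Carlo error comfortably
inside each tolerance band.

## Known limitations

* All effect formulas are rare-outcome approximations; above roughly 5%
  prevalence the odds-ratio decomposition degrades and the truth
  constructor refuses to go there.
* Mediator-mediator causal paths, exposure-covariate interactions and
  exact (non-rare) mediation formulas are out of scope.
* The multi-mediator interaction model is not identified by this
  regression system; interaction support is single-mediator only.
* Bootstrap resampling treats subjects as exchangeable within
  case/control strata; the matched-set structure of the original design
  is not resampled as pairs.
* Effect sizes imported from an mQTL reference are median-of-proportion
  differences; emulating them as mean shifts is an approximation stated
  rather than resolved.
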