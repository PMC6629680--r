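---
title: "Statistical methods behind ipmnomics"
author: "ipmnomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind ipmnomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ipmnomics` re-implements, as a tested and reusable pipeline, the
integrated statistical analysis of targeted metabolomic and lipidomic
concentration tables measured in pancreatic cyst fluid and plasma from a
pancreas-resection cohort (serous cystic neoplasms and IPMNs at three
grades of severity).  The pipeline covers: lognormal preprocessing with
left-censored imputation, a Bayesian hierarchical mixed model for
confounder adjustment and fold-change estimation, CPPLS-DA
classification with VIP-based recursive feature elimination, and
exploratory PCA / Ward clustering / Pearson marker screening.  Raw
patient data are not publicly deposited, so a synthetic cohort
generator reproduces the structure of the study's data and supplies
ground truth for every test.

# Preprocessing

Concentrations in µmol/L are assumed lognormal and analyzed on the
natural-log scale.  Natural log (not log10) is used because fold
changes are defined as $e^{\eta_{gj}-\eta_{hj}}$, which only reads as a
natural-scale ratio if the model lives on the natural-log scale.

**Modified 80 % rule.**  A molecule is dropped only when its missing
fraction exceeds 0.8 in *every* clinical group; the comparison is
strict, so a molecule at exactly 0.8 everywhere is retained.  The rule
is missingness-only and is unaffected by whether it is applied before
or after the log transform.

**QRILC-style imputation.**  Missing values in these platforms are
left-censored (below detection).  Per molecule, the mean and sd of the
complete log-scale distribution are estimated by regressing the
observed order statistics on standard-normal quantiles: if a fraction
$\pi$ is missing, the $i$-th of $n_{obs}$ observed order statistics is
assigned the overall plotting position $\pi + (1-\pi)(i-0.5)/n_{obs}$.
Intercept and slope of the regression estimate mean and sd, robust to
the left truncation.  Missing entries are then drawn from that normal
truncated *above* at the molecule's minimum observed value, so imputed
values are always strictly below everything observed for the molecule.
There is no printed limit of detection, so the per-molecule minimum
stands in for it.  Imputed draws are assigned to cells in sample-ID
order, which makes the result equivariant under column permutations.

# The hierarchical model

Each log concentration is modeled as
$$y_{gij} \mid \mu_{gij}, \sigma \sim N(\mu_{gij}, \sigma^2), \qquad
\mu_{gij} = \theta + \varphi_i + \lambda_j + \eta_{gj}
  + \gamma_{1j}\,\mathrm{age}_i + \gamma_{2j}\,\mathrm{bmi}_i$$
with a grand mean $\theta \sim t(3,0,10)$, sample effects
$\varphi_i \sim N(0,\alpha^2)$, molecule effects
$\lambda_j \sim N(0,\beta^2)$, group-by-molecule effects
$\eta_{gj} \sim N(0,\zeta_g^2)$, covariate-by-molecule effects
$\gamma_{vj} \sim N(0,\omega_v^2)$, and half-$t(3,0,10)$ priors on all
scales.  Coefficients sharing a discrete category are constrained to
sum to zero ($\sum_i \varphi_i = 0$, $\sum_j \lambda_j = 0$,
$\sum_g \eta_{gj} = 0$ per molecule $j$), which identifies the model.
Continuous covariates are mean-centered and sd-scaled before fitting
(keeps $\theta$ interpretable and the sampler well conditioned; results
are reported on the scaled-covariate scale with centering constants
stored in the fit).

## Constraint semantics

The source model states the constraint but not its measure-theoretic
form.  We read the constrained priors as the Gaussian *conditioned* on
the zero-sum hyperplane.  This is the only well-posed reading: the
alternative — multiplying the unconstrained densities and restricting
support (the common hard-constraint idiom) — leaves the joint improper
in the $\zeta$ direction, because integrating the restricted Gaussian
over the hyperplane produces a factor $(\sum_g \zeta_g^2)^{-1/2}$ per
molecule whose accumulation makes the $\zeta$-marginal divergent at the
origin for $m \ge k$.

Conditioning has two practical consequences.  First, a Gaussian block
with independent components conditioned on a zero sum is sampled
exactly by drawing unconstrained and projecting with weights equal to
the component variances; for $\varphi$ and $\lambda$ (equal
conditional variances with complete data) this reduces to subtracting
the mean.  Second, the conditional density of $\zeta_g^2 = u$ is
$$p(u \mid \cdot) \propto u^{-(\nu+m)/2-1}\,(u + C)^{m/2}\,
  e^{-(\nu/a + SS_g/2)/u},$$
with $C$ the sum of the other groups' squared scales — not inverse
gamma.  It is sampled exactly with a stepping-out slice sampler on
$\log u$.

## The sampler

No probabilistic-programming backend is available in the target
environment, so the model is fit with a bespoke blocked Gibbs sampler;
every full conditional is exact:

* $t$ and half-$t$ priors enter through their inverse-gamma
  scale-mixture representations (a half-$t_\nu(0,A)$ on a scale is
  equivalent to $\sigma^2 \mid a \sim \mathrm{IG}(\nu/2, \nu/a)$,
  $a \sim \mathrm{IG}(1/2, 1/A^2)$), making $\theta$, $\sigma^2$,
  $\alpha^2$, $\beta^2$, $\omega_v^2$ conjugate.  The zero-sum
  constraints remove one degree of freedom from the $\alpha$ and
  $\beta$ updates (shapes use $n-1$ and $m-1$).
* effect blocks are drawn from their exact constrained conditionals
  (variance-weighted projection);
* $\zeta_g^2$ uses the slice step above.

Four chains with over-dispersed initializations run by default; 20 000
retained draws match the posterior sample size of the source analysis.
Split R-hat is computed for the grand mean, all scales and every
$\eta_{gj}$; any value above 1.05 raises a convergence warning that is
also stored on the fit object.  Sum-to-zero constraints hold to
machine precision in every retained draw and are asserted in the test
suite.  The test suite also runs a reduced simulation-based
calibration: parameters drawn from the priors, data simulated forward,
and the ranks of the truths among thinned posterior draws checked for
uniformity — this is the strongest available end-to-end check that the
sampler targets exactly the declared model.

## What is (not) identifiable

A covariate effect that is *constant across molecules* lies exactly in
the span of the sample effects: if $\gamma_{1j} \equiv c$ then
$c\,\mathrm{age}_i$ is a per-sample shift, indistinguishable from
$\varphi_i$ (both are centered).  The posterior resolves the ridge by
prior preference and in practice drains a constant covariate effect
into $\varphi$.  Only the molecule-*varying* part of $\gamma_{\cdot j}$
is identified — which is also the only part that matters for
confounder adjustment, because a constant effect is removed by the
per-molecule standardization anyway.  Recovery tests therefore use
molecule-varying, mean-zero covariate truths.

## Fold changes and adjustment

The fold change of molecule $j$ between groups $g$ and $h$ is
$e^{\eta_{gj}-\eta_{hj}}$, computed within each posterior draw and
summarized by the posterior median (robust under exponentiation; the
source does not name its point summary) and the equal-tailed 95 %
interval.  A molecule is flagged significant when the interval
excludes 1.  Because the group scales $\zeta_g$ are shared across
molecules, fold changes are partially pooled: in a cohort where only a
few molecules carry effects, those effects are shrunk toward 1.  This
is a property of the model, not of the sampler, and the recovery tests
simulate forward from the model (background group effects drawn with
scale 0.25, a moderate realistic value chosen once) so that shrinkage
in the test world matches shrinkage in the model's own world.

Confounder adjustment subtracts the posterior-mean covariate
contributions (plug-in, not per-draw — downstream classification needs
a single adjusted matrix) and then standardizes each molecule to mean
zero and unit variance.  All visualization, clustering, PCA and
classification operate on this adjusted matrix.

## Covariate selection

Candidate covariate sets are scored by expected log pointwise
predictive density, estimated by Pareto-smoothed importance-sampling
leave-one-out (PSIS-LOO) over all $n \times m$ observations; WAIC is
available as an option (the source's citation does not pin down which
of the two was used; PSIS-LOO is the default here).  The PSIS
machinery (empirical-Bayes generalized-Pareto tail fit, smoothed tail
weights, regularized $\hat k$ diagnostics) is implemented from the
published algorithm and was cross-checked against an independent
implementation during development.  Selection needs relative, not
absolute, precision, so candidate fits default to reduced draws.

# CPPLS-DA

Canonical powered partial least squares forms, per component, candidate
loading weights that blend each molecule's standard deviation $S_j$ and
its correlations $C_{jq}$ with the (dummy-coded, centered) class
responses:
$$w_{jq}(p) \;\propto\; \mathrm{sign}(C_{jq})\,
  \left(\tfrac{|C_{jq}|}{\max|C|}\right)^{p/(1-p)}
  \left(\tfrac{S_j}{\max S}\right)^{(1-p)/p},$$
with the power $p$ chosen from a grid (default
$\{0.05, 0.10, \dots, 0.95\}$; the source never prints its grid) to
maximize the first canonical correlation between $X W(p)$ and the
response space; the canonical coefficient vector collapses the
candidate matrix to a single unit-norm weight vector.  At $p = 0.5$
both exponents equal one and the weights reduce to the ordinary PLS2
weights $X^\top Y$ up to the canonical combination — this anchor is
verified against an independently implemented NIPALS PLS in the
acceptance suite.  Components are extracted sequentially with standard
deflation; scores are mutually orthogonal by construction.

Classification uses linear discriminant analysis on the component
scores (the conventional companion of the reference implementation;
the source names only "CPPLS-DA"), with LDA class posteriors as the
continuous scores for ROC analysis.

**VIP.**  Variable importance in projection uses the standard
multi-component form
$\mathrm{VIP}_j = \sqrt{m \sum_a SS_a\, w_{ja}^2 / \sum_a SS_a}$ with
$SS_a$ the dummy-response variance explained by component $a$; the
normalization makes the mean squared VIP exactly one.

**Performance.**  Leave-one-out cross-validation refits the model $n$
times; held-out class labels and posteriors aggregate into one-vs-rest
sensitivity, specificity, balanced accuracy
($(\mathrm{sens}+\mathrm{spec})/2$, exact arithmetic) and AUC (the
Mann–Whitney statistic, ties counting one half).  Multi-class
reporting is one-vs-rest, mirroring the published table's rows.  A
training fold that loses an entire class falls back to the
majority-class rule with a logged warning.

**Recursive elimination.**  Each step records LOO-CV performance, fits
on all samples, ranks by VIP and drops
$\max(1, \lfloor 0.05\,m \rfloor)$ lowest-VIP molecules (VIP ties at
the boundary drop alphabetically-last IDs — determinism).  The loop
stops when fewer than $n_{comp}+1$ molecules would remain (the
source's "until the number of molecules allowed model identifiability"
is not quantified; this is the weakest count that keeps the component
extraction well-posed).  The number of components is selected once
before elimination by maximizing LOO-CV balanced accuracy over
$1..\min(8, n-2)$, and held fixed so the elimination trace is not
confounded by a changing model size.  The feature set with the highest
mean one-vs-rest balanced accuracy is selected, ties broken toward
fewer molecules.  As in the source, adjustment happens once before
cross-validation; the selection loop is single-level LOO, so reported
accuracies carry the usual optimism of non-nested selection — noted,
not "fixed", because replicating the published procedure is the point.

# Exploratory analyses

PCA is the SVD of the centered adjusted matrix; explained-variance
fractions are non-increasing, and each component is sign-fixed so its
largest-magnitude loading is positive.  Heatmap ordering uses
agglomerative clustering with Ward's method on Euclidean distances in
both dimensions.  The marker screen computes Pearson correlations of
every molecule against CA19-9, albumin and bilirubin, adjusts p-values
by Benjamini–Hochberg across the whole molecule-by-marker grid (the
source says only "adjusted"), and flags hits with $|r| > 0.6$ and
adjusted $p \le 0.05$ — the absolute value matters because negative
correlations are reported findings.  Correlations are computed on the
adjusted log-scale data by default, with the raw scale available.

# The synthetic cohort generator

The generator runs the hierarchical model forward: group sizes default
to the published cyst-fluid cohort (5/8/7/11 across SCN, LGD, HGD,
Cancer); ages and BMIs are drawn uniformly within each group's
published min–max (only ranges are printed); CA19-9 and bilirubin are
drawn log-uniformly within their ranges because they span orders of
magnitude; sex, statin use and diabetes are Bernoulli draws at the
printed frequencies.  The grand mean defaults to 1.0 on the
log-µmol/L scale (no molecule-level concentration table is printed);
sample-effect and molecule-effect scales default to 0.3 and 1.0 —
molecules legitimately span orders of magnitude, samples do not.
Class labels (TAG-dominated lipid classes plus amino/organic acid
blocks) are assigned in blocks so class-level fold-change summaries
are exercisable.

Missingness is left-censored by construction: per molecule, only the
lowest $q_{cens}$ fraction of values is eligible, each removed with a
logistic probability in its distance to the censoring threshold
(hard threshold at infinite steepness, removing exactly
$\lfloor q_{cens} n \rfloor$ values).  The default $q_{cens} = 0.1$ is
a free parameter — per-molecule missingness rates are not published.

What the generator does *not* emulate: instrument drift and batch
effects, correlated molecule panels (molecules are conditionally
independent given the effects), non-Gaussian tails, informative
missingness above the censoring threshold, and any mechanistic link
between clinical markers and concentrations.  A green test on
synthetic data therefore establishes correctness of the statistical
machinery under the model's own assumptions, not robustness to the
violations real instruments produce.

# Numerical choices and degenerate inputs

* Imputation requires at least 3 observed values per molecule;
  regression slopes that collapse (massive ties) fall back to the
  observed sd.
* `fit_hier_model` refuses incomplete or non-finite input; empty
  groups and unknown covariates are validation errors.
* CPPLS powers are restricted to the open interval (0, 1); degenerate
  (zero-variance) molecules get zero weight; an exhausted deflated
  matrix raises an error rather than emitting spurious components.
* AUC with an empty class is `NA`, never silently 0.
* All randomness flows from user seeds; pipeline stages derive their
  seeds deterministically from the root seed, so identical configs
  give byte-identical outputs.

# Known limitations

* The Gibbs sampler is exact for the declared model but, unlike
  gradient-based samplers, mixes by blocks; heavy-tailed hyperparameter
  posteriors (nearly unidentified group scales in effect-free cohorts)
  mix slowly and are flagged by R-hat rather than hidden.
* Plug-in (posterior-mean) adjustment understates adjustment
  uncertainty downstream, by design, to mirror the published workflow.
* Single-loop LOO with in-loop feature selection is optimistic; a
  nested CV is out of scope because the goal is replication of the
  published procedure.
* The performance numbers of the original study cannot be reproduced
  without the patient data; the package reproduces the table's internal
  arithmetic exactly and validates everything else by property-based
  testing on synthetic cohorts.
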