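---
title: "Measuring latrine use as a latent class: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring latrine use as a latent class: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latuse)
```

## Why a latent class?

Asking people whether they defecate in a latrine invites socially
desirable answers; in populations where latrine ownership is normative,
almost everyone says yes. `latuse` instead treats *consistent latrine
use* as an unobserved (latent) class and measures it through a battery of
psychosocial indicators — descriptive norms ("most men in my village use
a latrine in the dry season"), attitudes to sharing, convenience and
safety — each answered *agree*, *disagree* or *don't know*. "Don't know"
is a substantive answer, not nonresponse: someone who does not know
whether their neighbours use a latrine is telling you something about
their relationship to the behaviour, and in the reference model it is the
modal answer of the inconsistent-use class on two indicators. True item
nonresponse is a separate missing code.

## The measurement model

With classes $k = 1, \dots, K$, prevalences $\pi_k$, and conditional
response probabilities $\rho_{jkc}$ for category $c$ of indicator $j$,
the observed-data likelihood is

$$L = \prod_i \sum_k \pi_k \prod_{j \in \mathrm{obs}(i)} \rho_{j,k,y_{ij}},$$

a finite mixture of independent multinomials. Missing items are simply
skipped — full-information maximum likelihood under a
missing-at-random assumption — so partially answered questionnaires
still contribute. `fit_lca()` maximizes $L$ by EM.

Numerical choices:

* **Restarts and stopping.** Defaults are 50 random restarts
  (Dirichlet(1) rows for $\rho$, uniform-simplex $\pi$), an absolute
  log-likelihood tolerance of $10^{-8}$, and at most 5000 iterations; the
  best converged restart wins, and all restart log-likelihoods are kept
  so multimodality is visible. An error is raised if no restart
  converges.
* **Floors and boundaries.** $\rho$ is floored at $10^{-10}$ inside
  E-step logarithms to avoid $-\infty$; reported estimates may still
  reach 0 or 1 exactly. The floor can cost the likelihood a sub-$10^{-7}$
  wiggle near boundary optima, so the monotonicity guard only treats a
  material decrease as failure.
* **Label order.** Classes are always relabeled by descending
  prevalence, so class 1 is the largest class — in the reference model,
  the consistent-use class (its modal profile agrees with the published
  consistent-user pattern). All label-dependent outputs (pruning,
  pseudo-class outcomes) rely on this convention.
* **Patterns, not rows.** The E and M steps run on distinct response
  patterns with counts, so cost scales with the number of patterns
  ($\le 3^J$, and $\le N$), which is what makes the 25,100-person
  recovery simulations cheap.

Standard errors work in an unconstrained parameterization (a softmax for
$\pi$, one per indicator-class row for $\rho$, with boundary categories
excluded). The observed-data score and Hessian are analytic (a
Louis-type identity), so the default observed-information covariance is
exact and fast even with 16 indicators (about 65 free parameters); a
numeric-differentiation cross-check is part of the test suite. The
`sandwich` method aggregates scores within households with a
$G/(G-1)$ factor; with singleton clusters it degenerates to plain
heteroskedasticity-robust. Boundary estimates are reported with SE 0 and
a boundary flag — matching the convention of printing 1.00 (0.00).

## Choosing and pruning the model

`compare_class_solutions()` fits each candidate $K$ and applies, in
order: lowest BIC ($-2\ell + p\log N$, $p = (K-1) + K\sum_j(C_j-1)$);
for near-ties (BIC within 2) an interpretability guard rejecting any
solution with an expected class size below `min_class_n = 10`, because a
class of a handful of people cannot be carried into structural modelling;
and a relative-entropy floor of 0.80. Relative entropy,
$E = 1 - \sum_i\sum_k(-\tau_{ik}\ln\tau_{ik}) / (N \ln K)$, is 1 for a
one-class model by convention.

The Pearson statistic compares observed complete-pattern counts with
mixture-implied expectations, plus one aggregate cell for the expected
mass of never-observed patterns. With $3^J$ cells and a few hundred
respondents the asymptotic $\chi^2$ reference is meaningless, so the
p-value comes from a parametric bootstrap (simulate complete responders
from the fit, refit with a warm start, recompute; default 200
replicates). Patterns are built on complete responders only; FIML still
uses everyone for estimation. Model selection is not gated on this
p-value by default — it is a diagnostic.

`prune_uninformative()` implements the indicator-selection rule: build
Wald 95% intervals $\hat\rho \pm z_{0.975}\,\mathrm{SE}$, truncated to
$[0,1]$, for every (indicator, class, category); an indicator is retained
iff at least one category's intervals are disjoint across the two
classes. A boundary estimate has a degenerate point interval, so it is
disjoint from any interval excluding that point — without this, the
strongest indicators (those with a conditional probability of 1.00) could
never be judged. Verdicts are computed in a single pass over the
full-indicator fit and followed by one refit on the survivors; the rule
as printed is pairwise, so the function requires $K = 2$. The choice of
category-wise Wald intervals with an any-category-disjoint rule is a
design decision: the published description does not say which category or
interval type was used, and point ± SE reporting suggests Wald.

`polychoric_correlation()` (two-step: thresholds from inverse-normal
cumulative marginals, then likelihood maximization of the bivariate
normal correlation over $(-0.999, 0.999)$) supports the usual
pre-modelling diagnostic of inter-indicator association.

## From classes to regression: pseudo-class pooling

A modal class assignment pretends classification is certain.
`draw_pseudo_classes()` instead imputes membership $M = 5$ times by
inverting a uniform draw through each individual's posterior
$\tau_{ik}$. Each imputation's membership (class 1 = consistent use = 1)
is regressed on basic sanitation access — basic versus anything less,
following the sanitation-ladder definitions — by maximum-likelihood
logistic regression, unadjusted and adjusted for education (four levels,
referent less than primary), Afro-Ecuadorian ethnicity, gender (female,
referent male), cement walls, and non-asset-deprivation, with
household-clustered sandwich standard errors ($G/(G-1)$). Gender enters
as a covariate only; an interaction flag exists but is off by default,
since samples of this size cannot support effect-modification claims.
Missing covariates are handled complete-case per regression with dropped
counts recorded — covariate missingness in the emulated population is
at most about 3%.

`pool_rubin()` combines the $M$ fits: $\bar Q$, within-variance
$\bar W$, between-variance $B$, total $T = \bar W + (1 + 1/M)B$, and
Barnard–Rubin degrees of freedom (which behave sensibly when $B = 0$ or
$M$ is small); odds-ratio intervals use the $t$ quantile on the log-odds
scale. Methods narrating this workflow sometimes describe the outcome as
"the predicted probability of latrine use"; the implementation here
follows the imputed-membership reading — each imputation's outcome is a
hard 0/1 membership — which is what makes Rubin's rules applicable.

## The synthetic generator and the reconstruction

No individual-level data accompany the reference study, so the package
carries a generative model reconstructed from its printed tables.
For each of the five informative indicators we know the marginal
category proportions $m_{jc}$, one modal conditional probability per
class, and $\pi = (0.78, 0.22)$. The mixture constraints
$m_{jc} = \sum_k \pi_k \rho_{jkc}$ plus per-class sum-to-one constraints
then determine the remaining cells: exactly, when the two printed values
concern different categories; up to one degree of freedom otherwise, in
which case the minimum-norm least-squares completion is used, with
negative cells (an artifact of two-decimal rounding) pinned to zero and
re-solved, and rows renormalized. Marginal rows are normalized first
(two of the printed rows sum to 0.99 or 1.01). A printed 1.00 pins its
whole class row to a point mass. The largest implied-marginal residual
is about 0.015 — on the indicator whose printed row sums to 1.01 and
whose class-1 value sits at the boundary — so residuals are reported and
tested at 0.02 rather than the 0.01 one might hope for from exact tables.

`generate_survey()` then emulates the study design: 98 households by
default, sizes from a zero-truncated Poisson calibrated to 2.56 eligible
members per household (about 251 individuals), covariates drawn from the
published background-characteristics marginals (including their missing
fractions), ages from a shifted exponential matching the reported median
23 and SD 14, and indicators from $\rho$ given each individual's class.

Two generator parameters deserve comment:

* **Within-household concordance** (default 0.3) is the pairwise
  correlation of class membership between household members. It is
  implemented by letting each individual inherit a household-level class
  draw with probability $\sqrt{0.3}$, which preserves the marginal
  prevalence exactly and makes the parameter directly interpretable as
  the within-cluster outcome correlation that clustered standard errors
  exist to absorb. The reference analysis clusters by household but
  publishes no concordance value; 0.3 is a moderate value typical of
  household-level health behaviours, and it is configurable.
* **The structural exposure effect** (default 0) is a log odds ratio of
  basic sanitation on class membership, with the intercept re-solved so
  the marginal prevalence stays 0.78. Zero reproduces the published null
  finding; nonzero values support power and recovery studies.

The eleven pruned indicators, when requested, are generated as
class-independent noise at their published marginals — their true
conditionals were never printed, and class-independence is exactly the
configuration the pruning rule should reject.

## What the synthetic checks do and do not show

Parametric replicates from the reconstruction verify *internal*
correctness: prevalence and conditional probabilities are recovered to
two decimals from a large sample; pruning removes noise indicators in
well over 90% of study-scale replicates; pooled intervals for a null
exposure effect cover 1 at nominal rate under household clustering; EM
attains grid-search maxima on tiny instances.

They do not certify behaviour on real data, and one number makes the gap
concrete: the reconstruction's relative entropy. Fitted to its own
parametric replicates at $N = 251$ the model yields entropy around
0.93–0.94 (its exact population value is 0.935), while the published
value on the original data is 0.86. The difference is structural. A
printed boundary conditional (1.00) makes any non-modal answer on that
indicator decisive, and simulated data satisfy conditional independence
by construction, whereas the real responses misfit the model (its own
Pearson statistic, 395 on $3^5$ cells, says so); real misfitting
response patterns produce intermediate posteriors that pull empirical
entropy down. Real item nonresponse — present in the original analysis,
at an unpublished rate — flattens posteriors further. So the package
reports the replicate entropy honestly rather than matching the printed
value, and users applying the method to real surveys should expect
entropy (and every other diagnostic) to reflect their data's misfit, not
the generator's optimism.

Problem sizes used throughout the tests and the acceptance script — one
sample of 25,100 for recovery, 100 replicates of 251 for entropy and
pruning, 200 null studies for coverage — were chosen as the smallest
sizes at which Monte-Carlo error is clearly below the tolerances being
checked.

## Known limitations

* The measurement model assumes conditional independence of indicators
  given class; local dependence (likely in real norm batteries) is not
  modelled, only diagnosed via the bootstrap goodness of fit and the
  polychoric matrix.
* Covariates cannot enter the measurement model (no latent-class
  regression); measurement and structural steps are deliberately
  separate, as in the reference workflow.
* The pruning rule is defined for two classes only, and one pass; it is
  not a backward-elimination search.
* No survey weights or multi-wave designs: the target design is a single
  cross-section.
* The three-class branch of the comparison is supported for fitting, but
  the structural stage is binary-outcome only — the multinomial variant
  was rejected in the reference analysis and is out of scope.
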