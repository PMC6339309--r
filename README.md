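# latuse

Latent-class measurement of latrine use, with pseudo-class pooled
inference against household sanitation access.

## The problem

Whether people actually use a latrine is hard to measure: direct
self-report of defecation behaviour is distorted by social desirability,
and there is no gold-standard instrument. One way around this is to treat
*consistent latrine use* as a latent class: administer a battery of
psychosocial indicator questions (descriptive norms, convenience, safety,
attitudes to sharing — each answered *agree* / *disagree* / *don't
know*), model the answers with a latent class analysis (LCA), and then
ask whether membership in the consistent-use class is associated with
having a basic (private, improved) sanitation facility at home. The
motivating setting is a cross-sectional survey of adults and adolescents
(about 251 individuals in 98 households) in rural Esmeraldas, Ecuador.

`latuse` implements that workflow end to end for epidemiologists and WASH
(water, sanitation and hygiene) researchers:

1. **Measurement.** A finite mixture of independent multinomials fitted
   by EM. For individual *i* with responses *y<sub>ij</sub>* the
   observed-data likelihood is

   L = prod_i sum_k pi_k prod_{j in obs(i)} rho_{j,k,y_ij}

   where *pi<sub>k</sub>* are class prevalences and
   *rho<sub>jkc</sub>* the class-conditional response probabilities.
   Individuals with missing items contribute only their observed items
   (full-information maximum likelihood). Standard errors come from the
   analytic observed-data Hessian, or from a household-clustered sandwich.
2. **Model selection and pruning.** BIC, a parametric-bootstrap Pearson
   goodness of fit (the 3^J contingency table is far too sparse for the
   asymptotic chi-square), relative entropy
   E = 1 − Σ(−τ ln τ)/(N ln K), and the confidence-interval-overlap rule:
   an indicator is uninformative when its class-conditional CIs overlap
   between classes for every response category.
3. **Structural inference.** Class membership is imputed M times from
   each individual's posterior (pseudo-class draws); each imputation's
   membership is regressed on basic sanitation access with
   household-clustered standard errors; estimates are pooled by Rubin's
   rules with Barnard–Rubin degrees of freedom.
4. **Synthetic data.** The full three-category generative model of the
   published final two-class solution is reconstructed from its printed
   marginals and modal conditional probabilities via the mixture
   constraints, so simulations, power checks and all package tests run
   against a known truth.

## Worked example

```r
library(latuse)

# a study-scale synthetic survey (16 indicators, 98 households)
sim    <- generate_survey(latrine_use_model(include_noise = TRUE),
                          n_households = 98, seed = 42)
survey <- dplyr::select(sim, -.true_class, -basic_sanitation)

compare_class_solutions(survey, k_values = c(2, 3), n_starts = 20, seed = 1)
#>       k loglik n_params   bic      x2  rel_entropy min_expected_n ...
#> 1     2 -2235.       65 4833. 302261.        0.922           53.7
#> 2     3 -2214.       98 4974. 337431.        0.928           13.4
#> selected K = 2 (lowest BIC)

fit <- fit_lca(survey, k = 2, n_starts = 20, seed = 1)
prune_uninformative(fit, survey, seed = 2)
#> <lca_prune: 6 retained, 10 removed (95% Wald CIs)>
#> retained: men_dry_season, neighbors_rainy, children_rainy,
#>           household_crowding, neighbors_latrine, cabin_too_small
```

The two-class solution wins on BIC, and the CI-overlap rule recovers the
five informative indicators (plus, in this replicate, one false-positive
noise indicator — at N ≈ 251 that happens in a minority of runs). The
pruned refit keeps entropy above 0.9, and the pooled structural model:

```r
res <- run_structural_pipeline(survey, prune_uninformative(fit, survey, seed = 2)$refit,
                               m = 5, seed = 3)
res$adjusted
#> <pooled_result: M = 5 imputations, 256 obs, 95 clusters>
#>   basic_sanitation             OR  0.53  (0.24-1.19)
#>   ...
```

The exposure interval covers 1: with the generator's default null
structural effect, access to basic sanitation tells you nothing about
membership in the consistent-use class — the pattern the method is
designed to detect (or fail to detect) honestly, because classification
uncertainty is propagated into the interval instead of being ignored.

`tidy()`, `glance()` and `augment()` methods expose every fitted object
as a tibble, and `autoplot()` draws item-profile, model-comparison and
forest plots.

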