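---
title: "Propensity-score adjusted high-dimensional mediation: models, choices and limits"
author: "psmediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-score adjusted high-dimensional mediation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmediation)
```

## The problem

Observational epigenome studies routinely ask whether a binary exposure
$X$ (say, smoking) affects a continuous outcome $Y$ (say, lung function)
*through* one or more of $p \gg n$ candidate mediators
$M_1, \dots, M_p$ (say, genome-wide DNA-methylation values). The working
structural model is linear in both stages:

$$
M_{ik} = c_k + \alpha_k X_i + \Theta' Z_i + e_{ik}, \qquad
Y_i = c + \gamma X_i + \beta' M_i + \Phi' Z_i + \xi_i,
$$

where $Z$ collects $w$ baseline confounders, $\gamma$ is the direct
effect and $\alpha_k \beta_k$ is the indirect (mediation) effect through
$M_k$. Without randomized exposure, $Z$ distorts all three arrows
($X{\to}M$, $X{\to}Y$, $M{\to}Y$), so the selection-and-testing pipeline
must adjust for it at every stage.

The package implements four adjustment strategies around one common
four-stage pipeline:

1. **Propensity stage.** Logistic regression of $X$ on $Z$ yields the
   score $S_i = P(X_i = 1 \mid Z_i)$ and inverse-probability weights
   $w_i = X_i / S_i + (1 - X_i)/(1 - S_i)$.
2. **Screening stage.** Sure independence screening keeps the
   $d = \lceil 2n / \ln n \rceil$ mediators (capped at $p$) with the
   largest absolute marginal coefficient in the outcome model. The three
   propensity methods (PSR, PSW, PSU) screen with the score as a
   covariate, $Y \sim 1 + X + M_k + S$; COV screens with
   $Y \sim 1 + X + M_k + Z$.
3. **Selection stage.** Minimax-concave-penalty (MCP) least squares over
   the screened mediators, with $X$ (plus $S$ for PSR, $Z$ for COV)
   unpenalized, solved by coordinate descent along a decreasing
   $\lambda$ path and tuned by BIC. The support
   $C = \{k : \hat\beta_k \ne 0\}$ is the candidate set.
4. **Testing stage.** For each $k \in C$: $\hat\alpha_k$ from the
   method's exposure-mediator model, $\hat\beta_k$ from the selected MCP
   fit with oracle-property standard errors from the unpenalized
   post-selection refit, two-sided normal p-values on both paths,
   Benjamini-Hochberg adjustment over $C$, and the joint-significance
   rule $P_k = \max(P^{BH}_{\alpha_k}, P^{BH}_{\beta_k}) \le 0.05$.

The methods differ only in where the confounder adjustment enters:

| method | screening | MCP objective | $\hat\alpha_k$ model |
|---|---|---|---|
| PSR | $S$ covariate | $+\,\hat k S$ unpenalized | $M_k \sim 1 + X + S$ |
| PSW | $S$ covariate | unadjusted | weighted $M_k \sim 1 + X$ |
| PSU | $S$ covariate | unadjusted | $M_k \sim 1 + X + S$ |
| COV | $Z$ covariates | $+\,Z$ unpenalized | $M_k \sim 1 + X + Z$ |

PSW and PSU share the entire mediator-outcome pathway — identical
screened sets, MCP supports and $\beta$ p-values on the same data — and
differ only on the exposure-mediator side. This structural identity is a
deliberate design commitment (it is what makes the hybrid PSU "PSW's
outcome side plus PSR's mediator side") and is asserted by the test
suite.

### Why the PS methods screen with the score as a covariate

The marginal two-step weighted estimator — weighted least squares of
$Y \sim 1 + X + M_k$ to get $\hat\gamma_{k,w}$, the residual
$e_k = Y - \hat\gamma_{k,w} X$, then unweighted $e_k \sim 1 + M_k$ — is
implemented and exported (`marginalBetaTwoStep()`,
`screenMediators(estimator = "twoStep")`). It is not the default
PSW/PSU screening rule, for a structural reason worth spelling out:
weighting balances $Z$ across exposure groups, but it does not remove
the $M_k \leftarrow Z \rightarrow Y$ path from the *marginal*
mediator-outcome regression. Under the study design every mediator
carries the same confounder signal $\Theta'Z$, so all two-step marginal
coefficients share a large common offset, and at $p = 10{,}000$ the
screening tail consists of null mediators whose chance alignment with
the confounder factor is extreme. Those survivors then also carry a
selection-biased exposure coefficient, which the downstream joint test
cannot fully police: in our replications the false-positive rate
inflates several-fold. Conditioning the screening model on $S$ makes the
screening criterion consistent with the later $\alpha$-adjustment
(both condition on the same score), and the resulting operating
characteristics — selection counts, power, false positives and FDR —
reproduce the reference behavior of all three PS methods across every
study cell. The two-step rule remains available for comparison.

## Tunable parameters

* `dOverride` — screening dimension. Default
  $\lceil 2n/\ln n \rceil$ (106 at $n = 300$, 161 at $n = 500$),
  capped at $p$. The $O(n/\log n)$ order is the standard sure-screening
  scale: large enough that losing a true mediator is rare, small enough
  that the penalized stage is well conditioned.
* `delta` — MCP concavity (default 3, the conventional choice). The
  penalty is $\lambda(|b| - b^2/(2\delta\lambda))$ below the knee
  $|b| = \delta\lambda$ and constant $\delta\lambda^2/2$ beyond it; the
  saturation constant is the unique value making the penalty continuous.
  As $\delta \to \infty$ the solution path approaches the lasso's.
* `nlambda` — 50 log-spaced values from $\lambda_{max}$ (smallest
  $\lambda$ with an empty mediator support) down to
  $0.01\,\lambda_{max}$, solved with warm starts.
* `ic` — `"BIC"` (default) or `"AIC"`:
  $n\ln(\mathrm{RSS}/n) + \mathrm{df} \cdot \ln n$ (or $+\,2\,\mathrm{df}$),
  df counting the support plus the unpenalized terms.
* `level` — joint-test significance level, default 0.05.
* `clipScores` — optional clipping of $S$ to $[0.01, 0.99]$ before
  weighting; off by default, matching the plain inverse-probability
  formula. Near-degenerate scores are a real hazard in small or highly
  separable samples; the fitter refuses outright separation.
* `bhUniverse` — multiplicity universe of the BH correction; the
  default `"support"` corrects over the tested candidate set $C$ on
  both paths. `"screened"` treats all $d$ screened mediators as the
  hypothesis family (untested ones at $p = 1$); it is markedly more
  conservative and is provided because the choice is a genuinely open
  design question for this pipeline.

## Numerical choices

The coordinate-descent solver works on centered columns scaled to unit
quadratic mean, where the exact coordinate update is the firm threshold;
it uses Gram-matrix (covariance) updates, so one coordinate visit is
$O(1)$ with an $O(q)$ update only when a coefficient moves. Convergence
is declared when the largest coefficient change in a sweep falls below
$10^{-7}$ (at most $10^4$ sweeps per $\lambda$; non-convergence is an
error, not a warning). The penalized objective is non-increasing across
sweeps — a property the suite verifies — and on 2-mediator fixtures the
solution is checked against an exhaustive objective grid. Coefficients
are reported on the original mediator scale. Degenerate inputs are
handled explicitly: constant mediator columns are flagged and excluded
from ranking, constant adjustment columns are dropped with a warning,
rank-deficient refit designs and non-positive weights are errors, and
ties in the screening ranking break by ascending mediator index.

The reported $\hat\beta_k$ is the *penalized* MCP coefficient while its
standard error comes from the post-selection least-squares refit. The
alternative (reporting the refit coefficient) is tempting but does not
reproduce the documented behavior of these estimators at high dimension:
conditional-on-selection means of $\hat\alpha_k \hat\beta_k$ show mild
shrinkage for the strongest mediators (e.g. COV's systematic
under-estimation of a 0.96 effect to roughly 0.77-0.80 at
$p = 10{,}000$), which only the penalized estimate exhibits.

## The synthetic-data generator

`generateDataset()` draws, in a fixed order from one seed: ten
confounders (five independent Bernoulli(0.3), five standard normals with
exchangeable correlation 0.3), the exposure from the logistic model with
coefficients $(0.1, 0.3, 0.4, 0.4, 0.6, 0.1, 0.3, 0.4, 0.4, 0.6)$ and
intercept 0 (the intercept is a package choice — it yields treated
fractions around 60-65%, a realistic observational regime), per-mediator
intercepts $c_k \sim U(0, 2)$, mediator noise with SD 1.2 and outcome
noise with SD 1 (noise magnitudes are interpreted as standard
deviations, the convention of the surrounding software ecosystem), with
$\gamma = c = 0.5$. Three effect-size modes share the base vector
$t = (0.50, 0.60, 0.75, 0.80, 1.00, 1.20, 1.50, 2.00)$; mode 1 sets
$\alpha = 0.6t$, $\beta = 0.4t$ on the first eight mediators, plus two
outcome-only decoys ($\beta = 0.8$, $\alpha = 0$) and two exposure-only
decoys ($\alpha = 1.2$, $\beta = 0$). Everything beyond position 12 is
null, so exactly eight mediators carry a true indirect effect. All
confounder effects $\Theta$ are shared across mediators — a deliberately
harsh regime in which every null mediator is genuinely correlated with
the outcome through $Z$.

What the generator does *not* emulate about real methylation data:
bounded beta-values, probe-wise heteroscedasticity, correlated mediator
residuals (here $e_k$ are independent), batch structure, and missing
values. Passing the replication study therefore demonstrates correct
behavior of the statistical pipeline under its stated model, not
robustness to array artifacts.

A replication study (`runStudy()`) runs replicate $r$ with seed
$\mathrm{offset} + r$, so results are independent of the worker count,
and summarizes: MCP selection counts and joint-test power per true
mediator, mean false positives per replicate, mean per-replicate false
discovery proportion (0/0 counted as 0 — a convention; the alternative
of conditioning on a non-empty discovery set would inflate the average),
and conditional-on-selection effect estimates with their mean squared
error and empirical SE (both reported, since "MSE" is often used loosely
for either).

## Worked example

```{r example, eval = FALSE}
ds <- generateDataset(simulationConfig(n = 300, p = 1000, mode = 1, seed = 1))
res <- runMediation(ds, method = "PSU")
res
resultsTable(res)[, c("mediator", "alpha", "beta", "effect", "p_joint")]
```

## Problem sizes used by the checks

The packaged acceptance script replays the mode-1 study at 500
replicates for the $p = 1000$ cells ($n = 300$ and $n = 500$) and 200
replicates for the $p = 10{,}000$ cell; the in-suite acceptance tests
use 200 and 120 replicates respectively, with tolerances widened to
three Monte-Carlo standard errors of the smaller runs. These sizes keep
a full run on one CPU in the minutes range while leaving the
Monte-Carlo error well inside the tolerance bands.

## Known limitations

* Binary or survival outcomes, continuous exposures, and correlated
  mediator noise are out of scope.
* The joint-significance test is conservative for weak effects; no
  bootstrap or bias-corrected intervals are provided.
* No propensity-score matching or stratification; no iterated or
  conditional screening.
* The weakest designed mediator (indirect effect 0.06) is genuinely
  hard: even at $n = 500$ it survives screening in only about 80% of
  replicates, so its power ceiling is set by screening, not testing.
* The percent-of-total-effect column uses
  $100\,\hat\alpha_k\hat\beta_k / (\hat\gamma + \sum_{j \in C}
  \hat\alpha_j\hat\beta_j)$; other denominators are defensible and give
  different magnitudes, though the same signs.
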