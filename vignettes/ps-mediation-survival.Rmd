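---
title: "Propensity-score-adjusted high-dimensional mediation analysis for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-score-adjusted high-dimensional mediation analysis for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(himasurv)
```

## The problem

In epigenome-wide observational studies one often asks whether an exposure
(say, smoking) affects a survival outcome (overall survival of lung-cancer
patients) *through* molecular intermediates such as DNA methylation. Two
features make this hard. First, the candidate mediators number in the
hundreds of thousands while samples number in the hundreds, so the
mediator-outcome model cannot be fit jointly without screening and sparse
selection. Second, exposure is not randomised: baseline characteristics
(age, sex, treatment) confound the exposure-mediator, mediator-outcome and
exposure-outcome relations, and ignoring them biases both mediator
selection and effect estimates.

`himasurv` implements a four-step procedure for this setting. Writing
$T_i$ for the observed time, $\delta_i$ for the event indicator, $X_i$ for
a binary exposure, $M_{1i},\dots,M_{pi}$ for the candidate mediators and
$Z_i$ for measured confounders, the working models are a proportional
hazards model and a linear mediator model,

$$\lambda_i(t) = \lambda_0(t)\,
  \exp\{\gamma^* X_i + \beta^\top M_i + \tilde\varphi\, \pi_i\},
  \qquad
  M_{ki} = c_k + \alpha_k X_i + \tilde\phi_k\, \pi_i + e_{ki},$$

where $\pi_i = \Pr(X_i = 1 \mid Z_i)$ is the propensity score, estimated
by logistic regression and entered as a *single* adjustment covariate
(either $\pi_i$ or its logit). The mediated (indirect) effect of mediator
$k$ on the log-hazard scale is the product $\alpha_k \beta_k$; mediator
$k$ is a genuine mediator when $\alpha_k \beta_k \neq 0$.

## The four steps

**Step 0 — propensity adjustment.** `fit_propensity()` fits
$\text{logit}\,\Pr(X=1) = \theta_0 + \theta^\top Z$ by Newton-scored
maximum likelihood (an intercept is always included when fitting, whatever
the generating model). The fitted scores satisfy the score equation
$\sum_i \pi_i = \sum_i X_i$. Both the score and its logit are supported as
the downstream covariate; the logit form is what the replicated benchmark
study uses. Near-separation (any $|\hat\theta_0 + \hat\theta^\top Z_i| >
30$) triggers a warning and scores are clipped away from 0 and 1 rather
than silently diverging.

**Step 1 — sure independence screening.** With $p \gg n$ the mediators
are first reduced to the $d = \lceil 2n/\log n \rceil$ (natural log) with
the smallest marginal-association p-values. The factor 2 rather than 1
reflects that a mediator must survive on *both* paths to be selected
downstream. The default ranking is the outcome path: the Wald p-value of
$M_k$ in the Cox model with covariates $(X, \pi, M_k)$ — the marginal
model mirrors the structure of the full outcome model. An exposure-path
mode (p-value of $\alpha_k$ in $M_k \sim X + \pi$) is provided because in
methylation applications the exposure-mediator association is often the
stronger signal, and a union mode interleaves both rankings. Marginal
fits that fail to converge are recorded with p-value 1, never dropped.
Ties break to the lower mediator index, so screening is deterministic
and invariant to column order.

**Step 2 — MCP-penalized Cox selection.** Over the screened set the
package maximizes the penalized log partial likelihood
$l_n(Q) - \sum_{k} P_\lambda(\beta_k)$, with exposure and the adjustment
covariate(s) unpenalized and $P_\lambda$ the minimax concave penalty with
shape $a$ ($P_\lambda(t) = \lambda|t| - t^2/2a$ for $|t| \le a\lambda$,
constant beyond). MCP leaves large coefficients essentially unpenalized,
so selected effects are nearly unbiased — important here because the
selected $\hat\beta_k$ feed the indirect-effect estimates. $S_2$ is the
set of mediators with nonzero coefficients at the chosen $\lambda$.

**Step 3 — inference.** For each $k \in S_2$: $\hat\alpha_k$ comes from
OLS of $M_k$ on (intercept, $X$, adjustment), and $\hat\beta_k$ from one
unpenalized Cox refit on $(X, \text{adjustment}, M_{S_2})$, with standard
errors from the inverse observed information. Two tests of
$H_0: \alpha_k\beta_k = 0$ are computed: the Sobel test, using the
first-order delta-method standard error
$\hat\sigma_{\alpha\beta} = (\hat\beta^2\hat\sigma_\alpha^2 +
\hat\alpha^2\hat\sigma_\beta^2)^{1/2}$ with a two-sided normal p-value,
and the joint-significance test, whose p-value is the maximum of the two
normal path p-values. Raw p-values are Bonferroni-corrected by the factor
$|S_2|$ (the post-selection candidate count — not $p$, not $d$) and
capped at 1; a mediator is declared at adjusted $p < 0.05$ by default.
Indirect effects are also reported as hazard ratios
$\exp(\hat\alpha_k\hat\beta_k)$ with Wald intervals on the log scale
using the Sobel standard error. The total effect comes from a Cox fit of
the outcome on exposure and adjustment only.

Three comparison modes run the identical pipeline with different
adjustment: `ps` (the propensity covariate), `z` (all confounder columns
— the regression-adjustment comparator), and `naive` (no adjustment
anywhere — quantifies what confounding does).

## A small worked example

```{r example}
cfg <- sim_config(n_subjects = 300, n_mediators = 400, seed = 7)
ds <- generate_dataset(cfg)
ds
res <- run_pipeline(ds, pipeline_config(mode = "ps",
                                        covariate_form = "logit"))
res
res$records[, c("id", "alpha", "beta", "indirect", "p_sobel", "p_joint")]
```

Mediators 1–4 are the true mediators by construction; 7 and 8 predict the
outcome but are unaffected by exposure, so they enter $S_2$ and are then
correctly dismissed by both tests (their $\hat\alpha$ path is null).

## What the synthetic-data generator emulates

`generate_dataset()` reproduces the benchmark design used throughout the
package's tests: ten confounders (five Bernoulli(0.3), five equicorrelated
standard normals with pairwise correlation 0.3); exposure Bernoulli with
$\text{logit}^{-1}(\theta^\top Z)$ and $\theta = (0.2, 0.3, 0.3, 0.5,
0.6, 0.2, 0.3, 0.3, 0.5, 0.6)$ — no intercept; mediators $M_{ki} = c_k +
\alpha_k X_i + \phi^\top Z_i + e_{ki}$ with $c_k \sim U(0,1)$,
$e_{ki}\sim N(0,1)$ and one shared confounder loading $\phi$, which gives
every pair of mediators a correlation near 0.52 (as in methylation
arrays, where probes co-vary strongly); $\alpha = (0.5, 0.6, 0.5, 0.6,
0.5, 0.5, 0, 0, \dots)$ and $\beta = (0.6, 0.6, 0.5, 0.5, 0, 0, 0.5,
0.5, \dots)$, so exactly mediators 1–4 carry indirect effects with
products $(0.30, 0.36, 0.25, 0.30)$, mediators 5–6 are exposure-only and
7–8 outcome-only decoys; survival exponential with hazard $0.5\,
\exp(0.5 X + \beta^\top M + \varphi^\top Z)$ inverted analytically
($D = -\log U / \text{rate}$, exact for a constant baseline hazard); and
censoring $C \sim U(0, c_0)$.

The generator does *not* emulate several features of real methylation
data: beta-value boundedness on $[0,1]$, probe-specific variances,
batch/cell-type structure, non-proportional hazards, or informative
censoring. Passing tests therefore demonstrate correctness of the
procedure under its working model, not robustness to those violations.

### Censoring calibration

$c_0$ is found by root-finding: given a pilot draw of death times $D$,
the censoring fraction $\Pr(C < D) = E[\min(D, c_0)]/c_0$ is available in
closed form conditional on the pilot, is continuous and strictly
decreasing in $c_0$, and is solved with `uniroot()`. The pilot size
defaults to 100,000: calibration runs once per study, and a smaller pilot
(say 20,000) leaves enough Monte-Carlo error in the calibration itself
(~±0.005) to breach the ±0.01 accuracy the package promises for the
generated censoring rate.

### Seeds

`generate_dataset()` consumes `cfg$seed` and restores the caller's RNG
state; `run_simulation_study()` spawns one substream seed per replication
(plus one for calibration) from its master seed, so studies are
reproducible and independent of scheduling.

## Numerical design of the solvers

*Cox machinery.* Subjects are sorted by time once; risk sets are suffixes
and all quantities are accumulated in a single backward pass with Breslow
handling of ties (the simulated times are continuous, but real data tie).
The suffix accumulations use a streaming log-sum-exp rescaling (sums kept
on the scale of the running risk-set maximum of $\eta$), so the partial
likelihood stays finite for per-subject $|\eta|$ up to about 700.
Unpenalized fits use Newton-Raphson with step halving to a relative
log-likelihood tolerance of $10^{-9}$; marginal screening fits warm-start
from the adjustment-only model.

*MCP path.* The solver works per $\lambda$ on a descending log-spaced
grid of 50 values from $\lambda_{\max}$ (the smallest $\lambda$ with all
penalized coefficients zero, from the null-model score) down to
$0.05\,\lambda_{\max}$, warm-starting each point from the previous one.
Penalized columns are standardized internally (coefficients reported on
the original scale); the MCP threshold is scale-sensitive, so this keeps
a single $\lambda$ meaningful across columns. Each $\lambda$ is solved in
two phases: (1) iteratively reweighted least squares on the
diagonal-$\eta$-Hessian surrogate with cyclic coordinate descent and the
MCP firm-thresholding update, run to a loose tolerance with active-set
sweeps — this identifies the support. Because the diagonal surrogate
drops the negative risk-set cross terms it overestimates curvature, and
unit IRLS steps crawl; when an outer step leaves the active set
unchanged, the step is expanded by doubling while the true penalized
objective improves (a monotone safeguard). (2) The solution is polished
by exact Newton on the smooth penalized objective restricted to the
active set with signs fixed, then verified against the KKT conditions of
the zero coefficients ($|n^{-1}\partial l_n/\partial\beta_k| \le
\lambda$); violations re-enter phase 1. Final accuracy is a maximum
coefficient change below $10^{-7}$; at $\lambda = 0$ the solution matches
the unpenalized Newton fit within $10^{-5}$ in tests. Where the local
convexity condition of the coordinate update fails ($v_j \le 1/a$), the
update falls back to the soft threshold and the fit is flagged.

*Choice of $\lambda$.* The default is BIC on the partial likelihood,
$-2 l_n + \log(\#\text{events}) \cdot \#\{\hat\beta_k \neq 0\}$ — fully
deterministic, which keeps replicated studies reproducible. Seeded K-fold
cross-validation of the partial likelihood (Verweij–van Houwelingen) is
available; on the benchmark design it selects essentially the same
models as BIC. Under BIC the path
stops early once BIC has been past its minimum for 10 grid points with a
growing active set; the skipped dense tail cannot contain the BIC
optimum and is the most expensive part of the path. MCP shape $a = 3$ by
default (the convention of the penalty's standard implementations; any
$a > 1$ is accepted).

*Degenerate inputs.* No events, constant (zero-variance) penalized
columns, rank-deficient designs, single-arm exposure and non-binary
event codes are all hard errors with explicit messages; screening fits
that fail to converge score p-value 1; an empty $S_2$ yields a
zero-row record table and a direct-effect-only refit.

## Open design choices, and how they were settled

* **Score vs logit-score covariate.** The outcome and mediator models are
  stated with $\pi_i$ itself, but the replicated benchmark study carries
  the *logit* propensity score. Both are implemented
  (`covariate_form = "score"` is the package default;
  `run_simulation_study()` uses `"logit"` to mirror the benchmark). The
  two differ little on the benchmark design.
* **Intercept in the exposure DGP.** The generating logistic model has no
  intercept; the fitted propensity model always includes one.
* **Screening adjustment.** The marginal outcome model includes $X$ and
  the adjustment covariate alongside $M_k$ (consistent with the full
  model's structure); unadjusted screening is what the naive arm uses.
* **Estimation conditioning.** In replicated studies, per-mediator
  indirect-effect summaries average the replications in which that
  mediator entered $S_2$ (selection-conditional reporting, the
  convention for sparse-selection benchmarks; unselected cells would
  otherwise be undefined).
* **Censoring draws** are independent across censoring-rate settings.

## Known limitations

* A single linear propensity covariate cannot fully span the
  confounders' direct effect on the hazard; relative to full-confounder
  (`z`) adjustment this leaves a small residual attenuation in
  $\hat\beta_k$, and hence in
  $\hat\alpha_k\hat\beta_k$, while $\hat\alpha_k$ is essentially
  unbiased. The `z` mode shows no such attenuation. This is a property
  of covariate-style propensity adjustment under proportional hazards
  (non-collapsibility), not of the solver.
* The Sobel and joint tests are conservative under the composite null;
  no composite-null-calibrated test is provided.
* Matching, weighting and sub-classification on the propensity score,
  multi-level exposures, time-varying covariates, competing risks and
  left truncation are out of scope.

## Replicated benchmark studies

`run_simulation_study()` generates independent datasets, runs the
requested comparison arms on each, and reports mean TPR / FP / FDP per
test (selection accuracy against the known truth) and
selection-conditional means and MSEs of $\hat\alpha_k\hat\beta_k$ per
true-effect mediator. The package's acceptance checks run it at desk
scale — 200 replications with $p = 2{,}000$ (the screening size $d$
depends only on $n$, so selection dynamics are preserved), $n \in \{500,
1000\}$, censoring 15% and 30% — sizes chosen to make the full suite
reproducible on a single CPU; `scripts/acceptance.R` recomputes the same
quantities end to end.
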