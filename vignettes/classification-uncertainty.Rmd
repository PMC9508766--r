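---
title: "Assessing sensitivity of latent-subgroup treatment effects to classification uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing sensitivity of latent-subgroup treatment effects to classification uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A common way to study treatment effect heterogeneity is "classify-analyze":
measure a latent subgrouping of subjects with a finite mixture model over
observed indicators, impute each subject to the most probable class (modal
or hard assignment), and then estimate the average treatment effect (ATE)
within each imputed class. The catch is that modal assignment discards the
membership probabilities. A subject imputed to class 1 at probability 0.51
is treated exactly like one at 0.98, yet the first is far more likely to be
misclassified. Contamination of a class by members of another class biases
the class-specific effect estimate, and because misclassification is a
prediction error rather than a sampling error, the bias does not vanish as
the sample grows. latentsens implements a sensitivity analysis for this
problem: it quantifies how much a subgroup effect estimate depends on who
is assumed to belong to the subgroup, and how much the membership
probabilities themselves wobble under sampling uncertainty.

## Models and estimators

### Membership model

Latent classes are measured by a finite mixture over the indicator columns.
For categorical indicators the package fits a latent class model under
class-conditional independence: class prevalences $\pi_c$ and per-class,
per-indicator level probabilities $\rho_{cj\ell}$. For continuous
indicators it fits a Gaussian mixture with class-specific means and
diagonal covariances. Estimation is EM from `n_starts` seeded random
initializations (per-subject Dirichlet(1, ..., 1) responsibilities); the
best log-likelihood is kept. Posterior membership probabilities follow
Bayes' rule,
$\hat\lambda_{ic} \propto \hat\pi_c \prod_j \hat\rho_{c j x_{ij}}$,
and the modal assignment is $C_i = \arg\max_c \hat\lambda_{ic}$ with ties
broken to the lowest class index (a determinism choice; ties are measure
zero in practice). Classes are relabeled in order of decreasing prevalence
after fitting so repeated runs are comparable. The number of classes is
chosen by BIC over a candidate range, optionally screened so that every
modal class contains both treatment arms and outcome variation — a class
in which the effect simply cannot be computed is not a usable candidate.

### Subgroup effect estimator

Within an (imputed) subgroup $c$ of size $m_c$, with treatment $Z_i$,
outcome $Y_i$, covariates $X_i$, propensity score
$p(X_i) = \Pr(Z_i = 1 \mid X_i, C_i = c)$ and outcome regression
$m(z, X_i) = E(Y_i \mid Z_i = z, X_i, C_i = c)$, the package uses the
doubly-robust augmented inverse-propensity-weighted (AIPW) estimator

$$
\hat\tau_c = \frac{1}{m_c} \sum_{i : C_i = c}
\left[ (2Z_i - 1) W_i Y_i - (Z_i - \hat p_i)
\left\{ \frac{\hat m(1, X_i)}{\hat p_i} +
        \frac{\hat m(0, X_i)}{1 - \hat p_i} \right\} \right],
\qquad
W_i = \frac{Z_i}{\hat p_i} + \frac{1 - Z_i}{1 - \hat p_i},
$$

which is algebraically identical to the familiar
$\frac{1}{m_c}\sum_i \{ Z_i(Y_i - \hat m_1)/\hat p_i -
(1-Z_i)(Y_i - \hat m_0)/(1-\hat p_i) + \hat m_1 - \hat m_0 \}$ form (the
test suite asserts the identity against an independent implementation).
The variance estimate is the sum of squared centered per-subject influence
values divided by $m_c(m_c - 1)$, and the confidence interval is Wald with
the standard normal quantile; no small-sample t correction is applied.

Both nuisance models are fitted on the subgroup members only:

* **Propensity**: logistic with covariate main effects, estimated as a
  covariate-balancing propensity score — the coefficients solve the
  just-identified moment conditions
  $\sum_i \{Z_i/p_i - (1-Z_i)/(1-p_i)\}\,\tilde x_i = 0$ (intercept
  included) rather than the likelihood score, so at convergence the
  inverse-probability-weighted covariate means agree between arms to
  `cbps_tol` (default `1e-8`; the suite checks `1e-6`). The solver is a
  damped Newton iteration started at the maximum-likelihood estimate; if
  the moment system has no usable root (typical under near-separation in
  small subsets) the fit falls back to the MLE with a warning. The
  just-identified form was chosen over over-identified variants because it
  is exact, parameter-free and fast enough to refit hundreds of times.
* **Outcome**: a saturated regression with intercept, covariate main
  effects, treatment, and all treatment-by-covariate interactions, under
  an elastic-net penalty (mixing weight 0.5 by default, intercept never
  penalized, treatment penalized by default with a switch to exempt it).
  The penalty strength is chosen by seeded k-fold cross-validation;
  `penalty_lambda = 0` requests the unpenalized GLM instead. Categorical
  covariates are one-hot encoded against a first-level reference, and
  columns that become constant inside a subset (trajectory subsets can
  lose levels) are pruned before fitting.

Failures are data, not crashes: a subgroup with a single treatment arm,
complete separation, an undefined weight, or fewer than `class_floor`
members (default 10) yields an effect object with `defined = FALSE` and a
machine-readable reason that propagates through trajectories and
bootstrap draws.

## The sensitivity analysis

### Probability-ordered trajectories

For a class $c$, subjects are ordered by the strength of evidence that
they belong to it: first all subjects whose modal class is $c$, in
decreasing $\hat\lambda_{ic}$; then the remaining subjects, again in
decreasing $\hat\lambda_{ic}$ (ties to the lower subject index). Modal
members come first even when an outsider has a larger probability for $c$
— a subject at $(0.4, 0.3, 0.3)$ belongs to class 1 more strongly than one
at $(0.45, 0.55, 0)$, whose best class is 2. Walking this order produces
nested partitions $\hat S_c(j)$, and re-estimating the effect on each
partition produces a trajectory whose value at $j = m_c$ is exactly the
modal-assignment estimate. Evaluation is restricted to the window between
$m_c^*$ (count of $\hat\lambda_{ic} \ge$ `u_hi`, default 0.99) and
$m_c^{**}$ (count of $\hat\lambda_{ic} \ge$ `u_lo`, default 0.01): outside
it, partitions either add subjects with essentially no evidence of
membership or drop to sizes where weights explode. Nuisance models are
refit at every evaluated step; the cross-validation fold seed is held
fixed across steps so trajectory wiggle reflects subject composition, not
fold randomness. When the window exceeds `max_steps` (default 1000) an
even sub-grid is used that always includes $m_c^*$, $m_c$ and $m_c^{**}$.
The mixture model itself is never refit along the trajectory — partitions
derive from the single fitted $\hat\lambda$ matrix.

A flat trajectory inside the window says the effect estimate does not
hinge on the tentative members; a drifting one warns that contamination
by another class moves the estimate materially.

### Perturbed confidence intervals

Membership probabilities are themselves estimates. To propagate their
sampling uncertainty, the package perturbs the mixture parameters with a
parametric bootstrap: draw parameters from a multivariate normal centered
at the estimates with the estimated parameter covariance, recompute the
posterior probabilities, re-impute subjects by modal assignment, realign
labels to the estimated labeling (label switching guard), and recompute
the Wald interval under the perturbed memberships, refitting the nuisance
models each time. After `B` draws (default 1000) the combined interval
takes the $\alpha/2$ percentile of the per-draw lower endpoints and the
$1 - \alpha/2$ percentile of the uppers, with linear interpolation between
order statistics (R's type-7 quantile — stated explicitly because small-B
percentiles are convention-dependent). The percentile rule was preferred
over the union rule (min lower, max upper) because the union is hostage to
a single extreme draw; the union interval remains available as
`union_interval()` on the stored per-draw endpoints. Undefined draws are
skipped, counted, and reported; more than 20% skipped triggers a recorded
warning, and all-skipped is an error with a reason tally. Pointwise
trajectory bands apply the same machinery on a fixed grid of cumulative
proportions (`band_B` draws, default 200, since each draw costs a full
trajectory), masking grid points where more than half the draws are
undefined.

Two numerical conventions deserve emphasis because they are genuine design
choices rather than consequences of the method:

* **The scale of the parameter draw.** The multivariate normal lives on a
  packed unconstrained scale — multinomial logits of the prevalences and
  of each response-probability vector (last level as baseline), raw means
  and log standard deviations for the Gaussian family — so every draw maps
  back to valid probabilities without clipping. The parameter covariance
  is the inverse of the observed information, computed by central-
  difference numerical differentiation of the log-likelihood on that scale
  (step $10^{-5}(1 + |\theta|)$ per coordinate); when the information
  matrix cannot be inverted the package falls back to a nonparametric
  bootstrap covariance (200 resamples, single warm-started EM run each,
  classes realigned by parameter distance) with a warning.
* **Label alignment.** Each draw's columns are permuted to maximize the
  number of subjects whose modal label agrees with the estimated modal
  labels — exhaustively over permutations for $K \le 8$, greedily beyond
  (no optimal-assignment solver dependency; mixtures beyond eight classes
  are outside this package's intended range). Ties take the
  lexicographically smallest permutation. Per-draw agreement rates are
  recorded so poorly aligned draws can be inspected afterwards; they are
  kept, not down-weighted.

## The synthetic test bed

`synthetic_spec()` defines a generative model with known truth: true class
labels from the prevalences; categorical indicators from class-conditional
distributions (optionally sharpened by raising each probability vector to
a power and renormalizing); treatment from class-specific logistic models
on the indicator codes; and both potential outcomes drawn jointly through
a shared uniform (binary) or shared error (continuous), so individual
effects are well defined and the true subgroup ATE is computable by exact
enumeration over the indicator support (Monte Carlo with reported
simulation error for large supports).

Two stock designs set the study conditions used throughout the tests and
the acceptance script:

* `"separated"` — two equal classes, five binary indicators with response
  probabilities 0.9 vs 0.1. Under modal assignment fewer than 1% of
  subjects are misclassified (the probability that a Binomial(5, 0.9)
  falls at or below 2 is about 0.0086). Class 1 has a null effect by
  construction (zero treatment coefficient); class 2 a positive risk
  difference of about 0.11. This is the benign regime: estimates should
  recover the truth, Wald intervals should cover at roughly the nominal
  rate, and trajectories should be flat.
* `"overlapping"` — four indicators at 0.75 vs 0.25, which yields roughly
  15% misclassification under modal assignment, and a larger class-2
  effect so that contamination visibly biases the class-1 estimate. This
  is the stress regime: intervals that hold the imputed memberships fixed
  under-cover the true class effect, and perturbed intervals should
  recover at least that coverage.

These generators emulate the structure the estimators assume —
class-conditional independence of indicators, logistic assignment and
outcome models, no unmeasured confounding — and deliberately nothing
else. Real data violate class-conditional independence, carry missing
values beyond the complete-case rule, mix indicator types, and may hide
confounders; passing tests on the synthetic designs demonstrates
correctness of the machinery under its own assumptions, not robustness to
those violations.

The simulation scales used by the test suite are the package's choices
for a thorough-but-fast check: 100 replicates at $n = 2000$ for parameter
and effect recovery; 200 replicates at $n = 600$ with $B = 200$ draws
(unpenalized outcome fits, which are exact for the saturated design at
these sizes) for the coverage-ordering comparison; smaller toys for exact
hand-checkable identities. The acceptance script runs the same pipeline
once at $n = 2000$ plus a 60-replicate coverage block.

## Other decisions made where the design was open

* Quantile discretization of continuous indicators uses rank arithmetic
  (min-tie rank $r$ of $n$ maps to bin $\lceil rq/n \rceil$), so tied
  values share the lower bin and labels increase weakly with the value. A
  constant column collapses to one bin with a warning; heavy ties that
  realize fewer than $q$ bins warn with the achieved count. Discretized
  bins are treated as unordered categories by the mixture model.
* Propensity scores are not truncated by default; optional clipping to
  $[\epsilon, 1 - \epsilon]$ is available via `ps_clip`. Instability is
  surfaced through `positivity_check()` (single-arm flag, extreme-score
  count, maximum weight, separation flag) rather than silently clamped.
* A two-class model on a single binary indicator is not identifiable
  (three parameters, two observed cells); recovery checks therefore use
  several indicators. `fit_mixture()` does not forbid such models — the
  EM still converges — but their parameter covariance is meaningless.
* Seeds: one master seed in `run_config()`; every random component
  (EM starts, CV folds, bootstrap draws, band draws) derives its own
  stream from it by fixed offsets, so a whole analysis is reproducible
  from a single integer, and perturbation draws are bit-identical across
  reruns.

## Limitations

The package corrects nothing: it measures sensitivity. Bias-corrected
estimators, concomitant-variable (covariate-predicted) latent class
models, pseudo-class random assignment, mixture propensity models,
multilevel and longitudinal extensions, fuzzy clustering memberships, and
machine-learning nuisance learners with cross-fitting are all out of
scope. Missing data are handled by complete-case filtering only, which is
appropriate under missing-completely-at-random and optimistic otherwise.
Trajectory smoothing statistics (moving averages, local smoothers) are
not provided; the trajectory CSVs contain everything needed to compute
them downstream.
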