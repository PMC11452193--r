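---
title: "Modelling effort-based decisions on the Apple Gathering Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effort-based decisions on the Apple Gathering Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agtfit)
```

## The task and the choice model

The Apple Gathering Task (AGT) crosses four reward levels (3, 6, 9, 12
apples) with four effort levels (20--80% of the participant's maximum
voluntary contraction, MVC), each combination offered five times in a
seeded random order (80 trials). The participant accepts or refuses
each offer; accepted offers require a calibrated grip squeeze, except
that a quarter of accepted trials skip the exertion phase to limit
fatigue.

`agtfit` models each decision with a logistic subjective-value rule.
The winning model assigns the offer $(r, e)$ --- scaled reward
$r = \text{apples}/12 \in \{0.25, 0.5, 0.75, 1\}$ and effort
$e \in \{0.2, 0.4, 0.6, 0.8\}$ --- the value

$$V = K + \mathrm{LinR}\, r + \mathrm{LinE}\, e + \mathrm{E2}\, e^2,
\qquad P(\text{accept}) = \frac{1}{1 + e^{-V}}.$$

$K$ (acceptance bias) is the willingness to take on an effort
challenge irrespective of the offer; $\mathrm{LinR}$ scales the valuation
of reward; $\mathrm{LinE}$ and $\mathrm{E2}$ are linear and quadratic effort
costs (more negative = costlier; $\mathrm{E2} < 0$ makes high effort
disproportionately aversive). All four are unitless logit-scale
coefficients. No separate inverse temperature is included: choice
stochasticity is absorbed into the coefficient scale, and the winning
model has exactly these four named parameters.

**Predictor scaling.** The scaling above is a package convention,
fixed so that the case-control constraint $\mathrm{LinE} = -15$
("ConstE") produces linear effort costs of $-3$ to $-12$ logits across
the design --- steep enough that effort matters everywhere, shallow
enough that high-reward offers remain acceptable. `agt_scaling()`
accepts alternative strictly increasing maps into $(0, 1]$.

**The model space.** `enumerate_models()` builds a factorial registry
of 70 candidates: five reward forms (linear, quadratic,
linear+quadratic, square-root, log) by seven effort forms (none,
linear, quadratic, linear+quadratic as additive costs; hyperbolic,
exponential, power as multiplicative discounts of the reward term) by
bias on/off. The non-winning forms exist to exercise model comparison,
not as claims about any particular dataset; the hyperbolic discount is
parameterised with a log-scale rate, $1/(1 + e^{\mathrm{Hyp}} e)$, so
every finite parameter vector yields a finite likelihood. The winning
model is `r-linear_e-linquad_bias`; `winning_model("case_control")`
additionally fixes $\mathrm{LinE} = -15$, leaving three free parameters.
Constrained parameters are excluded from sampling and from
free-parameter counts everywhere.

## Hierarchical estimation

Participant parameters $\theta_i$ are partially pooled:
$\theta_{ij} \sim N(\mu_{j,g(i)}, \tau_j^2)$ with hyperpriors
$\mu \sim N(0, 10)$ and $\tau \sim \text{half-}N(0, 5)$ (package
conventions). Three prior schemes mirror the analysis design:
`shared` (one prior for everyone), `per_group` (separate group-level
priors for one parameter of interest at a time, all other parameters
shared --- the primary configuration), and `per_group_all` (all
parameters separated; the sensitivity analysis). Group labels enter
only through the priors, never the likelihood.

Two backends are provided.

* **`method = "map"`** (default): EM with a Laplace E-step. Each
  iteration solves the penalised logistic problem per participant by
  Newton's method with step halving, then updates $\mu$ (closed-form
  normal-normal) and $\tau$ (closed-form mode of the half-normal
  posterior) using $E[(\theta - \mu)^2] = (\hat\theta - \mu)^2 + V_i$
  with the Laplace variance $V_i$ --- this keeps $\tau$ away from the
  degenerate $\tau \to 0$ joint mode that plagues naive joint MAP.
  The EM is initialised at a pooled (single-parameter-set) logistic
  estimate: the likelihood has a long flat ridge in the
  $K$--$\mathrm{LinE}$--$\mathrm{E2}$ direction and an initialisation at
  zero converges slowly along it, biasing hypermeans. Posterior draws
  are Laplace normals around the participant modes.
* **`method = "mcmc"`**: Metropolis-within-Gibbs --- vectorised
  random-walk block updates per participant (scales adapted during
  warmup toward ~30% acceptance), conjugate Gibbs draws for the
  hypermeans, log-scale random walks for the hypersds. Defaults: 4
  chains, 1000 warmup + 1000 kept draws. Split-chain R-hat and an
  autocorrelation ESS are recorded for every reported quantity, and a
  warning (not an error) is raised when max R-hat exceeds 1.05.

The two backends agree on point estimates well within the posterior
uncertainty on recovery data; the MAP mode exists so test suites and
pipelines run in seconds.

**Model comparison** ranks fits by expected log pointwise predictive
density, estimated from retained pointwise log-likelihood draws with
truncated importance-sampling leave-one-out (weights truncated at
$\sqrt{S}$ times their mean). Standard errors of pairwise elpd
differences are paired over trials. Dataset identity across fits is
enforced by an md5 checksum of the records. In MAP mode the pointwise
matrix uses Laplace draws; at most `loglik_draws` (default 400) draws
are retained to bound memory.

## The synthetic cohort

No subject-level data are deposited for this task in depression, so
every stage is exercised on synthetic cohorts whose structure matches
the printed summaries:

* **Design**: 80 trials, balanced 4 x 4 grid, seeded permutation.
* **MVC calibration**: six truncated-Gaussian squeezes around a
  lognormal latent strength; MVC = max of the last three. Squeeze
  noise is 5% of strength.
* **Omission rule**: exactly `round(0.25 * n_accepted)` accepted
  trials (half away from zero) are flagged "no response required",
  sampled without replacement --- stratified-exact rather than i.i.d.,
  so the 25% figure is a testable invariant.
* **Success**: per-effort-level probabilities 0.97/0.95/0.92/0.88, all
  above the reported >80% bound at the top level; refused trials carry
  no exertion or success fields.
* **Groups**: CTR 57, REL 36, REM 46, MDD 41 (the final case-control
  sample). All groups share the reward/effort sensitivity
  distributions; the REM and MDD acceptance-bias means are lowered by
  0.39 pooled SD, planting the reported group difference in $K$ and
  only in $K$.
* **Parameter dispersion** (a convention --- the generative
  distribution of real parameters is unknown): $K \sim N(4, 3)$ for
  CTR/REL, $\mathrm{LinR} \sim N(13, 3)$, $\mathrm{LinE} \sim N(-15, 3)$,
  $\mathrm{E2} \sim N(-2, 1.5)$. These were calibrated once, jointly, to
  the printed summaries: overall acceptance averaging ~0.72 with a
  wide per-participant spread (minimum below 0.55, maximum above
  0.95, matching the reported 40--100% range), monotone
  effort/reward gradients, and an acceptance-scale group contrast
  near the reported d ~ 0.38.
* **Symptom factors** (Low Mood, Apathy, Hedonia, Dysfunctional
  Attitudes) are generated directly by the conditional-Gaussian
  construction $F = \rho z(\theta) + \sqrt{1-\rho^2}\,\varepsilon$
  rather than via factor analysis of questionnaire items; the default
  Low Mood--LinR target is $\rho = -0.344$. Ages are Gaussian
  truncated to 18--60; decision RTs are lognormal noise carried for
  format fidelity only and never analysed.

What a green test on this cohort does **not** establish: that real
participants follow the winning model, that real parameter dispersions
match these conventions, or that real-data effect sizes are
reproduced. The generator omits fatigue dynamics, questionnaire items,
RT structure and any reward-probability component.

## The model-agnostic arm

Acceptance proportions are arcsine transformed ($\arcsin\sqrt{p}$,
exact at 0 and 1, no continuity nudges) before any
Gaussian-assumption analysis. The mixed repeated-measures ANOVA tests
reward, effort and their interaction within subjects (univariate
averaged F on orthonormal within-subject contrasts), group between
subjects (sum-to-zero coding) and a mean-centred age covariate.
Greenhouse-Geisser $\varepsilon$ is estimated from the
contrast-projected error covariance,
$\varepsilon = \mathrm{tr}(S)^2 / (q\,\mathrm{tr}(S^2))$; the corrected p
value is reported as primary whenever the Mauchly test rejects
sphericity at 0.05, and $\varepsilon \equiv 1$ for two-level factors.
Planned contrasts (MDD+REM vs REL+CTR; MDD+REM+REL vs CTR) report F/p
from the covariate-adjusted linear model but Cohen's d from raw group
means with the pooled-sd denominator (sign: first side minus second)
--- effect sizes always exclude covariates. Design power uses the
noncentral F distribution with $\lambda = f^2 N$; the omnibus
four-group test is assumed since the original power procedure is
unstated. Post-hoc and exploratory correlations are uncorrected and
labelled as such.

## Numerical choices and degenerate inputs

* Logistic terms are evaluated through `plogis(..., log.p = TRUE)`:
  saturation never produces NaN.
* EM convergence: max participant-parameter change below `1e-4`, cap
  200 iterations; per-participant Newton stops at `1e-8` with step
  halving.
* Correlations with zero-variance inputs are returned as NA with an
  explicit `degenerate` flag, never silent NaN; the
  posterior-predictive r requires at least three participants and
  non-zero variance.
* Missing design cells are flagged in `acceptance_matrix()` and are a
  hard error in the ANOVA.
* Table validation reports *all* offending rows with their numbers.
* All randomness flows from integer seeds through an internal
  splitter; the caller's RNG state is saved and restored.

## Design choices made where the design was open

* The identity of the 70 candidate models is fixed as the 5 x 7 x 2
  factorial above, which reproduces the count and nests the winning
  model.
* The bias-only null used in comparisons (`bias_only_model()`) is the
  linear-reward/no-effort spec with $\mathrm{LinR}$ constrained to 0 ---
  the registry itself contains no intercept-only member.
* Joint fitting of all four case-control groups is assumed (whether
  the original pilot fit informed the case-control priors beyond
  ConstE is not stated).
* MAP is the default backend for runtime; MCMC is the reference.

## Known limitations

* **Recovery ceiling.** At the default dispersion the 80-trial design
  caps true-vs-recovered correlations near 0.94 ($K$), 0.75
  ($\mathrm{LinR}$) and 0.40 ($\mathrm{E2}$): the regressors $1, r, e^2$ are
  strongly collinear once weighted by $p(1-p)$, and most high-effort
  trials are near-deterministic. The packaged recovery study reports
  exactly this --- $K$ recovers well, $\mathrm{LinR}$ sits near 0.75--0.8
  and $\mathrm{E2}$ near 0.5 --- and the corresponding strict acceptance
  test is expected to flag $\mathrm{LinR}$/$\mathrm{E2}$. Larger
  dispersions shift which parameter suffers but not the budget. This
  mirrors the trade-off that motivated constraining $\mathrm{LinE}$ in
  the first place.
* The MAP hypermean uncertainty is a Laplace approximation
  ($1/\sqrt{n_g/\tau^2 + 1/100}$), adequate for ranking and contrasts
  but not for tail probabilities; use MCMC where intervals matter.
* Componentwise shrinkage ("posterior mean between the unpooled MLE
  and the hypermean") is a theorem only for one-parameter models; for
  the correlated three-parameter posterior the guarantee is vector
  contraction toward the hypermean, which is what the tests assert.
* The permutation-based type-I calibration of the group effect relies
  on the arcsine scale keeping cell means far from the boundaries;
  heavily saturated cohorts (everyone near 100% acceptance) would
  need exact permutation p values instead.
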