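# agtfit

Simulation and hierarchical Bayesian analysis of effort-based
decision-making on Apple Gathering Task (AGT) style experiments.

## The problem

In the AGT, participants repeatedly decide whether to squeeze a
grip-force device to a calibrated fraction of their maximum voluntary
contraction (MVC) in exchange for a reward (apples). The design crosses
four reward levels (3, 6, 9, 12 apples) with four effort levels (20,
40, 60, 80% MVC), each offer repeated five times (80 trials). Because
reward and effort vary independently and deterministically, the task
separates three latent drivers of the willingness to work: how much
reward is valued, how aversive effort is, and an overall bias to accept
challenges irrespective of either. In depression research, the question
is which of these is disrupted.

`agtfit` provides, for researchers who analyse such choice data (or
want to plan such a study):

* a **seeded task and cohort simulator** that emulates the AGT design —
  MVC calibration from six squeezes, exact 25% exertion omission among
  accepted trials, per-effort success probabilities, group-structured
  parameter differences, symptom factor scores with target correlations;
* the **factorial model space** of 70 subjective-value choice models
  (5 reward forms x 7 effort forms x acceptance bias on/off);
* **hierarchical estimation** with partial pooling (penalised-MAP with
  Laplace draws, or Metropolis-within-Gibbs MCMC), with shared or
  per-group group-level priors ("one parameter of interest at a time");
* **model comparison** by importance-sampling leave-one-out expected
  log predictive density, posterior-predictive checks, and
  parameter-recovery studies;
* the **model-agnostic statistical arm**: arcsine-transformed
  acceptance rates, mixed repeated-measures ANOVA with
  Greenhouse-Geisser correction and a mean-centred age covariate,
  planned group contrasts with Cohen's d (covariates excluded from
  effect sizes), noncentral-F design power, and parameter-symptom
  correlations.

## The model

The winning four-parameter model assigns each offer the subjective
value

    V = K + LinR * r + LinE * e + E2 * e^2

with scaled reward `r = apples / 12` and effort `e` the fraction of
MVC, and the offer is accepted with logistic probability
`P(accept) = 1 / (1 + exp(-V))`. `K` is the acceptance bias (overall
willingness to accept, independent of the offer), `LinR` the linear
reward sensitivity, and `LinE` / `E2` the linear and quadratic effort
sensitivities (negative values mean costlier effort; `E2 < 0` makes
high effort disproportionately costly). In the case-control
configuration `LinE` is constrained to `ConstE = -15` and three
parameters are free. Participant-level parameters are partially pooled
through Gaussian group-level distributions (hyperpriors: means
N(0, 10), sds half-N(0, 5)); group membership enters only the priors,
never the likelihood.

## Worked example

```r
library(agtfit)

coh <- simulate_cohort(default_cohort("case_control"), seed = 1)
coh
#> agt cohort: 180 participants, 14400 trials (seed 1)
#>   groups: CTR=57, MDD=41, REL=36, REM=46
#>   overall acceptance: 0.71 (range 0.06-0.99)

rm_anova(coh$records)
#> repeated-measures ANOVA (180 participants, arcsine scale, covariate age)
#>               effect       F  df1    df2 epsilon          p GG
#>               reward 944.235 1.79 313.40   0.597 2.919e-127  *
#>               effort 839.751 1.67 291.73   0.556 1.813e-112  *
#>        reward:effort  74.478 3.23 565.09   0.359  5.299e-43  *
#>                group   3.623 3.00 175.00      NA  1.427e-02
#>                  ...
```

Acceptance falls with effort and rises with reward (Greenhouse-Geisser
corrected df, flagged `GG` when the Mauchly test rejects sphericity),
and the groups differ. The planned contrast on arcsine acceptance:

```r
v <- arcsine_transform(coh$truth$acceptance_rate)
planned_contrast(v, coh$truth$group, c("MDD", "REM"), c("REL", "CTR"),
                 covariate = coh$truth$age)
#> contrast MDD+REM (n=87) vs REL+CTR (n=93)
#>   Cohen's d = -0.477 (covariates excluded); F(1,177) = 10.159, p = 0.001698
```

Fitting the winning model with separate group-level priors on the
acceptance bias shows the difference is carried by `K`, not by reward
or effort sensitivity:

```r
fit <- fit_agt(coh$records, model = winning_model("case_control"),
               scheme = "per_group", param_of_interest = "K",
               method = "map", seed = 2)
fit
#>   group-level means:
#>     K      CTR      4.499 (sd 0.313, group sd 2.364)
#>     K      MDD      2.871 (sd 0.409, group sd 2.622)
#>     K      REL      4.453 (sd 0.496, group sd 2.978)
#>     K      REM      3.139 (sd 0.460, group sd 3.120)
#>     LinR   all     12.232 (sd 0.184, group sd 2.465)
#>     E2     all     -1.225 (sd 0.118, group sd 1.579)
#>   constrained: LinE = -15

posterior_predictive_acceptance(fit)
#> posterior-predictive acceptance: r = 0.9999 over 180 participants
```

The depressed and remitted groups sit ~1.5 logits below the control
groups on `K`, the fitted model reproduces individual acceptance rates
almost perfectly (r = 0.9999), and the omnibus power of the four-group
design at a medium effect (`anova_power(0.25, c(57, 36, 46, 41))`)
evaluates to 0.804.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at a reduced demonstration
scale — cohort simulation, symptom factors, the ANOVA/contrast/power
arm, the hierarchical fit with per-group priors on `K`, the
posterior-predictive check and a parameter-recovery pass — and writes
the results JSON to `--out`.

## Layout

* `R/task.R` — design grid, offer scaling, subjective value, logistic
  choice, arcsine transform
* `R/models.R` — the 70-model factorial registry, winning-model
  definitions, Bernoulli likelihoods
* `R/simulate.R` — cohort generator (participants, MVC calibration,
  sessions, symptom factors)
* `R/fit.R`, `R/methods.R` — hierarchical estimation (`fit_agt`) and
  its S3 methods
* `R/compare.R` — LOO model comparison, posterior-predictive checks,
  recovery studies
* `R/stats.R` — RM-ANOVA with Greenhouse-Geisser, contrasts, power,
  correlations
* `R/io.R` — choice-table I/O with row-level validation, pipeline
  driver
* `vignettes/agt-methods.Rmd` — the modelling assumptions, parameter
  conventions, and known limitations
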