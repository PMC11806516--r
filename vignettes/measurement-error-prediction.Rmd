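---
title: "Simulating measurement error in predictive models of diet-health relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating measurement error in predictive models of diet-health relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepsim)
```

## The problem

Dietary intake is essentially never observed directly. Instruments such as
repeated 24-hour recalls report a single day's intake, which is an
error-prone surrogate for *usual intake* — the long-run average that
diet-health models actually care about. When the analytic goal is
prediction rather than estimation, a common argument says measurement error
can be ignored: just model the outcome from the error-prone measurements.
`mepsim` provides a simulation laboratory for examining what that choice
costs, for both regression models and fully connected neural networks, and
for studying the design levers that mitigate it: averaging replicates,
transforming to a scale on which errors are additive, and trading sample
size against replicate count.

## The generating models

Outcomes follow a generalized regression structure
$$E[Y \mid X, Z] = g^{-1}\!\big(\alpha_0 + \alpha' h(X, Z)\big),$$
with residual variance $\sigma^2_Y$ for the identity link and Bernoulli
sampling for the expit link. $X$ holds the $p$ error-prone usual intakes,
$Z$ the $q$ error-free covariates, and $h$ maps them to the features that
enter linearly (a ratio, products, logs, indicator thresholds, depending on
the scenario).

Replicate measurements arise on a Box-Cox transformed scale:
$$X^*_{\ell j} = f^{-1}\!\big(\beta_{0\ell} + \beta_{Z\ell}' Z + u_\ell +
\varepsilon_{\ell j}\big),$$
where $f$ is the Box-Cox transform with exponent $\lambda_\ell$,
$u \sim N(0, \Sigma_u)$ is the between-person effect drawn once per person,
and $\varepsilon_j \sim N(0, \Sigma_\varepsilon)$ is the within-person
(day-level) error drawn independently per replicate. Usual intake is
defined as the conditional expectation of the observed measurement,
$$X_\ell = E\big[f^{-1}(\beta_{0\ell} + \beta_{Z\ell}' Z + u_\ell +
\varepsilon_{\ell}) \mid Z, u_\ell\big].$$
With $\lambda = 1$, interpreted as the identity transform, the model
collapses to the classical additive model $X^* = X + \varepsilon$ used by
the nonlinear-outcome and binary-prediction scenarios.

### Observation scale for the skewed scenarios

For the two Box-Cox scenarios the package observes the replicates on the
raw intake scale, $X^* = f^{-1}(\beta_0 + u + \varepsilon)$. This is the
reading under which the whole exercise is coherent: the observed intakes
are right-skewed, a profile-likelihood Box-Cox fit on pooled replicates
recovers the generating exponent, and transform-then-average genuinely
differs from plain averaging. The alternative literal reading — observing
the additive value itself — would make the observed data Gaussian, pin the
estimated exponent near one, and render the transformed-average
preparation an affine copy of plain averaging. That additive observation
mode is still available (`observe = "additive"` in `error_model_spec()`)
because it is the scale on which the second-moment identities
($\operatorname{cov}(X^*) = \Sigma_u + \Sigma_\varepsilon$ across persons,
$\Sigma_u$ within person across replicates) hold exactly, which the test
suite exploits.

### Domain handling

The inverse Box-Cox requires $\lambda a + 1 > 0$, and intakes are
physically positive. Replicates violating either constraint are rejected
and redrawn (the whole day-error vector for that person-replicate), and the
rejection rate is recorded; at the shipped parameterisations it is of order
$10^{-6}$ or smaller. Rejection rather than clipping preserves the
distributional shape. The quadrature that defines usual intake truncates
its integration domain in exactly the same way, so the defined truth is the
expectation under the same law the generator samples from.
`true_usual_intake()` uses 41-node Gauss-Hermite quadrature; because the
inverse Box-Cox at the shipped exponents grows sub-cubically, the rule is
effectively exact there (the tests compare it to brute-force Monte Carlo).

## Variance-reduction theory

On the additive scale, averaging $k$ replicates divides the error variance
by $k$ (`averaged_error_variance()`). Under multiplicative lognormal
errors, averaging on the raw scale helps less: matching the raw-scale
variance of the averaged error $\frac{1}{k}\sum_j \exp(\varepsilon_j)$,
$\varepsilon_j \sim N(0, \sigma^2)$, to that of a single lognormal error
$\exp(\eta)$, $\eta \sim N(0, \sigma^2_R)$, gives
$$\sigma^2_R = \log\!\left(\frac{1 + \sqrt{1 + 4c}}{2}\right),
\qquad c = \frac{e^{2\sigma^2} - e^{\sigma^2}}{k},$$
the positive root of the quadratic in $e^{\sigma^2_R}$. The formula was
derived from the variance-matching condition and is verified in the tests
against a Monte-Carlo oracle that inverts the single-error variance map
numerically; it collapses to $\sigma^2$ at $k = 1$ and sits inside
$[\sigma^2/k,\, \sigma^2]$ for $k \ge 2$. The general
transform-then-average dominance (for smooth, convexly curved transforms,
averaging on the additive scale before transforming yields no more error
variance than averaging the transformed values) is checked by
`lemma1_gap()`, a seeded Monte-Carlo verifier with batch-mean standard
errors; affine transforms give equality, which doubles as a bias check on
the verifier itself.

For the sample-size/replicate-count trade-off, the normal-normal classical
model gives the residual error variance after observing a $k$-day average,
$$\operatorname{var}(\bar V \mid \bar X^*) =
\frac{\sigma^2_V \sigma^2_X}{\sigma^2_V + k \sigma^2_X},$$
(`conditional_error_variance()`), which vanishes as $k \to \infty$: with
enough replicates, error-prone prediction approaches error-free
prediction, regardless of $n$. `fit_mse_scaling()` fits the resulting
test-MSE decomposition $\sigma^2_Y + C_1/k + C_2/n^{1-\delta}$ by
nonnegative least squares; $\delta$ defaults to 0, the near-parametric
best case, and is configurable.

## Preparation strategies

`prepare()` implements the three ways replicates become predictors:
per-component averaging; concatenation (every replicate its own column,
component-major); and transformed averaging, which estimates a Box-Cox
exponent per component on the pooled training replicates (grid search on
$[-1, 2]$ in steps of 0.01, refined by golden-section search), transforms
each replicate, and averages on the transformed scale. The transformed
mean is fed to the learner directly — prediction needs a well-conditioned
predictor, not a particular scale — with `retransform = TRUE` available
for sensitivity runs. The exponent is estimated on training data only and
frozen when preparing test data. Whether the original studies estimated
the exponent or reused the generating value is not documented; estimation
is the realistic protocol and is the default here, and it also exercises
recovery of the generating exponent, which the acceptance checks assert.

## Learners

`fit_glm()` wraps ordinary least squares and logistic maximum likelihood.
`fit_mlp()` trains a fully connected feedforward network under the fixed
protocol used across the studies: five hidden layers of 50 rectified
linear nodes, batch normalisation on hidden pre-activations, dropout
0.001, minibatches of 1000, Adam (learning rate 0.1, weight decay 1e-4),
the learning rate divided by 10 every 300 epochs, at most 1500 epochs,
15% of the training set held out for validation, and early stopping
checked every 50 epochs. The trainer is written directly on R matrix
operations so each layer is a BLAS call, and its backpropagation is tested
against finite differences, including through batch normalisation.

Numerical choices the protocol leaves open, decided as follows:

* *Early-stopping criterion*: at each check the current validation loss is
  compared with the best seen; training stops when the relative
  improvement is below 1e-4, and the best-validation checkpoint is
  restored.
* *Output-bias initialisation*: the output layer's bias starts at the
  training-mean response (logit of the mean for the expit link), so the
  optimizer spends its budget on structure rather than on locating the
  outcome's scale. Remaining weights use uniform fan-in initialisation.
* *Standardisation*: predictors are standardised by training mean/sd in
  the simulations as well as any data analysis; a learning rate of 0.1 is
  not stable on raw intake scales. A flag can disable it.
* *Classification ties*: predicted probability exactly 0.5 classifies
  positive. The accuracy baseline is the training majority class.
* *Validation split*: random but seeded, stratified by class for binary
  outcomes.

A network with no hidden layers and identity output is a linear model fit
by Adam; trained to convergence it reproduces least squares to numerical
precision, which the tests use as an oracle-equivalence check.

## The four studies

`make_scenario()` carries the full parameterisations; `experiment_plan()`
plus `run_experiment()` run the grids and emit long-form records
(scenario, replication, n, k, preparation, learner, split, metric, value).

1. **Transformations and overfitting** (`sim1`): two components, exponent
   0.35, outcome linear in the ratio $X_1/X_2$ with
   $\alpha = (98.5, 4)$, $\sigma^2_Y = 1$, intercepts $(36, 27.5)$,
   $\Sigma_u = \begin{pmatrix}20 & 15.5\\ 15.5 & 25.5\end{pmatrix}$,
   $\Sigma_\varepsilon = \begin{pmatrix}38 & 20.5\\ 20.5 &
   34.5\end{pmatrix}$; 2-10 replicate days at $n = 12000$. The outcome
   feature is the ratio of the two components; the misspecified learners
   receive the components linearly, so neither regression nor network
   sees the true functional form.
2. **Budget trade-off** (`sim2`): as `sim1` with exponent 0.5 and the
   total number of measurements fixed (12000, 60000 or 120000), so
   $n = \text{total}/k$ along the days grid.
3. **Nonlinear outcomes** (`sim3a`/`sim3b`): classical additive error on
   two components whose means are linear in four correlated covariates;
   the outcome combines linear, product, log and ratio features plus
   $Z_3$; $n = 40000$, $k = 2$, 100 replications. The coefficient and
   mean-structure vectors for this study do not transcribe unambiguously;
   the factorisation used here — scenario a
   $\alpha = (350, 2, -1, 3, 2, 1, -4)$ with unit coefficient on $Z_3$,
   scenario b $\alpha = (350, 1, -1, 50, 25, 25, -1)$, mean rows
   $(100\,|\,50; 2, 0, -1, 0.5)$ and $(100\,|\,50; 0, 2, 1, -0.5)$ — is
   the unique clean split consistent with the stated feature set and with
   the log terms mattering more in scenario b. It is a documented
   reading, not an authoritative one.
4. **Binary prediction** (`sim4`): three components, classical additive
   error, $P(Y=1\mid X) = \operatorname{expit}(-1 + \tfrac{X_2}{30}
   [I(X_1 \ge 100) - I(X_3 \le 30)] + \tfrac{1}{4}\log X_3)$;
   $n = 10000$, $k = 2$, 100 replications; logistic regression against
   two network regimes (batch 1000/checks every 50 epochs, and batch
   250/checks every 10), each with plain averages and with the third
   component's average log-transformed.

### Arms in study 3

Besides the error-free (true intakes entered linearly) and error-prone
(averaged, with or without appended log features) arms, `run_sim3()`
includes an `oracle` arm: least squares on the *correct* feature set
evaluated at the true intakes. It is the operational version of the
theoretical MSE floor $\sigma^2_Y$ — the linear-terms error-free arm
cannot reach that floor, because the product feature leaves an irreducible
quadratic residual of variance
$\alpha_3^2(\sigma_1^2\sigma_2^2 + \sigma_{12}^2)$, orders of magnitude
above $\sigma^2_Y$ at the scenario-a parameters. The log-feature
comparison is asserted in scenario b, where the log coefficients (25
versus 2 and 1) make the improvement large enough to measure at desk
scale; in scenario a it is of order $10^{-2}$ MSE units against a
replication noise of hundreds, i.e. undetectable by any affordable
replication count.

## Desk scales

The shipped defaults reproduce the full-scale designs. The test suite
and the acceptance script run scaled-down versions chosen once as the
package's desk conditions: study 1 at $n = 2000$, days $\{2, 10\}$, 3
replications, 250-epoch budget; study 2 at a fixed budget of 24000
measurements over days $\{2, 6, 10\}$, 3 replications; study 3 at
$n = 4000$ with 4 (floor check) and 3 (log-feature check) replications;
study 4 at $n = 2500$, 3 replications. Epoch budgets scale with the
sample size through `scale_factor`, mirroring how the learning-rate
schedule is tied to the epoch count. Qualitative conclusions at these
scales match the full-scale patterns; the scaled runs cannot, and do not
try to, reproduce figure-level MSE magnitudes, which were never published
as numbers.

## What the generator does and does not emulate

The generator covers classical and Box-Cox-structured error with
correlated components, between/within-person variance decompositions
at magnitudes typical of dietary intake data, covariate-driven
intake, and balanced replicates. It deliberately omits systematic
(differential, intake-related) reporting bias, unbalanced replicate counts
(e.g. missing second recalls), serial correlation between adjacent days,
and zero-inflated episodically consumed components. Passing tests
therefore speak to the behaviour of learners under well-behaved classical
error, not to self-report bias correction.

## Reproducibility

Every source of randomness flows from one root seed through
`derive_seed()` sub-streams, so replications, splits and learners do not
perturb one another's draws; identical plans produce byte-identical
results CSVs (`write_results()`), and `run_manifest()` records the plan,
seed and versions alongside them.
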