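---
title: "Partitioning heritability between a polygenic score and family history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning heritability between a polygenic score and family history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopred)
```

## The model

Polygenic risk scores (PRS) summarize the common-variant genetic
predisposition an individual carries, but they miss rare pathogenic
variants, unmeasured common variants, non-additive and interaction effects,
and heritable familial exposures. Family history is an indirect readout of
exactly that missing genetic signal. `triopred` formalizes the combination
of the two with a latent factor model on parent–child trios.

For a z-scored continuous trait, every family member's trait is

$$Y = \alpha P + \beta G + \epsilon,$$

where $P$ is the genetic component captured by the PRS, $G$ is an
orthogonal latent genetic component, both standard normal, and $\epsilon$
is non-genetic residual noise. $\alpha^2$ is the heritability the PRS
captures, $\beta^2$ is the *under-captured heritability*, and
$h^2 = \alpha^2 + \beta^2$ is the total. Both components are transmitted
independently from parents to children, giving parent–child covariance
$1/2$ per component, spousal covariance $0$ (no assortative mating, no
consanguinity), and therefore:

* $\mathrm{Cov}(Y_C, Y_{M/F}) = h^2/2$,
* $\mathrm{Cov}(Y_C, P_C) = \alpha$, $\mathrm{Cov}(Y_{M/F}, P_C) = \alpha/2$,
* mid-parental variance explained
  $\mathrm{Corr}^2\!\big(Y_C, \tfrac{Y_M+Y_F}{2}\big) = \tfrac{(h^2)^2}{2}$.

The last identity is the key to estimation from summary statistics alone:
given a published PRS variance explained $r^2_{PRS}$ and a published
mid-parental variance explained $r^2_{mid}$,

$$\hat\alpha^2 = r^2_{PRS}, \qquad
  \hat\beta^2 = \sqrt{2\, r^2_{mid}} - r^2_{PRS}.$$

```{r}
est <- estimate_beta_sq_from_midparent(r2_prs = 0.367, r2_midparent = 0.449)
round(100 * est$beta_sq, 1)
```

Prediction is the conditional expectation of $Y_C$ under the joint
multivariate normal of $(Y_C, Y_M, Y_F, P_C)$, with the conditioning set
chosen by which parents were measured. Missing parents change the
conditioning set and hence the weights; they are never imputed as zero,
because mean-imputation silently changes the implied weights on the
remaining predictors.

```{r}
p <- est$params
predict_continuous(prs = 1, y_m = 1, y_f = 1, p)
expected_r2_joint(p, "both-parents")
```

## Binary diseases: the logit-link liability model

For a disease $Z$, the same two components act on a latent liability
$H = \alpha P + \beta G \sim N(0, \alpha^2+\beta^2)$ with a logit link:

$$Z \mid H, Q \sim \mathrm{Bernoulli}\big(\mathrm{expit}(\mu_0 + H +
\gamma Q)\big),$$

where $\mu_0$ is the baseline log-odds and $Q$ are measured covariates
(age, sex, ...). The logit link (rather than the probit of classical
liability-threshold models) is deliberate: it lets every parameter be read
off ordinary logistic regressions. $\alpha$ and $\beta$ are log-odds
effects per SD and are not bounded above; their liability-scale
heritability contributions are recovered with
`liability_scale_effect()`, which bridges the logistic and probit scales
via the explicit unit-variance logistic CDF
$F_L(x) = 1/(1+e^{-\pi x/\sqrt 3})$. We use this explicit CDF throughout:
it is the variance-1 member of the logistic family, which is what makes
$\tau^2$ interpretable as a fraction of a unit-variance liability.

Estimation of $\beta$ from summary statistics uses the observed odds
ratios of child disease on maternal and paternal disease history. The
theoretical odds ratio implied by the model is a two-dimensional integral
of Bernoulli kernels against the bivariate normal of child and parent
liabilities (variances $h^2$, covariance $h^2/2$); `triopred` evaluates it
with a tensor Gauss–Hermite rule after a Cholesky transform (64 nodes per
dimension by default — doubling the nodes changes the value by less than
$10^{-10}$ at representative parameters, which the tests check). A
one-dimensional bracketed minimization (Brent's method, bracket $[0, 5]$,
absolute tolerance $10^{-4}$) matches theoretical to observed log odds
ratios. The default objective is $|\Delta_M| + |\Delta_F|$, the sum of
absolute log-OR errors; the signed-sum variant $|\Delta_M + \Delta_F|$ is
available (`objective = "abs_sum"`) but allows the two parents' errors to
cancel, so it is not the default. Maternal and paternal theoretical ORs
differ only through the sex covariate, when one is in the schema.

```{r}
or_obs <- theoretical_parent_child_or(binary_params(-2, 0.3, 0.8))
estimate_beta_line_search(or_obs, or_obs, binary_params(-2, 0.3))$beta
```

### Predicting the child's liability

The joint predictor is $E[H_C \mid Z_M, Z_F, P_C]$. The parental
posteriors $f(H \mid Z)$ have no closed form, so each parent's liability
is integrated out by importance sampling: proposals come from the prior
$N(0, h^2)$ and carry self-normalized weights proportional to the
Bernoulli likelihood — the prior density cancels analytically. Weights are
computed in log space and shifted by their maximum before exponentiation,
so rare diseases (strongly negative $\mu_0$) remain numerically stable.
The effective sample size is reported, and falling below a floor (default
100) sets a flag on the result rather than raising an error. The inner
conditional expectation of $H_C$ given $(H_M, H_F, P_C)$ is linear, so the
predictor reduces to a weighted combination of the two posterior-mean
parental liabilities and the child's PRS, with a Monte-Carlo standard
error from the standard self-normalized importance-sampling variance
estimate (never suppressed).

Two consequences are worth noting:

* **Exact grouping.** Individuals who share the same parental statuses
  (and parental covariates) can share one importance-sample set per
  parent; each individual's own PRS enters only through the linear term.
  `predict_liability_table()` exploits this, so scoring a biobank-sized
  table costs a handful of sample sets, and the grouping is exact, not an
  approximation.
* **Closed-form fallback.** With no parental history the predictor is
  $\alpha\, p_C$ exactly, with no sampling and no Monte-Carlo error.

Parental covariates are generally unobserved. By default a parent is
represented at the covariate reference values (deviation zero, i.e. the
values at which $\mu_0$ is defined), with the sex covariate set by the
parent's role (`parent_reference_q()`). This is a documented convention,
not a claim about the right choice: covariates could equally be set to the
child's values or marginalized, and the functions accept explicit
`q_mother` / `q_father` vectors for either alternative.

## Estimation from individual-level training data

`fit_marginal_binary_models()` replicates the two-regression recipe:
child status on the standardized PRS plus covariates (giving
$\hat\alpha$, $\hat\mu_0$, $\hat\gamma$), and child status on maternal and
paternal history as two independent variables plus covariates (giving the
two observed ORs). Fits are plain maximum-likelihood logistic regressions
(IRLS, deviance tolerance $10^{-8}$, no regularization). Two conventions
had to be fixed where a recipe alone underdetermines them:

* $\hat\mu_0$ is the intercept evaluated at the covariate reference
  vector, taken as the training-sample means (reference level for sex);
  downstream covariates are then deviations from those means.
* The PRS is standardized on the training subset (a flag allows
  standardizing on a full cohort instead).

One caveat is inherent to the recipe: the covariate-adjusted logistic
coefficient of the PRS is a *marginal* effect (the latent $G$ is
integrated out), and odds ratios are non-collapsible, so $\hat\alpha$ is
mildly attenuated relative to the structural $\alpha$ — at
$(\mu_0, \alpha, \beta) = (-2, 0.3, 0.7)$ the attenuation is about 7%,
within the tolerances used in the tests. The implementation follows the
recipe as stated rather than attempting a de-attenuation, because the same
attenuation affects the observed parental ORs and largely cancels in the
line search for $\beta$; the round-trip recovery test quantifies the net
effect.

## The trio simulator

`simulate_continuous_trios()` and `simulate_binary_trios()` generate data
from exactly the generative laws above: parental components iid standard
normal, child components as the mid-parental average plus $N(0, 1/2)$
segregation noise (which realizes the parent–child covariance of $1/2$
without simulating loci — the model is defined on components, not
genotypes), traits with residual variance $1-h^2$, and Bernoulli disease
draws on the logit scale. Latent ground truth is retained behind a flag so
the same fixtures can serve as blind inputs. Default covariates mirror a
middle-aged population cohort loosely (age uniform on 40–69, sex
balanced); they are a plausible fixture, not an estimate of any
particular cohort. An optional `rho_pg` correlation between $P$ and $G$
exists purely as an assumption-violation hook for robustness experiments.

What the simulator deliberately does *not* emulate: assortative mating,
consanguinity, gene–environment interaction, age-dependent onset,
ascertainment, and phenotyping error. Tests passing on simulated trios
therefore validate the mathematics and the implementation, not the model's
adequacy for any real cohort.

## Evaluation metrics

`r2_and_rmse()` reports the squared Pearson correlation and an RMSE
back-transformed to the original measurement scale by per-stratum SDs
(sex-stratified when requested). For diseases, `auroc_auprc()` (Mann–
Whitney AUROC with midranks; step-wise average precision), a
structural-components DeLong paired test, `nri_at_percentiles()` and
`idi()` summarize discrimination and reclassification. Conventions that
the definitions leave open are fixed as follows: percentile cut-offs are
taken on the evaluation sample's own score distribution with "high risk"
meaning strictly above the cut-off value; and since the joint predictor is
a liability, not a probability, the IDI first maps each score to
probabilities by a one-dimensional logistic recalibration (making the IDI
invariant under affine score transforms). A cut-off that empties a risk
class yields a flagged `NA`, not a number.

## Numerical and testing choices

Problem sizes in the test suite were chosen so that statistical assertions
have comfortable power at desk scale: moment checks of the simulator at
$n = 5\times10^5$; population-$R^2$ agreement (empirical vs closed form
within $\pm 0.01$, vs in-sample OLS within $\pm 0.005$) at
$n = 2\times10^5$; binary parameter recovery ($\alpha$ within $\pm 0.03$,
$\beta$ within $\pm 0.05$) at $n = 2\times10^5$; and sampling-vs-quadrature
agreement within 3 Monte-Carlo SEs over a $3\times3\times3$ grid of
$(\mu_0, \alpha, \beta)$ at $L = 10^5$ importance samples (the production
default is $L = 10^6$).

For the directional claim that the joint predictor outranks the PRS alone
(higher AUROC, positive IDI, positive NRI at the 95th percentile on
held-out trios), the evaluation scenario uses a disease with a strong
under-captured familial component, $(\mu_0, \alpha, \beta) =
(-2, 0.3, 1.0)$. At weak familial signal the population NRI at an extreme
cut-off is genuinely near zero — its sign is then a coin flip in any
finite sample, and a directional test would be meaningless; the chosen
scenario is the regime (analogous to the diseases where family history is
known to matter most, such as Alzheimer's disease or COPD) in which the
ordering is a property of the model rather than of a seed.

Other deliberate choices: conditional-expectation weights come from direct
linear solves, never explicit inversion; infeasible summary statistics
(an implied $h^2$ outside $[r^2_{PRS}, 1]$) raise errors instead of being
clamped, with clamping reserved for violations within $10^{-6}$ of a
bound; the line-search objective is deterministic because the quadrature
rule is held fixed across evaluations; and a single seed deterministically
derives the independent maternal and paternal sampling streams.

## Limitations

The orthogonality of $P$ and $G$ and the constancy of $\alpha, \beta$
across generations are assumptions of convenience; strong gene–environment
interaction would correlate the components, and neither correlation nor
interaction is identifiable from summary statistics. Parental disease
history reflects lifetime risk only to the extent the parents have lived
through the risk period — no age-at-onset modelling is attempted. Sibling
and more distant relatives' histories are out of scope, as is the
construction of the PRS itself: `triopred` consumes a PRS as a
standardized column and never touches genotypes.
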