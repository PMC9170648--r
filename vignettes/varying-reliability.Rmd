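---
title: "Testing homogeneous within-person variance and varying reliability"
author: "varwithin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing homogeneous within-person variance and varying reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varwithin)
```

## The problem

Intraclass correlation coefficients are the standard reliability index for
repeated-measures designs.  For single scores,

$$\mathrm{ICC} = \frac{\sigma_0^2}{\sigma_0^2 + \sigma_\epsilon^2},$$

where $\sigma_0^2$ is the between-person variance of the person means and
$\sigma_\epsilon^2$ the within-person (trial-to-trial) variance.  The
formula presumes that one residual variance describes everybody.  In
cognitive tasks — reaction times especially — that presumption is
empirically doubtful: some people respond very consistently, others do not.
If $\sigma_\epsilon^2$ varies between persons, the classical ICC is only an
*average* reliability, and individual reliabilities can differ severalfold.

This package makes the homogeneity presumption testable, and, when it
fails, replaces the single ICC by person-specific ones.

## The model

The mixed-effects location-scale model (MELSM) couples two sub-models.  For
person $i$ and trial $j$,

$$y_{ij} \sim \mathcal{N}\!\big(\beta_{0i},\, \exp(\eta_{0i})\big),$$

where $\exp(\eta_{0i})$ is the person's residual **variance** (the
exponential keeps it positive; person variances are lognormal).  Both
intercepts are hierarchical, written in the non-centered parameterization:

$$\beta_{0i} = \beta_0 + \tau^{\mu} z^{\mu}_i, \qquad
  \eta_{0i} = \eta_0 + \tau^{\sigma}\big(z^{\mu}_i \rho +
              z^{\sigma}_i \sqrt{1 - \rho^2}\big),$$

with $z^{\mu}_i, z^{\sigma}_i \sim \mathcal{N}(0,1)$.  The Cholesky mixing
of the two latent vectors induces a correlation $\rho$ between location and
scale random effects (the mean–variance relation); $\rho$ carries a
standard normal prior on its Fisher-z transform, so $\rho = \tanh(z_f)$.
Weakly informative priors complete the model: $\beta_0, \eta_0 \sim
\mathcal{N}(0, 1)$ and half-Student-t (df 10, scale 1) priors on both
between-person SDs.

The person-specific reliability is then

$$\mathrm{ICC}_i = \frac{\sigma_0^2}{\sigma_0^2 + \exp(\eta_0 + u_{1i})},
\qquad u_{1i} = \eta_{0i} - \eta_0,$$

which collapses to the classical ICC when every $u_{1i} = 0$ — that is,
when $\tau^{\sigma} = 0$.

### Two spike-and-slab tests

Both tests use a Dirac spike: a point mass at exactly zero, against a
diffuse slab, with a latent Bernoulli indicator switching between the two
(the Kuo–Mallick scheme).  The proportion of MCMC draws with the indicator
at 1 estimates the posterior probability of the unrestricted model, and

$$BF_{0u} = \frac{1 - \Pr(\mathcal{M}_u \mid Y)}{\Pr(\mathcal{M}_u \mid Y)}
\bigg/ \frac{1 - \pi}{\pi}$$

converts it into a Bayes factor, correcting for the prior inclusion
probability $\pi$ (equal prior odds at $\pi = 0.5$).

* **Common-variance test** (`model_variant = "pick_group"`): the spike sits
  on $\tau^{\sigma}$ itself, $\tau^{\sigma}_* = \delta\,\tau^{\sigma}$.
  $\delta = 0$ is the common-variance model; $\delta = 1$ the unrestricted
  one.
* **Membership model** (`"membership"`): $\tau^{\sigma}$ stays in the
  model and each person gets their own indicator,
  $\eta_{0i} = \eta_0 + \tau^{\sigma}(\delta_i \cdot \lambda_i)$ with
  $\lambda_i = z^{\mu}_i \rho + z^{\sigma}_i\sqrt{1-\rho^2}$.  A person
  with $\delta_i = 0$ sits exactly at the average within-person variance,
  so $\Pr(\delta_i = 0 \mid Y)$ is their posterior probability of belonging
  to the common-variance (common-ICC) model.

A design note on the prior for $\eta_0$: its normal(0, 1) prior on the
log-variance scale mirrors the prior on $\beta_0$.  Both assume the outcome
lives on a scale where values of order one are plausible — seconds for
reaction times, or standardized scores.  Milliseconds do not qualify; the
command-line interface has a `--units ms` flag that rescales on input, and
`prior_spec()` exposes every location and scale.

## Sampling

The sampler is a bespoke Metropolis-within-Gibbs chain written in C++:

* every scalar (and every latent $z$ element) gets an adaptive random-walk
  proposal targeting 44% acceptance; step sizes adapt in batches of 50
  iterations during burn-in only, so retained draws come from a
  fixed-kernel Markov chain;
* $\beta_0$ uses its exact conjugate normal draw;
* indicators are drawn from their exact Bernoulli full conditionals —
  $\Pr(\delta = 1 \mid \text{rest}) \propto \pi L(\delta = 1)$ against
  $(1-\pi) L(\delta = 0)$, with the full-data likelihood for the global
  test and person $i$'s likelihood for the membership test;
* while an indicator is 0, the parameters it gates ($\tau^{\sigma}$,
  $z_f$, the $z^{\sigma}_i$) have full conditionals equal to their priors
  and are refreshed by direct prior draws, which is what lets the chain
  jump back into the slab.  No pseudo-priors are used.

Defaults are 20,000 iterations with 5,000 burn-in and four chains, which
gives stable posterior model probabilities on data of the size typical for
cognitive tasks (tens of persons, hundreds of trials).  One master seed
deterministically derives per-chain streams.  Numerical guards: $\eta_{0i}$
is clamped at $\pm 30$ inside exponentials (values beyond that are
astronomically improbable under the priors), initialization uses the grand
mean, the log pooled within-person variance, prior medians for the SDs and
small latent perturbations, with bounded retries should the log posterior
be non-finite, and constant data are rejected outright.

`diagnostics()` reports split R-hat, effective sample sizes (via `coda`),
acceptance rates, and — specific to transdimensional chains — the number of
indicator switches: a chain whose indicator never moves only bounds the
model probability, and is flagged.

When a probability estimate is exactly 0 or 1 the Bayes factor is infinite;
the package reports `Inf` together with the finite evidential bound
`BF > S` that $S$ draws can support.

## Synthetic data

`simulate_melsm()` draws data with exactly the model's structure: bivariate
normal random effects with SDs $\tau^{\mu}, \tau^{\sigma}$ and correlation
$\rho$, normal outcomes with lognormal person variances, and optionally a
`member_fraction` share of persons whose $u_{1i}$ is forced to exactly
zero (the membership regime).  The defaults — $\beta_0 = 0.7$ s,
$\eta_0 = -3.2$, $\tau^{\mu} = 0.1$, $\tau^{\sigma} = 0.4$, $\rho = 0.3$ —
mimic a classical Stroop task in seconds: mean reaction times around
0.5–1 s, person SDs roughly 0.09–0.3 s, and an average ICC near 0.2.

What the generator does *not* emulate: sequential dependence between
trials, condition effects (congruent/incongruent contrasts), response
accuracy processes, and the right-skewed ex-Gaussian shape of real reaction
times.  Passing tests on synthetic data therefore validate the estimation
machinery under the model's own assumptions, not robustness to the ways
real reaction-time data violate normality.

`clean_rt()` applies the usual reaction-time screen: trials below 0.2 s or
above 2 s are removed.  The wording of the rule is strict inequalities, so
boundary values are retained by default (`strict = FALSE` drops them), and
`require_correct` restricts to correct responses.

## Analysis layer

`model_evidence()` turns indicator draws into posterior model
probabilities, Bayes factors and Monte Carlo standard errors (binomial
error on the effective sample size of the indicator chain).
`icc_summary()` computes, per retained draw, the common ICC and every
person's varying ICC, and summarizes them by posterior means and
equal-tailed credible intervals (90% by default, configurable); persons
whose interval excludes the common-ICC posterior mean are flagged.  Fold
ratios (max/min of the posterior-mean person SDs, their squares on the
variance scale, and of the person ICCs) summarize the spread; they use
posterior means because that is how such spreads are usually quoted from
plotted point estimates.

`classify_members()` offers three decision rules: the prior-odds-corrected
Bayes factor with the customary symmetric band at 3 ("positive evidence";
the band is symmetric so that `common`, `varying` and `undecided` partition
the sample coherently), raw posterior odds with the same band, and the
median-probability rule ($\Pr > 0.5$, no undecided class).  Multiplicity in
the membership model is controlled, if desired, by lowering $\pi$ rather
than by any automatic correction.

`sensitivity_grid()` refits the membership model over a grid of prior
model probabilities $\Pr(\mathcal{M}_0) = 1 - \pi$ crossed with slab
scales, classifying each cell by posterior odds.  The grid exposes both the
half-t scale and its degrees of freedom; varying the *scale* (1–3) is the
sensible diffuseness knob at fixed df 10, since a larger slab scale is what
makes jumps into the slab harder and thereby favours the spike.

## Validation design and problem sizes

The test suite validates the sampler against independent oracles rather
than against itself:

* a two-person instance with all parameters but $\eta_0$ and $\delta$ held
  fixed, compared to deterministic quadrature of the joint over a fine
  grid;
* the reduced single-variance model, compared to the closed-form conjugate
  posterior of the mean;
* prior recovery with the likelihood switched off (indicator frequency
  $\approx \pi$, standard normal moments for $\beta_0$, half-t moments for
  $\tau^{\sigma}$ from numerical integration);
* an independent JAGS fit of the identical model on a small data set;
* calibration under the null ($\tau^{\sigma} = 0$: median $BF_{0u} > 1$
  over 20 replicates at $n = 40$, $J = 100$), power under heterogeneity
  ($\tau^{\sigma} = 0.5$: $\Pr(\mathcal{M}_u \mid Y) \ge 0.95$ in at least
  90% of replicates), and parameter recovery at $n = 100$, $J = 200$.

These runs use 3,000–12,000 iterations per chain with two chains — the
compiled sampler makes a full replicate battery a matter of seconds — and
the vignette-level defaults remain the longer chains quoted above.

One validation deserves its own note.  The membership model's ordering
property — persons with larger true $|u_{1i}|$ should have larger
posterior inclusion probabilities — is checked by rank correlation at
$n = 50$, $J = 200$.  Two regimes make that rank correlation
uninformative about the sampler.  With *no* true members, nothing anchors
the spike: $\eta_0$ drifts toward the densest cluster of person variances
(a genuine feature of the posterior, reproducible across sampler seeds),
and deviations are measured from the drifted value rather than the
generating one.  With *half* the sample as true members, the 25 exact
ties at $|u_{1i}| = 0$ cap the attainable Spearman correlation well below
one regardless of estimation quality.  The check therefore uses a mixture
with a 30% member share — enough mass at zero to anchor the spike, few
enough ties to leave the ranking informative — and takes the median over
five replicate data sets, because at $J = 200$ trials the rank correlation
between empirical person variances and the truth itself fluctuates around
0.85 from one data set to the next: single-dataset luck, not sampler
quality, is what a lone replicate would measure.

## Limitations

* The likelihood is normal; heavy-tailed or skewed outcomes are modeled
  only through their variance.  Within-person variability and measurement
  error are not separated.
* The scale sub-model carries no covariates; heterogeneity can be tested
  but not yet explained.
* Only single-score reliability is computed; average-score variants and
  between-group ICC comparisons are out of scope.
* Bayes factors here come from indicator frequencies, so their resolution
  is bounded by the draw count; decisive evidence is reported as a bound,
  not a number.
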