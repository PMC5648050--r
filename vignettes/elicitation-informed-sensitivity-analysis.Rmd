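---
title: "Elicitation-informed pattern-mixture sensitivity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elicitation-informed pattern-mixture sensitivity analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitpmm)
```

## The problem

Patient-reported quality-of-life (QoL) outcomes in randomised trials are
routinely missing, and the standard missing-at-random (MAR) analysis rests
on an untestable assumption: that responders and non-responders with the
same observed characteristics have the same outcome distribution. When
missingness plausibly depends on unobserved health — sicker patients
return fewer questionnaires — the data are missing not at random (MNAR)
and every analysis requires an external input about the non-responders.
`elicitpmm` supplies that input from structured expert elicitation and
propagates it, with its uncertainty, into the treatment-effect estimate.

## Pattern-mixture model

For arm $a \in \{O, E\}$ (control/open and treatment/endovascular roles;
any two-arm trial with a continuous utility outcome fits), write
$\mu_a$ for the responder mean, $\pi_a$ for the missing proportion, and
$\delta_a$ for the offset of the non-responder mean from the responder
mean. The arm mean is $\mu_a + \pi_a\delta_a$ and the estimand is

$$\Delta = (\mu_E + \pi_E\delta_E) - (\mu_O + \pi_O\delta_O).$$

The moment estimator (`moment_estimate()`) plugs in the responder means
and a mean/SD specification for each $\delta_a$; under independence

$$V(\Delta) = V(\mu_E) + \pi_E^2 V(\delta_E) + V(\mu_O) + \pi_O^2 V(\delta_O),$$

with an equal-tailed normal interval. `moment_estimate_pooled()` uses the
mixture moments of a pooled prior and adds the covariance cross-term
$-2\pi_E\pi_O\,\mathrm{cov}(\delta_E,\delta_O)$, reducing to the
independence formula when the pooled covariance is zero. Setting both
$\delta_a$ to point masses gives the fixed-$\delta$ analyses: zero for
MAR-style observed-data estimates, a grid of values for tipping-point
scans (`tipping_point_scan()`), which report where the confidence interval
first excludes zero and where the estimate reaches the minimum clinically
important difference (MCID).

The crucial structural fact is that $\delta_O,\delta_E$ do not enter the
observed-data likelihood: the data cannot update them. Their posterior
equals their prior, which is why eliciting that prior carefully is the
whole game, and why the test suite checks the prior/posterior equality
explicitly rather than treating it as a bug.

## Elicitation scale and anchors

Experts answer on the EQ-5D utility scale multiplied by 100, bounded to
$[-20, 100]$ — whole numbers are easier to manipulate on a slider than
utilities to two decimals. Each arm's question is anchored by the score of
a typical *responder* in that arm (`anchor_scores()`); the sensitivity
parameter is the elicited non-responder score minus the same-arm anchor,
divided by 100 (`to_delta()`). The direction (non-responder minus
responder) matters: negative offsets mean the experts believe
non-responders fare worse. Anchors are deliberately required configuration
with no default — they are trial-specific observed quantities, and a wrong
anchor silently shifts every prior.

Elicited distributions are normal and are used **untruncated** even though
the scale is bounded. The package fits no truncation because the elicited
normals are a modelling convenience the experts endorsed; instead
`build_expert_prior()` warns when more than 5% of a marginal's mass falls
outside $[-1.2, 1]$ on the utility scale, and `validate_response()` flags
(but does not reject) near-total-uncertainty answers, by default SD > 40
scale units — a normal that wide is effectively flat on a 120-unit scale.
Dropping such responses is an explicit, logged analyst action
(`filter_high_uncertainty()`), never a silent default, mirroring the
practice of reporting excluded experts.

## From three answers to a bivariate prior

The third question — the treatment-arm score *given* a stated control-arm
score — identifies the correlation $\rho$ between the two offsets. If the
expert's joint belief were exactly bivariate normal, the conditional at
conditioning point $v$ would have mean
$m_E + \rho\,(s_E/s_O)(v - m_O)$ and SD $s_E\sqrt{1-\rho^2}$, giving two
estimators:

- **mean-shift** (default): $\rho$ from the location shift of the
  conditional. This uses the quantity the question most directly elicits
  (a most-likely value), and is exact whenever the three answers are
  mutually consistent.
- **sd-ratio**: $|\rho| = \sqrt{1 - (s_{cond}/s_E)^2}$ from the variance
  deflation, signed by the mean-shift direction (or an explicit hint).
  Retained as a robustness check; uncertainty judgements are elicited
  less reliably than locations, so it is not the default.

Real experts are not perfectly coherent, so the estimators can disagree or
leave $[-1,1]$; values are clamped with a warning, a conditional SD above
the marginal maps to $\rho = 0$ with a warning, and conditioning exactly
at the marginal mean is rejected as uninformative. A categorical
correlation answer ("positive/zero/negative"), when recorded, overrides
the derived value only under `respect_categorical = TRUE`; the default
trusts the quantitative answer because the categorical question is coarser.

## Pooling and the community of priors

Individual priors are combined by equal-weight linear pooling
(`linear_pool()`): the panel prior is the finite mixture
$\sum_k w_k\,\mathrm{BVN}(\mu_k,\Sigma_k)$, not a single refitted normal.
Equal weights are a deliberate neutrality choice — no performance-based
scoring of experts is attempted. Mixture moments, sampling, and marginal
densities are exact (`pool_moments()`, `sample_pool()`,
`dpool_marginal()`).

Sensitivity of the conclusion to the diversity of opinion is explored with
a community of priors (`community_of_priors()`): the full panel, the
doctor and nurse subgroups, and the two extreme individuals. The extremes
are defined operationally — the experts minimising/maximising the prior
mean of the elicited treatment-arm minus control-arm non-responder
difference ($m_E - m_O$; a shared anchor gap adds a constant and cannot
reorder experts). The selection rule is overridable by explicit expert id,
since a panel could reasonably define "sceptical" differently (e.g. by an
exceedance probability).

## The Bayesian model

Observed outcomes in arm $a$ are modelled as
$y_i \sim N(\mu_a + x_i^\top\gamma_a,\ \sigma_a^2)$ with weak priors:
$\mu_a, \gamma_a \sim N(0, 10^2)$ (effectively flat on a utility scale)
and $\sigma_a \sim U(0, 5)$. Arm-specific residual SDs are the default —
the arms differ clinically — and covariates, when requested, are centred
on their overall mean so the intercept is the covariate-adjusted arm mean.
$(\delta_O,\delta_E)$ are drawn from the pooled mixture via a latent
component indicator. The missing proportions $\pi_a$ default to plug-in
values, matching the closed-form variance formula, which carries no
$V(\pi)$ term; `pi_mode = "beta_binomial"` gives them Beta(1,1) priors
when the analyst wants that uncertainty propagated. $\Delta$ is computed
per draw.

Because $\delta$ never enters the likelihood, the posterior factorises
exactly: $p(\mu,\sigma \mid y)\,p(\delta)\,p(\pi \mid \text{counts})$.
The sampler exploits this. With summary-level input
($\hat\mu_a \sim N(\mu_a, se_a^2)$, $se_a$ known) the $\mu_a$ posterior is
conjugate normal and all draws are independent. With patient-level data a
per-arm Gibbs sampler alternates the conjugate normal draw of
$(\mu_a,\gamma_a)$ with a truncated inverse-gamma draw of $\sigma_a^2$
implied by the uniform prior on $\sigma_a$. Draws are organised into
chains (default 4 × 2000 kept, 2000 warm-up for the Gibbs case) purely so
that split-$\hat R$ and autocorrelation-based effective sample size are
computed for every monitored parameter; reporting is refused when any
split-$\hat R$ exceeds 1.05 unless forced. For this model the diagnostics
sit at $\hat R \approx 1$ by construction — they are cheap insurance for
future model extensions (and they do trigger on artificial divergent
chains, as the tests verify).

Credible intervals are equal-tailed 2.5/97.5 percentiles: with mixture
priors the $\Delta$ posterior can be multimodal, where highest-density
regions would be disconnected and harder to report. Display rounding is 3
decimals; the worked-example comparisons use 2, as printed sources do.

`mar_fit()` is exactly `bayesian_fit()` with both offsets fixed at zero,
and the complete-case variant additionally sets $\pi_a = 0$; keeping one
code path makes the comparators definitional rather than reimplementations.

## Synthetic data: what it emulates, and what it does not

`generate_trial()` draws normal outcomes per arm and imposes missingness
with probability $\mathrm{logit}^{-1}(a + b\,y)$ — the canonical
"poor health reduces response" MNAR mechanism ($b<0$). Defaults are chosen
to emulate the motivating aneurysm-repair setting at 3 months: responder
means 0.69/0.76, outcome SD 0.3 (so 200 patients per arm give responder
SEs near 0.02–0.03), and intercepts giving missing proportions near
0.24/0.18, about 21% overall. The true $\delta_a$ implied by a
configuration is computed by numerical integration (`truth_delta()`), not
stored approximately, so tests have a sharp target; a covariate-driven
(MAR) variant and an MCAR variant exist to validate the comparators.

`generate_panel()` draws each expert's belief as an exact bivariate
normal around panel-level true offsets (defaults: $-0.04$ and $-0.01$,
elicited-uncertainty SD 0.16, across-expert spread 0.16, moderate positive
correlation 0.3, and a 35% nurse / 65% doctor role mix — the magnitudes of
a real elicited panel) and emits the three implied answers on the bounded
scale. Two realism constraints interact: beliefs are drawn on an unbounded
scale but a slider cannot record off-scale modes, so modes are clamped to
$[-20, 100]$ (with a warning) and the clamped value becomes the expert's
generating belief; and the conditioning point is placed about one marginal
SD from the mode *towards the interior*, shortened until both it and the
conditional mode fit on scale. Within those constraints the construction
is exactly invertible: `build_expert_prior()` recovers every generating
prior to numerical round-off, which is the backbone of the round-trip
tests.

What passing tests on these generators does **not** show: real experts
are not internally coherent bivariate normals, real elicited
distributions may be skewed or multimodal, real missingness is not
exactly logistic in the outcome, and real outcomes (EQ-5D utilities) are
bounded and lumpy rather than normal. The generators validate the
machinery — transforms, pooling algebra, propagation, calibration under a
correctly specified prior — not the substantive accuracy of any particular
panel's beliefs.

## Numerical choices and degenerate inputs

- Point-mass priors (SD 0) are admitted throughout so fixed-$\delta$
  analyses share the mixture machinery; a zero marginal SD forces the
  corresponding correlation to zero, keeping covariance matrices PSD.
- Pool weights must sum to 1 within $10^{-12}$; mixture covariance is
  symmetrised before eigen checks.
- Constant draw vectors produce a single saturated density-strip cell
  rather than a kernel-density failure; strips are max-normalised so the
  modal cell has intensity exactly 1.
- Bivariate sampling uses the explicit 2×2 Cholesky form
  $(z_1,\ \rho z_1 + \sqrt{1-\rho^2}\,z_2)$, valid for $|\rho| = 1$ and
  zero SDs.
- Seeded helpers (`sample_pool()`, generators, fits) restore the caller's
  RNG state, so embedding them in a larger simulation does not perturb its
  stream.

## Problem sizes used in the checks

The shipped checks run at deliberately modest scale: mixture-moment
Monte Carlo at $10^6$ draws, distributional equality via two-sample
Kolmogorov–Smirnov at ~8000 draws per side, and frequentist calibration
with 200 replicates of a 400-patient trial (coverage compared against the
binomial 3-SE band around 0.95, with the analysis prior drawn around the
quadrature truth so the model is correctly specified across replicates).
These sizes give standard errors comfortably below the tolerances tested
while keeping the whole suite under a minute of compute.

## Known limitations

- Only normal elicited distributions are supported; skewed or free-form
  beliefs are future work.
- The exceedance probability for an individual extreme expert depends on
  that expert's elicited SD; analyses that instead fix the extreme shift
  as known will give different probabilities.
- Covariate adjustment is a linear term on arm means; interactions and
  subgroup-specific offsets are out of scope.
- One outcome at one time point; longitudinal extensions would need
  time-indexed offsets.
- The Beta-binomial option propagates uncertainty in $\pi_a$ only into
  the Bayesian fit; the closed-form variance deliberately matches the
  independence formula, which treats $\pi_a$ as known.
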