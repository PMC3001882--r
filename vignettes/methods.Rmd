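---
title: "Inferring beliefs and preferences from reaction times: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring beliefs and preferences from reaction times: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decidetime)
```

# The scientific problem

In probabilistic associative-learning tasks, an auditory cue predicts the
category of a subsequent visual stimulus (say, a face or a house) with a
strength that changes over blocks of trials. Subjects asked to categorise
the visual stimulus as quickly as possible get faster as a cue becomes more
predictive. `decidetime` treats this learning-induced speed-up as the
signature of two hidden quantities that differ between people: their
*prior beliefs* about how volatile the cue-outcome association is, and
their *preferences* in the speed-accuracy trade-off. The package simulates
such an observer, derives the reaction times an optimal decision-maker
would produce, and — the main point — inverts that generative chain, so
that observed reaction times yield posterior distributions over the
observer's volatility assumption and loss-function parameters, together
with a free-energy bound on model evidence for comparing competing
perceptual models.

# The observer (perceptual model)

Per trial $k$ of one cue stream, the generative model assumed by the
observer is

$$
u_k \mid x_k \sim \mathcal N(\eta_{x_k}, \sigma_u^2), \qquad
x_k \mid a_k \sim \mathrm{Bernoulli}(s(a_k)),
$$

where $u_k$ is a scalar sensory signal, $x_k \in \{0,1\}$ the category
(face/house), $s(\cdot)$ the logistic sigmoid, and $a_k$ the cue-outcome
association on the logit scale. Two priors on $a_k$ define two observers:

* **static**: $a_k \equiv a \sim \mathcal N(0, \lambda^{-1})$ — the
  association is assumed fixed; $\lambda$ is the prior precision;
* **dynamic**: $a_k = a_{k-1} + \varepsilon_k$,
  $\varepsilon_k \sim \mathcal N(0, \lambda^{-1})$ — a Gaussian random
  walk; $1/\lambda$ is the assumed volatility.

$\eta_{0,1}$ and $\sigma_u$ are treated as known to the subject (the
categories are over-learned natural objects); the defaults
$\eta = \mp 1$, $\sigma_u = 0.5$ give a discrimination ratio
$|\eta_1 - \eta_0| / \sigma_u = 4$.

## Recognition

Recognition (belief updating) is a sequential mean-field scheme: the
trial-$k$ posterior is factorised as
$q(x_k)\,q(a_k) = \mathrm{Bernoulli}(\mu_x)\,\mathcal N(\mu_a,
\sigma^2_a)$, with the previous posterior (plus diffusion, for the dynamic
model) as prior. Because
$\log p(x\mid a) = x a - \log(1 + e^a)$, the optimal Bernoulli factor has
log-odds equal to the sensory log-likelihood ratio plus $\mathbb E_q[a]$.
For the Gaussian factor the package matches the first two moments of the
*tilted* density

$$
\tilde p(a) \propto \mathcal N(a; m, V)\, e^{\mu_x a - \log(1+e^a)},
$$

computed by mode-recentred Gauss–Hermite quadrature (20 nodes). We chose
moment matching over the cheaper Laplace (mode + curvature) rule after
measuring both against dense-grid exact Bayes: the Laplace mean is
systematically biased by up to $\sim$0.1 on the logit scale for prior
variances near 1 (the posterior is a skewed logistic-Gaussian), whereas
the moment-matched factor agrees with the exact posterior mean to better
than 0.01 at high discriminability. The coordinate pair is solved by a
damped fixed-point iteration with a bracketed-bisection fallback on the
monotone map $a \mapsto \mathbb E_{\tilde p}[a]$; when the mean-field
problem is bistable (ambiguous stimulus against a strong prior), the root
with the higher per-trial free energy is taken. This makes the filter
deterministic and convergent for any $\lambda \in e^{[-8, 8]}$.

The pre-stimulus prediction $\xi_k$ (the probability assigned to "house"
before seeing $u_k$) is the Gaussian prior pushed through the sigmoid with
the MacKay variance correction,
$\xi = s\!\big(m / \sqrt{1 + \pi V / 8}\big)$.

The per-trial perceptual free energy (reported in recognition traces) is
the standard variational bound — expected log-joint plus entropies — with
$\mathbb E_q[\log(1+e^a)]$ evaluated by the same quadrature, so the bound
property against grid-quadrature evidence holds to quadrature accuracy
(tested on randomized instances).

Two structural facts worth noting, both covered by tests: the static
model's posterior variance decreases monotonically in $k$ (the observer
becomes incorrigible), while the dynamic model's is floored by the
volatility; and at convergence the dynamic update reduces to a
Rescorla–Wagner rule, $\Delta\mu_a \propto (\mu_x - \xi)$, whose effective
learning rate is a decreasing function of $\lambda$.

## What the oracle comparisons do and do not show

The grid-Bayes comparisons are run at discrimination ratio 8 (clearly
separated categories). At the default ratio 4 a few percent of sensory
samples fall on the wrong side of the category midpoint; on such trials
the exact posterior over $a$ is a mixture over category assignments that
*no* mean-field scheme can represent, and the deviation of $\mu_a$ from
the exact mean can reach $\sim$0.1. This is a property of the model class,
not of the implementation; the high-discriminability tests isolate
implementation correctness.

# From beliefs to reaction times (response model)

The loss of choosing category $y$ at peristimulus time $t$ when the truth
is $x$ is $\ell = \mathbf 1[y \neq x] + \beta_e t$: one unit per error,
$\beta_e$ per second of deliberation ($\beta_e$ is literally the error
rate a subject will trade for a one-second delay). Within a trial, the
belief relaxes exponentially from $\xi$ to its converged value $\mu_x$ at
rate $\beta_s$ (the sensitivity to the post-hoc prediction error
$\delta\mu = \mu_x - \xi$). The resulting posterior risk, up to terms
constant in $t$, is

$$
\rho(t) = \tilde\delta\, e^{-\beta_s t} + \beta_e\, t ,
$$

with $\tilde\delta$ the prediction-error magnitude signed for the chosen
category. For $\tilde\delta > 0$ the risk is convex and minimised at

$$
t^\* = \max\!\left(0, \frac{1}{\beta_s}
        \log\frac{\beta_s \tilde\delta}{\beta_e}\right),
$$

which is affine in $\log|\delta\mu|$ (a Hick-law-like form). When the
prediction error carries the categorisation-error sign
($\tilde\delta \le 0$), the optimal decision time is zero: a wrong
expectation plus delay cost makes immediate (possibly wrong) responding
optimal. Observed reaction times are $y_k = t^\*_k + \epsilon_k$ with
i.i.d. Gaussian noise of precision $\phi$; error trials in real data are
given reaction time zero and weight $10^{-8}$, which removes them from the
likelihood without disturbing the learning trajectory.

The closed form is pinned by a dense-grid minimisation oracle in the test
suite (agreement to $10^{-3}$ s over 200 random configurations).

# Inverting the response model

The experimenter's unknowns are $\theta = (\log\lambda, \log\beta_e,
\log\beta_s)$ (log-normal priors: variance $10^2$ with means 0, except
$\log\lambda$ under the static model where the printed prior mean is 2)
and the noise precision $\phi$. The posterior is approximated by
$q(\theta)\, q(\phi)$ with $q(\theta)$ Gaussian (Laplace) and $q(\phi)$
Gamma, estimated by alternating

1. regularised Gauss–Newton ascent on $\theta$ (Jacobian of the
   nested filter's predicted reaction times by central finite differences,
   step $10^{-4}$; Levenberg damping; a step is accepted only if the free
   energy does not decrease), with the Laplace covariance taken from the
   curvature at the mode, and
2. the conjugate Gamma update of $\phi$ from the weighted residuals
   (including the trace correction for parameter uncertainty).

Two practical devices make this robust, both adopted after observing the
failure modes they prevent. First, *precision annealing*: the first
Gauss–Newton phase holds $\phi$ at its prior mean; releasing the
$\phi$-update too early lets the scheme attribute all misfit to noise and
freeze the parameters at the prior. Second, *informed multi-starts*: the
deterministic starts place $\log\lambda$ on a grid around the prior mean
(the profile over $\log\lambda$ can be multimodal) and set $\log\beta_e$
so that predicted reaction times land in the range of the observed ones —
starting $\beta$ at its prior mean can leave every predicted time clipped
at zero, a plateau with no gradient. The best free energy across starts
wins; ties go to the start closest to the prior mean.

## The noise-precision prior

The printed prior mean for $\phi$ is $10^4\,\mathrm s^{-2}$. We pair it
with a deliberately weak shape (0.01), i.e. a prior that contributes a
negligible pseudo-sample, for two reasons. The priors of this model family
are described as weakly informative, and a Gamma prior with the printed
mean and a variance of $10^6$ would instead contribute one hundred
pseudo-observations of precision $10^4$ — at realistic noise levels
(signal-to-noise around 0 dB, where $\phi$ is of order 1–100) that prior
provably biases the noise precision high by a factor of about 3 and
shrinks every credible interval accordingly: measured 99%-interval
coverage falls to 0.80–0.86. With the weak shape, coverage over simulated
subjects is 0.93–0.97, close to nominal. Both moments remain arguments of
`prior_spec()`.

Belief trajectories are reconstructed at the posterior mode of
$\log\lambda$, with per-trial variance propagated by the delta method
(first-order sensitivity of the sufficient statistics to $\log\lambda$);
the tests verify this against Monte-Carlo propagation within a factor of
two.

# Model comparison

Per subject and cue stream, the free energy is an approximate log model
evidence; differences are approximate log Bayes factors (3 is the
conventional "strong" threshold). Evidences from a subject's cue streams
are summed before group analysis (each cue stream is an independent
replication under the same subject). At the group level a random-effects
scheme places a Dirichlet prior (all ones) on model frequencies and
iterates the standard variational updates; exceedance probabilities use
the Beta closed form for two models and seeded Monte-Carlo otherwise.

# The synthetic task and the Monte-Carlo study

`simulate_session()` emulates the structure of the motivating experiment:
two (by default) interleaved and independent cue streams; blocks of 28–40
trials (lengths uniform); predictive blocks cycling through association
levels 0.9 and 0.7, alternating with chance-level (0.5) blocks; successive
predictive blocks flip the predicted category within a stream, and
even-numbered streams predict the opposite category, so the marginal
outcome frequency is 1/2 by design. The exact probability levels and
session layout of the original experiment are not recoverable, so all of
this is configuration. One master seed drives per-component child streams
(schedule, association path, outcomes, interleaving), so components can be
regenerated independently and sessions are bit-reproducible.

What the generator does *not* emulate: inter-trial-interval jitter,
stimulus-image variability beyond the scalar signal, motor/non-decision
time (an optional constant offset is excluded from inversion by default),
and choice errors (choices are not modelled probabilistically; error
trials enter only through weights). Passing tests on synthetic sessions
therefore demonstrate correctness of the inference machinery under the
model's own assumptions, not fidelity to every property of human data.

The Monte-Carlo harness (`run_mc_cell()`) reproduces the design of the
validation study: series A (static-generated) and B (dynamic-generated),
50 simulated subjects per cell, 100-trial sessions, true log-parameters
uniform within $\pm 2$ of the prior means, reaction-time noise set by a
target SNR ($10\log_{10}$ of the variance ratio; 40, 20, 0 dB), inversion
under both models, and cell summaries of the evidence difference and
log-space SSE. One added condition defines a valid simulated subject: the
deterministic reaction-time series must have a standard deviation of at
least 0.1 s (draws below it are rejected and counted). Parameter draws
violating it produce essentially constant — mostly zero — reaction times;
such subjects are unidentifiable for any method, and empirical
reaction-time series always vary on this scale.

Under these conditions the dynamic series is decisive (the true model wins
every comparison at 40 dB; mean evidence differences of order $10^2$)
while the static series at 0 dB is near-indifferent, reflecting that the
static observer is a limiting case of the dynamic one. At high SNR our
static-series evidence differences are larger than the published ones by
roughly two orders of magnitude; the flip side is that our static
precision parameter is well recovered where the published study reports it
as essentially unidentifiable (log-space SSE of order $10^3$). Both
discrepancies are one structural property: in this implementation the
static $\lambda$ shapes the early-trial predictions and is therefore
identifiable — and not mimicable by the dynamic model — at low noise. The
original sampling intervals are not recoverable, so this regime difference
cannot be resolved further.

## Problem sizes

The default validation workloads are sized for a laptop core: 100
randomized oracle instances per recognition check, 200 for the
reaction-time oracle, 20 recovery sessions at 40 dB, 50
calibration replicates at 0 dB, and 10–50 subjects per Monte-Carlo cell.
All are configuration, not constants of the method.

# Numerical choices, degenerate inputs, limitations

* Fixed-point tolerance $10^{-8}$; posterior variances floored at
  $10^{-8}$; the sigmoid saturates gracefully at $|a| > 30$.
* Ambiguous stimuli at exactly symmetric evidence resolve to
  $\mu_x = \xi$; zero prediction errors yield `NA` learning rates rather
  than exceptions.
* Recognition failures inside the inversion objective are treated as
  rejected optimizer steps, never as crashes.
* Outer-loop convergence: free-energy change below $10^{-4}$, at most 64
  iterations; the recorded free-energy sequence is non-decreasing.
* The Gauss–Newton covariance is a Laplace approximation at a (possibly
  multimodal) mode: interval calibration is good on average but individual
  subjects with bistable recognition landscapes can be overconfident about
  $\log\lambda$.
* Choices and reaction times are not modelled jointly; extending the
  likelihood to the bivariate Bernoulli–Gaussian case is deliberately out
  of scope.
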