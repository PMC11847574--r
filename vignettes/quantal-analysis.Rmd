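---
title: "Quantal analysis by exact grid inference: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis by exact grid inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

## The generative model

Chemical synapses release transmitter from a small number of independent
sites. `synquant` models the amplitude of an evoked postsynaptic response as
the outcome of `n` Bernoulli release trials, each succeeding with
probability `p`, where every successful release contributes an amplitude
drawn from a gamma *uniquantal* distribution with shape $\gamma$ and scale
$\lambda$. The quantal size $q = \gamma\lambda$ is the mean single-site
response, and the uniquantal coefficient of variation is
$v = 1/\sqrt{\gamma}$. A sweep with $j$ successes therefore has amplitude
distributed as the $j$-fold gamma convolution $G(x \mid j\gamma, \lambda)$,
and a failure sweep shows only baseline noise, modeled as a zero-mean
Gaussian whose SD $\epsilon$ is measured directly from the raw recordings
(failure sweeps or a quiet window), not inferred. The observable amplitude
density under condition $k$ is the composite mixture

$$
Q(x \mid k) \;=\; B(0; n, p_k)\, N(x \mid 0, \epsilon)
  \;+\; \sum_{j=1}^{n} B(j; n, p_k)\, G(x \mid j\gamma, \lambda),
$$

with $B$ the binomial pmf. Recording the same connection under several
release-probability conditions (in practice, different extracellular
Ca^2+^ concentrations) is what makes the parameters identifiable: the
per-condition mean response obeys $\mu_k = n\,p_k\,q$, so each condition's
$p_k = \mu_k/(nq)$ is a latent quantity tied to the observed mean, and the
shapes of the amplitude histograms across conditions constrain $n$, $q$ and
$\gamma$ jointly.

Two modeling conventions matter in practice:

* **Sign.** The gamma density lives on the positive axis, so amplitudes are
  analyzed as positive magnitudes; loaders flip the sign of inward currents
  or hyperpolarizing potentials (`sign = -1`). Individual sweeps may still
  be negative - the noise component has full support.
* **Noise enters the mixture only through the failure component.** Success
  components are pure gamma convolutions. The forward simulator, in
  contrast, adds measurement noise to every sweep, which is what a real
  recording does; the small resulting mismatch is one reason the simulator
  is a more honest test bed than data drawn from the likelihood itself.

## The likelihood

For a parameter point $(n, q, \gamma)$ the log-likelihood of an observation
set is

$$
\mathcal{L} \;=\; \sum_{i} \log N(0 \mid 0, \mathrm{s.e.}(x_i))
  \;+\; \sum_{i}\sum_{x \in x_i} \log Q(x \mid k_i),
$$

where the first sum runs over conditions and the per-condition term
$-\log(\mathrm{s.e.}_i\sqrt{2\pi})$ weights conditions by how precisely
their mean response is known (more sweeps, smaller standard error, larger
weight). Because this term depends only on the data, it is constant across
parameter space and cancels in posterior normalization; it is nevertheless
computed and reported as part of the log-likelihood for fidelity to the
method's definition. Standard errors use the unbiased $(m-1)$ sample SD.
All products are accumulated in log space: with dozens to hundreds of
sweeps, direct density products underflow 64-bit floats.

A parameter point whose implied $p_i = \mu_i/(nq)$ falls outside $[0,1]$
for any condition that contributes amplitudes is infeasible and receives
log-likelihood $-\infty$ (zero posterior mass), not an error. Conditions
without amplitudes cannot render a point infeasible - with no sweeps there
is no composite density to evaluate - which is also what makes the
zero-data limit exact: with empty amplitude vectors the likelihood surface
is flat and the posterior reduces to the prior.

## Exact inference on a discrete grid

Only two parameters ($q$ and $\gamma$) are continuous, so instead of
sampling, the posterior is enumerated exactly on a three-dimensional grid
and the Bayes-rule integrals are replaced by sums. Markov-chain approaches
are a poor fit here: the discrete `n` axis breaks differentiability
(ruling out Hamiltonian samplers), and random-walk Metropolis mixes
inefficiently across it. Grid enumeration is deterministic, exact up to
floating-point rounding, and cheap at the default resolution.

Priors follow Jeffreys' rule per parameter: $f(n) \propto 1/n$ (a Zipf
proportionality over the discrete site count), and uniform in $\log q$ and
$\log\gamma$ - hence both continuous axes are sampled log-uniformly,
endpoints inclusive.

Grid supports are set implicitly from the data and two operator ranges:

| Setting | Default | Meaning |
|---|---|---|
| `n_max` | 12 | upper bound of the `n` axis; operator-set. The default covers typical central-synapse site counts and bounds runtime |
| `q_resolution` | 128 | points along $\log q$ |
| `gamma_resolution` | 64 | points along $\log\gamma$ |
| `cv_range` | [0.05, 1.0] | admissible uniquantal CV; $\gamma$ support is $[1/v_{max}^2, 1/v_{min}^2] = [1, 400]$ |
| `p_range` | [0.04, 0.96] | tractable release probabilities; with the observed means, sets the $q$ support to $[\min\mu/(n_{max}\,p_{max}),\ \max\mu/p_{min}]$ |

The $q$ support uses the global minimum and maximum of the condition means
(not per-condition ranges): any $q$ compatible with *some* condition at
*some* feasible $(n, p)$ must lie in this interval, and the feasibility
masking above trims the rest pointwise.

### Numerical choices

* **Offset.** Before exponentiation the log-likelihood is offset by
  $L = -\mathrm{mean}$ of its finite values ($-\infty$ points excluded).
  The normalized posterior is invariant to any constant shift, so an
  additional internal shift by the finite maximum is applied at
  exponentiation; this makes the computation immune to overflow and
  underflow for arbitrarily peaked likelihood surfaces while keeping the
  documented offset semantics (the invariance is tested).
* **Exactness.** The vectorized log-space evaluation is checked against a
  naive per-point Bayes computation (plain density products, no log
  tricks) on grids small enough for direct products; agreement is at the
  level of accumulated rounding, below $10^{-10}$ relative error.
* **Quadrature in validation.** Composite-density mass checks integrate
  piecewise with breakpoints at the mixture-component means $0, q, 2q,
  \dots, nq$; a single adaptive pass over the whole line can step over
  narrow components when $\epsilon \ll q$.

### Estimators

Point estimates are posterior medians (half-quantiles) of the marginals:
for `n`, the smallest value whose cumulative marginal reaches 0.5 - a
deterministic, conservative tie-break consistent with the $1/n$ prior; for
$\log q$ and $\log\gamma$, the median with linear interpolation of the
cumulative mass between grid points, exponentiated. Derived quantities
follow algebraically: $\hat\lambda = \hat q/\hat\gamma$ and
$\hat p_i = \mu_i/(\hat n \hat q)$. A $\hat p_i > 1$ is reported as-is with
a warning flag rather than clipped: it is a diagnostic of model misfit, and
clipping would hide it.

### What recovery tests do and do not show

The validation suite simulates a connection with $n = 5$, $q = 0.1$,
CV $= 0.3$, $\epsilon = 0.02$ at $p = \{0.3, 0.7\}$ with 150 sweeps per
condition and refits it across seeded replicates. Quantal size is recovered
essentially without bias (median error a few percent). The discrete site
count is the hardest parameter: neighboring values of $n$ (with $q$
rescaled along $\mu = npq$) produce composite densities that differ only
subtly, so at this recording size the posterior over $n$ is genuinely
spread over 2-3 adjacent values and the exact-hit rate of the median sits
near one half, recovering the truth within $\pm 1$ essentially always.
This is a property of the information in the data, not of the inference:
the same pipeline concentrates the posterior on the true $n$ as sweep
counts grow, and the posterior itself (its spread across $n$) is the
honest report of that uncertainty. Users comparing site counts between
groups should compare posteriors or use many sweeps per condition, not
single point estimates from short recordings.

## The forward simulator

`simulate_observations()` samples the generative process directly: binomial
release counts, gamma quantal sums, Gaussian noise on every sweep. It
reproduces the study conditions used throughout validation (two to three
Ca^2+^-like conditions, tens to hundreds of sweeps, noise an order of
magnitude below the multi-quantal response). The returned observation set
carries either the true $\epsilon$ (`known` mode) or an SD estimated from
simulated failure sweeps (`estimated` mode). `simulate_event_train()`
builds trace fixtures for the event detector: unit-peak
difference-of-exponentials kernels (defaults 0.3 ms rise, 3 ms decay, the
scale of glycinergic IPSCs) at Poisson times, plus white Gaussian noise,
with ground-truth times and amplitudes attached.

What the simulator does *not* emulate - and hence what passing tests do not
certify about real recordings: correlated (non-white) noise and baseline
drift, stimulation artifacts in amplitude tables, short-term plasticity
within sweeps, non-uniform per-site release probabilities, intrasite
quantal variance, and series-resistance filtering. The artifact-subtraction
and kinetics code is exercised on synthetic traces with known ground truth
for the same reason.

## Derived electrophysiological measures

These are deliberately small, explicit computations with guarded domains:

* `synaptic_conductance()`: $\sigma = I/(V_{rev} - V_{cell})$; pA and mV in,
  nS out. `scaled_conductance()` expresses $\sigma$ as percent of the
  cell's resting conductance, removing cell-size dependence.
* `corrected_ipsp()`: rescales an IPSP recorded at $V_m$ to its value at
  rest under a linear driving-force model,
  $\mathrm{IPSP}\,(V_{rest}-V_{rev})/(V_m-V_{rev})$.
* `iv_conductance()` fits the I-V line by least squares;
  `recurrent_inhibition_conductance()` is the during-train minus resting
  slope difference, with negative values flagged (warning) rather than
  suppressed.
* `subtract_artifact()` fits a single or double exponential to the artifact
  tail and subtracts its forward extrapolation; the double-exponential fit
  is initialized from the single fit with bounded positive time constants,
  since nonlinear least squares needs a starting point and the single fit
  is always well-posed on a decaying tail. The input trace is never
  modified.
* `response_kinetics()` measures amplitude against a local baseline (mean
  of a 2 ms pre-window by default, configurable) and rise/decay times
  between fractional levels with linear interpolation; 10-90% for evoked
  responses, 20-80% for small spontaneous events where baseline noise makes
  the outer deciles unreliable.
* `onset_latency()` uses the derivative-threshold rule (first post-stimulus
  point where the derivative exceeds 5 baseline-derivative SDs) and signals
  no response with `NA` rather than an error. Jitter comparisons are
  meaningful within a cell only; the package computes per-sweep onsets and
  leaves cross-cell comparisons to the user's judgment.
* `detect_minis()` keeps candidate peaks at least 1.5 baseline-noise SDs
  above the local baseline whose 20-80% rise exceeds 0.1 ms and decay
  exceeds 0.5 ms. The baseline noise SD is supplied by the caller from an
  event-free window - an automatic search would make the detection
  threshold depend on the detector's own output. On white noise at 50 kHz
  the waveform criteria alone reject essentially all threshold crossings
  (false positives well below one per 10 s in the seeded checks).

## Nested-data statistics

Electrophysiology datasets are hierarchical: events within cells within
animals. Treating all events as independent inflates effective sample size
and false-positive rates. The toolkit implements the decision rule used to
route each dataset:

1. `icc_1_1()` estimates the one-way random-effects intraclass correlation
   from ANOVA mean squares,
   $(MS_b - MS_w)/(MS_b + (k-1)\,MS_w)$, the standard Shrout-Fleiss
   ICC(1,1) with the $(k-1)$ denominator; for unbalanced designs $k$ is the
   usual one-way correction $k_0 = (N - \sum n_i^2/N)/(a-1)$. Labels follow
   the conventional cut-points (poor $\le$ 0.50 < moderate $\le$ 0.75 <
   good $\le$ 0.90 < excellent).
2. `choose_analysis_path()`: ICC $\le$ 0.50 - most variance is within
   units - treat observations as independent (`bootstrap_effect()`); ICC >
   0.50 with $\ge$ 20 observations per unit - `hierarchical_bootstrap_effect()`;
   ICC > 0.50 with few observations per unit - a linear mixed model is
   recommended (routing only; fitting an LMM is out of scope, any standard
   fitter applies).
3. Effect sizes are the bootstrapped mean difference (absolute units) and
   Hedges' *g* (pooled-SD standardized, case minus control), 10,000
   replicas by default, with percentile 95% CIs; a comparison is flagged
   "meaningful" when the CI excludes 0. Percentile (not BCa) intervals are
   used because the reported objects are the plain resampling
   distributions. Replicas with zero pooled SD leave *g* undefined; they
   are dropped and counted rather than raised, since degenerate resamples
   are expected for small coarse-valued samples. A `paired` flag resamples
   index pairs for within-cell comparisons such as latency/jitter.
4. The hierarchical bootstrap resamples units with replacement (at the
   group's unit count), then `k` events per sampled unit (`k` = the maximum
   events-per-unit in that group), giving every unit equal expected weight
   regardless of its event count.

## Problem sizes in the validation suite

The suite favors exact small fixtures (hand-built ANOVA tables, planted
event traces, closed-form kinetics) plus seeded simulations sized to run
comfortably on one CPU: oracle-equivalence on a 4 x 16 x 8 grid with 50
sweeps; moment identities at 5,000 sweeps; the recovery study at 20
replicates of the full 128 x 64 grid with `n_max = 10`; bootstrap CI
coverage at 200 outer replications of 1,000 replicas. These sizes are the
package's validation choices and are stated here so they can be scaled up
by anyone wanting tighter Monte Carlo error.

## Known limitations

* The uniquantal family is gamma only; Gaussian or log-normal alternatives
  and model comparison across families are out of scope.
* All release sites share one `p` per condition; site heterogeneity maps
  into the estimated CV.
* The composite model omits noise on success components (see above); with
  $\epsilon$ well below $q$ this is negligible, but quantal analysis of
  very low signal-to-noise recordings should expect some upward bias in
  the estimated uniquantal CV.
* `n` point estimates from short recordings are coarse (see the recovery
  discussion); the marginal posterior is the better report.
* The event detector is a threshold-plus-waveform rule on the raw trace;
  it does not template-match or deconvolve overlapping events closer than
  its refractory setting.
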