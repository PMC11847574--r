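# synquant

Bayesian quantal analysis and nested-data statistics for synaptic
electrophysiology.

## The problem

How many release sites does a synaptic connection have, how large is the
response to a single released vesicle, and how likely is each site to
release? These quantal parameters cannot be read off a single amplitude
histogram, but they become identifiable when the same connection is
recorded under several release-probability conditions (e.g. different
extracellular Ca²⁺ concentrations). `synquant` is for electrophysiologists
who have such amplitude tables — and for anyone validating quantal-analysis
methodology on simulated data.

The core model: an evoked amplitude is the outcome of `n` independent
Bernoulli release trials with per-site probability `p`, each success
contributing a gamma-distributed uniquantal amplitude with shape γ and
scale λ (quantal size `q = γλ`, uniquantal CV `v = 1/√γ`). With baseline
noise SD ε measured from the raw data, the composite amplitude density
under condition `k` is

    Q(x | k) = B(0; n, pₖ) · N(x | 0, ε) + Σⱼ₌₁..ₙ B(j; n, pₖ) · G(x | jγ, λ)

and each condition's release probability is tied to its observed mean
response through μₖ = n·pₖ·q. Inference is exact: the posterior over
`(n, log q, log γ)` is enumerated on a discrete grid (Zipf prior 1/n over
`n`, log-uniform priors for `q` and γ), marginalized by summation, and
summarized by posterior medians. No sampling, no tuning, fully
deterministic.

Around the core, the package provides the measures that accompany quantal
experiments — synaptic and recurrent-inhibition conductances, driving-force
IPSP correction, stimulus-artifact subtraction, 10–90%/20–80% kinetics,
onset latency, paired-pulse ratio, miniature-event detection — plus a
statistics toolkit for nested data: ICC(1,1), bootstrapped mean difference
and Hedges' *g*, a two-level hierarchical bootstrap, and the rule that
routes a dataset to the right analysis. A forward simulator of the
binomial–gamma model makes everything testable with known ground truth.

## Worked example

Simulate a connection with 5 release sites, quantal size 0.1 mV,
uniquantal CV 0.3 and 0.02 mV baseline noise, recorded at two release
probabilities (150 sweeps each), then recover the parameters:

```r
library(synquant)

truth  <- quantal_params(n = 5, q = 0.1, cv = 0.3)
design <- simulation_design(truth, condition_ps = c(0.3, 0.7),
                            sweeps_per_condition = 150,
                            noise_sd = 0.02, seed = 42)
obs <- simulate_observations(design)
obs
#> Observation set: 2 condition(s), noise SD 0.02
#>  condition sweeps   mean       se
#>          1    150 0.1532 0.008654
#>          2    150 0.3574 0.009547

fit <- fit_bqa(obs, grid_spec(n_max = 10))
fit
#> Quantal parameter estimates (posterior medians)
#>   release sites n : 5
#>   quantal size q  : 0.09186
#>   gamma shape     : 7.774  (CV 0.359, scale lambda 0.01182)
#>   release probability per condition:
#>     p[1] = 0.3336
#>     p[2] = 0.7781
#>   grid: n_max 10, 128 x 64 (log q x log gamma)
```

The fit recovers the planted site count, a quantal size within ~8% of
truth, and release probabilities close to the simulated 0.3 and 0.7. The
full marginal posteriors are in `fit$estimates$marginals`; on short
recordings the marginal over `n` is the honest report of site-count
uncertainty (see the vignette).

Nested-data statistics follow the same pattern:

```r
r <- icc_1_1(group_sample(c(1, 2, 1.5, 5, 6, 5.5, 2, 3, 2.5),
                          group = "WT",
                          unit_id = rep(c("c1", "c2", "c3"), each = 3)))
r
#> ICC(1,1) = 0.9444  [excellent reliability]
#>   MS between 13, MS within 0.25, k 3 (3 units, 9 obs)
choose_analysis_path(r, min_obs_per_unit = 3)
#> [1] "lmm_recommended"
```

Most of the variance here lies between cells, and with only 3 observations
per cell a hierarchical bootstrap would resample too thinly, so the router
recommends a mixed model.

A thin command-line wrapper over the same functions lives at
`inst/cli/synquant.R` (subcommands `bqa`, `simulate`, `measure`, `stats`).

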