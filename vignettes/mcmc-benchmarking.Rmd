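---
title: "Benchmarking MCMC samplers for ODE-constrained Bayesian estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking MCMC samplers for ODE-constrained Bayesian estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

mcmcbench targets Bayesian parameter estimation for ordinary differential
equation (ODE) models of the kind used throughout systems biology. A model
is

$$\dot{x} = f(x, t, \eta), \qquad x(t_0) = x_0(\eta),$$

with states $x \in \mathbb{R}^{n_x}$ and dynamic parameters $\eta$.
Measurements observe $y = h(x, t, \eta)$ at $n_t$ time points under
independent additive Gaussian noise with per-observable standard
deviations $\sigma_i$, which are themselves unknown, so the full parameter
vector is $\theta = (\eta, \sigma)$. With a uniform box prior
$[\theta_{\min}, \theta_{\max}]$ the unnormalized log-posterior is the
Gaussian log-likelihood

$$\log p(\mathcal{D} \mid \theta) = \sum_{i=1}^{n_y} \sum_{k=1}^{n_t}
  \left[ -\log\!\big(\sigma_i \sqrt{2\pi}\big)
         - \frac{(\tilde{y}_{ik} - y_i(t_k))^2}{2\sigma_i^2} \right]$$

inside the box and $-\infty$ outside. The prior's normalization constant
is dropped throughout (only log-posterior differences enter
Metropolis-Hastings ratios and optimization), so reported values are
comparable within a problem, not across problems. Missing observations are
skipped element-wise. The marginal likelihood is never computed; all
sampling uses the unnormalized posterior.

Posteriors of ODE models are routinely nasty: structural
non-identifiabilities produce exact multi-modality, stopping measurements
before steady state produces banana-shaped tails, and oscillatory or
chaotic dynamics shatter the likelihood into many modes. The package
therefore couples its samplers to a benchmark collection that exhibits
exactly these pathologies, and to an analysis pipeline that measures
whether a sampler actually explored the posterior before crediting it with
effective samples.

# Benchmark collection

Seven estimation problems are built in, each a `benchmark_problem` holding
the model, the prior box, the generating parameters (where defined), and
the measurement design (`n_t` equidistant points, endpoints inclusive).

| name | system | n_theta | posterior character |
|------|--------|---------|----------------------|
| M1a  | mRNA transfection (experimental-data variant) | 5 | bimodal |
| M1b  | mRNA transfection (simulated data) | 5 | bimodal |
| M2   | bistable mass-action switch | 8 | steep rim |
| M3   | saturated growth | 3 | correlated, banana tails |
| M4   | reaction network with supercritical Hopf bifurcation | 11 | weakly multi-modal |
| M5   | driven Van der Pol oscillator | 9 | strongly multi-modal (chaos) |
| M6   | Lorenz attractor | 9 | strongly multi-modal (chaos) |

M1 models transfection with GFP mRNA: $\dot m = -\delta m$,
$\dot G = k_{TL} m - \beta G$, with $m(t_0) = m_0$ and only the protein
$G$ observed. Only the product $k_{TL} m_0$ is identifiable, and the
degradation rates $\beta$ and $\delta$ can be interchanged without
changing $G(t)$, so the posterior has two exactly symmetric modes — the
package's canonical multimodal test case. All M1 parameters are sampled on
the log10 scale; every other problem is sampled on the linear scale.

M1 and M3 have closed-form solutions (for M1,
$G(t) = \frac{k_{TL} m_0}{\delta - \beta} (e^{-\beta (t - t_0)} -
e^{-\delta (t - t_0)})$ for $t \ge t_0$ and $0$ before; for M3,
$x(t) = \frac{b_1}{b_2}(1 - e^{-b_2 t})$). The models declare these
solutions and `simulate_problem()` uses them by default; the test suite
verifies agreement with the numerical integrator to a relative error
below $10^{-6}$ on the full measurement grids. The closed forms also
carry analytic observable sensitivities, which makes gradient-based
optimization and the desk-scale studies fast.

For M2 and M4 the package ships default right-hand sides — Wilhelm's
minimal bistable mass-action system for M2, and a three-species extended
Brusselator-type network (Hopf bifurcation in the recycling rate) for M4.
These defaults are clearly labelled and the `ode_model()` constructor
makes every right-hand side pluggable, so a different published variant
can be substituted without touching anything downstream. M5's periodic
drive enters as $d \cos(x_3)$ with $\dot x_3 = \omega$, an autonomous
embedding of the drive phase whose initial value is the third
initial-state parameter.

Remaining problems integrate numerically with `deSolve::lsoda` at
`rtol = 1e-8`, `atol = 1e-10` (configurable). A solver failure is returned
as a flagged result and consumed downstream as log-posterior $-\infty$ —
never as a silently truncated trajectory.

## Synthetic data

`generate_data()` simulates the model at the generating parameters on the
problem's equidistant grid and adds independent $N(0, \sigma_i^2)$ noise
per observable, reproducibly under a fixed seed. This emulates the noise
model the likelihood assumes — which is the point of a calibrated
benchmark: estimator and generator agree, so failures are attributable to
the sampler, not to model misspecification. Real data differ in ways the
generator deliberately does not emulate: non-Gaussian and
intensity-dependent noise, irregular sampling, systematic errors and
missingness. Passing benchmarks here therefore demonstrates correct
sampling of the stated posterior, not robustness to misspecification.
Ragged real datasets are supported through the CSV import
(`read_dataset()`, header `time,y1,...`), with missing values skipped in
the likelihood.

# Samplers

All samplers share the Metropolis-Hastings kernel (`mh_step()`) and a
Gaussian random-walk proposal whose covariance adapts to the chain
history.

**AM.** Adaptive Metropolis updates the running mean and covariance by a
rank-1 recursion (the recursive covariance is exactly the batch
covariance of the samples). Two scalings are provided: `dim` sets the
proposal covariance to $(2.38^2/d)\,\hat\Sigma + \varepsilon I$, the
classical dimension-based rule; `acc` multiplies
$\hat\Sigma + \varepsilon I$ by an adaptive scalar whose log is nudged by
$i^{-0.51}(\text{accepted} - 0.234)$ toward a 0.234 acceptance rate.
The decay exponent 0.51 lies in $(0.5, 1]$, guaranteeing diminishing
adaptation. Covariance adaptation starts after 100 iterations (an
$\varepsilon I$ proposal before), with
$\varepsilon = 10^{-8} \cdot \text{mean}(\theta_{\max} - \theta_{\min})^2$.
For efficiency the Cholesky factor of the proposal shape is refreshed
every 25 iterations; the acc-scale is applied at draw time every
iteration, so scale adaptation is not delayed.

**DRAM.** On a first-stage rejection, delayed rejection retries from a
proposal down-scaled by a factor 5 per stage (covariance /25 at stage
two) and accepts with the standard two-stage probability
$\alpha_2 = \min\{1, \frac{\pi(y_2)\, q(y_2 \to y_1)\,(1 - \alpha_1(y_2, y_1))}
{\pi(x)\, q(x \to y_1)\,(1 - \alpha_1(x, y_1))}\}$, preserving
reversibility; two total tries by default. DRAM is tied to the `dim`
scaling (requesting `acc` is a configuration error, matching the
reference implementation it follows).

**MALA.** The Metropolis-adjusted Langevin algorithm proposes from
$N\!\big(\theta + \tfrac{\epsilon^2}{2} G^{-1} \nabla \log p,\;
\epsilon^2 G^{-1}\big)$ with $G$ the expected Fisher information, and
accepts with the full asymmetric ratio (gradient and metric re-evaluated
at the proposal). $\epsilon$ adapts toward a 0.574 acceptance rate with
the same $i^{-0.51}$ decay. Gradients and $G$ come from
`sensitivities()`: analytic for the closed-form models, forward
sensitivity ODEs (augmented system) otherwise. The metric includes the
noise-parameter block $\mathrm{diag}(2 n_i / \sigma_i^2)$; cross terms
between $\eta$ and $\sigma$ vanish for Gaussian noise and are set to
zero. $G$ is symmetrized and regularized by $\lambda I$ with
$\lambda = 10^{-8} \max(\mathrm{diag}\, G)$, and flagged when the
unregularized condition number exceeds $10^{12}$.

**PT.** Parallel tempering runs $L$ chains on tempered posteriors
$p(\mathcal{D}\mid\theta)^{1/\beta_l} p(\theta)$ with
$1 = \beta_1 < \dots < \beta_L$ (initial ladder geometric up to
$\beta_{L_0} = 10^4$, $L_0 = 10$ by default). Each chain advances by an
AM(acc) step (MALA optionally); swaps are proposed either between all
adjacent pairs (`aa`) or between the pair with the most similar
log-likelihood (`ee`), accepted with probability
$\min\{1, \exp[(1/\beta_l - 1/\beta_m)(\log L_m - \log L_l)]\}$.
Temperature spacings adapt in log-difference space by a stochastic
approximation step toward a 0.23 swap rate. With `adaptive_temps = TRUE`
the hottest chain is dropped when its adjacent log-spacing collapses
below 0.01 ($L \ge 2$ always); the default is a fixed ladder, which is
also the more robust choice in the benchmark results. With $L_0 = 1$ PT
degenerates exactly to AM(acc) — identical traces under identical seeds,
which the tests assert.

**PHS.** Parallel hierarchical sampling runs $K$ auxiliary AM(acc)
chains, all on the untempered posterior, and exchanges the main chain's
state with a uniformly chosen auxiliary every iteration,
unconditionally — the exchange is always accepted because all chains
share the same target. Four auxiliaries by default, each with its own
adapted proposal.

**Randomness.** Each run consumes a single RNG stream with a fixed
per-iteration draw schedule: every chain draws its proposal vector and
acceptance uniform each iteration whether or not the move is accepted,
and swap decisions draw afterwards. Within-chain randomness is therefore
invariant to swap outcomes — the property that separate per-chain streams
would otherwise provide — and every run is bit-reproducible from
`(algorithm, control, init, seed)`. Study-level seeds are derived
deterministically from the master seed via one `sample.int()` call per
study.

# Initialization

`init_from_prior()` draws uniformly from the box (RND). Multi-start
initialization (MS) runs `multistart_optimize()` — prior draws followed by
bounded L-BFGS-B maximization of the log-posterior with analytic gradients
where available — and `init_from_multistart()` selects starting points:
the single best optimum for single-chain samplers; for multi-chain
samplers, near-duplicate optima are collapsed (scaled distance
$< 10^{-4}$), optima within `delta = 10` log-posterior units of the best
are retained, and chain starts are sampled uniformly from the retained
set (with replacement when chains outnumber optima). On M1b this places a
two-chain configuration in both symmetry-related basins in most seeds.
In studies, one multi-start per scenario is performed and its CPU time is
spread across the scenario's runs, so efficiency comparisons include the
initialization overhead.

# Analysis pipeline

The pipeline turns a pile of runs into per-scenario quality and
efficiency measures.

**Burn-in.** `estimate_burnin()` scans 20 equispaced truncation
candidates (0%, 5%, ..., 95%). At each candidate the Geweke test compares
the first 10% of the remaining chain against its last 50%, standardized
by spectral variance-of-mean estimates (autoregressive zero-frequency
estimator), with Bonferroni-Holm correction across parameters at level
0.05. The burn-in is the first candidate at which all corrected tests
pass; if none passes the run is flagged non-converged and assigned
ESS 0. One known limitation: a candidate whose leading window straddles a
sharp mean changepoint can absorb the step into the spectral variance and
pass early, so detection is guaranteed only to within one grid step below
the changepoint.

**Similarity grouping.** All runs of a benchmark are compared pairwise on
equal-length post-burn-in suffixes: a pair is similar iff the two-chain
multivariate Gelman-Rubin-Brooks statistic stays below 1.1 *and* the
between-run Geweke mean-comparison test (Holm-corrected) passes. Groups
are the connected components of the similarity graph — a run similar to
any member joins the whole group — and groups smaller than 5% of the run
count are neglected, mirroring the 115-of-2300 rule of the full-scale
design. Runs flagged non-converged participate with the second half of
their trace (they typically end up in neglected singletons) but never
receive a nonzero ESS.

**Exploration quality.** For every retained group the pipeline pools the
members' samples and records the best observed log-posterior, a per-
parameter outer interval (1%-99%) and an inner interval (5%-95%). Group
$G$ covers $G'$ iff $G$'s best log-posterior is within
$\delta_{\text{mode}} = 5$ of $G'$'s (mode criterion) and, when $G'$
itself reached the high-posterior region, $G$'s outer interval contains
$G'$'s inner interval in every parameter (tail criterion). A group is
well-exploring iff it covers all other retained groups, and a scenario's
EQ is the fraction of its runs in well-exploring groups. The relevance
condition on the tail criterion is a deliberate design choice: tails
worth covering are tails of the posterior's relevant region, and at desk
scale (tens of runs rather than thousands) groups of
never-converged runs can survive the 5% size filter — without the
condition their non-representative spread would veto every genuinely
exploring group. The mode criterion still forces any well-exploring group
to match the best log-posterior found anywhere. Both quantile pairs and
$\delta_{\text{mode}}$ are configuration knobs surfaced in
`assess_exploration()`.

**ESS and conditioned efficiency.** For runs in well-exploring groups the
integrated autocorrelation time is estimated per parameter by Sokal's
adaptive truncated estimator (`autocorr_time_sokal()`: FFT
autocorrelation of the mean-removed padded series,
$\tau = 1 + 2\sum_{k \le W} \rho_k$, window $W$ the smallest with
$W \ge 6\tau(W)$, floored at 1) and
$\text{ESS} = N / \max_i \tau_i$ — the maximum over parameters because
the estimator is univariate. Runs outside well-exploring groups, and
non-converged runs, count ESS 0: a fast run that never explored is worth
nothing, which is exactly what the EQ-conditioned efficiency
$\text{EQ} \times \text{ESS}/s$ encodes. CPU seconds are measured around
the sampling loop and include the amortized multi-start cost where MS
initialization is used.

# Numerical choices and problem sizes

* Solver tolerances `rtol = 1e-8`, `atol = 1e-10`; closed forms where
  declared; failures map to $-\infty$.
* FIM regularization $10^{-8}\max(\mathrm{diag})$; condition-number flag
  at $10^{12}$.
* Adaptation: decay $i^{-0.51}$; targets 0.234 (random walk), 0.574
  (MALA), 0.23 (swaps); adaptation start 100; Cholesky refresh every 25
  iterations; acc-scale clamped to $\pm 30$ log-units; temperature
  log-spacings clamped to $\pm 18.4$.
* Proposals rejected outside the box still count as proposals in the
  acceptance rate — such runs are cheap, which is precisely what
  EQ-conditioning penalizes.
* Duplicate-optimum collapsing at scaled distance $10^{-4}$; multi-start
  filter width 10 log-units.
* The package's own validation studies run at desk scale, chosen so the
  whole suite completes on one CPU in well under an hour: the M3 study
  uses 3 scenarios (AM(acc), PT with fixed $L = 5$, PHS with MS
  initialization) at 20 runs x 5e4 iterations; stationarity oracles use
  1e5 iterations and 3 seeds; the M1b mode-hopping check uses PT at
  1e5 iterations over 10 seeds. The full-scale design these mirror
  (23 scenarios x 100 runs x 1e6 iterations) is configurable through the
  same interfaces.

# Known limitations

* The tail criterion checks per-parameter marginal intervals, not joint
  regions; a group could cover all marginals while missing a joint
  feature.
* Burn-in detection resolves changepoints only to the 5% candidate grid,
  and the spectral variance can absorb a straddled step (above).
* The AR-based spectral variance and the sequential Geweke scheme share
  the usual weakness of mean-based diagnostics: a chain stuck in one mode
  of a multimodal posterior can look converged — which is exactly why the
  pipeline adds grouping and EQ on top.
* M2/M4 right-hand sides are documented defaults standing in for the
  published variants; all conclusions drawn from them should treat the
  dynamics as representative, not authoritative.
* Chaotic problems (M5, M6) are reproducible only at fixed solver
  tolerances; trajectories are not stable across tolerance changes, and
  no sampler in the collection explores their posteriors well.
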