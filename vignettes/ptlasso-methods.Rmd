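---
title: "Model reduction of reaction networks by tempered MCMC with Lasso priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model reduction of reaction networks by tempered MCMC with Lasso priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ptlasso)
```

## The problem

Mechanistic models of cell signalling are usually written as mass-action
reaction networks and calibrated against time-course data. As models grow,
two problems compound: many reactions are not actually constrained by the
data, and the parameter posterior becomes high-dimensional, rugged and
multimodal. `ptlasso` treats model *reduction* as part of Bayesian
parameter estimation: it samples the posterior over log10 rate constants
with parallel tempering (PT) MCMC under a Laplace (Lasso) shrinkage prior,
so that rate constants the data do not require collapse onto the prior —
flagging their reactions as removable — while informative rate constants
escape it and are calibrated at the same time.

## Model and energy

For observed species $s$ at times $t$ the likelihood is Gaussian,

$$\log L(\theta) = -\sum_{s,t}
  \frac{(Y^{sim}_{s,t}(\theta) - Y^{obs}_{s,t})^2}{2\sigma_{s,t}^2},$$

with $\sigma_{s,t}$ the replicate standard deviation of the observed data
(normalization constants are dropped throughout; they cancel in Metropolis
ratios). Sampling is over $\theta$ = log10 rate constants, each confined
to a box (a uniform prior: zero inside, infinite energy outside) and,
under the Lasso penalty, carrying a Laplace prior with location $\mu$ and
width $b$ in log10 units. The sampler works with the posterior energy
(low energy = high posterior density)

$$E(\theta) = -\log L(\theta) + \sum_i \frac{|\theta_i - \mu|}{b}.$$

Because sampling is in log space, "zero" is represented by a large
negative location (default $\mu = -10$, i.e. $10^{-10}$): a rate constant
that small cannot affect the dynamics on the simulated timescale, so a
posterior confined near $\mu$ is operationally a deleted reaction. The
sampling floor for generative models uses $10^{-12}$ in linear space,
below that proxy.

The grouped variant targets whole reaction *modules*: every reaction $i$
in module $m$ has $\theta'_i = k'_i + \lambda'_m$, one shared
Laplace-penalized penalty parameter $\lambda'_m$ per module plus a
reaction-specific factor $k'_i$ restricted to an open box $(LB, UB)$
(infinite energy at and beyond the boundary). Defaults $\mu = -25$,
$LB = -5$, $UB = 10$: when $\lambda'_m \approx \mu$ the largest
attainable rate is $\approx 10^{UB + \mu} = 10^{-15}$, dynamically nil,
so shrinking one $\lambda'_m$ deletes the whole module. Hard constraints
(strict inequalities over named parameters, evaluated in log10 space)
carry infinite penalty; soft constraints add finite weighted quadratic
penalties on trajectory features.

## Sampler

Each chain runs Metropolis-Hastings with an isotropic Gaussian proposal
in log10 space, accepting with probability $\min(1, e^{-\beta\,\Delta E})$
at inverse temperature $\beta$. A ladder of chains (default 6, geometric
from $\beta = 1$ to $0.05$) runs `n_mcmc` (default 25) MH steps between
replica-exchange sweeps; adjacent pairs, hottest first, swap their full
configurations with probability $\min(1, e^{\Delta\beta\,\Delta E})$. One
parameter vector per chain is recorded at every swap; the post-burn-in
record of the $\beta = 1$ chain is the posterior sample.

During burn-in only, per-chain proposal scales are adapted
multiplicatively toward the optimal acceptance rate 0.234
(`scale * exp(0.5 (rate - 0.234))` per swap), then frozen so the sampling
phase satisfies detailed balance. Scales are clamped to $[10^{-3}, 2]$
log10 units: the upper clamp matters in practice, because a chain that
spends its burn-in far from the fit basin otherwise adapts to step sizes
that freeze it once it arrives somewhere sharp. Burn-in must be long
enough for every chain to reach its basin before the freeze; the
benchmark settings below were chosen accordingly.

Randomness is organized as one L'Ecuyer-CMRG stream per chain plus a
dedicated stream for the swap pass, so runs are bit-reproducible for a
given seed and independent of execution interleaving. Chains are advanced
serially. Out-of-bounds proposals are rejected through their infinite
energy (no reflection), which keeps the proposal trivially symmetric.
Initialization either draws from the prior until the energy falls below a
threshold, or warm-starts from stored samples of an earlier run.

## Simulation

Mass-action dynamics are integrated with lsoda (stiff-capable, switching
Adams/BDF) at `rtol = 1e-6`, `atol = 1e-9`; tempered chains routinely
propose stiff corners. The derivative function is generated from the
network structure once per fit and evaluated in C (the network is encoded
as integer factor/stoichiometry tables for a generic compiled routine; an
equivalent generated-R closure backs it and is used for cross-checking).
Piecewise-constant stimulus inputs clamp their species and are handled
exactly by restarting the integration at each discontinuity. Networks
consisting solely of first-order conversions (the complete-graph
benchmarks) are propagated exactly through the eigendecomposition of
their rate matrix, with a fallback to lsoda if the eigenbasis is
ill-conditioned. Multi-experiment likelihoods whose experiments share an
observation grid under constant inputs (the dose series) are integrated
as one stacked system in a single solver call.

Numerical policy: small negative integrator slop is clipped to 0 before
the likelihood; an integration needing more than 500 internal steps per
segment — an order of magnitude above what well-posed stiff corners of
these models need — is treated as failed; any integration failure maps to
infinite energy (rejection), never an error. Replicate standard
deviations can vanish (e.g. where the true value is 0), so likelihood
sigmas are floored at `max(sd_floor, 1% of the largest observed mean)`.

## Reduction calls

`classify_parameters()` computes, per Laplace-penalized parameter, the
fraction of posterior samples inside $[\mu - c\,b,\ \mu + c\,b]$ with
$c = 3$ (covering $1 - e^{-3} \approx 95\%$ of the Laplace mass) and
calls the parameter *extraneous* when that fraction reaches the mass
threshold, *necessary* otherwise. The threshold default is 0.9 rather
than 0.95: a posterior exactly equal to the box-truncated prior has
$\approx 0.95$–$0.97$ of its mass inside the boundary, so demanding 0.95
would turn the defining case of "extraneous" into a coin flip on MCMC
noise, while observed necessary parameters sit far below 0.9. Both knobs
are configurable.

`extract_supports()` maps each sample to the set of parameters above an
activity threshold (default $-5$, halfway between $\mu = -10$ and the
data-informed region and far above $\mu + 3b$) and tabulates support
frequencies; mutually exclusive supports are alternate reduced models.
`select_b()` implements the elbow rule for the regularization strength:
the smallest $b$ whose mean negative log likelihood stays within one
reference standard deviation of an unregularized PT run (`scan_b()`
drives the sweep). `sensitivity_mu()` re-runs the classification at
$\mu \pm \delta$ on the same sample to flag borderline calls.

## Convergence diagnostics

`psrf()`/`mpsrf()` implement the classical (non-split, non-rank-
normalized) Gelman-Rubin and Brooks-Gelman statistics,

$$PSRF^2 = \frac{m+1}{m}\frac{\hat V}{W} - \frac{n-1}{mn}, \qquad
  MPSRF^2 = \frac{n-1}{n} +
  \frac{m+1}{m}\lambda_{max}\!\left(W^{-1}B/n\right),$$

computed across independently seeded runs; max univariate PSRF < 1.2 is
the convergence standard, with MPSRF as the stricter joint check.
`combine_chains()` gates the concatenation of M parallel shorter runs on
the univariate PSRF of their energy traces (< 1.2), and
`acceptance_report()` exposes per-chain step and per-pair swap acceptance
rates (rates with zero attempts are flagged undefined).

## Synthetic benchmarks and their study conditions

All benchmark data are generated in code, seeded, and carry provenance
sufficient to regenerate them exactly.

* **Complete 3-/5-node networks** (`generate_dataset("k3"/"k5")`): the
  pulse generator A$\to$B$\to$C ($k_{AB} = 0.1$, $k_{BC} = 1\,s^{-1}$,
  A(0) = 100 molecules, everything else 0) simulated and observed on
  species B only; 10 replicates of Gaussian noise with sd = 30% of the
  true value; 8 evenly spaced observation times over $(0, 30]$ s
  (an artifact choice of this package; $t = 0$ is
  excluded because B(0) = 0 gives degenerate noise). Fitting prior:
  the complete 6- or 20-reaction network, $\mu = -10$, $b = 1$, bounds
  $[-12, 3]$.
* **Noise on parameters** (`generate_dataset("k3-paramnoise")`): the
  log10 truth perturbed per replicate with Gaussian sd 0.05; replicate
  model outputs averaged pointwise.
* **Dose-response** (`generate_dataset("dose-linear"/"dose-adapting")`):
  the combined linear + perfectly-adapting prior network over clamped
  signal S, observed response R and hidden intermediate X. The union of
  the two classic motifs names five reactions; the shipped six-parameter
  prior completes it with basal signal-independent R production
  (`k_0r`) — the basal synthesis term of the linear motif — which is
  this package's reconstruction choice and is flagged as such in the
  fixture file. Linear data: S = 1..4, truth $k_{srs} = 10$,
  $k_{r0} = 0.01$, 4 time points including $t = 0$ over $[0, 600]$ s
  (16 records), noise sd = 10%. The window extends to the
  dose-proportional plateau deliberately: the saturation level
  $R^* = (k_{srs}/k_{r0})S$ is what identifies the decay rate, and with
  a shorter window the Lasso correctly (for those data) deletes it.
  Adapting data: one experiment with S stepping 1$\to$2 at $t = 5$ s,
  truth $k_{srs} = 10$, $k_{xrx} = 10$, $k_{sxs} = 1$, $k_{x0} = 1$,
  12 points over $(0, 10]$ s covering both fast post-step transients
  (relaxation $\sim 0.1$ s) and both plateaus densely. The plateau
  coverage matters: sparse plateaus admit an integral-control variant
  (X accumulating without decay) whose drooping plateau is otherwise
  indistinguishable at 10% noise. Hyperparameters $b = 0.5$ (linear) and
  $b = 1$ (adapting) at $\mu = -10$, bounds $[-12, 6]$.
* **Modular toy** (`generate_modular_toy_data()`): a synthetic
  receptor-style network of this package (not a published model) with
  three labelled modules — activation (S-driven I$\to$A and back),
  output (A-driven production of observed R, decay), and slow feedback
  (A-driven accumulation of F, F-catalyzed deactivation) — built so the
  feedback module is numerically dispensable under a 0.25 s input pulse
  and required under 60 s continuous input, where the observed
  rise-peak-decline of R cannot be produced by the monotone
  feedback-free model. Grouped fits use the defaults $\mu = -25$,
  $b = 2$, $(LB, UB) = (-5, 10)$.

What these generators emulate is measurement noise (or, in the
parameter-noise variant, lognormal cell-to-cell parameter variability)
around a deterministic mass-action truth whose network is a sub-network
of the fitting prior. They do not emulate intrinsic stochasticity,
model misspecification (the true dynamics always live inside the prior
network class), non-Gaussian or correlated noise, or unobserved
perturbations — so passing benchmarks demonstrates correct inference
and reduction under the stated noise model, not robustness to the ways
real data violate it.

## Problem sizes

The shipped tests and the acceptance script run the benchmarks at desk
scale: 1,500 swaps (300 burn-in) × 6 chains × 25 MH steps for the 3-node
fits, 2,000/400 for the 5-node fit, 2,000/600 × 20 for the linear dose
fit, 3,500/1,500 × 15 for the adapting dose fit, and 1,000/400 × 15 for
the grouped toy fits — hundreds of thousands of energy evaluations per
fit rather than the hours-long production runs this kind of sampler
normally gets. The longer burn-ins of
the dose fits reflect their multimodal landscapes (a basal-production
decoy basin neighbours the adaptive motif); samples recorded before a
chain settles would otherwise contaminate the confinement fractions.

## Known limitations

* Proposals are isotropic; strongly correlated posteriors (the
  $k_{sxs}$–$k_{xrx}$ ridge) mix slowly along their long axis, and
  likelihood-flat directions decorrelate only through tempering.
* Basin discovery is brute-force: on multimodal landscapes PT needs
  enough hot-chain exploration, and at desk scale a rare mode can be
  visited asymmetrically (the 5-node alternate models are found, but
  not with their symmetric frequencies — sampling, not energetics).
* Temperatures are not adapted, swaps are synchronous, and there is no
  on-the-fly convergence termination.
* The grouped composition $\theta' = k' + \lambda'$ is only
  penalty-identified: within a module, $k'$ offsets trade freely against
  $\lambda'$, and across modules only the sum of displacements from
  $\mu$ is penalized, so module-level amplification trades are
  penalty-neutral; classifications are about modules, not individual
  grouped rate constants.
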