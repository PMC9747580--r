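---
title: "Bayesian nonparametric inference for pulsed-illumination smFRET photon traces"
author: "pulseFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian nonparametric inference for pulsed-illumination smFRET photon traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseFRET)
```

## The problem

In a pulsed-illumination single-molecule FRET experiment a donor--acceptor
dye pair reports on the conformational state of one immobilised
macromolecule.  A laser fires every $\tau$ seconds (25--100 ns); each pulse
may excite the donor, which either emits a photon or transfers its energy
to the acceptor, which then emits.  Two detection channels record, for a
small fraction of pulses, the channel and the *microtime* $\mu$ — the delay
between the pulse and the photon, measured with ps resolution.  The
molecule meanwhile hops between a small number of conformational ("system")
states with dwell times of milliseconds; each state $\sigma_i$ has its own
FRET transfer rate $\lambda^{\mathrm{FRET}}_i$, hence its own FRET
efficiency

$$\varepsilon_i = \frac{\lambda^{\mathrm{FRET}}_i}
  {\lambda^{\mathrm{FRET}}_i + \lambda_d},$$

where $\lambda_d$ is the donor relaxation rate (inverse lifetime).
pulseFRET infers, directly from single-photon arrivals and without binning,
the number of system states, the pulse-to-pulse transition matrix
$\Pi_\sigma$ (hence per-state escape rates), the FRET rates, the
fluorophore relaxation rates, and the per-pulse excitation probability
$\pi_{ex}$.

## Model

Two physically motivated approximations organise everything:

1. system kinetics (ms) are far slower than the interpulse period (tens of
   ns), so the system state is constant within a pulse window and evolves as
   a discrete-time Markov chain, $s_{n+1}\mid s_n \sim \Pi_\sigma$ with
   $\Pi_\sigma = \exp(\tau G)$ for the continuous-time generator $G$;
2. the interpulse period is much longer than the fluorophore lifetimes
   (a few ns), so the dyes relax to the ground state before the next pulse
   and pulses are conditionally independent given the state.  The
   constructors warn when $\tau$ is less than five times the slowest
   lifetime.

Per pulse, excitation happens with probability $\pi_{ex}$; the excited
donor decays through an exponential race between emission (rate
$\lambda_d$) and transfer (rate $\lambda^{\mathrm{FRET}}_s$), so donor-band
emission times have density
$\lambda_d e^{-\lambda_{tot} t}$ with
$\lambda_{tot} = \lambda_d + \lambda^{\mathrm{FRET}}_s$, and acceptor-band
times are hypoexponential ($\lambda_{tot}$ then $\lambda_a$).  Detection
adds, in order: routing of each band to the channels by the 2x2
crosstalk/efficiency matrix (row deficits are photon loss), Gaussian IRF
jitter $N(m_{irf}, \sigma_{irf}^2)$, and per-channel background photons
(probability `bgProb[k]` per pulse, uniform microtime).  The IRF
convolution has the exponentially-modified-Gaussian closed form; it is
evaluated through `pnorm`'s log tail so it is stable for any argument, and
the acceptor density switches to its Erlang limit when
$|\lambda_a - \lambda_{tot}| \le 10^{-7}\lambda_{tot}$.

The outcome space of a pulse is {empty, donor photon, acceptor photon,
both}.  Signal and background in one channel enter as an additive mixture;
the $O(p_{sig} p_{bg})$ probability that both occur in the same channel is
folded into the empty-pulse mass rather than the density shapes, and
both-channel pulses are modelled as signal in one channel times background
in the other, symmetrised (a single excitation cannot emit in both bands).
With this bookkeeping the four outcome pieces sum to one exactly, which the
test suite verifies by quadrature.  Densities are evaluated on $[0, \tau)$
without renormalisation; the neglected mass outside the window is
negligible provided $\tau$ exceeds several lifetimes and
$m_{irf} \gtrsim 5\sigma_{irf}$, which all shipped configurations satisfy.

The trace likelihood is the scaled product of per-pulse factors
$\Pi_\sigma \odot D_n$, where the detection matrix $D_n$ has constant rows
$p(w_n \mid s_n = \sigma_i)$.  Runs of empty pulses collapse into powers of
the empty-pulse kernel $A = \mathrm{diag}(d_\varnothing)\,\Pi_\sigma$;
cached dyadic powers $A^{2^j}$ (each rescaled, with the log of the scale
accumulated) make any gap length an $O(\log k)$ operation, so the cost of a
forward pass is linear in the number of photons, not pulses.

## Samplers

The parametric Gibbs sweep (fixed number of states $M$) updates

1. photophysical rates and $\pi_{ex}$ by Metropolis--Hastings blocks:
   multiplicative log-normal random walks for rates (logit-normal for
   $\pi_{ex}$), Gamma priors on rates, Beta prior on $\pi_{ex}$.  The
   blocks target the trajectory-conditional posterior: given $s_{1:N}$ the
   likelihood factorises into one density term per photon epoch plus
   per-state empty-pulse terms $d_\varnothing(m)^{E_m}$, so a block costs
   only the photons in the states it touches.  A state not visited by the
   current trajectory has the prior as its full conditional and its FRET
   rate is redrawn from the prior directly.
2. the propagator rows by conjugacy,
   $\pi_m \sim \mathrm{Dirichlet}(n_m + \alpha\beta)$, with $n_m$ the
   trajectory's transition counts out of state $m$;
3. the trajectory by grouped forward-filtering backward-sampling: the
   filter is stored only at photon epochs; empty runs are filled by exact
   Markov-bridge sampling under $A$.  A run that stays constant (the
   overwhelmingly common case for slow kinetics) is accepted in
   $O(\log k)$; on rejection the midpoint is drawn with the constant path's
   weight removed and the recursion continues on explicitly non-constant
   segments, so the decomposition is exact, not approximate — transition
   counts are always sampled, never replaced by expectations;
4. the initial distribution by conjugacy,
   $\rho_{start} \sim \mathrm{Dirichlet}(c + e_{s_1})$.

Proposal scales adapt toward 30% acceptance during the first `nTune`
sweeps only (default: half the run, matching the default burn-in), so the
post-tuning chain is a fixed-kernel sampler.  Correctness of the pieces is
checked against brute-force oracles: the grouped likelihood against a
naive pulse-by-pulse product, FFBS against exhaustive trajectory
enumeration, conjugate draws against closed-form Dirichlet moments, and
the full sweep against simulation-based calibration (prior draws,
simulated data, rank-uniformity of the truth among posterior draws).

The nonparametric sampler is the same sweep run over a truncated state
space of `mMax` candidates (default 10) under a hierarchical
Dirichlet-process prior: base measure
$\beta \sim \mathrm{Dirichlet}(\gamma/M_{max},\dots)$ and rows
$\pi_m \sim \mathrm{Dirichlet}(\alpha\beta)$, with $\gamma = \alpha = 1$ by
default.  By default $\beta$ is fixed uniform (identical prior weights
across the state space); setting `sampleBeta = TRUE` resamples it each
sweep through the auxiliary table-count construction, which is exact but
costs a Bernoulli draw per observed transition and is therefore intended
for shorter traces.  The number of system states is read off as the number
of states whose trajectory occupancy exceeds 1% of pulses (the threshold is
an argument); unvisited states drift over their priors and die out.

### Initialisation

The chain starts from a near-static propagator (self-probability
$1 - 10^{-5}$), the physically sensible regime under assumption 1.  This
choice matters: photon epochs pin the trajectory wherever the data demand
a switch, so the switching scale anneals *up* to the data within a few
sweeps, whereas a diffuse start mixes pathologically slowly (with mostly
empty pulses, the transition counts of a diffuse trajectory simply echo
the current propagator).  Rates start at their prior means with FRET rates
spread over an efficiency grid, and $\pi_{ex}$ at twice the observed
photon fraction; all starting values can be overridden.

## Reported quantities

Escape rates are recovered from sampled propagators by the matrix
logarithm, $\lambda^{esc}_i = -[\log \Pi_\sigma]_{ii}/\tau$ (eigendecomposition,
with a $-\log(\mathrm{diag})/\tau$ fallback flagged when the logarithm is
not a real generator).  In the truncated nonparametric chain a switch
between two occupied states occasionally routes through a transiently
visited state, and a state can make a brief excursion that returns; to
count the former and not the latter, the sampled propagator is first
censored onto the occupied states via its stochastic complement
$P_{OO} + P_{OJ}(I - P_{JJ})^{-1}P_{JO}$ before taking the logarithm.
Label switching is resolved by ranking occupied states by FRET efficiency
within each sweep.  Summaries report, per state: the joint MAP estimate
(the highest-log-posterior sweep among those with the modal state count),
marginal kernel-density modes (Silverman bandwidth; smoothing is used for
these marginal summaries and plots only), and central 95% credible
intervals expressed as $-$lower/$+$upper offsets from the MAP.

## The synthetic generator

`generateDataset()` mirrors the generative model pulse by pulse in
compiled code: Markov transitions between windows, the emission race, the
acceptor delay, routing, Gaussian jitter (clamped into $[0,\tau)$), and
per-channel uniform background with the earlier photon kept on a
collision.  Two study configurations ship as defaults:

* `twoStateBenchmarkConfig()`: escape rates 40 1/s both states,
  efficiencies 0.22/0.59, $\tau$ = 25 ns, 500 ms (2e7 pulses);
* `threeStateBenchmarkConfig()`: a chain of three states through the
  middle one, escape rates 1200/2400/1200 1/s, efficiencies
  0.22/0.53/0.70, ~150 ms (6e6 pulses).

Values the benchmarks do not pin down were fixed once at realistic
single-molecule settings: donor/acceptor lifetimes 3.5/3.0 ns, detection
efficiencies 0.55/0.60 with 5% donor-to-acceptor crosstalk and no
acceptor-to-donor leakage, Gaussian IRF with 1 ns offset and 0.1 ns width,
background $10^{-5}$ per channel per pulse (about 400 counts/s), and
excitation probabilities of $10^{-3}$ and $5\times10^{-3}$ per pulse,
which put both traces in the $10^4$--$10^5$ detected-photon budget typical
of single-molecule recordings.

What the generator does *not* emulate: diffusing molecules, photobleaching
and blinking, triplet shelving, detector dead time and afterpulsing,
microtime quantisation (6 ps in typical hardware, far below the 100 ps IRF
width), and non-Gaussian IRF tails.  Passing tests therefore demonstrate
correctness of the inference under the stated noise model, not robustness
to every artefact of real hardware.

### A statistical caveat on the slow benchmark

At 40 1/s over 500 ms a trace holds only ~20 dwell transitions, so the
*realised* switching rate of any single simulation scatters around the
nominal rate with ~22% relative standard deviation, and the posterior —
correctly — concentrates near the realised rate.  Point summaries of the
escape rates from a single slow trace therefore inherit this seed-level
scatter no matter how well the sampler mixes; the three-state benchmark,
with hundreds of transitions, pins the rates much more tightly.  The test
suite's two-state escape-rate check is strict about the nominal truth and
can fail on an unlucky realisation for exactly this reason; the state
count, the efficiencies, and the credible-interval coverage are stable.

## Numerical choices

* Forward products are renormalised at every photon epoch and every
  applied dyadic power; the log likelihood is the accumulated log scale.
* Dyadic power caches are level-rescaled so $A^{2^{24}}$-sized powers never
  underflow.
* Matrix exponentials go through `Matrix::expm`; matrix logarithms through
  a complex eigendecomposition with a reconstruction check and a flagged
  diagonal fallback.
* Propagator validity is enforced to row sums within $10^{-12}$; tiny
  negative entries from the exponential are clamped and rows rescaled.
* Ties and degenerate inputs: zero-FRET states have identically zero
  acceptor density; the single-state space short-circuits to scalar
  arithmetic; an impossible observation returns $-\infty$ with a
  diagnostic rather than an error.
* All randomness flows through R's RNG (also inside the compiled core), so
  `set.seed()`/`seed` arguments make every pipeline bit-reproducible.

## Problem sizes used by the test suite

The suite exercises the full benchmark regimes exactly as stated above
(2e7- and 6e6-pulse traces, 3000-sweep nonparametric chains).  Property
tests run at smaller, statistically calibrated sizes chosen so that each
check retains power: enumeration oracles at 6--8 pulses with $10^5$ FFBS
draws, simulation-based calibration with 200 prior replicates of $10^4$
pulses and 50 sweeps, interval coverage over 20 replicates of a
fast-switching two-state system, and simulator fidelity at $10^5$--$10^6$
photons/pulses.

## Known limitations

* Continuous illumination, alternating-colour pulses, and direct acceptor
  excitation are out of scope; the observation model assumes one
  donor-exciting pulse train.
* The detector calibration (route matrix, IRF, background) is a fixed
  input, as in the experimental practice of calibrating these upstream;
  miscalibration propagates into rate estimates.
* The truncated HDP with fixed uniform base measure is an approximation to
  the full infinite-state prior; truncation insensitivity is tested, but
  pathological data could in principle saturate `mMax`.
* Slice/beam samplers, sticky self-transition biases, and
  marginal-likelihood model comparison are not implemented.
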