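---
title: "Maximum-likelihood noise analysis of synaptic currents: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood noise analysis of synaptic currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnsfa)
```

## The problem

Postsynaptic receptor channels are essentially inaccessible to single-channel
recording in their native environment, yet their biophysical parameters — the
unitary current $i_{ch}$, gating rate constants, the number of receptors bound
with transmitter on each trial ($N_{ch}$), and the peak open probability
$P_{o,peak}$ — shape synaptic transmission.  What *is* routinely recorded is a
set of macroscopic postsynaptic currents: sums of hundreds of stochastically
gating channels, with strong trial-to-trial amplitude variability because the
number of activated receptors varies from release to release (quantal
variability), and with coloured instrumentation noise on top.

The classical tool, peak-scaled non-stationary fluctuation analysis (PS NSFA),
scales the ensemble mean waveform to each trace's peak, subtracts, and fits
the variance-mean relation of the residual fluctuations with the parabola
$\sigma^2 = i_{ch}\langle I\rangle - \langle I\rangle^2/N + \sigma_0^2$.  It
estimates only $i_{ch}$, loses $N_{ch}$ and all kinetics, and fails outright
when open states have different conductances or when receptor kinetics vary
from trial to trial.  This package implements the maximum-likelihood
alternative (ML NSFA): a full Gaussian likelihood of the trace set under an
aggregated Markov channel model, evaluated efficiently through the
semiseparable structure of the single-channel covariance matrix, together
with the stochastic simulator used to validate it and the PS NSFA baseline
for comparison.

## Model

A channel is a continuous-time Markov chain over $N_s$ states with generator
$Q$ (columns sum to zero; ligand-binding rates are multiplied by the agonist
concentration).  Synaptic release is idealised as a brief saturating pulse
that leaves every available channel in the fully liganded state at the pulse
end ($p(0)$ a delta vector); a protocol object can instead equilibrate the
channels at arbitrary concentration epochs and propagate through an explicit
pulse.  With per-state unitary currents $i$ (one value per conductance
class), the single-channel current has mean
$\mu(t) = i^\top e^{Qt} p(0)$ and covariance
$c_{m1}(t,t') = i^\top e^{Q(t'-t)}\,(p(t)\circ i) - \mu(t)\mu(t')$ for
$t \le t'$.

A macroscopic trace with $N_{ch,i}$ channels is modelled, in the large-count
limit, as Gaussian with mean $N_{ch,i}\,\mu$ and covariance
$N_{ch,i}\,c_{m1}$.  The per-trace channel numbers are nuisance parameters:
each is estimated by the closed-form maximiser of its single-trace
likelihood,
$$N_{ch,i} = \frac{-n + \sqrt{n^2 + 4\,(c^\top c_{m1}^{-1} c)(\mu^\top c_{m1}^{-1}\mu)}}{2\,\mu^\top c_{m1}^{-1}\mu},$$
evaluated on a high signal-to-noise window of the decay (from the peak of the
model mean down to 30% of it by default; the published recommendation is
0.1–0.5).  Coloured background noise enters as an additive correction to the
log-likelihood, $+\tfrac12\,\mathrm{tr}(c_{m1}^{-1}c_{noise})\,
N\,\langle 1/N_{ch}\rangle$, with $\langle 1/N_{ch}\rangle$ the mean of the
reciprocal per-trace estimates.  The additive constant $NN_T\log(2\pi)/2$ is
omitted throughout.

Two details of the channel-number treatment deserve emphasis, because they
decide whether the estimator works at all:

* **The profile is bounded.**  The fitting protocol bounds every parameter
  within $[\theta_{ref}/50,\,50\,\theta_{ref}]$; the same bounds are applied
  to the profiled channel numbers.  Left unbounded, the likelihood admits a
  degenerate ridge — ever more channels with ever smaller open probability —
  along which the closed-form profile absorbs the background noise.
* **The channel numbers are frozen during optimisation.**  They are
  estimated once, at the reference parameter point, substituted into the
  likelihood, and the rate/current parameters are then optimised;
  re-estimating them at every candidate parameter point turns the ridge into
  the global optimum (it beats the generating parameters by hundreds of
  log-units on the bundled fixtures).  At the optimum the per-trace numbers
  are re-evaluated and reported.

An optional variant of the profile subtracts the expected noise quadratic
form (the exact profile retains it; the closed form as usually written omits
it).  The default keeps the closed form, which reproduces the known upward
bias of the channel-number estimates under noise (about +10% on the bundled
fixtures); the bias does not propagate into the unitary current, which is
pinned by the variance-to-mean ratio in which the channel count cancels.

## Fast likelihood evaluation

On a uniform grid the lower triangle of $c_{m1}$ factorises through the
spectral decomposition $Q = U\,\mathrm{diag}(\lambda)\,U^{-1}$ into rank
$N_s{+}1$ generators.  The package works with the per-step transfer form
$c_{m1}[i,j] = p_i^\top E^{\,i-j} q_j$, $E = \mathrm{diag}(e^{\lambda h}, 1)$,
which keeps every factor bounded (the textbook $A_{ik} = e^{\lambda_k t_i}$,
$B_{kj}=e^{-\lambda_k t_j}$ split overflows for stiff modes on long windows).
A structured Cholesky factorisation then runs in $O(N_T N_s^2)$, solves and
log-determinants in $O(N_T N_s)$ per right-hand side, and
$\mathrm{tr}(c_{m1}^{-1} c_{noise})$ for an AR(1)-sum noise covariance in
$O(N_T N_s^3)$ via a backward/forward recursion over the quasiseparable
inverse — all linear in the number of samples.  Eigenvalues may be complex
(non-reversible schemes): the algebra is carried in complex arithmetic and
imaginary residues of every observable are checked before casting to real.
Degenerate spectra are rejected with an explicit error rather than silently
switched around, since the factorisation assumes distinct eigenvalues.  When
a Cholesky pivot fails, a diagonal jitter of $10^{-10}$ times the largest
diagonal entry is added once (with a message); pivots below $10^{-250}$ are
treated as failure so underflow cannot masquerade as a valid likelihood.

All of this is verified in the test suite against dense linear algebra
(Cholesky, `solve`, scaling-and-squaring matrix exponentials) on grids of up
to 60 points for every bundled scheme, at $10^{-6}$ relative tolerance.

## Simulator

Macroscopic currents are simulated as aggregated multinomial state counts:
per time step the population in each state is redistributed according to the
columns of $e^{Q\,\Delta t}$, which is exact in distribution at the sample
times and fast for thousands of channels (a per-channel continuous-time path
simulator exists in the test suite as an independent oracle).  Channel
numbers are rounded Gaussian draws truncated at 1.  Background noise is a
sum of four AR(1) processes initialised from their stationary distributions.

The published noise parameters are $\phi = (0.0067, 0.61, 0.96, 0.999)$ with
component amplitudes $(0.32, 1.0, 1.42, 0.72)$ pA and a stated total SD of
3 pA.  Read as innovation SDs the sum would have SD 16.9 pA and be dominated
by a 200 ms-correlated drift; we read the amplitudes as the component
stationary SDs (the quantities a four-exponential autocovariance fit yields,
totalling 1.9 pA — the same order as the stated 3 pA) and rescale the summed
process so its stationary SD is exactly 3 pA.

The bundled fixtures regenerate the published simulation conditions: the
7-state GABA-A receptor scheme (unbound R; singly/doubly liganded RG, RG2;
open O1, O2; desensitised D1, D2; unbinding with statistical factors
$k_{off}$ and $2k_{off}$), a two-conductance variant
($i_1 = 2$, $i_2 = 1$ pA with modified gating), the 3-state abstract
receptor in reference/slowed-closing/doubled-number versions, and a
heterogeneous-kinetics version with $k_{off}$, $d_2$, $r_2$ varied uniformly
by ±20% from trace to trace.  Channel-number distributions are 250 ± 50,
500 ± 50, 400 ± 50 and 800 ± 71 as published.

Two measurement conventions are fixed by the published summary statistics
rather than stated outright, and we chose them once, from the deterministic
model, before running any estimator:

* **Record length.**  The peak-scaled variance-mean relation needs the mean
  current to decay to a small fraction of its peak, so the record is 200 ms
  after the pulse; likelihood analyses use the decaying phase from 1 ms
  after the pulse (as published) up to about 50 ms — the segment length
  implied by the published mono-exponential decay statistic; the tail
  beyond carries little kinetic information.
* **Decay time.**  The decay of these schemes is multi-exponential; a
  mono-exponential fitted over the whole 200 ms record gives ~73 ms and is
  dominated by the slow resensitisation modes.  The published 43.4 ms
  corresponds to a mono-exponential over the first ~50 ms after the peak
  (about one e-fold), so `trace_statistics()` fits `A exp(-t/tau)` with the
  amplitude profiled out over a 50 ms span from each trace's peak.

What the generator deliberately does not emulate: electrode/filter transfer
functions, baseline drift removal, event detection, non-stationary noise.
Passing tests therefore validate the estimators under ideal sampling of the
model's own world; on real recordings the noise model must be estimated from
baseline segments (`estimate_noise_model()`) and the initial-condition
idealisation must be justified by a fast transmitter transient.

## Optimisation

The negative log-likelihood is minimised over log-parameters (positivity by
construction) with a bounded quasi-Newton method (L-BFGS-B, finite-difference
gradients).  Initial points are drawn log-uniformly within a factor 10 of the
reference values, bounds are a factor 50, and the minimisation is graduated:
the first stage uses 3 traces sampled at 50 points, and each stage doubles
both counts until the full sample is used, warm-starting from the previous
optimum.  Coarse stages can wander (heavily subsampled grids cannot
distinguish fast-flicker gating from the truth), so a stage result is only
accepted if it improves the full-data objective — a cheap monotone
safeguard.  Restarts: the first starts at the reference point, the rest at
random initial points; the best full-data log-likelihood wins.  Relative
function tolerance is $10^{-8}$ with at most 500 iterations per stage
(reduced in the desk-scale validation runs, which also use 2 restarts).

Identifiability under the bundled conditions mirrors the published pattern:
$i_{ch}$, $k_{off}$, $d_2$, $r_2$ are well determined; $a_1$ only to order
of magnitude; $b_1$ and $d_1$ effectively bounded from below.  Binding rates
never enter post-pulse likelihoods (concentration is zero after the pulse)
and are excluded from the default free-parameter set.

`compare_models()` contrasts two bootstrap reports term by term: the
relative difference of the bootstrap means is flagged when it exceeds twice
the combined replicate scatter (the standard two-sample criterion at about
2 sigma), which reproduces the published discrimination between a gating
change (closing rate and peak open probability flagged) and a
receptor-number change (only $N_{ch}$ flagged).  The scatter scale is the
replicate SD: on these fixtures the estimator is precise enough that
percent-level pool artifacts would otherwise register as significant.

## Single-trace likelihoods and MCMC

For heterogeneous receptor populations the ensemble likelihood is
mis-specified, but each trace can be analysed on its own.  Single-trace
likelihood surfaces are strongly right-skewed in $i_{ch}$, so the maximiser
is not a representative summary; instead a coordinate-wise slice sampler
(stepping-out and shrinkage) draws from the likelihood treated as an
unnormalised density over log-parameters, with the channel number profiled
at every point, and the posterior mean is reported.  Chains are seeded
independently per trace; the first 20% is discarded as burn-in, without
thinning.  The sampler itself is validated against a known Gaussian target.

## Peak-scaled NSFA baseline

`psnsfa_fit()` implements the baseline: peak scaling per trace (peaks read
off a 1 ms box-smoothed copy; the scaled difference uses the raw traces),
per-timepoint ensemble variance against ensemble mean with no binning, and a
weighted parabola fit restricted to the rising limb (mean currents up to the
smoothed variance maximum).  Weights are $1/\mathrm{var}(\sigma^2_t)$ with
the Gaussian formula $2\sigma^4/(N-1)$ evaluated at the model-predicted
variance and refined by iterative reweighting: weights computed from the raw
empirical curve chase its downward fluctuations and bias the slope low by
tens of percent at the small ensemble sizes this analysis is used with.
When the background-noise SD is known it should be passed (`noise_sd`), which
fixes $\sigma_0^2$ instead of fitting it and conditions the parabola much
better.  For fixed channel counts and a single conductance the fit recovers
the unitary current to a few percent; its published failure modes — a value
between the two conductances on the two-conductance fixture, and a ~1.9-fold
overestimate under heterogeneous kinetics — are reproduced quantitatively.

Under the bundled study conditions our PS implementation is unbiased with
bootstrap RMS errors of roughly 33% at $N=5$ and 7% at $N=100$; the
published table reports 23% and 4.5%.  The gap persists under every
fit-protocol variant compatible with the published description that we
tried, and is documented rather than tuned away; all mean-value comparisons
(two-conductance and heterogeneous biases) agree.

## Problem sizes of the bundled validation runs

The desk-scale validation (test suite and the acceptance script) regenerates
1000-trace pools and uses reduced replicate counts: about 10 ML bootstrap
replicates where the published tables use 60 (with 2 restarts rather than
10), 100–200 PS bootstrap replicates where they use 250–1000, 3–6 fit
replicates per condition for the model-comparison and two-conductance
analyses, and 15–25 MCMC chains of 400–500 samples where the original uses
50 chains of 1000.  `study_design()` records both the full-scale and the
desk-scale counts; the full protocol is a straightforward overnight run of
the same functions.

## Known limitations

* The Gaussian (large-$N_{ch}$) limit is the model; exact aggregated-Markov
  likelihoods are out of scope.
* Distinct eigenvalues are assumed; degenerate spectra require perturbing
  the rates.
* The channel-number profile is a plug-in approximation; its noise-induced
  upward bias is reported, not corrected, to match the published estimator.
* The graduated optimiser is a local method with restarts; for weakly
  identified rates (e.g. the singly-liganded branch at small sample sizes)
  it reports whatever the flat ridge admits, as the published error tables
  also show.
* Piecewise-constant concentration epochs only; no fitting of transmitter
  time courses.
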