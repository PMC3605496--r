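---
title: "Synfire chain embedding: model, mean-field analysis, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synfire chain embedding: model, mean-field analysis, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synfirecap)
```

# The model

`synfirecap` studies how many synfire chains — sequences of neuron pools
linked all-to-all by feedforward connections, supporting the propagation of
synchronous spike packets ("waves") — can be embedded in a balanced
recurrent network of conductance-based integrate-and-fire neurons, and what
limits that number.

**Neurons.** Leaky integrate-and-fire with instantaneous synapses. In the
conductance variant each presynaptic spike multiplies the distance to the
corresponding reversal potential: an excitatory input maps
`V -> V + g_E (V_E - V)`, an inhibitory one `V -> V + g_I (V_I - V)`. A
current-based variant with fixed jump amplitudes `a_E`, `a_I` is provided
for the model comparison. A spike is fired when `V` reaches the threshold
`V_Theta`; the potential is reset to `V_R` and clamped there for the
refractory time `tau_ref`, during which inputs are discarded. The default
operating point is: reversal potentials 0 / −80 mV, rest and reset −70 mV,
threshold −55 mV, membrane time constant `tau_P` = 20 ms, refractory period
2 ms, `g_E` = 0.005, `g_I` = 0.11 (all exposed through
[`neuron_params()`]).

**Embedding.** From `N_E` excitatory and `N_I = gamma N_E` inhibitory
neurons (`gamma` = 1/4), `p` excitatory pools of `n_E` distinct neurons are
drawn, with the constraint that every neuron appears in `floor(p n_E/N_E)`
or `ceil(p n_E/N_E)` pools; inhibitory "shadow" pools of `n_I = gamma n_E`
neurons are built the same way. All E-pools are ordered into a single ring,
and each pool projects all-to-all to the next E-pool and its shadow I-pool.
Every excitatory synapse belongs to exactly one pool-to-pool link — the
embedding is at *combinatorial capacity*, so the connectivity per neuron is
`C_E = p n_E^2 / N_E` and the embedding level (pools per neuron) is
`alpha = C_E / n_E^2`. Inhibitory neurons project to uniformly random
targets such that every neuron's inhibitory in-degree is `gamma'` times its
excitatory in-degree (`gamma' = gamma` = 1/4 by default). We use
`N_E = 10 C_E`, which makes the pairwise connection probability 10%.

**Delays.** Each excitatory synapse's transmission delay is
`tau_A(link) + tau_B(synapse)` with `tau_A` uniform on [0.5, 4.5) ms shared
by all synapses of one link and `tau_B` uniform on [0, 0.5) ms per synapse.
The narrow intra-link spread creates the integration window through which
background input modulates packet propagation — this is what regulates the
number of waves. Inhibitory synapses draw both components independently.
The implied mean excitatory delay is 2.75 ms.

**Drive.** The network receives no tonic external input. Waves are started
by stimulus packets — `n_E` spikes with 0.1 ms Gaussian jitter, delivered
to each neuron of a target pool with independent `tau_B` delays — repeated
every `T_stim` = 40 ms from t = 200 ms on, which drives the wave count to
its self-regulated ceiling. An optional balanced Poisson ramp (four equal
decrements over the first four stimuli) is available but off by default; in
our simulations the system reaches its equilibrium without it.

# Packet and wave extraction

Spike packets are read off each pool's pooled raster by anchoring a window
of width `T_w` = 3 ms at every spike, marking windows with more than
`n_theta` spikes, keeping maximal runs of at least 6 consecutive marked
windows, and reducing each run to the window of maximal count (middle one
on ties); the packet time is the median of the window's spikes (lower
middle element for even counts). We use `n_theta = round(0.4 n_E)` as the
default threshold and expose it. Two deliberate tie-breaks are our own:
when the selected windows of two nearby packets overlap (waves passing the
same pool less than `T_w` apart), boundary spikes are assigned to the
earlier packet, so every spike counted into the wave rate `nu_W` belongs to
exactly one packet; and when two successor-pool packets both fall in the
linking window, the earlier is linked. Packets on consecutive pools are
linked into waves when their gap lies in [0.5, 6] ms. The wave count `h(t)`
treats a wave as alive from its first packet to its last packet plus one
mean link interval. Equilibrium statistics are taken over
`[max(1000 ms, t_mean), end]`, where `t_mean` is when `h(t)` first exceeds
its long-run mean.

This detector assumes the non-packet spike rate inside a pool is low; it is
not a general synchrony detector and will lose precision when background
activity within the window approaches `n_theta`.

# Mean-field analysis

With `h` waves propagating, the population rate splits into wave spiking
and stochastic (fluctuation-driven) spiking, `nu = nu_W + nu_S`, and the
asynchronous background input rates seen by a neuron are
`lambda_E ~ C_E nu` and `lambda_I = gamma' lambda_E` (the correction for
excluding a neuron's own predecessor-pool packets,
`n_E / (C_E (1 + nu_S/nu_W))`, is neglected; see Limitations). Two measured
response functions close the loop:

* `f_S(lambda_E)` — the stochastic rate of a single neuron under balanced
  Poisson bombardment, estimated by [`estimate_fS()`] on a grid of
  `lambda_E` values and linearly interpolated. The reference protocol is
  100 runs of 5000 ms per grid point (first 1000 ms discarded) at the
  network's own time step: the grid rate at `dt` = 0.1 ms differs
  systematically from the continuum limit at high input rates, so the
  table must be measured with the same integrator as the network. Our test
  suite checks convergence of the integrator to an exact event-driven
  reference as `dt` shrinks, and checks agreement of the measured rate with
  that reference at `dt` = 0.005 ms.
* `P_S`, `p_f`, `T` — survival probability over `L` pools, packet
  participation probability, and pool-to-pool time, measured by
  [`characterize_propagation()`] on a non-embedded feedforward control
  chain bathed in Poisson background, stimulated in its third pool. The
  control chain uses the full two-component delay model, so `T` includes
  the mean transmission delay (~2.75 ms) plus the spike-generation lag.
  `p_f` is measured from the packet in the last pool of surviving trials.

[`solve_selfconsistent()`] finds the background-rate fixed point
`lambda_E = C_E [ (h/N_E) n_E p_f(lambda_E)/T(lambda_E) + f_S(lambda_E) ]`
by bisection over the table support, returning the smallest root (the
low-rate asynchronous branch) with a stability flag
`|C_E dF_S/dlambda_E| < 1`. Under ongoing stimulation every `T_stim`, wave
lifetimes are exponential with expected value
`T_S = T L / log(1/P_S)`, and the equilibrium wave count is
`h_eq = T_S / T_stim`; [`equilibrium_state()`] solves the full balance
condition and also reports the cheaper approximation that evaluates all
quantities at the propagation threshold `lambda_E,max(n_E)` (the rate where
`P_S` crosses 0.5, found by linear interpolation of the measured row).

**Capacity.** The largest embedding level at a given activity is
`alpha_max = C_E / n_E,min^2` with `n_E,min` the smallest pool size that
still propagates at `lambda_E = C_E nu`. Two connectivity limits truncate
the capacity curve: `C_E,max1 = 1/(dF_S/dlambda_E)` (stability of the
stochastic-rate fixed point) and `C_E,max2` where stochastic spikes exceed
half of all spiking. Conditioning on a wave density `h_eq/N_E` instead of a
rate is solved parametrically per pool size from the lifetime balance plus
the background self-consistency, then interpolated onto the requested
connectivity grid.

# The diffusion (Siegert) comparison

For the conductance/current model comparison we use the first-passage rate
formula `rate = 1/(tau_ref + tau I)` with `I` the standard integral of
`sqrt(pi) e^{z^2}(1+erf z)` between `(V_R-mu)/(sqrt2 sigma)` and
`(V_Theta-mu)/(sqrt2 sigma)`. The moments of the free membrane potential
follow the effective-time-constant diffusion approximation: for
conductance synapses `1/tau = 1/tau_P + lambda_E g_E + lambda_I g_I`,
`mu = tau (V_P/tau_P + lambda_E g_E V_E + lambda_I g_I V_I)` and
`sigma^2 = (tau/2)(lambda_E g_E^2 (V_E-mu)^2 + lambda_I g_I^2 (V_I-mu)^2)`;
for current synapses `tau = tau_P`, `mu = V_P + tau_P(lambda_E a_E +
lambda_I a_I)`, `sigma^2 = (tau_P/2)(lambda_E a_E^2 + lambda_I a_I^2)`.
The `sigma^2` form is one canonical reading of the effective-time-constant
approximation; we cross-validate it against threshold-free ensemble
simulations in the tests rather than treating it as beyond question.

Numerics: the integrand grows like `e^{z^2}`, so the upper tail is
integrated after substituting `w = z_u - z` and factoring out `e^{z_u^2}`,
with `1 + erf(z)` evaluated as `2*pnorm(sqrt(2) z)`; the left tail uses the
scaled complementary error function, switching to its asymptotic series
beyond |z| = 15 where the scaled form itself would overflow internally.
Deeply subthreshold operating points thus return accurate tiny rates
instead of overflowing. Quadrature tolerance is 1e-10 relative.

The minimum pool size in this simplified picture requires `n` synchronous
inputs of effective amplitude `a_E` to shift 95% of the membrane-potential
distribution above threshold: `n_E,min = ceil((V_Theta - mu +
1.645 sigma)/a_E)`, with `a_E = g_E (V_E - V_avg)`, `V_avg = (V_R +
V_Theta)/2` for the conductance model (0.3125 mV at the default `g_E`).
This neglects the intra-link delay spread entirely, which is why the
simplified sweeps ([`sweep_comparison()`]) are used only for the
qualitative conductance-vs-current contrast, never as a substitute for the
measured propagation tables. [`fit_current_to_conductance()`] solves the
two moment equations for `(a_E, a_I)` given a chosen `V_P`; the choice
`V_P = mu` makes the fitted model exactly balanced
(`a_E lambda_E + a_I lambda_I = 0`).

# Numerical and design choices

* **Time step.** `dt` = 0.1 ms everywhere by default; delays, spike times
  and stimulus arrivals live on this grid. Within a step the integrator
  applies leak decay, then all excitatory jumps, then all inhibitory jumps
  (same-type jumps commute; the E-before-I order is a fixed convention,
  since instantaneous synapses leave simultaneous-event order undefined),
  and tests the threshold once at the step end. `n` same-type conductance
  jumps compose exactly as `(1 - g)^n`, so the per-step update is
  count-based and exact given the ordering convention. These conventions
  matter quantitatively at high input rates, where the effective membrane
  time constant approaches `dt`: propagation thresholds measured at
  `dt` = 0.1 ms are integrator-convention-dependent there, which is
  precisely why all mean-field inputs are measured with the same
  integrator that runs the network.
* **Refractory end.** Inputs arriving in a step in which the neuron is
  still refractory are discarded, including the step at which
  refractoriness ends.
* **Seeding.** One engine, one RNG: the compiled core draws its Poisson
  counts from R's RNG in a fixed iteration order, so every run is
  bit-reproducible from a single integer seed; stream seeds for trials and
  grid cells are derived by a polynomial hash so that adding cells never
  perturbs existing ones.
* **Delays on the grid.** Rounded half-up, minimum one step.
* **Bisection.** Driven to an interval of 1e-10 (relative), which on
  piecewise-linear tables is essentially exact; the self-consistency
  residual at returned solutions is checked to be below 1e-6 relative.
  `P_S` is clipped to [1e-6, 1-1e-6] before any `log(1/P_S)`.
* **Stability derivative.** Central finite difference of the interpolated
  table over one grid interval; the scheme is a documented choice, not
  canonical.
* **Pool assignment.** Balanced membership is realized by shuffling the
  replicated id multiset and repairing within-pool duplicates by swaps
  across pools; neurons are distinct within a pool but recur across pools.

# The synthetic-data generator and what tests show

All test inputs are generated in code: planted-packet rasters (known packet
times/sizes over low-rate Poisson background) validate the detector's
recall and precision; miniature embeddings and short control chains
exercise the full pipeline. The generator emulates the model's own
statistical structure — Poisson background, Gaussian-jittered packets,
uniform two-component delays — and deliberately nothing else: no synaptic
rise times, no heterogeneity of neuron parameters, no distance-dependent
connectivity, no correlated external input. Tests passing on these inputs
demonstrate the algorithms implement the stated definitions and reproduce
the model's internal relationships; they say nothing about biological
recordings, where background rates, packet shapes and nonstationarity
violate the detector's assumptions.

**Problem sizes.** The reference protocols (100-pool chains, 100 trials
per cell, pool sizes 20–220, rates 1–300 kHz, 100×5000 ms rate
estimates) are all available through the exported functions. The test
suite runs reduced versions chosen as desk-scale study conditions:
21-pool chains with 8 trials per cell on rate grids concentrated
around the survival crossings for the ordering properties; a 41-pool chain with 16 trials around the
propagation threshold of `n_E` = 100 for the equilibrium analysis; rate
tables from 40–60 runs of 2–3 s; and one driven embedding of `C_E` = 500,
`N_E` = 5000, `n_E` = 100 (250 pools, ~3.9 million synapses, 10 s
simulated). Shorter chains shift survival thresholds slightly upward
(survival is measured over fewer pools) but preserve every ordering and
scaling relation tested.

# Known limitations

* The mean-field treatment feeds neurons *pure Poisson* background and
  characterizes propagation on an *isolated* chain. In the embedded
  network each neuron also receives synchronous packet volleys from the
  other pools it belongs to; these volleys drive most spikes, put neurons
  into post-spike recovery, and thereby suppress both the stochastic
  response and packet survival relative to the isolated-chain tables. The
  neglected correction scales like `n_E/C_E`. At cortical-scale
  connectivity (`C_E` of several thousand, `n_E/C_E` of order 1%) it is a
  small bias; at the desk-scale geometry used in the test suite
  (`C_E` = 500, viable `n_E` ≈ 100, so `n_E/C_E` = 0.2) it is first-order,
  and the driven embedding equilibrates at a markedly lower background
  rate than the isolated-chain threshold. A short ring (250 pools) adds
  wave collisions — both with other waves lapping the ring and with
  freshly stimulated packets — as an extra death mechanism absent from
  the analysis. The corresponding quantitative acceptance check documents
  this gap rather than hiding it; the properties that do transfer at desk
  scale (stable self-regulated wave ceiling, no rate explosion, equal E
  and I rates, and the predicted *sign* of the bias) are asserted as
  tests.
* Propagation thresholds at background rates of hundreds of kHz sit in
  the regime where the effective membrane time constant approaches the
  grid step; their absolute values depend on the within-step conventions
  above and should be compared across conditions (pool size, inhibition),
  not read as continuum quantities.
* No synaptic rise times, adaptation, conduction-delay correlations, or
  finite-size fluctuation corrections.

# Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from scratch with the installed
package: the embedding levels and pool counts of the two reference
geometries (`C_E` = 8000 with `n_E` = 72 and 200), and the survival
probability over 98 pools of a wave in a 100-pool control chain at
`n_E` = 52, `lambda_E` = 20 kHz (20 trials) — a pool size below the viable
range, for which the expected survival is zero. See the README for
invocation.
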