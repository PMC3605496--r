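# synfirecap

Simulation and mean-field analysis of **synfire chain embedding** in
cortical-scale balanced networks of conductance-based integrate-and-fire
neurons.

A synfire chain is a sequence of neuron pools linked all-to-all by
feedforward connections; a synchronous spike packet injected into one pool
propagates pool-to-pool as a *wave*. This package is for computational
neuroscientists who want to know how many pool-to-pool links such a network
can store — its **embedding capacity** — and what limits that number. It
implements:

* a fast time-stepped simulator (Rcpp core) for networks in which *every*
  excitatory synapse belongs to a pool-to-pool link (combinatorial
  capacity), with E/I-balanced "shadow" pools and two-component
  transmission delays (per-link `τ_A` ~ U[0.5, 4.5) ms plus per-synapse
  `τ_B` ~ U[0, 0.5) ms);
* spike-packet detection and wave linking from rasters, and time-resolved
  wave counts `h(t)`;
* measurement of the propagation characteristics of an isolated control
  chain under Poisson background — survival probability `P_S`,
  participation probability `p_f`, pool-to-pool time `T` — and of the
  single-neuron stochastic response `f_S(λ_E)`;
* a mean-field solver built on those tables. With `h` waves the rate
  splits as `ν = ν_W + ν_S`, background input is `λ_E ≈ C_E ν`,
  `λ_I = γ′ λ_E`, and the self-consistent state solves

  `λ_E = C_E [ (h/N_E) · n_E · p_f(λ_E)/T(λ_E) + f_S(λ_E) ]`.

  Wave lifetimes are exponential, `T_S = T·L / log(1/P_S)`, so ongoing
  stimulation every `T_stim` equilibrates at `h_eq = T_S/T_stim`; the
  capacity at a given activity level is `α_max = C_E / n²_E,min` with two
  connectivity limits (stability of the stochastic-rate fixed point, and
  the requirement that at least half of all spikes belong to waves);
* a closed-form diffusion (Siegert first-passage) analysis comparing
  conductance- and current-based synapses, including moment-matched
  current-model fits.

## Worked example

Build a scaled-down embedding (`C_E` = 500 inputs/neuron, `N_E` = 5000,
pools of `n_E` = 100, hence `p` = 250 pools at combinatorial capacity),
drive it with wave-initiating stimuli every 40 ms, and extract waves:

```r
library(synfirecap)

cfg  <- embedding_config(C_E = 500, n_E = 100, N_E = 5000, seed = 11)
derive_counts(cfg)
#> $p        [1] 250      # pools in the ring
#> $alpha    [1] 0.05     # pools per excitatory neuron, C_E/n_E^2
#> $N_I      [1] 1250
#> $n_I      [1] 25
#> $C_I      [1] 125

spec <- build_embedding(cfg)                       # ~3.9 million synapses
sp   <- run_network(spec, neuron_params(),
                    stimulus_protocol(target_pool = 1, period = 40),
                    duration = 10000, seed = 21)

det <- detection_params(100)
pk  <- detect_packets_by_pool(sp, spec, det)
wv  <- link_waves(pk, det, n_pools = spec$p, ring = TRUE)
st  <- equilibrium_statistics(sp, wv, params = det)
st[c("nu_Hz", "nu_W_Hz", "mean_h", "max_h")]
#> $nu_Hz    [1] 37.65    # population rate at equilibrium
#> $nu_W_Hz  [1] 32.70    # of which spikes belonging to wave packets
#> $mean_h   [1] 5.85     # mean number of co-active waves
#> $max_h    [1] 8        # self-regulated ceiling
```

The run shows the defining behavior: although a new wave is injected every
40 ms throughout, the number of co-active waves saturates — background
input generated by the waves themselves rises until packet survival drops,
and the wave count self-regulates with no rate explosion.

The mean-field side starts from measured tables, e.g. the propagation
threshold of a given pool size:

```r
p  <- neuron_params()                      # g_E = 0.005, g_I = 0.11, ...
r  <- characterize_propagation(80, lambda_E = 2, gamma = 0.25, params = p,
                               trials = 3, seed = 31, n_pools = 21)
r[c("P_S", "p_f", "T")]
#> $P_S [1] 1          # every trial survives at this low background rate
#> $p_f [1] 1          # every neuron joins each packet
#> $T   [1] 3.073      # ms per pool: 2.75 ms mean delay + spike lag
```

`build_propagation_table()` + `estimate_fS()` feed
`solve_selfconsistent()`, `equilibrium_state()` and `capacity_curve()`;
`sweep_comparison()` runs the conductance-vs-current diffusion analysis.
A thin command-line wrapper over the same functions is installed at
`inst/cli/synfirecap.R` (subcommands `build`, `simulate`, `characterize`,
`detect`, `meanfield`, `capacity`, `compare`, `fixture`).

See the vignette (`vignettes/synfire-embedding-methods.Rmd`) for the model
assumptions, estimation protocols, numerical choices, and known
limitations of the desk-scale analyses.

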