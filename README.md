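# neurotherm

Stochastic and information thermodynamics for neural systems, in R.

Neurons and synapses are small, noisy, driven systems: every act of sensing,
learning or remembering dissipates energy, and the dissipation is tied to the
information being handled. `neurotherm` implements the bookkeeping that makes
that statement quantitative, for researchers in computational neuroscience and
stochastic thermodynamics who want tested, reusable building blocks rather
than one-off scripts:

* a **discrete-state master-equation engine** with full entropy accounting —
  Shannon entropy, Kullback–Leibler divergence, mutual information, and the
  entropy balance `dS/dt = Ṡ_pr − Ṡ_fl` with the production rate
  `Ṡ_pr = ½ Σ (w_zz′ p_z′ − w_z′z p_z) ln[(w_zz′ p_z′)/(w_z′z p_z)] ≥ 0`
  and its quadratic lower bound;
* **1-D Langevin simulation** (Euler–Maruyama, reproducible per-trajectory
  noise streams) and gridded Fokker–Planck thermodynamics
  (`J = μF P − ½(μσ)² ∂P/∂z`, `Ṡ_pr = (2/(μσ)²)∫ J²/P dz`);
* the **Brownian particle in gravity** as a fully closed-form reference:
  fluctuation–dissipation (`σ_v = √(k_B T/m)`), velocity/position moments,
  the mean energy balance, and the exact position-entropy ledger;
* **bipartite information flows**: local entropy production, flow, and the
  Maxwell-demon identity `Ṡ_pr,x = Ṡ_x + Ṡ_fl,x − İ_x`, with a ledger that
  flags apparent second-law violations;
* a **noisy linear recurrent network** inferring a stochastic stimulus
  velocity: Gaussian tuning curves, the network enhancement factor
  `κ = 1/(1 − w̄τ_n0)`, the stationary mutual information
  `I ∝ C₀ τ_n² τ_c/(τ_n + τ_c)`, and the entropy-production cost of tracking;
* **stochastic BCM plasticity**: the collective-weight double well, the
  bistability condition `λτ_w τ_n0 f̄² > 4β`, Kramers dwell times, the
  two-state memory reduction and its identity
  `Ṡ_w = −ḊKL` (total dissipation = initially stored information);
* a **pair-approximation solver** for chains of `K`-state synapses with
  neighbour-dependent rates: `N_s K + (N_s−1)K²` closed equations instead of
  `K^N_s`, with information-gain rate and per-synapse entropy production.

Everything returns tibbles, report objects have `tidy()`/`glance()` methods,
and `plot_*()` helpers produce ggplot2 figures. Every closed form is exposed
so it can serve as an oracle against the matching simulation (and the test
suite uses them exactly that way).

## Worked example

Is the nominal synaptic population bistable, and how stable are its states?

```r
library(neurotherm)

bp <- bcm_params()          # nominal: lambda 1.3, beta 1.2, f_bar 0.9 Hz,
bistability(bp)             # tau_w 200 s, tau_n0 0.3 s, sigma_w 5, Ns 1000
#> <bistability_report> condition 63.18 > threshold 4.8 -> bistable
#>   fixed points: w_d = 0, w_m = 0.0597793, w_u = 3.02664
```

The plasticity drive (63.18) exceeds the threshold (4.8) more than
twelve-fold, so the collective weight has a weak state at `w̄ = 0` and a
strong state at `w̄ = 3.03 s⁻¹`, separated by a barrier at `w̄ = 0.060`.
How high is that barrier compared with the collective noise?

```r
kramers_times(bp)$barrier_d_over_D
#> [1] 0.02358849
```

Only 0.024 diffusion units: the weak state is *not* metastable at these
parameters — noise alone carries the population over the barrier within a few
hundred seconds (spontaneous "false memories"), while the strong state sits
behind a barrier of ~1.5·10³ diffusion units and is effectively permanent.
This asymmetry — cheap learning, durable memory — is the central qualitative
feature of the model, and the package computes both sides of it.

A driven three-state ring shows the entropy accounting at work:

```r
ring <- rate_matrix(matrix(c(0, 2, 1,  1, 0, 2,  2, 1, 0), 3, 3))
entropy_rates(ring, stationary_distribution(ring))
#> # A tibble: 1 × 3
#>   entropy_production entropy_flow    ds_dt
#>                <dbl>        <dbl>    <dbl>
#> 1              0.693        0.693 1.73e-31
```

At the non-equilibrium steady state the entropy production (`ln 2` nats/time
for this 2:1 driving) is exactly balanced by the flow into the environment,
and the system entropy is constant.

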