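---
title: "Methods: entropy, information and energy in stochastic neural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy, information and energy in stochastic neural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models behind `neurotherm`, the conventions and
numerical choices the implementation commits to, and the places where a
design decision was genuinely open. It is the package's methodological
reference; the README shows usage.

## 1. Master equations and the entropy ledger

A finite-state Markov jump process with rates `w[z, z']` (from `z'` to `z`)
evolves as `dp/dt = A p` with the generator built by `generator()`. The
entropy balance splits the rate of Shannon entropy into a non-negative
production term and a flow term,

    dS/dt = S_pr - S_fl,
    S_pr  = 1/2 * sum_{z,z'} (w_zz' p_z' - w_z'z p_z) ln[(w_zz' p_z')/(w_z'z p_z)],
    S_fl  = 1/2 * sum_{z,z'} (w_zz' p_z' - w_z'z p_z) ln[w_zz'/w_z'z].

Conventions, fixed once and used everywhere:

* links with zero flux in both directions contribute zero (`0 ln 0 = 0`);
* a unidirectional link carrying flux makes `S_pr = +Inf`, which is
  *returned*, not raised — the divergence is physical (a strictly
  irreversible transition) and callers must see it;
* all entropies are in nats; `nats_to_bits()` converts.

**Quadratic lower bound.** From `ln(1+x) >= x/(1+x)` one obtains a valid
per-link bound only when the logarithm is expanded around the *larger* of
the two one-way fluxes; `entropy_production_bound()` therefore uses
`max(w_zz' p_z', w_z'z p_z)` in the denominator. With the smaller flux the
"bound" can exceed the true production (fluxes 2 and 1 give ln 2 ≈ 0.693
versus 0.75), so that variant is not implemented.

**Integration.** `evolve_master()` and `pair_evolve()` use `deSolve::lsoda`
with `rtol = 1e-10`, `atol = 1e-12`. The stiff-capable integrator is not a
luxury: two-state reductions of bistable systems produce rates differing by
many orders of magnitude. The matrix exponential (`Matrix::expm`) appears
only as an independent oracle in the tests, never in the implementation
path.

## 2. Langevin simulation and gridded Fokker–Planck thermodynamics

The continuous counterpart `dz = mu F(z,t) dt + mu sigma dW` uses the noise
convention `<eta(t) eta(t')> = delta(t - t')`, so the diffusion coefficient
is `D = (mu sigma)^2 / 2`. Choices:

* **Euler–Maruyama, fixed step.** All package-level claims about ensembles
  are distributional (means, variances, densities), for which weak order 1
  suffices; a higher-order scheme would buy nothing but opacity in the noise
  convention. A warning fires when `dt` exceeds a tenth of the local
  relaxation time.
* **Reproducibility.** Each trajectory draws from its own stream seeded by a
  deterministic function of the ensemble seed and the trajectory index
  (`derive_seeds()`). Trajectory `j` is bit-identical regardless of how many
  trajectories are simulated — ensemble size is not allowed to leak into
  individual noise histories.
* **Grids.** Spatial derivatives are second-order central differences
  (one-sided at the boundaries), integrals are trapezoidal; both match the
  `O(dz^2)` error budget of the checks. Density cells below `1e-300`
  contribute nothing to the production integral: they carry no resolvable
  flux.
* `discretize_model()` maps a Langevin model to a nearest-neighbour birth–
  death chain (`w_± = D/dz^2 ± mu F/(2 dz)`, clipped at zero). The tests use
  it to show the discrete and continuous entropy accounts converge to each
  other as the grid refines — the two engines are mutually consistent, not
  merely individually plausible.

## 3. The Brownian particle in gravity

The particle (mass `m`, friction `k`, bath temperature `T`, optional drive
`F0(t)`) is the closed-form reference system: every thermodynamic quantity
has an exact expression against which the generic machinery is tested.
Parameter notes:

* `T` defaults to 300 K. The headline velocity scales (2 μm/s for a
  microgram particle, 0.002 μm/s for a gram) are insensitive to any
  physiological temperature choice within 290–310 K.
* The masses are taken as printed (1 μg, 1 g) rather than recomputed from a
  size and density; the derived numbers follow from the mass directly.
* The drive integral `∫ e^{γt'} F0(t') dt'` is evaluated in closed form when
  `F0` is constant and by adaptive quadrature (`stats::integrate`,
  `rel.tol 1e-10`) otherwise.
* The position-entropy ledger `dS_x/dt = S_pr,x − S_fl,x` holds *exactly*
  and by construction; numerically the identity is verified relative to the
  size of the balancing terms, since the flow can exceed the net rate by
  many orders of magnitude and absolute comparisons would only measure
  floating-point cancellation.
* The production/flow grouping `(mg + F0)^2 / (γ k^2 σ_x^2)` was fixed by
  two independent consistency requirements — it reproduces the undriven
  asymptote `m^3 g^2/(k^3 σ_x^2)` and equals `k <v>^2 / (k_B T)` under
  fluctuation–dissipation — and both are asserted in the tests.

## 4. Bipartite systems: which entropy rate enters the demon identity

For two subsystems that never jump simultaneously, the package reports
*both* of the local entropy-rate notions that appear in this literature,
because they are not interchangeable:

* `ds_x_partial` — the contribution of X-jumps to the rate of the *joint*
  entropy. The partial rates sum exactly to `dS_xy/dt`, and satisfy
  `S_pr,x = ds_x_partial + S_fl,x` with no information term.
* `ds_x` — the rate of the *marginal* entropy `S_x` (in a bipartite system
  only X-jumps move the X-marginal). This is the quantity for which the
  demon identity holds:

      S_pr,x = ds_x + S_fl,x − I_x,

  with the information flow `I_x` of the X-jumps. The two notions differ by
  exactly that flow, `ds_x = ds_x_partial + I_x`, and the flows sum to the
  mutual-information rate.

Writing one symbol for both rates makes the joint-entropy split and the
demon identity look simultaneously true with a single definition; they are
not, and `local_entropy_terms()` keeps them apart so that every identity in
the module holds to `1e-10` on random instances. Conditional-probability
logarithms with a vanishing marginal follow the flux-weighted convention of
the single-system engine (a zero flux silences the term; a live flux against
a zero probability propagates the divergence).

The Maxwell-demon regime (`ds_x + S_fl,x < 0` while `S_pr,x >= 0`, possible
only with `I_x < 0`) is exercised by a fixed 2×2 instance found by seeded
search over random rate tensors and frozen in the test helpers; at its
stationary state the X-subsystem visibly "violates" the second law until the
information flow is put on the books.

## 5. Neural inference of a stochastic velocity

The linear recurrent population model is used in its mean-field form: the
population rate relaxes toward `kappa * cbar(v)` with effective constants
`kappa = 1/(1 - w_bar tau_n0)`, `tau_n = kappa tau_n0`,
`sigma_r = kappa sigma_r0`. Design choices:

* **Preferred-velocity ensemble.** The population average of the Gaussian
  tuning curve is taken over preferred velocities `u_i ~ Normal(0, alpha^2)`.
  In the `alpha >> epsilon` regime this yields
  `cbar(v) = (r_m epsilon/alpha) exp(-v^2/2 alpha^2)`; the exact Gaussian
  integral (`r_m epsilon / sqrt(alpha^2 + epsilon^2)` at the peak) and a
  Monte-Carlo average over a million neurons stand as oracles in the tests.
  A warning fires if `alpha/epsilon < 10`, where the series forms degrade.
* **Stimulus generator.** The stationary-information formula assumes the
  squared velocity decorrelates exponentially with time `tau_c`. The
  generator uses the simplest Gaussian process with that property: an OU
  velocity with relaxation time `2 tau_c` and variance `sqrt(C0/2)`, since
  for a Gaussian OU process `cov(v^2)` decays at twice the velocity rate
  with amplitude twice the squared variance. Other stimulus constructions
  can be swapped in through the `stimulus_model` contract, but the defaults
  define the study conditions and are not tuned per analysis.
* **Verified grouping.** The stationary mutual information is implemented as
  `prefactor * C0 tau_n^2 tau_c / (tau_n + tau_c)`. The grouping was fixed
  *before* coding by evaluating the defining double integral: with
  `a = 1/tau_n`, the large-`t` limit of
  `e^{-2t/tau_n} ∫∫ e^{(t1+t2)/tau_n} C0 e^{-|t1-t2|/tau_c}` is
  `C0/(a (a + 1/tau_c))`, which is exactly that expression. The quadrature
  cross-check (bounded kernel `e^{(t1-t)/tau_n} e^{(t2-t)/tau_n}`, trapezoid
  on a 601-point grid) is part of the acceptance tests at 0.5%.
* **Conditional entropy production.** The printed closed form of the
  tracking cost is typographically ambiguous, so the implementation derives
  it from the continuous production integral with the Gaussian conditional
  law, giving

      S = e^{-4t/tau_n} / (tau_n (1 - e^{-2t/tau_n}))
          + N (<rbar(t)> - kappa cbar(v))^2 / (sigma_r^2 tau_n).

  The grid evaluation of the same Gaussian density through the generic
  Fokker–Planck engine reproduces it to 1%, and its long-time prefactor
  `N (eps kappa r_m)^2/(4 alpha^6 sigma_r^2 tau_n)` matches the
  mutual-information prefactor up to `2 sigma_r^2/tau_n` — the
  information/energy proportionality the model is built to exhibit.
* **Negative rates.** The linear SDE can transiently produce negative rates;
  they are left unclipped because all closed forms assume the exactly
  Gaussian law. The simulated fraction of negative samples is reported as a
  diagnostic attribute.

## 6. Stochastic BCM plasticity

The collective weight of `n_s` synapses moves in the quartic effective
potential `V0` with the stimulus perturbation `dV`; both are the exact
integrals of the force and are verified against quadrature at `1e-10`. The
bistability condition, fixed points, Kramers times and the two-state
reduction follow the standard weak-noise construction; curvatures in the
Kramers prefactor are analytic.

Parameter interpretation and regime facts, established before the
acceptance checks were written:

* The nominal configuration (`bcm_params()` defaults: λ = 1.3, β = 1.2,
  f̄ = 0.9 Hz, τ_w = 200 s, σ_w = 5, N_s = 1000, τ_n0 = 0.3 s, tuning peak
  10 Hz at 10 mm/s, width 0.1 mm/s) uses the single-neuron constant τ_n0
  wherever the reduced force appears; no separate enhanced constant enters
  this module.
* With these numbers the down-state barrier is `V0(w_m) ≈ 2.9e-6` while the
  collective diffusion scale is `D = σ_w²/(N_s τ_w) = 1.25e-4`: the barrier
  is ~0.02 diffusion units. The down state is therefore only marginally
  metastable — noise alone induces up-transitions on a few-hundred-second
  scale (spontaneous "false memories"), while the up state sits behind
  ~1.5e3 diffusion units and is effectively permanent. Consequences: the
  up-transition statistics at long horizons are noise-dominated, and a
  too-fast stimulus cannot be distinguished from no stimulus by the final
  state at 2000 s. The deterministic mechanism — a slow ramp sweeping the
  tuning curve deposits a net positive weight kick, a 100× faster ramp does
  not — is tested noise-free with the weight floored at zero.
* At the pulse peak the input rate reaches `r_m = 10 Hz`, where `βr ≫ 1`
  puts the BCM rule deep in its depression branch; without a floor the
  pulse transiently drives the collective weight far negative before
  recovery. The floor (`floor_at_zero`) is therefore available but off by
  default, preserving the analytic potential picture.
* The threshold variable must be fast compared with the *local weight
  relaxation time* near the strong state (~40 s at the nominal parameters),
  not merely with τ_w; the two-equation/one-equation comparison in the
  tests uses τ_θ = 1 s for that reason, while the default τ_θ = 10 s matches
  the physiological order of magnitude and triggers the quasi-static
  warning only when τ_θ/τ_w > 0.2.
* **Escape studies** use a time-rescaled configuration (λ × 10, τ_w / 10 —
  an exact time rescaling that preserves the fixed points and barrier/noise
  ratios) with σ_w chosen so the down barrier is 4–5 diffusion units: large
  enough for the weak-noise formula to be meaningful, small enough that a
  few hundred escapes are simulated in seconds. The equal-depth
  ("symmetric") double well used for the `T_d = T_u` check is the β_f = 8/9
  member of the family (λ = 10/9 at τ_w = 20 s), where the three fixed
  points are exactly equidistant.
* The exact mean-first-passage-time double integral (reflecting lower
  boundary, absorbing past the barrier) is evaluated in exponent-difference
  form to avoid overflow beyond the barrier, and serves as a second,
  simulation-free oracle for the Kramers expression.

The two-state memory obeys `S_w = -dD_KL/dt >= 0` with total dissipation
equal to the initially stored information, independent of the memory
lifetime; both identities are checked by quadrature at `1e-8` and across two
decades of `omega_0`.

## 7. Pair approximation for synapse chains

For `n_s` synapses with `K` states and nearest-neighbour-dependent rates,
the joint law is closed over singles and adjacent pairs with the three-site
factorization `P(l, s', r) ≈ P(l, s') P(s', r)/P(s')`. Implementation
decisions:

* **Boundaries.** Synapse 1 depends only on synapse 2 (and mirrored at
  `n_s`): its pair flux needs no closure at all. The missing neighbour is
  passed to the user's rate function as `NA`, keeping the boundary
  convention explicit and overridable.
* **Component count.** The integrated system has exactly
  `n_s K + (n_s − 1) K²` components (the smaller `K(K+1) n_s/2` counts
  independent components after the normalization and marginal constraints);
  both counts are asserted for `K = 2`.
* **Consistency projection.** The closed equations preserve normalization
  and marginal consistency exactly in continuous time; at finite integrator
  tolerance small drifts can accumulate. After each output time the maximal
  marginal mismatch is measured and, above `1e-6`, the tables are corrected
  by iterative proportional fitting toward the stored singles. In the test
  problems the projection never has to fire, but it bounds the failure mode
  on stiffer chains.
* **Zero guards.** Closure denominators are floored at `1e-300` with the
  convention that a vanishing numerator pair silences the term.
* The KL functional of the pair representation (pairs minus interior
  singles) provides the information-gain rate; its fluxes come from the same
  closed equations, so the rate is exactly zero at a stationary pair
  distribution and matches the finite-difference KL of the reconstructed
  joint on small chains to within the closure error.
* The "learning" driver used in examples and tests — a multiplicative boost
  of up-transitions, optionally cooperative in the number of strong
  neighbours — is an illustrative fixture, not a mechanistic claim about any
  specific receptor pathway.

Exact solutions (`exact_evolve`) are available up to 65 536 joint states via
a sparse generator; beyond that the solver refuses and points to the pair
route.

## 8. What the generators do and do not emulate

The synthetic inputs are mathematical reference processes: OU stimuli with
exponentially decorrelating squared velocity, Gaussian white synaptic noise,
uniform random rate tensors for the identity checks. They reproduce the
*assumptions* of the closed forms, which is precisely what makes them usable
as oracles — and is also their limitation. Passing tests show the
implementation solves these models correctly; they do not show that real
stimuli decorrelate exponentially, that synaptic noise is white, or that
cortical plasticity follows the BCM rule. Heterogeneous weight matrices,
spiking dynamics, multidimensional Fokker–Planck problems and 2-D synapse
lattices are out of scope.

## 9. Problem sizes

The shipped tests and the acceptance script use: random discrete systems of
2–5 states (200 instances for the identity suite); 2000–4000-trajectory
ensembles for distributional checks at 3 standard errors; 2000-point grids
for 1% Fokker–Planck comparisons and 601-point-per-axis grids for the 0.5%
mutual-information quadrature; 220 first-passage escapes against the Kramers
prediction (factor-2 agreement on the log scale); ten seeded 2000 s learning
runs per stimulus condition; and 6-synapse binary chains (64 joint states)
for pair-versus-exact comparisons at total-variation 0.05. These sizes were
chosen so each check's statistical resolution comfortably exceeds the
tolerance it enforces.
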