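#' Boltzmann constant (J/K)
#' @export
kB <- 1.380649e-23

#' Brownian particle in gravity: parameter set
#'
#' A particle of mass `m` falling under gravity with friction coefficient `k`,
#' thermal noise at bath temperature `T`, and an optional modulating external
#' force `F0(t)`. The velocity obeys
#' \deqn{m\dot v = -k v + F(t) + \sqrt{2 m k}\,\sigma_v\,\eta, \quad
#'       F(t) = m g + F_0(t),}
#' and in the overdamped limit the height obeys
#' \eqn{\dot x = -F(t)/k - \sqrt{2\gamma}\,\sigma_x\,\eta}. Derived scales:
#' \eqn{\gamma = k/m}, \eqn{\sigma_v = \sqrt{k_B T/m}} (fluctuation-
#' dissipation), \eqn{\sigma_x = \sigma_v/\gamma}.
#'
#' @param m Mass (kg).
#' @param k Friction coefficient (kg/s).
#' @param T Bath temperature (K), default 300.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @param F0 External force: a constant (N) or a function of time; default 0.
#' @return An object of class `particle_params` with fields `gamma`,
#'   `sigma_v`, `sigma_x` precomputed.
#' @export
#' @examples
#' pp <- particle_params(m = 1e-9, k = 2e-8)
#' pp$sigma_v # about 2 um/s at 300 K
particle_params <- function(m, k, T = 300, g = 9.81, F0 = 0) {
  assert_positive(m, "m"); assert_positive(k, "k"); assert_positive(T, "T")
  F0_fun <- if (is.function(F0)) F0 else {
    force(F0); function(t) rep(F0, length(t))
  }
  gamma <- k / m
  sigma_v <- sqrt(kB * T / m)
  structure(list(
    m = m, k = k, T = T, g = g, F0 = F0_fun,
    gamma = gamma, sigma_v = sigma_v, sigma_x = sigma_v / gamma
  ), class = "particle_params")
}

#' @export
print.particle_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<particle_params> m = %g kg, k = %g kg/s, T = %g K\n",
    "  gamma = %g 1/s, sigma_v = %g m/s, sigma_x = %g m\n"),
    x$m, x$k, x$T, x$gamma, x$sigma_v, x$sigma_x))
  invisible(x)
}

#' Thermal velocity scale from the fluctuation-dissipation theorem
#'
#' \eqn{\sigma_v = \sqrt{k_B T / m}}: the stationary standard deviation of the
#' velocity of a thermalized particle of mass `m` at temperature `T`.
#'
#' @param m Mass (kg).
#' @param T Temperature (K).
#' @return Velocity standard deviation (m/s).
#' @export
#' @examples
#' sigma_v_fdt(1e-9, 300) * 1e6 # ~2 um/s for a 1-ug particle
sigma_v_fdt <- function(m, T = 300) {
  assert_positive(m, "m"); assert_positive(T, "T")
  sqrt(kB * T / m)
}

# exp(gamma t') F(t')/m integrated over [0, t]; closed form for constant F0.
.drive_integral <- function(params, t) {
  Fconst <- params$F0(c(0, t / 2, t))
  if (max(abs(Fconst - Fconst[1])) < 1e-300 * max(1, abs(Fconst[1]))) {
    Ftot <- params$m * params$g + Fconst[1]
    return(Ftot / (params$m * params$gamma) * (exp(params$gamma * t) - 1))
  }
  integrate(function(s) exp(params$gamma * s) *
              (params$m * params$g + params$F0(s)) / params$m,
            0, t, rel.tol = 1e-10)$value
}

#' Velocity mean and variance at time t
#'
#' Gaussian law of the underdamped velocity:
#' mean \eqn{[v_0 + \int_0^t e^{\gamma t'} F(t')/m\,dt'] e^{-\gamma t}},
#' variance \eqn{\sigma_v^2 (1 - e^{-2\gamma t})}.
#'
#' @param params A [particle_params()].
#' @param v0 Initial velocity (m/s).
#' @param t Time(s) (s), each >= 0.
#' @return Tibble with columns `t`, `mean`, `var`.
#' @export
velocity_moments <- function(params, v0, t) {
  stopifnot(inherits(params, "particle_params"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  mean_v <- vapply(t, function(ti) {
    if (ti == 0) return(v0)
    (v0 + .drive_integral(params, ti)) * exp(-params$gamma * ti)
  }, numeric(1))
  tibble(t = t, mean = mean_v,
         var = params$sigma_v^2 * (1 - exp(-2 * params$gamma * t)))
}

#' Position mean and variance in the overdamped limit
#'
#' Mean \eqn{x_0 - (1/k)\int_0^t F(t')\,dt'} (the height decreases as the
#' particle falls) and variance \eqn{2\sigma_x^2\gamma t}, the signature of
#' unrestricted Brownian motion.
#'
#' @inheritParams velocity_moments
#' @param x0 Initial position (m).
#' @return Tibble with columns `t`, `mean`, `var`.
#' @export
position_moments <- function(params, x0, t) {
  stopifnot(inherits(params, "particle_params"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  mean_x <- vapply(t, function(ti) {
    if (ti == 0) return(x0)
    drive <- integrate(function(s) params$m * params$g + params$F0(s),
                       0, ti, rel.tol = 1e-10)$value
    x0 - drive / params$k
  }, numeric(1))
  tibble(t = t, mean = mean_x,
         var = 2 * params$sigma_x^2 * params$gamma * t)
}

#' Rate of change of mean mechanical energy
#'
#' Energy balance of the falling particle:
#' \deqn{d\langle E\rangle/dt = -k\langle v^2\rangle + \langle v\rangle F_0(t)
#'       + k\sigma_v^2}
#' (friction loss, external-force work, thermal energy input). The overdamped
#' variant is \eqn{-(mg/k)(mg + F_0)}.
#'
#' @param params A [particle_params()].
#' @param mean_v Mean velocity (m/s).
#' @param mean_v2 Mean squared velocity (m^2/s^2), must be >= `mean_v`^2.
#' @param F0_t External force at the evaluation time (N).
#' @param overdamped If `TRUE`, return the overdamped form instead.
#' @return Power (W).
#' @export
mech_energy_rate <- function(params, mean_v, mean_v2, F0_t = 0,
                             overdamped = FALSE) {
  stopifnot(inherits(params, "particle_params"))
  if (overdamped) {
    return(-(params$m * params$g / params$k) * (params$m * params$g + F0_t))
  }
  if (mean_v2 < mean_v^2 - 1e-12 * abs(mean_v2)) {
    abort("`mean_v2` must be >= mean_v^2.")
  }
  -params$k * mean_v2 + mean_v * F0_t + params$k * params$sigma_v^2
}

#' Entropy ledger of the particle position
#'
#' Closed-form entropy bookkeeping for the overdamped position distribution:
#' \deqn{S_x = \tfrac12\ln(4\pi e\,\sigma_x^2\gamma t), \quad
#'       dS_x/dt = 1/(2t),}
#' \deqn{\dot S_{pr,x} = \frac{1}{2t} + \frac{(mg+F_0)^2}{\gamma k^2\sigma_x^2},
#'       \quad \dot S_{fl,x} = \frac{(mg+F_0)^2}{\gamma k^2\sigma_x^2},}
#' so `ds_dt = entropy_production - entropy_flow` exactly. With no driving the
#' production rate decays to the asymptote \eqn{m^3 g^2/(k^3\sigma_x^2)}; the
#' flow equals \eqn{k\langle v\rangle^2 / (k_B T)} with
#' \eqn{\langle v\rangle = (mg+F_0)/k}.
#'
#' @inheritParams velocity_moments
#' @param t Time(s), each > 0.
#' @return Tibble with columns `t`, `entropy`, `ds_dt`, `entropy_production`,
#'   `entropy_flow` (nats, nats/s).
#' @export
position_entropy_terms <- function(params, t) {
  stopifnot(inherits(params, "particle_params"))
  if (any(t <= 0)) abort("`t` must be > 0.")
  F0t <- params$F0(t)
  drive2 <- (params$m * params$g + F0t)^2
  fl <- drive2 / (params$gamma * params$k^2 * params$sigma_x^2)
  tibble(
    t = t,
    entropy = 0.5 * log(4 * pi * exp(1) * params$sigma_x^2 * params$gamma * t),
    ds_dt = 1 / (2 * t),
    entropy_production = 1 / (2 * t) + fl,
    entropy_flow = fl
  )
}

#' First-law residual in the overdamped regime
#'
#' Residual of
#' \eqn{d\langle E\rangle/dt = -k_B T\,\dot S_{fl,x} + F_0\langle v\rangle}
#' with the overdamped forms of both sides; zero identically for any constant
#' `F0`. The helper flags times where the overdamped approximation itself is
#' doubtful (`gamma * t < 10`).
#'
#' @inheritParams position_entropy_terms
#' @return Tibble with columns `t`, `residual` (W) and `overdamped_ok`.
#' @export
first_law_check <- function(params, t) {
  stopifnot(inherits(params, "particle_params"))
  if (any(t <= 0)) abort("`t` must be > 0.")
  F0t <- params$F0(t)
  mean_v <- (params$m * params$g + F0t) / params$k
  lhs <- vapply(F0t, function(f)
    mech_energy_rate(params, 0, 0, f, overdamped = TRUE), numeric(1))
  s_fl <- position_entropy_terms(params, t)$entropy_flow
  rhs <- -kB * params$T * s_fl + F0t * mean_v
  tibble(t = t, residual = abs(lhs - rhs),
         overdamped_ok = params$gamma * t >= 10)
}

#' Langevin model of the particle velocity
#'
#' The underdamped velocity dynamics as a [langevin_model()]:
#' \eqn{\dot v = \gamma(F(t)/k - v) + \sqrt{2\gamma}\,\sigma_v\,\eta}, i.e.
#' `mu = gamma`, `sigma = sigma_v sqrt(2/gamma)`, `F = F(t)/k - v`.
#'
#' @param params A [particle_params()].
#' @return A [langevin_model()] whose state variable is the velocity (m/s).
#' @export
particle_velocity_model <- function(params) {
  stopifnot(inherits(params, "particle_params"))
  langevin_model(
    force = function(z, t) (params$m * params$g + params$F0(t)) / params$k - z,
    mu = params$gamma,
    sigma = params$sigma_v * sqrt(2 / params$gamma)
  )
}

#' Langevin model of the overdamped particle position
#'
#' \eqn{\dot x = -F(t)/k - \sqrt{2\gamma}\,\sigma_x\,\eta}: `mu = 1/k`,
#' `F = -F(t)`, `sigma` chosen so the diffusion coefficient is
#' \eqn{\gamma\sigma_x^2}.
#'
#' @inheritParams particle_velocity_model
#' @return A [langevin_model()] whose state variable is the height (m).
#' @export
particle_position_model <- function(params) {
  stopifnot(inherits(params, "particle_params"))
  langevin_model(
    force = function(z, t) -(params$m * params$g + params$F0(t)) + 0 * z,
    mu = 1 / params$k,
    sigma = sqrt(2 * params$gamma) * params$sigma_x * params$k
  )
}
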