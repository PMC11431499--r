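#' Stochastic BCM plasticity: parameter set
#'
#' Parameters of the stochastic BCM rule for `n_s` plastic synapses on a
#' single postsynaptic neuron,
#' \deqn{\dot w_i = \lambda f_i r (r - \theta) - w_i/\tau_w +
#'       \sqrt{2\sigma_w^2/\tau_w}\,\xi_i, \qquad
#'       \tau_\theta \dot\theta = -\theta + \beta r^2,}
#' and of its population-mean reduction (quasi-static threshold
#' \eqn{\theta \approx \beta r^2}, quasi-static neural rate
#' \eqn{r \approx c(v) + \tau_{n0}\bar f \bar w}):
#' \deqn{\dot{\bar w} = F_w(\bar w, c) +
#'       \sqrt{2\sigma_w^2/(N_s\tau_w)}\,\bar\xi.}
#' The defaults are the nominal configuration used throughout: plasticity
#' amplitude 1.3, threshold coupling 1.2, presynaptic rate 0.9 Hz, weight
#' decay 200 s, threshold time constant 10 s, per-synapse noise 5.0, 1000
#' synapses, neuron time constant 0.3 s, and a Gaussian input tuning curve
#' with peak 10 Hz at preferred velocity 10 mm/s and width 0.1 mm/s.
#'
#' @param lam Plasticity amplitude \eqn{\lambda}.
#' @param beta Sliding-threshold coupling \eqn{\beta}.
#' @param f_bar Mean presynaptic firing rate (Hz).
#' @param tau_w Weight decay time constant (s).
#' @param tau_theta Threshold time constant (s); `tau_theta/tau_w` should be
#'   small for the one-equation reduction (a warning is issued otherwise).
#' @param sigma_w Single-synapse weight noise standard deviation.
#' @param n_s Number of synapses.
#' @param tau_n0 Single-neuron time constant (s).
#' @param r_m,u,epsilon Input tuning curve: peak rate (Hz), preferred
#'   velocity and width (velocity units).
#' @return An object of class `bcm_params`; the collective diffusion
#'   coefficient `D = sigma_w^2/(n_s tau_w)` is precomputed.
#' @export
bcm_params <- function(lam = 1.3, beta = 1.2, f_bar = 0.9, tau_w = 200,
                       tau_theta = 10, sigma_w = 5, n_s = 1000,
                       tau_n0 = 0.3, r_m = 10, u = 10, epsilon = 0.1) {
  for (nm in c("lam", "beta", "f_bar", "tau_w", "tau_theta", "n_s",
               "tau_n0", "r_m", "epsilon")) {
    assert_positive(get(nm), nm)
  }
  if (sigma_w < 0) abort("`sigma_w` must be >= 0.")
  if (tau_theta / tau_w > 0.2) {
    warn("tau_theta/tau_w is not small; the quasi-static threshold reduction may be poor.")
  }
  structure(list(
    lam = lam, beta = beta, f_bar = f_bar, tau_w = tau_w,
    tau_theta = tau_theta, sigma_w = sigma_w, n_s = n_s, tau_n0 = tau_n0,
    r_m = r_m, u = u, epsilon = epsilon,
    D = sigma_w^2 / (n_s * tau_w)
  ), class = "bcm_params")
}

#' @export
print.bcm_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<bcm_params> lambda = %g, beta = %g, f_bar = %g Hz, tau_w = %g s,\n",
    "  sigma_w = %g, n_s = %g, tau_n0 = %g s, D = %g\n"),
    x$lam, x$beta, x$f_bar, x$tau_w, x$sigma_w, x$n_s, x$tau_n0, x$D))
  invisible(x)
}

#' Deterministic drift of the full two-variable BCM rule
#'
#' The drift parts of the weight and sliding-threshold equations, before any
#' timescale separation: \eqn{\dot w_i = \lambda f r(r-\theta) - w_i/\tau_w}
#' and \eqn{\dot\theta = (-\theta + \beta r^2)/\tau_\theta}.
#'
#' @param w_i Synaptic weight.
#' @param theta Sliding threshold.
#' @param r Postsynaptic rate (Hz).
#' @param params A [bcm_params()].
#' @param f Presynaptic rate for this synapse (defaults to `params$f_bar`).
#' @return One-row tibble (vectorized over inputs) with `dw` and `dtheta`.
#' @export
drift_full <- function(w_i, theta, r, params, f = params$f_bar) {
  stopifnot(inherits(params, "bcm_params"))
  tibble(
    dw = params$lam * f * r * (r - theta) - w_i / params$tau_w,
    dtheta = (-theta + params$beta * r^2) / params$tau_theta
  )
}

#' Generalized force on the population-mean synaptic weight
#'
#' \deqn{F_w(\bar w, c) = \lambda\bar f\,[c + \tau_{n0}\bar f\bar w]^2
#'  \big(1 - \beta[c + \tau_{n0}\bar f\bar w]\big) - \bar w/\tau_w,}
#' with the quasi-static rate \eqn{r = c + \tau_{n0}\bar f\bar w}.
#'
#' @param w_bar Population-mean weight (1/s); vectorized.
#' @param c Sensory input rate (Hz); vectorized or scalar.
#' @param params A [bcm_params()].
#' @return Force (1/s^2).
#' @export
population_force <- function(w_bar, c = 0, params) {
  stopifnot(inherits(params, "bcm_params"))
  r <- c + params$tau_n0 * params$f_bar * w_bar
  params$lam * params$f_bar * r^2 * (1 - params$beta * r) - w_bar / params$tau_w
}

#' Bistability analysis of the collective weight dynamics
#'
#' The deterministic dynamics at zero input have fixed points at
#' \eqn{\bar w_d = 0} and, when the bistability condition
#' \eqn{\lambda\tau_w\tau_{n0}\bar f^2 > 4\beta} holds, at
#' \deqn{\bar w_{m,u} = \frac{1 \mp \sqrt{1 - \beta_f}}{2\beta\tau_{n0}\bar f},
#'  \qquad \beta_f = \frac{4\beta}{\lambda\tau_w\tau_{n0}\bar f^2}.}
#'
#' @param params A [bcm_params()].
#' @return An object of class `bistability_report` (see [tidy()] and
#'   [glance()] methods) with fields `condition` (the value
#'   \eqn{\lambda\tau_w\tau_{n0}\bar f^2}), `threshold` (\eqn{4\beta}),
#'   `beta_f`, `bistable`, and fixed points `w_d`, `w_m`, `w_u` (the latter
#'   two `NA` in the monostable regime).
#' @export
#' @examples
#' bistability(bcm_params()) # nominal parameters: 63.18 > 4.8
bistability <- function(params) {
  stopifnot(inherits(params, "bcm_params"))
  cond <- params$lam * params$tau_w * params$tau_n0 * params$f_bar^2
  beta_f <- 4 * params$beta / cond
  bistable <- beta_f < 1
  denom <- 2 * params$beta * params$tau_n0 * params$f_bar
  root <- if (beta_f <= 1) sqrt(1 - beta_f) else NA_real_
  structure(list(
    condition = cond, threshold = 4 * params$beta, beta_f = beta_f,
    bistable = bistable,
    w_d = 0,
    w_m = if (beta_f <= 1) (1 - root) / denom else NA_real_,
    w_u = if (beta_f <= 1) (1 + root) / denom else NA_real_,
    params = params
  ), class = "bistability_report")
}

#' @export
print.bistability_report <- function(x, ...) {
  cat(sprintf("<bistability_report> condition %.4g %s threshold %.4g -> %s\n",
              x$condition, if (x$bistable) ">" else "<=", x$threshold,
              if (x$bistable) "bistable" else "monostable"))
  if (x$bistable) {
    cat(sprintf("  fixed points: w_d = %g, w_m = %.6g, w_u = %.6g\n",
                x$w_d, x$w_m, x$w_u))
  }
  invisible(x)
}

#' @rdname bistability
#' @param x A `bistability_report`.
#' @param ... Unused.
#' @method tidy bistability_report
#' @export
tidy.bistability_report <- function(x, ...) {
  tibble(
    fixed_point = c("down", "middle", "up"),
    w_bar = c(x$w_d, x$w_m, x$w_u),
    stability = c("stable", "unstable", "stable")
  )
}

#' @rdname bistability
#' @method glance bistability_report
#' @export
glance.bistability_report <- function(x, ...) {
  tibble(condition = x$condition, threshold = x$threshold,
         beta_f = x$beta_f, bistable = x$bistable)
}

#' Effective potential of the collective weight
#'
#' \eqn{V(\bar w, c) = V_0(\bar w) + \Delta V(\bar w, c) =
#' -\int_0^{\bar w} F_w(x, c)\,dx} with the core potential
#' \deqn{V_0 = \frac{\bar w^2}{2\tau_w} -
#'   \frac{\lambda\bar f^3\tau_{n0}^2}{3}\bar w^3 +
#'   \frac{\lambda\beta\bar f^4\tau_{n0}^3}{4}\bar w^4}
#' and the stimulus perturbation
#' \deqn{\Delta V = -\lambda\bar f c^2(1-\beta c)\bar w -
#'  \tfrac12\lambda\bar f^2\tau_{n0} c(2-3\beta c)\bar w^2 +
#'  \lambda\bar f^3\tau_{n0}^2\beta c\,\bar w^3.}
#'
#' @inheritParams population_force
#' @return Tibble with columns `w_bar`, `c`, `V0`, `dV`, `V`.
#' @export
bcm_potential <- function(w_bar, c = 0, params) {
  stopifnot(inherits(params, "bcm_params"))
  lam <- params$lam; beta <- params$beta; f <- params$f_bar
  a <- params$tau_n0 * f
  V0 <- w_bar^2 / (2 * params$tau_w) - lam * f * a^2 / 3 * w_bar^3 +
    lam * beta * f * a^3 / 4 * w_bar^4
  dV <- -lam * f * c^2 * (1 - beta * c) * w_bar -
    0.5 * lam * f * a * c * (2 - 3 * beta * c) * w_bar^2 +
    lam * f * a^2 * beta * c * w_bar^3
  tibble(w_bar = w_bar, c = c, V0 = V0, dV = dV, V = V0 + dV)
}

#' Curvature of the effective potential
#'
#' Analytic second derivative \eqn{V''(\bar w, c)}, used by the Kramers
#' prefactor.
#'
#' @inheritParams population_force
#' @return Curvature values (1/s^2 per weight^0 ... i.e. d^2V/dw^2).
#' @export
bcm_potential_curvature <- function(w_bar, c = 0, params) {
  stopifnot(inherits(params, "bcm_params"))
  lam <- params$lam; beta <- params$beta; f <- params$f_bar
  a <- params$tau_n0 * f
  1 / params$tau_w - 2 * lam * f * a^2 * w_bar + 3 * lam * beta * f * a^3 * w_bar^2 -
    lam * f * a * c * (2 - 3 * beta * c) + 6 * lam * f * a^2 * beta * c * w_bar
}

#' Kramers dwell times of the down and up states
#'
#' \deqn{T_d = \frac{2\pi}{\sqrt{V''_d |V''_m|}}
#'   \exp\Big\{\frac{N_s\tau_w}{\sigma_w^2}
#'   [(V_{0,m} - V_{0,d}) + (\Delta V_m - \Delta V_d)]\Big\}}
#' and analogously \eqn{T_u}, with curvatures of \eqn{V(\bar w, c)} evaluated
#' analytically at the zero-input fixed points. The exponent is the barrier
#' measured in units of the collective diffusion coefficient
#' \eqn{D = \sigma_w^2/(N_s\tau_w)}.
#'
#' @param params A [bcm_params()]; must be in the bistable regime.
#' @param c Input rate during the dwell (default 0).
#' @return One-row tibble with `T_d`, `T_u` (s), the barrier heights in
#'   diffusion units (`barrier_d_over_D`, `barrier_u_over_D`), and
#'   `weak_noise_ok` flags (barrier at least 3 diffusion units).
#' @export
kramers_times <- function(params, c = 0) {
  stopifnot(inherits(params, "bcm_params"))
  bis <- bistability(params)
  if (!bis$bistable) abort("Kramers times require the bistable regime.")
  pot <- function(w) bcm_potential(w, c, params)
  Vd <- pot(bis$w_d); Vm <- pot(bis$w_m); Vu <- pot(bis$w_u)
  cd <- bcm_potential_curvature(bis$w_d, c, params)
  cm <- bcm_potential_curvature(bis$w_m, c, params)
  cu <- bcm_potential_curvature(bis$w_u, c, params)
  if (cd <= 0 || cu <= 0 || cm >= 0) {
    warn("potential curvatures have unexpected signs at the fixed points under this input.")
  }
  barrier_d <- (Vm$V0 - Vd$V0) + (Vm$dV - Vd$dV)
  barrier_u <- (Vm$V0 - Vu$V0) + (Vm$dV - Vu$dV)
  tibble(
    T_d = 2 * pi / sqrt(abs(cd) * abs(cm)) * exp(barrier_d / params$D),
    T_u = 2 * pi / sqrt(abs(cu) * abs(cm)) * exp(barrier_u / params$D),
    barrier_d_over_D = barrier_d / params$D,
    barrier_u_over_D = barrier_u / params$D,
    weak_noise_ok = barrier_d / params$D >= 3 & barrier_u / params$D >= 3
  )
}

#' Two-state reduction of the bistable collective weight
#'
#' Collapses the continuous bistable dynamics to jumps between the down and
#' up states with rates \eqn{\omega_{ud} = 1/T_d} (down to up) and
#' \eqn{\omega_{du} = 1/T_u}, whose master equation is
#' \eqn{\dot p_u = \omega_{ud}(1 - p_u) - \omega_{du} p_u}.
#'
#' @inheritParams kramers_times
#' @return A [two_state_model()] whose baseline rates come from `c = 0` and
#'   whose active rates come from the supplied `c`.
#' @export
two_state_reduce <- function(params, c = 0) {
  k0 <- kramers_times(params, 0)
  kc <- if (c == 0) k0 else kramers_times(params, c)
  two_state_model(omega_ud0 = 1 / k0$T_d, omega_du0 = 1 / k0$T_u,
                  omega_ud = 1 / kc$T_d, omega_du = 1 / kc$T_u)
}

#' Two-state synaptic memory model
#'
#' Explicit container for the reduced memory dynamics: baseline
#' (post-stimulus) rates `omega_ud0`, `omega_du0` define the resting state
#' \eqn{p_{u,\infty} = \omega_{ud,0}/\omega_0} with
#' \eqn{\omega_0 = \omega_{ud,0} + \omega_{du,0}} and the memory lifetime
#' \eqn{T_m = 1/\omega_0}; optional active rates describe the stimulus-on
#' period.
#'
#' @param omega_ud0,omega_du0 Baseline transition rates (1/s), > 0.
#' @param omega_ud,omega_du Active (stimulus-on) rates; default the baseline.
#' @return An object of class `two_state_model`.
#' @export
two_state_model <- function(omega_ud0, omega_du0,
                            omega_ud = omega_ud0, omega_du = omega_du0) {
  assert_positive(omega_ud0, "omega_ud0"); assert_positive(omega_du0, "omega_du0")
  omega0 <- omega_ud0 + omega_du0
  structure(list(
    omega_ud0 = omega_ud0, omega_du0 = omega_du0,
    omega_ud = omega_ud, omega_du = omega_du,
    omega0 = omega0, p_u_inf = omega_ud0 / omega0,
    memory_lifetime = 1 / omega0
  ), class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<two_state_model> omega_ud0 = %.4g, omega_du0 = %.4g 1/s\n",
    "  p_u_inf = %.4g, memory lifetime T_m = %.4g s\n"),
    x$omega_ud0, x$omega_du0, x$p_u_inf, x$memory_lifetime))
  invisible(x)
}

#' @rdname two_state_model
#' @param x A `two_state_model`.
#' @param ... Unused.
#' @method glance two_state_model
#' @export
glance.two_state_model <- function(x, ...) {
  tibble(omega_ud0 = x$omega_ud0, omega_du0 = x$omega_du0,
         omega0 = x$omega0, p_u_inf = x$p_u_inf,
         memory_lifetime = x$memory_lifetime)
}

#' Baseline rate matrix of a two-state memory model
#'
#' States ordered (down, up); useful for cross-checking the relaxation law
#' against [evolve_master()].
#'
#' @param ts A [two_state_model()].
#' @return A [rate_matrix()].
#' @export
two_state_rate_matrix <- function(ts) {
  stopifnot(inherits(ts, "two_state_model"))
  rate_matrix(matrix(c(0, ts$omega_ud0, ts$omega_du0, 0), 2, 2),
              states = c("down", "up"))
}

#' Relaxation of the up-state occupancy
#'
#' \eqn{p_u(t) = [p_u(0) - p_{u,\infty}] e^{-\omega_0 t} + p_{u,\infty}}.
#'
#' @inheritParams two_state_rate_matrix
#' @param p_u0 Initial up-state probability.
#' @param t Time(s).
#' @return Tibble with columns `t`, `p_u`.
#' @export
two_state_relax <- function(ts, p_u0, t) {
  stopifnot(inherits(ts, "two_state_model"))
  tibble(t = t, p_u = (p_u0 - ts$p_u_inf) * exp(-ts$omega0 * t) + ts$p_u_inf)
}

#' Information decay and entropy production of the two-state memory
#'
#' After learning leaves the up-state occupancy perturbed by
#' \eqn{\Delta = p_u(0) - p_{u,\infty}}, the stored information (KL
#' divergence from the resting distribution) decays as
#' \deqn{D_{KL}(t) = (p_{d,\infty} - \Delta e^{-\omega_0 t})
#'  \ln[1 - (\Delta/p_{d,\infty}) e^{-\omega_0 t}] +
#'  (p_{u,\infty} + \Delta e^{-\omega_0 t})
#'  \ln[1 + (\Delta/p_{u,\infty}) e^{-\omega_0 t}],}
#' and the entropy production rate of the relaxing weights is exactly the
#' information loss rate, \eqn{\dot S_w = -\dot D_{KL} \ge 0}. The total
#' entropy produced over the whole relaxation equals the initially stored
#' information \eqn{D_{KL}(0)} and is independent of the memory lifetime.
#'
#' @inheritParams two_state_rate_matrix
#' @param t Time(s) (s).
#' @param delta Initial perturbation \eqn{\Delta}, in
#'   \eqn{(-p_{u,\infty},\,p_{d,\infty})}.
#' @return Tibble with columns `t`, `d_kl`, `d_kl_rate`,
#'   `entropy_production` (nats, nats/s).
#' @export
memory_information <- function(ts, t, delta) {
  stopifnot(inherits(ts, "two_state_model"))
  pu <- ts$p_u_inf; pd <- 1 - pu
  if (delta <= -pu || delta >= pd) {
    abort("`delta` must lie in (-p_u_inf, p_d_inf).")
  }
  e <- exp(-ts$omega0 * t)
  term_d <- (pd - delta * e) * log1p(-delta * e / pd)
  term_u <- (pu + delta * e) * log1p(delta * e / pu)
  rate <- -ts$omega0 * delta * e *
    (log1p(delta * e / pu) - log1p(-delta * e / pd))
  tibble(t = t, d_kl = term_d + term_u, d_kl_rate = rate,
         entropy_production = -rate)
}

#' Total entropy produced while a memory fades
#'
#' Closed form \eqn{S_{w,tot} = p_d(0)\ln[p_d(0)/p_{d,\infty}] +
#' p_u(0)\ln[p_u(0)/p_{u,\infty}] = D_{KL}(t{=}0)}.
#'
#' @inheritParams memory_information
#' @return Total entropy produced (nats).
#' @export
memory_total_entropy <- function(ts, delta) {
  stopifnot(inherits(ts, "two_state_model"))
  pu <- ts$p_u_inf; pd <- 1 - pu
  if (delta <= -pu || delta >= pd) {
    abort("`delta` must lie in (-p_u_inf, p_d_inf).")
  }
  pu0 <- pu + delta; pd0 <- pd - delta
  xlogx_ratio <- function(p, pref) if (p == 0) 0 else p * log(p / pref)
  xlogx_ratio(pd0, pd) + xlogx_ratio(pu0, pu)
}

#' Simulate the collective weight under a moving stimulus
#'
#' Euler-Maruyama integration of the population weight SDE with input
#' \eqn{c(t) = c(v(t))} from the Gaussian tuning curve and a velocity ramp
#' \eqn{v(t) = v_0 + a t} (or an arbitrary velocity function). Trajectories
#' are vectorized and share the stimulus; each draws noise from its own
#' seeded stream.
#'
#' @param params A [bcm_params()].
#' @param v_fun Velocity path: function of time, or `NULL` to use the ramp
#'   `v0 + accel * t`.
#' @param v0,accel Ramp parameters (velocity units, velocity/s), used when
#'   `v_fun` is `NULL`. Defaults 7 and 0.02.
#' @param w0 Initial collective weight.
#' @param dt Time step (s).
#' @param t_end Final time (s).
#' @param n_traj Number of trajectories.
#' @param seed Integer seed.
#' @param floor_at_zero Reflect the weight at 0 (display convenience;
#'   default `FALSE`, preserving the analytic potential picture).
#' @param keep_every Thinning factor for storage.
#' @return Tibble with columns `traj`, `time`, `w`; attributes `seed`, `dt`.
#' @export
simulate_learning <- function(params, v_fun = NULL, v0 = 7, accel = 0.02,
                              w0 = 0, dt = 0.05, t_end = 2000, n_traj = 1L,
                              seed = 1L, floor_at_zero = FALSE,
                              keep_every = 20L) {
  stopifnot(inherits(params, "bcm_params"))
  assert_positive(dt, "dt")
  if (dt > params$tau_n0 / 2) {
    warn("dt is not small compared with tau_n0.")
  }
  if (is.null(v_fun)) v_fun <- function(t) v0 + accel * t
  n_steps <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  cvec <- tuning_curve(v_fun(times), params$u, params$r_m, params$epsilon)
  amp <- sqrt(2 * params$D * dt)
  seeds <- derive_seeds(seed, n_traj)
  keep_idx <- seq(1L, n_steps + 1L, by = keep_every)
  # noise is generated per trajectory stream but the update is vectorized
  # across trajectories step by step, in blocks to bound memory
  out_w <- matrix(NA_real_, length(keep_idx), n_traj)
  w <- rep(w0, n_traj)
  block <- 4096L
  noise <- matrix(0, block, n_traj)
  rng_states <- vector("list", n_traj)
  for (j in seq_len(n_traj)) {
    set.seed(seeds[j]); rng_states[[j]] <- get(".Random.seed", envir = globalenv())
  }
  keep_ptr <- 1L
  if (keep_idx[1] == 1L) { out_w[1L, ] <- w; keep_ptr <- 2L }
  i <- 1L
  while (i <= n_steps) {
    nb <- min(block, n_steps - i + 1L)
    for (j in seq_len(n_traj)) {
      assign(".Random.seed", rng_states[[j]], envir = globalenv())
      noise[seq_len(nb), j] <- rnorm(nb)
      rng_states[[j]] <- get(".Random.seed", envir = globalenv())
    }
    for (b in seq_len(nb)) {
      step <- i + b - 1L
      w <- w + population_force(w, cvec[step], params) * dt +
        amp * noise[b, ]
      if (floor_at_zero) w <- pmax(w, 0)
      if (keep_ptr <= length(keep_idx) && keep_idx[keep_ptr] == step + 1L) {
        out_w[keep_ptr, ] <- w
        keep_ptr <- keep_ptr + 1L
      }
    }
    i <- i + nb
  }
  out <- tibble(
    traj = rep(seq_len(n_traj), each = length(keep_idx)),
    time = rep(times[keep_idx], n_traj),
    w = as.numeric(out_w)
  )
  attr(out, "seed") <- seed
  attr(out, "dt") <- dt
  out
}

#' First-passage times of the collective weight out of the down state
#'
#' Simulates the zero-input weight SDE from `w_start` until absorption at
#' `w_absorb` (beyond the barrier) and returns the passage time of each
#' trajectory. The ensemble mean estimates the Kramers dwell time `T_d`.
#'
#' @inheritParams simulate_learning
#' @param c Input rate held fixed during the passage (default 0).
#' @param w_start Starting weight (default the down state, 0).
#' @param w_absorb Absorbing threshold; default halfway between the middle
#'   and up fixed points.
#' @param t_max Hard cap per trajectory (s); unabsorbed trajectories return
#'   `NA`.
#' @return Numeric vector of first-passage times (s), one per trajectory.
#' @export
first_passage_times <- function(params, c = 0, w_start = 0, w_absorb = NULL,
                                dt = 0.1, n_traj = 100L, seed = 1L,
                                t_max = NULL) {
  stopifnot(inherits(params, "bcm_params"))
  bis <- bistability(params)
  if (!bis$bistable) abort("first-passage analysis requires bistability.")
  if (is.null(w_absorb)) w_absorb <- (bis$w_m + bis$w_u) / 2
  kt <- kramers_times(params, c)
  if (is.null(t_max)) t_max <- 50 * kt$T_d
  amp <- sqrt(2 * params$D * dt)
  seeds <- derive_seeds(seed, n_traj)
  n_max <- ceiling(t_max / dt)
  fpt <- rep(NA_real_, n_traj)
  alive <- seq_len(n_traj)
  w <- rep(w_start, n_traj)
  rng_states <- vector("list", n_traj)
  for (j in seq_len(n_traj)) {
    set.seed(seeds[j]); rng_states[[j]] <- get(".Random.seed", envir = globalenv())
  }
  block <- 4096L
  i <- 0L
  while (i < n_max && length(alive) > 0) {
    nb <- min(block, n_max - i)
    noise <- matrix(0, nb, length(alive))
    for (jj in seq_along(alive)) {
      j <- alive[jj]
      assign(".Random.seed", rng_states[[j]], envir = globalenv())
      noise[, jj] <- rnorm(nb)
      rng_states[[j]] <- get(".Random.seed", envir = globalenv())
    }
    wa <- w[alive]
    done <- logical(length(alive))
    for (b in seq_len(nb)) {
      live <- !done
      if (!any(live)) break
      wa[live] <- wa[live] + population_force(wa[live], c, params) * dt +
        amp * noise[b, live]
      hit <- live & wa >= w_absorb
      if (any(hit)) {
        fpt[alive[hit]] <- (i + b) * dt
        done <- done | hit
      }
    }
    w[alive] <- wa
    alive <- alive[!done]
    i <- i + nb
  }
  fpt
}
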