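#' Noisy linear recurrent population inferring a stimulus velocity
#'
#' Parameters of the stochastic linear recurrent rate network whose
#' population-averaged activity \eqn{\bar r} obeys
#' \deqn{\dot{\bar r} = -[\bar r - \kappa \bar c(v)]/\tau_n +
#'       \sqrt{2\sigma_r^2/(N\tau_n)}\,\bar\eta(t),}
#' with network enhancement factor \eqn{\kappa = 1/(1 - \bar w \tau_{n0})},
#' effective time constant \eqn{\tau_n = \kappa\tau_{n0}} and effective noise
#' \eqn{\sigma_r = \kappa\sigma_{r0}}.
#'
#' @param N Number of neurons.
#' @param tau_n0 Single-neuron time constant (s).
#' @param sigma_r0 Single-neuron rate-noise standard deviation (Hz).
#' @param w_bar Population-mean synaptic weight (1/s); requires
#'   `w_bar * tau_n0 < 1`.
#' @param r_m Maximal tuning-curve rate (Hz).
#' @param epsilon Tuning-curve width (velocity units).
#' @param alpha Population velocity range (velocity units). The closed forms
#'   are large-`alpha` expansions; a warning is issued if `alpha/epsilon < 10`.
#' @return An object of class `population_params` with derived fields
#'   `kappa`, `tau_n`, `sigma_r`.
#' @export
population_params <- function(N, tau_n0, sigma_r0, w_bar, r_m, epsilon, alpha) {
  assert_positive(N, "N"); assert_positive(tau_n0, "tau_n0")
  assert_positive(sigma_r0, "sigma_r0"); assert_positive(r_m, "r_m")
  assert_positive(epsilon, "epsilon"); assert_positive(alpha, "alpha")
  if (w_bar < 0) abort("`w_bar` must be >= 0.")
  if (w_bar * tau_n0 >= 1) {
    abort("`w_bar * tau_n0` must be < 1 (network would be unstable).")
  }
  if (alpha / epsilon < 10) {
    warn("alpha/epsilon < 10: the large-alpha series may be inaccurate.")
  }
  kappa <- 1 / (1 - w_bar * tau_n0)
  structure(list(
    N = N, tau_n0 = tau_n0, sigma_r0 = sigma_r0, w_bar = w_bar,
    r_m = r_m, epsilon = epsilon, alpha = alpha,
    kappa = kappa, tau_n = kappa * tau_n0, sigma_r = kappa * sigma_r0
  ), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<population_params> N = %g, kappa = %.4g, tau_n = %.4g s, ",
    "sigma_r = %.4g Hz\n"), x$N, x$kappa, x$tau_n, x$sigma_r))
  invisible(x)
}

#' Gaussian tuning curve of a single neuron
#'
#' \eqn{c_i(v) = r_m \exp[-(v - u_i)^2/(2\epsilon^2)]}: the mean firing rate
#' of a neuron with preferred velocity `u` in response to stimulus velocity
#' `v`. At `v = u +/- 2 epsilon` the response is `exp(-2) ~= 0.14` of the
#' peak.
#'
#' @param v Stimulus velocity (vectorized).
#' @param u Preferred velocity.
#' @param r_m Maximal rate (Hz).
#' @param epsilon Tuning width (> 0).
#' @return Firing rate(s) (Hz).
#' @export
#' @examples
#' tuning_curve(10.2, u = 10, r_m = 10, epsilon = 0.1) / 10 # exp(-2)
tuning_curve <- function(v, u, r_m, epsilon) {
  assert_positive(epsilon, "epsilon")
  r_m * exp(-(v - u)^2 / (2 * epsilon^2))
}

#' Population-averaged tuning curve
#'
#' With preferred velocities distributed as `Normal(0, alpha^2)` across the
#' population, the average of [tuning_curve()] over neurons is, for
#' \eqn{\alpha \gg \epsilon},
#' \deqn{\bar c(v) = \frac{r_m\epsilon}{\alpha} e^{-v^2/2\alpha^2}
#'  \approx \frac{r_m\epsilon}{\alpha}\Big(1 - \frac{v^2}{2\alpha^2}\Big).}
#'
#' @param v Stimulus velocity (vectorized).
#' @param params A [population_params()].
#' @param order `"exact"` for the Gaussian form, `"series"` for its
#'   \eqn{O(\alpha^{-2})} truncation.
#' @return Mean rate(s) (Hz).
#' @export
population_tuning <- function(v, params, order = c("exact", "series")) {
  stopifnot(inherits(params, "population_params"))
  order <- match.arg(order)
  lead <- params$r_m * params$epsilon / params$alpha
  if (order == "exact") {
    lead * exp(-v^2 / (2 * params$alpha^2))
  } else {
    lead * (1 - v^2 / (2 * params$alpha^2))
  }
}

#' Stochastic stimulus with exponentially correlated squared velocity
#'
#' A stationary Ornstein-Uhlenbeck velocity process constructed so that the
#' squared velocity has the covariance assumed by the stationary
#' mutual-information formula:
#' \eqn{\mathrm{cov}(v^2(t_1), v^2(t_2)) = C_0 e^{-|t_1-t_2|/\tau_c}}.
#' For a zero-mean Gaussian OU process with relaxation time \eqn{\tau_v} and
#' variance \eqn{s^2}, \eqn{\mathrm{cov}(v^2) = 2 s^4 e^{-2|\Delta|/\tau_v}},
#' so the generator uses \eqn{\tau_v = 2\tau_c} and \eqn{s^2 = \sqrt{C_0/2}}.
#'
#' @param C0 Stationary covariance amplitude of `v^2` (velocity^4).
#' @param tau_c Correlation time of `v^2` (s), > 0.
#' @param v_offset Constant offset added to the OU process (default 0); note
#'   a nonzero offset changes the v^2 covariance structure.
#' @return An object of class `stimulus_model`.
#' @export
stimulus_model <- function(C0, tau_c, v_offset = 0) {
  assert_positive(C0, "C0")
  if (!is.numeric(tau_c) || tau_c < 0) abort("`tau_c` must be >= 0.")
  structure(list(C0 = C0, tau_c = tau_c, v_offset = v_offset,
                 tau_v = 2 * tau_c, s2 = sqrt(C0 / 2)),
            class = "stimulus_model")
}

#' @export
print.stimulus_model <- function(x, ...) {
  cat(sprintf("<stimulus_model> C0 = %g, tau_c = %g s (OU: tau_v = %g, var = %g)\n",
              x$C0, x$tau_c, x$tau_v, x$s2))
  invisible(x)
}

#' Sample stimulus velocity paths
#'
#' Exact (conditional-Gaussian) sampling of the OU stimulus on an arbitrary
#' time grid, starting from the stationary law. Per-path streams are derived
#' from `seed` as in [simulate_sde()].
#'
#' @param stim A [stimulus_model()].
#' @param times Increasing time grid.
#' @param n_traj Number of paths.
#' @param seed Integer seed.
#' @return Tibble with columns `traj`, `time`, `v`.
#' @export
sample_stimulus <- function(stim, times, n_traj = 1L, seed = 1L) {
  stopifnot(inherits(stim, "stimulus_model"))
  if (any(diff(times) <= 0)) abort("`times` must be increasing.")
  s <- sqrt(stim$s2)
  rho <- if (stim$tau_v > 0) exp(-diff(times) / stim$tau_v) else rep(0, length(times) - 1)
  seeds <- derive_seeds(seed, n_traj)
  vmat <- matrix(NA_real_, length(times), n_traj)
  for (j in seq_len(n_traj)) {
    set.seed(seeds[j])
    z <- rnorm(length(times))
    v <- numeric(length(times))
    v[1] <- s * z[1]
    for (i in seq_along(rho)) {
      v[i + 1] <- rho[i] * v[i] + s * sqrt(1 - rho[i]^2) * z[i + 1]
    }
    vmat[, j] <- v
  }
  tibble(
    traj = rep(seq_len(n_traj), each = length(times)),
    time = rep(times, n_traj),
    v = as.numeric(vmat) + stim$v_offset
  )
}

#' Simulate the population-rate stochastic dynamics
#'
#' Euler-Maruyama integration of the population SDE (see
#' [population_params()]). Transiently negative rates are not clipped — the
#' Gaussian closed forms assume a linear model — but the fraction of negative
#' samples is reported in the `negative_fraction` attribute.
#'
#' @param params A [population_params()].
#' @param v_fun Stimulus velocity as a function of time (or a constant).
#' @param r0 Initial population rate (Hz).
#' @param dt Time step (s), must be well below `tau_n`.
#' @param t_end Final time (s).
#' @param n_traj Number of trajectories.
#' @param seed Integer seed.
#' @param keep_every Thinning factor for storage.
#' @return Tibble with columns `traj`, `time`, `r`.
#' @export
simulate_population <- function(params, v_fun, r0, dt, t_end, n_traj = 1L,
                                seed = 1L, keep_every = 1L) {
  stopifnot(inherits(params, "population_params"))
  if (!is.function(v_fun)) {
    v_const <- v_fun; v_fun <- function(t) rep(v_const, length(t))
  }
  if (dt > params$tau_n / 10) {
    warn("dt is not small compared with tau_n; results may be biased.")
  }
  model <- langevin_model(
    force = function(z, t) {
      -(z - params$kappa * population_tuning(v_fun(t), params)) / params$tau_n
    },
    mu = 1,
    sigma = sqrt(2 * params$sigma_r^2 / (params$N * params$tau_n))
  )
  out <- simulate_sde(model, r0, dt, t_end, n_traj, seed, keep_every)
  names(out)[names(out) == "z"] <- "r"
  attr(out, "negative_fraction") <- mean(out$r < 0)
  out
}

#' Conditional mean population rate given a stimulus path
#'
#' The noise-averaged solution of the population SDE conditioned on the
#' velocity path:
#' \deqn{\langle\bar r(v,t)\rangle = \bar r_0 e^{-t/\tau_n} +
#'  \frac{\epsilon\kappa r_m}{\alpha}(1 - e^{-t/\tau_n}) -
#'  \frac{\epsilon\kappa r_m}{2\tau_n\alpha^3} e^{-t/\tau_n}
#'  \int_0^t e^{t'/\tau_n} v^2(t')\,dt'}
#' (`order = "series"`, the large-`alpha` form), or the exact exponential
#' filter of \eqn{\kappa\bar c(v(t'))} (`order = "exact"`).
#'
#' @inheritParams simulate_population
#' @param t Evaluation time(s) (s).
#' @param order `"series"` or `"exact"`.
#' @return Tibble with columns `t`, `mean`.
#' @export
conditional_mean <- function(params, v_fun, r0, t, order = c("series", "exact")) {
  stopifnot(inherits(params, "population_params"))
  order <- match.arg(order)
  if (!is.function(v_fun)) {
    v_const <- v_fun; v_fun <- function(t) rep(v_const, length(t))
  }
  tn <- params$tau_n
  lead <- params$epsilon * params$kappa * params$r_m / params$alpha
  m <- vapply(t, function(ti) {
    if (ti == 0) return(r0)
    if (order == "series") {
      # integrate with the bounded kernel exp((t'-t)/tau_n)
      filt <- integrate(function(s) exp((s - ti) / tn) * v_fun(s)^2,
                        0, ti, rel.tol = 1e-10, subdivisions = 500L)$value
      r0 * exp(-ti / tn) + lead * (1 - exp(-ti / tn)) -
        lead / (2 * tn * params$alpha^2) * filt
    } else {
      filt <- integrate(function(s) exp((s - ti) / tn) *
                          params$kappa * population_tuning(v_fun(s), params),
                        0, ti, rel.tol = 1e-10, subdivisions = 500L)$value
      r0 * exp(-ti / tn) + filt / tn
    }
  }, numeric(1))
  tibble(t = t, mean = m)
}

# shared prefactor N (eps kappa r_m)^2 / (8 alpha^6 sigma_r^2(t))
.mi_prefactor <- function(params, t = Inf) {
  s2t <- params$sigma_r^2 * (1 - exp(-2 * t / params$tau_n))
  params$N * (params$epsilon * params$kappa * params$r_m)^2 /
    (8 * params$alpha^6 * s2t)
}

#' Mutual information between population rate and stimulus (finite time)
#'
#' Evaluates
#' \deqn{I(\bar r, v) = \frac{N(\epsilon\kappa r_m)^2}{8\alpha^6\sigma_r^2(t)}
#'   \int_0^t\!\!\int_0^t e^{(t_1 - t)/\tau_n} e^{(t_2 - t)/\tau_n}
#'   \mathrm{cov}(v^2(t_1), v^2(t_2))\,dt_1 dt_2}
#' with the squared-velocity covariance either supplied analytically
#' (`cov_fun(t1, t2)`), taken from a [stimulus_model()] (exponential), or
#' estimated from `n_mc` sampled stimulus paths. The double integral uses the
#' trapezoid rule on an `n_grid` x `n_grid` grid.
#'
#' @param params A [population_params()].
#' @param stimulus A [stimulus_model()], used for the analytic covariance or
#'   for sampling.
#' @param t Observation time (s), > 0.
#' @param method `"analytic"` (exponential covariance of `stimulus`),
#'   `"mc"` (estimate the covariance from sample paths), or a custom
#'   `cov_fun`.
#' @param cov_fun Optional covariance function `f(t1, t2)` (overrides
#'   `method`).
#' @param n_mc Number of Monte-Carlo stimulus paths for `method = "mc"`.
#' @param n_grid Quadrature grid size per axis.
#' @param seed Seed for the Monte-Carlo path sampling.
#' @return Mutual information (nats).
#' @export
mutual_info_numeric <- function(params, stimulus, t,
                                method = c("analytic", "mc"),
                                cov_fun = NULL, n_mc = 200L, n_grid = 201L,
                                seed = 1L) {
  stopifnot(inherits(params, "population_params"))
  if (t <= 0) abort("`t` must be > 0.")
  method <- match.arg(method)
  tg <- seq(0, t, length.out = n_grid)
  wts <- trapz_weights(tg)
  if (!is.null(cov_fun)) {
    C <- outer(tg, tg, cov_fun)
  } else if (method == "analytic") {
    stopifnot(inherits(stimulus, "stimulus_model"))
    C <- stimulus$C0 * exp(-abs(outer(tg, tg, "-")) / stimulus$tau_c)
  } else {
    stopifnot(inherits(stimulus, "stimulus_model"))
    paths <- sample_stimulus(stimulus, tg, n_traj = n_mc, seed = seed)
    V2 <- matrix(paths$v^2, nrow = length(tg))
    C <- stats::cov(t(V2))
  }
  kern <- exp((tg - t) / params$tau_n)
  dbl <- as.numeric(t(kern * wts) %*% C %*% (kern * wts))
  .mi_prefactor(params, t) * dbl
}

#' Stationary mutual information for an exponentially correlated stimulus
#'
#' The long-time limit of [mutual_info_numeric()] for
#' \eqn{\mathrm{cov}(v^2(t_1),v^2(t_2)) = C_0 e^{-|t_1-t_2|/\tau_c}}:
#' \deqn{I_\infty = \frac{N(\epsilon\kappa r_m)^2}{8\alpha^6\sigma_r^2}\,
#'       \frac{C_0\,\tau_n^2\,\tau_c}{\tau_n + \tau_c}.}
#' Vanishes for fast stimuli (\eqn{\tau_c \to 0}) and saturates for slow ones
#' (\eqn{\tau_c \gg \tau_n}).
#'
#' @inheritParams mutual_info_numeric
#' @param C0 Covariance amplitude of the squared velocity.
#' @param tau_c Correlation time of the squared velocity (s), >= 0.
#' @return Mutual information (nats).
#' @export
mutual_info_stationary <- function(params, C0, tau_c) {
  stopifnot(inherits(params, "population_params"))
  if (!is.numeric(tau_c) || tau_c < 0) abort("`tau_c` must be >= 0.")
  tn <- params$tau_n
  .mi_prefactor(params, Inf) * C0 * tn^2 * tau_c / (tn + tau_c)
}

#' Conditional entropy production rate of the tracking population
#'
#' The entropy production rate of the population activity conditioned on the
#' stimulus path, obtained by inserting the Gaussian conditional density into
#' the continuous-state production-rate integral:
#' \deqn{\dot S_{\rho(\bar r | v)} =
#'   \frac{e^{-4t/\tau_n}}{\tau_n (1 - e^{-2t/\tau_n})} +
#'   \frac{N[\langle\bar r(t)\rangle - \kappa\bar c(v(t))]^2}
#'        {\sigma_r^2 \tau_n}.}
#' The first term is the relaxation cost of the sharpening conditional
#' variance; the second is the tracking cost, proportional to the squared lag
#' between the filtered activity and the instantaneous drive. For a constant
#' stimulus it decays to zero: stationary velocities are tracked essentially
#' for free.
#'
#' @inheritParams conditional_mean
#' @param t Evaluation time(s), each > 0.
#' @return Tibble with columns `t`, `entropy_production`, and the two parts
#'   `relaxation_term`, `tracking_term` (nats/s).
#' @export
conditional_entropy_production <- function(params, v_fun, r0, t,
                                           order = c("series", "exact")) {
  stopifnot(inherits(params, "population_params"))
  order <- match.arg(order)
  if (any(t <= 0)) abort("`t` must be > 0.")
  if (!is.function(v_fun)) {
    v_const <- v_fun; v_fun <- function(t) rep(v_const, length(t))
  }
  tn <- params$tau_n
  m <- conditional_mean(params, v_fun, r0, t, order = order)$mean
  cbar <- population_tuning(v_fun(t), params,
                            order = if (order == "series") "series" else "exact")
  relax <- exp(-4 * t / tn) / (tn * (1 - exp(-2 * t / tn)))
  track <- params$N * (m - params$kappa * cbar)^2 / (params$sigma_r^2 * tn)
  tibble(t = t, entropy_production = relax + track,
         relaxation_term = relax, tracking_term = track)
}

#' Long-time tracking entropy production (squared-velocity form)
#'
#' The long-time reduction of [conditional_entropy_production()]: the
#' tracking term becomes
#' \deqn{\frac{N(\epsilon\kappa r_m)^2}{4\alpha^6\sigma_r^2\tau_n}
#'   \Big[v^2(t) - \frac{e^{-t/\tau_n}}{\tau_n}\int_0^t e^{t'/\tau_n}
#'   v^2(t')\,dt'\Big]^2,}
#' i.e. the squared deviation of the instantaneous squared velocity from its
#' exponentially filtered history. The prefactor is, up to the factor
#' \eqn{2\sigma_r^2(t)/\tau_n} from the variance normalization, the same as
#' in the mutual-information formula: information gained and energy spent
#' have identical parameter dependence.
#'
#' @param params A [population_params()].
#' @param v2_now Instantaneous squared velocity \eqn{v^2(t)}.
#' @param v2_filtered Exponentially filtered squared velocity.
#' @return Entropy production rate (nats/s).
#' @export
tracking_entropy_production <- function(params, v2_now, v2_filtered) {
  stopifnot(inherits(params, "population_params"))
  params$N * (params$epsilon * params$kappa * params$r_m)^2 /
    (4 * params$alpha^6 * params$sigma_r^2 * params$tau_n) *
    (v2_now - v2_filtered)^2
}
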