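#' One-dimensional Langevin model
#'
#' The stochastic dynamics \eqn{\dot z = \mu F(z, t) + \mu\sigma\,\eta(t)}
#' with delta-correlated unit-variance Gaussian noise
#' \eqn{\langle\eta(t)\eta(t')\rangle = \delta(t - t')}. The effective
#' diffusion coefficient is \eqn{D = (\mu\sigma)^2 / 2}.
#'
#' @param force Function `F(z, t)` returning the deterministic generalized
#'   force (vectorized in `z`).
#' @param mu Mobility-like prefactor (> 0).
#' @param sigma Noise magnitude (>= 0).
#' @return An object of class `langevin_model`.
#' @export
#' @examples
#' ou <- langevin_model(function(z, t) -z, mu = 1, sigma = sqrt(2))
langevin_model <- function(force, mu, sigma) {
  stopifnot(is.function(force))
  assert_positive(mu, "mu")
  if (!is.numeric(sigma) || sigma < 0) abort("`sigma` must be >= 0.")
  structure(list(force = force, mu = mu, sigma = sigma),
            class = "langevin_model")
}

#' @export
print.langevin_model <- function(x, ...) {
  cat(sprintf("<langevin_model> mu = %g, sigma = %g, D = %g\n",
              x$mu, x$sigma, (x$mu * x$sigma)^2 / 2))
  invisible(x)
}

#' Simulate a Langevin equation by Euler-Maruyama
#'
#' Fixed-step Euler-Maruyama iterates of
#' \eqn{z_{n+1} = z_n + \mu F(z_n, t_n)\,dt + \mu\sigma\sqrt{dt}\,\xi_n}.
#' Each trajectory draws its Gaussian increments from its own seeded stream
#' derived from `seed`, so trajectory `i` is reproducible independently of
#' `n_traj` and of the order of simulation.
#'
#' @param model A [langevin_model()].
#' @param z0 Initial value (scalar, shared by all trajectories).
#' @param dt Time step (> 0).
#' @param t_end Final time.
#' @param n_traj Number of trajectories.
#' @param seed Integer seed for the ensemble.
#' @param keep_every Store every `keep_every`-th step (default 1 = all).
#' @return A tibble with columns `traj`, `time`, `z`; the seed and step are
#'   recorded in attributes `seed` and `dt`.
#' @export
simulate_sde <- function(model, z0, dt, t_end, n_traj = 1L, seed = 1L,
                         keep_every = 1L) {
  stopifnot(inherits(model, "langevin_model"))
  assert_positive(dt, "dt")
  n_steps <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  # crude step-size warning against the local relaxation scale at z0
  f0 <- model$force(z0, 0)
  f1 <- model$force(z0 + 1e-6 * max(1, abs(z0)), 0)
  slope <- abs(model$mu * (f1 - f0) / (1e-6 * max(1, abs(z0))))
  if (is.finite(slope) && slope > 0 && dt > 0.1 / slope) {
    warn(sprintf("dt = %g exceeds a tenth of the local relaxation time %g.",
                 dt, 1 / slope))
  }
  amp <- model$mu * model$sigma * sqrt(dt)
  seeds <- derive_seeds(seed, n_traj)
  keep_idx <- seq(1L, n_steps + 1L, by = keep_every)
  # vectorized across trajectories; noise drawn per trajectory stream in
  # blocks so trajectory j is identical no matter how many others run
  out_z <- matrix(NA_real_, nrow = length(keep_idx), ncol = n_traj)
  z <- rep(z0, n_traj)
  rng_states <- vector("list", n_traj)
  for (j in seq_len(n_traj)) {
    set.seed(seeds[j])
    rng_states[[j]] <- get(".Random.seed", envir = globalenv())
  }
  block <- 4096L
  noise <- matrix(0, block, n_traj)
  keep_ptr <- 1L
  if (keep_idx[1] == 1L) { out_z[1L, ] <- z; keep_ptr <- 2L }
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
      z <- z + model$mu * model$force(z, times[step]) * dt + amp * noise[b, ]
      if (keep_ptr <= length(keep_idx) && keep_idx[keep_ptr] == step + 1L) {
        out_z[keep_ptr, ] <- z
        keep_ptr <- keep_ptr + 1L
      }
    }
    i <- i + nb
  }
  out <- tibble(
    traj = rep(seq_len(n_traj), each = length(keep_idx)),
    time = rep(times[keep_idx], times = n_traj),
    z = as.numeric(out_z)
  )
  attr(out, "seed") <- seed
  attr(out, "dt") <- dt
  out
}

#' Gridded probability density
#'
#' A density `P(z)` sampled on a uniform grid, normalized by the trapezoid
#' rule.
#'
#' @param z Uniform, increasing grid.
#' @param p Non-negative density values on the grid.
#' @param time Time stamp attached to the density (default 0).
#' @param renormalize If `TRUE` (default), rescale `p` so that the trapezoid
#'   integral is exactly 1; otherwise an integral further than `1e-6` from 1
#'   is an error.
#' @return An object of class `grid_density`.
#' @export
grid_density <- function(z, p, time = 0, renormalize = TRUE) {
  if (length(z) != length(p)) abort("`z` and `p` must have equal length.")
  if (length(z) < 5) abort("grid must have at least 5 points.")
  dz <- diff(z)
  if (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-8 * dz[1]) {
    abort("`z` must be a uniform increasing grid.")
  }
  if (any(p < 0)) abort("`p` must be non-negative.")
  tot <- pracma::trapz(z, p)
  if (renormalize) {
    p <- p / tot
  } else if (abs(tot - 1) > 1e-6) {
    abort(sprintf("density integrates to %.8g, not 1.", tot))
  }
  structure(list(z = z, p = p, time = time, dz = dz[1]),
            class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf("<grid_density> %d points on [%g, %g], t = %g\n",
              length(x$z), min(x$z), max(x$z), x$time))
  invisible(x)
}

# second-order first derivative on a uniform grid (central; one-sided ends)
grid_deriv <- function(y, dz) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dz)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dz)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dz)
  d
}

#' Fokker-Planck probability current on a grid
#'
#' \eqn{J = \mu F P - \tfrac12 (\mu\sigma)^2 \partial P/\partial z}, with the
#' spatial derivative by second-order central differences (one-sided at the
#' boundaries).
#'
#' @param P A [grid_density()].
#' @param model A [langevin_model()].
#' @return A tibble with columns `z`, `p`, `current`.
#' @export
fp_current <- function(P, model) {
  stopifnot(inherits(P, "grid_density"), inherits(model, "langevin_model"))
  Fz <- model$force(P$z, P$time)
  J <- model$mu * Fz * P$p - 0.5 * (model$mu * model$sigma)^2 * grid_deriv(P$p, P$dz)
  tibble(z = P$z, p = P$p, current = J)
}

#' Entropy production and flow rates from a gridded density
#'
#' For continuous dynamics,
#' \deqn{\dot S_{pr} = \frac{2}{(\mu\sigma)^2} \int \frac{J^2}{P}\,dz \ge 0,
#'  \qquad \dot S_{fl} = \frac{2}{\mu\sigma^2} \int J F \, dz,}
#' evaluated by the trapezoid rule. Cells with `P` below `1e-300` contribute
#' zero (they carry no flux at machine precision).
#'
#' @inheritParams fp_current
#' @return One-row tibble with `entropy_production` and `entropy_flow`
#'   (nats/time).
#' @export
fp_entropy_rates <- function(P, model) {
  stopifnot(inherits(P, "grid_density"), inherits(model, "langevin_model"))
  if (model$sigma == 0) abort("entropy rates are undefined for sigma = 0.")
  cur <- fp_current(P, model)
  Fz <- model$force(P$z, P$time)
  ig_pr <- numeric(length(P$z))
  live <- P$p > 1e-300
  ig_pr[live] <- cur$current[live]^2 / P$p[live]
  s_pr <- 2 / (model$mu * model$sigma)^2 * pracma::trapz(P$z, ig_pr)
  s_fl <- 2 / (model$mu * model$sigma^2) * pracma::trapz(P$z, cur$current * Fz)
  tibble(entropy_production = s_pr, entropy_flow = s_fl)
}

#' Discretize a Langevin model to a nearest-neighbor rate matrix
#'
#' Standard finite-volume discretization of the Fokker-Planck operator:
#' hopping rates between adjacent grid cells
#' \eqn{w_{\pm} = D/\Delta z^2 \pm \mu F/(2\Delta z)} (clipped at zero), which
#' converges to the continuous dynamics as the grid refines. Used to
#' cross-check the continuous entropy rates against the discrete
#' [entropy_rates()] engine.
#'
#' @param model A [langevin_model()].
#' @param z Uniform grid of cell centers.
#' @param time Time at which to evaluate the force.
#' @return A [rate_matrix()] over the grid cells.
#' @export
discretize_model <- function(model, z, time = 0) {
  dz <- z[2] - z[1]
  n <- length(z)
  D <- (model$mu * model$sigma)^2 / 2
  Fz <- model$mu * model$force(z, time)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    # rate from cell i to i+1 evaluated at the shared interface
    fmid <- (Fz[i] + Fz[i + 1]) / 2
    w[i + 1, i] <- max(D / dz^2 + fmid / (2 * dz), 0)
    w[i, i + 1] <- max(D / dz^2 - fmid / (2 * dz), 0)
  }
  rate_matrix(w, states = paste0("z", seq_len(n)))
}
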