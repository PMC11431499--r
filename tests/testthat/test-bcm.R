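# time-rescaled nominal configuration for escape studies: multiplying the
# plasticity amplitude by 10 and dividing tau_w by 10 leaves the fixed points
# and the barrier/diffusion ratio structure intact while running 10x faster;
# sigma_w is then chosen so the down-state barrier is 4 diffusion units
# (the weak-noise reduced-barrier regime where escapes are observable)
fast_bcm <- function(barrier_units = 4) {
  p0 <- bcm_params(lam = 13, tau_w = 20, tau_theta = 1, sigma_w = 1)
  bis <- bistability(p0)
  barrier <- bcm_potential(bis$w_m, 0, p0)$V0
  sigma_w <- sqrt(barrier * p0$n_s * p0$tau_w / barrier_units)
  bcm_params(lam = 13, tau_w = 20, tau_theta = 1, sigma_w = sigma_w)
}

# equal-depth (symmetric) double well: beta_f = 8/9, i.e. lam = 10/9 at the
# otherwise nominal parameters with tau_w = 20; the three fixed points are
# then equidistant and V0(w_u) = 0
balanced_bcm <- function(barrier_units = 4) {
  p0 <- bcm_params(lam = 10 / 9, tau_w = 20, tau_theta = 1, sigma_w = 1)
  bis <- bistability(p0)
  barrier <- bcm_potential(bis$w_m, 0, p0)$V0
  sigma_w <- sqrt(barrier * p0$n_s * p0$tau_w / barrier_units)
  bcm_params(lam = 10 / 9, tau_w = 20, tau_theta = 1, sigma_w = sigma_w)
}

# exact mean first-passage time of dw = -V'(w) dt + sqrt(2D) dW from w0 to b
# (reflecting lower boundary), by the classical double-integral formula,
# evaluated in exponent-difference form to avoid overflow past the barrier
mfpt_exact <- function(params, w0, b, lo = -0.5, n = 1500) {
  D <- params$D
  z <- seq(lo, b, length.out = n)
  dz <- z[2] - z[1]
  V <- bcm_potential(z, 0, params)$V0
  expo <- outer(V, V, "-") / D          # (V(y) - V(z)) / D
  expo[upper.tri(expo)] <- -Inf          # inner integral runs over z <= y
  sel <- z >= w0
  sum(exp(expo[sel, , drop = FALSE])) * dz^2 / D
}

test_that("full BCM drift reduces correctly in its limits", {
  bp <- bcm_params()
  d0 <- drift_full(w_i = 2, theta = 1, r = 0, bp)
  expect_equal(d0$dw, -2 / bp$tau_w)
  # quasi-static threshold turns the rule into the one-equation form
  r <- 0.7
  dq <- drift_full(w_i = 1, theta = bp$beta * r^2, r = r, bp)
  expect_equal(dq$dw, bp$lam * bp$f_bar * r^2 * (1 - bp$beta * r) - 1 / bp$tau_w)
  expect_equal(dq$dtheta, 0)
})

test_that("two-equation dynamics track the reduced rule after transients", {
  # the scale the threshold must beat is the local weight relaxation time
  # near the strong fixed point (~1/V0pp(w_u) ~ 40 s at these parameters),
  # not tau_w itself; tau_theta = 1 s gives clean separation, while
  # tau_theta ~ 10 s already destabilizes the strong state via threshold lag
  bp <- bcm_params(tau_theta = 1)
  a <- bp$tau_n0 * bp$f_bar
  full_rhs <- function(t, y, parms) {
    r <- a * y[1]
    d <- drift_full(y[1], y[2], r, bp)
    list(c(d$dw, d$dtheta))
  }
  red_rhs <- function(t, y, parms) {
    list(population_force(y, 0, bp))
  }
  times <- seq(0, 400, 1)
  w0 <- 2
  full <- deSolve::lsoda(c(w0, bp$beta * (a * w0)^2), times, full_rhs,
                         rtol = 1e-10, atol = 1e-12)
  red <- deSolve::lsoda(w0, times, red_rhs, rtol = 1e-10, atol = 1e-12)
  late <- times > 50
  expect_lt(max(abs(full[late, 2] / red[late, 2] - 1)), 0.02)
})

test_that("the down state and the closed-form roots are zeros of the force", {
  bp <- bcm_params()
  expect_equal(population_force(0, 0, bp), 0)
  bis <- bistability(bp)
  expect_lt(abs(population_force(bis$w_u, 0, bp)), 1e-12)
  expect_lt(abs(population_force(bis$w_m, 0, bp)), 1e-12)
  # root-finder oracle
  root_u <- uniroot(function(w) population_force(w, 0, bp),
                    c(bis$w_m * 1.5, bis$w_u * 2), tol = 1e-14)$root
  expect_lt(abs(root_u - bis$w_u), 1e-10)
  root_m <- uniroot(function(w) population_force(w, 0, bp),
                    c(1e-4, bis$w_u / 2), tol = 1e-14)$root
  expect_lt(abs(root_m - bis$w_m), 1e-10)
})

test_that("bistability report reproduces the nominal-parameter numbers", {
  bis <- bistability(bcm_params())
  expect_equal(bis$condition, 63.18, tolerance = 1e-12)
  expect_equal(bis$threshold, 4.8)
  expect_true(bis$bistable)
  expect_equal(glance(bis)$beta_f, 4.8 / 63.18)
  td <- tidy(bis)
  expect_equal(td$w_bar[1], 0)
  expect_true(td$w_bar[2] < td$w_bar[3])
})

test_that("the saddle-node is degenerate at beta_f = 1 and absent beyond", {
  # choose lam so that beta_f = 1 exactly
  base <- bcm_params()
  lam_crit <- 4 * base$beta / (base$tau_w * base$tau_n0 * base$f_bar^2)
  bp <- bcm_params(lam = lam_crit)
  bis <- bistability(bp)
  expect_equal(bis$w_m, bis$w_u)
  mono <- bistability(bcm_params(lam = 0.05))
  expect_false(mono$bistable)
  expect_true(is.na(mono$w_u))
  expect_error(kramers_times(bcm_params(lam = 0.05)), "bistable")
  # continuity: w_u - w_m -> 0 as beta_f -> 1-
  gaps <- vapply(c(0.9, 0.99, 0.999), function(bf) {
    b <- bistability(bcm_params(lam = 4 * base$beta /
                                  (bf * base$tau_w * base$tau_n0 * base$f_bar^2)))
    b$w_u - b$w_m
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("the potential is the integral of minus the force", {
  bp <- bcm_params()
  bis <- bistability(bp)
  grid <- seq(0, 1.2 * bis$w_u, length.out = 25)
  for (cc in c(0, 0.4)) {
    pot <- bcm_potential(grid, cc, bp)
    expect_equal(pot$V[1], 0)
    quad <- vapply(grid, function(wb) {
      if (wb == 0) return(0)
      -integrate(function(x) population_force(x, cc, bp), 0, wb,
                 rel.tol = 1e-12)$value
    }, numeric(1))
    expect_lt(max(abs(pot$V - quad)), 1e-10)
  }
  # analytic curvature matches a finite-difference second derivative
  h <- 1e-5
  for (w in c(0, 0.5, 2)) {
    fd <- (bcm_potential(w + h, 0.3, bp)$V - 2 * bcm_potential(w, 0.3, bp)$V +
             bcm_potential(w - h, 0.3, bp)$V) / h^2
    expect_equal(bcm_potential_curvature(w, 0.3, bp), fd, tolerance = 1e-5)
  }
})

test_that("a weak stimulus lowers the barrier out of the down state", {
  bp <- bcm_params()
  bis <- bistability(bp)
  pot_m <- bcm_potential(bis$w_m, c = 0.3, bp)
  pot_d <- bcm_potential(bis$w_d, c = 0.3, bp)
  expect_lt(pot_m$dV - pot_d$dV, 0)
})

test_that("the Kramers exponent is linear in the synapse count", {
  bp1 <- fast_bcm()
  bp2 <- bcm_params(lam = 13, tau_w = 20, tau_theta = 1,
                    sigma_w = bp1$sigma_w, n_s = 2000)
  k1 <- kramers_times(bp1, 0)
  k2 <- kramers_times(bp2, 0)
  expect_equal(k2$barrier_d_over_D, 2 * k1$barrier_d_over_D)
  # prefactor is Ns-independent: log-time difference equals barrier difference
  expect_equal(log(k2$T_d) - log(k1$T_d),
               k2$barrier_d_over_D - k1$barrier_d_over_D)
})

test_that("the symmetric double well has equal dwell times", {
  bp <- balanced_bcm()
  bis <- bistability(bp)
  expect_equal(bis$w_u - bis$w_m, bis$w_m - bis$w_d, tolerance = 1e-10)
  kt <- kramers_times(bp, 0)
  expect_equal(kt$T_d, kt$T_u, tolerance = 1e-10)
  expect_equal(kt$barrier_d_over_D, kt$barrier_u_over_D, tolerance = 1e-10)
})

test_that("Kramers times agree with the exact first-passage integral", {
  bp <- fast_bcm(barrier_units = 5)
  bis <- bistability(bp)
  kt <- kramers_times(bp, 0)
  expect_true(kt$weak_noise_ok)
  b <- (bis$w_m + bis$w_u) / 2
  exact <- mfpt_exact(bp, 0, b)
  expect_lt(abs(log(kt$T_d) - log(exact)), log(2))
})

test_that("stimulus accelerates the down-to-up escape", {
  bp <- fast_bcm()
  k0 <- kramers_times(bp, 0)
  # a weak input tilts the potential toward the strong state; with the
  # barrier this low the input also flattens the down-state curvature,
  # which kramers_times flags
  kc <- suppressWarnings(kramers_times(bp, 0.2))
  expect_lt(kc$T_d, k0$T_d)
})

test_that("two-state reduction matches the master-equation relaxation", {
  bp <- balanced_bcm()
  ts <- two_state_reduce(bp)
  expect_equal(ts$p_u_inf, ts$omega_ud0 / (ts$omega_ud0 + ts$omega_du0))
  expect_equal(ts$memory_lifetime, 1 / ts$omega0)
  # at the nominal (strongly tilted) parameters the up state is so stable
  # that the reverse rate underflows: omega_du/omega_ud is effectively 0
  kt_nominal <- kramers_times(bcm_params())
  expect_gt(kt_nominal$barrier_u_over_D / kt_nominal$barrier_d_over_D, 1e3)
  p_u0 <- min(ts$p_u_inf + 0.2, 0.99)
  tg <- seq(0, 3 * ts$memory_lifetime, length.out = 7)
  analytic <- two_state_relax(ts, p_u0, tg)$p_u
  traj <- trajectory_matrix(evolve_master(two_state_rate_matrix(ts),
                                          c(1 - p_u0, p_u0), tg))
  expect_lt(max(abs(traj[, "up"] - analytic)), 1e-8)
})

test_that("memory information identities hold", {
  ts <- two_state_model(omega_ud0 = 0.25, omega_du0 = 1)  # p_u_inf = 0.2
  expect_equal(ts$p_u_inf, 0.2)
  delta <- 0.3
  mi0 <- memory_information(ts, 0, delta)
  # at t = 0 the divergence equals the closed-form total entropy
  expect_equal(mi0$d_kl, memory_total_entropy(ts, delta), tolerance = 1e-12)
  # entropy production rate is the information loss rate, non-negative
  tg <- seq(0, 40, 0.5)
  mi <- memory_information(ts, tg, delta)
  expect_true(all(mi$entropy_production >= 0))
  expect_equal(mi$entropy_production, -mi$d_kl_rate)
  # d_kl_rate is the numerical derivative of d_kl
  h <- 1e-6
  for (tt in c(0.5, 2, 10)) {
    fd <- (memory_information(ts, tt + h, delta)$d_kl -
             memory_information(ts, tt - h, delta)$d_kl) / (2 * h)
    expect_equal(memory_information(ts, tt, delta)$d_kl_rate, fd,
                 tolerance = 1e-6)
  }
  # quadrature of the production rate recovers the closed-form total
  quad <- integrate(function(t) memory_information(ts, t, delta)$entropy_production,
                    0, Inf, rel.tol = 1e-12)$value
  expect_lt(abs(quad - memory_total_entropy(ts, delta)), 1e-8)
  # zero perturbation stores and dissipates nothing
  expect_equal(memory_information(ts, c(0, 1, 5), 0)$d_kl, rep(0, 3))
  expect_equal(memory_total_entropy(ts, 0), 0)
  expect_error(memory_information(ts, 1, 0.9), "delta")
})

test_that("total dissipated entropy is independent of the memory lifetime", {
  delta <- 0.15
  totals <- vapply(c(0.05, 0.5, 5), function(om0) {
    # keep p_u_inf = 0.2 while scaling omega0 across two decades
    ts <- two_state_model(omega_ud0 = 0.2 * om0, omega_du0 = 0.8 * om0)
    quad <- integrate(function(t) memory_information(ts, t, delta)$entropy_production,
                      0, Inf, rel.tol = 1e-12)$value
    quad
  }, numeric(1))
  expect_lt(max(abs(totals - totals[1])), 1e-10)
  # small perturbations: S_tot ~ delta^2 / (2 p_u p_d)
  ts <- two_state_model(0.2, 0.8)
  d <- 1e-3
  expect_equal(memory_total_entropy(ts, d), d^2 / (2 * 0.2 * 0.8),
               tolerance = 1e-2)
})

test_that("the stimulus pulse, not the ramp tail, drives the deterministic transition", {
  # noise-free mechanism check with the weight floored at zero: a slow ramp
  # leaves a net positive kick as the input sweeps through the potentiating
  # window, a 100x steeper ramp does not
  bp <- bcm_params(sigma_w = 0)
  bis <- bistability(bcm_params())
  slow <- simulate_learning(bp, v0 = 7, accel = 0.02, dt = 0.01, t_end = 400,
                            n_traj = 1, floor_at_zero = TRUE, keep_every = 100)
  expect_gt(tail(slow$w, 1), bis$w_m)
  steep <- simulate_learning(bp, v0 = 7, accel = 2, dt = 0.001, t_end = 10,
                             n_traj = 1, floor_at_zero = TRUE, keep_every = 100)
  expect_lt(max(steep$w), bis$w_m)
})

test_that("weak plasticity leaves no persistent strong-synapse state", {
  bp <- bcm_params(lam = 0.05)
  traj <- simulate_learning(bp, v0 = 7, accel = 0.02, dt = 0.05, t_end = 1500,
                            n_traj = 3, seed = 21, keep_every = 40)
  late <- traj$time > 500
  bis_nominal <- bistability(bcm_params())
  means <- tapply(traj$w[late], traj$traj[late], mean)
  expect_true(all(means < bis_nominal$w_u / 2))
})

test_that("learning simulations are reproducible and seed-stream stable", {
  bp <- bcm_params()
  a <- simulate_learning(bp, dt = 0.05, t_end = 20, n_traj = 2, seed = 4,
                         keep_every = 100)
  b <- simulate_learning(bp, dt = 0.05, t_end = 20, n_traj = 2, seed = 4,
                         keep_every = 100)
  expect_identical(a$w, b$w)
  c4 <- simulate_learning(bp, dt = 0.05, t_end = 20, n_traj = 4, seed = 4,
                          keep_every = 100)
  expect_identical(a$w[a$traj == 2], c4$w[c4$traj == 2])
})

test_that("nominal-parameter runs end in the strong state for most seeds", {
  bp <- bcm_params()
  bis <- bistability(bp)
  traj <- simulate_learning(bp, v0 = 7, accel = 0.02, dt = 0.05, t_end = 2000,
                            n_traj = 10, seed = 1, keep_every = 400)
  finals <- traj$w[traj$time == max(traj$time)]
  expect_gte(sum(finals > bis$w_m), 8)
})
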