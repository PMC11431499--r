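#' Chain of coupled multi-state synapses
#'
#' `n_s` synapses arranged along a dendrite, each in one of `K` discrete
#' morphological states `1..K`. Transitions of synapse `i` from state `s'` to
#' `s` occur at rate `rate_fun(s, s_prime, left, right)`, which may depend on
#' the states of the two nearest neighbours; at the boundaries the missing
#' neighbour is passed as `NA` (synapse 1 depends only on synapse 2, synapse
#' `n_s` only on synapse `n_s - 1`).
#'
#' @param n_s Number of synapses (>= 2).
#' @param k States per synapse (>= 2).
#' @param rate_fun Function `(to, from, left, right) -> rate` (1/time),
#'   deterministic, non-negative; `left`/`right` are `NA` at the boundaries.
#' @param e0 Energy scale per synapse in units of kB*T (default 1e5), used
#'   to convert entropy production into an energetic cost.
#' @return An object of class `chain_model` with the rates pre-tabulated.
#' @export
#' @examples
#' # independent symmetric two-state synapses
#' ch <- chain_model(3, 2, function(to, from, left, right) 1)
chain_model <- function(n_s, k, rate_fun, e0 = 1e5) {
  stopifnot(n_s >= 1, k >= 2, is.function(rate_fun))
  if (n_s == 1) {
    # degenerate chain: a single synapse with no neighbours (exact solver only)
    w1 <- matrix(0, k, k)
    for (to in 1:k) for (from in 1:k) {
      if (to != from) w1[to, from] <- rate_fun(to, from, NA, NA)
    }
    if (any(w1 < 0)) abort("rates must be non-negative.")
    return(structure(list(n_s = 1L, k = as.integer(k), rate_fun = rate_fun,
                          w_single = w1, e0 = e0),
                     class = "chain_model"))
  }
  # tabulate: interior rates w[to, from, left, right]; boundary rates
  # wl[to, from, neighbour] for synapse 1 and wr[to, from, neighbour] for n_s
  w_int <- array(0, dim = c(k, k, k, k))
  for (to in 1:k) for (from in 1:k) for (l in 1:k) for (r in 1:k) {
    if (to != from) w_int[to, from, l, r] <- rate_fun(to, from, l, r)
  }
  w_left <- array(0, dim = c(k, k, k))
  w_right <- array(0, dim = c(k, k, k))
  for (to in 1:k) for (from in 1:k) for (nb in 1:k) {
    if (to != from) {
      w_left[to, from, nb] <- rate_fun(to, from, NA, nb)
      w_right[to, from, nb] <- rate_fun(to, from, nb, NA)
    }
  }
  if (any(w_int < 0) || any(w_left < 0) || any(w_right < 0)) {
    abort("rates must be non-negative.")
  }
  structure(list(n_s = as.integer(n_s), k = as.integer(k),
                 rate_fun = rate_fun, w_int = w_int,
                 w_left = w_left, w_right = w_right, e0 = e0),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %d synapses, %d states each (joint space %g)\n",
              x$n_s, x$k, as.double(x$k)^x$n_s))
  invisible(x)
}

# rate of synapse i: to <- from given neighbour states (NA at boundaries)
.chain_rate <- function(chain, i, to, from, left, right) {
  if (chain$n_s == 1L) chain$w_single[to, from]
  else if (i == 1L) chain$w_left[to, from, right]
  else if (i == chain$n_s) chain$w_right[to, from, left]
  else chain$w_int[to, from, left, right]
}

# enumerate the joint space as an n_s-column matrix of states (row = config);
# index = 1 + sum (s_i - 1) k^(i-1)
.chain_configs <- function(chain) {
  as.matrix(expand.grid(rep(list(seq_len(chain$k)), chain$n_s)))
}
.config_index <- function(chain, cfg) {
  1L + as.integer(sum((cfg - 1L) * chain$k^(seq_along(cfg) - 1L)))
}

#' Exact generator of the chain master equation
#'
#' Sparse generator on the flattened `K^n_s` joint space with single-flip
#' transitions. Refuses joint spaces larger than 65536 states; use
#' [pair_evolve()] for long chains.
#'
#' @param chain A [chain_model()].
#' @return A sparse `dgCMatrix` generator `A` with `dP/dt = A P`.
#' @export
chain_generator <- function(chain) {
  stopifnot(inherits(chain, "chain_model"))
  n_joint <- as.double(chain$k)^chain$n_s
  if (n_joint > 65536) {
    abort(paste0("joint space of size ", format(n_joint),
                 " exceeds the exact-solver cap (65536); ",
                 "use the pair approximation (pair_evolve)."))
  }
  cfgs <- .chain_configs(chain)
  n <- nrow(cfgs)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (row in seq_len(n)) {
    cfg <- cfgs[row, ]
    for (i in seq_len(chain$n_s)) {
      from <- cfg[i]
      left <- if (i > 1L) cfg[i - 1L] else NA_integer_
      right <- if (i < chain$n_s) cfg[i + 1L] else NA_integer_
      for (to in seq_len(chain$k)) {
        if (to == from) next
        rate <- .chain_rate(chain, i, to, from, left, right)
        if (rate <= 0) next
        cfg2 <- cfg; cfg2[i] <- to
        ii <- c(ii, .config_index(chain, cfg2)); jj <- c(jj, row); vv <- c(vv, rate)
        ii <- c(ii, row); jj <- c(jj, row); vv <- c(vv, -rate)
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

#' Exactly evolve the joint distribution of a small chain
#'
#' Integrates the full master equation on the flattened joint space
#' (stiff-capable integrator, rtol 1e-10).
#'
#' @param chain A [chain_model()] with `K^n_s <= 65536`.
#' @param p0 Initial joint probability vector over configurations, indexed
#'   with synapse 1 varying fastest.
#' @param times Increasing time grid.
#' @return Matrix with one row per time (rownames = time) and one column per
#'   configuration; the time grid in attribute `"time"`.
#' @export
exact_evolve <- function(chain, p0, times) {
  A <- chain_generator(chain)
  assert_prob(p0, arg = "p0")
  if (length(p0) != nrow(A)) abort("`p0` has the wrong length.")
  sol <- deSolve::lsoda(
    y = as.numeric(p0), times = if (times[1] > 0) c(0, times) else times,
    func = function(t, y, parms) list(as.numeric(A %*% y)),
    rtol = 1e-10, atol = 1e-12
  )
  sol <- sol[match(times, sol[, "time"]), -1, drop = FALSE]
  attr(sol, "time") <- times
  sol
}

#' Exact stationary joint distribution of a small chain
#'
#' @inheritParams exact_evolve
#' @return Joint probability vector.
#' @export
chain_stationary <- function(chain) {
  A <- as.matrix(chain_generator(chain))
  n <- nrow(A)
  p <- qr.solve(rbind(A, rep(1, n)), c(rep(0, n), 1))
  p[p < 0 & p > -1e-12] <- 0
  p / sum(p)
}

#' Pair distribution: singles and nearest-neighbour pair marginals
#'
#' The pair-approximation state: single-site tables `P_i(s)` for
#' `i = 1..n_s` and pair tables `P_{i,i+1}(s, s')` for `i = 1..n_s - 1`,
#' each normalized, with consistent marginals.
#'
#' @param singles `n_s x k` matrix, rows normalized.
#' @param pairs `(n_s - 1) x k x k` array; `pairs[i, s, s']` is
#'   `P_{i,i+1}(s_i = s, s_{i+1} = s')`.
#' @param tol Consistency tolerance for marginals (default 1e-8).
#' @return An object of class `pair_distribution`.
#' @export
pair_distribution <- function(singles, pairs, tol = 1e-8) {
  singles <- as.matrix(singles)
  pairs <- as.array(pairs)
  n_s <- nrow(singles); k <- ncol(singles)
  if (!all(dim(pairs) == c(n_s - 1, k, k))) {
    abort("`pairs` must be (n_s - 1) x k x k.")
  }
  for (i in seq_len(n_s)) assert_prob(singles[i, ], tol = tol,
                                      arg = sprintf("singles[%d, ]", i))
  for (i in seq_len(n_s - 1)) {
    assert_prob(as.numeric(pairs[i, , ]), tol = tol,
                arg = sprintf("pairs[%d, , ]", i))
    left_marg <- rowSums(pairs[i, , , drop = TRUE])
    right_marg <- colSums(pairs[i, , , drop = TRUE])
    if (max(abs(left_marg - singles[i, ])) > tol) {
      abort(sprintf("pair %d left marginal inconsistent with single %d.", i, i))
    }
    if (max(abs(right_marg - singles[i + 1, ])) > tol) {
      abort(sprintf("pair %d right marginal inconsistent with single %d.", i, i + 1))
    }
  }
  structure(list(singles = singles, pairs = pairs, n_s = n_s, k = k),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> %d synapses, %d states\n", x$n_s, x$k))
  invisible(x)
}

#' Pair distribution of independent synapses
#'
#' Product construction: every pair table is the outer product of the
#' singles.
#'
#' @param singles `n_s x k` matrix of single-site distributions.
#' @return A [pair_distribution()].
#' @export
pair_independent <- function(singles) {
  singles <- as.matrix(singles)
  n_s <- nrow(singles); k <- ncol(singles)
  pairs <- array(0, c(n_s - 1, k, k))
  for (i in seq_len(n_s - 1)) pairs[i, , ] <- outer(singles[i, ], singles[i + 1, ])
  pair_distribution(singles, pairs)
}

#' Marginalize an exact joint distribution to a pair distribution
#'
#' @param chain A [chain_model()].
#' @param p_joint Joint probability vector over configurations.
#' @return A [pair_distribution()].
#' @export
pair_from_joint <- function(chain, p_joint) {
  cfgs <- .chain_configs(chain)
  k <- chain$k; n_s <- chain$n_s
  singles <- matrix(0, n_s, k)
  pairs <- array(0, c(n_s - 1, k, k))
  for (i in seq_len(n_s)) {
    for (s in seq_len(k)) singles[i, s] <- sum(p_joint[cfgs[, i] == s])
  }
  for (i in seq_len(n_s - 1)) {
    for (s in seq_len(k)) for (sp in seq_len(k)) {
      pairs[i, s, sp] <- sum(p_joint[cfgs[, i] == s & cfgs[, i + 1] == sp])
    }
  }
  pair_distribution(singles, pairs)
}

#' Reconstruct the joint distribution from a pair distribution
#'
#' The pair-approximation (Markov-chain) reconstruction
#' \deqn{P(s_1,\dots,s_N) \approx \frac{\prod_i P_{i,i+1}(s_i, s_{i+1})}
#'       {\prod_{i=2}^{N-1} P_i(s_i)},}
#' exact whenever the joint law has nearest-neighbour (Markov-chain)
#' dependence. The result is renormalized if its total deviates from 1 by
#' more than 1e-8 (the deviation is recorded in the `"deficit"` attribute).
#'
#' @param pd A [pair_distribution()] with `k^n_s <= 65536`.
#' @return Joint probability vector over configurations (synapse 1 fastest).
#' @export
reconstruct_joint <- function(pd) {
  stopifnot(inherits(pd, "pair_distribution"))
  n_joint <- as.double(pd$k)^pd$n_s
  if (n_joint > 65536) abort("joint space too large to reconstruct.")
  chain_dims <- rep(list(seq_len(pd$k)), pd$n_s)
  cfgs <- as.matrix(expand.grid(chain_dims))
  logp <- numeric(nrow(cfgs))
  for (i in seq_len(pd$n_s - 1)) {
    pij <- pd$pairs[i, , ]
    vals <- pij[cbind(cfgs[, i], cfgs[, i + 1])]
    logp <- logp + ifelse(vals > 0, log(vals), -Inf)
  }
  if (pd$n_s > 2) {
    for (i in 2:(pd$n_s - 1)) {
      vals <- pd$singles[i, cfgs[, i]]
      logp <- logp - log(pmax(vals, 1e-300))
    }
  }
  p <- exp(logp)
  p[is.nan(p)] <- 0
  tot <- sum(p)
  deficit <- abs(tot - 1)
  if (deficit > 1e-8) p <- p / tot
  attr(p, "deficit") <- deficit
  p
}

# ---- pair dynamics ---------------------------------------------------------

# pack/unpack the ODE state vector: singles (n_s*k) then pairs ((n_s-1)*k^2)
.pd_pack <- function(pd) c(as.numeric(pd$singles), as.numeric(pd$pairs))
.pd_unpack <- function(y, n_s, k) {
  list(singles = matrix(y[seq_len(n_s * k)], n_s, k),
       pairs = array(y[-seq_len(n_s * k)], c(n_s - 1, k, k)))
}

# three-site closure P(l, s' , r) ~ P_l(l, s') P_r(s', r) / P(s'), guarded
.closure <- function(p_left, p_right, p_mid) {
  if (p_left <= 0 || p_right <= 0) return(0)
  p_left * p_right / max(p_mid, 1e-300)
}

# time derivative of the packed pair state under the closed pair equations
.pair_rhs <- function(chain, singles, pairs) {
  k <- chain$k; n_s <- chain$n_s
  d_singles <- matrix(0, n_s, k)
  d_pairs <- array(0, c(n_s - 1, k, k))

  # synapse flip terms -------------------------------------------------------
  # boundary synapse 1: rate depends on neighbour s2 directly
  for (s1 in 1:k) for (s1p in 1:k) {
    if (s1 == s1p) next
    for (s2 in 1:k) {
      gain <- chain$w_left[s1, s1p, s2] * pairs[1, s1p, s2]
      loss <- chain$w_left[s1p, s1, s2] * pairs[1, s1, s2]
      flux <- gain - loss
      d_singles[1, s1] <- d_singles[1, s1] + flux
      d_pairs[1, s1, s2] <- d_pairs[1, s1, s2] + flux
    }
  }
  # boundary synapse n_s
  for (sn in 1:k) for (snp in 1:k) {
    if (sn == snp) next
    for (sm in 1:k) {
      gain <- chain$w_right[sn, snp, sm] * pairs[n_s - 1, sm, snp]
      loss <- chain$w_right[snp, sn, sm] * pairs[n_s - 1, sm, sn]
      flux <- gain - loss
      d_singles[n_s, sn] <- d_singles[n_s, sn] + flux
      d_pairs[n_s - 1, sm, sn] <- d_pairs[n_s - 1, sm, sn] + flux
    }
  }
  # interior synapses: closure over (left, i, right)
  if (n_s > 2) {
    for (i in 2:(n_s - 1)) {
      for (si in 1:k) for (sip in 1:k) {
        if (si == sip) next
        for (l in 1:k) for (r in 1:k) {
          gain <- chain$w_int[si, sip, l, r] *
            .closure(pairs[i - 1, l, sip], pairs[i, sip, r], singles[i, sip])
          loss <- chain$w_int[sip, si, l, r] *
            .closure(pairs[i - 1, l, si], pairs[i, si, r], singles[i, si])
          flux <- gain - loss
          d_singles[i, si] <- d_singles[i, si] + flux
          # flips of i move both adjacent pair tables
          d_pairs[i - 1, l, si] <- d_pairs[i - 1, l, si] + flux
          d_pairs[i, si, r] <- d_pairs[i, si, r] + flux
        }
      }
    }
  }
  list(singles = d_singles, pairs = d_pairs)
}

# iterative proportional fitting step restoring marginal consistency
.pd_project <- function(singles, pairs, sweeps = 2L) {
  n_s <- nrow(singles); k <- ncol(singles)
  singles <- pmax(singles, 0)
  singles <- singles / rowSums(singles)
  pairs <- pmax(pairs, 0)
  for (i in seq_len(n_s - 1)) pairs[i, , ] <- pairs[i, , ] / sum(pairs[i, , ])
  for (sw in seq_len(sweeps)) {
    for (i in seq_len(n_s - 1)) {
      pij <- pairs[i, , ]
      rm_ <- rowSums(pij)
      scale_l <- ifelse(rm_ > 0, singles[i, ] / pmax(rm_, 1e-300), 1)
      pij <- pij * scale_l
      cm_ <- colSums(pij)
      scale_r <- ifelse(cm_ > 0, singles[i + 1, ] / pmax(cm_, 1e-300), 1)
      pij <- t(t(pij) * scale_r)
      pairs[i, , ] <- pij / sum(pij)
    }
  }
  list(singles = singles, pairs = pairs)
}

#' Evolve a pair distribution under the closed pair equations
#'
#' Integrates the `n_s K + (n_s - 1) K^2` component system obtained by
#' marginalizing the chain master equation and closing three-site terms with
#' \deqn{P(s_{i-1}, s_i', s_{i+1}) \approx
#'       \frac{P(s_{i-1}, s_i') P(s_i', s_{i+1})}{P(s_i')}.}
#' The closure is exact for neighbour-independent rates and for joint laws
#' with Markov-chain structure. After integration, marginal consistency is
#' monitored; if the drift exceeds `project_tol`, tables are corrected by
#' iterative proportional fitting toward the averaged marginals.
#'
#' @param chain A [chain_model()].
#' @param pd0 Initial [pair_distribution()].
#' @param times Increasing time grid.
#' @param project_tol Marginal-consistency threshold triggering projection
#'   (default 1e-6).
#' @return A list of [pair_distribution()] objects, one per time point, with
#'   attribute `"time"`; element names are the times.
#' @export
pair_evolve <- function(chain, pd0, times, project_tol = 1e-6) {
  stopifnot(inherits(chain, "chain_model"), inherits(pd0, "pair_distribution"))
  if (chain$n_s < 2) abort("pair dynamics need at least 2 synapses; use exact_evolve.")
  if (pd0$n_s != chain$n_s || pd0$k != chain$k) {
    abort("`pd0` does not match the chain dimensions.")
  }
  k <- chain$k; n_s <- chain$n_s
  rhs <- function(t, y, parms) {
    st <- .pd_unpack(y, n_s, k)
    d <- .pair_rhs(chain, st$singles, st$pairs)
    list(c(as.numeric(d$singles), as.numeric(d$pairs)))
  }
  sol <- deSolve::lsoda(
    y = .pd_pack(pd0), times = if (times[1] > 0) c(0, times) else times,
    func = rhs, rtol = 1e-10, atol = 1e-12
  )
  sol <- sol[match(times, sol[, "time"]), -1, drop = FALSE]
  out <- vector("list", length(times))
  for (ti in seq_along(times)) {
    st <- .pd_unpack(sol[ti, ], n_s, k)
    mism <- 0
    for (i in seq_len(n_s - 1)) {
      mism <- max(mism,
                  max(abs(rowSums(st$pairs[i, , ]) - st$singles[i, ])),
                  max(abs(colSums(st$pairs[i, , ]) - st$singles[i + 1, ])))
    }
    if (mism > project_tol) st <- .pd_project(st$singles, st$pairs)
    out[[ti]] <- pair_distribution(st$singles, st$pairs, tol = 1e-6)
    attr(out[[ti]], "marginal_mismatch") <- mism
  }
  attr(out, "time") <- times
  names(out) <- format(times)
  out
}

#' Stationary pair distribution by long-time relaxation
#'
#' Relaxes the pair equations from a uniform product state until the rhs
#' norm falls below `tol`.
#'
#' @param chain A [chain_model()].
#' @param t_relax Relaxation horizon per sweep.
#' @param max_sweeps Maximum number of relaxation sweeps.
#' @param tol Convergence threshold on the rhs max-norm.
#' @return A [pair_distribution()].
#' @export
pair_stationary <- function(chain, t_relax = 50, max_sweeps = 40L, tol = 1e-10) {
  uni <- matrix(1 / chain$k, chain$n_s, chain$k)
  pd <- pair_independent(uni)
  for (sw in seq_len(max_sweeps)) {
    traj <- pair_evolve(chain, pd, c(0, t_relax))
    pd <- traj[[2]]
    d <- .pair_rhs(chain, pd$singles, pd$pairs)
    nrm <- max(abs(c(as.numeric(d$singles), as.numeric(d$pairs))))
    if (nrm < tol) break
  }
  pd
}

#' Information gain rate of a learning chain
#'
#' Rate of change of the KL divergence between the (pair-approximate) joint
#' law and a stationary reference,
#' \eqn{\dot D_{KL}(P \| P_{ss})}, assembled from the pair-equation fluxes:
#' \deqn{\dot D = \sum_i \sum_{s,s'} \dot P_{i,i+1}(s,s')
#'  \ln\frac{P_{i,i+1}(s,s')}{P^{ss}_{i,i+1}(s,s')}
#'  - \sum_{i=2}^{N-1} \sum_s \dot P_i(s) \ln\frac{P_i(s)}{P^{ss}_i(s)},}
#' the time derivative of the pair-approximation KL functional. Positive
#' while learning drives the chain away from the reference; negative while
#' the chain relaxes back (information loss); zero at the reference.
#'
#' @param chain A [chain_model()] (the dynamics generating the fluxes).
#' @param pd Current [pair_distribution()].
#' @param pd_ss Stationary reference [pair_distribution()] of the same shape.
#' @return Information gain rate (nats/time).
#' @export
info_gain_rate <- function(chain, pd, pd_ss) {
  stopifnot(inherits(pd, "pair_distribution"),
            inherits(pd_ss, "pair_distribution"))
  if (pd$n_s != pd_ss$n_s || pd$k != pd_ss$k) abort("shape mismatch.")
  d <- .pair_rhs(chain, pd$singles, pd$pairs)
  tot <- 0
  for (i in seq_len(pd$n_s - 1)) {
    num <- pd$pairs[i, , ]; den <- pd_ss$pairs[i, , ]
    live <- d$pairs[i, , ] != 0
    if (any(live & (num <= 0 | den <= 0))) return(Inf)
    lr <- matrix(0, pd$k, pd$k)
    lr[num > 0 & den > 0] <- log(num[num > 0 & den > 0] / den[num > 0 & den > 0])
    tot <- tot + sum(d$pairs[i, , ] * lr)
  }
  for (i in if (pd$n_s > 2) 2:(pd$n_s - 1) else integer(0)) {
    num <- pd$singles[i, ]; den <- pd_ss$singles[i, ]
    live <- d$singles[i, ] != 0
    if (any(live & (num <= 0 | den <= 0))) return(Inf)
    lr <- numeric(pd$k)
    lr[num > 0 & den > 0] <- log(num[num > 0 & den > 0] / den[num > 0 & den > 0])
    tot <- tot - sum(d$singles[i, ] * lr)
  }
  tot
}

#' Entropy production of the chain in the pair approximation
#'
#' Per-synapse entropy production rates
#' \deqn{\dot S_{pr,i} = \tfrac12 \sum [J_+ - J_-] \ln(J_+/J_-)}
#' over the closed (pair-approximate) one-flip fluxes of synapse `i`, each
#' term non-negative; the total is their sum, and the energetic cost rate is
#' `e0 * total` in kB*T per unit time.
#'
#' @inheritParams info_gain_rate
#' @return A list with `total` (nats/time), `per_synapse` (numeric vector),
#'   and `energy_rate` (kB*T/time).
#' @export
chain_entropy_production <- function(chain, pd) {
  stopifnot(inherits(chain, "chain_model"), inherits(pd, "pair_distribution"))
  k <- chain$k; n_s <- chain$n_s
  singles <- pd$singles; pairs <- pd$pairs
  per <- numeric(n_s)
  # boundary synapse 1
  for (s1 in 1:k) for (s1p in 1:k) {
    if (s1 >= s1p) next
    for (s2 in 1:k) {
      jp <- chain$w_left[s1, s1p, s2] * pairs[1, s1p, s2]
      jm <- chain$w_left[s1p, s1, s2] * pairs[1, s1, s2]
      per[1] <- per[1] + flux_log(jp, jm) + flux_log(jm, jp)
    }
  }
  # boundary synapse n_s
  for (sn in 1:k) for (snp in 1:k) {
    if (sn >= snp) next
    for (sm in 1:k) {
      jp <- chain$w_right[sn, snp, sm] * pairs[n_s - 1, sm, snp]
      jm <- chain$w_right[snp, sn, sm] * pairs[n_s - 1, sm, sn]
      per[n_s] <- per[n_s] + flux_log(jp, jm) + flux_log(jm, jp)
    }
  }
  # interior
  if (n_s > 2) {
    for (i in 2:(n_s - 1)) {
      for (si in 1:k) for (sip in 1:k) {
        if (si >= sip) next
        for (l in 1:k) for (r in 1:k) {
          jp <- chain$w_int[si, sip, l, r] *
            .closure(pairs[i - 1, l, sip], pairs[i, sip, r], singles[i, sip])
          jm <- chain$w_int[sip, si, l, r] *
            .closure(pairs[i - 1, l, si], pairs[i, si, r], singles[i, si])
          per[i] <- per[i] + flux_log(jp, jm) + flux_log(jm, jp)
        }
      }
    }
  }
  list(total = sum(per), per_synapse = per,
       energy_rate = chain$e0 * sum(per))
}
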