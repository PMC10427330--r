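# Independent oracles and random generators shared across tests.

# Quadrature oracle for the normal CDF: integrates the density directly,
# independent of the closed-form CDF used by the implementation.
cdf_quadrature <- function(ns, p) {
  stats::integrate(function(x) stats::dnorm(x, ns$mean, ns$sd),
                   lower = ns$mean - 12 * ns$sd, upper = p,
                   rel.tol = 1e-12)$value
}

# Fixed-point iteration oracle for stable roots of F(p) = p: the basic
# dynamic contracts onto stable fixed points, so iterating p <- F(p)
# from inside a basin converges there.
fp_iterate <- function(ns, p0, tol = 1e-13, max_iter = 100000L) {
  p <- p0
  for (i in seq_len(max_iter)) {
    pn <- ns_cdf(ns, min(max(p, 0), 1))
    if (abs(pn - p) < tol) return(pn)
    p <- pn
  }
  stop("fixed-point iteration did not converge from ", p0)
}

# Brute-force root enumeration by dense sign-change scan of F(p) - p.
scan_roots_basic <- function(ns, n = 1e5L) {
  grid <- seq(0, 1, length.out = n)
  v <- ns_cdf(ns, grid) - grid
  s <- sign(v)
  idx <- which(s[-n] != s[-1L] & s[-n] != 0)
  vapply(idx, function(i)
    stats::uniroot(function(p) ns_cdf(ns, p) - p, grid[c(i, i + 1L)],
                   tol = 1e-13)$root, numeric(1))
}

# Classical fixed-step RK4, pure R: independent of the package's
# adaptive C++ stepper. Suitable for short spans at small steps.
rk4_integrate <- function(f, x0, times, h = 1e-3) {
  out <- matrix(NA_real_, length(times), length(x0))
  out[1, ] <- x0
  x <- x0
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    n_sub <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / n_sub
    for (k in seq_len(n_sub)) {
      k1 <- f(x)
      k2 <- f(x + hh / 2 * k1)
      k3 <- f(x + hh / 2 * k2)
      k4 <- f(x + hh * k3)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1L, ] <- x
  }
  out
}

# Reduction of raw-model derivatives via the chain rule; the identity
# reduce(raw_rhs) == rhs(reduce(raw_state)) pins the reduced equations
# to the five-compartment flow diagram.
reduce_derivs <- function(raw_state, raw_derivs) {
  N <- raw_state[[2]]; V <- raw_state[[3]]; C <- raw_state[[5]]
  I <- N + V
  dS <- raw_derivs[[1]]; dN <- raw_derivs[[2]]; dV <- raw_derivs[[3]]
  dC <- raw_derivs[[5]]
  dI <- dN + dV
  c(S = dS, I = dI,
    y = dV / I - (V / I) * dI / I,
    p = dC / V - (C / V) * dV / V)
}

random_ns <- function() {
  norm_sensitivity(stats::runif(1, 0.25, 0.8), stats::runif(1, 0.005, 0.09))
}

random_params <- function(K = 1, p_tilde = NULL) {
  # rosy-belief worlds only: the naive belief must not undershoot the
  # cooperation it induces, F(p_tilde) <= p_tilde (the model's standing
  # assumption; gap invariance requires it)
  repeat {
    ns <- random_ns()
    pt <- if (is.null(p_tilde)) stats::runif(1, 0.85, 0.999) else p_tilde
    if (ns_cdf(ns, pt) <= pt) break
  }
  community_params(inflow = stats::runif(1, 0.2, 2),
                   learning = stats::runif(1, 0.2, 2),
                   outflow = stats::runif(1, 0.05, 1.5),
                   phi = stats::runif(1, 0.05, 1.5),
                   K = K, p_tilde = pt, norms = ns)
}

# Admissible random state: S + I <= K, p below the naive belief.
random_state <- function(params) {
  sfrac <- stats::runif(1, 0.05, 0.9)
  ifrac <- stats::runif(1, 0.05, 0.95) * (1 - sfrac)
  community_state(S = sfrac * params$K, I = ifrac * params$K,
                  y = stats::runif(1, 0.05, 0.95),
                  p = stats::runif(1, 0, params$p_tilde))
}

coordination_ns <- function() norm_sensitivity(0.5, 0.04)
cooperation_ns <- function() norm_sensitivity(0.7, 0.04)
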