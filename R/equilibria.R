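#' Equilibrium savvy fraction of insiders
#'
#' At any equilibrium with both insiders and outsiders present, the
#' savvy fraction balances learning against leaving:
#' y* = 1 / (1 + omega/lambda) = lambda / (lambda + omega). It depends
#' on the outflow and learning rates only through their ratio.
#'
#' @param outflow leaving-rate coefficient omega >= 0.
#' @param learning learning-rate coefficient lambda > 0.
#' @return y* in (0, 1\].
#' @export
savvy_fraction_eq <- function(outflow, learning) {
  stopifnot(is.numeric(outflow), is.numeric(learning),
            all(outflow >= 0))
  if (any(learning <= 0))
    stop("`learning` must be positive: with no learning the savvy ",
         "fraction formula y* = 1/(1 + omega/lambda) is undefined")
  learning / (learning + outflow)
}

#' Savvy cooperation levels at the mixed equilibrium
#'
#' At a mixed (insider/outsider) equilibrium the savvy cooperation
#' frequency solves p = F(y* p + (1 - y*) F(p_tilde)) with
#' y* = lambda/(lambda + omega): savvy individuals' cooperation rate
#' equals the threshold CDF evaluated at the true mean cooperation,
#' averaged over savvy and naive insiders. The presence of naive
#' insiders shifts the effective reaction curve up, which is how rosy
#' beliefs boost cooperation. Each root's one-dimensional stability
#' follows from the slope of the self-consistency map:
#' stable iff y* f(p_bar*) < 1.
#'
#' @param params a [community_params()] with `learning > 0`.
#' @param n_grid grid size for sign-change bracketing.
#' @return data.frame with columns `p_star`, `p_bar`, `Delta`,
#'   `p_stability` (ascending in `p_star`), restricted to roots with a
#'   non-negative belief gap (the model's admissible region).
#' @export
savvy_coop_equilibria <- function(params, n_grid = 2001L) {
  stopifnot(inherits(params, "community_params"))
  ys <- savvy_fraction_eq(params$outflow, params$learning)
  ns <- params$norms
  Fq <- ns_cdf(ns, params$p_tilde)
  g <- function(p) stats::pnorm(ys * p + (1 - ys) * Fq, ns$mean, ns$sd) - p
  grid <- seq(0, 1, length.out = n_grid)
  vals <- g(grid)
  roots <- grid[vals == 0]
  sgn <- sign(vals)
  for (i in seq_len(n_grid - 1L)) {
    if (sgn[i] != 0 && sgn[i + 1L] != 0 && sgn[i] != sgn[i + 1L])
      roots <- c(roots, stats::uniroot(g, c(grid[i], grid[i + 1L]),
                                       tol = 1e-13)$root)
  }
  roots <- sort(unique(roots))
  p_bar <- ys * roots + (1 - ys) * Fq
  keep <- params$p_tilde - p_bar >= -1e-10
  roots <- roots[keep]; p_bar <- p_bar[keep]
  slope <- ys * ns_pdf(ns, p_bar)
  stab <- ifelse(abs(slope - 1) < 1e-8, "marginal",
                 ifelse(slope < 1, "stable", "unstable"))
  data.frame(p_star = roots, p_bar = p_bar,
             Delta = pmax(params$p_tilde - p_bar, 0),
             p_stability = factor(stab, levels = c("stable", "unstable",
                                                   "marginal")))
}

#' Community reproduction ratio
#'
#' R-hat = inflow / (omega * Delta* * y*): the per-capita joining rate
#' of a small community in a fully susceptible population over the
#' per-capita rate at which its insiders become discouraged, evaluated
#' at a candidate behavioural equilibrium (p*, y*). Analogous to the
#' basic reproduction number of epidemiology: a mixed
#' insider/outsider equilibrium exists iff R-hat > 1.
#'
#' @param params a [community_params()].
#' @param p_star candidate savvy cooperation level.
#' @param y_star candidate savvy fraction (default
#'   [savvy_fraction_eq()]).
#' @return R-hat >= 0, or `Inf` when the discouragement rate vanishes
#'   (omega = 0 or Delta* = 0 or y* = 0): the community absorbs
#'   everyone.
#' @export
reproduction_ratio <- function(params, p_star,
                               y_star = savvy_fraction_eq(params$outflow,
                                                          params$learning)) {
  stopifnot(inherits(params, "community_params"))
  Fq <- ns_cdf(params$norms, params$p_tilde)
  Delta <- params$p_tilde - (y_star * p_star + (1 - y_star) * Fq)
  if (Delta < -1e-10)
    stop("negative belief gap at the candidate equilibrium")
  Delta <- max(Delta, 0)
  den <- params$outflow * Delta * y_star
  if (den == 0) return(Inf)
  params$inflow / den
}

#' Mixed-equilibrium population compartments
#'
#' Closed-form insider/outsider split at a mixed equilibrium with
#' behavioural coordinates (p*, y*):
#' S* = K / R-hat, I* = K (1 - 1/R-hat) / (1 + omega Delta* y* / phi),
#' D* = (omega Delta* y* / phi) I*. The triple sums to K exactly.
#'
#' @inheritParams reproduction_ratio
#' @return named numeric (S, I, D).
#' @export
population_equilibrium <- function(params, p_star,
                                   y_star = savvy_fraction_eq(params$outflow,
                                                              params$learning)) {
  if (params$phi <= 0)
    stop("`phi` must be positive for the mixed population equilibrium")
  R <- reproduction_ratio(params, p_star, y_star)
  if (!is.finite(R))
    stop("reproduction ratio is infinite (no discouragement): the mixed ",
         "equilibrium degenerates to the all-insider state")
  if (R <= 1)
    stop("no interior equilibrium: R-hat = ", signif(R, 6),
         " <= 1, the only stable state has everyone outside the community")
  Fq <- ns_cdf(params$norms, params$p_tilde)
  Delta <- params$p_tilde - (y_star * p_star + (1 - y_star) * Fq)
  ratio_DI <- params$outflow * Delta * y_star / params$phi
  S <- params$K / R
  I <- params$K * (1 - 1 / R) / (1 + ratio_DI)
  c(S = S, I = I, D = ratio_DI * I)
}

jacobian_community <- function(params, state, rel_step = 1e-7,
                               clamp = FALSE) {
  x <- as.numeric(as_state(state))
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (rhs_reduced_eval(params, xp, clamp = clamp) -
               rhs_reduced_eval(params, xm, clamp = clamp)) / (2 * h)
  }
  dimnames(J) <- list(c("S", "I", "y", "p"), c("S", "I", "y", "p"))
  J
}

#' Linear stability of a community equilibrium
#'
#' Eigen-decomposition of the central-difference Jacobian of the
#' reduced vector field (relative step 1e-7) at an equilibrium state.
#' Classification uses the maximum real part with a +/- `dead_band`
#' dead-band. The all-insider high-cooperation state is a line of
#' equilibria (the savvy fraction is neutral there): a single near-zero
#' eigenvalue yields class `marginal_line`, with the remaining spectrum
#' deciding attraction toward the line. The Jacobian uses the smooth
#' (unclamped) extension of the belief-gap flows, which equals the
#' one-sided derivative from the admissible region at Delta = 0.
#'
#' @param params a [community_params()].
#' @param state an equilibrium state; residual `||rhs||` must be below
#'   `resid_tol`.
#' @param dead_band dead-band on eigenvalue real parts.
#' @param resid_tol maximum allowed equilibrium residual.
#' @return list with `eigenvalues` (complex, sorted by decreasing real
#'   part) and `class` (one of "stable", "unstable", "marginal",
#'   "marginal_line").
#' @export
stability <- function(params, state, dead_band = 1e-8, resid_tol = 1e-6) {
  st <- as_state(state)
  resid <- max(abs(community_rhs(params, st)))
  if (resid > resid_tol)
    stop("state is not an equilibrium: ||rhs|| = ", signif(resid, 4),
         " > ", resid_tol)
  J <- jacobian_community(params, st)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  re <- Re(ev)
  near0 <- abs(re) < dead_band
  cls <- if (sum(near0) == 1L) {
    rest <- re[!near0]
    if (all(rest < 0)) "marginal_line" else "unstable"
  } else if (max(re) > dead_band) {
    "unstable"
  } else if (max(re) < -dead_band) {
    "stable"
  } else {
    "marginal"
  }
  list(eigenvalues = ev, class = cls)
}

#' Boundary behaviour and invasion rate at the community-crash state
#'
#' At the all-outsider ("crash") state, S = K and I -> 0; the
#' behavioural coordinates (y, p) of a vanishingly small insider
#' population follow their own boundary dynamics
#' dy/dt = lambda Delta (1-y) - omega Delta y (1-y) - inflow y,
#' dp/dt = F(p_bar) - p. This finds the boundary attractor (y0, p0) by
#' relaxation integration (with a Newton fallback), then evaluates the
#' per-capita invasion growth rate of the insider population,
#' r = inflow - omega Delta0 y0. The crash is stable (the community
#' cannot rebound) iff r < 0.
#'
#' The boundary system can be bistable: a freshly seeded community is
#' naive-dominated (start y ~ 0, p = F(p_tilde)), while a community
#' that has collapsed is savvy-dominated with low cooperation (start
#' y ~ 1, p ~ 0). Both attractors are located; `rate` and `stable`
#' refer to the collapse-side attractor, which governs whether a
#' crashed community rebounds, while the seed-side attractor (reported
#' under `$seed`) governs growth of a newly seeded community and can
#' disagree at intermediate inflow rates -- the source of hysteresis.
#'
#' @param params a [community_params()].
#' @param tol residual tolerance for the boundary attractor.
#' @return list with `rate` (r at the collapse-side attractor), `y`,
#'   `p`, `Delta`, `stable` (r < 0), `converged`, and `seed` (list
#'   `rate`, `y`, `p`, `Delta` for the naive-seeded attractor).
#' @export
crash_invasion_rate <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "community_params"))
  Fq <- ns_cdf(params$norms, params$p_tilde)
  pv <- par_vec(params)
  bres <- function(x) { # boundary residual
    y <- x[1]; p <- x[2]
    p_bar <- y * p + (1 - y) * Fq
    Delta <- max(params$p_tilde - p_bar, 0)
    c(params$learning * Delta * (1 - y) -
        params$outflow * Delta * y * (1 - y) - params$inflow * y,
      ns_cdf(params$norms, min(max(p_bar, 0), 1)) - p)
  }
  relax <- function(x) {
    converged <- FALSE
    for (k in 1:50) {
      res <- .cpp_integrate(2L, pv, x, c(0, 200), 1e-10, 1e-13)
      x <- res$states[2, ]
      if (max(abs(bres(x))) < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      # Newton fallback from the relaxed point
      for (it in 1:100) {
        r0 <- bres(x)
        if (max(abs(r0)) < tol) { converged <- TRUE; break }
        J <- matrix(0, 2, 2)
        for (j in 1:2) {
          h <- 1e-7 * max(abs(x[j]), 1e-3)
          xp <- x; xp[j] <- xp[j] + h
          xm <- x; xm[j] <- xm[j] - h
          J[, j] <- (bres(xp) - bres(xm)) / (2 * h)
        }
        step <- tryCatch(solve(J, r0), error = function(e) NULL)
        if (is.null(step)) break
        x <- pmin(pmax(x - step, 0), 1)
      }
    }
    list(x = x, converged = converged)
  }
  describe <- function(x) {
    y0 <- x[[1]]; p0 <- x[[2]]
    Delta0 <- max(params$p_tilde - (y0 * p0 + (1 - y0) * Fq), 0)
    list(rate = params$inflow - params$outflow * Delta0 * y0,
         y = y0, p = p0, Delta = Delta0)
  }
  seed_rx <- relax(c(y = 1e-3, p = Fq))          # freshly seeded: naive
  crash_rx <- relax(c(y = 1 - 1e-3, p = 1e-3))   # collapsed: savvy, low p
  if (!seed_rx$converged || !crash_rx$converged)
    warning("boundary attractor did not converge to tolerance; invasion ",
            "rate estimated at the relaxed point")
  col <- describe(crash_rx$x)
  c(col,
    list(stable = col$rate < 0,
         converged = seed_rx$converged && crash_rx$converged,
         seed = describe(seed_rx$x)))
}

make_equilibrium <- function(params, state, kind, R_hat = NA_real_,
                             stab = NULL) {
  st <- as_state(state)
  if (is.null(stab)) stab <- stability(params, st)
  structure(list(state = st, kind = kind,
                 eigenvalues = stab$eigenvalues,
                 stability = stab$class, R_hat = R_hat,
                 p_bar = mean_cooperation(st, params),
                 Delta = max(params$p_tilde - mean_cooperation(st, params), 0),
                 total_cooperation = total_cooperation(st, params)),
            class = "community_equilibrium")
}

#' @export
print.community_equilibrium <- function(x, ...) {
  st <- x$state
  cat(sprintf("%s equilibrium (%s)\n", x$kind, x$stability))
  cat(sprintf("  S = %.6g, I = %.6g, y = %.6g, p = %.6g\n",
              st[["S"]], st[["I"]], st[["y"]], st[["p"]]))
  cat(sprintf("  p_bar = %.6g, total cooperation = %.6g, R_hat = %s\n",
              x$p_bar, x$total_cooperation,
              if (is.na(x$R_hat)) "-" else signif(x$R_hat, 6)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Enumerate all equilibria of the community model
#'
#' Assembles, with stability classification:
#' * the all-outsider crash state (S = K, I = 0) with the boundary
#'   behavioural attractor attached;
#' * the all-insider high-cooperation equilibrium (I = K, p = p_tilde),
#'   present only when the naive belief is self-confirming
#'   (F(p_tilde) = p_tilde, i.e. a coordination-dilemma belief); it is
#'   a line of equilibria in y, reported once at the representative
#'   y = lambda/(lambda + omega);
#' * every mixed insider/outsider equilibrium built from the roots of
#'   [savvy_coop_equilibria()] with a positive belief gap and
#'   reproduction ratio R-hat > 1 (requires phi > 0).
#'
#' @param params a [community_params()].
#' @return list of `community_equilibrium` objects, class
#'   `equilibrium_set`.
#' @export
enumerate_equilibria <- function(params) {
  stopifnot(inherits(params, "community_params"))
  out <- list()

  # (a) all-outsider crash state
  cb <- crash_invasion_rate(params)
  crash_state <- community_state(S = params$K, I = 0, y = cb$y, p = cb$p)
  crash_eigs <- tryCatch(stability(params, crash_state)$eigenvalues,
                         error = function(e) complex(0))
  crash_stab <- list(
    eigenvalues = crash_eigs,
    class = if (cb$rate < -1e-10) "stable"
            else if (cb$rate > 1e-10) "unstable" else "marginal")
  out <- c(out, list(make_equilibrium(params, crash_state,
                                      "all_outsider_crash",
                                      R_hat = NA_real_, stab = crash_stab)))

  # (b) all-insider high equilibrium (self-confirming naive belief)
  Fq <- ns_cdf(params$norms, params$p_tilde)
  if (abs(Fq - params$p_tilde) < 1e-8) {
    y_repr <- if (params$learning > 0)
      savvy_fraction_eq(params$outflow, params$learning) else 1
    hi <- community_state(S = 0, I = params$K, y = y_repr,
                          p = params$p_tilde)
    out <- c(out, list(make_equilibrium(params, hi, "all_insider_high",
                                        R_hat = Inf)))
  }

  # (c) mixed equilibria
  if (params$learning > 0 && params$phi > 0) {
    roots <- savvy_coop_equilibria(params)
    ys <- savvy_fraction_eq(params$outflow, params$learning)
    for (i in seq_len(nrow(roots))) {
      if (roots$Delta[i] <= 1e-8) next  # coincides with the all-insider line
      R <- reproduction_ratio(params, roots$p_star[i], ys)
      if (!is.finite(R) || R <= 1) next
      pop <- population_equilibrium(params, roots$p_star[i], ys)
      st <- community_state(S = pop[["S"]], I = pop[["I"]], y = ys,
                            p = roots$p_star[i])
      out <- c(out, list(make_equilibrium(params, st, "mixed", R_hat = R)))
    }
  }
  structure(out, class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(length(x), "equilibria:\n")
  for (e in x) print(e)
  invisible(x)
}

#' Serialise an equilibrium set to JSON
#'
#' @param eqs an `equilibrium_set` from [enumerate_equilibria()].
#' @param path optional file path; if `NULL`, the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to file).
#' @export
equilibria_json <- function(eqs, path = NULL) {
  stopifnot(inherits(eqs, "equilibrium_set"))
  recs <- lapply(eqs, function(e) {
    list(kind = e$kind,
         state = as.list(stats::setNames(as.numeric(e$state),
                                         c("S", "I", "y", "p"))),
         p_bar = e$p_bar, Delta = e$Delta,
         total_cooperation = e$total_cooperation,
         R_hat = if (is.na(e$R_hat)) NULL
                 else if (is.infinite(e$R_hat)) "Inf" else e$R_hat,
         eigenvalues = list(re = Re(e$eigenvalues),
                            im = Im(e$eigenvalues)),
         stability = e$stability)
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
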