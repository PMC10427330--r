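#' Norm-sensitivity distribution
#'
#' Constructs the population distribution of cooperation thresholds
#' ("norm sensitivities"). An individual with threshold x cooperates when
#' they believe a fraction p >= x of the community cooperates, so the
#' fraction of the population willing to cooperate at perceived
#' cooperation level p is the cumulative distribution function F(p).
#' We take F to be the CDF of a normal distribution with mean `mean` and
#' variance `variance`, evaluated on \[0, 1\] without truncation or
#' renormalisation: F(0) > 0 means some individuals cooperate
#' unconditionally, F(1) < 1 means some never cooperate.
#'
#' @param mean location of the threshold distribution, in (0, 1).
#' @param variance variance of the threshold distribution, > 0
#'   (probability-scale squared).
#' @return an object of class `norm_sensitivity` with fields `mean`,
#'   `variance` and `sd`.
#' @examples
#' ns <- norm_sensitivity(0.5, 0.04)
#' ns_cdf(ns, 0.5)  # 0.5: the CDF at its own mean
#' @export
norm_sensitivity <- function(mean, variance) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(variance), length(variance) == 1L, is.finite(variance))
  if (mean <= 0 || mean >= 1)
    stop("`mean` must lie strictly inside (0, 1), got ", mean)
  if (variance <= 0)
    stop("`variance` must be strictly positive, got ", variance)
  structure(list(mean = mean, variance = variance, sd = sqrt(variance)),
            class = "norm_sensitivity")
}

#' @export
print.norm_sensitivity <- function(x, ...) {
  cat(sprintf("Norm-sensitivity distribution: Normal(mean = %g, variance = %g)\n",
              x$mean, x$variance))
  cat(sprintf("  F(0) = %.6g, F(1) = %.6g\n",
              ns_cdf(x, 0), ns_cdf(x, 1)))
  invisible(x)
}

check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`", what, "` must lie in [0, 1]")
  p
}

#' Fraction cooperating at perceived cooperation level p
#'
#' Evaluates F(p), the proportion of the population whose threshold is
#' below p, i.e. the fraction that will cooperate given that a proportion
#' p of the community is (believed to be) cooperating.
#'
#' @param ns a [norm_sensitivity()] object.
#' @param p perceived cooperation level(s) in \[0, 1\] (vectorised).
#' @return F(p) in (0, 1).
#' @export
ns_cdf <- function(ns, p) {
  stopifnot(inherits(ns, "norm_sensitivity"))
  check_prob(p)
  stats::pnorm(p, mean = ns$mean, sd = ns$sd)
}

#' Density of the norm-sensitivity distribution
#'
#' f(p) = F'(p), the density of cooperation thresholds at p.
#'
#' @inheritParams ns_cdf
#' @return f(p) >= 0.
#' @export
ns_pdf <- function(ns, p) {
  stopifnot(inherits(ns, "norm_sensitivity"))
  check_prob(p)
  stats::dnorm(p, mean = ns$mean, sd = ns$sd)
}

#' Right-hand side of the basic threshold dynamic
#'
#' The basic conditional-cooperation dynamic is dp/dt = F(p) - p: the
#' cooperation level moves toward the fraction of the population willing
#' to cooperate at the current level. This is a continuous-time
#' Granovetter-Schelling threshold dynamic.
#'
#' @inheritParams ns_cdf
#' @return F(p) - p (per unit time), vectorised over `p`.
#' @export
rhs_basic <- function(ns, p) {
  ns_cdf(ns, p) - p
}

#' Fixed points of the basic threshold dynamic
#'
#' Finds all roots of F(p) = p on \[0, 1\] by sign-change bracketing on a
#' uniform grid followed by bisection, and classifies each root's
#' stability from the slope: stable iff f(p*) < 1, unstable iff
#' f(p*) > 1, marginal when |f(p*) - 1| is below `marginal_tol`.
#' Because F(0) > 0 and F(1) < 1, the root count is odd (1 or 3) except
#' exactly at a saddle-node tangency, where a double root is reported
#' with stability "marginal".
#'
#' @inheritParams ns_cdf
#' @param n_grid number of grid points for sign-change bracketing.
#' @param tol bisection tolerance on the root location.
#' @param marginal_tol dead-band on |f(p*) - 1| for the marginal class.
#' @return a data.frame with columns `location` (ascending) and
#'   `stability` (factor: stable / unstable / marginal).
#' @export
fixed_points <- function(ns, n_grid = 2001L, tol = 1e-12,
                         marginal_tol = 1e-8) {
  stopifnot(inherits(ns, "norm_sensitivity"))
  g <- function(p) stats::pnorm(p, ns$mean, ns$sd) - p
  grid <- seq(0, 1, length.out = n_grid)
  vals <- g(grid)
  roots <- numeric(0)
  # exact zeros on the grid
  zero_idx <- which(vals == 0)
  roots <- c(roots, grid[zero_idx])
  sgn <- sign(vals)
  for (i in seq_len(n_grid - 1L)) {
    if (sgn[i] != 0 && sgn[i + 1L] != 0 && sgn[i] != sgn[i + 1L]) {
      r <- stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = tol)
      roots <- c(roots, r$root)
    }
  }
  roots <- sort(roots)
  # near-tangency: a grazing contact may produce no sign change; detect by
  # checking local minima of |g| that sit below tolerance
  if (length(roots) %% 2L == 0L || length(roots) == 0L) {
    absg <- abs(vals)
    for (i in 2:(n_grid - 1L)) {
      if (absg[i] <= absg[i - 1L] && absg[i] <= absg[i + 1L] &&
          absg[i] < 1e-7 && (length(roots) == 0L ||
                             min(abs(roots - grid[i])) > 2 / n_grid)) {
        opt <- stats::optimize(function(p) abs(g(p)),
                               c(grid[i - 1L], grid[i + 1L]), tol = tol)
        if (opt$objective < 1e-9) roots <- sort(c(roots, opt$minimum))
      }
    }
  }
  if (length(roots) == 0L)
    stop("no fixed point found: F(p) - p has no root on [0, 1] ",
         "(should be impossible for a continuous CDF with F(0) > 0, F(1) < 1)")
  slope <- ns_pdf(ns, roots)
  stability <- ifelse(abs(slope - 1) < marginal_tol, "marginal",
                      ifelse(slope < 1, "stable", "unstable"))
  data.frame(location = roots,
             stability = factor(stability,
                                levels = c("stable", "unstable", "marginal")))
}

#' Classify the social dilemma implied by a threshold distribution
#'
#' A "coordination" dilemma has three fixed points of F(p) = p (bistable
#' low- and high-cooperation states separated by an unstable one); a
#' "cooperation" dilemma has a single low-cooperation fixed point. A
#' distribution exactly at the tangency between the two regimes is
#' flagged "marginal".
#'
#' @inheritParams ns_cdf
#' @return one of "coordination", "cooperation", "marginal".
#' @export
classify_dilemma <- function(ns) {
  fp <- fixed_points(ns)
  if (any(fp$stability == "marginal")) return("marginal")
  if (nrow(fp) >= 3L) "coordination" else "cooperation"
}

#' Naive belief: the high-cooperation fixed point of a reference dilemma
#'
#' Newcomers to the community are assumed to believe cooperation sits at
#' the high-cooperation equilibrium of a reference coordination dilemma.
#' Returns the largest stable root of F(p) = p for the reference
#' distribution; errors if the reference is monostable (no high branch).
#'
#' @param reference a [norm_sensitivity()] object with three fixed points.
#' @return the naive belief p-tilde in (0, 1).
#' @export
naive_belief <- function(reference) {
  fp <- fixed_points(reference)
  if (nrow(fp) < 3L)
    stop("no high-cooperation solution: the reference distribution is ",
         "monostable (", nrow(fp), " fixed point); the naive belief is ",
         "defined as the high root of a coordination dilemma")
  stable <- fp$location[fp$stability == "stable"]
  max(stable)
}

#' Critical variance at which bistability is lost
#'
#' For a threshold distribution with mean mu > 0.5, increasing the
#' variance merges the upper two roots of F(p) = p in a saddle-node
#' (tangency) bifurcation, turning a coordination dilemma into a
#' cooperation dilemma. This solves the tangency system
#' F(p) = p, f(p) = 1 simultaneously for (p, sigma) by damped Newton
#' iteration with an analytic Jacobian, initialised from a coarse sigma
#' grid scan, and returns sigma squared.
#'
#' @param mu mean of the threshold distribution, in (0.5, 1).
#' @param tol residual tolerance for the Newton solve.
#' @return a list with `variance` (sigma squared at tangency), `p`
#'   (location of the double root), `sigma`, and `residual`.
#' @export
critical_variance <- function(mu, tol = 1e-12) {
  stopifnot(is.numeric(mu), length(mu) == 1L)
  if (mu <= 0.5 || mu >= 1)
    stop("`mu` must lie in (0.5, 1) for the upper-tangency regime")

  n_fp <- function(sigma)
    nrow(fixed_points(norm_sensitivity(mu, sigma^2), n_grid = 2001L))
  # coarse bracket on sigma for the 3 -> 1 transition
  sig_grid <- seq(0.02, 0.45, by = 0.005)
  counts <- vapply(sig_grid, n_fp, integer(1))
  ix <- which(counts[-length(counts)] >= 3L & counts[-1L] <= 1L)
  if (length(ix) == 0L)
    stop("no tangency found: the fixed-point count never drops from 3 to 1 ",
         "over sigma in [0.02, 0.45]")
  sig0 <- sig_grid[ix[1L]]
  # initial p: the larger of the two colliding roots at sig0
  fp0 <- fixed_points(norm_sensitivity(mu, sig0^2))
  p0 <- max(fp0$location)

  # Newton on G(p, sigma) = (Phi(z) - p, phi(z)/sigma - 1), z = (p - mu)/sigma
  x <- c(p0, sig0)
  for (iter in 1:100) {
    p <- x[1]; sigma <- x[2]
    z <- (p - mu) / sigma
    Fv <- stats::pnorm(z)
    fv <- stats::dnorm(z) / sigma
    G <- c(Fv - p, fv - 1)
    if (max(abs(G)) < tol) break
    # analytic Jacobian, rows (G1, G2), columns (p, sigma)
    dphidz <- -z * stats::dnorm(z)
    J <- matrix(c(fv - 1,                       # dG1/dp
                  dphidz / sigma^2,             # dG2/dp
                  stats::dnorm(z) * (-z / sigma),  # dG1/dsigma
                  (dphidz * (-z / sigma)) / sigma - stats::dnorm(z) / sigma^2),
                nrow = 2)
    step <- tryCatch(solve(J, G), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in critical_variance Newton")
    # damping: halve until the residual norm decreases
    lam <- 1
    repeat {
      xn <- x - lam * step
      if (xn[2] > 1e-4 && xn[1] > 0 && xn[1] < 1.5) {
        zn <- (xn[1] - mu) / xn[2]
        Gn <- c(stats::pnorm(zn) - xn[1], stats::dnorm(zn) / xn[2] - 1)
        if (sum(Gn^2) < sum(G^2) || lam < 1e-6) break
      }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    x <- x - lam * step
  }
  p <- x[1]; sigma <- x[2]
  z <- (p - mu) / sigma
  resid <- max(abs(c(stats::pnorm(z) - p, stats::dnorm(z) / sigma - 1)))
  if (resid > 1e-10)
    stop("critical_variance Newton failed to converge: residual ", resid)
  list(variance = sigma^2, p = p, sigma = sigma, residual = resid)
}
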