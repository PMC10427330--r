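set_scan_param <- function(params, name, value) {
  switch(name,
    ratio = community_params(params$inflow, 1, value, params$phi,
                             params$K, params$p_tilde, params$norms),
    inflow = community_params(value, params$learning, params$outflow,
                              params$phi, params$K, params$p_tilde,
                              params$norms),
    learning = community_params(params$inflow, value, params$outflow,
                                params$phi, params$K, params$p_tilde,
                                params$norms),
    outflow = community_params(params$inflow, params$learning, value,
                               params$phi, params$K, params$p_tilde,
                               params$norms),
    phi = community_params(params$inflow, params$learning, params$outflow,
                           value, params$K, params$p_tilde, params$norms),
    variance = community_params(params$inflow, params$learning,
                                params$outflow, params$phi, params$K,
                                params$p_tilde,
                                norm_sensitivity(params$norms$mean, value)),
    stop("unknown scan parameter `", name, "`; use one of ratio, inflow, ",
         "learning, outflow, phi, variance"))
}

#' Scan equilibria along one parameter axis
#'
#' Enumerates the equilibria of the community model over an ordered
#' parameter grid, matches branches across the grid by nearest-neighbour
#' continuation in (p*, I*), and refines every change in mixed-
#' equilibrium count (a fold / saddle-node) by bisection on the count.
#'
#' @param params baseline [community_params()].
#' @param parameter one of `"ratio"` (omega/lambda with lambda fixed at
#'   1), `"inflow"`, `"learning"`, `"outflow"`, `"phi"`, `"variance"`.
#' @param values ordered grid of parameter values.
#' @param fold_tol bisection tolerance on fold locations.
#' @return an object of class `scan_branch`: list with `table` (one row
#'   per equilibrium per grid value, with branch ids) and `folds`
#'   (data.frame of refined fold locations and the counts on either
#'   side).
#' @export
scan_equilibria <- function(params, parameter, values, fold_tol = 1e-8) {
  stopifnot(inherits(params, "community_params"))
  if (length(values) == 0L) stop("empty parameter grid")
  if (is.unsorted(values, strictly = TRUE))
    stop("`values` must be sorted strictly increasing")

  count_mixed <- function(v) {
    eqs <- enumerate_equilibria(set_scan_param(params, parameter, v))
    sum(vapply(eqs, function(e) e$kind == "mixed", logical(1)))
  }

  rows <- list()
  counts <- integer(length(values))
  prev_mixed <- NULL  # data.frame p_star/branch for continuation
  next_branch <- 1L
  for (i in seq_along(values)) {
    v <- values[i]
    eqs <- enumerate_equilibria(set_scan_param(params, parameter, v))
    df <- do.call(rbind, lapply(eqs, function(e) {
      st <- e$state
      data.frame(parameter = parameter, value = v, kind = e$kind,
                 p_star = st[["p"]], y_star = st[["y"]],
                 S_star = st[["S"]], I_star = st[["I"]],
                 D_star = params$K - st[["S"]] - st[["I"]],
                 total_cooperation = e$total_cooperation,
                 stability = e$stability,
                 R_hat = e$R_hat,
                 stringsAsFactors = FALSE)
    }))
    counts[i] <- sum(df$kind == "mixed")
    # branch matching on mixed equilibria by nearest p_star
    df$branch_id <- NA_integer_
    fixed_kind <- df$kind != "mixed"
    df$branch_id[fixed_kind] <- match(df$kind[fixed_kind],
                                      c("all_outsider_crash",
                                        "all_insider_high")) - 3L # -2, -1
    mi <- which(df$kind == "mixed")
    if (length(mi)) {
      if (is.null(prev_mixed) || nrow(prev_mixed) == 0L) {
        df$branch_id[mi] <- seq(next_branch, length.out = length(mi))
        next_branch <- next_branch + length(mi)
      } else {
        used <- integer(0)
        for (j in mi) {
          d <- abs(prev_mixed$p_star - df$p_star[j]) +
            abs(prev_mixed$I_star - df$I_star[j]) / params$K
          d[prev_mixed$branch_id %in% used] <- Inf
          jm <- which.min(d)
          if (is.finite(d[jm])) {
            df$branch_id[j] <- prev_mixed$branch_id[jm]
            used <- c(used, prev_mixed$branch_id[jm])
          } else {
            df$branch_id[j] <- next_branch
            next_branch <- next_branch + 1L
          }
        }
      }
      prev_mixed <- df[mi, c("p_star", "I_star", "branch_id")]
    } else {
      prev_mixed <- df[integer(0), c("p_star", "I_star", "branch_id")]
    }
    rows[[i]] <- df
  }
  tab <- do.call(rbind, rows)

  # refine fold locations by bisection on the mixed-equilibrium count
  folds <- data.frame(value = numeric(0), count_below = integer(0),
                      count_above = integer(0))
  for (i in seq_len(length(values) - 1L)) {
    if (counts[i] != counts[i + 1L]) {
      lo <- values[i]; hi <- values[i + 1L]
      clo <- counts[i]; chi <- counts[i + 1L]
      while (hi - lo > fold_tol) {
        mid <- (lo + hi) / 2
        cm <- count_mixed(mid)
        if (cm == clo) lo <- mid else { hi <- mid; chi <- cm }
      }
      folds <- rbind(folds, data.frame(value = (lo + hi) / 2,
                                       count_below = clo,
                                       count_above = chi))
    }
  }
  structure(list(table = tab, folds = folds, parameter = parameter,
                 values = values, counts = counts),
            class = "scan_branch")
}

#' @export
print.scan_branch <- function(x, ...) {
  cat(sprintf("Equilibrium scan over `%s` (%d grid values)\n",
              x$parameter, length(x$values)))
  cat("  mixed-equilibrium counts:",
      paste(rle(x$counts)$values, collapse = " -> "), "\n")
  if (nrow(x$folds)) {
    cat("  folds at:\n")
    for (i in seq_len(nrow(x$folds)))
      cat(sprintf("    %s = %.8g (%d -> %d mixed equilibria)\n",
                  x$parameter, x$folds$value[i], x$folds$count_below[i],
                  x$folds$count_above[i]))
  } else cat("  no folds detected\n")
  invisible(x)
}

#' Write a scan table as CSV
#'
#' @param scan a `scan_branch` from [scan_equilibria()].
#' @param path output file path.
#' @export
write_scan_csv <- function(scan, path) {
  write_trajectory_csv(scan$table[, c("parameter", "value", "branch_id",
                                      "p_star", "y_star", "S_star",
                                      "I_star", "D_star",
                                      "total_cooperation", "stability")],
                       path)
}

#' Critical outflow/learning ratio(s): folds of the savvy equilibria
#'
#' The savvy cooperation equilibria solve p = F(y p + (1-y) F(p_tilde))
#' with y = 1/(1 + ratio). As the outflow/learning ratio grows, y falls,
#' the effective reaction curve shifts up, and pairs of roots are
#' created or annihilated where the curve is tangent to the diagonal.
#' This solves the tangency system
#' \{F(u) = p, y f(u) = 1\}, u = y p + (1-y) F(p_tilde),
#' by damped Newton from bracketing scans, and returns every fold ratio
#' in ascending order: one in the coordination regime (low/middle
#' annihilation), up to two in the cooperation regime (pair creation
#' then annihilation), none for sufficiently large variance.
#'
#' @param ns a [norm_sensitivity()] object.
#' @param p_tilde naive belief in (0, 1\].
#' @param tol Newton residual tolerance.
#' @return numeric vector (possibly empty) of fold ratios, ascending;
#'   attribute `"points"` holds the tangency (p, y) pairs.
#' @export
critical_ratio <- function(ns, p_tilde, tol = 1e-12) {
  stopifnot(inherits(ns, "norm_sensitivity"))
  check_prob(p_tilde, "p_tilde")
  q <- ns_cdf(ns, p_tilde)

  count_roots <- function(y) {
    g <- function(p) stats::pnorm(y * p + (1 - y) * q, ns$mean, ns$sd) - p
    grid <- seq(0, 1, length.out = 2001L)
    vals <- g(grid)
    s <- sign(vals)
    # count admissible roots: positive belief gap (p_bar < p_tilde); a
    # root with zero gap is the all-insider state, not a mixed branch
    roots <- numeric(0)
    for (i in which(s[-length(s)] != s[-1L] & s[-length(s)] != 0))
      roots <- c(roots, stats::uniroot(g, grid[c(i, i + 1L)],
                                       tol = 1e-12)$root)
    sum(p_tilde - (y * roots + (1 - y) * q) > 1e-8)
  }

  newton_tangency <- function(p0, y0) {
    x <- c(p0, y0)
    for (it in 1:200) {
      p <- x[1]; y <- x[2]
      u <- y * p + (1 - y) * q
      fu <- stats::dnorm(u, ns$mean, ns$sd)
      fpu <- -((u - ns$mean) / ns$variance) * fu
      G <- c(stats::pnorm(u, ns$mean, ns$sd) - p, y * fu - 1)
      if (max(abs(G)) < tol) return(list(p = p, y = y, ok = TRUE))
      J <- matrix(c(fu * y - 1, y^2 * fpu,
                    fu * (p - q), fu + y * fpu * (p - q)), 2, 2)
      step <- tryCatch(solve(J, G), error = function(e) NULL)
      if (is.null(step)) return(list(ok = FALSE))
      lam <- 1
      repeat {
        xn <- x - lam * step
        if (xn[1] > -0.1 && xn[1] < 1.1 && xn[2] > 1e-6 && xn[2] <= 1) {
          un <- xn[2] * xn[1] + (1 - xn[2]) * q
          Gn <- c(stats::pnorm(un, ns$mean, ns$sd) - xn[1],
                  xn[2] * stats::dnorm(un, ns$mean, ns$sd) - 1)
          if (sum(Gn^2) < sum(G^2) || lam < 1e-6) break
        }
        lam <- lam / 2
        if (lam < 1e-8) break
      }
      x <- x - lam * step
    }
    list(ok = FALSE)
  }

  # scan the savvy fraction y downward from 1 (ratio upward from 0)
  y_grid <- seq(0.999, 0.02, by = -0.001)
  counts <- vapply(y_grid, count_roots, numeric(1))
  out <- numeric(0)
  pts <- list()
  for (i in seq_len(length(y_grid) - 1L)) {
    if (counts[i] != counts[i + 1L]) {
      # initialise the tangency Newton from the bracket side that still
      # carries the colliding root pair (the larger count), at the root
      # whose self-consistency slope is nearest 1
      y0 <- if (counts[i] >= counts[i + 1L]) y_grid[i] else y_grid[i + 1L]
      g <- function(p) stats::pnorm(y0 * p + (1 - y0) * q,
                                    ns$mean, ns$sd) - p
      grid <- seq(0, 1, length.out = 4001L)
      vals <- g(grid)
      s <- sign(vals)
      roots <- numeric(0)
      for (k in which(s[-length(s)] != s[-1L] & s[-length(s)] != 0))
        roots <- c(roots, stats::uniroot(g, grid[c(k, k + 1L)],
                                         tol = 1e-12)$root)
      if (length(roots) == 0L) next
      slopes <- y0 * ns_pdf(ns, y0 * roots + (1 - y0) * q)
      p0 <- roots[which.min(abs(slopes - 1))]
      sol <- newton_tangency(p0, y0)
      if (sol$ok) {
        r <- (1 - sol$y) / sol$y
        if (length(out) == 0L || min(abs(out - r)) > 1e-8) {
          out <- c(out, r)
          pts <- c(pts, list(c(p = sol$p, y = sol$y)))
        }
      }
    }
  }
  ord <- order(out)
  structure(out[ord], points = pts[ord])
}

#' Regime diagram over the threshold-distribution variance
#'
#' For a grid of variances at fixed mean, records the dilemma type of
#' the basic threshold dynamic and the fold ratios of the community
#' model: coordination regimes have a single fold (annihilation of the
#' low/middle equilibria), cooperation regimes have two folds bounding
#' a three-equilibria window or none when the variance is large enough
#' that the equilibrium simply grows smoothly with the ratio.
#'
#' @param mu mean of the threshold distribution.
#' @param sigma2_values variance grid.
#' @param p_tilde naive belief (default: "auto" high root of the
#'   Normal(0.5, 0.04) coordination reference).
#' @return data.frame with columns `sigma2`, `dilemma`, `n_folds`,
#'   `ratio_lower`, `ratio_upper`.
#' @export
regime_diagram <- function(mu, sigma2_values,
                           p_tilde = naive_belief(norm_sensitivity(0.5, 0.04))) {
  rows <- lapply(sigma2_values, function(s2) {
    ns <- norm_sensitivity(mu, s2)
    folds <- critical_ratio(ns, p_tilde)
    data.frame(sigma2 = s2, dilemma = classify_dilemma(ns),
               n_folds = length(folds),
               ratio_lower = if (length(folds)) min(folds) else NA_real_,
               ratio_upper = if (length(folds) > 1L) max(folds) else NA_real_)
  })
  do.call(rbind, rows)
}
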