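#' Parameters of the community-membership model
#'
#' Bundles the rates and constants of the four-compartment community
#' model. Outsiders who are susceptible join the community by contact
#' with insiders at rate `inflow * S * I / K`, entering as naive members
#' who believe cooperation sits at the naive belief p-tilde. Naive
#' insiders learn the true mean cooperation at per-capita rate
#' `learning * Delta` (Delta = belief gap), becoming savvy. Savvy
#' insiders, disillusioned by the same gap, leave at per-capita rate
#' `outflow * Delta` and become discouraged outsiders, who wane back to
#' susceptible at rate `phi`.
#'
#' @param inflow contact/joining rate coefficient (per unit time), >= 0.
#' @param learning learning-speed coefficient (per unit time), >= 0.
#' @param outflow leaving-rate coefficient omega (per unit time), >= 0.
#' @param phi resusceptibility rate, discouraged -> susceptible, >= 0.
#' @param K total population size, > 0.
#' @param p_tilde naive belief in (0, 1\]; the cooperation level that
#'   newcomers assume. Pass `"auto"` to use the high-cooperation fixed
#'   point of `reference` (see [naive_belief()]).
#' @param norms a [norm_sensitivity()] object: the threshold
#'   distribution of the population.
#' @param reference reference distribution used when `p_tilde = "auto"`;
#'   defaults to the coordination dilemma Normal(0.5, 0.04).
#' @return an object of class `community_params`.
#' @examples
#' ns <- norm_sensitivity(0.7, 0.04)
#' pars <- community_params(inflow = 1, learning = 1, outflow = 0.5,
#'                          phi = 1, K = 1, p_tilde = "auto", norms = ns)
#' @export
community_params <- function(inflow, learning, outflow, phi, K = 1,
                             p_tilde = "auto", norms,
                             reference = norm_sensitivity(0.5, 0.04)) {
  stopifnot(inherits(norms, "norm_sensitivity"))
  for (nm in c("inflow", "learning", "outflow", "phi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single non-negative number")
  }
  if (!is.numeric(K) || length(K) != 1L || K <= 0)
    stop("`K` must be a single positive number")
  if (identical(p_tilde, "auto")) {
    p_tilde <- naive_belief(reference)
  } else if (!is.numeric(p_tilde) || length(p_tilde) != 1L ||
             p_tilde <= 0 || p_tilde > 1) {
    stop("`p_tilde` must be in (0, 1] or \"auto\"")
  }
  structure(list(inflow = inflow, learning = learning, outflow = outflow,
                 phi = phi, K = K, p_tilde = p_tilde, norms = norms),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("Community model parameters:\n")
  cat(sprintf("  inflow = %g, learning = %g, outflow (omega) = %g, phi = %g\n",
              x$inflow, x$learning, x$outflow, x$phi))
  cat(sprintf("  K = %g, naive belief p_tilde = %.8g\n", x$K, x$p_tilde))
  cat(sprintf("  norms: Normal(mean = %g, variance = %g) -> %s dilemma\n",
              x$norms$mean, x$norms$variance, classify_dilemma(x$norms)))
  invisible(x)
}

#' State of the community-membership model
#'
#' The reduced coordinates: S susceptible outsiders, I insiders, y the
#' savvy fraction of insiders, p the cooperation frequency among savvy
#' insiders. Discouraged outsiders are the residual D = K - S - I.
#'
#' @param S susceptible count, >= 0.
#' @param I insider count, >= 0.
#' @param y fraction of insiders that are savvy, in \[0, 1\].
#' @param p cooperation frequency among savvy insiders, in \[0, 1\].
#' @param K total population (for validating S + I <= K); optional.
#' @return a named numeric vector of class `community_state`.
#' @export
community_state <- function(S, I, y, p, K = NULL) {
  x <- c(S = S, I = I, y = y, p = p)
  if (any(!is.finite(x))) stop("state components must be finite")
  if (S < 0 || I < 0) stop("S and I must be non-negative")
  check_prob(y, "y"); check_prob(p, "p")
  if (!is.null(K) && S + I > K * (1 + 1e-12))
    stop("S + I exceeds K: the discouraged compartment D = K - S - I ",
         "would be negative")
  structure(x, class = "community_state")
}

as_state <- function(x) {
  if (inherits(x, "community_state")) return(x)
  stopifnot(is.numeric(x), length(x) == 4L)
  community_state(x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Mean cooperation level among insiders
#'
#' Naive insiders cooperate at the fixed level F(p-tilde) implied by
#' their belief; savvy insiders cooperate at p. The community-wide mean
#' is the savvy-fraction-weighted average
#' p-bar = y p + (1 - y) F(p-tilde).
#'
#' @param state a [community_state()] (or numeric (S, I, y, p)).
#' @param params a [community_params()].
#' @return p-bar in \[0, 1\].
#' @export
mean_cooperation <- function(state, params) {
  st <- as_state(state)
  st[["y"]] * st[["p"]] +
    (1 - st[["y"]]) * ns_cdf(params$norms, params$p_tilde)
}

#' Belief gap between naive expectation and reality
#'
#' Delta = p-tilde - p-bar, the excess of the naive belief over the true
#' mean cooperation level. It drives both learning (naive -> savvy) and
#' disillusioned leaving (savvy -> discouraged). The model assumes rosy
#' beliefs, so Delta >= 0 is forward-invariant from admissible states;
#' a negative gap (possible only from inadmissible initial conditions)
#' is clamped to 0 with a warning.
#'
#' @inheritParams mean_cooperation
#' @return Delta >= 0.
#' @export
belief_gap <- function(state, params) {
  d <- params$p_tilde - mean_cooperation(state, params)
  if (d < 0) {
    warning("negative belief gap (p_bar > p_tilde) clamped to 0; the model ",
            "assumes naive beliefs at least as high as true cooperation")
    d <- 0
  }
  d
}

#' Time derivatives of the reduced community model
#'
#' The four-variable vector field. With D = K - S - I and
#' Delta = p_tilde - p_bar:
#' \deqn{dS/dt = \phi D - \iota S I / K}
#' \deqn{dI/dt = \iota S I / K - \omega \Delta y I}
#' \deqn{dy/dt = \lambda \Delta (1-y) - \omega \Delta y (1-y) - (\iota S/K) y}
#' \deqn{dp/dt = F(\bar p) - p}
#' Learning and leaving flows use max(Delta, 0): they are defined for
#' rosy beliefs only and switch off if the state strays into p_bar >
#' p_tilde (set `clamp = FALSE` for the smooth extension, used when
#' linearising at a Delta = 0 equilibrium from the admissible side).
#'
#' @inheritParams mean_cooperation
#' @param clamp clamp a negative belief gap to zero (default TRUE).
#' @return named numeric vector of derivatives (S, I, y, p).
#' @export
community_rhs <- function(params, state, clamp = TRUE) {
  rhs_reduced_eval(params, as.numeric(as_state(state)), clamp = clamp)
}

# unvalidated evaluation of the reduced vector field; used by the
# Jacobian finite differences, which may step just outside the state
# domain at boundary equilibria (I = 0, S = 0)
rhs_reduced_eval <- function(params, x, clamp = TRUE) {
  S <- x[[1]]; I <- x[[2]]; y <- x[[3]]; p <- x[[4]]
  K <- params$K
  D <- K - S - I
  Fq <- ns_cdf(params$norms, params$p_tilde)
  p_bar <- y * p + (1 - y) * Fq
  Delta <- params$p_tilde - p_bar
  if (clamp) Delta <- max(Delta, 0)
  join <- params$inflow * S * I / K
  c(S = params$phi * D - join,
    I = join - params$outflow * Delta * y * I,
    y = params$learning * Delta * (1 - y) -
        params$outflow * Delta * y * (1 - y) -
        (params$inflow * S / K) * y,
    p = ns_cdf(params$norms, min(max(p_bar, 0), 1)) - p)
}

#' Time derivatives of the raw five-compartment model
#'
#' The underlying head-count formulation from which the reduced model is
#' derived: S susceptibles, N naive insiders, V savvy insiders, D
#' discouraged, C savvy cooperators (C <= V). Newly savvy individuals
#' adopt the current savvy mean behaviour C/V, and leavers are an
#' unbiased sample of savvy cooperators; both choices are forced by the
#' reduced dp/dt = F(p_bar) - p. The reduction map is I = N + V,
#' y = V / I, p = C / V.
#'
#' @param params a [community_params()].
#' @param raw_state numeric (S, N, V, D, C).
#' @param p_limit cooperation frequency to use for the C/V ratio when
#'   V = 0 (the savvy-free limit); defaults to F(p_tilde).
#' @return named numeric vector of derivatives (S, N, V, D, C); the four
#'   population derivatives (S, N, V, D) always sum to zero
#'   (conservation of K; C is a sub-count of V, not a fifth
#'   compartment).
#' @export
raw_rhs <- function(params, raw_state, p_limit = NULL) {
  stopifnot(is.numeric(raw_state), length(raw_state) == 5L)
  S <- raw_state[[1]]; N <- raw_state[[2]]; V <- raw_state[[3]]
  D <- raw_state[[4]]; C <- raw_state[[5]]
  K <- params$K
  Fq <- ns_cdf(params$norms, params$p_tilde)
  p <- if (V > 0) C / V else if (is.null(p_limit)) Fq else p_limit
  I <- N + V
  p_bar <- if (I > 0) (N * Fq + V * p) / I else params$p_tilde
  Delta <- max(params$p_tilde - p_bar, 0)
  join <- params$inflow * S * I / K
  learn <- params$learning * Delta * N
  leave_rate <- params$outflow * Delta
  pb <- min(max(p_bar, 0), 1)
  c(S = params$phi * D - join,
    N = join - learn,
    V = learn - leave_rate * V,
    D = leave_rate * V - params$phi * D,
    C = learn * p + V * (ns_cdf(params$norms, pb) - p) - leave_rate * C)
}

#' Map a raw five-compartment state to reduced coordinates
#'
#' @inheritParams raw_rhs
#' @return a [community_state()] (S, I, y, p).
#' @export
reduce_state <- function(raw_state, params, p_limit = NULL) {
  S <- raw_state[[1]]; N <- raw_state[[2]]; V <- raw_state[[3]]
  C <- raw_state[[5]]
  I <- N + V
  Fq <- ns_cdf(params$norms, params$p_tilde)
  y <- if (I > 0) V / I else 0
  p <- if (V > 0) C / V else if (is.null(p_limit)) Fq else p_limit
  community_state(S = S, I = I, y = y, p = p)
}

#' Map a reduced state to raw five-compartment coordinates
#'
#' @inheritParams mean_cooperation
#' @return numeric (S, N, V, D, C).
#' @export
lift_state <- function(state, params) {
  st <- as_state(state)
  S <- st[["S"]]; I <- st[["I"]]; y <- st[["y"]]; p <- st[["p"]]
  V <- y * I
  c(S = S, N = (1 - y) * I, V = V, D = params$K - S - I, C = p * V)
}

#' Total cooperation mass in the community
#'
#' The total amount of cooperation across the population is the mean
#' insider cooperation level times the number of insiders, p_bar * I.
#' For fixed composition (y, p) it grows linearly with community size.
#'
#' @inheritParams mean_cooperation
#' @return p_bar * I >= 0.
#' @export
total_cooperation <- function(state, params) {
  st <- as_state(state)
  mean_cooperation(st, params) * st[["I"]]
}
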