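par_vec <- function(params) {
  c(params$inflow, params$learning, params$outflow, params$phi,
    params$K, params$p_tilde, params$norms$mean, params$norms$sd)
}

finalize_trajectory <- function(times, states, params) {
  S <- states[, 1]; I <- states[, 2]; y <- states[, 3]; p <- states[, 4]
  # numerical negativity below absolute tolerance is clipped; anything
  # larger is a genuine integration failure
  clip0 <- function(v, what, tol) {
    bad <- v < -tol
    if (any(bad))
      stop("integration produced ", what, " = ", min(v),
           " (beyond numerical noise); last valid time ",
           times[which(bad)[1]])
    pmax(v, 0)
  }
  tolK <- 1e-8 * params$K
  S <- clip0(S, "S", tolK); I <- clip0(I, "I", tolK)
  y <- pmin(clip0(y, "y", 1e-8), 1)
  p <- pmin(clip0(p, "p", 1e-8), 1)
  Fq <- ns_cdf(params$norms, params$p_tilde)
  p_bar <- y * p + (1 - y) * Fq
  traj <- data.frame(time = times, S = S, I = I, D = params$K - S - I,
                     y = y, p = p, p_bar = p_bar,
                     total_cooperation = p_bar * I)
  class(traj) <- c("community_trajectory", "data.frame")
  attr(traj, "params") <- params
  traj
}

#' Integrate the reduced community model
#'
#' Adaptive Dormand-Prince 5(4) integration of the four-variable
#' community model, sampled on a uniform (or user-supplied) time grid.
#' The discouraged compartment D is carried as the residual K - S - I,
#' so total population is conserved exactly.
#'
#' @param params a [community_params()].
#' @param state0 initial [community_state()] (or numeric (S, I, y, p)).
#' @param t_end final time (> 0); ignored if `times` is given.
#' @param n_samples number of output samples (including t = 0).
#' @param times optional explicit, strictly increasing sample times.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return a `community_trajectory` data.frame with columns `time, S, I,
#'   D, y, p, p_bar, total_cooperation`.
#' @examples
#' ns <- norm_sensitivity(0.5, 0.04)
#' pars <- community_params(1, 1, 0.1, 1, K = 1, p_tilde = "auto", norms = ns)
#' tr <- integrate_community(pars, community_state(0.9, 0.1, 0.5, 0.5), 50)
#' tail(tr, 1)
#' @export
integrate_community <- function(params, state0, t_end = NULL,
                                n_samples = 201L, times = NULL,
                                rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "community_params"))
  st <- as_state(state0)
  if (st[["S"]] + st[["I"]] > params$K * (1 + 1e-12))
    stop("initial S + I exceeds K")
  if (is.null(times)) {
    stopifnot(is.numeric(t_end), t_end > 0)
    times <- seq(0, t_end, length.out = n_samples)
  }
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  res <- .cpp_integrate(0L, par_vec(params), as.numeric(st), times,
                        rtol, atol)
  finalize_trajectory(times, res$states, params)
}

#' Integrate the raw five-compartment model
#'
#' Head-count formulation (S, N, V, D, C); see [raw_rhs()]. Used as an
#' independent route to the same dynamics as [integrate_community()]:
#' reducing its output must agree with the reduced integration.
#'
#' @inheritParams integrate_community
#' @param raw0 initial numeric (S, N, V, D, C) summing to K.
#' @return a data.frame with columns `time, S, N, V, D, C`.
#' @export
integrate_raw <- function(params, raw0, t_end = NULL, n_samples = 201L,
                          times = NULL, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "community_params"),
            is.numeric(raw0), length(raw0) == 5L)
  if (abs(sum(raw0[1:4]) - params$K) > 1e-9 * params$K)
    stop("raw initial state must have S + N + V + D = K")
  if (raw0[5] > raw0[3] * (1 + 1e-12))
    stop("savvy cooperators C cannot exceed the savvy count V")
  if (is.null(times)) {
    stopifnot(is.numeric(t_end), t_end > 0)
    times <- seq(0, t_end, length.out = n_samples)
  }
  res <- .cpp_integrate(1L, par_vec(params), as.numeric(raw0), times,
                        rtol, atol)
  out <- as.data.frame(res$states)
  names(out) <- c("S", "N", "V", "D", "C")
  cbind(time = times, out)
}

#' Write / read a trajectory as CSV
#'
#' Full float precision (17 significant digits) so that a written
#' trajectory re-reads losslessly and repeated runs are byte-identical.
#'
#' @param traj a `community_trajectory` (any data.frame of numerics).
#' @param path output file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns the data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(lapply(traj, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  }))
  names(df) <- names(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
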