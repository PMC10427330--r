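#' Classify the long-run attractor of a community trajectory
#'
#' Inspects the insider time series I(t) after discarding an initial
#' transient. If the post-transient amplitude is below `amp_tol * K`
#' the trajectory has settled on a fixed point. Otherwise oscillation
#' peaks are located from the excursions of I(t) above its mid-range
#' level; sustained, regular oscillations are a limit cycle, and cycles
#' whose troughs take the community nearly extinct (min I < 1e-4 K)
#' with long quiescent gaps between short excursions (gap > 5x
#' excursion width) are classified as bursting: episodes of rapid
#' community growth and crash separated by near-empty periods.
#'
#' @param traj a `community_trajectory` (or any data.frame with `time`
#'   and `I` columns).
#' @param transient_fraction fraction of the trajectory discarded as
#'   transient (default 0.5).
#' @param K total population size; taken from the trajectory's
#'   parameters when available.
#' @param amp_tol relative amplitude below which the attractor is a
#'   fixed point.
#' @param min_peaks minimum number of peaks required to call a cycle.
#' @return list of class `cycle_summary`: `classification` (one of
#'   "fixed_point", "limit_cycle", "bursting"), `period` (median
#'   inter-peak interval, NA for a fixed point), `n_peaks`,
#'   `amplitude_drift` (relative drift in peak height per period), and
#'   `ranges` (per-column min/max over the post-transient window).
#' @export
classify_attractor <- function(traj, transient_fraction = 0.5, K = NULL,
                               amp_tol = 1e-6, min_peaks = 5L) {
  stopifnot(is.data.frame(traj), all(c("time", "I") %in% names(traj)))
  if (is.null(K)) {
    pr <- attr(traj, "params")
    K <- if (!is.null(pr)) pr$K else max(traj$I)
  }
  stopifnot(transient_fraction >= 0, transient_fraction < 1)
  n <- nrow(traj)
  keep <- traj$time >= traj$time[1] +
    transient_fraction * (traj$time[n] - traj$time[1])
  post <- traj[keep, , drop = FALSE]
  if (nrow(post) < 20L)
    stop("trajectory too short after discarding the transient; ",
         "integrate longer or sample more densely")

  num_cols <- names(post)[vapply(post, is.numeric, logical(1))]
  ranges <- sapply(post[setdiff(num_cols, "time")], range)
  rownames(ranges) <- c("min", "max")

  I <- post$I; tt <- post$time
  amp <- max(I) - min(I)
  if (amp < amp_tol * K) {
    out <- list(classification = "fixed_point", period = NA_real_,
                n_peaks = 0L, amplitude_drift = NA_real_, ranges = ranges)
    class(out) <- "cycle_summary"
    return(out)
  }

  # segments of I above the mid-range level; one peak per excursion
  mid <- min(I) + amp / 2
  above <- I > mid
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- which(runs$values)
  # drop excursions clipped by the window edges
  seg <- seg[starts[seg] > 1L & ends[seg] < length(I)]
  if (length(seg) < min_peaks)
    stop("only ", length(seg), " oscillation peak(s) in the ",
         "post-transient window; integrate over a longer time span ",
         "to classify the attractor (need >= ", min_peaks, ")")
  peak_t <- peak_h <- widths <- numeric(length(seg))
  for (k in seq_along(seg)) {
    i0 <- starts[seg[k]]; i1 <- ends[seg[k]]
    j <- i0 - 1L + which.max(I[i0:i1])
    peak_t[k] <- tt[j]; peak_h[k] <- I[j]
    widths[k] <- tt[i1] - tt[i0]
  }
  gaps <- diff(peak_t) - (utils::head(widths, -1L) + widths[-1L]) / 2
  period <- stats::median(diff(peak_t))
  n_per <- length(seg) - 1L
  drift <- abs(peak_h[length(peak_h)] - peak_h[1]) / (amp * max(n_per, 1L))

  bursting <- min(I) < 1e-4 * K &&
    stats::median(gaps) > 5 * stats::median(widths)
  out <- list(classification = if (bursting) "bursting" else "limit_cycle",
              period = period, n_peaks = length(seg),
              amplitude_drift = drift, ranges = ranges)
  class(out) <- "cycle_summary"
  out
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat("Attractor classification:", x$classification, "\n")
  if (x$classification != "fixed_point")
    cat(sprintf("  period ~ %.6g, %d peaks, amplitude drift %.3g/period\n",
                x$period, x$n_peaks, x$amplitude_drift))
  cat("  post-transient ranges:\n")
  print(signif(x$ranges, 6))
  invisible(x)
}
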