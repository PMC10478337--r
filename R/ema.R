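#' Adaptive EMA schedule
#'
#' Holds the maximum iteration count and the two constants of the adaptive
#' smoothing-coefficient schedule `eps(i) = 1 - amplitude * exp(-rate * i /
#' iters)`. With the published constants (amplitude 0.2, rate 8) the
#' coefficient starts at 0.8, leaving room for the noisy branch to absorb the
#' clean branch's weights quickly, and approaches 1 so late-training
#' turbulence from noisy samples is suppressed.
#'
#' @param iters maximum number of training iterations (>= 1).
#' @param amplitude initial gap below 1.
#' @param rate exponential decay rate of the gap.
#' @return an object of class `ema_schedule`.
#' @export
ema_schedule <- function(iters, amplitude = 0.2, rate = 8) {
  iters <- as.integer(iters)
  if (iters < 1L) stop("iters must be >= 1")
  structure(list(iters = iters, amplitude = amplitude, rate = rate),
            class = "ema_schedule")
}

#' Adaptive EMA smoothing coefficient
#'
#' `eps(i) = 1 - amplitude * exp(-rate * i / iters)`; strictly increasing in
#' `i`, equal to `1 - amplitude` (0.8 by default) at `i = 0`.
#'
#' @param i iteration in `[0, iters]`.
#' @param sched an [ema_schedule()].
#' @return the smoothing coefficient, in `[1 - amplitude, 1)`.
#' @export
adaptive_coef <- function(i, sched) {
  stopifnot(inherits(sched, "ema_schedule"))
  if (any(i < 0) || any(i > sched$iters))
    stop("i must lie in [0, iters]")
  1 - sched$amplitude * exp(-sched$rate * i / sched$iters)
}

#' EMA weight update
#'
#' Blends the clean branch's weights into the noisy branch:
#' `theta_noisy <- eps * theta_noisy + (1 - eps) * theta_clean`, elementwise
#' over the flat parameter lists. A convex combination: every updated value
#' lies between the two inputs.
#'
#' @param theta_noisy,theta_clean `branch_weights` (or plain lists/vectors)
#'   of identical structure.
#' @param eps smoothing coefficient in [0, 1].
#' @return the updated noisy-branch weights, same structure as `theta_noisy`.
#' @export
ema_update <- function(theta_noisy, theta_clean, eps) {
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  if (is.numeric(theta_noisy) && is.numeric(theta_clean)) {
    if (length(theta_noisy) != length(theta_clean)) stop("length mismatch")
    return(eps * theta_noisy + (1 - eps) * theta_clean)
  }
  if (length(theta_noisy) != length(theta_clean)) stop("length mismatch")
  out <- theta_noisy
  for (k in seq_along(out)) {
    if (length(theta_noisy[[k]]) != length(theta_clean[[k]]))
      stop("parameter ", k, " length mismatch")
    out[[k]][] <- eps * theta_noisy[[k]] + (1 - eps) * theta_clean[[k]]
  }
  out
}
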