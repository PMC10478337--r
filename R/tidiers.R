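# broom-style accessors and plotting for fitted objects and reports

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training run
#'
#' Returns the per-iteration log as a plain data.frame (one row per
#' iteration with losses, Lovász score mean, tau, EMA coefficient, learning
#' rate and switch fraction).
#'
#' @param x an `atst_fit`.
#' @param ... unused.
#' @return a data.frame.
#' @exportS3Method generics::tidy
tidy.atst_fit <- function(x, ...) x$log

#' One-row summary of a training run
#'
#' @param x an `atst_fit`.
#' @param ... unused.
#' @return a one-row data.frame with the final losses, final tau, the
#'   fraction of late-training weak targets switched to clean predictions,
#'   and the run's configuration fingerprint.
#' @exportS3Method generics::glance
glance.atst_fit <- function(x, ...) {
  lg <- x$log
  n <- nrow(lg)
  late <- lg$switch_fraction[max(1, n - 49):n]
  data.frame(iters = n,
             final_l_mseg = lg$l_mseg[n],
             final_l_pseg_noisy = lg$l_pseg_noisy[n],
             final_tau = lg$tau[n],
             late_switch_fraction = mean(late, na.rm = TRUE),
             supervised_only = x$cfg$supervised_only,
             seed = x$cfg$seed)
}

#' Plot a training run
#'
#' Loss curves plus the Lovász score/tau trajectory and the switch fraction,
#' drawn with base graphics.
#'
#' @param x an `atst_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.atst_fit <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(lg$iteration,
                    cbind(lg$l_mseg, lg$l_pseg_clean, lg$l_pseg_noisy),
                    type = "l", lty = 1, xlab = "iteration", ylab = "loss",
                    main = "branch losses", ...)
  graphics::legend("topright", c("manual", "pseudo (clean)", "pseudo (noisy)"),
                   col = 1:3, lty = 1, bty = "n", cex = 0.8)
  graphics::matplot(lg$iteration, cbind(lg$s_mean, lg$tau, lg$switch_fraction),
                    type = "l", lty = 1, xlab = "iteration", ylab = "value",
                    main = "target switching")
  graphics::legend("topright", c("S_lovasz", "tau", "switch fraction"),
                   col = 1:3, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
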