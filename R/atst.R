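#' Lovász extension of the Jaccard loss
#'
#' Evaluates the Lovász extension of the Jaccard (IoU) set loss at the
#' per-pixel error vector `m` (`m_i = 1 - p_i` on foreground, `m_i = p_i` on
#' background): errors are sorted in decreasing order and accumulated against
#' the discrete gradient of the Jaccard loss along that order. On binary
#' predictions the extension coincides exactly with `1 - IoU`; on soft
#' predictions it is the tightest convex surrogate. Value in [0, 1].
#'
#' For an all-background target the Jaccard loss is degenerate; the mean
#' error is returned with attribute `degenerate = TRUE`.
#'
#' @param g binary target ([label_mask()] or 0/1 array/vector).
#' @param p probability map of the same shape, values in [0, 1].
#' @return scalar in [0, 1].
#' @export
lovasz_extension_value <- function(g, p) {
  gv <- as.numeric(if (inherits(g, "label_mask")) g$voxels else g)
  pv <- as.numeric(if (is.list(p) && !is.null(p$prob)) p$prob else p)
  if (length(gv) != length(pv)) stop("shapes differ")
  if (sum(gv) == 0) {
    m <- ifelse(gv == 1, 1 - pv, pv)
    return(structure(mean(m), degenerate = TRUE))
  }
  m <- ifelse(gv == 1, 1 - pv, pv)
  ord <- order(m, decreasing = TRUE)
  ms <- m[ord]
  gs <- gv[ord]
  # discrete Jaccard-loss gradient along the sorted order
  gts <- sum(gs)
  intersection <- gts - cumsum(gs)
  union <- gts + cumsum(1 - gs)
  jacc <- 1 - intersection / union
  grad <- c(jacc[1], diff(jacc))
  sum(ms * grad)
}

#' Symmetric Bernoulli divergence between probability maps
#'
#' Mean per-pixel symmetrized Kullback-Leibler divergence of the Bernoulli
#' distributions `(p, 1-p)` and `(q, 1-q)`:
#' `0.5 * KL(p || q) + 0.5 * KL(q || p)`, with both maps clamped to
#' `[eps, 1-eps]`. Non-negative, zero iff `p == q`, symmetric in its
#' arguments. A Jensen-Shannon variant is available via `method = "js"`.
#'
#' @param p,q probability maps of identical shape.
#' @param eps clamping constant.
#' @param method `"symkl"` (default) or `"js"`.
#' @return scalar divergence, >= 0.
#' @export
sym_divergence <- function(p, q, eps = 1e-6, method = c("symkl", "js")) {
  method <- match.arg(method)
  pv <- as.numeric(if (is.list(p) && !is.null(p$prob)) p$prob else p)
  qv <- as.numeric(if (is.list(q) && !is.null(q$prob)) q$prob else q)
  if (length(pv) != length(qv)) stop("shapes differ")
  pv <- pmin(pmax(pv, eps), 1 - eps)
  qv <- pmin(pmax(qv, eps), 1 - eps)
  klb <- function(a, b) a * log(a / b) + (1 - a) * log((1 - a) / (1 - b))
  if (method == "symkl") {
    mean(0.5 * klb(pv, qv) + 0.5 * klb(qv, pv))
  } else {
    m <- (pv + qv) / 2
    mean(0.5 * klb(pv, m) + 0.5 * klb(qv, m))
  }
}

#' Lovász score of a clean-branch prediction
#'
#' `S = LEV(gt_pseudo, p_clean) / exp(div(gt_pseudo, p_noisy))`: the Lovász
#' extension of the clean branch's error against the HU pseudo-label,
#' discounted by the divergence between the (probability-lifted) pseudo-label
#' and the noisy branch's prediction. A small score indicates the clean
#' branch agrees closely with the pseudo-label; the score is compared against
#' the sliding threshold tau to decide when the clean branch's own prediction
#' replaces the pseudo-label as the weak branch's supervision target.
#'
#' @param gt_pseudo binary pseudo-label.
#' @param p_clean,p_noisy probability maps of the same shape from the clean
#'   and noisy branches.
#' @param eps clamping constant used when lifting the hard label to a
#'   probability map for the divergence.
#' @param divergence `"symkl"` or `"js"`.
#' @return scalar score, finite and >= 0.
#' @export
s_lovasz <- function(gt_pseudo, p_clean, p_noisy, eps = 1e-6,
                     divergence = "symkl") {
  gv <- as.numeric(if (inherits(gt_pseudo, "label_mask")) gt_pseudo$voxels
                   else gt_pseudo)
  lev <- as.numeric(lovasz_extension_value(gv, p_clean))
  gprob <- pmin(pmax(gv, eps), 1 - eps)
  dv <- sym_divergence(gprob, p_noisy, eps = eps, method = divergence)
  lev / exp(dv)
}

#' Sliding-score state for automatic target switching
#'
#' Keeps the recent history of Lovász scores and the switching threshold tau,
#' defined as the `h_percentile`-th percentile of the last `window_len`
#' scores. Tau stays unset until the window has filled once, so early
#' training always supervises the weak branch with HU pseudo-labels.
#'
#' @param window_len history length in iterations (default 100).
#' @param h_percentile percentile in (0, 100) defining tau (default 50).
#' @return an object of class `atst_state`.
#' @export
atst_state <- function(window_len = 100L, h_percentile = 50) {
  window_len <- as.integer(window_len)
  if (window_len < 1L) stop("window_len must be >= 1")
  if (h_percentile <= 0 || h_percentile >= 100)
    stop("h_percentile must be in (0, 100)")
  structure(list(s_history = numeric(0), window_len = window_len,
                 h_percentile = h_percentile, tau = NA_real_),
            class = "atst_state")
}

#' Insert a score and refresh tau
#'
#' Appends `s` to the sliding history (evicting the oldest value at
#' capacity). Once the window has filled, tau is the `h_percentile`-th
#' percentile (linear interpolation) of the window; before that it remains
#' unset (`NA`).
#'
#' @param state an [atst_state()].
#' @param s finite non-negative score.
#' @return the updated state.
#' @export
update_tau <- function(state, s) {
  stopifnot(inherits(state, "atst_state"))
  if (!is.finite(s)) stop("score must be finite")
  h <- c(state$s_history, as.numeric(s))
  if (length(h) > state$window_len)
    h <- h[(length(h) - state$window_len + 1L):length(h)]
  state$s_history <- h
  if (length(h) >= state$window_len)
    state$tau <- unname(stats::quantile(h, state$h_percentile / 100, type = 7))
  state
}

#' Select the weak branch's supervision target
#'
#' Implements the switching rule: while tau is unset, or while
#' `s - tau < 0`, the target is the HU pseudo-label; once `s - tau >= 0`
#' (tie switches) the target becomes the clean branch's prediction binarized
#' at `binarize_thr`.
#'
#' @param s the current Lovász score for this image.
#' @param state an [atst_state()] carrying tau.
#' @param p_clean clean-branch probability map.
#' @param gt_pseudo the HU pseudo-label ([label_mask()] or 0/1 array).
#' @param binarize_thr binarization threshold for the switched target.
#' @return a list of class `atst_target` with fields `mask` (0/1 array),
#'   `source` (`"pseudo_label"` or `"clean_prediction"`) and `score`.
#' @export
select_target <- function(s, state, p_clean, gt_pseudo, binarize_thr = 0.5) {
  stopifnot(inherits(state, "atst_state"))
  gv <- if (inherits(gt_pseudo, "label_mask")) gt_pseudo$voxels else gt_pseudo
  pv <- if (is.list(p_clean) && !is.null(p_clean$prob)) p_clean$prob else p_clean
  if (!is.na(state$tau) && (s - state$tau) >= 0) {
    mask <- (pv >= binarize_thr) * 1L
    dim(mask) <- dim(pv)
    structure(list(mask = mask, source = "clean_prediction", score = s),
              class = "atst_target")
  } else {
    structure(list(mask = gv * 1L, source = "pseudo_label", score = s),
              class = "atst_target")
  }
}
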