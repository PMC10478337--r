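#' Generate the synthetic ablation benchmark data
#'
#' A fixed study layout on phantoms: a small expert-labelled training set, a
#' larger HU-pseudo-labelled set (1:2 ratio, mirroring the best-performing
#' labelled-to-pseudo ratio), and a held-out test set with true lesion
#' masks. Case seeds are derived deterministically from `seed`.
#'
#' @param seed root seed.
#' @param n_labeled,n_pseudo,n_test case counts.
#' @param spec a [phantom_spec()] template (its own seed is ignored).
#' @param side model input side length.
#' @return list with `labeled`, `pseudo` (slice datasets) and `test_cases`
#'   (list of `volume`/`lung`/`truth`).
#' @export
ablation_data <- function(seed = 1L, n_labeled = 20L, n_pseudo = 40L,
                          n_test = 10L, spec = phantom_spec(), side = 64L) {
  mk <- function(s, label) {
    sp <- spec; sp$seed <- s
    ph <- generate_phantom(sp)
    lab <- if (label == "gt") ph$lesion else generate_pseudolabel(ph$volume, ph$lung)
    list(volume = ph$volume, label = lab, lung = ph$lung, truth = ph$lesion)
  }
  base <- seed * 10000L
  labeled <- lapply(base + seq_len(n_labeled), mk, label = "gt")
  pseudo <- lapply(base + 1000L + seq_len(n_pseudo), mk, label = "pseudo")
  test <- lapply(base + 2000L + seq_len(n_test), mk, label = "gt")
  list(labeled = slice_dataset(labeled, side = side),
       pseudo = slice_dataset(pseudo, side = side),
       test_cases = test)
}

#' Train one ablation arm and score it
#'
#' Arms: `"unet"` (single supervised branch, labelled data only), `"ema"`
#' (dual branch, fixed EMA coefficient, no target switching), `"adaptive_ema"`
#' (dual branch, adaptive EMA, no switching), `"no_atst"` (synonym of
#' adaptive_ema, the "-ATST" arm) and `"atst"` (the full method). Scoring is
#' the median over test cases of the volume DSC of the clean branch's
#' binarized prediction against the true lesion mask.
#'
#' @param arm arm name.
#' @param data from [ablation_data()].
#' @param seed training seed.
#' @param iters SGD iterations.
#' @return list with `median_dsc`, `per_case` DSC vector and the `fit`.
#' @export
run_ablation_arm <- function(arm = c("unet", "ema", "adaptive_ema", "no_atst",
                                     "atst"),
                             data, seed = 1L, iters = 400L) {
  arm <- match.arg(arm)
  cfg <- switch(arm,
    unet = train_config(iters = iters, seed = seed, supervised_only = TRUE),
    ema = train_config(iters = iters, seed = seed,
                       ema = list(mode = "fixed"),
                       atst = list(enabled = FALSE)),
    adaptive_ema = ,
    no_atst = train_config(iters = iters, seed = seed,
                           atst = list(enabled = FALSE)),
    atst = train_config(iters = iters, seed = seed))
  fit <- train(cfg, data$labeled, if (arm == "unet") NULL else data$pseudo)
  per_case <- vapply(data$test_cases, function(tc) {
    pr <- predict_volume(fit, tc$volume, tc$lung)
    as.numeric(dsc(binarize(pr, 0.5), tc$truth))
  }, numeric(1))
  list(median_dsc = stats::median(per_case), per_case = per_case, fit = fit)
}

#' Run the scaled-down ablation benchmark
#'
#' Repeats [run_ablation_arm()] over several seeds (fresh phantom data per
#' seed) and tabulates median test DSC per arm and seed, the scaled-down
#' analogue of an ablation table. Expected direction: unet <= adaptive EMA
#' <= full method.
#'
#' @param seeds integer vector of run seeds.
#' @param arms arms to run.
#' @param iters SGD iterations per run.
#' @param keep_fits retain fitted models (memory-heavy).
#' @return data.frame with columns `seed`, `arm`, `median_dsc`,
#'   `late_switch_fraction`; fits attached as attribute when requested.
#' @export
ablation_benchmark <- function(seeds = 1:5,
                               arms = c("unet", "adaptive_ema", "atst"),
                               iters = 400L, keep_fits = FALSE) {
  rows <- list(); fits <- list()
  for (s in seeds) {
    data <- ablation_data(seed = s)
    for (a in arms) {
      res <- run_ablation_arm(a, data, seed = s, iters = iters)
      lsf <- mean(utils::tail(res$fit$log$switch_fraction, 50))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, arm = a, median_dsc = res$median_dsc,
        late_switch_fraction = if (is.finite(lsf)) lsf else NA_real_)
      if (keep_fits) fits[[paste(a, s, sep = "_")]] <- res$fit
    }
  }
  out <- do.call(rbind, rows)
  if (keep_fits) attr(out, "fits") <- fits
  out
}
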