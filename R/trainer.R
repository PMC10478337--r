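#' Training configuration
#'
#' All knobs of the dual-branch training loop. The `"desk"` profile (the
#' default) trains 64x64 slices with a compact backbone for a few hundred
#' iterations so the whole pipeline runs on a laptop CPU; the `"full"`
#' profile carries the published settings (256x256 inputs, batch 64 + 64,
#' 40000 SGD iterations, initial learning rate 0.01).
#'
#' @param profile `"desk"` or `"full"` (published full-scale settings).
#' @param iters total SGD iterations.
#' @param lr initial learning rate; decayed exponentially to `lr *
#'   lr_decay_factor` at the final iteration.
#' @param lr_decay_factor total exponential decay over the run.
#' @param momentum SGD momentum.
#' @param batch_labeled,batch_pseudo slices per batch from the manually
#'   labelled and pseudo-labelled pools.
#' @param backbone a [backbone_config()].
#' @param lambda_max,ramp_fraction pseudo-stream weight schedule, see
#'   [lambda_schedule()].
#' @param ema list: `mode` one of `"adaptive"`, `"fixed"`, `"off"`;
#'   `fixed_eps` used when fixed; `amplitude`, `rate` of the adaptive
#'   schedule.
#' @param atst list: `enabled`, `window_len`, `h_percentile`,
#'   `binarize_thr`, `divergence` (`"symkl"` or `"js"`).
#' @param consistency_weight weight of an optional mean-squared consistency
#'   term between the clean and noisy branches' predictions on pseudo
#'   images, added to the clean branch's objective (0 disables it, the
#'   default: the branch objectives then contain no path from the noisy
#'   branch back into the clean one).
#' @param noisy_grad whether the noisy branch receives its own gradient step
#'   in addition to the EMA blend.
#' @param augment apply random crop + horizontal flip augmentation.
#' @param supervised_only train a single supervised branch on labelled data
#'   only (the plain U-Net arm); ignores the pseudo stream entirely.
#' @param seed root seed for initialization, batch sampling and
#'   augmentation.
#' @param checkpoint_every write a checkpoint every this many iterations to
#'   `out_dir` (0 disables).
#' @return an object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "full"),
                         iters = NULL, lr = 0.01, lr_decay_factor = 0.1,
                         momentum = 0.9,
                         batch_labeled = NULL, batch_pseudo = NULL,
                         backbone = NULL,
                         lambda_max = 1.0, ramp_fraction = 0.1,
                         ema = list(), atst = list(),
                         consistency_weight = 0,
                         noisy_grad = TRUE, augment = TRUE,
                         supervised_only = FALSE,
                         seed = 1L, checkpoint_every = 0L) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    iters <- iters %||% 400L
    batch_labeled <- batch_labeled %||% 4L
    batch_pseudo <- batch_pseudo %||% 4L
    backbone <- backbone %||% backbone_config(side = 64L, width = 8L, depth = 3L)
  } else {
    iters <- iters %||% 40000L
    batch_labeled <- batch_labeled %||% 64L
    batch_pseudo <- batch_pseudo %||% 64L
    backbone <- backbone %||% backbone_config(side = 256L, width = 16L,
                                              depth = 4L, convs_per_block = 2L)
  }
  ema <- utils::modifyList(list(mode = "adaptive", fixed_eps = 0.99,
                                amplitude = 0.2, rate = 8), ema)
  atst <- utils::modifyList(list(enabled = TRUE, window_len = 100L,
                                 h_percentile = 50, binarize_thr = 0.5,
                                 divergence = "symkl"), atst)
  if (!ema$mode %in% c("adaptive", "fixed", "off"))
    stop("ema$mode must be adaptive, fixed or off")
  stopifnot(iters >= 1, batch_labeled >= 1, batch_pseudo >= 1)
  structure(list(profile = profile, iters = as.integer(iters), lr = lr,
                 lr_decay_factor = lr_decay_factor, momentum = momentum,
                 batch_labeled = as.integer(batch_labeled),
                 batch_pseudo = as.integer(batch_pseudo),
                 backbone = backbone, lambda_max = lambda_max,
                 ramp_fraction = ramp_fraction, ema = ema, atst = atst,
                 consistency_weight = consistency_weight,
                 noisy_grad = isTRUE(noisy_grad), augment = isTRUE(augment),
                 supervised_only = isTRUE(supervised_only),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

# ---- independent RNG streams --------------------------------------------
# Separate streams for labelled-batch sampling, pseudo-batch sampling and
# their augmentations, so the labelled path draws identical numbers whether
# or not a pseudo stream exists (exact reduction to supervised training).

rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  e
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

# ---- slice datasets ------------------------------------------------------

#' Build a slice dataset from volumes and masks
#'
#' Applies the HU window ([hu_clip_normalize()]) and resampling
#' ([to_model_input()]) per case and pairs every axial slice with its label
#' slice (resampled nearest-neighbour). Slices whose lung mask is empty are
#' excluded: they carry no trainable anatomy and destabilize the Dice term.
#'
#' @param cases list of cases; each case is a list with `volume`
#'   ([hu_volume()]), `label` ([label_mask()], the supervision target) and
#'   optionally `lung` ([label_mask()]).
#' @param side model input side length.
#' @return list of samples, each `list(image, mask)` of `side x side`
#'   matrices; attribute `case` records the source case index.
#' @export
slice_dataset <- function(cases, side = 64L) {
  out <- list()
  src <- integer(0)
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    img <- to_model_input(hu_clip_normalize(cs$volume), side = side)
    lab <- cs$label$voxels
    lung <- if (!is.null(cs$lung)) cs$lung$voxels else NULL
    for (s in seq_len(dim(img)[3])) {
      if (!is.null(lung) && sum(lung[, , s]) == 0L) next
      m <- lab[, , s]
      if (!all(dim(m) == c(side, side)))
        m <- (resize_slice(m, side, side, bilinear = FALSE) >= 0.5) * 1L
      out[[length(out) + 1L]] <- list(image = img[, , s], mask = m * 1)
      src <- c(src, ci)
    }
  }
  if (!length(out)) stop("dataset has no usable slices")
  attr(out, "case") <- src
  out
}

#' Random crop and left-right flip augmentation
#'
#' The same transform is applied to an image and its mask: with probability
#' 0.5 a horizontal flip, then a random crop of 70-100% of the side which is
#' resampled back to full size (bilinear for the image, nearest for the mask
#' so it stays binary). Deterministic under `seed`.
#'
#' @param images,masks arrays `side x side x n` (or single matrices).
#' @param seed optional seed; when `NULL`, the current RNG state is used.
#' @return list with transformed `images` and `masks` of unchanged shape.
#' @export
augment <- function(images, masks, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  side <- dim(images)[1]
  for (i in seq_len(dim(images)[3])) {
    im <- images[, , i]; mk <- masks[, , i]
    if (stats::runif(1) < 0.5) {
      im <- im[rev(seq_len(side)), ]   # left-right flip (x axis)
      mk <- mk[rev(seq_len(side)), ]
    }
    cs <- round(stats::runif(1, 0.7, 1.0) * side)
    if (cs < side) {
      ox <- sample.int(side - cs + 1L, 1L) - 1L
      oy <- sample.int(side - cs + 1L, 1L) - 1L
      im <- im[(ox + 1):(ox + cs), (oy + 1):(oy + cs)]
      mk <- mk[(ox + 1):(ox + cs), (oy + 1):(oy + cs)]
      im <- fast_resize(im, side, bilinear = TRUE)
      mk <- (fast_resize(mk, side, bilinear = FALSE) >= 0.5) * 1
    }
    images[, , i] <- im; masks[, , i] <- mk
  }
  list(images = images, masks = masks)
}

# vectorized square resize used inside the augmentation loop (hot path)
fast_resize <- function(m, side, bilinear = TRUE) {
  n <- nrow(m)
  if (n == side) return(m)
  if (!bilinear) {
    idx <- pmin(n, pmax(1, ceiling((seq_len(side) - 0.5) * n / side)))
    return(m[idx, idx])
  }
  p <- (seq_len(side) - 0.5) * n / side - 0.5
  i0 <- pmax(0, pmin(n - 1, floor(p)))
  i1 <- pmin(n - 1, i0 + 1)
  w <- pmin(pmax(p - i0, 0), 1)
  i0 <- i0 + 1; i1 <- i1 + 1
  wx <- matrix(w, side, side); wy <- t(wx)
  m[i0, i0] * (1 - wx) * (1 - wy) + m[i1, i0] * wx * (1 - wy) +
    m[i0, i1] * (1 - wx) * wy + m[i1, i1] * wx * wy
}

sample_batch <- function(dataset, n) {
  idx <- sample.int(length(dataset), n, replace = length(dataset) < n)
  side <- nrow(dataset[[1]]$image)
  imgs <- array(0, c(side, side, n)); msks <- array(0, c(side, side, n))
  for (j in seq_len(n)) {
    imgs[, , j] <- dataset[[idx[j]]]$image
    msks[, , j] <- dataset[[idx[j]]]$mask
  }
  list(images = imgs, masks = msks, idx = idx)
}

# ---- training loop -------------------------------------------------------

#' Train the dual-branch model
#'
#' Runs the full loop: every iteration samples a labelled and (unless
#' `supervised_only`) a pseudo-labelled batch, forwards the clean branch on
#' both and the noisy branch on the pseudo batch, scores each pseudo image
#' with the Lovász score and selects its weak supervision target, takes SGD
#' steps on the clean branch (manual + lambda-weighted pseudo loss) and on
#' the noisy branch (lambda-weighted loss against the selected targets), and
#' finally blends the clean weights into the noisy branch by the adaptive
#' EMA. Fully deterministic given `(cfg$seed, data)`.
#'
#' @param cfg a [train_config()].
#' @param labeled_set slice dataset ([slice_dataset()]) with expert masks.
#' @param pseudo_set slice dataset with HU pseudo-label masks; may be `NULL`
#'   when `cfg$supervised_only`.
#' @param out_dir optional directory for checkpoints.
#' @return an object of class `atst_fit`: list with `clean` and `noisy`
#'   branch weights, the per-iteration `log` data.frame (columns iteration,
#'   l_mseg, l_pseg_clean, l_pseg_noisy, s_mean, tau, eps, lr,
#'   switch_fraction), the final `atst` state and the `cfg`.
#' @export
train <- function(cfg, labeled_set, pseudo_set = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  if (!length(labeled_set)) stop("labeled dataset is empty")
  dual <- !cfg$supervised_only
  if (dual && !length(pseudo_set)) stop("pseudo dataset is empty")

  clean <- build_backbone(cfg$backbone, seed = cfg$seed)
  noisy <- clean  # branches start identical
  v_clean <- lapply(unclass(clean), function(w) { w[] <- 0; w })
  v_noisy <- v_clean
  ctx_clean <- net_context()
  ctx_noisy <- net_context()
  sched <- ema_schedule(cfg$iters, cfg$ema$amplitude, cfg$ema$rate)
  astate <- atst_state(cfg$atst$window_len, cfg$atst$h_percentile)

  st_lab <- rng_stream(cfg$seed + 101L)
  st_lab_aug <- rng_stream(cfg$seed + 303L)
  st_pse <- rng_stream(cfg$seed + 202L)
  st_pse_aug <- rng_stream(cfg$seed + 404L)

  nb_l <- cfg$batch_labeled; nb_p <- cfg$batch_pseudo
  log <- data.frame(iteration = seq_len(cfg$iters), l_mseg = NA_real_,
                    l_pseg_clean = NA_real_, l_pseg_noisy = NA_real_,
                    s_mean = NA_real_, tau = NA_real_, eps = NA_real_,
                    lr = NA_real_, switch_fraction = NA_real_)

  for (i in seq_len(cfg$iters)) {
    it0 <- i - 1L  # schedules are 0-based
    lr_i <- cfg$lr * cfg$lr_decay_factor^(it0 / cfg$iters)
    lam <- if (dual) lambda_schedule(it0, cfg$iters, cfg$lambda_max,
                                     cfg$ramp_fraction) else 0

    lb <- with_stream(st_lab, sample_batch(labeled_set, nb_l))
    if (cfg$augment) {
      ab <- with_stream(st_lab_aug, augment(lb$images, lb$masks))
      lb$images <- ab$images; lb$masks <- ab$masks
    }

    if (dual) {
      pb <- with_stream(st_pse, sample_batch(pseudo_set, nb_p))
      if (cfg$augment) {
        ab <- with_stream(st_pse_aug, augment(pb$images, pb$masks))
        pb$images <- ab$images; pb$masks <- ab$masks
      }
      x_clean <- array(c(lb$images, pb$images),
                       c(dim(lb$images)[1:2], nb_l + nb_p))
    } else {
      x_clean <- lb$images
    }

    fw_c <- net_forward(clean, x_clean, keep_cache = TRUE, ctx = ctx_clean)
    p_lab <- fw_c$prob[, , seq_len(nb_l), drop = FALSE]
    l_mseg <- seg_loss(p_lab, lb$masks)
    g_lab <- seg_loss_grad(p_lab, lb$masks)

    l_pseg_clean <- l_pseg_noisy <- NA_real_
    s_mean <- switch_frac <- NA_real_
    if (dual) {
      p_pse_c <- fw_c$prob[, , nb_l + seq_len(nb_p), drop = FALSE]
      l_pseg_clean <- seg_loss(p_pse_c, pb$masks)
      fw_n <- net_forward(noisy, pb$images, keep_cache = TRUE, ctx = ctx_noisy)
      p_pse_n <- fw_n$prob

      # per-image Lovász score and target selection against current tau
      targets <- array(0, dim(pb$masks))
      svals <- numeric(nb_p); sw <- logical(nb_p)
      for (j in seq_len(nb_p)) {
        svals[j] <- s_lovasz(pb$masks[, , j], p_pse_c[, , j], p_pse_n[, , j],
                             divergence = cfg$atst$divergence)
        if (cfg$atst$enabled) {
          tg <- select_target(svals[j], astate, p_pse_c[, , j], pb$masks[, , j],
                              cfg$atst$binarize_thr)
          targets[, , j] <- tg$mask
          sw[j] <- tg$source == "clean_prediction"
        } else {
          targets[, , j] <- pb$masks[, , j]
        }
      }
      s_mean <- mean(svals)
      switch_frac <- mean(sw)
      if (cfg$atst$enabled) astate <- update_tau(astate, s_mean)

      l_pseg_noisy <- seg_loss(p_pse_n, targets)

      # clean step: stacked gradient [manual | lambda * pseudo]
      g_pse <- lam * seg_loss_grad(p_pse_c, pb$masks)
      if (cfg$consistency_weight > 0) {
        # mean-squared consistency between branch predictions, at the logit
        np <- prod(dim(p_pse_c)[1:2])
        g_cons <- cfg$consistency_weight * 2 * (p_pse_c - p_pse_n) *
          p_pse_c * (1 - p_pse_c) / np / nb_p
        g_pse <- g_pse + g_cons
      }
      dLdp <- array(c(g_lab, g_pse), dim(fw_c$prob))
      grads_c <- net_backward(ctx_clean, dLdp)
      bad <- !is.finite(l_mseg + lam * l_pseg_clean)
      if (bad) stop("non-finite clean loss at iteration ", i)
      for (k in seq_along(clean)) {
        v_clean[[k]][] <- cfg$momentum * v_clean[[k]] - lr_i * grads_c[[k]]
        clean[[k]][] <- clean[[k]] + v_clean[[k]]
      }
      # noisy step (Eq. 6), optional
      if (cfg$noisy_grad && lam > 0) {
        g_n <- lam * seg_loss_grad(p_pse_n, targets)
        grads_n <- net_backward(ctx_noisy, array(g_n, dim(p_pse_n)))
        if (!is.finite(l_pseg_noisy)) stop("non-finite noisy loss at iteration ", i)
        for (k in seq_along(noisy)) {
          v_noisy[[k]][] <- cfg$momentum * v_noisy[[k]] - lr_i * grads_n[[k]]
          noisy[[k]][] <- noisy[[k]] + v_noisy[[k]]
        }
      }
      # EMA blend clean -> noisy
      eps_i <- switch(cfg$ema$mode,
                      adaptive = adaptive_coef(it0, sched),
                      fixed = cfg$ema$fixed_eps,
                      off = NA_real_)
      if (!is.na(eps_i))
        noisy <- ema_update(noisy, clean, eps_i)
    } else {
      grads_c <- net_backward(ctx_clean, g_lab)
      if (!is.finite(l_mseg)) stop("non-finite loss at iteration ", i)
      for (k in seq_along(clean)) {
        v_clean[[k]][] <- cfg$momentum * v_clean[[k]] - lr_i * grads_c[[k]]
        clean[[k]][] <- clean[[k]] + v_clean[[k]]
      }
      eps_i <- NA_real_
    }

    log$l_mseg[i] <- l_mseg
    log$l_pseg_clean[i] <- l_pseg_clean
    log$l_pseg_noisy[i] <- l_pseg_noisy
    log$s_mean[i] <- s_mean
    log$tau[i] <- astate$tau
    log$eps[i] <- if (dual) eps_i else NA_real_
    log$lr[i] <- lr_i
    log$switch_fraction[i] <- switch_frac

    if (!is.null(out_dir) && cfg$checkpoint_every > 0 &&
        (i %% cfg$checkpoint_every == 0 || i == cfg$iters)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(iteration = i, clean = clean, noisy = noisy, cfg = cfg,
                   seed = cfg$seed),
              file.path(out_dir, sprintf("checkpoint_%06d.rds", i)))
    }
  }

  structure(list(clean = clean, noisy = if (dual) noisy else NULL,
                 log = log, atst = astate, cfg = cfg),
            class = "atst_fit")
}

#' @export
print.atst_fit <- function(x, ...) {
  cat(sprintf("<atst_fit> %s profile, %d iterations%s\n", x$cfg$profile,
              x$cfg$iters,
              if (x$cfg$supervised_only) " (supervised only)" else ""))
  n <- nrow(x$log)
  tail_rows <- x$log[max(1, n - 4):n, c("iteration", "l_mseg", "l_pseg_noisy",
                                        "tau", "switch_fraction")]
  print(tail_rows, row.names = FALSE)
  invisible(x)
}

#' Slice-wise inference on a volume
#'
#' Runs the clean branch over every axial slice (after HU windowing and
#' resampling to the model side), reassembles the probabilities at the
#' volume's native in-plane resolution, and zeroes probabilities outside the
#' lung mask when one is given (lesions are only reported within the lungs).
#'
#' @param weights trained `branch_weights` (the clean branch of an
#'   [atst_fit], or the fit itself).
#' @param volume a [hu_volume()].
#' @param lung optional [label_mask()] gate of matching shape.
#' @return array of foreground probabilities with the volume's shape.
#' @export
predict_volume <- function(weights, volume, lung = NULL) {
  if (inherits(weights, "atst_fit")) weights <- weights$clean
  cfg <- attr(weights, "cfg")
  stopifnot(inherits(volume, "hu_volume"))
  if (!is.null(lung) && !identical(dim(lung$voxels), dim(volume$voxels)))
    stop("lung mask shape does not match volume")
  x <- to_model_input(hu_clip_normalize(volume), side = cfg$side)
  prob_small <- net_forward(weights, x)$prob
  dm <- dim(volume$voxels)
  out <- array(0, dm)
  for (s in seq_len(dm[3])) {
    sl <- prob_small[, , s]
    out[, , s] <- if (all(dm[1:2] == dim(sl))) sl
                  else resize_slice(sl, dm[1], dm[2], bilinear = TRUE)
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  if (!is.null(lung)) out <- out * (lung$voxels == 1L)
  out
}

#' Binarize a probability map
#'
#' `1[p >= thr]` (inclusive threshold); idempotent on already-binary input.
#'
#' @param p probability array in [0, 1].
#' @param thr threshold strictly inside (0, 1).
#' @param spacing voxel spacing for the returned mask.
#' @return a [label_mask()] with role `"lesion"`.
#' @export
binarize <- function(p, thr = 0.5, spacing = c(1, 1, 1)) {
  if (thr <= 0 || thr >= 1) stop("thr must be in (0, 1)")
  if (is.list(p) && !is.null(p$prob)) p <- p$prob
  label_mask(p >= thr, spacing = spacing, role = "lesion")
}
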